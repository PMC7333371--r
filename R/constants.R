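# Screen marker panel and the direction each marker moves under
# senescence induction: proliferation markers (cell number, Ki67) fall,
# morphology (cell/nuclear area) and senescence effectors/markers
# (p16, p21, IL-6, SA-beta-gal) rise.
SENESCENCE_DIRECTION <- c(
  cell_number = -1, ki67 = -1, cell_area = +1, nuclear_area = +1,
  p16 = +1, p21 = +1, il6 = +1, sabgal = +1
)

SCREEN_MARKERS <- names(SENESCENCE_DIRECTION)
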