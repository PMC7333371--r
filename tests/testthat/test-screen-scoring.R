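marker_cols <- c("cell_number", "ki67", "cell_area", "nuclear_area",
                 "p16", "p21", "il6", "sabgal")

# minimal screen table: one experiment block with given control wells and
# per-target well means
tiny_screen <- function(ctrl, targets, experiment = "exp1") {
  rows <- list()
  for (i in seq_len(nrow(ctrl))) {
    rows[[length(rows) + 1]] <- data.frame(
      experiment = experiment, well = paste0("c", i), sirna = "cyclophilinB",
      role = "neg_control", t(ctrl[i, ]), stringsAsFactors = FALSE)
  }
  for (s in names(targets)) {
    for (i in seq_len(nrow(targets[[s]]))) {
      rows[[length(rows) + 1]] <- data.frame(
        experiment = experiment, well = paste0(s, i), sirna = s,
        role = "target", t(targets[[s]][i, ]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[5:12] <- marker_cols
  out
}

ctrl_wells <- function() {
  # per-marker mean 100, sd 10 exactly (3 wells at 90/100/110)
  matrix(rep(c(90, 100, 110), each = 8), nrow = 3, byrow = TRUE)
}

test_that("Z-scores follow the control-referenced formula", {
  tgt <- matrix(100, 3, 8)
  tgt[, 2] <- 120  # ki67 two control SDs up
  scr <- tiny_screen(ctrl_wells(), list(sirnaA = tgt))
  scr2 <- tiny_screen(ctrl_wells(), list(sirnaA = tgt), experiment = "exp2")
  z <- suppressWarnings(zscores(rbind(scr, scr2)))
  zm <- zscore_matrix(z)
  expect_equal(unname(zm["sirnaA", "ki67"]), 2)
  expect_equal(unname(zm["sirnaA", "p21"]), 0)
})

test_that("per-experiment Z-scores are averaged unweighted", {
  up1 <- matrix(100, 3, 8); up1[, 2] <- 110   # z = 1 in exp1
  up3 <- matrix(100, 3, 8); up3[, 2] <- 130   # z = 3 in exp2
  scr <- rbind(tiny_screen(ctrl_wells(), list(sirnaA = up1), "exp1"),
               tiny_screen(ctrl_wells(), list(sirnaA = up3), "exp2"))
  z <- zscores(scr)
  expect_equal(unname(zscore_matrix(z)["sirnaA", "ki67"]), 2)
  expect_equal(unique(z$n_experiments), 2)
})

test_that("zero control SD and missing controls are reported with context", {
  flat <- matrix(100, 3, 8)
  scr <- tiny_screen(flat, list(sirnaA = matrix(100, 3, 8)))
  expect_error(zscores(scr), "zero control SD")
  expect_error(zscores(scr[scr$sirna != "cyclophilinB", ]), "negative control")
  two_ctrl <- tiny_screen(ctrl_wells()[1:2, , drop = FALSE],
                          list(sirnaA = matrix(100, 3, 8)))
  expect_error(suppressWarnings(zscores(two_ctrl)), "fewer than 3")
})

test_that("marker flags respect direction and boundary conventions", {
  m <- matrix(0, 3, 8, dimnames = list(c("s1", "s2", "s3"), marker_cols))
  m["s1", "ki67"] <- -1.5       # flagged (decrease)
  m["s2", "cell_area"] <- -2    # wrong direction, not flagged
  m["s3", "p21"] <- 1.0         # boundary: >= semantics for non-Ki67
  fl <- marker_flags(m)
  expect_true(fl["s1", "ki67"])
  expect_false(fl["s2", "cell_area"])
  expect_true(fl["s3", "p21"])
  # Ki67 boundary is strict
  m["s1", "ki67"] <- -1.0
  expect_false(marker_flags(m)["s1", "ki67"])
  bad <- m; colnames(bad)[1] <- "mystery"
  expect_error(marker_flags(bad), "unknown marker")
})

test_that("flags are invariant to affine rescaling of raw marker values", {
  truth <- screen_truth(designed_hit = list(sirna01 = c("ki67", "p16")))
  scr <- gen_screen(3, truth, n_experiments = 2, wells_per_condition = 4,
                    seed = 5)
  f1 <- marker_flags(zscores(scr))
  scr2 <- scr
  scr2$ki67 <- scr2$ki67 * 7 + 100
  scr2$p16 <- scr2$p16 * 0.01 - 3
  f2 <- marker_flags(zscores(scr2))
  expect_identical(f1, f2)
})

test_that("top-hit rule requires Ki67, cell number and a morphology change", {
  f <- matrix(FALSE, 3, 8, dimnames = list(c("a", "b", "c"), marker_cols))
  f["a", c("ki67", "cell_number", "cell_area")] <- TRUE
  f["b", c("ki67", "cell_area")] <- TRUE
  f["c", c("ki67", "cell_number", "p16")] <- TRUE  # no morphology change
  hits <- classify_top_hits(f)
  expect_equal(unname(hits$top_hit), c(TRUE, FALSE, FALSE))
})

test_that("summary percentages reproduce the screen report fractions", {
  # 26 candidates, 21 Ki67-flagged, 13 top hits, 12 with p16+p21,
  # 11 with IL-6, 8 with SA-beta-gal
  f <- matrix(FALSE, 26, 8,
              dimnames = list(sprintf("s%02d", 1:26), marker_cols))
  f[1:21, "ki67"] <- TRUE
  f[1:13, c("cell_number", "cell_area")] <- TRUE
  f[1:12, c("p16", "p21")] <- TRUE
  f[1:11, "il6"] <- TRUE
  f[1:8, "sabgal"] <- TRUE
  hits <- classify_top_hits(f)
  expect_equal(hits$counts$n_top_hits, 13)
  expect_equal(unname(hits$percentages["top_hits_of_ki67"]), 61.9)
  expect_equal(unname(hits$percentages["top_p16_p21"]), 92.3)
  expect_equal(unname(hits$percentages["top_il6"]), 84.6)
  expect_equal(unname(hits$percentages["top_sabgal"]), 61.5)
  expect_equal(unname(hits$percentages["ki67"]), 80.8)  # 21/26 half-up
})

test_that("designed 3-SD hits are recovered with high sensitivity and few false flags", {
  truth <- screen_truth(designed_hit = list(
    sirna01 = c("ki67", "cell_number", "cell_area", "p16", "p21")))
  sens <- logical(20)
  fpr <- numeric(20)
  for (s in 1:20) {
    scr <- gen_screen(5, truth, n_experiments = 3, wells_per_condition = 5,
                      seed = 100 + s)
    fl <- marker_flags(zscores(scr))
    hits <- classify_top_hits(fl)
    sens[s] <- hits$top_hit[["sirna01"]]
    fpr[s] <- mean(fl[paste0("sirna0", 2:5), ])
  }
  expect_gte(mean(sens), 0.95)
  expect_lte(mean(fpr), 0.10)
})
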