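test_that("d_ratio evaluates the amplitude ratio exactly", {
  expect_equal(d_ratio(c(0, 3), c(0, 3), c(0, 3)), 1)
  expect_equal(d_ratio(c(1, 2), c(0, 3), 0:3), 2 / 3)
  expect_error(d_ratio(1, 2, c(5, 5)), "degenerate amplitude")
  expect_error(d_ratio(numeric(0), 1, 0:3), "non-empty")

  # brute-force oracle on random 50-point vectors
  set.seed(21)
  for (i in 1:20) {
    all_z <- stats::rnorm(50)
    xi <- sample(50, 12); yi <- sample(50, 26)
    ref <- (max(all_z[xi]) - min(all_z[yi])) / (max(all_z) - min(all_z))
    expect_equal(d_ratio(all_z[xi], all_z[yi], all_z), ref)
  }
})

test_that("the quarter partition splits 50 points into 12/26/12", {
  p <- part_indices(50, pattern_criteria())
  expect_equal(p$L, 1:12)
  expect_equal(p$M, 13:38)
  expect_equal(p$H, 39:50)
  expect_error(part_indices(2, pattern_criteria()), "too few")
})

test_that("each omics pattern rule is applied verbatim", {
  t <- 50
  x <- seq(0, 1, length.out = t)
  # two-peak curve: peaks in L and H, trough in M, amplitude ratio ~0.6
  two_peak <- 6 * exp(-((x - 0.08) / 0.1)^2) + 6 * exp(-((x - 0.92) / 0.1)^2) + 2.4
  expect_true(classify_pattern(fake_cline(two_peak), "transcriptome")$passed)
  expect_true(classify_pattern(fake_cline(two_peak), "bimodal")$passed)

  # constant-ish below 1.64 passes fragment; the rule is absolute, not scale-free
  flat_low <- rep(-2, t) + stats::rnorm(t, sd = 0.01)
  expect_true(classify_pattern(fake_cline(flat_low), "methylation")$passed)
  expect_false(classify_pattern(fake_cline(flat_low + 4), "fragment")$passed)

  # single interior peak passes unimodal
  one_peak <- 8 * exp(-((x - 0.5) / 0.15)^2)
  expect_true(classify_pattern(fake_cline(one_peak), "somatic_mutation")$passed)

  # monotone increasing line fails steepest descent (d_ratio(L,H) <= 0)
  expect_false(classify_pattern(fake_cline(seq(0, 5, length.out = t)),
                                "steepest_descent")$passed)
  # monotone decreasing passes it
  expect_true(classify_pattern(fake_cline(seq(5, 0, length.out = t)), "cnv")$passed)

  expect_error(classify_pattern(fake_cline(two_peak), "unknown_omics"),
               "unknown")
})

test_that("classification is affine-invariant except for the absolute fragment bound", {
  t <- 50
  x <- seq(0, 1, length.out = t)
  two_peak <- 5 * exp(-((x - 0.06) / 0.12)^2) + 4 * exp(-((x - 0.9) / 0.12)^2)
  for (scale_by in c(0.1, 3)) {
    for (shift_by in c(-5, 2)) {
      v1 <- classify_pattern(fake_cline(two_peak), "bimodal")
      v2 <- classify_pattern(fake_cline(scale_by * two_peak + shift_by), "bimodal")
      expect_equal(v1$passed, v2$passed)
      expect_equal(v1$d_values, v2$d_values, tolerance = 1e-10)
    }
  }
  # fragment is not: shifting above 1.64 flips the verdict
  low <- rep(0, t) + stats::rnorm(t, sd = 0.05)
  expect_true(classify_pattern(fake_cline(low), "fragment")$passed)
  expect_false(classify_pattern(fake_cline(low + 10), "fragment")$passed)
})

test_that("raising alpha can only turn pass into fail", {
  set.seed(33)
  x <- seq(0, 1, length.out = 50)
  for (i in 1:10) {
    z <- stats::rnorm(50) + 3 * exp(-((x - 0.5) / 0.2)^2)
    cl <- fake_cline(z)
    for (omics in c("bimodal", "unimodal", "steepest_descent")) {
      passes <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(a)
        classify_pattern(cl, omics, pattern_criteria(alpha = a))$passed, TRUE)
      expect_true(all(diff(as.integer(passes)) <= 0))
    }
  }
})

test_that("degenerate points are excluded from z-score sets but keep their index", {
  z <- c(rep(10, 12), rep(0, 26), rep(10, 12))
  degen <- rep(FALSE, 50); degen[45:50] <- TRUE
  z[45:50] <- -99  # must be ignored, else amplitude explodes
  vd <- classify_pattern(fake_cline(z, degenerate = degen), "bimodal")
  expect_true(vd$passed)

  all_degen_H <- rep(FALSE, 50); all_degen_H[39:50] <- TRUE
  expect_error(classify_pattern(fake_cline(z, degenerate = all_degen_H), "bimodal"),
               "no non-degenerate point")
})

test_that("agreement rates are simple pass percentages", {
  expect_equal(agreement_rate(c(rep(TRUE, 10), rep(FALSE, 5))), 200 / 3)
  expect_equal(round(agreement_rate(c(rep(TRUE, 10), rep(FALSE, 5))), 1), 66.7)
  expect_equal(agreement_rate(rep(FALSE, 4)), 0)
  expect_equal(round(agreement_rate(c(rep(TRUE, 14), FALSE)), 1), 93.3)
  vds <- list(structure(list(passed = TRUE), class = "pattern_verdict"),
              structure(list(passed = FALSE), class = "pattern_verdict"))
  expect_equal(agreement_rate(vds), 50)
  expect_error(agreement_rate(list()), "no verdicts")
})
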