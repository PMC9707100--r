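test_that("the core is the LCC at the high-part local z maximum, ties to the highest cutoff", {
  g <- path_graph(letters[1:10])
  # scores put a,b,c,d above the top cutoffs; construct the cline by hand
  tab <- perturbation_table(stats::setNames(c(10, 9, 8, 7, 3, 3, 2, 2, 1, 1),
                                            letters[1:10]))
  t <- 12
  z <- c(1, 1, 1, 1, 1, 1, 1, 1, 2, 5, 3, 0)   # H = indices 10..12, peak at 10
  cuts <- seq(0.5, 6, length.out = t)
  cl <- fake_cline(z, cutoffs = cuts)
  crit <- pattern_criteria(quarter = 0.25)
  out <- extract_core(cl, g, tab, crit)
  expect_equal(out$cutoff, cuts[10])
  expect_equal(out$zscore, 5)
  # genes with score > cuts[10]=5: a(10) b(9) c(8) d(7) -> connected path a-b-c-d
  expect_setequal(out$core, c("a", "b", "c", "d"))

  # strictly decreasing H part: boundary local max at the first H point
  z2 <- seq(12, 1, length.out = t)
  out2 <- extract_core(fake_cline(z2, cutoffs = cuts), g, tab, crit)
  expect_equal(out2$cutoff, cuts[10])

  # tie across the H plateau resolves to the highest cutoff
  z3 <- c(rep(0, 9), 4, 4, 4)
  out3 <- extract_core(fake_cline(z3, cutoffs = cuts), g, tab, crit)
  expect_equal(out3$cutoff, cuts[12])

  degen <- rep(FALSE, t); degen[10:12] <- TRUE
  expect_error(extract_core(fake_cline(z, cutoffs = cuts, degenerate = degen),
                            g, tab, crit),
               "degenerate")
})

test_that("a warp map redirects core selection to the ucurve's high-part peak", {
  g <- path_graph(letters[1:10])
  tab <- perturbation_table(stats::setNames(c(10, 9, 8, 7, 3, 3, 2, 2, 1, 1),
                                            letters[1:10]))
  t <- 20
  u <- seq(0, 1, length.out = t)
  # ucurve with a clear high-part maximum near 0.9
  xx <- seq(0, 1, length.out = 200)
  uc <- fit_ucurve(fake_cline(5 * exp(-((xx - 0.9) / 0.1)^2), cutoffs = xx),
                   degree = 6)
  cuts <- seq(0.5, 6, length.out = t)
  cl <- fake_cline(predict(uc, u), cutoffs = cuts)
  wm <- cwdtw_map(cl, uc, scale = 2)
  out <- extract_core(cl, g, tab, pattern_criteria(), warp = wm, ucurve = uc)
  # the aligned selection point sits near the peak position 0.9 of [0,1]
  expect_gte(out$cutoff, cuts[16])
  expect_error(extract_core(cl, g, tab, pattern_criteria(), warp = wm),
               "ucurve")
})

test_that("neighbourhood extraction takes the top-k LCC and warns when undersized", {
  g <- path_graph(letters[1:10])
  tab <- perturbation_table(stats::setNames(10:1, letters[1:10]))
  expect_warning(nb <- extract_neighbourhood(g, tab, k = 1500),
                 "using all")
  expect_setequal(nb, letters[1:10])

  # top-k split into two components: the larger one wins
  edges <- rbind(cbind(sprintf("a%02d", 1:8), sprintf("a%02d", c(2:8, 1))),
                 cbind(sprintf("b%02d", 1:4), sprintf("b%02d", c(2:4, 1))))
  g2 <- suppressMessages(interactome(edges))
  sc <- stats::setNames(rep(5, 12), c(sprintf("a%02d", 1:8), sprintf("b%02d", 1:4)))
  tab2 <- perturbation_table(sc)
  nb2 <- extract_neighbourhood(g2, tab2, k = 12)
  expect_setequal(nb2, sprintf("a%02d", 1:8))
})

test_that("region assembly removes the core from the neighbourhood", {
  rs <- assemble_regions(c("a", "b"), letters[1:10], cancer = "X",
                         omics = "transcriptome", core_cutoff = 3)
  expect_length(rs$periphery, 8)
  expect_length(intersect(rs$core, rs$periphery), 0)
  expect_setequal(rs$neighbourhood, letters[1:10])

  expect_message(rs2 <- assemble_regions(c("x", "y"), letters[1:5]),
                 "disjoint")
  expect_setequal(rs2$periphery, letters[1:5])
  expect_setequal(rs2$neighbourhood, c(letters[1:5], "x", "y"))
})

test_that("the MOPC bundle counts per-gene omics membership", {
  mk <- function(om, core, peri) assemble_regions(core, union(core, peri),
                                                  cancer = "X", omics = om)
  regions <- list(mk("transcriptome", "c1", c("p1", "p2", "shared")),
                  mk("methylation", "c2", c("p3", "shared")),
                  mk("somatic_mutation", "c3", c("p4", "shared")),
                  mk("cnv", "c4", c("p5", "shared")))
  b <- assemble_mopc(regions)
  expect_equal(unname(b$membership[["shared"]]), 4L)
  expect_equal(unname(b$membership[["c1"]]), 1L)
  expect_setequal(b$union_core, c("c1", "c2", "c3", "c4"))
  # shared is 1 of 6 periphery genes in >= 2 omics
  expect_equal(b$multi_omics_share[["periphery"]], 100 / 6)
  expect_equal(b$multi_omics_share[["core"]], 0)

  # four disjoint single-omics regions: everything membership 1, shares 0
  regions0 <- list(mk("transcriptome", "c1", "p1"), mk("methylation", "c2", "p2"),
                   mk("somatic_mutation", "c3", "p3"), mk("cnv", "c4", "p4"))
  b0 <- assemble_mopc(regions0)
  expect_true(all(b0$membership == 1L))
  expect_equal(unname(b0$multi_omics_share), c(0, 0))

  expect_error(assemble_mopc(list(mk("cnv", "c1", "p1"), mk("cnv", "c2", "p2"))),
               "duplicate omics")
})

test_that("extracted cores are always connected in the interactome", {
  fx <- archetype_fixture("bimodal", seed = 101)
  out <- extract_core(fx$cline, fx$g, fx$table)
  expect_gt(length(out$core), 1)
  expect_equal(lcc_size(fx$g, out$core), length(out$core))
})

test_that("gene sets round-trip through GMT", {
  sets <- list(core = c("a", "b"), periphery = c("c", "d", "e"))
  tmp <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, tmp)
  back <- read_gmt(tmp)
  expect_equal(back$core, sets$core)
  expect_equal(back$periphery, sets$periphery)
})
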