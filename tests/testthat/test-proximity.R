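test_that("jaccard handles identity, overlap and empty sets", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(character(0), character(0)), 0)
  expect_equal(jaccard(c("a"), c("b")), 0)
  set.seed(4)
  for (i in 1:10) {
    A <- sample(letters, 8); B <- sample(letters, 12)
    expect_equal(jaccard(A, B), jaccard(B, A))
    expect_gte(jaccard(A, B), 0); expect_lte(jaccard(A, B), 1)
  }
})

test_that("hypergeometric overlap p-values match closed forms and pmf summation", {
  expect_equal(overlap_pvalue(0, 3, 5, 10), 1)
  expect_equal(overlap_pvalue(3, 3, 5, 10), choose(5, 3) / choose(10, 3))
  expect_error(overlap_pvalue(4, 3, 5, 10), "inconsistent")

  # enumeration oracle: direct summation of the pmf over i >= k
  set.seed(12)
  for (i in 1:30) {
    N <- sample(20:60, 1)
    n <- sample(3:15, 1); M <- sample(3:15, 1)
    k <- sample(0:min(n, M), 1)
    direct <- sum(vapply(k:min(n, M), function(j)
      exp(lchoose(M, j) + lchoose(N - M, n - j) - lchoose(N, n)), 0))
    expect_equal(overlap_pvalue(k, n, M, N), direct, tolerance = 1e-12)
  }
})

test_that("overlap p-value is non-increasing in the observed overlap", {
  ps <- vapply(0:8, function(k) overlap_pvalue(k, 8, 10, 40), 0)
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("set distances follow the nearest-member definition", {
  g <- path_graph(letters[1:4])
  d <- set_distance(g, "a", "d")
  expect_equal(d$d_AB, 3)

  # A == B: d_AB = 0 and s_AA = -d_AA < 0 on a connected graph
  d2 <- set_distance(g, c("a", "c"), c("a", "c"))
  expect_equal(d2$d_AB, 0)
  expect_equal(d2$d_AA, 2)
  expect_equal(d2$s_AB, -2)
  expect_lt(d2$s_AB, 0)

  # literal include-self convention collapses within-set terms to zero
  d3 <- set_distance(g, c("a", "c"), c("b", "d"), within = "include_self")
  expect_equal(d3$d_AA, 0)
  expect_equal(d3$s_AB, d3$d_AB)

  # symmetry of d_AB and s_AB
  tg <- toy_graph()
  set.seed(6)
  A <- sample(interactome_genes(tg), 5); B <- sample(interactome_genes(tg), 7)
  expect_equal(set_distance(tg, A, B)$d_AB, set_distance(tg, B, A)$d_AB)
  expect_equal(set_distance(tg, A, B)$s_AB, set_distance(tg, B, A)$s_AB)
})

test_that("genes outside the largest component are dropped with coverage reported", {
  edges <- rbind(cbind(letters[1:5], letters[2:6]), c("x", "y"))
  g <- suppressMessages(interactome(edges))
  d <- set_distance(g, c("a", "x"), c("c"))
  expect_equal(d$coverage, 2 / 3)
  expect_equal(d$d_AB, (2 + 2) / 2)
  expect_error(set_distance(g, c("x"), c("a")), "coverage")
})

test_that("adding a gene of A to B cannot increase the average distance", {
  tg <- toy_graph()
  set.seed(9)
  for (i in 1:10) {
    A <- sample(interactome_genes(tg), 6)
    B <- sample(setdiff(interactome_genes(tg), A), 6)
    before <- set_distance(tg, A, B)$d_AB
    after <- set_distance(tg, A, union(B, A[1]))$d_AB
    expect_lte(after, before + 1e-12)
  }
})

test_that("Mann-Whitney p-values: exact enumeration, approximation, and edge cases", {
  # extreme ranking closed form: 2 / C(6,3)
  expect_equal(mannwhitney_u(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(mannwhitney_u(c(1, 2, 3), c(10, 11, 12), "less"), 0.05)
  expect_gte(mannwhitney_u(c(5, 6, 7), c(5, 6, 7)), 0.9)
  expect_warning(p <- mannwhitney_u(rep(2, 4), rep(2, 3)), "tied")
  expect_equal(p, 1)

  # approximation within 0.02 of exact at small combined sizes (the bound
  # holds for every possible U once both groups have at least 5 members)
  set.seed(10)
  for (i in 1:40) {
    nx <- sample(5:6, 1); ny <- sample(5:6, 1)
    x <- stats::rnorm(nx); y <- stats::rnorm(ny, mean = sample(c(0, 1), 1))
    exact <- mannwhitney_u(x, y)
    approx <- mannwhitney_u(x, y, exact_limit = 0L)
    expect_lt(abs(exact - approx), 0.02)
  }

  # agreement with the standard implementation as an independent check
  set.seed(11)
  x <- stats::rnorm(6); y <- stats::rnorm(6, 0.5)
  expect_equal(mannwhitney_u(x, y),
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("proximity matrices are symmetric with consistent entries", {
  tg <- toy_graph()
  set.seed(13)
  sets <- list(s1 = sample(interactome_genes(tg), 5),
               s2 = sample(interactome_genes(tg), 6),
               s3 = sample(interactome_genes(tg), 4))
  m <- proximity_matrices(tg, sets)
  for (stat in names(m)) expect_true(isSymmetric(m[[stat]]))
  expect_equal(m$jaccard["s1", "s2"], jaccard(sets$s1, sets$s2))
  expect_equal(m$d_AB["s1", "s3"], set_distance(tg, sets$s1, sets$s3)$d_AB)
  expect_equal(m$d_AB["s2", "s2"], 0)
})
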