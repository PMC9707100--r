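test_that("excess overlap follows its defining ratio", {
  uni <- sprintf("u%03d", 1:100)
  expect_equal(excess_overlap(uni[1:10], uni, uni), 1)  # B = universe
  A <- uni[1:10]; B <- uni[c(1, 2, 30, 40, 50)]
  expect_equal(excess_overlap(A, B, uni), (2 / 5) / (10 / 100))
  expect_error(excess_overlap(c("zz"), B, uni), "disjoint")
  expect_error(excess_overlap(A, character(0), uni), "non-empty")

  # oracle identity on random draws
  set.seed(3)
  for (i in 1:20) {
    A <- sample(uni, 25); B <- sample(uni, 15)
    ref <- (length(intersect(A, B)) / length(B)) /
      (length(intersect(A, uni)) / length(uni))
    expect_equal(excess_overlap(A, B, uni), ref)
  }
})

test_that("ORA ranks a fully covering set first with a tiny p-value", {
  uni <- sprintf("u%04d", 1:1000)
  coll <- geneset_collection(list(hit = uni[1:5], miss = uni[500:549]), uni)
  res <- ora(uni[1:5], coll)
  expect_equal(res$set[1], "hit")
  expect_lt(res$p_value[1], 1e-12)
  expect_equal(res$p_value[1], 1 / choose(1000, 5), tolerance = 1e-12)
  expect_equal(res$p_value[res$set == "miss"], 1)  # k = 0
  expect_true(all(res$p_adjust >= res$p_value))
  expect_error(ora(c("not_there"), coll), "empty")
})

test_that("a planted enriched set outranks random sets", {
  cfg <- synth_config(seed = 7)
  uni <- sprintf("g%04d", 1:600)
  set.seed(7)
  query <- sample(uni, 40)
  coll <- make_geneset_collection(cfg, uni, query)
  res <- ora(query, coll)
  expect_equal(res$set[1], "planted")
  expect_lt(res$p_value[1], 0.001)
})

test_that("SNPs map to host genes with BED half-open intervals and multi-hosting", {
  gi <- data.frame(chrom = "chr1",
                   start = c(100, 150, 400),
                   end = c(200, 250, 500),
                   gene = c("g1", "g2", "g3"))
  pairs <- data.frame(snp_id = c("s1", "s2", "s3", "s4"),
                      chrom = "chr1",
                      pos = c(150, 300, 180, 100),
                      gene = "g3")
  eq <- eqtl_data(pairs, gi)
  hosts <- map_snps_to_genes(eq)
  expect_equal(hosts$s1, "g1")             # inside [100,200) only
  expect_length(hosts$s2, 0)               # intergenic
  expect_setequal(hosts$s3, c("g1", "g2")) # overlapping genes, both returned
  expect_length(hosts$s4, 0)               # 1-based 100 = 0-based 99 < start

  bad <- data.frame(snp_id = "s1", chrom = "chr9", pos = 1, gene = "g1")
  expect_error(eqtl_data(bad, gi), "chr9")
  expect_error(eqtl_data(pairs, transform(gi, end = start)), "start < end")
})

test_that("regulated amounts count distinct genes per direction", {
  gi <- data.frame(chrom = "chr1",
                   start = c(0, 1000, 2000, 3000),
                   end = c(1000, 2000, 3000, 4000),
                   gene = c("q1", "q2", "y1", "y2"))
  # three SNPs hosted in X = {q1, q2} regulating two distinct Y genes
  pairs <- data.frame(snp_id = c("s1", "s2", "s3"),
                      chrom = "chr1",
                      pos = c(500, 600, 1500),
                      gene = c("y1", "y2", "y1"))
  eq <- eqtl_data(pairs, gi)
  X <- c("q1", "q2"); Y <- c("y1", "y2")
  expect_equal(regulated_amount(X, Y, eq, "of_Y_by_X"), 2L)
  expect_equal(regulated_amount(X, Y, eq, "of_X_over_Y"), 2L)
  expect_equal(regulated_amount("q1", Y, eq, "of_Y_by_X"), 2L)
  expect_equal(regulated_amount("q1", Y, eq, "of_X_over_Y"), 1L)
  expect_equal(regulated_amount(X, "y2", eq, "of_Y_by_X"), 1L)
  expect_equal(regulated_amount(character(0), Y, eq), 0L)
  # single-pair case: 1 in both directions
  eq1 <- eqtl_data(pairs[1, ], gi)
  expect_equal(regulated_amount("q1", "y1", eq1, "of_Y_by_X"), 1L)
  expect_equal(regulated_amount("q1", "y1", eq1, "of_X_over_Y"), 1L)
})

test_that("regulated amount grows monotonically under superset growth", {
  cfg <- synth_config(seed = 5)
  nodes <- sprintf("g%04d", 1:600)
  set.seed(5)
  X <- sample(nodes, 40); Y <- sample(setdiff(nodes, X), 30)
  eq <- make_eqtl(cfg, X, Y, enrichment = 2)
  hosts <- map_snps_to_genes(eq)
  a1 <- regulated_amount(X[1:10], Y, eq, hosts = hosts)
  a2 <- regulated_amount(X, Y, eq, hosts = hosts)
  a3 <- regulated_amount(X, Y[1:10], eq, hosts = hosts)
  expect_lte(a1, a2)
  expect_lte(a3, a2)
})

test_that("eQTL tables round-trip through TSV + BED", {
  gi <- data.frame(chrom = "chr1", start = c(0, 1000), end = c(1000, 2000),
                   gene = c("q1", "y1"))
  pairs <- data.frame(snp_id = "s1", chrom = "chr1", pos = 500, gene = "y1")
  ptsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  utils::write.table(pairs, ptsv, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gi[, c("chrom", "start", "end", "gene")], bed,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  eq <- read_eqtl(ptsv, bed)
  expect_equal(eq$esite, "s1")
  expect_equal(eq$egene, "y1")
  expect_equal(regulated_amount("q1", "y1", eq), 1L)
})
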