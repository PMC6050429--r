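test_that("Phred quality converts error rates in either log base", {
  expect_equal(phred_q(1), 0)
  expect_equal(phred_q(1, base = 2), 0)
  expect_equal(phred_q(0.01, base = 10), 20)
  expect_equal(phred_q(0.25, base = 2), 20)
  expect_equal(phred_q(0.001), 30)
  expect_error(phred_q(0), "error_rate")
  expect_error(phred_q(1.2), "error_rate")
})

test_that("read filtering applies the three discard rules", {
  # a read with 25% N bases is discarded by the N rule
  r_n <- read_record("n", qualities = rep(40, 100), fraction_N = 0.25)
  res <- filter_reads(list(r_n))
  expect_length(res$kept, 0)
  expect_equal(unname(res$discarded["n_bases"]), 1L)

  # a pristine read is kept
  r_ok <- read_record("ok", qualities = rep(40, 100))
  res <- filter_reads(list(r_ok))
  expect_length(res$kept, 1)
  expect_equal(sum(res$discarded), 0L)

  # hand-enumerated batch of 10 constructed reads:
  # 2 adapters, 2 with >20% N, 3 with >50% of bases below Q20, 3 clean
  reads <- c(
    lapply(1:2, function(i) read_record(paste0("a", i), rep(40, 10),
                                        has_adapter = TRUE)),
    lapply(1:2, function(i) read_record(paste0("n", i), rep(40, 10),
                                        fraction_N = 0.21)),
    lapply(1:3, function(i) read_record(paste0("q", i),
                                        c(rep(10, 6), rep(40, 4)))),
    lapply(1:3, function(i) read_record(paste0("c", i), rep(30, 10)))
  )
  res <- filter_reads(reads)
  expect_length(res$kept, 3)
  expect_equal(unname(res$discarded), c(2L, 2L, 3L))

  # boundary: exactly 50% low-quality bases is tolerated
  r_edge <- read_record("edge", c(rep(19, 5), rep(40, 5)))
  expect_length(filter_reads(list(r_edge))$kept, 1)
})

test_that("RPKM follows counts / (mapped millions x length kb)", {
  tab <- count_table(matrix(c(100, 0), 2, 1,
                            dimnames = list(c("g1", "g2"), "s1")),
                     length_kb = c(2, 1), mapped_millions = 10)
  r <- rpkm(tab)
  expect_equal(unname(r["g1", 1]), 5.0)
  expect_equal(unname(r["g2", 1]), 0)

  # doubling the mapped total halves every RPKM in that sample;
  # doubling a count doubles its RPKM
  set.seed(3)
  counts <- matrix(rpois(20, 50), 5, 4,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  lk <- runif(5, 0.5, 5)
  mm <- runif(4, 5, 50)
  r1 <- rpkm(count_table(counts, lk, mm))
  r2 <- rpkm(count_table(counts, lk, mm * 2))
  expect_equal(r2, r1 / 2)
  r3 <- rpkm(count_table(counts * 2, lk, mm))
  expect_equal(r3, r1 * 2)

  expect_error(count_table(counts, rep(0, 5), mm), "positive")
  expect_error(count_table(counts, lk, rep(0, 4)), "positive")
})

test_that("BH adjustment matches the naive double-loop oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  for (i in 1:100) {
    n <- sample(1:40, 1)
    p <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    expect_equal(bh_adjust(p), bh_naive(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("DEG calling thresholds the BH-adjusted q-values", {
  df <- data.frame(gene_id = paste0("g", 1:4), log2fc = c(2, -2, 1, 0),
                   pvalue = rep(1, 4))
  out <- call_degs(df)
  expect_true(all(out$direction == "none"))

  out <- call_degs(data.frame(gene_id = "g1", log2fc = 3, pvalue = 0.5),
                   q_threshold = 0)
  expect_identical(out$direction, "none")

  expect_error(call_degs(data.frame(gene_id = c("a", "a"), log2fc = 0,
                                    pvalue = 0.5)), "duplicate")

  # planted effect at large sample size: >= 90% of planted genes called up
  syn <- synthetic_counts(n_genes = 400, n_samples_per_group = 10,
                          n_up = 50, n_down = 0, effect_log2fc = 3,
                          dispersion = 0.05, seed = 7)
  calls <- call_degs(syn$stats, q_threshold = 0.01)
  planted <- calls[calls$gene_id %in% syn$truth$payload$up, ]
  expect_gte(mean(planted$direction == "up"), 0.9)
  # and directionality is honest: no planted-up gene called down
  expect_false(any(planted$direction == "down"))
})

test_that("hypergeometric enrichment matches exhaustive enumeration for N <= 20", {
  # spot value: N=20, K=5, n=8, k=4
  bg <- paste0("g", 1:20)
  sets <- list(T1 = bg[1:5])
  lst <- c(bg[1:4], bg[6:9])
  res <- hypergeom_enrichment(lst, sets, bg)
  expect_equal(res$pvalue, hyper_enum(4, 5, 8, 20))

  # random small instances
  set.seed(9)
  for (i in 1:12) {
    N <- sample(8:20, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    bg <- paste0("g", seq_len(N))
    sets <- list(T1 = bg[seq_len(K)])
    lst <- sample(bg, n)
    k <- sum(lst %in% sets$T1)
    res <- hypergeom_enrichment(lst, sets, bg)
    expect_equal(res$pvalue, hyper_enum(k, K, n, N), tolerance = 1e-12)
  }

  # degenerate: term == list == background gives p = 1
  bg <- paste0("g", 1:6)
  res <- hypergeom_enrichment(bg, list(ALL = bg), bg)
  expect_equal(res$pvalue, 1)
  expect_equal(res$k, res$K)

  expect_error(hypergeom_enrichment(c("zz"), list(T1 = bg[1:2]), bg),
               "absent from the background")
})

test_that("GMT files round-trip gene sets", {
  sets <- list(TERM1 = c("a", "b", "c"), TERM2 = c("d", "e"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path, descriptions = c(TERM1 = "first"))
  expect_identical(read_gmt(path), sets)
  writeLines("broken_line_without_tabs", path)
  expect_error(read_gmt(path), "malformed")
})
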