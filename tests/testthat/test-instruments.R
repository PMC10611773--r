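test_that("select_instruments falls back to the relaxed threshold when sparse", {
  set.seed(11)
  # 12 genome-wide hits, more at the relaxed threshold
  p <- c(runif(12, 1e-12, 4e-8), runif(30, 1e-7, 4e-5), runif(58, 0.01, 1))
  rows <- make_sumstats(sprintf("rs%03d", 1:100), "A", "G", 0.05, 0.01,
                        pval = p)
  sel <- select_instruments(rows, 5e-8, 5e-5, min_count = 13)
  expect_equal(attr(sel, "threshold_used"), 5e-5)
  expect_true(attr(sel, "relaxed"))
  expect_equal(nrow(sel), 42)

  # enough hits: primary threshold, no relaxation
  sel2 <- select_instruments(rows, 5e-8, 5e-5, min_count = 5)
  expect_false(attr(sel2, "relaxed"))
  expect_equal(nrow(sel2), 12)
})

test_that("selection matches a direct count oracle and nests across thresholds", {
  set.seed(12)
  p <- runif(100, 1e-10, 1e-3)
  rows <- make_sumstats(sprintf("rs%03d", 1:100), "A", "G", 0.05, 0.01,
                        pval = p)
  sel <- select_instruments(rows, 5e-8, 5e-5, min_count = 5)
  if (sum(p <= 5e-8) >= 5) {
    expect_setequal(sel$variant_id, rows$variant_id[p <= 5e-8])
  }
  loose <- select_instruments(rows, 5e-4, 5e-4, min_count = 1)
  tight <- select_instruments(rows, 1e-4, 1e-4, min_count = 1)
  expect_true(all(tight$variant_id %in% loose$variant_id))

  flat <- make_sumstats(c("rs1", "rs2"), "A", "G", 0.05, 0.01, pval = 0.5)
  expect_error(select_instruments(flat, 5e-8, 5e-5, 1),
               class = "mr_no_instruments")
})

test_that("clumping keeps the lower-p variant of a correlated nearby pair", {
  rows <- make_sumstats(c("rs_a", "rs_b"), "A", "G", 0.05, 0.01,
                        pval = c(1e-10, 1e-9), pos = c(1e6, 1.005e6))
  ld <- ld_matrix(matrix(c(1, 0.5, 0.5, 1), 2), ids = c("rs_a", "rs_b"))
  cl <- clump(rows, ld, r2_max = 0.001, window_kb = 10000)
  expect_equal(cl$data$variant_id, "rs_a")
  expect_equal(cl$excluded$reason, "ld_with_kept")

  # mutually uncorrelated candidates are all kept
  ld0 <- ld_matrix(diag(2), ids = c("rs_a", "rs_b"))
  expect_equal(nrow(clump(rows, ld0)$data), 2)

  # outside the window the LD constraint does not apply
  rows_far <- rows; rows_far$pos <- c(1e6, 2e10)
  expect_equal(nrow(clump(rows_far, ld, window_kb = 10000)$data), 2)
})

test_that("clump output matches a brute-force greedy oracle on random instances", {
  for (seed in 1:20) {
    set.seed(seed)
    ids <- sprintf("rs%02d", 1:10)
    rows <- make_sumstats(ids, "A", "G", 0.05, 0.01,
                          pval = runif(10, 1e-12, 1e-6),
                          pos = sort(sample(1e6:5e7, 10)))
    ld <- random_ld(ids, seed + 100)
    cl <- clump(rows, ld, r2_max = 0.1, window_kb = 1e5)
    kept <- cl$data$variant_id
    # oracle: greedy by ascending p over the same instance
    ord <- order(rows$pval, rows$variant_id)
    expect_kept <- character(0)
    for (i in ord) {
      ok <- all(vapply(expect_kept, function(v)
        unclass(ld)[rows$variant_id[i], v] <= 0.1, logical(1)))
      if (ok) expect_kept <- c(expect_kept, rows$variant_id[i])
    }
    expect_equal(kept, expect_kept)
    # pairwise constraint holds among kept
    if (length(kept) > 1) {
      pairs <- combn(kept, 2)
      expect_true(all(apply(pairs, 2, function(p)
        unclass(ld)[p[1], p[2]] <= 0.1)))
    }
    # maximality: every rejected variant conflicts with some kept one
    rejected <- setdiff(ids, kept)
    for (v in rejected) {
      expect_true(any(vapply(kept, function(k)
        unclass(ld)[v, k] > 0.1, logical(1))))
    }
  }
})

test_that("candidates absent from the LD matrix are excluded, never kept", {
  rows <- make_sumstats(c("rs_a", "rs_b"), "A", "G", 0.05, 0.01,
                        pval = c(1e-10, 1e-9))
  ld <- ld_matrix(matrix(1), ids = "rs_a")
  cl <- clump(rows, ld)
  expect_equal(cl$data$variant_id, "rs_a")
  expect_equal(cl$excluded$variant_id, "rs_b")
  expect_equal(cl$excluded$reason, "no_ld_info")
})

test_that("find_proxy returns the best qualifying proxy or nothing", {
  out_rows <- make_sumstats(c("p1", "p2", "p3"), "A", "G", 0.05, 0.01)
  ids <- c("target", "p1", "p2", "p3")
  m <- diag(4)
  m[1, 2:4] <- m[2:4, 1] <- c(0.91, 0.99, 0.93)
  ld <- ld_matrix(m, ids = ids)
  pr <- find_proxy("target", out_rows, ld, r2_min = 0.9)
  expect_equal(pr$variant_id, "p2")
  expect_equal(pr$r2, 0.99)

  m2 <- diag(4); m2[1, 2:4] <- m2[2:4, 1] <- 0.5
  expect_null(find_proxy("target", out_rows, ld_matrix(m2, ids = ids)))
  expect_error(find_proxy("p1", out_rows, ld), class = "mr_misuse")
})

test_that("instrument strength follows the closed form and its monotonicities", {
  s0 <- instrument_strength(0, 0.01, 0.3, 1e5)
  expect_equal(s0$r2, 0)
  expect_equal(s0$F, 0)

  # r2 = 0.001 at n = 360,000: F = r2 (n-2) / (1 - r2)
  beta <- sqrt(0.001 / (2 * 0.25 * 0.75))
  s <- instrument_strength(beta, 0.01, 0.25, 360000)
  expect_equal(s$r2, 0.001)
  expect_equal(s$F, 0.001 * 359998 / 0.999, tolerance = 1e-12)
  expect_equal(round(s$F, 2), 360.36)

  # allele-flip invariance and monotonicity in n
  s_flip <- instrument_strength(-beta, 0.01, 0.75, 360000)
  expect_equal(s_flip$r2, s$r2)
  expect_gt(instrument_strength(beta, 0.01, 0.25, 500000)$F, s$F)
  expect_error(instrument_strength(0.1, 0.01, 1.2, 1e5),
               class = "mr_domain_error")
})

test_that("simulated default instrument sets pass the weak-instrument gate", {
  sim <- simulate_mr_dataset(mr_truth(theta = 0, J = 60, seed = 99))
  st <- instrument_strength(sim$exposure$beta, sim$exposure$se,
                            sim$exposure$eaf, sim$exposure$n)
  expect_gt(mean(st$F), 10)
})

test_that("LD matrix I/O accepts square and long formats", {
  ids <- c("rs1", "rs2", "rs3")
  m <- diag(3); m[1, 2] <- m[2, 1] <- 0.4
  f1 <- tempfile(fileext = ".tsv")
  write.table(cbind(id = ids, as.data.frame(m, col.names = ids)), f1,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("id", ids))
  got1 <- read_ld_matrix(f1)
  expect_equal(unclass(got1)[1, 2], 0.4)

  f2 <- tempfile(fileext = ".tsv")
  write.table(data.frame(id1 = "rs1", id2 = "rs2", r2 = 0.4), f2,
              sep = "\t", quote = FALSE, row.names = FALSE)
  got2 <- read_ld_matrix(f2)
  expect_equal(unclass(got2)["rs1", "rs2"], 0.4)
  expect_equal(diag(unclass(got2)), c(rs1 = 1, rs2 = 1))

  expect_error(ld_matrix(matrix(c(1, 0.3, 0.2, 1), 2), ids = c("a", "b")),
               class = "mr_config_error")
})
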