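test_that("wald ratio follows the delta-method arithmetic", {
  w <- wald_ratio(bx = 0.1, by = 0.02, sex = 0.01, sey = 0.005)
  expect_equal(w$estimate, 0.2)
  expect_equal(w$se, 0.05)
  expect_equal(wald_ratio(0.1, 0, 0.01, 0.005)$estimate, 0)
  # negative outcome effect with positive exposure effect: protective OR
  expect_lt(exp(wald_ratio(0.08, -0.03, 0.01, 0.005)$estimate), 1)
  expect_error(wald_ratio(0, 0.02, 0.01, 0.005), class = "mr_degenerate")
})

test_that("IVW degenerates to the Wald ratio at k = 1 and pools exactly", {
  d1 <- make_hdata(0.1, 0.02, 0.01, 0.005)
  ivw1 <- mr_ivw(d1)
  w <- wald_ratio(0.1, 0.02, 0.01, 0.005)
  expect_identical(ivw1$estimate, w$estimate)
  expect_identical(ivw1$se, w$se)

  # three variants with identical ratio 0.5: estimate 0.5, Q = 0, no inflation
  d3 <- make_hdata(c(0.1, 0.2, 0.05), c(0.05, 0.1, 0.025),
                   0.01, c(0.004, 0.008, 0.002))
  ivw3 <- mr_ivw(d3)
  expect_equal(ivw3$estimate, 0.5)
  expect_equal(ivw3$extra$Q, 0, tolerance = 1e-24)
  expect_equal(ivw3$extra$overdispersion, 1)
})

test_that("multiplicative random-effects se never undercuts the fixed-effect se", {
  for (seed in 1:25) {
    set.seed(seed)
    k <- sample(3:20, 1)
    d <- make_hdata(runif(k, 0.02, 0.1), rnorm(k, 0, 0.05),
                    0.01, runif(k, 0.005, 0.02))
    fit <- mr_ivw(d)
    se_fixed <- sqrt(1 / sum(d$beta_exposure^2 / d$se_outcome^2))
    expect_gte(fit$se, se_fixed - 1e-14)
    q <- fit$extra$Q
    if (q <= k - 1) expect_equal(fit$se, se_fixed)
  }
})

test_that("Egger recovers an exact linear relation and enforces k >= 3", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  intercept <- 0.01; slope <- 0.3
  d <- make_hdata(bx, intercept + slope * bx, 0.01, 0.005)
  e <- mr_egger(d)
  expect_equal(e$estimate, slope, tolerance = 1e-10)
  expect_equal(e$extra$intercept, intercept, tolerance = 1e-10)
  expect_equal(e$extra$overdispersion, 1)

  expect_error(mr_egger(make_hdata(c(0.1, 0.2), c(0.02, 0.04), 0.01, 0.005)),
               class = "mr_insufficient_instruments")
})

test_that("weighted median interpolates the 50th weighted percentile", {
  d <- make_hdata(c(1, 1, 1), c(0.1, 0.2, 0.9), 0.01, c(0.02, 0.02, 0.02))
  m <- mr_weighted_median(d, n_boot = 50, seed = 1)
  expect_equal(m$estimate, 0.2)

  # identical ratios collapse to that ratio with vanishing bootstrap se
  dc <- make_hdata(c(0.1, 0.2, 0.3), c(0.05, 0.1, 0.15), 1e-6, 1e-7)
  mc <- mr_weighted_median(dc, n_boot = 100, seed = 1)
  expect_equal(mc$estimate, 0.5)
  expect_lt(mc$se, 1e-4)
})

test_that("weighted mode finds the majority cluster", {
  d <- make_hdata(rep(1, 4), c(0.5, 0.5, 0.5, 5), 0.01, rep(0.02, 4))
  m <- mr_weighted_mode(d, n_boot = 50, seed = 1)
  expect_equal(m$estimate, 0.5, tolerance = 0.1)
  expect_error(mr_weighted_mode(make_hdata(1, 0.5, 0.01, 0.02)),
               class = "mr_insufficient_instruments")
})

test_that("estimators are invariant to variant order and joint sign flips", {
  set.seed(5)
  k <- 15
  d <- make_hdata(runif(k, 0.02, 0.1), rnorm(k, 0.02, 0.03),
                  runif(k, 0.002, 0.01), runif(k, 0.005, 0.02))
  perm <- sample(k)
  dp <- d[perm, ]
  expect_equal(mr_ivw(dp)$estimate, mr_ivw(d)$estimate)
  expect_equal(mr_egger(dp)$estimate, mr_egger(d)$estimate)
  expect_equal(mr_weighted_median(dp, 10, 1)$estimate,
               mr_weighted_median(d, 10, 1)$estimate)
  expect_equal(mr_weighted_mode(dp, 1, 10, 1)$estimate,
               mr_weighted_mode(d, 1, 10, 1)$estimate)

  # joint (bx, by) sign flip per variant: Egger orientation handles it
  flip <- rep(c(1, -1), length.out = k)
  df <- d
  df$beta_exposure <- d$beta_exposure * flip
  df$beta_outcome <- d$beta_outcome * flip
  expect_equal(mr_ivw(df)$estimate, mr_ivw(d)$estimate)
  expect_equal(mr_egger(df)$estimate, mr_egger(d)$estimate)
  expect_equal(mr_egger(df)$extra$intercept, mr_egger(d)$extra$intercept)
  expect_equal(mr_weighted_median(df, 10, 1)$estimate,
               mr_weighted_median(d, 10, 1)$estimate)
  expect_equal(mr_weighted_mode(df, 1, 10, 1)$estimate,
               mr_weighted_mode(d, 1, 10, 1)$estimate)
})

test_that("weighted median resists 40% pleiotropic instruments where IVW drifts", {
  # valid instruments carry ratio 0.3; 40% carry a large directional offset
  set.seed(21)
  reps <- 30
  med_err <- ivw_err <- numeric(reps)
  for (r in seq_len(reps)) {
    k <- 30
    bx <- runif(k, 0.05, 0.15)
    alpha <- c(rep(0, 18), rep(0.04, 12))
    sey <- rep(0.004, k)
    by <- 0.3 * bx + alpha + rnorm(k, 0, sey)
    d <- make_hdata(bx, by, 0.001, sey)
    med_err[r] <- mr_weighted_median(d, n_boot = 20, seed = r)$estimate - 0.3
    ivw_err[r] <- mr_ivw(d)$estimate - 0.3
  }
  expect_lt(abs(mean(med_err)), 0.05)
  expect_gt(mean(ivw_err), 0.1)
})

test_that("single-SNP and leave-one-out decompositions are consistent", {
  d <- make_hdata(c(0.1, 0.2), c(0.03, 0.05), 0.01, c(0.004, 0.006))
  loo <- mr_leave_one_out(d)
  # with k = 2, each LOO row is exactly the other variant's Wald ratio
  expect_equal(loo$estimate[1], 0.05 / 0.2)
  expect_equal(loo$estimate[2], 0.03 / 0.1)

  ss <- mr_single_snp(d)
  expect_equal(ss$ratio, c(0.3, 0.25))
  expect_equal(ss$se, c(0.04, 0.03))

  expect_warning(loo1 <- mr_leave_one_out(make_hdata(0.1, 0.03, 0.01, 0.004)))
  expect_equal(nrow(loo1), 0)
})

test_that("a dominant outlier moves its leave-one-out row the most", {
  set.seed(9)
  k <- 12
  bx <- runif(k, 0.05, 0.15)
  by <- 0.2 * bx + rnorm(k, 0, 0.002)
  by[4] <- by[4] + 0.1  # injected pleiotropic outlier
  d <- make_hdata(bx, by, 0.005, 0.002)
  full <- mr_ivw(d)$estimate
  loo <- mr_leave_one_out(d)
  shifts <- abs(loo$estimate - full)
  expect_equal(which.max(shifts), 4)
})
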