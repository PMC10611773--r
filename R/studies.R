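#' Estimator parameter-recovery study
#'
#' Repeatedly simulates paired summary statistics with a known causal
#' effect, harmonises them, fits the Wald ratio (strongest instrument),
#' IVW, MR-Egger, weighted median and weighted mode, and tallies 95% CI
#' coverage of the truth, mean estimate and Monte Carlo error. This is the
#' package's main calibration surface: with no pleiotropy every estimator
#' should cover the truth at close to nominal rate and IVW should be
#' unbiased within Monte Carlo error.
#'
#' @param theta true causal effect.
#' @param J instruments per replicate.
#' @param reps number of replicates.
#' @param n_boot bootstrap draws for median/mode standard errors.
#' @param seed base seed; replicate r uses seed + r.
#' @param ... further arguments to \code{\link{mr_truth}}.
#' @return list: \code{coverage} (named fraction per method),
#'   \code{mean_estimate}, \code{sd_estimate}, \code{mc_se} (of the IVW
#'   mean), \code{reps}, \code{theta}.
#' @export
recovery_study <- function(theta, J = 50, reps = 200, n_boot = 200,
                           seed = 1, ...) {
  methods <- c("wald", "ivw_mre", "egger", "weighted_median",
               "weighted_mode")
  est <- matrix(NA_real_, reps, length(methods),
                dimnames = list(NULL, methods))
  cover <- matrix(NA, reps, length(methods),
                  dimnames = list(NULL, methods))
  for (r in seq_len(reps)) {
    sim <- simulate_mr_dataset(mr_truth(theta = theta, J = J,
                                        seed = seed + r, ...))
    h <- harmonise(sim$exposure, sim$outcome)
    fit <- mr_fit(h, n_boot = n_boot, seed = seed + r)
    tab <- fit$estimates
    strongest <- which.min(h$data$pval_exposure)
    w <- wald_ratio(h$data$beta_exposure[strongest],
                    h$data$beta_outcome[strongest],
                    h$data$se_exposure[strongest],
                    h$data$se_outcome[strongest])
    tab <- rbind(tab, data.frame(method = "wald", estimate = w$estimate,
                                 se = w$se, ci_low = w$ci_low,
                                 ci_high = w$ci_high, pval = w$pval,
                                 k = 1L))
    for (m in methods) {
      row <- tab[tab$method == m, ]
      if (nrow(row) == 1) {
        est[r, m] <- row$estimate
        cover[r, m] <- row$ci_low <= theta && theta <= row$ci_high
      }
    }
  }
  list(coverage = colMeans(cover, na.rm = TRUE),
       mean_estimate = colMeans(est, na.rm = TRUE),
       sd_estimate = apply(est, 2, stats::sd, na.rm = TRUE),
       mc_se = stats::sd(est[, "ivw_mre"], na.rm = TRUE) / sqrt(reps),
       reps = reps, theta = theta)
}

#' Egger-intercept calibration under pleiotropy scenarios
#'
#' Simulates replicates with balanced (mean-zero) or directional
#' (mean-shifted) per-variant direct effects and records how often the
#' MR-Egger intercept test rejects at \code{alpha}. Under balanced
#' pleiotropy the rejection rate should sit near \code{alpha}; under
#' directional pleiotropy it should rise well above it.
#'
#' @param pleiotropy \code{"balanced"} or \code{"directional"}.
#' @param theta true causal effect.
#' @param pleio_sd direct-effect SD (outcome scale).
#' @param pleio_mean direct-effect mean under "directional".
#' @param J,reps,seed study dimensions.
#' @param alpha test level.
#' @return list: \code{rejection_rate}, \code{mean_intercept},
#'   \code{reps}.
#' @export
egger_calibration_study <- function(pleiotropy = c("balanced",
                                                   "directional"),
                                    theta = 0.2, pleio_sd = 0.02,
                                    pleio_mean = 0.02, J = 50, reps = 200,
                                    seed = 1, alpha = 0.05) {
  pleiotropy <- match.arg(pleiotropy)
  if (pleiotropy == "balanced") pleio_mean <- 0
  rej <- logical(reps); ints <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_mr_dataset(mr_truth(
      theta = theta, J = J, pleiotropy = pleiotropy, pleio_sd = pleio_sd,
      pleio_mean = pleio_mean, seed = seed + r))
    h <- harmonise(sim$exposure, sim$outcome)
    e <- mr_egger(h)
    rej[r] <- e$extra$intercept_pval < alpha
    ints[r] <- e$extra$intercept
  }
  list(rejection_rate = mean(rej), mean_intercept = mean(ints),
       reps = reps)
}

#' MR-PRESSO outlier-detection operating characteristics
#'
#' Clean replicates measure the false-outlier rate; contaminated
#' replicates add a direct effect of \code{outlier_size} residual
#' standard deviations to one variant's outcome association and measure
#' how often exactly that variant is flagged.
#'
#' @param inject add the single outlier? (FALSE measures the clean rate).
#' @param outlier_size direct effect in units of the variant's outcome se.
#' @param J,reps,seed,n_sim study dimensions.
#' @param theta true causal effect.
#' @return list: \code{detection_rate} (injected variant flagged),
#'   \code{any_outlier_rate}, \code{reps}.
#' @export
presso_study <- function(inject = TRUE, outlier_size = 10, J = 50,
                         reps = 100, n_sim = 1000, theta = 0.2, seed = 1) {
  detected <- any_out <- logical(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_mr_dataset(mr_truth(theta = theta, J = J,
                                        seed = seed + r))
    out <- sim$outcome
    target <- NA_character_
    if (inject) {
      i <- 1 + (r %% J)
      out$beta[i] <- out$beta[i] + outlier_size * out$se[i]
      target <- out$variant_id[i]
    }
    h <- harmonise(sim$exposure, out)
    pr <- mr_presso(h, n_sim = n_sim, seed = seed + 10000 + r)
    detected[r] <- !is.na(target) && target %in% pr$outliers
    any_out[r] <- length(pr$outliers) > 0
  }
  list(detection_rate = if (inject) mean(detected) else NA_real_,
       any_outlier_rate = mean(any_out), reps = reps)
}

#' Colocalisation scenario-identification study
#'
#' Generates regional datasets under each causal configuration (H0-H4)
#' and checks that the maximum-posterior hypothesis matches the
#' generator's label; for the shared-causal scenario it also records how
#' often PP_H4 clears the 0.8 evidence bound.
#'
#' @param scenarios generator scenarios to cover.
#' @param J regional variants.
#' @param reps replicates per scenario.
#' @param seed base seed.
#' @param ... further arguments to \code{\link{region_truth}}.
#' @return list per scenario: \code{accuracy} (max-posterior matches),
#'   \code{mean_pp} (5-vector), \code{pp_h4_gt_0.8} (shared only).
#' @export
coloc_scenario_study <- function(scenarios = c("none", "exposure",
                                               "outcome", "distinct",
                                               "shared"),
                                 J = 200, reps = 50, seed = 1, ...) {
  target <- c(none = "H0", exposure = "H1", outcome = "H2",
              distinct = "H3", shared = "H4")
  out <- list()
  for (sc in scenarios) {
    hit <- logical(reps)
    pp4 <- numeric(reps)
    ppm <- matrix(0, reps, 5)
    for (r in seq_len(reps)) {
      reg <- simulate_region(region_truth(J = J, scenario = sc,
                                          seed = seed + 100 * r, ...))
      res <- coloc_pp(reg$exposure, reg$outcome)
      hit[r] <- names(which.max(res$pp)) == target[[sc]]
      pp4[r] <- res$pp[["H4"]]
      ppm[r, ] <- res$pp
    }
    out[[sc]] <- list(accuracy = mean(hit),
                      mean_pp = stats::setNames(colMeans(ppm),
                                                paste0("H", 0:4)),
                      pp_h4_gt_0.8 = mean(pp4 > 0.8))
  }
  out
}
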