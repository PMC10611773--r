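#' I-squared from a Q statistic
#'
#' The fraction of variability in the Wald ratios beyond chance,
#' I2 = max(0, (Q - df) / Q), truncated at zero.
#'
#' @param Q Cochran's Q statistic.
#' @param df degrees of freedom (k - 1).
#' @return I-squared as a fraction in [0, 1).
#' @export
i_squared <- function(Q, df) {
  ifelse(Q > 0, pmax(0, (Q - df) / Q), 0)
}

#' Cochran's Q heterogeneity test
#'
#' Q = sum over variants of (bx^2 / sey^2) * (ratio - theta)^2, i.e. the
#' inverse-variance-weighted squared deviations of the per-variant Wald
#' ratios from the pooled estimate, with first-order weights. Heterogeneity
#' is conventionally flagged at p < 0.05 (balanced pleiotropy assumed).
#'
#' @param h a \code{\link{harmonised_set}} or compatible data frame.
#' @param theta pooled estimate to test against; defaults to the IVW
#'   estimate.
#' @return list of class \code{heterogeneity_result}: Q, df, pval, I2.
#' @export
cochran_q <- function(h, theta = NULL) {
  d <- mr_data(h)
  k <- nrow(d)
  if (k < 2) {
    stop_mrbridge("heterogeneity undefined for fewer than 2 instruments",
                  "mr_insufficient_instruments")
  }
  if (is.null(theta)) theta <- mr_ivw(d)$estimate
  q <- sum((d$beta_outcome - theta * d$beta_exposure)^2 / d$se_outcome^2)
  df <- k - 1L
  structure(list(Q = q, df = df,
                 pval = stats::pchisq(q, df, lower.tail = FALSE),
                 I2 = i_squared(q, df)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.2f on %d df, p = %.3g, I2 = %.1f%%\n",
              x$Q, x$df, x$pval, 100 * x$I2))
  invisible(x)
}

# leave-one-out fixed-effect IVW slope for each variant, O(k) total
theta_loo_vec <- function(bx, by, w) {
  sxx <- sum(w * bx^2); sxy <- sum(w * bx * by)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' Residual-sum-of-squares test for horizontal pleiotropy. Each variant's
#' outcome effect is compared against its expectation under the
#' leave-one-out IVW slope; the observed weighted RSS is referred to a
#' parametric null distribution simulated from the per-variant sampling
#' distributions. Variants whose squared standardised residual is extreme
#' (Bonferroni-corrected empirical p below \code{outlier_p}) are flagged as
#' outliers, and the distortion test compares the all-variant IVW estimate
#' with the outlier-corrected one against random same-size removals.
#' Requires at least 4 instruments.
#'
#' @param h a \code{\link{harmonised_set}} or compatible data frame.
#' @param n_sim parametric simulations for the null (default 1000).
#' @param outlier_p familywise threshold for the per-variant test
#'   (default 0.05).
#' @param seed RNG seed (required for reproducibility).
#' @return list of class \code{presso_result}: \code{rss_obs},
#'   \code{global_pval}, \code{outlier_pvals} (Bonferroni-corrected, named
#'   by rsid), \code{outliers}, \code{distortion_pval},
#'   \code{estimate_raw}, \code{estimate_corrected}.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_p = 0.05, seed = NULL) {
  d <- mr_data(h)
  k <- nrow(d)
  if (k < 4) {
    stop_mrbridge("MR-PRESSO requires at least 4 instruments",
                  "mr_insufficient_instruments")
  }
  if (!is.null(seed)) set.seed(seed)
  w <- 1 / d$se_outcome^2
  th_loo <- theta_loo_vec(d$beta_exposure, d$beta_outcome, w)
  e_obs <- (d$beta_outcome - th_loo * d$beta_exposure) / d$se_outcome
  rss_obs <- sum(e_obs^2)

  # parametric null: redraw both betas around the LOO-expected values
  bx_sim <- matrix(stats::rnorm(k * n_sim, d$beta_exposure, d$se_exposure),
                   nrow = k)
  by_sim <- matrix(stats::rnorm(k * n_sim, th_loo * d$beta_exposure,
                                d$se_outcome), nrow = k)
  sxx <- colSums(w * bx_sim^2)
  sxy <- colSums(w * bx_sim * by_sim)
  th_loo_sim <- (rep(sxy, each = k) - w * bx_sim * by_sim) /
    (rep(sxx, each = k) - w * bx_sim^2)
  e_sim <- (by_sim - th_loo_sim * bx_sim) / d$se_outcome
  rss_sim <- colSums(e_sim^2)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  out_p_raw <- (1 + rowSums(e_sim^2 >= e_obs^2)) / (n_sim + 1)
  out_p <- pmin(1, out_p_raw * k)  # Bonferroni
  names(out_p) <- d$variant_id
  outliers <- d$variant_id[out_p < outlier_p]

  est_raw <- mr_ivw(d)
  est_corr <- NULL; distortion_p <- NA_real_
  if (length(outliers) > 0 && k - length(outliers) >= 2) {
    keep <- !(d$variant_id %in% outliers)
    est_corr <- mr_ivw(d[keep, , drop = FALSE])
    d_obs <- (est_raw$estimate - est_corr$estimate) / abs(est_corr$estimate)
    n_out <- length(outliers)
    d_null <- vapply(seq_len(min(n_sim, 1000)), function(s) {
      rm_idx <- sample.int(k, n_out)
      e2 <- mr_ivw(d[-rm_idx, , drop = FALSE])$estimate
      (est_raw$estimate - e2) / abs(e2)
    }, numeric(1))
    distortion_p <- mean(abs(d_null) >= abs(d_obs))
  }
  structure(list(rss_obs = rss_obs, global_pval = global_p,
                 outlier_pvals = out_p, outliers = outliers,
                 distortion_pval = distortion_p, estimate_raw = est_raw,
                 estimate_corrected = est_corr, n_sim = n_sim),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.3f, global p = %.4g (%d sims)\n",
              x$rss_obs, x$global_pval, x$n_sim))
  if (length(x$outliers)) {
    cat("Outliers:", paste(x$outliers, collapse = ", "),
        sprintf("(distortion p = %.3g)\n", x$distortion_pval))
  } else {
    cat("No outliers detected\n")
  }
  invisible(x)
}

#' Funnel-plot data for the per-variant Wald ratios
#'
#' Each variant's ratio against its precision (1 / se of the ratio);
#' symmetric scatter around the pooled estimate suggests balanced
#' pleiotropy. The IVW and (when estimable) Egger reference values are
#' attached as attributes.
#'
#' @param h a \code{\link{harmonised_set}} or compatible data frame.
#' @return data frame (variant_id, ratio, precision) with attributes
#'   \code{ivw} and \code{egger}.
#' @export
funnel_table <- function(h) {
  d <- mr_data(h)
  if (nrow(d) < 2) {
    stop_mrbridge("funnel data needs at least 2 instruments",
                  "mr_insufficient_instruments")
  }
  se_ratio <- d$se_outcome / abs(d$beta_exposure)
  tab <- data.frame(variant_id = d$variant_id,
                    ratio = d$beta_outcome / d$beta_exposure,
                    precision = 1 / se_ratio, stringsAsFactors = FALSE)
  attr(tab, "ivw") <- mr_ivw(d)$estimate
  attr(tab, "egger") <- if (nrow(d) >= 3) mr_egger(d)$estimate else NA_real_
  tab
}
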