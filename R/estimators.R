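mr_data <- function(h) {
  d <- if (inherits(h, "harmonised_set")) h$data else as.data.frame(h)
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_mrbridge(paste("missing column(s):", paste(miss, collapse = ", ")),
                  "mr_config_error")
  }
  if (is.null(d$variant_id)) d$variant_id <- paste0("v", seq_len(nrow(d)))
  drop <- d$beta_exposure == 0
  if (any(drop)) {
    warning(sprintf("%d variant(s) with zero exposure effect removed",
                    sum(drop)))
    d <- d[!drop, , drop = FALSE]
  }
  d
}

mr_estimate <- function(method, estimate, se, k, extra = list()) {
  z <- stats::qnorm(0.975)
  structure(list(method = method, estimate = estimate, se = se,
                 ci_low = estimate - z * se, ci_high = estimate + z * se,
                 pval = if (se > 0) 2 * stats::pnorm(-abs(estimate / se))
                        else as.numeric(estimate == 0),
                 k = k, extra = extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s: estimate %.*f (95%% CI %.*f to %.*f), se %.*f, p = %.3g, k = %d\n",
              x$method, digits, x$estimate, digits, x$ci_low, digits,
              x$ci_high, digits, x$se, x$pval, x$k))
  if (!is.null(x$extra$intercept)) {
    cat(sprintf("  intercept %.*f (se %.*f, p = %.3g)\n", digits,
                x$extra$intercept, digits, x$extra$intercept_se,
                x$extra$intercept_pval))
  }
  invisible(x)
}

#' Wald ratio for a single variant
#'
#' The per-variant causal estimate: outcome association divided by exposure
#' association, with the first-order delta-method standard error
#' \code{sey / |bx|}.
#'
#' @param bx,by exposure and outcome per-allele effects.
#' @param sex,sey their standard errors (> 0).
#' @return an \code{mr_estimate} of method \code{"wald"}.
#' @export
wald_ratio <- function(bx, by, sex, sey) {
  if (bx == 0) {
    stop_mrbridge("degenerate instrument: exposure effect is zero",
                  "mr_degenerate")
  }
  if (sex <= 0 || sey <= 0) {
    stop_mrbridge("standard errors must be positive", "mr_domain_error")
  }
  mr_estimate("wald", by / bx, sey / abs(bx), 1L)
}

#' Inverse-variance-weighted estimator (multiplicative random effects)
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' through the origin with weights 1/sey^2 — equivalently an
#' inverse-variance meta-analysis of the per-variant Wald ratios. The
#' multiplicative random-effects model inflates the fixed-effect standard
#' error by sqrt(max(1, Q / (k - 1))), so heterogeneity widens but never
#' narrows the interval. With a single variant the result equals the Wald
#' ratio exactly.
#'
#' @param h a \code{\link{harmonised_set}} or data frame with columns
#'   \code{beta_exposure}, \code{se_exposure}, \code{beta_outcome},
#'   \code{se_outcome}.
#' @return an \code{mr_estimate} of method \code{"ivw_mre"}; \code{extra}
#'   carries \code{Q} and the overdispersion factor.
#' @export
mr_ivw <- function(h) {
  d <- mr_data(h)
  k <- nrow(d)
  if (k == 0) stop_mrbridge("no usable instruments", "mr_no_instruments")
  if (k == 1) {
    # exact degeneracy to the single-variant Wald ratio
    est <- mr_estimate("ivw_mre", d$beta_outcome / d$beta_exposure,
                       d$se_outcome / abs(d$beta_exposure), 1L,
                       extra = list(Q = 0, overdispersion = 1))
    return(est)
  }
  w <- 1 / d$se_outcome^2
  est <- sum(w * d$beta_exposure * d$beta_outcome) /
    sum(w * d$beta_exposure^2)
  q <- sum(w * (d$beta_outcome - est * d$beta_exposure)^2)
  phi <- if (k >= 2) max(1, q / (k - 1)) else 1
  se <- sqrt(phi / sum(w * d$beta_exposure^2))
  mr_estimate("ivw_mre", est, se, k,
              extra = list(Q = q, overdispersion = phi))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with an
#' intercept, weights 1/sey^2, after orienting each variant so that its
#' exposure effect is non-negative. The slope estimates the causal effect
#' under the InSIDE assumption; a non-zero intercept indicates directional
#' pleiotropy. Residual overdispersion scales both standard errors by
#' sqrt(max(1, RSS_w / (k - 2))). Requires at least three variants.
#'
#' @inheritParams mr_ivw
#' @return an \code{mr_estimate} of method \code{"egger"}; \code{extra}
#'   carries the intercept triple.
#' @export
mr_egger <- function(h) {
  d <- mr_data(h)
  k <- nrow(d)
  if (k < 3) {
    stop_mrbridge("MR-Egger requires at least 3 instruments",
                  "mr_insufficient_instruments")
  }
  s <- sign(d$beta_exposure)
  bx <- abs(d$beta_exposure)
  by <- d$beta_outcome * s
  w <- 1 / d$se_outcome^2
  X <- cbind(1, bx)
  xtwx <- crossprod(X, w * X)
  coefs <- solve(xtwx, crossprod(X, w * by))
  resid <- by - X %*% coefs
  phi <- max(1, sum(w * resid^2) / (k - 2))
  covm <- phi * solve(xtwx)
  slope <- coefs[2]; slope_se <- sqrt(covm[2, 2])
  int <- coefs[1]; int_se <- sqrt(covm[1, 1])
  mr_estimate("egger", slope, slope_se, k,
              extra = list(intercept = int, intercept_se = int_se,
                           intercept_pval = 2 * stats::pnorm(-abs(int / int_se)),
                           overdispersion = phi))
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]; w <- weights[ord] / sum(weights)
  cw <- cumsum(w) - 0.5 * w
  if (cw[1] >= 0.5) return(r[1])
  below <- max(which(cw < 0.5))
  if (below == length(r)) return(r[length(r)])
  r[below] + (r[below + 1] - r[below]) *
    (0.5 - cw[below]) / (cw[below + 1] - cw[below])
}

boot_draws <- function(d, n_boot) {
  k <- nrow(d)
  list(bx = matrix(stats::rnorm(k * n_boot, d$beta_exposure, d$se_exposure),
                   nrow = k),
       by = matrix(stats::rnorm(k * n_boot, d$beta_outcome, d$se_outcome),
                   nrow = k))
}

#' Weighted median estimator
#'
#' The inverse-variance-weighted 50th percentile of the per-variant Wald
#' ratios (linear interpolation over cumulative normalised weights).
#' Consistent when at least half the weight comes from valid instruments.
#' The standard error comes from a parametric bootstrap: per-variant betas
#' resampled from their normal sampling distributions.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @return an \code{mr_estimate} of method \code{"weighted_median"}.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  d <- mr_data(h)
  k <- nrow(d)
  if (k < 3) {
    stop_mrbridge("weighted median requires at least 3 instruments",
                  "mr_insufficient_instruments")
  }
  ratios <- d$beta_outcome / d$beta_exposure
  weights <- (d$beta_exposure / d$se_outcome)^2
  est <- weighted_median_point(ratios, weights)
  if (!is.null(seed)) set.seed(seed)
  bd <- boot_draws(d, n_boot)
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- bd$bx[, b]
    ok <- bx != 0
    weighted_median_point(bd$by[ok, b] / bx[ok],
                          (bx[ok] / d$se_outcome[ok])^2)
  }, numeric(1))
  mr_estimate("weighted_median", est, stats::sd(boots), k)
}

weighted_mode_point <- function(ratios, weights, bandwidth_factor = 1) {
  spread <- min(stats::sd(ratios), stats::mad(ratios))
  if (spread == 0) spread <- stats::sd(ratios)
  if (spread == 0) return(ratios[1])
  h <- bandwidth_factor * 0.9 * spread * length(ratios)^(-1 / 5)
  dens <- stats::density(ratios, weights = weights / sum(weights), bw = h,
                         n = 512)
  mean(dens$x[dens$y == max(dens$y)])
}

#' Weighted mode estimator
#'
#' The mode of an inverse-variance-weighted kernel density over the
#' per-variant Wald ratios; consistent when the largest cluster of
#' instruments is valid (plurality rule). Bandwidth is a modified Silverman
#' rule on the ratio spread, scaled by \code{bandwidth_factor}; standard
#' error by parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor multiplier on the Silverman bandwidth
#'   (default 1).
#' @return an \code{mr_estimate} of method \code{"weighted_mode"}.
#' @export
mr_weighted_mode <- function(h, bandwidth_factor = 1, n_boot = 1000,
                             seed = NULL) {
  d <- mr_data(h)
  k <- nrow(d)
  if (k < 3) {
    stop_mrbridge("weighted mode requires at least 3 instruments",
                  "mr_insufficient_instruments")
  }
  ratios <- d$beta_outcome / d$beta_exposure
  weights <- (d$beta_exposure / d$se_outcome)^2
  est <- weighted_mode_point(ratios, weights, bandwidth_factor)
  if (!is.null(seed)) set.seed(seed)
  bd <- boot_draws(d, n_boot)
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- bd$bx[, b]
    ok <- bx != 0
    weighted_mode_point(bd$by[ok, b] / bx[ok],
                        (bx[ok] / d$se_outcome[ok])^2, bandwidth_factor)
  }, numeric(1))
  mr_estimate("weighted_mode", est, stats::sd(boots), k)
}

#' Per-variant Wald ratios (single-SNP analysis)
#'
#' @inheritParams mr_ivw
#' @return data frame: variant_id, ratio, se, ci bounds, p.
#' @export
mr_single_snp <- function(h) {
  d <- mr_data(h)
  ratio <- d$beta_outcome / d$beta_exposure
  se <- d$se_outcome / abs(d$beta_exposure)
  z <- stats::qnorm(0.975)
  data.frame(variant_id = d$variant_id, ratio = ratio, se = se,
             ci_low = ratio - z * se, ci_high = ratio + z * se,
             pval = 2 * stats::pnorm(-abs(ratio / se)),
             stringsAsFactors = FALSE)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the multiplicative random-effects IVW with each variant
#' removed in turn; a row that moves the estimate far outside the joint
#' interval flags a single variant driving the result.
#'
#' @inheritParams mr_ivw
#' @return data frame: variant_id (the one removed), estimate, se, ci, p.
#' @export
mr_leave_one_out <- function(h) {
  d <- mr_data(h)
  k <- nrow(d)
  if (k < 2) {
    warning("leave-one-out skipped: fewer than 2 instruments")
    return(data.frame(variant_id = character(0), estimate = numeric(0),
                      se = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), pval = numeric(0)))
  }
  rows <- lapply(seq_len(k), function(i) {
    e <- mr_ivw(d[-i, , drop = FALSE])
    data.frame(variant_id = d$variant_id[i], estimate = e$estimate,
               se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
               pval = e$pval, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
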