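#' Fit the full set of two-sample MR estimators
#'
#' The package's central fitting function: takes a harmonised
#' exposure/outcome set and runs the requested causal estimators —
#' multiplicative random-effects IVW (the headline analysis), MR-Egger,
#' weighted median and weighted mode — plus Cochran's Q heterogeneity at
#' the IVW estimate. With a single variant the fit degenerates to the Wald
#' ratio. Estimators whose instrument-count preconditions are not met are
#' skipped with a record of why, so a sparse instrument set still yields
#' the estimators it can support.
#'
#' @param h a \code{\link{harmonised_set}} (or compatible data frame).
#' @param methods which estimators to run.
#' @param n_boot bootstrap replicates for median/mode standard errors.
#' @param seed RNG seed for the bootstraps.
#' @param bandwidth_factor weighted-mode bandwidth multiplier.
#' @return an object of class \code{mr_fit} with components
#'   \code{estimates} (one row per method), \code{heterogeneity}
#'   (\code{\link{cochran_q}} at the IVW estimate), \code{egger_intercept},
#'   \code{skipped}, \code{data} and \code{k}.
#' @examples
#' sim <- simulate_mr_dataset(mr_truth(theta = 0.2, J = 30, seed = 1))
#' h <- harmonise(sim$exposure, sim$outcome)
#' fit <- mr_fit(h, seed = 1, n_boot = 200)
#' fit
#' coef(fit)
#' @export
mr_fit <- function(h, methods = c("ivw", "egger", "weighted_median",
                                  "weighted_mode"),
                   n_boot = 1000, seed = NULL, bandwidth_factor = 1) {
  d <- mr_data(h)
  k <- nrow(d)
  ests <- list()
  skipped <- character(0)
  if (k == 1) {
    ests$wald <- wald_ratio(d$beta_exposure, d$beta_outcome,
                            d$se_exposure, d$se_outcome)
    ests$wald$method <- "wald"
  }
  run <- function(name, fn) {
    tryCatch(fn(), mrbridge_error = function(e) {
      skipped[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  if ("ivw" %in% methods) ests$ivw <- run("ivw", function() mr_ivw(d))
  if ("egger" %in% methods) ests$egger <- run("egger", function() mr_egger(d))
  if ("weighted_median" %in% methods) {
    ests$weighted_median <- run("weighted_median", function()
      mr_weighted_median(d, n_boot = n_boot, seed = seed))
  }
  if ("weighted_mode" %in% methods) {
    ests$weighted_mode <- run("weighted_mode", function()
      mr_weighted_mode(d, bandwidth_factor = bandwidth_factor,
                       n_boot = n_boot,
                       seed = if (is.null(seed)) NULL else seed + 1L))
  }
  ests <- Filter(Negate(is.null), ests)
  tab <- do.call(rbind, lapply(ests, function(e) {
    data.frame(method = e$method, estimate = e$estimate, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
               k = e$k, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  het <- if (k >= 2 && !is.null(ests$ivw)) {
    cochran_q(d, theta = ests$ivw$estimate)
  } else NULL
  egger_int <- if (!is.null(ests$egger)) ests$egger$extra[
    c("intercept", "intercept_se", "intercept_pval")] else NULL
  structure(list(estimates = tab, fits = ests, heterogeneity = het,
                 egger_intercept = egger_int, skipped = skipped,
                 data = d, k = k,
                 exposure_meta = if (inherits(h, "harmonised_set"))
                   h$exposure_meta else NULL,
                 outcome_meta = if (inherits(h, "harmonised_set"))
                   h$outcome_meta else NULL),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR fit: %d instrument(s)\n", x$k))
  if (!is.null(x$exposure_meta)) {
    cat(sprintf("%s -> %s\n", x$exposure_meta$trait, x$outcome_meta$trait))
  }
  tab <- x$estimates
  tab[, 2:6] <- lapply(tab[, 2:6], signif, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  if (!is.null(f$heterogeneity)) {
    h <- f$heterogeneity
    cat(sprintf("\nHeterogeneity: Q = %.2f on %d df, p = %.3g, I2 = %.1f%%\n",
                h$Q, h$df, h$pval, 100 * h$I2))
  }
  if (!is.null(f$egger_intercept)) {
    cat(sprintf("Egger intercept: %.4f (se %.4f, p = %.3g)\n",
                f$egger_intercept$intercept, f$egger_intercept$intercept_se,
                f$egger_intercept$intercept_pval))
  }
  if (length(f$skipped)) {
    cat("Skipped:", paste(names(f$skipped), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$estimate, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$estimates
  m <- cbind(est$estimate - z * est$se, est$estimate + z * est$se)
  dimnames(m) <- list(est$method,
                      paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                             " %"))
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' Scatter plot of outcome against exposure effects with fitted slopes
#'
#' @param x an \code{mr_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.mr_fit <- function(x, ...) {
  d <- x$data
  s <- sign(d$beta_exposure)
  bx <- abs(d$beta_exposure); by <- d$beta_outcome * s
  graphics::plot(bx, by, xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome", pch = 19, ...)
  graphics::arrows(bx, by - 1.96 * d$se_outcome, bx,
                   by + 1.96 * d$se_outcome, angle = 90, code = 3,
                   length = 0.02, col = "grey60")
  cols <- c(ivw_mre = "black", egger = "red3", weighted_median = "blue3",
            weighted_mode = "darkgreen", wald = "black")
  for (i in seq_len(nrow(x$estimates))) {
    meth <- x$estimates$method[i]
    int <- if (meth == "egger") x$egger_intercept$intercept else 0
    graphics::abline(int, x$estimates$estimate[i],
                     col = cols[[meth]] %||% "grey40", lty = i)
  }
  graphics::legend("topleft", legend = x$estimates$method, bty = "n",
                   col = vapply(x$estimates$method,
                                function(m) cols[[m]] %||% "grey40", ""),
                   lty = seq_len(nrow(x$estimates)))
  invisible(x)
}
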