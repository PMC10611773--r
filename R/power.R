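#' Minimum detectable odds ratio for a binary outcome
#'
#' Inverts the standard two-sample MR power approximation for binary
#' outcomes: with r = n_controls / n_cases, the smallest detectable
#' log odds ratio per 1 SD of the exposure at the given power and
#' two-sided alpha is
#' \deqn{\beta = (z_{1-\alpha/2} + z_{power}) /
#'   (\sqrt{n \cdot r2} \cdot \sqrt{r} / (1 + r))}
#' where n is the outcome sample size and r2 the total variance in the
#' exposure explained by the instruments. Note sqrt(r)/(1+r) equals
#' sqrt(v(1-v)) with v the case fraction.
#'
#' @param r2 total variance explained by the instruments, in (0, 1).
#' @param n_outcome outcome-GWAS sample size.
#' @param n_cases,n_controls case/control counts
#'   (must sum to n_outcome).
#' @param power target power (default 0.80).
#' @param alpha two-sided type-1 error rate (default 0.05).
#' @return list with \code{or} (full precision) and \code{or_2dp}
#'   (rounded half-up to 2 decimals, the reporting convention).
#' @export
min_detectable_or <- function(r2, n_outcome, n_cases, n_controls,
                              power = 0.80, alpha = 0.05) {
  check_power_spec(r2, n_outcome, n_cases, n_controls, power, alpha)
  r <- n_controls / n_cases
  zsum <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  beta <- zsum / (sqrt(n_outcome * r2) * sqrt(r) / (1 + r))
  or <- exp(beta)
  list(or = or, or_2dp = floor(or * 100 + 0.5) / 100)
}

#' Power to detect a given odds ratio
#'
#' Forward form of the same approximation, for round-tripping with
#' \code{\link{min_detectable_or}}:
#' power = Phi(sqrt(n r2) |log OR| sqrt(r)/(1+r) - z_{1-alpha/2}).
#'
#' @inheritParams min_detectable_or
#' @param or_alt alternative-hypothesis odds ratio (> 0).
#' @return power in (0, 1).
#' @export
power_at_or <- function(r2, n_outcome, n_cases, n_controls, or_alt,
                        alpha = 0.05) {
  check_power_spec(r2, n_outcome, n_cases, n_controls, 0.5, alpha)
  if (or_alt <= 0) stop_mrbridge("or_alt must be positive", "mr_domain_error")
  r <- n_controls / n_cases
  stats::pnorm(sqrt(n_outcome * r2) * abs(log(or_alt)) * sqrt(r) / (1 + r) -
                 stats::qnorm(1 - alpha / 2))
}

check_power_spec <- function(r2, n_outcome, n_cases, n_controls, power,
                             alpha) {
  if (r2 <= 0 || r2 >= 1) {
    stop_mrbridge("r2 must lie in (0, 1)", "mr_domain_error")
  }
  if (n_cases <= 0) {
    stop_mrbridge("n_cases must be positive", "mr_degenerate")
  }
  if (n_cases + n_controls != n_outcome) {
    stop_mrbridge("n_cases + n_controls must equal n_outcome",
                  "mr_config_error")
  }
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1) {
    stop_mrbridge("power and alpha must lie in (0, 1)", "mr_domain_error")
  }
  invisible(TRUE)
}
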