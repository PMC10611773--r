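#' Ground truth for a synthetic two-sample MR dataset
#'
#' Defines the generating parameters of a paired exposure/outcome GWAS
#' summary-statistic simulation. The defaults emulate the forward design
#' the package targets: a rank-normalised continuous exposure from a
#' UK-Biobank-scale GWAS (n = 360,000) instrumented by tens of variants
#' with mean F near 60, against a FinnGen-scale binary hearing-loss
#' outcome (n = 252,719, case fraction 7.64\%).
#'
#' @param theta true causal effect (log-OR per SD for binary outcomes).
#' @param J number of instruments (>= 3).
#' @param pleiotropy \code{"none"}, \code{"balanced"} (mean-zero direct
#'   effects) or \code{"directional"} (mean-shifted, violating the Egger
#'   intercept null).
#' @param pleio_sd SD of the per-variant direct effect on the outcome.
#' @param pleio_mean mean direct effect under \code{"directional"}.
#' @param pleio_frac fraction of variants carrying a direct effect.
#' @param n_exposure exposure-GWAS sample size.
#' @param n_outcome outcome-GWAS sample size.
#' @param outcome_type \code{"binary"} or \code{"continuous"}.
#' @param case_fraction case fraction for binary outcomes, in (0, 1).
#' @param beta_sd SD of the true per-allele exposure effects (SD units);
#'   the default 0.021 gives mean per-variant F around 60 at the default
#'   exposure sample size.
#' @param seed master seed (mandatory: outputs are byte-identical under a
#'   fixed seed).
#' @return object of class \code{mr_truth}.
#' @export
mr_truth <- function(theta = 0, J = 80,
                     pleiotropy = c("none", "balanced", "directional"),
                     pleio_sd = 0, pleio_mean = 0, pleio_frac = 1,
                     n_exposure = 360000, n_outcome = 252719,
                     outcome_type = c("binary", "continuous"),
                     case_fraction = 0.0764, beta_sd = 0.021, seed) {
  pleiotropy <- match.arg(pleiotropy)
  outcome_type <- match.arg(outcome_type)
  if (missing(seed)) stop_mrbridge("seed is mandatory", "mr_config_error")
  if (J < 3) stop_mrbridge("need at least 3 instruments", "mr_config_error")
  if (outcome_type == "binary" &&
      (case_fraction <= 0 || case_fraction >= 1)) {
    stop_mrbridge("case_fraction must lie in (0, 1)", "mr_config_error")
  }
  structure(list(theta = theta, J = J, pleiotropy = pleiotropy,
                 pleio_sd = pleio_sd, pleio_mean = pleio_mean,
                 pleio_frac = pleio_frac, n_exposure = n_exposure,
                 n_outcome = n_outcome, outcome_type = outcome_type,
                 case_fraction = case_fraction, beta_sd = beta_sd,
                 seed = seed), class = "mr_truth")
}

NONPAL_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                         "G","A", "G","T", "T","C", "T","G"),
                       ncol = 2, byrow = TRUE)

sumstats_frame <- function(id, chrom, pos, ea, oa, eaf, beta, se, n) {
  data.frame(variant_id = id, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se,
             pval = 2 * stats::pnorm(-abs(beta / se)), n = n,
             info = 1, stringsAsFactors = FALSE)
}

#' Simulate paired exposure/outcome GWAS summary statistics
#'
#' Generates J independent instruments: MAF ~ Uniform(0.05, 0.5); true
#' per-allele exposure effects ~ Normal(0, beta_sd); exposure standard
#' errors follow the theoretical 1/sqrt(2 maf (1-maf) n) for an
#' SD-standardised trait, and observed effects are drawn around the truth.
#' The outcome's true effect is theta * bx_true plus any per-variant
#' direct (pleiotropic) effect; binary outcomes live on the log-odds scale
#' with standard errors inflated by case imbalance,
#' 1/sqrt(2 maf (1-maf) n v (1-v)). P-values are the honest two-sided
#' normal tails. Variants are placed on distinct chromosomes/positions
#' with non-palindromic allele codings so harmonisation is exact.
#'
#' @param truth an \code{\link{mr_truth}}.
#' @return list: \code{exposure} and \code{outcome} summary-statistic
#'   tables, \code{truth} echo (including the realised per-variant direct
#'   effects), and \code{exposure_meta}/\code{outcome_meta}.
#' @export
simulate_mr_dataset <- function(truth) {
  stopifnot(inherits(truth, "mr_truth"))
  set.seed(truth$seed)
  J <- truth$J
  maf <- stats::runif(J, 0.05, 0.5)
  # effects reported on the exposure-increasing allele, as instrument
  # lists conventionally are: half-normal magnitudes
  bx_true <- abs(stats::rnorm(J, 0, truth$beta_sd))
  sex <- 1 / sqrt(2 * maf * (1 - maf) * truth$n_exposure)
  bx_obs <- stats::rnorm(J, bx_true, sex)

  # direct effects drawn once, shared across balanced/directional scenarios
  affected <- stats::runif(J) < truth$pleio_frac
  alpha0 <- stats::rnorm(J, 0, truth$pleio_sd) * affected
  alpha <- switch(truth$pleiotropy,
                  none = rep(0, J),
                  balanced = alpha0,
                  directional = alpha0 + truth$pleio_mean * affected)
  by_true <- truth$theta * bx_true + alpha
  v <- truth$case_fraction
  sey <- if (truth$outcome_type == "binary") {
    1 / sqrt(2 * maf * (1 - maf) * truth$n_outcome * v * (1 - v))
  } else {
    1 / sqrt(2 * maf * (1 - maf) * truth$n_outcome)
  }
  by_obs <- stats::rnorm(J, by_true, sey)

  ids <- sprintf("rs%06d", seq_len(J))
  chrom <- as.character(rep_len(1:22, J))
  pos <- 1e6 + 1e7 * (seq_len(J) - 1) %/% 22
  pair <- NONPAL_PAIRS[sample.int(nrow(NONPAL_PAIRS), J, replace = TRUE), ,
                       drop = FALSE]
  exposure <- sumstats_frame(ids, chrom, pos, pair[, 1], pair[, 2], maf,
                             bx_obs, sex, truth$n_exposure)
  outcome <- sumstats_frame(ids, chrom, pos, pair[, 1], pair[, 2], maf,
                            by_obs, sey, truth$n_outcome)
  truth_echo <- truth
  truth_echo$bx_true <- bx_true
  truth_echo$alpha <- alpha
  truth_echo$maf <- maf
  n_cases <- if (truth$outcome_type == "binary")
    round(v * truth$n_outcome) else NA_real_
  list(exposure = exposure, outcome = outcome, truth = truth_echo,
       exposure_meta = study_meta("synthetic exposure", "continuous",
                                  truth$n_exposure, source = "synthgen"),
       outcome_meta = if (truth$outcome_type == "binary") {
         study_meta("synthetic outcome", "binary", truth$n_outcome,
                    n_cases, truth$n_outcome - n_cases, "synthgen")
       } else {
         study_meta("synthetic outcome", "continuous", truth$n_outcome,
                    source = "synthgen")
       })
}

#' Ground truth for a synthetic regional (colocalisation) dataset
#'
#' @param J number of regional variants.
#' @param rho AR(1) LD-correlation parameter in [0, 1); pairwise signed
#'   correlation rho^|i-j|, r-squared its square.
#' @param scenario which colocalisation hypothesis to instantiate:
#'   \code{"none"} (H0), \code{"exposure"} (H1), \code{"outcome"} (H2),
#'   \code{"distinct"} (H3), \code{"shared"} (H4).
#' @param lambda_exposure,lambda_outcome non-centrality of the causal
#'   variant's z-score for each trait; the default 12 emulates a strong
#'   regional GWAS hit at biobank scale.
#' @param n_exposure,n_outcome sample sizes used for the per-variant
#'   standard errors.
#' @param seed master seed (mandatory).
#' @return object of class \code{region_truth}.
#' @export
region_truth <- function(J = 200, rho = 0.9,
                         scenario = c("none", "exposure", "outcome",
                                      "distinct", "shared"),
                         lambda_exposure = 12, lambda_outcome = 12,
                         n_exposure = 322154, n_outcome = 250389, seed) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop_mrbridge("seed is mandatory", "mr_config_error")
  if (rho < 0 || rho >= 1) {
    stop_mrbridge("rho must lie in [0, 1)", "mr_config_error")
  }
  structure(list(J = J, rho = rho, scenario = scenario,
                 lambda_exposure = lambda_exposure,
                 lambda_outcome = lambda_outcome,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 seed = seed), class = "region_truth")
}

#' Simulate a regional dataset for colocalisation
#'
#' Draws the two traits' regional z-scores jointly from a multivariate
#' normal with AR(1) correlation Sigma (rho^|i-j|): mean
#' lambda * Sigma[, causal] under the scenario's causal configuration,
#' covariance Sigma. Betas are recovered through the theoretical
#' per-variant standard errors. The shared scenario uses one causal index
#' for both traits (mid-region); the distinct scenario uses indices at the
#' region's quarter points, far enough apart to be in negligible LD.
#' Positions are laid inside the hg19 FTO window so the regional tables
#' drop straight into \code{\link{extract_region}}.
#'
#' @param truth a \code{\link{region_truth}}.
#' @return list: \code{exposure}/\code{outcome} regional tables (with a
#'   \code{"build"} attribute), \code{ld} (\code{\link{ld_matrix}} of
#'   r-squared), \code{truth} echo with \code{causal_exposure} and
#'   \code{causal_outcome} variant ids (NA when absent).
#' @export
simulate_region <- function(truth) {
  stopifnot(inherits(truth, "region_truth"))
  set.seed(truth$seed)
  J <- truth$J
  sigma <- truth$rho^abs(outer(seq_len(J), seq_len(J), "-"))
  ch <- tryCatch(chol(sigma), error = function(e)
    stop_mrbridge("LD kernel is not positive definite", "mr_domain_error"))
  c1 <- switch(truth$scenario, none = NA_integer_, outcome = NA_integer_,
               exposure = as.integer(ceiling(J / 2)),
               shared = as.integer(ceiling(J / 2)),
               distinct = as.integer(ceiling(J / 4)))
  c2 <- switch(truth$scenario, none = NA_integer_, exposure = NA_integer_,
               outcome = as.integer(ceiling(J / 2)),
               shared = as.integer(ceiling(J / 2)),
               distinct = as.integer(ceiling(3 * J / 4)))
  mvn <- function(mu) mu + drop(crossprod(ch, stats::rnorm(J)))
  mu1 <- if (is.na(c1)) rep(0, J) else truth$lambda_exposure * sigma[, c1]
  mu2 <- if (is.na(c2)) rep(0, J) else truth$lambda_outcome * sigma[, c2]
  z1 <- mvn(mu1)
  z2 <- mvn(mu2)
  maf <- stats::runif(J, 0.05, 0.5)
  se1 <- 1 / sqrt(2 * maf * (1 - maf) * truth$n_exposure)
  se2 <- 1 / sqrt(2 * maf * (1 - maf) * truth$n_outcome)

  ids <- sprintf("rs16_%04d", seq_len(J))
  win <- fto_region()
  pos <- round(seq(win$start, win$end, length.out = J))
  pair <- NONPAL_PAIRS[sample.int(nrow(NONPAL_PAIRS), J, replace = TRUE), ,
                       drop = FALSE]
  exposure <- sumstats_frame(ids, "16", pos, pair[, 1], pair[, 2], maf,
                             z1 * se1, se1, truth$n_exposure)
  outcome <- sumstats_frame(ids, "16", pos, pair[, 1], pair[, 2], maf,
                            z2 * se2, se2, truth$n_outcome)
  attr(exposure, "build") <- win$build
  attr(outcome, "build") <- win$build
  truth_echo <- truth
  truth_echo$causal_exposure <- if (is.na(c1)) NA_character_ else ids[c1]
  truth_echo$causal_outcome <- if (is.na(c2)) NA_character_ else ids[c2]
  list(exposure = exposure, outcome = outcome,
       ld = ld_matrix(sigma^2, ids = ids), truth = truth_echo)
}

#' Write a summary-statistic table as TSV
#' @param rows summary-statistic data frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_sumstats <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
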