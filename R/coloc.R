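#' Genomic region specification
#'
#' 1-based inclusive coordinates with the genome build carried as a
#' metadata string; no liftover is ever attempted.
#'
#' @param chrom chromosome label (e.g. "16").
#' @param start,end 1-based inclusive bounds, start < end.
#' @param build genome build tag (default "hg19").
#' @return object of class \code{region_spec}.
#' @export
region_spec <- function(chrom, start, end, build = "hg19") {
  if (start >= end) stop_mrbridge("start must be < end", "mr_config_error")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 build = build), class = "region_spec")
}

#' Parse "chr16:53737875-54155853" into a region_spec
#' @param x region string.
#' @param build genome build tag.
#' @return a \code{\link{region_spec}}.
#' @export
parse_region <- function(x, build = "hg19") {
  m <- regmatches(x, regexec("^(chr)?([0-9XYM]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) == 0) {
    stop_mrbridge(sprintf("cannot parse region '%s'", x), "mr_config_error")
  }
  strip <- function(s) as.numeric(gsub(",", "", s))
  region_spec(m[3], strip(m[4]), strip(m[5]), build = build)
}

#' The FTO-locus window used for BMI/hearing colocalisation
#'
#' chr16:53,737,875-54,155,853 on hg19.
#' @return a \code{\link{region_spec}}.
#' @export
fto_region <- function() region_spec("16", 53737875, 54155853, "hg19")

#' Restrict a summary-statistic table to a genomic region
#'
#' Keeps rows with region.start <= pos <= region.end on the region's
#' chromosome, preserving order. If the table carries a \code{"build"}
#' attribute that differs from the region's build, an error is raised
#' rather than silently mixing coordinate systems.
#'
#' @param rows summary-statistic data frame with chrom and pos.
#' @param region a \code{\link{region_spec}}.
#' @return the sub-table.
#' @export
extract_region <- function(rows, region) {
  b <- attr(rows, "build")
  if (!is.null(b) && !identical(b, region$build)) {
    stop_mrbridge(sprintf("genome build mismatch: rows are %s, region is %s",
                          b, region$build), "mr_build_mismatch")
  }
  chrom <- sub("^chr", "", as.character(rows$chrom))
  keep <- chrom == sub("^chr", "", region$chrom) &
    rows$pos >= region$start & rows$pos <= region$end
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wakefield log approximate Bayes factor
#'
#' For an estimate beta with standard error se and a normal effect prior
#' with standard deviation prior_sd: with z = beta/se, V = se^2,
#' W = prior_sd^2 and r = W / (W + V),
#' log ABF = 0.5 * log(1 - r) + z^2 * r / 2, computed in log space.
#'
#' @param beta,se association estimate and standard error (se > 0).
#' @param prior_sd prior standard deviation of the true effect
#'   (conventionally 0.2 for SD-scale continuous traits, 0.15 for
#'   log-odds binary traits).
#' @return log ABF, vectorised.
#' @export
wakefield_abf <- function(beta, se, prior_sd = 0.2) {
  if (any(se <= 0) || any(prior_sd <= 0)) {
    stop_mrbridge("se and prior_sd must be positive", "mr_domain_error")
  }
  z <- beta / se
  if (any(!is.finite(z))) {
    stop_mrbridge("non-finite z-score", "mr_domain_error")
  }
  v <- se^2
  w <- prior_sd^2
  r <- w / (w + v)
  0.5 * log1p(-r) + z^2 * r / 2
}

#' Single-causal-variant colocalisation posteriors
#'
#' Bayesian colocalisation of two traits over a shared set of regional
#' variants, assuming at most one causal variant per trait. Per-variant
#' Wakefield log ABFs are accumulated by log-sum-exp into likelihoods for
#' the five hypotheses — H0 no association, H1 exposure only, H2 outcome
#' only, H3 two distinct causal variants, H4 one shared causal variant —
#' and combined with per-variant prior probabilities p1, p2, p12.
#' PP_H4 > 0.8 is the conventional evidence bound for colocalisation.
#'
#' @param region_exposure,region_outcome regional summary-statistic tables
#'   sharing variant ids (at least 2 shared variants).
#' @param p1,p2 prior probability a variant is associated with the
#'   exposure only / outcome only (default 1e-4 each).
#' @param p12 prior probability a variant is associated with both
#'   (default 1e-5).
#' @param prior_sd_exposure,prior_sd_outcome ABF effect-prior SDs
#'   (defaults 0.2 and 0.15 for a continuous exposure and a binary
#'   outcome).
#' @return object of class \code{coloc_result}: \code{pp} (named H0..H4,
#'   sums to 1), \code{labf_exposure}, \code{labf_outcome},
#'   \code{h4_contribution} (per-variant probability of being the shared
#'   causal variant, sums to 1), \code{colocalised} (PP_H4 > 0.8),
#'   \code{priors}, \code{n_variants}, \code{top_variant}.
#' @export
coloc_pp <- function(region_exposure, region_outcome, p1 = 1e-4, p2 = 1e-4,
                     p12 = 1e-5, prior_sd_exposure = 0.2,
                     prior_sd_outcome = 0.15) {
  shared <- intersect(region_exposure$variant_id, region_outcome$variant_id)
  if (length(shared) < 2) {
    stop_mrbridge("colocalisation needs at least 2 shared variants",
                  "mr_insufficient_region")
  }
  e <- region_exposure[match(shared, region_exposure$variant_id), ]
  o <- region_outcome[match(shared, region_outcome$variant_id), ]
  l1 <- wakefield_abf(e$beta, e$se, prior_sd_exposure)
  l2 <- wakefield_abf(o$beta, o$se, prior_sd_outcome)
  lh1 <- logsumexp(l1)
  lh2 <- logsumexp(l2)
  lh4 <- logsumexp(l1 + l2)
  lh3 <- logdiffexp(lh1 + lh2, lh4)  # cross terms i != j
  lw <- c(H0 = 0,
          H1 = log(p1) + lh1,
          H2 = log(p2) + lh2,
          H3 = log(p1) + log(p2) + lh3,
          H4 = log(p12) + lh4)
  pp <- exp(lw - logsumexp(lw))
  h4c <- exp((l1 + l2) - lh4)
  names(h4c) <- shared
  structure(list(pp = pp, labf_exposure = stats::setNames(l1, shared),
                 labf_outcome = stats::setNames(l2, shared),
                 h4_contribution = h4c,
                 colocalised = unname(pp["H4"] > 0.8),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 n_variants = length(shared),
                 top_variant = shared[which.max(h4c)]),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalisation over %d shared variants (p1=%g, p2=%g, p12=%g)\n",
              x$n_variants, x$priors["p1"], x$priors["p2"], x$priors["p12"]))
  print(round(x$pp, 4))
  cat(sprintf("Colocalised (PP_H4 > 0.8): %s; top shared-causal candidate: %s (%.1f%%)\n",
              x$colocalised, x$top_variant,
              100 * max(x$h4_contribution)))
  invisible(x)
}
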