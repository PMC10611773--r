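#' Construct an LD matrix of pairwise r-squared values
#'
#' @param r2 square numeric matrix of pairwise r-squared values with unit
#'   diagonal; dimnames give the variant ids (or pass \code{ids}).
#' @param ids optional character vector of variant ids.
#' @return object of class \code{ld_matrix}.
#' @export
ld_matrix <- function(r2, ids = NULL) {
  r2 <- as.matrix(r2)
  if (!is.null(ids)) dimnames(r2) <- list(ids, ids)
  if (is.null(rownames(r2))) {
    stop_mrbridge("LD matrix requires variant ids", "mr_config_error")
  }
  if (nrow(r2) != ncol(r2) || !identical(rownames(r2), colnames(r2))) {
    stop_mrbridge("LD matrix must be square with matching ids",
                  "mr_config_error")
  }
  if (max(abs(r2 - t(r2))) > 1e-12) {
    stop_mrbridge("LD matrix must be symmetric within 1e-12",
                  "mr_config_error")
  }
  if (any(abs(diag(r2) - 1) > 0)) {
    stop_mrbridge("LD matrix diagonal must be exactly 1", "mr_config_error")
  }
  if (min(r2) < 0 || max(r2) > 1) {
    stop_mrbridge("LD r-squared values must lie in [0, 1]", "mr_config_error")
  }
  structure(r2, class = c("ld_matrix", "matrix"))
}

#' Read an LD matrix from TSV
#'
#' Accepts either a square matrix with a header row and an id column, or a
#' long-format triplet file with columns \code{id1}, \code{id2}, \code{r2}
#' (missing pairs default to r-squared 0).
#'
#' @param path TSV file path.
#' @return an \code{\link{ld_matrix}}.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (identical(sort(names(raw)), sort(c("id1", "id2", "r2")))) {
    ids <- sort(unique(c(raw$id1, raw$id2)))
    m <- diag(length(ids))
    dimnames(m) <- list(ids, ids)
    for (k in seq_len(nrow(raw))) {
      m[raw$id1[k], raw$id2[k]] <- raw$r2[k]
      m[raw$id2[k], raw$id1[k]] <- raw$r2[k]
    }
    return(ld_matrix(m))
  }
  ids <- raw[[1]]
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids
  ld_matrix(m)
}

ld_r2 <- function(ld, id_a, id_b) {
  if (!(id_a %in% rownames(ld)) || !(id_b %in% rownames(ld))) return(NA_real_)
  unclass(ld)[id_a, id_b]
}

#' Select instrument candidates by p-value threshold with fallback
#'
#' Returns rows passing the genome-wide threshold; when fewer than
#' \code{min_count} pass, re-selects at the relaxed fallback threshold
#' (mirroring the practice of relaxing to 5e-5 when too few genome-wide
#' hits exist for sensitivity analyses) and flags the relaxation.
#'
#' @param rows summary-statistic data frame.
#' @param p_threshold primary threshold (default 5e-8).
#' @param fallback_threshold relaxed threshold (default 5e-5).
#' @param min_count minimum instruments before falling back (default 13).
#' @return the selected rows with attributes \code{threshold_used} and
#'   \code{relaxed}.
#' @export
select_instruments <- function(rows, p_threshold = 5e-8,
                               fallback_threshold = 5e-5, min_count = 13) {
  primary <- rows[rows$pval <= p_threshold, , drop = FALSE]
  if (nrow(primary) >= min_count) {
    out <- primary; used <- p_threshold; relaxed <- FALSE
  } else {
    fb <- rows[rows$pval <= fallback_threshold, , drop = FALSE]
    if (nrow(fb) > nrow(primary)) {
      out <- fb; used <- fallback_threshold; relaxed <- TRUE
    } else {
      out <- primary; used <- p_threshold; relaxed <- FALSE
    }
  }
  if (nrow(out) == 0) {
    stop_mrbridge("no instruments at either threshold", "mr_no_instruments")
  }
  rownames(out) <- NULL
  attr(out, "threshold_used") <- used
  attr(out, "relaxed") <- relaxed
  out
}

#' Greedy LD clumping
#'
#' Sorts candidates by ascending p-value (ties broken lexicographically by
#' variant id) and accepts a variant only if its r-squared with every
#' already-accepted variant within \code{window_kb} on the same chromosome
#' is at most \code{r2_max}. Candidates absent from the LD matrix are
#' excluded with reason \code{"no_ld_info"}, never silently kept.
#'
#' @param candidates summary-statistic data frame (needs chrom, pos, pval).
#' @param ld an \code{\link{ld_matrix}}.
#' @param r2_max clumping threshold (default 0.001).
#' @param window_kb window in kilobases within which the LD constraint
#'   applies (default 10000).
#' @return an \code{instrument_set}: list with \code{data} (kept rows,
#'   including per-variant \code{r2} and \code{F} when eaf and n present),
#'   \code{excluded} (id + reason), \code{r2_total}.
#' @export
clump <- function(candidates, ld, r2_max = 0.001, window_kb = 10000) {
  ord <- order(candidates$pval, candidates$variant_id)
  cand <- candidates[ord, , drop = FALSE]
  in_ld <- cand$variant_id %in% rownames(ld)
  excluded <- data.frame(variant_id = cand$variant_id[!in_ld],
                         reason = rep("no_ld_info", sum(!in_ld)),
                         stringsAsFactors = FALSE)
  cand <- cand[in_ld, , drop = FALSE]
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in which(kept)) {
      same_chr <- identical(cand$chrom[i], cand$chrom[j])
      within <- same_chr &&
        abs(cand$pos[i] - cand$pos[j]) <= window_kb * 1000
      if (within && ld_r2(ld, cand$variant_id[i], cand$variant_id[j]) > r2_max) {
        ok <- FALSE; break
      }
    }
    kept[i] <- ok
  }
  if (any(!kept)) {
    excluded <- rbind(excluded, data.frame(
      variant_id = cand$variant_id[!kept],
      reason = rep("ld_with_kept", sum(!kept)), stringsAsFactors = FALSE))
  }
  out <- cand[kept, , drop = FALSE]
  rownames(out) <- NULL
  if (all(c("eaf", "n") %in% names(out)) && !anyNA(out$eaf) && !anyNA(out$n)) {
    st <- instrument_strength(out$beta, out$se, out$eaf, out$n)
    out$r2 <- st$r2
    out$F <- st$F
  }
  structure(list(data = out, excluded = excluded,
                 r2_total = if ("r2" %in% names(out)) sum(out$r2) else NA_real_,
                 r2_max = r2_max, window_kb = window_kb),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %d variant(s) after clumping (r2 <= %g, %d kb window)\n",
              nrow(x$data), x$r2_max, x$window_kb))
  if (!is.na(x$r2_total)) {
    cat(sprintf("Variance explained: %.3f%%; F range %.1f-%.1f (mean %.1f)\n",
                100 * x$r2_total, min(x$data$F), max(x$data$F),
                mean(x$data$F)))
  }
  if (nrow(x$excluded)) cat(sprintf("%d excluded\n", nrow(x$excluded)))
  invisible(x)
}

#' Find a proxy variant for an instrument missing from the outcome GWAS
#'
#' Among outcome variants with LD r-squared to the target of at least
#' \code{r2_min}, returns the one with maximal r-squared, or \code{NULL}
#' when none qualifies.
#'
#' @param target variant id absent from \code{outcome_rows}.
#' @param outcome_rows outcome summary-statistic data frame.
#' @param ld an \code{\link{ld_matrix}} covering the target.
#' @param r2_min minimum proxy r-squared (default 0.9).
#' @return list(variant_id, r2) or \code{NULL}.
#' @export
find_proxy <- function(target, outcome_rows, ld, r2_min = 0.9) {
  if (target %in% outcome_rows$variant_id) {
    stop_mrbridge("target is present in the outcome rows; no proxy needed",
                  "mr_misuse")
  }
  avail <- intersect(outcome_rows$variant_id, rownames(ld))
  if (!(target %in% rownames(ld)) || length(avail) == 0) return(NULL)
  r2s <- vapply(avail, function(v) ld_r2(ld, target, v), numeric(1))
  ok <- which(r2s >= r2_min)
  if (length(ok) == 0) return(NULL)
  best <- ok[which.max(r2s[ok])]
  list(variant_id = avail[best], r2 = unname(r2s[best]))
}

#' Per-variant instrument strength
#'
#' Variance explained by one variant in an SD-standardised continuous
#' trait, r2 = 2 * eaf * (1 - eaf) * beta^2, and the corresponding F
#' statistic F = r2 * (n - 2) / (1 - r2). F above 10 conventionally
#' indicates little weak-instrument bias.
#'
#' @param beta,se per-allele effect and standard error (SD units).
#' @param eaf effect-allele frequency in (0, 1).
#' @param n sample size (> 2).
#' @return list(r2, F), vectorised.
#' @export
instrument_strength <- function(beta, se, eaf, n) {
  if (any(eaf <= 0 | eaf >= 1)) {
    stop_mrbridge("eaf must lie strictly inside (0, 1)", "mr_domain_error")
  }
  if (any(n <= 2) || any(se <= 0)) {
    stop_mrbridge("need n > 2 and se > 0", "mr_domain_error")
  }
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  list(r2 = r2, F = r2 * (n - 2) / (1 - r2))
}
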