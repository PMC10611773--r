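#' Canonical summary-statistic columns
#'
#' Every GWAS summary-statistic table in this package is a data frame with
#' the canonical columns \code{variant_id}, \code{chrom}, \code{pos},
#' \code{effect_allele}, \code{other_allele}, \code{eaf}, \code{beta},
#' \code{se}, \code{pval}, \code{n} and (optionally) \code{info}. Effects are
#' per effect-allele copy: SD units for continuous traits, log-odds for
#' binary traits.
#'
#' @name sumstats-format
NULL

SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pval", "n", "info")

#' Column-mapping dialects for summary-statistic files
#'
#' Returns a named character vector mapping canonical column names to the
#' header names used by a given export style. Built-in dialects cover
#' UK-Biobank-style (\code{"ukb"}), FinnGen-style (\code{"finngen"}) and
#' GIANT-style (\code{"giant"}) headers, plus \code{"default"} (canonical
#' names used verbatim). A custom mapping may be supplied as a named vector
#' \code{c(variant_id = "SNP", beta = "b", ...)}.
#'
#' @param name dialect name or a named character vector.
#' @return named character vector, canonical name -> file column name.
#' @export
sumstats_dialect <- function(name = "default") {
  if (is.character(name) && length(name) > 1) {
    if (is.null(names(name))) {
      stop_mrbridge("custom dialect must be a named vector", "mr_config_error")
    }
    return(name)
  }
  switch(name,
    default = stats::setNames(SUMSTATS_COLS, SUMSTATS_COLS),
    ukb = c(variant_id = "rsid", chrom = "chr", pos = "pos",
            effect_allele = "alt", other_allele = "ref", eaf = "af",
            beta = "beta", se = "se", pval = "pval",
            n = "n_complete_samples", info = "info"),
    finngen = c(variant_id = "rsids", chrom = "#chrom", pos = "pos",
                effect_allele = "alt", other_allele = "ref", eaf = "af_alt",
                beta = "beta", se = "sebeta", pval = "pval", n = "n"),
    giant = c(variant_id = "MarkerName", chrom = "Chr", pos = "Pos",
              effect_allele = "Allele1", other_allele = "Allele2",
              eaf = "FreqAllele1", beta = "b", se = "SE", pval = "p",
              n = "N"),
    stop_mrbridge(sprintf("unknown dialect '%s'", name), "mr_config_error")
  )
}

#' Study metadata for one GWAS
#'
#' Holds trait name and type, sample counts and a source label. For binary
#' traits the case and control counts must sum to the total, and the case
#' percentage (100 * cases / total) is carried to two decimals as reported
#' in study tables.
#'
#' @param trait trait name.
#' @param type \code{"continuous"} or \code{"binary"}.
#' @param n_total total sample size.
#' @param n_cases,n_controls case/control counts (binary traits).
#' @param source free-text source label.
#' @return an object of class \code{study_meta}.
#' @export
study_meta <- function(trait, type = c("continuous", "binary"), n_total,
                       n_cases = NA_real_, n_controls = NA_real_,
                       source = "") {
  type <- match.arg(type)
  if (type == "binary") {
    if (is.na(n_cases) || is.na(n_controls)) {
      stop_mrbridge("binary traits require n_cases and n_controls",
                    "mr_config_error")
    }
    if (n_cases + n_controls != n_total) {
      stop_mrbridge("n_cases + n_controls must equal n_total",
                    "mr_config_error")
    }
  }
  structure(list(trait = trait, type = type, n_total = n_total,
                 n_cases = n_cases, n_controls = n_controls,
                 source = source,
                 case_percentage = if (type == "binary")
                   round(100 * n_cases / n_total, 2) else NA_real_),
            class = "study_meta")
}

#' @export
print.study_meta <- function(x, ...) {
  cat(sprintf("Study: %s (%s, %s), n = %s", x$trait, x$type, x$source,
              format(x$n_total, big.mark = ",")))
  if (x$type == "binary") {
    cat(sprintf("; cases = %s (%.2f%%)", format(x$n_cases, big.mark = ","),
                x$case_percentage))
  }
  cat("\n")
  invisible(x)
}

validate_sumstats <- function(df) {
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  if (!"info" %in% names(df)) df$info <- NA_real_
  bad <- character(nrow(df))
  snv <- df$effect_allele %in% names(COMPLEMENT) &
    df$other_allele %in% names(COMPLEMENT)
  bad[!snv] <- "not_biallelic_snv"
  bad[snv & df$effect_allele == df$other_allele] <- "identical_alleles"
  bad[bad == "" & (is.na(df$se) | df$se <= 0)] <- "nonpositive_se"
  bad[bad == "" & (is.na(df$beta) | !is.finite(df$beta))] <- "missing_beta"
  bad[bad == "" & (is.na(df$pval) | df$pval <= 0 | df$pval > 1)] <- "invalid_pval"
  bad[bad == "" & !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)] <- "invalid_eaf"
  bad[bad == "" & !is.na(df$info) & (df$info < 0 | df$info > 1)] <- "invalid_info"
  bad[bad == "" & duplicated(df$variant_id)] <- "duplicate_id"
  kept <- df[bad == "", , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "n_dropped") <- sum(bad != "")
  attr(kept, "drop_log") <- data.frame(
    variant_id = df$variant_id[bad != ""], reason = bad[bad != ""],
    stringsAsFactors = FALSE)
  kept
}

#' Read a GWAS summary-statistic table
#'
#' Reads a delimited text file, renames columns through a dialect mapping
#' (see \code{\link{sumstats_dialect}}), and validates every row against the
#' variant-association invariants (biallelic SNV, distinct uppercase alleles,
#' se > 0, p in (0, 1], frequencies in [0, 1]). Invalid rows are dropped and
#' counted; the drop log is attached as attribute \code{"drop_log"}.
#'
#' @param path file path.
#' @param dialect dialect name or named mapping; see
#'   \code{\link{sumstats_dialect}}.
#' @param delim field delimiter, \code{"\t"} (default) or \code{","}.
#' @return validated data frame of variant associations with attributes
#'   \code{n_dropped} and \code{drop_log}.
#' @export
read_sumstats <- function(path, dialect = "default", delim = "\t") {
  if (!file.exists(path)) {
    stop_mrbridge(sprintf("file not found: %s", path), "mr_config_error")
  }
  if (!delim %in% c("\t", ",")) {
    stop_mrbridge("delimiter must be tab or comma", "mr_config_error")
  }
  map <- sumstats_dialect(dialect)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  mandatory <- setdiff(SUMSTATS_COLS, "info")
  missing_cols <- mandatory[!map[mandatory] %in% names(raw) |
                              is.na(map[mandatory])]
  if (length(missing_cols)) {
    stop_mrbridge(sprintf("mapped column(s) missing from %s: %s", path,
                          paste(missing_cols, collapse = ", ")),
                  "mr_config_error")
  }
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    lapply(stats::setNames(SUMSTATS_COLS, SUMSTATS_COLS),
                           function(cn) {
                             fc <- map[cn]
                             if (!is.na(fc) && fc %in% names(raw)) raw[[fc]]
                             else NA_real_
                           }))
  if (all(is.na(out$info))) {
    message("info column absent; imputation-quality filter treated as pass")
  }
  out <- validate_sumstats(out)
  if (attr(out, "n_dropped") > 0) {
    message(sprintf("read_sumstats: dropped %d invalid row(s) from %s",
                    attr(out, "n_dropped"), basename(path)))
  }
  if (nrow(out) == 0) {
    stop_mrbridge(sprintf("no valid rows in %s", path), "mr_empty_input")
  }
  out
}

#' Construct a harmonised exposure/outcome set directly
#'
#' Low-level constructor used by the harmoniser, the simulator and tests.
#' Rows must already share one effect allele.
#'
#' @param data data frame with at least \code{variant_id},
#'   \code{beta_exposure}, \code{se_exposure}, \code{beta_outcome},
#'   \code{se_outcome}; optionally alleles, \code{eaf}, \code{chrom},
#'   \code{pos}.
#' @param exposure_meta,outcome_meta optional \code{\link{study_meta}}.
#' @param audit optional audit data frame (variant_id, action, reason).
#' @return object of class \code{harmonised_set}.
#' @export
harmonised_set <- function(data, exposure_meta = NULL, outcome_meta = NULL,
                           audit = NULL) {
  need <- c("variant_id", "beta_exposure", "se_exposure", "beta_outcome",
            "se_outcome")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop_mrbridge(paste("harmonised data missing column(s):",
                        paste(miss, collapse = ", ")), "mr_config_error")
  }
  if (any(data$se_exposure <= 0) || any(data$se_outcome <= 0)) {
    stop_mrbridge("standard errors must be positive", "mr_config_error")
  }
  if (is.null(audit)) {
    audit <- data.frame(variant_id = data$variant_id, action = "kept",
                        reason = "", stringsAsFactors = FALSE)
  }
  structure(list(data = data, exposure_meta = exposure_meta,
                 outcome_meta = outcome_meta, audit = audit),
            class = "harmonised_set")
}

#' @export
print.harmonised_set <- function(x, ...) {
  acts <- table(factor(x$audit$action,
                       levels = c("kept", "flipped", "excluded")))
  cat(sprintf(
    "Harmonised set: %d variant pair(s) retained (%d kept as-is, %d flipped, %d excluded)\n",
    nrow(x$data), acts[["kept"]], acts[["flipped"]], acts[["excluded"]]))
  if (!is.null(x$exposure_meta)) cat("Exposure: ", x$exposure_meta$trait, "\n")
  if (!is.null(x$outcome_meta)) cat("Outcome:  ", x$outcome_meta$trait, "\n")
  invisible(x)
}

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns outcome associations to the exposure effect allele for every
#' variant present in both tables. Swapped alleles flip the outcome beta
#' sign and complement its frequency; complementary-strand codings are
#' resolved by allele matching for non-palindromic variants. Palindromic
#' (A/T, C/G) variants are retained only when the exposure minor allele
#' frequency is at most \code{palindrome_maf_max}, with strand inferred by
#' comparing the outcome frequency and its complement against the exposure
#' frequency (closest wins); palindromic variants without an outcome
#' frequency are excluded. Variants with imputation info below
#' \code{info_min} (when info is available) are excluded. Every decision is
#' recorded in the audit log.
#'
#' @param exposure,outcome validated summary-statistic data frames
#'   (see \code{\link{read_sumstats}}).
#' @param palindrome_maf_max retain palindromic variants only up to this
#'   exposure MAF (default 0.4).
#' @param info_min minimum imputation info score (default 0.9).
#' @param exposure_meta,outcome_meta optional \code{\link{study_meta}}.
#' @return a \code{\link{harmonised_set}}.
#' @export
harmonise <- function(exposure, outcome, palindrome_maf_max = 0.4,
                      info_min = 0.9, exposure_meta = NULL,
                      outcome_meta = NULL) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0) {
    stop_mrbridge("no variants shared between exposure and outcome",
                  "mr_no_overlap")
  }
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]
  if (!"info" %in% names(ex)) ex$info <- NA_real_
  if (!"info" %in% names(ou)) ou$info <- NA_real_
  if (!"eaf" %in% names(ou)) ou$eaf <- NA_real_

  n <- length(shared)
  action <- character(n); reason <- character(n)
  by <- numeric(n); sey <- numeric(n); eaf_out <- numeric(n)

  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    low_info <- (!is.na(ex$info[i]) && ex$info[i] < info_min) ||
      (!is.na(ou$info[i]) && ou$info[i] < info_min)
    if (low_info) {
      action[i] <- "excluded"; reason[i] <- "low_info"; next
    }
    pal <- is_palindromic(ea_x, oa_x)
    if (pal) {
      same_pair <- setequal(c(ea_y, oa_y), c(ea_x, oa_x))
      if (!same_pair) {
        action[i] <- "excluded"; reason[i] <- "allele_mismatch"; next
      }
      if (is.na(ex$eaf[i])) {
        action[i] <- "excluded"; reason[i] <- "palindromic_no_eaf"; next
      }
      maf <- min(ex$eaf[i], 1 - ex$eaf[i])
      if (maf > palindrome_maf_max) {
        action[i] <- "excluded"; reason[i] <- "palindromic_high_maf"; next
      }
      if (is.na(ou$eaf[i])) {
        action[i] <- "excluded"; reason[i] <- "palindromic_no_eaf"; next
      }
      # orient by allele label first, then check frequency agreement
      b <- ou$beta[i]; f <- ou$eaf[i]; flipped <- FALSE
      if (ea_y == oa_x) { b <- -b; f <- 1 - f; flipped <- TRUE }
      if (abs(f - ex$eaf[i]) > abs((1 - f) - ex$eaf[i])) {
        b <- -b; f <- 1 - f; flipped <- !flipped
      }
      by[i] <- b; sey[i] <- ou$se[i]; eaf_out[i] <- f
      action[i] <- if (flipped) "flipped" else "kept"
      next
    }
    cea <- complement_allele(ea_y); coa <- complement_allele(oa_y)
    if (ea_y == ea_x && oa_y == oa_x) {
      by[i] <- ou$beta[i]; eaf_out[i] <- ou$eaf[i]; action[i] <- "kept"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      by[i] <- -ou$beta[i]; eaf_out[i] <- 1 - ou$eaf[i]
      action[i] <- "flipped"; reason[i] <- "allele_swap"
    } else if (cea == ea_x && coa == oa_x) {
      by[i] <- ou$beta[i]; eaf_out[i] <- ou$eaf[i]; action[i] <- "kept"
      reason[i] <- "strand_flip"
    } else if (cea == oa_x && coa == ea_x) {
      by[i] <- -ou$beta[i]; eaf_out[i] <- 1 - ou$eaf[i]
      action[i] <- "flipped"; reason[i] <- "strand_and_allele_swap"
    } else {
      action[i] <- "excluded"; reason[i] <- "allele_mismatch"; next
    }
    sey[i] <- ou$se[i]
  }

  keep <- action != "excluded"
  dat <- data.frame(variant_id = shared[keep],
                    chrom = ex$chrom[keep], pos = ex$pos[keep],
                    effect_allele = ex$effect_allele[keep],
                    other_allele = ex$other_allele[keep],
                    eaf = ex$eaf[keep],
                    beta_exposure = ex$beta[keep],
                    se_exposure = ex$se[keep],
                    pval_exposure = ex$pval[keep],
                    beta_outcome = by[keep], se_outcome = sey[keep],
                    eaf_outcome = eaf_out[keep],
                    stringsAsFactors = FALSE)
  rownames(dat) <- NULL
  audit <- data.frame(variant_id = shared, action = action, reason = reason,
                      stringsAsFactors = FALSE)
  harmonised_set(dat, exposure_meta = exposure_meta,
                 outcome_meta = outcome_meta, audit = audit)
}

#' Write a harmonised set as TSV with an audit sidecar
#'
#' @param h a \code{\link{harmonised_set}}.
#' @param path output TSV path; the audit log is written next to it with
#'   suffix \code{.audit.tsv}.
#' @return invisibly, the two paths written.
#' @export
write_harmonised <- function(h, path) {
  utils::write.table(h$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  audit_path <- sub("\\.tsv$", "", path)
  audit_path <- paste0(audit_path, ".audit.tsv")
  utils::write.table(h$audit, audit_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, audit_path))
}
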