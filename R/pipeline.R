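default_thresholds <- function() {
  list(p = 5e-8, fallback = 5e-5, min_count = 13, clump_r2 = 0.001,
       clump_kb = 10000, proxy_r2 = 0.9, palindrome_maf = 0.4,
       info_min = 0.9, exclude_ld_r2 = 0.8)
}

merge_defaults <- function(user, defaults) {
  for (nm in names(defaults)) {
    if (is.null(user[[nm]])) user[[nm]] <- defaults[[nm]]
  }
  user
}

load_side <- function(side) {
  tab <- if (!is.null(side$table)) side$table
  else read_sumstats(side$file, side$dialect %||% "default",
                     side$delim %||% "\t")
  meta <- if (!is.null(side$meta)) {
    if (inherits(side$meta, "study_meta")) side$meta
    else do.call(study_meta, side$meta)
  }
  list(table = tab, meta = meta)
}

align_proxy_row <- function(target_exp_row, proxy_row) {
  # r2 carries no sign, so orient the proxy by allele-frequency agreement
  if (is.na(proxy_row$eaf) || is.na(target_exp_row$eaf)) return(NULL)
  b <- proxy_row$beta; f <- proxy_row$eaf
  if (abs(f - target_exp_row$eaf) > abs((1 - f) - target_exp_row$eaf)) {
    b <- -b; f <- 1 - f
  }
  out <- proxy_row
  out$variant_id <- target_exp_row$variant_id
  out$effect_allele <- target_exp_row$effect_allele
  out$other_allele <- target_exp_row$other_allele
  out$beta <- b; out$eaf <- f
  out
}

run_pair <- function(pair, th, est_cfg, seed) {
  exposure <- load_side(pair$exposure)
  outcome <- load_side(pair$outcome)
  ld <- if (!is.null(pair$ld)) pair$ld
  else if (!is.null(pair$ld_file)) read_ld_matrix(pair$ld_file)
  notes <- character(0)
  if (!is.null(pair$sample_overlap) && pair$sample_overlap > 0) {
    notes <- c(notes, sprintf(
      "exposure and outcome samples overlap (up to %.0f%%); weak-instrument bias may act towards the confounded estimate",
      100 * pair$sample_overlap))
  }

  cand <- select_instruments(exposure$table, th$p, th$fallback, th$min_count)
  threshold_used <- attr(cand, "threshold_used")
  relaxed <- attr(cand, "relaxed")
  if (!is.null(ld)) {
    iset <- clump(cand, ld, th$clump_r2, th$clump_kb)
    instruments <- iset$data
    clump_excluded <- iset$excluded
  } else {
    instruments <- cand
    clump_excluded <- data.frame(variant_id = character(0),
                                 reason = character(0))
    notes <- c(notes, "no LD matrix supplied; candidates treated as independent (no clumping)")
  }

  proxies <- list()
  missing_ids <- setdiff(instruments$variant_id, outcome$table$variant_id)
  if (length(missing_ids) && !is.null(ld)) {
    for (tid in missing_ids) {
      pr <- find_proxy(tid, outcome$table, ld, th$proxy_r2)
      if (is.null(pr)) next
      sub <- align_proxy_row(
        instruments[instruments$variant_id == tid, ][1, ],
        outcome$table[outcome$table$variant_id == pr$variant_id, ][1, ])
      if (is.null(sub)) next
      outcome$table <- rbind(outcome$table, sub)
      proxies[[tid]] <- list(proxy = pr$variant_id, r2 = pr$r2)
    }
  }

  h <- harmonise(instruments, outcome$table,
                 palindrome_maf_max = th$palindrome_maf,
                 info_min = th$info_min,
                 exposure_meta = exposure$meta, outcome_meta = outcome$meta)

  excluded_ids <- character(0)
  if (!is.null(pair$exclude_variants)) {
    excluded_ids <- unlist(pair$exclude_variants)
    if (!is.null(ld)) {
      expand_r2 <- pair$exclude_ld_r2 %||% th$exclude_ld_r2
      for (v in intersect(excluded_ids, rownames(ld))) {
        linked <- rownames(ld)[unclass(ld)[v, ] >= expand_r2]
        excluded_ids <- union(excluded_ids, linked)
      }
    }
    h$data <- h$data[!h$data$variant_id %in% excluded_ids, , drop = FALSE]
  }
  if (nrow(h$data) == 0) {
    stop_mrbridge("no instruments remain after harmonisation/exclusion",
                  "mr_no_instruments")
  }

  fit <- mr_fit(h, n_boot = est_cfg$n_boot, seed = seed,
                bandwidth_factor = est_cfg$bandwidth_factor)
  presso <- tryCatch(
    mr_presso(h, n_sim = est_cfg$presso_n_sim, seed = seed + 1L),
    mrbridge_error = function(e) conditionMessage(e))
  funnel <- if (fit$k >= 2) funnel_table(h) else NULL
  single <- mr_single_snp(h)
  loo <- suppressWarnings(mr_leave_one_out(h))

  pw <- NULL
  if (!is.null(outcome$meta) && outcome$meta$type == "binary" &&
      all(c("r2") %in% names(instruments))) {
    r2_tot <- sum(instruments$r2[instruments$variant_id %in%
                                   h$data$variant_id])
    if (r2_tot > 0) {
      mo <- min_detectable_or(r2_tot, outcome$meta$n_total,
                              outcome$meta$n_cases, outcome$meta$n_controls)
      pw <- data.frame(n_instruments = nrow(h$data),
                       r2_percent = 100 * r2_tot,
                       detectable_or = mo$or_2dp)
    }
  }

  list(label = pair$label, fit = fit, presso = presso, funnel = funnel,
       single_snp = single, loo = loo, power = pw, harmonised = h,
       manifest = list(label = pair$label,
                       threshold_used = threshold_used, relaxed = relaxed,
                       n_candidates = nrow(cand),
                       clump_excluded = clump_excluded,
                       proxies = proxies,
                       exclusion_list = excluded_ids,
                       audit = h$audit, notes = notes))
}

#' Run the full bidirectional MR analysis from a configuration
#'
#' Config-driven orchestration: for every configured exposure/outcome
#' pair — "forward" and "reverse" are just direction labels — the engine
#' selects instruments (with p-value-threshold fallback), LD-clumps them,
#' looks up proxies for instruments missing from the outcome GWAS,
#' harmonises alleles, applies any per-analysis variant exclusion list
#' (with LD-aware expansion), fits all estimators, and runs the
#' heterogeneity/pleiotropy diagnostics. Results are written as TSV tables
#' plus a JSON manifest recording every threshold, seed and per-variant
#' decision; re-running an identical config reproduces the tables
#' byte-identically. A failing pair is recorded and does not abort the
#' other pairs.
#'
#' @param cfg a configuration list, or path to a YAML file. Mandatory:
#'   \code{seed} and \code{pairs} (each pair: \code{label},
#'   \code{exposure}, \code{outcome} given as \code{file}/\code{dialect}
#'   or in-memory \code{table}, optional \code{meta}, \code{ld_file} or
#'   \code{ld}, \code{exclude_variants}, \code{sample_overlap}). Optional:
#'   \code{thresholds}, \code{estimators}
#'   (\code{n_boot}, \code{bandwidth_factor}, \code{presso_n_sim}),
#'   \code{coloc} (\code{exposure}, \code{outcome}, \code{region},
#'   \code{build}, priors), \code{out_dir}.
#' @param out_dir output directory (overrides \code{cfg$out_dir}); when
#'   NULL nothing is written and the bundle is only returned.
#' @return invisibly, the report bundle: per-pair results, coloc result,
#'   manifest, and output paths.
#' @export
run_bidirectional <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  if (is.null(cfg$seed)) {
    stop_mrbridge("config must set a seed", "mr_config_error")
  }
  if (is.null(cfg$pairs) || length(cfg$pairs) == 0) {
    stop_mrbridge("config must define at least one pair", "mr_config_error")
  }
  th <- merge_defaults(cfg$thresholds %||% list(), default_thresholds())
  est_cfg <- merge_defaults(cfg$estimators %||% list(),
                            list(n_boot = 1000, bandwidth_factor = 1,
                                 presso_n_sim = 1000))
  out_dir <- out_dir %||% cfg$out_dir

  results <- list(); errors <- list()
  for (i in seq_along(cfg$pairs)) {
    pair <- cfg$pairs[[i]]
    pair$label <- pair$label %||% paste0("pair_", i)
    res <- tryCatch(run_pair(pair, th, est_cfg, cfg$seed + 1000L * i),
                    mrbridge_error = function(e) e)
    if (inherits(res, "condition")) {
      errors[[pair$label]] <- conditionMessage(res)
    } else {
      results[[pair$label]] <- res
    }
  }

  coloc_res <- NULL
  if (!is.null(cfg$coloc)) {
    cc <- cfg$coloc
    region <- parse_region(cc$region, build = cc$build %||% "hg19")
    ce <- load_side(cc$exposure)$table
    co <- load_side(cc$outcome)$table
    coloc_res <- coloc_pp(extract_region(ce, region),
                          extract_region(co, region),
                          p1 = cc$p1 %||% 1e-4, p2 = cc$p2 %||% 1e-4,
                          p12 = cc$p12 %||% 1e-5,
                          prior_sd_exposure = cc$prior_sd_exposure %||% 0.2,
                          prior_sd_outcome = cc$prior_sd_outcome %||% 0.15)
  }

  bundle <- list(results = results, errors = errors, coloc = coloc_res,
                 thresholds = th, estimators = est_cfg, seed = cfg$seed)
  if (!is.null(out_dir)) {
    bundle$paths <- write_report_bundle(bundle, out_dir)
  }
  invisible(bundle)
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  bind_with_label <- function(field) {
    rows <- lapply(bundle$results, function(r) {
      x <- r[[field]]
      if (is.null(x) || nrow(x) == 0) return(NULL)
      cbind(analysis = r$label, x)
    })
    do.call(rbind, Filter(Negate(is.null), rows))
  }
  wt <- function(df, f) {
    if (is.null(df)) df <- data.frame()
    utils::write.table(df, pth(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  est <- do.call(rbind, lapply(bundle$results, function(r)
    cbind(analysis = r$label, r$fit$estimates,
          or = exp(r$fit$estimates$estimate),
          or_ci_low = exp(r$fit$estimates$ci_low),
          or_ci_high = exp(r$fit$estimates$ci_high))))
  wt(est, "estimates.tsv")

  diag <- do.call(rbind, lapply(bundle$results, function(r) {
    het <- r$fit$heterogeneity
    ei <- r$fit$egger_intercept
    pr <- r$presso
    data.frame(analysis = r$label,
               Q = het$Q %||% NA_real_, df = het$df %||% NA_integer_,
               Q_pval = het$pval %||% NA_real_,
               I2_percent = if (is.null(het)) NA_real_ else 100 * het$I2,
               egger_intercept = ei$intercept %||% NA_real_,
               egger_intercept_se = ei$intercept_se %||% NA_real_,
               egger_intercept_pval = ei$intercept_pval %||% NA_real_,
               presso_global_pval = if (is.character(pr)) NA_real_
                 else pr$global_pval,
               presso_outliers = if (is.character(pr)) pr
                 else paste(pr$outliers, collapse = ","),
               presso_distortion_pval = if (is.character(pr)) NA_real_
                 else pr$distortion_pval)
  }))
  wt(diag, "diagnostics.tsv")
  wt(bind_with_label("single_snp"), "single_snp.tsv")
  wt(bind_with_label("loo"), "loo.tsv")
  wt(bind_with_label("funnel"), "funnel.tsv")
  wt(bind_with_label("power"), "power.tsv")

  if (!is.null(bundle$coloc)) {
    cc <- bundle$coloc
    wt(data.frame(hypothesis = names(cc$pp), pp = as.numeric(cc$pp),
                  n_variants = cc$n_variants, top_variant = cc$top_variant,
                  colocalised = cc$colocalised), "coloc.tsv")
  }

  manifest <- list(seed = bundle$seed, thresholds = bundle$thresholds,
                   estimators = bundle$estimators,
                   pairs = lapply(bundle$results, `[[`, "manifest"),
                   errors = bundle$errors)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list.files(out_dir, full.names = TRUE)
}
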