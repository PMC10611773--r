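# small in-code fixtures shared across test files

make_sumstats <- function(ids, ea, oa, beta, se, eaf = 0.3, pval = NULL,
                          n = 1e5, info = 1, chrom = "1",
                          pos = seq_along(ids) * 1e6) {
  k <- length(ids)
  data.frame(variant_id = ids, chrom = rep_len(chrom, k),
             pos = rep_len(pos, k),
             effect_allele = rep_len(ea, k), other_allele = rep_len(oa, k),
             eaf = rep_len(eaf, k), beta = rep_len(beta, k),
             se = rep_len(se, k),
             pval = if (is.null(pval))
               2 * pnorm(-abs(rep_len(beta, k) / rep_len(se, k)))
             else rep_len(pval, k),
             n = rep_len(n, k), info = rep_len(info, k),
             stringsAsFactors = FALSE)
}

# harmonised-style data frame straight from per-variant effects
make_hdata <- function(bx, by, sex, sey, ids = sprintf("v%02d", seq_along(bx))) {
  data.frame(variant_id = ids, beta_exposure = bx, se_exposure = sex,
             beta_outcome = by, se_outcome = sey, stringsAsFactors = FALSE)
}

write_tsv_fixture <- function(df, file = tempfile(fileext = ".tsv")) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  file
}

random_ld <- function(ids, seed) {
  set.seed(seed)
  k <- length(ids)
  a <- matrix(runif(k * k), k)
  m <- (a + t(a)) / 2
  diag(m) <- 1
  ld_matrix(m, ids = ids)
}
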