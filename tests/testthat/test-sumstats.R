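test_that("read_sumstats round-trips a well-formed table and drops invalid rows", {
  df <- make_sumstats(sprintf("rs%d", 1:5), "A", "G", beta = 0.1, se = 0.01)
  f <- write_tsv_fixture(df)
  got <- read_sumstats(f)
  expect_equal(nrow(got), 5)
  expect_equal(got$variant_id, df$variant_id)
  expect_equal(got$beta, df$beta)

  df_bad <- df
  df_bad$se[2] <- 0              # invariant: se > 0
  df_bad$effect_allele[4] <- "AT" # multi-allelic rejected at read time
  f2 <- write_tsv_fixture(df_bad)
  got2 <- suppressMessages(read_sumstats(f2))
  expect_equal(nrow(got2), 3)
  expect_equal(attr(got2, "n_dropped"), 2)
  log <- attr(got2, "drop_log")
  expect_setequal(log$reason, c("nonpositive_se", "not_biallelic_snv"))
})

test_that("missing mandatory column and zero valid rows raise distinct errors", {
  df <- make_sumstats("rs1", "A", "G", 0.1, 0.01)
  df$beta <- NULL
  f <- write_tsv_fixture(df)
  expect_error(read_sumstats(f), class = "mr_config_error")

  df2 <- make_sumstats(c("rs1", "rs2"), "A", "G", 0.1, se = 0)
  f2 <- write_tsv_fixture(df2)
  expect_error(suppressMessages(read_sumstats(f2)), class = "mr_empty_input")
})

test_that("built-in dialects map export-style headers onto canonical columns", {
  fin <- data.frame(`#chrom` = "1", pos = 100, ref = "G", alt = "A",
                    rsids = "rs1", pval = 1e-9, beta = 0.1, sebeta = 0.01,
                    af_alt = 0.3, n = 250000, check.names = FALSE)
  f <- tempfile(fileext = ".tsv")
  write.table(fin, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- suppressMessages(read_sumstats(f, dialect = "finngen"))
  expect_equal(got$effect_allele, "A")
  expect_equal(got$other_allele, "G")
  expect_equal(got$se, 0.01)
})

test_that("study_meta bookkeeping reproduces published case percentages", {
  snhl <- study_meta("SNHL", "binary", 252719, 19313, 233406, "FinnGen R6")
  nihl <- study_meta("NIHL", "binary", 249936, 655, 249281, "FinnGen R6")
  arhi <- study_meta("ARHI", "binary", 250389, 87056, 163333, "UKB")
  expect_equal(snhl$case_percentage, 7.64)
  expect_equal(nihl$case_percentage, 0.26)
  expect_equal(arhi$case_percentage, 34.77)
  expect_error(study_meta("x", "binary", 100, 10, 80),
               class = "mr_config_error")
})

test_that("harmonise flips swapped alleles and resolves strand codings", {
  ex <- make_sumstats("rs1", "A", "G", beta = 0.05, se = 0.01, eaf = 0.3)
  # same variant coded on the other allele in the outcome
  ou <- make_sumstats("rs1", "G", "A", beta = 0.1, se = 0.02, eaf = 0.7)
  h <- harmonise(ex, ou)
  expect_equal(h$data$beta_outcome, -0.1)
  expect_equal(h$data$eaf_outcome, 0.3)
  expect_equal(h$audit$action, "flipped")

  # complementary-strand coding, same orientation: sign preserved
  ou2 <- make_sumstats("rs1", "T", "C", beta = 0.1, se = 0.02, eaf = 0.3)
  h2 <- harmonise(ex, ou2)
  expect_equal(h2$data$beta_outcome, 0.1)
  expect_equal(h2$audit$action, "kept")

  # complementary strand plus allele swap: sign flipped
  ou3 <- make_sumstats("rs1", "C", "T", beta = 0.1, se = 0.02, eaf = 0.7)
  h3 <- harmonise(ex, ou3)
  expect_equal(h3$data$beta_outcome, -0.1)

  # incompatible alleles are excluded, not guessed
  ou4 <- make_sumstats("rs1", "A", "C", beta = 0.1, se = 0.02)
  expect_equal(nrow(harmonise(ex, ou4)$data), 0)
  ex2 <- rbind(ex, make_sumstats("rs2", "A", "G", 0.04, 0.01))
  ou5 <- rbind(ou4, make_sumstats("rs2", "A", "G", 0.1, 0.02))
  h5 <- harmonise(ex2, ou5)
  expect_equal(h5$audit$reason[h5$audit$variant_id == "rs1"],
               "allele_mismatch")
})

test_that("palindromic variants follow the MAF-0.4 rule and frequency inference", {
  # MAF 0.45 > 0.4: excluded outright
  ex <- make_sumstats("rs1", "A", "T", beta = 0.05, se = 0.01, eaf = 0.45)
  ou <- make_sumstats("rs1", "A", "T", beta = 0.1, se = 0.02, eaf = 0.45)
  h0 <- harmonise(ex, ou)
  expect_equal(nrow(h0$data), 0)
  expect_equal(h0$audit$reason, "palindromic_high_maf")

  # MAF 0.2: frequencies agree -> kept as coded
  ex2 <- make_sumstats("rs1", "A", "T", beta = 0.05, se = 0.01, eaf = 0.2)
  ou2 <- make_sumstats("rs1", "A", "T", beta = 0.1, se = 0.02, eaf = 0.22)
  h2 <- harmonise(ex2, ou2)
  expect_equal(h2$data$beta_outcome, 0.1)

  # outcome frequency nearer the complement -> strand flip (sign flip)
  ou3 <- make_sumstats("rs1", "A", "T", beta = 0.1, se = 0.02, eaf = 0.8)
  h3 <- harmonise(ex2, ou3)
  expect_equal(h3$data$beta_outcome, -0.1)
  expect_equal(h3$audit$action, "flipped")

  # palindromic without an outcome frequency: excluded with reason
  ou4 <- ou2; ou4$eaf <- NA_real_
  ex3 <- rbind(ex2, make_sumstats("rs2", "A", "G", 0.04, 0.01))
  ou5 <- rbind(ou4, make_sumstats("rs2", "A", "G", 0.1, 0.02))
  h5 <- harmonise(ex3, ou5)
  expect_equal(h5$audit$reason[h5$audit$variant_id == "rs1"],
               "palindromic_no_eaf")
})

test_that("low imputation info excludes a variant; absent info passes", {
  ex <- make_sumstats(c("rs1", "rs2"), "A", "G", 0.05, 0.01, info = 1)
  ou <- make_sumstats(c("rs1", "rs2"), "A", "G", 0.1, 0.02,
                      info = c(0.85, 0.95))
  h <- harmonise(ex, ou)
  expect_equal(h$data$variant_id, "rs2")
  expect_equal(h$audit$reason[h$audit$variant_id == "rs1"], "low_info")

  ou$info <- NA_real_
  h2 <- harmonise(ex, ou)
  expect_equal(nrow(h2$data), 2)
})

test_that("harmonisation is idempotent and invariant to strand recoding", {
  set.seed(42)
  k <- 12
  ea <- sample(c("A", "C"), k, TRUE)
  oa <- ifelse(ea == "A", "G", "T")
  ex <- make_sumstats(sprintf("rs%d", 1:k), ea, oa,
                      beta = rnorm(k, 0, 0.05), se = runif(k, 0.005, 0.02),
                      eaf = runif(k, 0.1, 0.9))
  ou <- ex
  ou$beta <- rnorm(k, 0, 0.05)
  ou$se <- runif(k, 0.005, 0.02)
  h1 <- harmonise(ex, ou)

  # idempotence: feed the aligned outcome back through
  ou_aligned <- ou
  ou_aligned$beta <- h1$data$beta_outcome[match(ou$variant_id,
                                                h1$data$variant_id)]
  ou_aligned$eaf <- h1$data$eaf_outcome[match(ou$variant_id,
                                              h1$data$variant_id)]
  h2 <- harmonise(ex, ou_aligned)
  expect_equal(h2$data, h1$data)
  expect_true(all(h2$audit$action == "kept"))

  # flip-invariance: complementary strand plus allele swap in the input
  ou_flip <- ou
  flip <- c(A = "T", C = "G", G = "C", T = "A")
  ou_flip$effect_allele <- unname(flip[ou$other_allele])
  ou_flip$other_allele <- unname(flip[ou$effect_allele])
  ou_flip$beta <- -ou$beta
  ou_flip$eaf <- 1 - ou$eaf
  h3 <- harmonise(ex, ou_flip)
  expect_equal(h3$data$beta_outcome, h1$data$beta_outcome)
  expect_equal(h3$data$eaf_outcome, h1$data$eaf_outcome)
})

test_that("audit log conserves the intersection exactly", {
  set.seed(7)
  ex <- make_sumstats(sprintf("rs%d", 1:20),
                      sample(c("A", "C", "G", "T"), 20, TRUE), "A",
                      beta = rnorm(20, 0, 0.05), se = 0.01,
                      eaf = runif(20, 0.05, 0.95),
                      info = sample(c(0.8, 1), 20, TRUE))
  ex$other_allele <- ifelse(ex$effect_allele == "A", "T", "A")
  ou <- ex[sample(1:20, 15), ]
  ou$beta <- rnorm(15)
  h <- harmonise(ex, ou)
  inter <- length(intersect(ex$variant_id, ou$variant_id))
  expect_equal(nrow(h$audit), inter)
  expect_equal(sum(h$audit$action != "excluded"), nrow(h$data))
  expect_equal(sum(h$audit$action == "excluded") + nrow(h$data), inter)
})

test_that("empty intersection raises a no-overlap error", {
  ex <- make_sumstats("rs1", "A", "G", 0.05, 0.01)
  ou <- make_sumstats("rs9", "A", "G", 0.1, 0.02)
  expect_error(harmonise(ex, ou), class = "mr_no_overlap")
})

test_that("write_harmonised emits the set and its audit sidecar", {
  ex <- make_sumstats(c("rs1", "rs2"), "A", "G", 0.05, 0.01)
  ou <- make_sumstats(c("rs1", "rs2"), "A", "G", 0.1, 0.02)
  h <- harmonise(ex, ou)
  f <- tempfile(fileext = ".tsv")
  paths <- write_harmonised(h, f)
  expect_true(all(file.exists(paths)))
  back <- read.delim(paths[1])
  expect_equal(back$beta_outcome, h$data$beta_outcome)
  audit <- read.delim(paths[2])
  expect_equal(nrow(audit), 2)
})
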