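test_that("config invariants are enforced before sampling", {
  expect_error(cohort_config(n_enrolled = 10, dropout_n = 8, low_dna_n = 2),
               "smaller than n_enrolled")
  expect_error(cohort_config(maf = c(rs1 = 0.6)), "0, 0.5")
  expect_error(cohort_config(t1_t3_corr = 1.4), "-1, 1")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(t1_sd = -2), "positive")
})

test_that("flow accounting follows the configured enrolment flow", {
  co <- generate_cohort(cohort_config(seed = 42))
  acc <- setNames(co$accounting$n, co$accounting$stage)
  expect_equal(acc[["enrolled"]], 239)
  expect_equal(acc[["dropped"]], 53)
  expect_equal(acc[["completed_followup"]], 186)
  expect_equal(acc[["excluded_no_genotype"]], 3)
  expect_equal(acc[["analyzable_pairs"]], 183)
  expect_equal(nrow(co$participants), 183)
  expect_equal(nrow(co$neonates), 183)
  # accounting identity holds for other flows
  co2 <- generate_cohort(cohort_config(seed = 1, n_enrolled = 100,
                                       dropout_n = 20, low_dna_n = 7))
  expect_equal(co2$accounting$n[co2$accounting$stage == "analyzable_pairs"],
               100 - 20 - 7)
})

test_that("identical seed gives bit-identical cohorts; seeds differ", {
  a <- generate_cohort(cohort_config(seed = 77, n_enrolled = 50,
                                     dropout_n = 5, low_dna_n = 1))
  b <- generate_cohort(cohort_config(seed = 77, n_enrolled = 50,
                                     dropout_n = 5, low_dna_n = 1))
  c <- generate_cohort(cohort_config(seed = 78, n_enrolled = 50,
                                     dropout_n = 5, low_dna_n = 1))
  expect_identical(a$participants, b$participants)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$neonates, b$neonates)
  expect_false(identical(a$participants$vitd_t1, c$participants$vitd_t1))
})

test_that("generator leaves the global RNG stream untouched", {
  set.seed(123)
  before <- rnorm(3)
  set.seed(123)
  invisible(generate_cohort(cohort_config(seed = 9, n_enrolled = 30,
                                          dropout_n = 0, low_dna_n = 0)))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("genotypes are drawn under HWE at the configured MAF", {
  co <- generate_cohort(cohort_config(seed = 31, n_enrolled = 5000,
                                      dropout_n = 0, low_dna_n = 0))
  qc <- snp_qc(co)
  expect_true(all(qc$hwe_p > 0.001))
  cfg_maf <- cohort_config()$maf
  expect_true(all(abs(qc$maf - unname(cfg_maf[qc$rsid])) < 0.02))
  # HWE holds across replicate seeds
  pvals <- sapply(1:10, function(s) {
    co <- generate_cohort(cohort_config(seed = 1000 + s, n_enrolled = 2000,
                                        dropout_n = 0, low_dna_n = 0))
    min(snp_qc(co)$hwe_p)
  })
  expect_gte(mean(pvals > 0.001), 0.9)
})

test_that("25(OH)D marginals match the configured calibration", {
  co <- generate_cohort(cohort_config(seed = 8, n_enrolled = 20000,
                                      dropout_n = 0, low_dna_n = 0))
  expect_lt(abs(mean(co$participants$vitd_t1) - 14.00), 0.2)
  expect_lt(abs(sd(co$participants$vitd_t1) - 6.97), 0.3)
  expect_lt(abs(mean(co$participants$vitd_t3) - 21.21), 0.3)
  r <- pearson_cor(co$participants$vitd_t1, co$participants$vitd_t3)
  expect_lt(abs(r$r - 0.425), 0.06)
})

test_that("null construction: no genetic effect when beta and gamma are zero", {
  co <- make_null_cohort(5000, seed = 21, gamma = 0, beta_snp = 0)
  df <- profile_table(co)
  fit <- fit_linear(df$vitd_t3, cbind(grs = df$vitd_grs))
  row <- fit$terms[fit$terms$term == "grs", ]
  expect_lt(abs(row$beta), 3 * row$se)
})

test_that("beta_snp produces the T3 decrement but leaves T1 alone", {
  co <- generate_cohort(cohort_config(seed = 13, n_enrolled = 5000,
                                      dropout_n = 0, low_dna_n = 0))
  df <- profile_table(co)
  t3 <- fit_linear(df$vitd_t3, cbind(grs = df$vitd_grs))
  row3 <- t3$terms[t3$terms$term == "grs", ]
  expect_lt(abs(row3$beta - (-1.8)), 3 * row3$se)
  t1 <- fit_linear(df$vitd_t1, cbind(grs = df$vitd_grs))
  row1 <- t1$terms[t1$terms$term == "grs", ]
  expect_lt(abs(row1$beta), 3 * row1$se)
})

test_that("checkerboard fixture covers the categorical space", {
  fix <- checkerboard_fixture()
  expect_equal(nrow(fix$participants), 12L)
  d <- derive_phenotypes(fix)
  expect_true(all(table(d$vitd_status_t1) >= 1))
  expect_true(all(table(d$vitd_status_t3) >= 1))
  expect_true(all(table(d$birth_weight_cat) >= 1))
  expect_true(all(table(d$birth_length_cat) >= 1))
  expect_true(all(table(d$head_circ_cat) >= 1))
  prof <- grs_profiles(fix)
  expect_equal(sum(prof$complete), 11L)
  comp <- prof[prof$complete, ]
  expect_equal(comp$vitd_grs, comp$synthesis_grs + comp$metabolism_grs)
  # every risk-allele count value appears
  man <- fix$manifest
  counts <- unlist(lapply(seq_len(nrow(man)), function(i) {
    g <- fix$genotypes[fix$genotypes$rsid == man$rsid[i], ]
    count_risk_alleles(g$allele1, g$allele2, man$risk_allele[i])
  }))
  expect_setequal(unique(counts[!is.na(counts)]), 0:2)
  expect_equal(sum(is.na(counts)), 1L)
})
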