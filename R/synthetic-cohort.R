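default_mafs <- c(rs12785878 = 0.28, rs12794714 = 0.35, rs2282679 = 0.25,
                  rs6013897 = 0.18, rs2228570 = 0.39, rs7975232 = 0.33)

#' Generator configuration for synthetic cohorts
#'
#' Defaults emulate the statistical structure of a West Sumatran
#' mother-infant vitamin D cohort: 239 women enrolled, 53 lost to
#' follow-up, 3 completers excluded for low DNA yield (183 analyzable
#' pairs); six biallelic SNPs under HWE with minor allele frequencies
#' between 0.18 and 0.39 (risk allele = minor allele); first-trimester
#' 25(OH)D 14.00 +/- 6.97 ng/mL; third-trimester levels centred at
#' 21.21 +/- 10.16 ng/mL, correlated 0.425 with the first trimester and
#' lowered by `beta_snp` ng/mL per risk allele (centred at the expected
#' allele count so the marginal mean stays at `t3_mean`); newborn
#' outcomes 3204.87 +/- 494.99 g, 48.56 +/- 2.87 cm, 33.89 +/- 2.52 cm,
#' with a configurable GRS x T3-25(OH)D interaction on head circumference
#' (`gamma_interaction`, cm per risk-allele x ng/mL). The default
#' `beta_snp = 1.8` is a calibration chosen so the dichotomized total-GRS
#' group contrast at T3 is about 4.6 ng/mL, not an estimate.
#'
#' @param seed Integer seed; the generator draws all randomness inside a
#'   locally seeded RNG scope (global RNG state untouched).
#' @param n_enrolled,dropout_n,low_dna_n Participant-flow counts; must
#'   satisfy `dropout_n + low_dna_n < n_enrolled`.
#' @param maf Named vector of per-SNP minor-allele frequencies in (0, 0.5].
#' @param beta_snp T3 25(OH)D decrement per risk allele (ng/mL).
#' @param t1_mean,t1_sd,t3_mean,t3_sd Marginal 25(OH)D moments (ng/mL).
#' @param t1_t3_corr Latent T1-T3 correlation in [-1, 1].
#' @param gamma_interaction Head-circumference interaction coefficient
#'   (cm per risk-allele x ng/mL), applied to centred GRS and T3.
#' @param missing_rate Per-call genotype missingness in [0, 1).
#' @param covariates,outcomes,visits Named lists of means/SDs for the
#'   maternal covariates, newborn outcomes and per-visit measurement
#'   pairs; see defaults.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(seed = 42L,
                          n_enrolled = 239L, dropout_n = 53L, low_dna_n = 3L,
                          maf = default_mafs,
                          beta_snp = 1.8,
                          t1_mean = 14.00, t1_sd = 6.97,
                          t3_mean = 21.21, t3_sd = 10.16,
                          t1_t3_corr = 0.425,
                          gamma_interaction = 0.08,
                          missing_rate = 0,
                          covariates = list(
                            age_mean = 29.7, age_sd = 5.68,
                            bmi_mean = 23.45, bmi_sd = 4.56,
                            height_mean = 154.5, height_sd = 5.9,
                            ga_mean = 38.88, ga_sd = 1.91,
                            outdoor_mean = 62, outdoor_sd = 50,
                            supplement_p = 0.35, coastal_p = 0.5),
                          outcomes = list(
                            bw_mean = 3204.87, bw_sd = 494.99,
                            bl_mean = 48.56, bl_sd = 2.87,
                            hc_mean = 33.89, hc_sd = 2.52,
                            male_p = 0.5),
                          visits = list(
                            sbp = c(107.08, 111.51, 10.5),
                            dbp = c(72.86, 76.60, 7.6),
                            weight = c(56.32, 63.93, 11.4),
                            muac = c(27.02, 27.82, 3.8),
                            hb = c(11.58, 11.81, 1.39),
                            corr = 0.6)) {
  cfg <- list(seed = as.integer(seed), n_enrolled = as.integer(n_enrolled),
              dropout_n = as.integer(dropout_n),
              low_dna_n = as.integer(low_dna_n), maf = maf,
              beta_snp = beta_snp, t1_mean = t1_mean, t1_sd = t1_sd,
              t3_mean = t3_mean, t3_sd = t3_sd, t1_t3_corr = t1_t3_corr,
              gamma_interaction = gamma_interaction,
              missing_rate = missing_rate, covariates = covariates,
              outcomes = outcomes, visits = visits)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$dropout_n + cfg$low_dna_n >= cfg$n_enrolled) {
    stop("dropout_n + low_dna_n must be smaller than n_enrolled",
         call. = FALSE)
  }
  if (cfg$dropout_n < 0 || cfg$low_dna_n < 0) {
    stop("flow counts must be non-negative", call. = FALSE)
  }
  if (any(cfg$maf <= 0 | cfg$maf > 0.5)) {
    stop("minor allele frequencies must lie in (0, 0.5]", call. = FALSE)
  }
  sds <- c(cfg$t1_sd, cfg$t3_sd, cfg$covariates$age_sd, cfg$covariates$bmi_sd,
           cfg$outcomes$bw_sd, cfg$outcomes$bl_sd, cfg$outcomes$hc_sd)
  if (any(sds <= 0)) stop("all standard deviations must be positive",
                          call. = FALSE)
  if (abs(cfg$t1_t3_corr) > 1) stop("t1_t3_corr must be in [-1, 1]",
                                    call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' Read a generator configuration from YAML
#'
#' Top-level keys override the corresponding [cohort_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  if ("maf" %in% names(overrides)) overrides$maf <- unlist(overrides$maf)
  do.call(cohort_config, overrides)
}

#' Generate a synthetic mother-infant cohort
#'
#' Draws genotypes per SNP under Hardy-Weinberg equilibrium at the
#' configured minor-allele frequencies, 25(OH)D trajectories with the
#' configured T1-T3 correlation and per-risk-allele T3 decrement, maternal
#' covariates and newborn outcomes at the configured moments, and a
#' head-circumference GRS x T3 interaction; then applies the enrolment ->
#' dropout -> low-DNA-yield exclusion flow uniformly at random. The same
#' seed yields bit-identical output.
#'
#' @param config A `cohort_config`.
#' @param manifest SNP manifest; defaults to the bundled panel. The
#'   configured MAF applies to each SNP's risk allele.
#' @return A `cohort_dataset` (with the generating `config` attached).
#' @export
generate_cohort <- function(config = cohort_config(),
                            manifest = default_manifest()) {
  config <- validate_config(unclass(config))
  manifest <- validate_manifest(manifest)
  maf <- config$maf
  if (is.null(names(maf))) names(maf) <- manifest$rsid
  if (!setequal(names(maf), manifest$rsid)) {
    stop("config$maf names must match the manifest rsIDs", call. = FALSE)
  }
  withr::with_seed(config$seed, generate_cohort_impl(config, manifest, maf))
}

generate_cohort_impl <- function(config, manifest, maf) {
  n <- config$n_enrolled
  ids <- sprintf("S%05d", seq_len(n))

  # genotypes: risk-allele count ~ Binomial(2, maf) is exactly HWE
  counts <- vapply(manifest$rsid,
                   function(snp) stats::rbinom(n, 2L, maf[[snp]]),
                   integer(n))
  if (n == 1L) counts <- matrix(counts, nrow = 1L,
                                dimnames = list(NULL, manifest$rsid))
  grs <- rowSums(counts)
  grs_center <- 2 * sum(maf[manifest$rsid])

  # 25(OH)D trajectories (ng/mL), left-truncated at 0
  z1 <- stats::rnorm(n)
  rho <- config$t1_t3_corr
  z3 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  vitd_t1 <- pmax(0, config$t1_mean + config$t1_sd * z1)
  vitd_t3 <- pmax(0, config$t3_mean + config$t3_sd * z3 -
                    config$beta_snp * (grs - grs_center))

  cv <- config$covariates
  age <- cv$age_mean + cv$age_sd * stats::rnorm(n)
  height <- cv$height_mean + cv$height_sd * stats::rnorm(n)
  prepreg_bmi <- pmax(13, cv$bmi_mean + cv$bmi_sd * stats::rnorm(n))
  prepreg_weight <- prepreg_bmi * (height / 100)^2
  ga <- cv$ga_mean + cv$ga_sd * stats::rnorm(n)
  outdoor <- pmax(0, cv$outdoor_mean + cv$outdoor_sd * stats::rnorm(n))
  supplement <- stats::runif(n) < cv$supplement_p
  geography <- ifelse(stats::runif(n) < cv$coastal_p, "coastal", "mountainous")

  vpair <- function(spec) {
    zc <- stats::rnorm(n)
    r <- config$visits$corr
    t1 <- spec[1] + spec[3] * zc
    t3 <- spec[2] + spec[3] * (r * zc + sqrt(1 - r^2) * stats::rnorm(n))
    list(t1 = t1, t3 = t3)
  }
  sbp <- vpair(config$visits$sbp); dbp <- vpair(config$visits$dbp)
  wt <- vpair(config$visits$weight); mu <- vpair(config$visits$muac)
  hb <- vpair(config$visits$hb)

  oc <- config$outcomes
  sex <- ifelse(stats::runif(n) < oc$male_p, "male", "female")
  birth_weight <- pmax(500, oc$bw_mean + oc$bw_sd * stats::rnorm(n))
  birth_length <- pmax(30, oc$bl_mean + oc$bl_sd * stats::rnorm(n))
  head_circ <- pmax(20, oc$hc_mean + oc$hc_sd * stats::rnorm(n) +
                      config$gamma_interaction * (grs - grs_center) *
                      (vitd_t3 - config$t3_mean))

  participants <- tibble::tibble(
    sample_id = ids, age = age, height = height,
    prepreg_weight = prepreg_weight, prepreg_bmi = prepreg_bmi,
    muac = mu$t1, geography = geography, outdoor_activity = outdoor,
    supplement_use = supplement, vitd_t1 = vitd_t1, vitd_t3 = vitd_t3,
    gestational_age_birth = ga,
    sbp_t1 = sbp$t1, sbp_t3 = sbp$t3, dbp_t1 = dbp$t1, dbp_t3 = dbp$t3,
    weight_t1 = wt$t1, weight_t3 = wt$t3, muac_t1 = mu$t1, muac_t3 = mu$t3,
    hb_t1 = hb$t1, hb_t3 = hb$t3)
  neonates <- tibble::tibble(
    sample_id = ids, sex = sex, birth_weight = birth_weight,
    birth_length = birth_length, head_circumference = head_circ)

  # long genotype table from counts
  geno <- tidyr::pivot_longer(
    tibble::as_tibble(cbind(tibble::tibble(sample_id = ids),
                            tibble::as_tibble(counts))),
    cols = -"sample_id", names_to = "rsid", values_to = "count")
  geno <- dplyr::left_join(
    geno, manifest[c("rsid", "risk_allele", "other_allele")], by = "rsid")
  geno$allele1 <- ifelse(geno$count >= 1, geno$risk_allele, geno$other_allele)
  geno$allele2 <- ifelse(geno$count == 2, geno$risk_allele, geno$other_allele)
  if (config$missing_rate > 0) {
    miss <- stats::runif(nrow(geno)) < config$missing_rate
    geno$allele1[miss] <- NA_character_
    geno$allele2[miss] <- NA_character_
  }
  geno <- geno[c("sample_id", "rsid", "allele1", "allele2")]

  # participant flow: dropout before delivery, then low-DNA exclusion
  dropped <- sample(ids, config$dropout_n)
  completed <- setdiff(ids, dropped)
  low_dna <- sample(completed, config$low_dna_n)

  participants <- participants[participants$sample_id %in% completed, ]
  neonates <- neonates[neonates$sample_id %in% completed, ]
  geno <- geno[geno$sample_id %in% setdiff(completed, low_dna), ]

  cohort <- assemble_cohort(participants, neonates, geno, manifest,
                            n_enrolled = config$n_enrolled,
                            n_dropped = config$dropout_n)
  cohort$config <- validate_config(config)
  cohort
}

#' Deterministic 12-participant test fixture
#'
#' A hand-written miniature cohort covering every risk-allele count, every
#' maternal vitamin D category at both trimesters, both sides of every
#' newborn anthropometry cut-off, one missing genotype call (S012,
#' rs2228570) and one missing third-trimester visit (S011). Eleven of the
#' twelve samples therefore have complete GRS profiles.
#'
#' @return A `cohort_dataset` with 12 analyzable pairs.
#' @export
checkerboard_fixture <- function() {
  manifest <- default_manifest()
  ids <- sprintf("S%03d", 1:12)
  counts <- rbind(
    c(0, 0, 0, 0, 0, 0),
    c(2, 2, 2, 2, 2, 2),
    c(1, 1, 1, 1, 1, 1),
    c(1, 0, 1, 0, 1, 0),
    c(0, 1, 0, 1, 0, 1),
    c(2, 0, 0, 1, 1, 0),
    c(0, 2, 1, 0, 0, 1),
    c(1, 2, 0, 0, 2, 0),
    c(0, 0, 2, 2, 0, 0),
    c(2, 1, 0, 1, 0, 2),
    c(1, 1, 2, 0, 1, 1),
    c(0, 1, 1, 1, NA, 0))
  colnames(counts) <- manifest$rsid
  geno <- tidyr::pivot_longer(
    tibble::as_tibble(cbind(tibble::tibble(sample_id = ids),
                            tibble::as_tibble(counts))),
    cols = -"sample_id", names_to = "rsid", values_to = "count")
  geno <- dplyr::left_join(
    geno, manifest[c("rsid", "risk_allele", "other_allele")], by = "rsid")
  geno$allele1 <- ifelse(geno$count >= 1, geno$risk_allele, geno$other_allele)
  geno$allele2 <- ifelse(geno$count == 2, geno$risk_allele, geno$other_allele)
  geno <- geno[c("sample_id", "rsid", "allele1", "allele2")]

  participants <- tibble::tibble(
    sample_id = ids,
    age = c(24, 28, 31, 35, 22, 29, 33, 27, 30, 26, 38, 32),
    height = c(150, 155, 160, 152, 158, 149, 163, 154, 151, 157, 160, 153),
    prepreg_weight = c(45, 52, 65, 58, 48, 70, 55, 50, 62, 47, 68, 54),
    prepreg_bmi = round(c(45, 52, 65, 58, 48, 70, 55, 50, 62, 47, 68, 54) /
                          (c(150, 155, 160, 152, 158, 149, 163, 154, 151,
                             157, 160, 153) / 100)^2, 2),
    muac = c(24, 26, 28, 25, 23, 30, 27, 26, 29, 24, 31, 27),
    geography = rep(c("coastal", "mountainous"), 6),
    outdoor_activity = c(2, 5, 1, 3, 6, 2, 4, 1, 5, 3, 2, 4),
    supplement_use = rep(c(TRUE, FALSE), 6),
    vitd_t1 = c(5, 13, 25, 8, 15, 22, 11, 19, 30, 6, 14, 21),
    vitd_t3 = c(10, 18, 28, 11, 24, 31, 9, 26, 35, 13, NA, 19),
    gestational_age_birth = c(39, 38, 40, 36, 39, 37, 41, 38, 39, 40, 38, 37),
    sbp_t1 = c(105, 110, 100, 115, 108, 102, 112, 107, 103, 118, 109, 106),
    sbp_t3 = c(110, 113, 104, 118, 112, 108, 115, 109, 108, 121, 113, 110),
    dbp_t1 = c(70, 74, 68, 78, 72, 69, 76, 71, 70, 80, 73, 72),
    dbp_t3 = c(74, 77, 71, 80, 76, 72, 79, 74, 75, 83, 77, 75),
    weight_t1 = c(46, 53, 66, 59, 49, 71, 56, 51, 63, 48, 69, 55),
    weight_t3 = c(54, 61, 74, 66, 57, 79, 64, 58, 71, 55, 77, 62),
    muac_t1 = c(24, 26, 28, 25, 23, 30, 27, 26, 29, 24, 31, 27),
    muac_t3 = c(25, 27, 28.5, 26, 24, 30.5, 27.5, 26.5, 30, 25, 31.5, 27.5),
    hb_t1 = c(11.2, 12.0, 10.8, 11.6, 12.4, 11.0, 11.8, 12.2, 10.9, 11.4,
              12.1, 11.7),
    hb_t3 = c(11.5, 12.1, 11.0, 11.9, 12.5, 11.3, 12.0, 12.3, 11.2, 11.6,
              12.4, 11.9))
  neonates <- tibble::tibble(
    sample_id = ids,
    sex = rep(c("female", "male"), 6),
    birth_weight = c(2400, 3500, 3100, 2450, 3300, 2600, 3900, 2499, 3204.87,
                     2800, 3600, 2550),
    birth_length = c(47, 52, 50, 46, 51, 48, 53, 49.9, 48.56, 50, 52, 47.5),
    head_circumference = c(32, 36, 35, 31.5, 35.5, 33, 37, 34.9, 33.89, 35,
                           36.5, 32.5))
  assemble_cohort(participants, neonates, geno, manifest,
                  n_enrolled = 12L, n_dropped = 0L)
}
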