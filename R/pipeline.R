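#' @importFrom rlang hash
NULL

# Build a numeric covariate matrix from the derived phenotype table.
# Understands the derived names used in the stage defaults: "preterm"
# (gestational age at birth < 37 weeks), "geography" (coastal = 1) and
# "sex" (male = 1); logicals become 0/1.
covariate_matrix <- function(df, covariates) {
  if (length(covariates) == 0L) return(NULL)
  cols <- lapply(covariates, function(nm) {
    if (nm == "preterm") {
      if (!"gestational_age_birth" %in% names(df)) {
        stop("preterm adjustment needs gestational_age_birth", call. = FALSE)
      }
      return(as.numeric(df$gestational_age_birth < 37))
    }
    if (!nm %in% names(df)) {
      stop("covariate not found in dataset: ", nm, call. = FALSE)
    }
    v <- df[[nm]]
    if (nm == "geography") return(as.numeric(v == "coastal"))
    if (nm == "sex") return(as.numeric(v == "male"))
    if (is.logical(v)) return(as.numeric(v))
    as.numeric(v)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

# derived phenotype table joined to GRS profiles
analysis_table <- function(cohort) {
  derived <- derive_phenotypes(cohort)
  prof <- grs_profiles(cohort)
  dplyr::inner_join(derived, prof, by = "sample_id")
}

#' Descriptive comparisons by vitamin D status
#'
#' Table-1-style report: per trimester, means +/- SD of maternal and
#' newborn variables in vitamin D deficient (VDD, 25(OH)D < 12 ng/mL)
#' versus non-deficient (NVD) mothers with pooled two-sample t p-values,
#' plus paired first-versus-third-trimester comparisons (systolic and
#' diastolic blood pressure, body weight, MUAC, haemoglobin). Any
#' comparison with fewer than 3 observations in a group is skipped with a
#' warning.
#'
#' @param cohort A `cohort_dataset`.
#' @return List of tibbles `by_status` and `paired`.
#' @export
stage_descriptives <- function(cohort) {
  df <- analysis_table(cohort)
  by_trimester <- function(tri) {
    status <- df[[paste0("vitd_status_", tri)]]
    vdd <- !is.na(status) & status == "deficient"
    nvd <- !is.na(status) & status != "deficient"
    vars <- c("age", paste0("sbp_", tri), paste0("dbp_", tri), "height",
              paste0("weight_", tri), "prepreg_bmi", paste0("muac_", tri),
              paste0("hb_", tri), "outdoor_activity")
    if (tri == "t3") {
      vars <- c(vars, "birth_weight", "birth_length", "head_circumference",
                "gestational_age_birth")
    }
    vars <- intersect(vars, names(df))
    rows <- lapply(vars, function(v) {
      a <- df[[v]][vdd]; b <- df[[v]][nvd]
      msa <- mean_sd(a); msb <- mean_sd(b)
      ht <- if (msa$n >= 3 && msb$n >= 3) {
        tryCatch(two_sample_t(a, b), error = function(e) NULL)
      } else {
        warning("skipping ", v, " at ", tri, ": group with n < 3",
                call. = FALSE)
        NULL
      }
      tibble::tibble(trimester = tri, variable = v,
                     n_vdd = msa$n, mean_vdd = msa$mean, sd_vdd = msa$sd,
                     n_nvd = msb$n, mean_nvd = msb$mean, sd_nvd = msb$sd,
                     t = ht$t %||% NA_real_, p = ht$p %||% NA_real_)
    })
    dplyr::bind_rows(rows)
  }
  paired_vars <- c("sbp", "dbp", "weight", "muac", "hb")
  paired <- dplyr::bind_rows(lapply(paired_vars, function(v) {
    c1 <- paste0(v, "_t1"); c3 <- paste0(v, "_t3")
    if (!all(c(c1, c3) %in% names(df))) return(NULL)
    ht <- tryCatch(paired_t(df[[c1]], df[[c3]]), error = function(e) {
      warning("paired comparison skipped for ", v, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    keep <- !is.na(df[[c1]]) & !is.na(df[[c3]])
    tibble::tibble(variable = v, n = sum(keep),
                   mean_t1 = mean(df[[c1]][keep]),
                   mean_t3 = mean(df[[c3]][keep]),
                   t = ht$t %||% NA_real_, p = ht$p %||% NA_real_)
  }))
  list(by_status = dplyr::bind_rows(by_trimester("t1"), by_trimester("t3")),
       paired = paired)
}

#' Vitamin D status versus newborn anthropometry
#'
#' Table-2-style report. Grouping uses the third-trimester IOM status (the
#' canonical trimester for status grouping here). For each continuous
#' newborn outcome: means +/- SD per status category, the
#' covariate-adjusted GLM p-value for the status factor (headline, F test
#' of the 2-df factor), and the one-vs-reference logistic p-value for the
#' corresponding binary anthropometry category (labelled separately).
#'
#' @param cohort A `cohort_dataset`.
#' @param covariates Adjustment set; the default mirrors the footnote
#'   convention: age, pre-pregnancy BMI, preterm status, sun exposure
#'   (outdoor activity) and supplement use.
#' @return List with `means` (category x outcome grid) and `models`
#'   (per-outcome adjusted p-values).
#' @export
stage_status_anthro <- function(cohort,
                                covariates = c("age", "prepreg_bmi",
                                               "preterm", "outdoor_activity",
                                               "supplement_use")) {
  df <- analysis_table(cohort)
  status <- df$vitd_status_t3
  outcomes <- c(birth_weight = "birth_weight_cat",
                birth_length = "birth_length_cat",
                head_circumference = "head_circ_cat")
  means <- dplyr::bind_rows(lapply(names(outcomes), function(oc) {
    dplyr::bind_rows(lapply(levels(status), function(lev) {
      x <- df[[oc]][!is.na(status) & status == lev]
      ms <- mean_sd(x)
      tibble::tibble(outcome = oc, status = lev, n = ms$n,
                     mean = ms$mean, sd = ms$sd)
    }))
  }))
  present <- levels(droplevels(status[!is.na(status)]))
  if (length(present) < 2L) {
    warning("fewer than 2 vitamin D status categories present; ",
            "adjusted models skipped", call. = FALSE)
    return(list(means = means, models = tibble::tibble()))
  }
  covm <- covariate_matrix(df, covariates)
  dummies <- vapply(present[-1], function(lev) as.numeric(status == lev),
                    numeric(nrow(df)))
  colnames(dummies) <- paste0("status_", present[-1])
  models <- dplyr::bind_rows(lapply(names(outcomes), function(oc) {
    y <- df[[oc]]
    keep <- if (is.null(covm)) {
      stats::complete.cases(y, dummies)
    } else {
      stats::complete.cases(y, dummies, covm)
    }
    full <- fit_linear(y, cbind(dummies, covm), adjustment_set = covariates)
    reduced <- fit_linear(y[keep],
                          if (is.null(covm)) NULL else
                            covm[keep, , drop = FALSE],
                          adjustment_set = covariates)
    ft <- ftest_nested(full, reduced)
    cat_col <- outcomes[[oc]]
    logi <- tryCatch({
      fits <- fit_multinomial(df[[cat_col]], cbind(dummies, covm),
                              reference = levels(df[[cat_col]])[2],
                              adjustment_set = covariates)
      min(vapply(fits, function(f) {
        min(f$terms$p[grepl("^status_", f$terms$term)])
      }, numeric(1)))
    }, error = function(e) NA_real_)
    tibble::tibble(outcome = oc, n_used = full$n_used,
                   p_glm = ft$p, f_stat = ft$f,
                   p_logistic = logi)
  }))
  list(means = means, models = models)
}

grs_outcomes <- c(vitd_t1 = "25(OH)D T1", vitd_t3 = "25(OH)D T3",
                  delta_25ohd = "Change in 25(OH)D")

#' GRS versus 25(OH)D association report
#'
#' Table-3-style report: for each of the three GRS schemes crossed with
#' the three 25(OH)D outcomes (T1, T3, change), group means +/- SD by the
#' dichotomized score and the covariate-adjusted linear-model p-value for
#' the group contrast. Significance is flagged nominally and against the
#' 9-test Bonferroni family.
#'
#' @param cohort A `cohort_dataset`.
#' @param covariates Adjustment set; default mirrors the footnote
#'   convention: age, BMI, supplement use, sun exposure and geography.
#' @param alpha_family Family-wise alpha (default 0.05).
#' @return A 9-row tibble; the `test_family` used is attached as
#'   attribute `"family"`.
#' @export
stage_grs_association <- function(cohort,
                                  covariates = c("age", "prepreg_bmi",
                                                 "supplement_use",
                                                 "outdoor_activity",
                                                 "geography"),
                                  alpha_family = 0.05) {
  df <- analysis_table(cohort)
  fam <- bonferroni(alpha_family, m = 9, name = "grs_association")
  covm <- covariate_matrix(df, covariates)
  rows <- list()
  for (scheme in grs_schemes) {
    group <- df[[paste0(scheme, "_group")]]
    for (oc in names(grs_outcomes)) {
      y <- df[[oc]]
      lo <- y[!is.na(group) & group == levels(group)[1]]
      hi <- y[!is.na(group) & group == levels(group)[2]]
      mlo <- mean_sd(lo); mhi <- mean_sd(hi)
      fit <- tryCatch(
        fit_linear(y, cbind(grs_group = as.numeric(group) - 1, covm),
                   adjustment_set = covariates),
        error = function(e) NULL)
      beta <- se <- p <- NA_real_; n_used <- NA_integer_
      if (!is.null(fit)) {
        row <- fit$terms[fit$terms$term == "grs_group", ]
        beta <- row$beta; se <- row$se; p <- row$p; n_used <- fit$n_used
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scheme = scheme, outcome = oc,
        group_low = levels(group)[1], n_low = mlo$n,
        mean_low = mlo$mean, sd_low = mlo$sd,
        group_high = levels(group)[2], n_high = mhi$n,
        mean_high = mhi$mean, sd_high = mhi$sd,
        beta = beta, se = se, p = p, n_used = n_used,
        sig_nominal = !is.na(p) & p < alpha_family,
        sig_bonferroni = !is.na(p) & p < fam$threshold)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "family") <- fam
  out
}

interaction_outcomes <- c("birth_weight", "birth_length",
                          "head_circumference")

#' GRS x 25(OH)D interaction report
#'
#' Table-4-style report: the product-term coefficient (beta +/- SE, p) for
#' each of the 3 GRS schemes x 2 exposures (T1, T3 25(OH)D) x 3 newborn
#' outcomes = 18 models, flagged against the 18-test Bonferroni family.
#' A companion stratified display gives mean third-trimester 25(OH)D by
#' total-GRS group within head-circumference strata (small < 35 cm vs
#' normal), with two-sample t p-values.
#'
#' @param cohort A `cohort_dataset`.
#' @param covariates Adjustment set; default: age, pre-pregnancy BMI,
#'   supplement use, gestational age at birth and infant sex.
#' @param grs_coding `"count"` (continuous allele count, default) or
#'   `"group"` (dichotomized, reproducing the stratified display coding).
#' @param alpha_family Family-wise alpha.
#' @return List with `interactions` (18-row tibble, family attached as
#'   attribute) and `stratified` (the companion display).
#' @export
stage_interaction <- function(cohort,
                              covariates = c("age", "prepreg_bmi",
                                             "supplement_use",
                                             "gestational_age_birth", "sex"),
                              grs_coding = c("count", "group"),
                              alpha_family = 0.05) {
  grs_coding <- match.arg(grs_coding)
  df <- analysis_table(cohort)
  fam <- bonferroni(alpha_family, m = 18, name = "grs_interaction")
  covm <- covariate_matrix(df, covariates)
  rows <- list()
  for (scheme in grs_schemes) {
    grs <- if (grs_coding == "count") {
      df[[paste0(scheme, "_grs")]]
    } else {
      df[[paste0(scheme, "_group")]]
    }
    for (expo in c("vitd_t1", "vitd_t3")) {
      for (oc in interaction_outcomes) {
        fit <- tryCatch(
          interaction_fit(df[[oc]], grs, df[[expo]], covariates = covm),
          error = function(e) NULL)
        beta <- se <- p <- NA_real_; n_used <- NA_integer_
        if (!is.null(fit)) {
          beta <- fit$interaction$beta; se <- fit$interaction$se
          p <- fit$interaction$p; n_used <- fit$n_used
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          scheme = scheme, exposure = expo, outcome = oc,
          beta = beta, se = se, p = p, n_used = n_used,
          sig_nominal = !is.na(p) & p < alpha_family,
          sig_bonferroni = !is.na(p) & p < fam$threshold)
      }
    }
  }
  interactions <- dplyr::bind_rows(rows)
  attr(interactions, "family") <- fam

  strat <- dplyr::bind_rows(lapply(levels(df$head_circ_cat), function(hc) {
    sub <- df[!is.na(df$head_circ_cat) & df$head_circ_cat == hc, ]
    lo <- sub$vitd_t3[!is.na(sub$vitd_group) &
                        sub$vitd_group == levels(sub$vitd_group)[1]]
    hi <- sub$vitd_t3[!is.na(sub$vitd_group) &
                        sub$vitd_group == levels(sub$vitd_group)[2]]
    mlo <- mean_sd(lo); mhi <- mean_sd(hi)
    ht <- if (mlo$n >= 3 && mhi$n >= 3) {
      tryCatch(two_sample_t(lo, hi), error = function(e) NULL)
    } else NULL
    tibble::tibble(head_circ_cat = hc,
                   n_low_grs = mlo$n, mean_25ohd_low_grs = mlo$mean,
                   sd_low_grs = mlo$sd,
                   n_high_grs = mhi$n, mean_25ohd_high_grs = mhi$mean,
                   sd_high_grs = mhi$sd,
                   t = ht$t %||% NA_real_, p = ht$p %||% NA_real_)
  }))
  list(interactions = interactions, stratified = strat)
}

#' Per-SNP dominant-model associations
#'
#' Supplementary-style report: for each manifest SNP, risk-allele carriers
#' versus non-carriers (dominant model) against 25(OH)D at T1, T3 and the
#' change score, with covariate-adjusted linear-model p-values.
#' Monomorphic SNPs (all carriers or none) are skipped with a warning.
#'
#' @inheritParams stage_grs_association
#' @return Tibble with one row per SNP x outcome.
#' @export
stage_per_snp <- function(cohort,
                          covariates = c("age", "prepreg_bmi",
                                         "supplement_use",
                                         "outdoor_activity", "geography")) {
  df <- analysis_table(cohort)
  manifest <- cohort$manifest
  covm <- covariate_matrix(df, covariates)
  geno <- cohort$genotypes
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    spec <- manifest[i, ]
    g <- geno[geno$rsid == spec$rsid, ]
    carrier <- stats::setNames(
      dominant_carrier(g$allele1, g$allele2, spec$risk_allele), g$sample_id)
    carr <- carrier[df$sample_id]
    if (length(unique(carr[!is.na(carr)])) < 2L) {
      warning("skipping monomorphic (or all-carrier) SNP ", spec$rsid,
              call. = FALSE)
      next
    }
    for (oc in names(grs_outcomes)) {
      y <- df[[oc]]
      yes <- mean_sd(y[which(carr)]); no <- mean_sd(y[which(!carr)])
      fit <- tryCatch(
        fit_linear(y, cbind(carrier = as.numeric(carr), covm),
                   adjustment_set = covariates),
        error = function(e) NULL)
      row <- if (!is.null(fit)) fit$terms[fit$terms$term == "carrier", ] else NULL
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rsid = spec$rsid, gene = spec$gene, outcome = oc,
        n_carrier = yes$n, mean_carrier = yes$mean, sd_carrier = yes$sd,
        n_noncarrier = no$n, mean_noncarrier = no$mean, sd_noncarrier = no$sd,
        beta = row$beta %||% NA_real_, se = row$se %||% NA_real_,
        p = row$p %||% NA_real_)
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a cohort, runs QC and every report stage, and
#' writes TSV reports plus a JSON run manifest (package version, seed,
#' config hash, per-stage row counts and the Bonferroni families) to the
#' output directory. Reruns with the same seed and inputs are
#' byte-identical.
#'
#' @param x A `cohort_config` (the cohort is generated) or a
#'   `cohort_dataset`.
#' @param out_dir Output directory.
#' @return Invisibly, a named list of the stage results.
#' @export
run_all <- function(x, out_dir) {
  if (inherits(x, "cohort_config")) {
    cohort <- generate_cohort(x)
  } else if (inherits(x, "cohort_dataset")) {
    cohort <- x
  } else {
    stop("x must be a cohort_config or cohort_dataset", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  qc <- snp_qc(cohort)
  desc <- stage_descriptives(cohort)
  status_anthro <- stage_status_anthro(cohort)
  assoc <- stage_grs_association(cohort)
  inter <- stage_interaction(cohort)
  per_snp <- stage_per_snp(cohort)

  wt <- function(df, name) {
    readr::write_tsv(df, file.path(out_dir, name), progress = FALSE)
  }
  wt(cohort$accounting, "accounting.tsv")
  wt(qc, "snp_qc.tsv")
  wt(desc$by_status, "descriptives_by_status.tsv")
  wt(desc$paired, "descriptives_paired.tsv")
  wt(status_anthro$means, "status_anthro_means.tsv")
  if (nrow(status_anthro$models) > 0) {
    wt(status_anthro$models, "status_anthro_models.tsv")
  }
  wt(assoc, "grs_association.tsv")
  wt(inter$interactions, "grs_interaction.tsv")
  wt(inter$stratified, "interaction_stratified_25ohd.tsv")
  wt(per_snp, "per_snp_dominant.tsv")

  seed <- if (!is.null(cohort$config)) cohort$config$seed else NA
  manifest <- list(
    package = "vitdgrs",
    version = as.character(utils::packageVersion("vitdgrs")),
    seed = seed,
    config_hash = if (!is.null(cohort$config)) rlang::hash(cohort$config) else NA,
    accounting = stats::setNames(as.list(cohort$accounting$n),
                                 cohort$accounting$stage),
    families = list(
      association = unclass(attr(assoc, "family")),
      interaction = unclass(attr(inter$interactions, "family"))),
    stage_rows = list(
      snp_qc = nrow(qc),
      descriptives_by_status = nrow(desc$by_status),
      grs_association = nrow(assoc),
      grs_interaction = nrow(inter$interactions),
      per_snp = nrow(per_snp)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, qc = qc, descriptives = desc,
                 status_anthro = status_anthro, association = assoc,
                 interaction = inter, per_snp = per_snp))
}
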