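#' Count risk alleles in a genotype
#'
#' @param allele1,allele2 Character vectors of alleles (one call per
#'   element); `NA` pairs are missing calls.
#' @param risk_allele The 25(OH)D-lowering allele for this SNP (scalar).
#' @return Integer vector in `{0, 1, 2}`; `NA` for missing calls.
#' @examples
#' count_risk_alleles(c("A", "A", "G"), c("A", "G", "G"), "A")
#' @export
count_risk_alleles <- function(allele1, allele2, risk_allele) {
  stopifnot(length(risk_allele) == 1L)
  out <- (allele1 == risk_allele) + (allele2 == risk_allele)
  out[is.na(allele1) | is.na(allele2)] <- NA_integer_
  as.integer(out)
}

#' Dominant-model carrier status
#'
#' Carrier = at least one copy of the risk allele (the dominant genetic
#' model contrasts carriers against homozygous non-carriers).
#'
#' @inheritParams count_risk_alleles
#' @return Logical vector; `NA` for missing calls.
#' @export
dominant_carrier <- function(allele1, allele2, risk_allele) {
  count_risk_alleles(allele1, allele2, risk_allele) >= 1L
}

#' Minor allele frequency at one SNP
#'
#' Frequency of the rarer allele among called alleles; by construction in
#' `[0, 0.5]` and invariant to which allele label is counted.
#'
#' @inheritParams count_risk_alleles
#' @return A proportion in `[0, 0.5]`.
#' @export
compute_maf <- function(allele1, allele2) {
  alleles <- c(allele1, allele2)
  alleles <- alleles[!is.na(alleles)]
  if (length(alleles) == 0L) stop("no called genotypes", call. = FALSE)
  counts <- table(alleles)
  if (length(counts) > 2L) {
    stop("more than two alleles observed: ",
         paste(names(counts), collapse = ", "), call. = FALSE)
  }
  if (length(counts) == 1L) return(0)
  min(counts) / sum(counts)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson 1-df chi-square comparing observed genotype counts against the
#' expectations `(p^2 n, 2pq n, q^2 n)` under the allele frequency `p`
#' estimated from the same counts. A monomorphic SNP has nothing to test:
#' by convention it returns `chi2 = 0, p = 1` (flagged in QC output rather
#' than erroring, so a QC sweep never divides by zero).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (any consistent allele labelling).
#' @return List with `chi2` and `p` (upper-tail, 1 df).
#' @examples
#' hwe_test(30, 40, 30) # chi2 = 4
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotype", call. = FALSE)
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) {
    return(list(chi2 = 0, p = 1))
  }
  expected <- c(p^2, 2 * p * q, q^2) * n
  observed <- c(n_AA, n_Aa, n_aa)
  chi2 <- sum((observed - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Per-SNP quality control report
#'
#' Call rate, minor allele frequency and the HWE chi-square for every
#' manifest SNP, with a pass flag at the chosen HWE alpha. Monomorphic
#' SNPs are flagged.
#'
#' @param genotypes Long genotype tibble (see [read_genotypes()]), or a
#'   `cohort_dataset`.
#' @param manifest SNP manifest; taken from the cohort when omitted.
#' @param alpha HWE significance level for the pass flag (default 0.05).
#' @return Tibble: `rsid`, `n_called`, `maf`, `hwe_chi2`, `hwe_p`,
#'   `monomorphic`, `pass`.
#' @export
snp_qc <- function(genotypes, manifest = NULL, alpha = 0.05) {
  if (inherits(genotypes, "cohort_dataset")) {
    manifest <- manifest %||% genotypes$manifest
    genotypes <- genotypes$genotypes
  }
  manifest <- validate_manifest(manifest)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    spec <- manifest[i, ]
    g <- genotypes[genotypes$rsid == spec$rsid, ]
    called <- !is.na(g$allele1) & !is.na(g$allele2)
    g <- g[called, ]
    n_called <- nrow(g)
    if (n_called == 0L) {
      return(tibble::tibble(rsid = spec$rsid, n_called = 0L, maf = NA_real_,
                            hwe_chi2 = NA_real_, hwe_p = NA_real_,
                            monomorphic = NA, pass = FALSE))
    }
    counts <- table(factor(count_risk_alleles(g$allele1, g$allele2,
                                              spec$risk_allele),
                           levels = 0:2))
    hw <- hwe_test(counts[["2"]], counts[["1"]], counts[["0"]])
    maf <- compute_maf(g$allele1, g$allele2)
    tibble::tibble(rsid = spec$rsid, n_called = n_called, maf = maf,
                   hwe_chi2 = hw$chi2, hwe_p = hw$p,
                   monomorphic = maf == 0, pass = hw$p > alpha)
  })
  dplyr::bind_rows(rows)
}

grs_schemes <- c("vitd", "synthesis", "metabolism")

scheme_snps <- function(manifest, scheme) {
  scheme <- match.arg(scheme, grs_schemes)
  switch(scheme,
         vitd = manifest$rsid,
         synthesis = manifest$rsid[manifest$group == "synthesis"],
         metabolism = manifest$rsid[manifest$group == "metabolism"])
}

#' Build an unweighted genetic risk score
#'
#' Sum of risk-allele counts over the scheme's SNPs: all six (`"vitd"`),
#' the two synthesis-pathway SNPs (`"synthesis"`), or the four
#' metabolism-pathway SNPs (`"metabolism"`). Complete-case: a missing
#' constituent genotype makes the score missing (the cohort convention is
#' per-analysis complete-case, with no dosage imputation).
#'
#' @param counts Named integer vector of risk-allele counts, names = rsIDs.
#' @param manifest SNP manifest.
#' @param scheme One of `"vitd"`, `"synthesis"`, `"metabolism"`.
#' @return Integer score, or `NA` if any constituent is missing.
#' @export
build_grs <- function(counts, manifest, scheme = "vitd") {
  snps <- scheme_snps(manifest, scheme)
  vals <- counts[snps]
  if (length(vals) != length(snps) || anyNA(vals)) return(NA_integer_)
  as.integer(sum(vals))
}

#' Dichotomize a genetic risk score
#'
#' Cut-points follow the cohort's reporting convention: total score
#' `<=3` vs `>=4`; synthesis score `<2` vs `>=2`; metabolism score `<=3`
#' vs `>=4`. The two groups partition every attainable score.
#'
#' @param score Integer score(s) from [build_grs()].
#' @param scheme One of `"vitd"`, `"synthesis"`, `"metabolism"`.
#' @return Factor with the two group labels; `NA` stays `NA`.
#' @export
dichotomize_grs <- function(score, scheme = "vitd") {
  scheme <- match.arg(scheme, grs_schemes)
  labels <- switch(scheme,
                   vitd = c("<=3", ">=4"),
                   synthesis = c("<2", ">=2"),
                   metabolism = c("<=3", ">=4"))
  cut_at <- switch(scheme, vitd = 4L, synthesis = 2L, metabolism = 4L)
  factor(ifelse(is.na(score), NA_character_,
                ifelse(score >= cut_at, labels[2], labels[1])),
         levels = labels)
}

#' Per-sample GRS profiles
#'
#' Risk-allele counts, all three scores, their dichotomized groups, and a
#' completeness flag for every genotyped sample. For complete profiles the
#' total score is the sum of the synthesis and metabolism scores (the two
#' pathway groups partition the panel).
#'
#' @param genotypes Long genotype tibble or a `cohort_dataset`.
#' @param manifest SNP manifest; taken from the cohort when omitted.
#' @return Tibble: `sample_id`, `vitd_grs`, `synthesis_grs`,
#'   `metabolism_grs`, `vitd_group`, `synthesis_group`, `metabolism_group`,
#'   `complete`.
#' @export
grs_profiles <- function(genotypes, manifest = NULL) {
  if (inherits(genotypes, "cohort_dataset")) {
    manifest <- manifest %||% genotypes$manifest
    genotypes <- genotypes$genotypes
  }
  manifest <- validate_manifest(manifest)
  geno <- dplyr::left_join(genotypes, manifest[c("rsid", "risk_allele")],
                           by = "rsid")
  # risk allele differs by SNP, so count per row rather than per call
  geno$count <- as.integer((geno$allele1 == geno$risk_allele) +
                             (geno$allele2 == geno$risk_allele))
  wide <- tidyr::pivot_wider(geno[c("sample_id", "rsid", "count")],
                             names_from = "rsid", values_from = "count")
  # samples may lack rows for some SNPs entirely
  for (snp in setdiff(manifest$rsid, names(wide))) wide[[snp]] <- NA_integer_
  prof <- tibble::tibble(
    sample_id = wide$sample_id,
    vitd_grs = apply_grs(wide, manifest, "vitd"),
    synthesis_grs = apply_grs(wide, manifest, "synthesis"),
    metabolism_grs = apply_grs(wide, manifest, "metabolism"))
  prof$vitd_group <- dichotomize_grs(prof$vitd_grs, "vitd")
  prof$synthesis_group <- dichotomize_grs(prof$synthesis_grs, "synthesis")
  prof$metabolism_group <- dichotomize_grs(prof$metabolism_grs, "metabolism")
  prof$complete <- !is.na(prof$vitd_grs)
  prof
}

apply_grs <- function(wide, manifest, scheme) {
  snps <- scheme_snps(manifest, scheme)
  m <- as.matrix(wide[snps])
  out <- rowSums(m)
  as.integer(out)
}
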