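#' Read genotype calls
#'
#' The canonical genotype format is a long TSV with header
#' `sample_id  rsid  allele1  allele2`, one row per sample x SNP call --
#' the natural shape for per-SNP assay output (e.g. KASP). A minimal VCF
#' adapter (files ending `.vcf`) reads biallelic records restricted to the
#' manifest rsIDs, using only the GT field.
#'
#' Alleles are validated against the manifest: a call carrying an allele
#' that is neither the risk nor the other allele of its SNP is recorded as
#' missing, with a warning. Rows for SNPs absent from the manifest are
#' dropped with a warning. Samples with no valid manifest call at all are
#' excluded with a warning. Missing calls are `NA`/`NA`; nulls propagate --
#' there is no imputation anywhere in this package.
#'
#' @param path Path to a genotype TSV or VCF file.
#' @param manifest SNP manifest, as from [read_manifest()].
#' @return A tibble with columns `sample_id`, `rsid`, `allele1`, `allele2`
#'   (alleles `NA` for missing calls), one row per sample x manifest SNP
#'   actually observed in the file.
#' @export
read_genotypes <- function(path, manifest) {
  if (!file.exists(path)) stop("genotype file not found: ", path, call. = FALSE)
  manifest <- validate_manifest(manifest)
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    geno <- read_genotypes_vcf(path, manifest)
  } else {
    geno <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                            progress = FALSE)
    required <- c("sample_id", "rsid", "allele1", "allele2")
    if (!all(required %in% names(geno))) {
      stop("genotype TSV must have columns: ",
           paste(required, collapse = ", "), call. = FALSE)
    }
    geno <- geno[required]
  }
  validate_genotypes(geno, manifest)
}

read_genotypes_vcf <- function(path, manifest) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  keep <- fix$ID %in% manifest$rsid
  if (!any(keep)) stop("VCF contains no manifest SNPs", call. = FALSE)
  out <- vector("list", sum(keep))
  rows <- which(keep)
  for (i in seq_along(rows)) {
    r <- rows[i]
    alleles <- c(fix$REF[r], fix$ALT[r])
    calls <- gt[r, , drop = TRUE]
    split_gt <- strsplit(calls, "[/|]")
    a1 <- vapply(split_gt, function(g) {
      if (length(g) < 1L || is.na(g[1]) || g[1] == ".") NA_character_
      else alleles[as.integer(g[1]) + 1L]
    }, character(1))
    a2 <- vapply(split_gt, function(g) {
      if (length(g) < 2L || is.na(g[2]) || g[2] == ".") NA_character_
      else alleles[as.integer(g[2]) + 1L]
    }, character(1))
    out[[i]] <- tibble::tibble(sample_id = colnames(gt), rsid = fix$ID[r],
                               allele1 = unname(a1), allele2 = unname(a2))
  }
  dplyr::bind_rows(out)
}

validate_genotypes <- function(geno, manifest) {
  unknown_snp <- !geno$rsid %in% manifest$rsid
  if (any(unknown_snp)) {
    warning("dropping ", sum(unknown_snp), " genotype rows for SNPs not in manifest: ",
            paste(unique(geno$rsid[unknown_snp]), collapse = ", "), call. = FALSE)
    geno <- geno[!unknown_snp, , drop = FALSE]
  }
  if (nrow(geno) == 0L) stop("no genotypes at manifest SNPs", call. = FALSE)
  dup <- duplicated(geno[c("sample_id", "rsid")])
  if (any(dup)) {
    stop("duplicate genotype call for sample/SNP pair(s): ",
         paste(utils::head(paste(geno$sample_id[dup], geno$rsid[dup]), 5),
               collapse = "; "), call. = FALSE)
  }
  allowed <- stats::setNames(
    lapply(seq_len(nrow(manifest)),
           function(i) c(manifest$risk_allele[i], manifest$other_allele[i])),
    manifest$rsid)
  ok <- vapply(seq_len(nrow(geno)), function(i) {
    al <- allowed[[geno$rsid[i]]]
    a1 <- geno$allele1[i]; a2 <- geno$allele2[i]
    (is.na(a1) && is.na(a2)) || (!is.na(a1) && !is.na(a2) && a1 %in% al && a2 %in% al)
  }, logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " genotype call(s) carry alleles outside the manifest ",
            "for their SNP; recorded as missing", call. = FALSE)
    geno$allele1[!ok] <- NA_character_
    geno$allele2[!ok] <- NA_character_
  }
  called_per_sample <- stats::aggregate(
    !is.na(geno$allele1), by = list(sample_id = geno$sample_id), FUN = sum)
  none <- called_per_sample$sample_id[called_per_sample$x == 0L]
  if (length(none) > 0L) {
    warning("excluding ", length(none),
            " sample(s) with zero called manifest SNPs: ",
            paste(utils::head(none, 5), collapse = ", "), call. = FALSE)
    geno <- geno[!geno$sample_id %in% none, , drop = FALSE]
  }
  tibble::as_tibble(geno)
}

# Maternal phenotype columns; visit-pair columns (x_t1/x_t3) are optional
# but used by the descriptive stage when present.
pheno_numeric_cols <- c(
  "age", "height", "prepreg_weight", "prepreg_bmi", "muac",
  "outdoor_activity", "vitd_t1", "vitd_t3", "gestational_age_birth",
  "sbp_t1", "sbp_t3", "dbp_t1", "dbp_t3", "weight_t1", "weight_t3",
  "muac_t1", "muac_t3", "hb_t1", "hb_t3")
neonate_cols <- c("birth_weight", "birth_length", "head_circumference")

#' Read the phenotype table
#'
#' One CSV row per mother, with neonatal outcome columns on the same row.
#' Documented header (units follow the cohort conventions): `sample_id`,
#' `age` (years), `height` (cm), `prepreg_weight` (kg), `prepreg_bmi`
#' (kg/m^2), `muac` (cm), `geography` (`mountainous`/`coastal`),
#' `outdoor_activity` (hours/day), `supplement_use` (logical),
#' `vitd_t1`/`vitd_t3` (serum 25(OH)D, ng/mL), `gestational_age_birth`
#' (weeks), `sex`, `birth_weight` (g), `birth_length` (cm),
#' `head_circumference` (cm), plus optional per-visit pairs
#' (`sbp_t1`/`sbp_t3` mmHg, `weight_t1`/`weight_t3` kg, `muac_t1`/`muac_t3`
#' cm, `hb_t1`/`hb_t3` g/dL). Missing numeric cells become `NA`, never 0.
#' Negative 25(OH)D or anthropometry values are a hard error.
#'
#' @param path Path to the phenotype CSV.
#' @return A list with elements `participants` (maternal tibble) and
#'   `neonates` (tibble `sample_id`, `sex`, `birth_weight`, `birth_length`,
#'   `head_circumference` for rows with any outcome recorded).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("phenotype CSV must have a sample_id column", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in phenotype file", call. = FALSE)
  }
  num_cols <- intersect(c(pheno_numeric_cols, neonate_cols), names(df))
  for (col in num_cols) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  if ("supplement_use" %in% names(df)) {
    df$supplement_use <- as.logical(df$supplement_use)
  }
  for (col in intersect(c("vitd_t1", "vitd_t3", neonate_cols), names(df))) {
    bad <- !is.na(df[[col]]) & df[[col]] < 0
    if (any(bad)) {
      stop("negative ", col, " for sample(s): ",
           paste(df$sample_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  participants <- df[setdiff(names(df), c(neonate_cols, "sex"))]
  neo_present <- intersect(neonate_cols, names(df))
  has_neo <- if (length(neo_present) > 0L) {
    rowSums(!is.na(df[neo_present])) > 0
  } else rep(FALSE, nrow(df))
  neonates <- df[has_neo, intersect(c("sample_id", "sex", neonate_cols), names(df))]
  list(participants = tibble::as_tibble(participants),
       neonates = tibble::as_tibble(neonates))
}

#' Assemble the joined analysis dataset
#'
#' Inner-joins mothers, neonates and genotyped samples on `sample_id` and
#' produces the participant-flow accounting (enrolled, dropped, completed,
#' excluded for low DNA yield / no genotypes, analyzable). The join never
#' fabricates records: the analyzable count is at most the smallest of the
#' three input sets.
#'
#' @param participants Maternal tibble (see [read_phenotypes()]).
#' @param neonates Neonatal tibble.
#' @param genotypes Long genotype tibble (see [read_genotypes()]).
#' @param manifest SNP manifest.
#' @param n_enrolled,n_dropped Optional enrolment-flow counts for the
#'   accounting report when the phenotype table only holds completers;
#'   default to the numbers implied by the inputs (enrolled = mothers
#'   present, dropped = 0).
#' @return A `cohort_dataset`: list with `participants`, `neonates`,
#'   `genotypes`, `manifest` and an `accounting` tibble.
#' @export
assemble_cohort <- function(participants, neonates, genotypes, manifest,
                            n_enrolled = NULL, n_dropped = NULL) {
  manifest <- validate_manifest(manifest)
  if (anyDuplicated(participants$sample_id)) {
    stop("duplicate sample_id among participants", call. = FALSE)
  }
  if (anyDuplicated(neonates$sample_id)) {
    stop("duplicate sample_id among neonates", call. = FALSE)
  }
  geno_ids <- unique(genotypes$sample_id)
  ids <- intersect(intersect(participants$sample_id, neonates$sample_id),
                   geno_ids)
  if (length(ids) == 0L) {
    warning("no sample_id is shared by mothers, neonates and genotypes; ",
            "0 analyzable pairs", call. = FALSE)
  }
  completed <- intersect(participants$sample_id, neonates$sample_id)
  n_enrolled <- n_enrolled %||% (nrow(participants) + (n_dropped %||% 0L))
  n_dropped <- n_dropped %||% (n_enrolled - nrow(participants))
  accounting <- tibble::tibble(
    stage = c("enrolled", "dropped", "completed_followup",
              "excluded_no_genotype", "analyzable_pairs"),
    n = c(n_enrolled, n_dropped, length(completed),
          length(setdiff(completed, geno_ids)), length(ids)))
  structure(
    list(participants = participants[participants$sample_id %in% ids, ],
         neonates = neonates[neonates$sample_id %in% ids, ],
         genotypes = genotypes[genotypes$sample_id %in% ids, ],
         manifest = manifest,
         accounting = accounting),
    class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  n <- x$accounting$n[x$accounting$stage == "analyzable_pairs"]
  cat("<cohort_dataset> ", n, " analyzable mother-infant pairs, ",
      nrow(x$manifest), " SNPs\n", sep = "")
  print(x$accounting)
  invisible(x)
}

#' Write a cohort dataset to disk
#'
#' Writes the genotype TSV, phenotype CSV and manifest TSV in the formats
#' [read_genotypes()], [read_phenotypes()] and [read_manifest()] accept, so
#' synthetic and real data travel through the identical path.
#'
#' @param cohort A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(manifest = file.path(dir, "snp_manifest.tsv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             phenotypes = file.path(dir, "phenotypes.csv"))
  readr::write_tsv(cohort$manifest, paths["manifest"], progress = FALSE)
  readr::write_tsv(cohort$genotypes, paths["genotypes"], progress = FALSE)
  pheno <- dplyr::left_join(
    cohort$participants,
    cohort$neonates[intersect(c("sample_id", "sex", neonate_cols),
                              names(cohort$neonates))],
    by = "sample_id")
  readr::write_csv(pheno, paths["phenotypes"], progress = FALSE)
  invisible(paths)
}

#' Read a cohort dataset written by [write_cohort()]
#'
#' @param dir Directory holding `snp_manifest.tsv`, `genotypes.tsv` and
#'   `phenotypes.csv`.
#' @inheritParams assemble_cohort
#' @return A `cohort_dataset`.
#' @export
read_cohort <- function(dir, n_enrolled = NULL, n_dropped = NULL) {
  manifest <- read_manifest(file.path(dir, "snp_manifest.tsv"))
  genotypes <- read_genotypes(file.path(dir, "genotypes.tsv"), manifest)
  pheno <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  assemble_cohort(pheno$participants, pheno$neonates, genotypes, manifest,
                  n_enrolled = n_enrolled, n_dropped = n_dropped)
}
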