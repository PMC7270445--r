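#' Read a SNP manifest
#'
#' The manifest is the single source of truth for the SNP panel: which
#' variants enter the risk scores, which allele of each is the
#' 25(OH)D-lowering ("risk") allele, and whether the gene acts in vitamin D
#' synthesis or metabolism. The pipeline refuses to run without explicit
#' risk alleles, so swapping a risk-allele convention is a configuration
#' change, never a code change.
#'
#' Accepted formats:
#' * TSV with header columns `rsid`, `gene`, `risk_allele`, `other_allele`,
#'   `group`;
#' * YAML: a list of records with the same fields (files ending in
#'   `.yml`/`.yaml`).
#'
#' @param path Path to a manifest file. `NULL` (default) loads the bundled
#'   six-SNP vitamin D panel (DHCR7 rs12785878, CYP2R1 rs12794714,
#'   GC rs2282679, CYP24A1 rs6013897, VDR rs2228570 and rs7975232).
#' @return A tibble with one row per SNP and columns `rsid`, `gene`,
#'   `risk_allele`, `other_allele`, `group` (`"synthesis"` or
#'   `"metabolism"`).
#' @examples
#' man <- read_manifest()
#' table(man$group)
#' @export
read_manifest <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "snp_manifest.tsv", package = "vitdgrs",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("manifest file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    if (length(recs) == 0L) stop("manifest is empty: ", path, call. = FALSE)
    man <- dplyr::bind_rows(lapply(recs, tibble::as_tibble))
  } else {
    man <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  }
  validate_manifest(man)
}

validate_manifest <- function(man) {
  required <- c("rsid", "gene", "risk_allele", "other_allele", "group")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols) > 0L) {
    stop("manifest is missing required fields: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  man <- tibble::as_tibble(man)[required]
  if (nrow(man) == 0L) stop("manifest contains no SNPs", call. = FALSE)
  if (anyDuplicated(man$rsid)) {
    stop("duplicate rsID in manifest: ",
         paste(unique(man$rsid[duplicated(man$rsid)]), collapse = ", "),
         call. = FALSE)
  }
  bad_group <- setdiff(unique(man$group), c("synthesis", "metabolism"))
  if (length(bad_group) > 0L) {
    stop("unknown pathway group label: ", paste(bad_group, collapse = ", "),
         " (expected 'synthesis' or 'metabolism')", call. = FALSE)
  }
  for (col in c("risk_allele", "other_allele")) {
    ok <- !is.na(man[[col]]) & man[[col]] %in% c("A", "C", "G", "T")
    if (!all(ok)) {
      stop("invalid ", col, " for ", paste(man$rsid[!ok], collapse = ", "),
           ": must be a single nucleotide A/C/G/T", call. = FALSE)
    }
  }
  same <- man$risk_allele == man$other_allele
  if (any(same)) {
    stop("risk and other allele identical for: ",
         paste(man$rsid[same], collapse = ", "), call. = FALSE)
  }
  man
}

#' @rdname read_manifest
#' @export
default_manifest <- function() read_manifest(NULL)
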