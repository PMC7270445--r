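test_that("bundled manifest carries the six-SNP panel with valid fields", {
  man <- read_manifest()
  expect_equal(nrow(man), 6L)
  expect_equal(sum(man$group == "synthesis"), 2L)
  expect_equal(sum(man$group == "metabolism"), 4L)
  expect_setequal(man$rsid, c("rs12785878", "rs12794714", "rs2282679",
                              "rs6013897", "rs2228570", "rs7975232"))
  expect_equal(man$risk_allele[man$rsid == "rs12794714"], "A")
  expect_equal(man$risk_allele[man$rsid == "rs7975232"], "A")
  expect_true(all(man$risk_allele != man$other_allele))
})

test_that("manifest validation rejects malformed inputs", {
  man <- read_manifest()
  dup <- rbind(man, man[1, ])
  expect_error(validate_manifest(dup), "duplicate rsID")
  bad_group <- man; bad_group$group[1] <- "transport"
  expect_error(validate_manifest(bad_group), "unknown pathway group")
  same <- man; same$other_allele[2] <- same$risk_allele[2]
  expect_error(validate_manifest(same), "identical")
  empty <- tempfile(fileext = ".tsv")
  writeLines("rsid\tgene\trisk_allele\tother_allele\tgroup", empty)
  expect_error(read_manifest(empty), "no SNPs")
})

test_that("manifest round-trips through YAML", {
  man <- read_manifest()
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(seq_len(nrow(man)), function(i) as.list(man[i, ])),
                   path)
  expect_equal(read_manifest(path), man)
})

test_that("genotype TSV reading validates alleles against the manifest", {
  man <- read_manifest()
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trsid\tallele1\tallele2",
               "S001\trs2282679\tA\tC",
               "S002\trs2282679\tT\tC",     # T not an allele of rs2282679
               "S002\trs6013897\tT\tA",
               "S003\trs2282679\tA\tA"),
             path)
  expect_warning(g <- read_genotypes(path, man), "outside the manifest")
  expect_equal(g$allele1[g$sample_id == "S001"], "A")
  expect_equal(g$allele2[g$sample_id == "S001"], "C")
  bad <- g[g$sample_id == "S002" & g$rsid == "rs2282679", ]
  expect_true(is.na(bad$allele1))
  expect_true(is.na(bad$allele2))
})

test_that("samples with zero called manifest SNPs are excluded", {
  man <- read_manifest()
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trsid\tallele1\tallele2",
               "S001\trs2282679\tA\tC",
               "S002\trs2282679\tG\tG"),   # only an invalid call
             path)
  suppressWarnings(expect_warning(g <- read_genotypes(path, man),
                                  "zero called"))
  expect_false("S002" %in% g$sample_id)
})

test_that("VCF GT records map to allele pairs", {
  man <- read_manifest()
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS001\tS002",
    "20\t52742479\trs6013897\tT\tA\t.\tPASS\t.\tGT\t0/1\t1/1",
    "4\t72608383\trs2282679\tA\tC\t.\tPASS\t.\tGT\t0/0\t./."),
    path)
  g <- read_genotypes(path, man)
  het <- g[g$sample_id == "S001" & g$rsid == "rs6013897", ]
  expect_setequal(c(het$allele1, het$allele2), c("T", "A"))
  hom <- g[g$sample_id == "S002" & g$rsid == "rs6013897", ]
  expect_equal(c(hom$allele1, hom$allele2), c("A", "A"))
  miss <- g[g$sample_id == "S002" & g$rsid == "rs2282679", ]
  expect_true(is.na(miss$allele1) && is.na(miss$allele2))
})

test_that("phenotype reading types records and rejects negative measurements", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,age,vitd_t1,vitd_t3,birth_weight,birth_length,head_circumference,sex",
               "S001,25,10.5,18.2,3100,49,34,female",
               "S002,31,14.0,,2600,51,35,male",
               "S003,28,22.3,25.1,3400,50,36,female"),
             path)
  ph <- read_phenotypes(path)
  expect_equal(nrow(ph$participants), 3L)
  expect_equal(nrow(ph$neonates), 3L)
  expect_true(is.na(ph$participants$vitd_t3[2]))
  expect_type(ph$participants$vitd_t1, "double")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,vitd_t1,birth_weight", "S001,12,-5"), bad)
  expect_error(read_phenotypes(bad), "negative birth_weight")
})

test_that("assemble inner-joins and accounts for exclusions", {
  co <- checkerboard_fixture()
  # 12 mothers, drop genotypes for 2 -> 10 analyzable
  geno <- co$genotypes[!co$genotypes$sample_id %in% c("S001", "S002"), ]
  out <- assemble_cohort(co$participants, co$neonates, geno, co$manifest,
                         n_enrolled = 15L, n_dropped = 3L)
  acc <- setNames(out$accounting$n, out$accounting$stage)
  expect_equal(acc[["enrolled"]], 15)
  expect_equal(acc[["dropped"]], 3)
  expect_equal(acc[["completed_followup"]], 12)
  expect_equal(acc[["excluded_no_genotype"]], 2)
  expect_equal(acc[["analyzable_pairs"]], 10)

  disjoint <- co$neonates
  disjoint$sample_id <- paste0("X", disjoint$sample_id)
  expect_warning(out0 <- assemble_cohort(co$participants, disjoint,
                                         co$genotypes, co$manifest),
                 "0 analyzable")
  expect_equal(nrow(out0$participants), 0L)

  dup <- rbind(co$participants, co$participants[1, ])
  expect_error(assemble_cohort(dup, co$neonates, co$genotypes, co$manifest),
               "duplicate sample_id")
})

test_that("assemble never fabricates records", {
  fix <- checkerboard_fixture()
  for (drop_n in 0:3) {
    geno <- fix$genotypes[!fix$genotypes$sample_id %in%
                            sprintf("S%03d", seq_len(drop_n)), ]
    mothers <- fix$participants[1:10, ]
    out <- assemble_cohort(mothers, fix$neonates, geno, fix$manifest)
    n_analyzable <- out$accounting$n[out$accounting$stage == "analyzable_pairs"]
    expect_lte(n_analyzable, min(nrow(mothers), nrow(fix$neonates),
                                 length(unique(geno$sample_id))))
    expect_equal(n_analyzable, 10 - drop_n)
  }
  co <- generate_cohort(cohort_config(seed = 11, n_enrolled = 60,
                                      dropout_n = 10, low_dna_n = 5))
  expect_equal(co$accounting$n[co$accounting$stage == "analyzable_pairs"], 45)
})

test_that("write/read round-trip reproduces the dataset", {
  co <- generate_cohort(cohort_config(seed = 3, n_enrolled = 25,
                                      dropout_n = 4, low_dna_n = 1,
                                      missing_rate = 0.1))
  dir <- tempfile()
  write_cohort(co, dir)
  back <- suppressWarnings(read_cohort(dir, n_enrolled = 25, n_dropped = 4))
  expect_equal(back$manifest, co$manifest)
  g0 <- dplyr::arrange(co$genotypes, sample_id, rsid)
  g1 <- dplyr::arrange(back$genotypes, sample_id, rsid)
  expect_identical(g1$allele1, g0$allele1)
  expect_identical(g1$allele2, g0$allele2)
  expect_equal(back$participants$vitd_t1, co$participants$vitd_t1,
               tolerance = 0)
  expect_equal(back$neonates$birth_weight, co$neonates$birth_weight,
               tolerance = 0)
  # the written dataset holds only analyzable pairs, so only that stage of
  # the accounting is reproducible from disk
  expect_equal(back$accounting$n[back$accounting$stage == "analyzable_pairs"],
               co$accounting$n[co$accounting$stage == "analyzable_pairs"])
})
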