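write_variant_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  path
}

test_that("protein-level TSV ingest enforces the schema", {
  df <- data.frame(
    protein_id = c("P04275", "Q99999"), position = c(1584L, 7L),
    ref_aa = c("V", "A"), alt_aa = c("M", "T"), clin_sig = c("Pathogenic", NA)
  )
  f <- write_variant_tsv(df)
  recs <- read_variants(f, format = "tsv", dataset = "clinvar")
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$dataset, c("clinvar", "clinvar"))
  expect_true(all(c("af", "score", "ddg", "protein_class") %in% names(recs)))

  f2 <- write_variant_tsv(df[, c("protein_id", "position", "ref_aa")])
  expect_error(read_variants(f2, format = "tsv"), "alt_aa")
  df$alt_aa[1] <- "V"
  expect_error(read_variants(write_variant_tsv(df), format = "tsv"), "synonymous")
})

test_that("VEP VCF ingest honours the header CSQ order and canonical flag", {
  # CSQ subfields deliberately in a non-standard order
  vcf <- c(
    "##fileformat=VCFv4.2",
    paste0('##INFO=<ID=CSQ,Number=.,Type=String,Description="VEP. Format: ',
           'CANONICAL|Amino_acids|Consequence|SWISSPROT|Protein_position">'),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    paste(c("1", "100", ".", "A", "G", ".", "PASS",
            "CSQ=YES|V/M|missense_variant|P04275|1584"), collapse = "\t"),
    paste(c("1", "200", ".", "C", "T", ".", "PASS",
            "CSQ=YES|L/L|synonymous_variant|P11111|12"), collapse = "\t"),
    paste(c("1", "300", ".", "G", "A", ".", "PASS",
            "CSQ=|A/T|missense_variant|P22222|9"), collapse = "\t"),
    paste(c("1", "400", ".", "G", "C", ".", "PASS",
            "CSQ=YES|A|missense_variant|P33333|oops"), collapse = "\t")
  )
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_message(recs <- read_variants(f, format = "vep_vcf"), "skipped")
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$protein_id, "P04275")
  expect_equal(recs$position, 1584L)
  expect_equal(recs$ref_aa, "V")
  expect_equal(recs$alt_aa, "M")

  novcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
                     collapse = "\t")), novcf)
  expect_error(read_variants(novcf, format = "vep_vcf"), "CSQ")
})

test_that("dataset filters implement the cohort selection rules", {
  recs <- data.frame(
    protein_id = "P1", position = 1:6, ref_aa = "A", alt_aa = "V",
    af = c(0.06, 0.04, 0.2, NA, 0.5, 0.06),
    filter_status = c("PASS", "PASS", "lowqual", "PASS", "PASS", NA),
    clin_sig = c("Pathogenic", "likely pathogenic", "Uncertain significance",
                 "Benign", "PATHOGENIC", NA),
    score = c(0.1, 0.2, 0.3, 0.4, 0.9, 1.0)
  )
  gn <- filter_dataset(recs, "gnomad_benign")
  expect_equal(gn$position, c(1L, 5L))
  cv <- filter_dataset(recs, "clinvar_pathogenic")
  expect_equal(cv$position, c(1L, 2L, 5L))
  top <- filter_dataset(recs, "score_top", params = list(q = 0.2))
  expect_equal(sort(top$score), c(0.9, 1.0))
  bottom <- filter_dataset(recs, "score_bottom", params = list(q = 0.2))
  expect_equal(sort(bottom$score), c(0.1, 0.2))
  expect_error(filter_dataset(recs[, 1:4], "gnomad_benign"), "af")
})

test_that("predicate filters and fixed-cutoff score filters are idempotent", {
  set.seed(41)
  recs <- data.frame(
    protein_id = "P1", position = 1:50, ref_aa = "A", alt_aa = "V",
    af = runif(50), filter_status = sample(c("PASS", "FAIL"), 50, TRUE),
    clin_sig = sample(c("Pathogenic", "Benign", "Likely pathogenic"), 50, TRUE),
    score = runif(50)
  )
  for (mode in c("clinvar_pathogenic", "gnomad_benign", "none")) {
    once <- filter_dataset(recs, mode)
    expect_identical(filter_dataset(once, mode), once)
  }
  once <- filter_dataset(recs, "score_top", params = list(cutoff = 0.8))
  expect_identical(filter_dataset(once, "score_top", params = list(cutoff = 0.8)), once)
})

test_that("classification maps attach with NA for unmatched keys", {
  recs <- data.frame(protein_id = c("P1", "P2", "P3"), position = 1:3,
                     ref_aa = "A", alt_aa = "V")
  cmap <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tclass", "P1\tenzyme", "P2\treceptor"), cmap)
  dmap <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("key\tdisease", "P1:1:A:V\tmetabolic", "P3\tneurological"), dmap)
  out <- attach_classifications(recs, class_map = cmap, disease_map = dmap)
  expect_equal(out$protein_class, c("enzyme", "receptor", NA))
  expect_equal(out$disease_category, c("metabolic", NA, "neurological"))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tclass", "P1\tenzyme", "P1\tkinase"), bad)
  expect_error(attach_classifications(recs, class_map = bad), "P1")
})

test_that("feature matrix localises failures and keeps cells binary", {
  dir <- withr::local_tempdir()
  helix <- generate_backbone(data.frame(length = 9, phi = -57, psi = -47, plddt = 92),
                             protein_id = "HLX")
  write_synthetic_model(helix, file.path(dir, "HLX.pdb"))
  recs <- data.frame(
    protein_id = c("HLX", "HLX", "NOFILE"), position = c(5L, 5L, 2L),
    ref_aa = c("A", "W", "A"), alt_aa = c("K", "G", "T"),
    ddg = c(2.0, NA, -2.0), stringsAsFactors = FALSE
  )
  expect_message(
    fm <- build_feature_matrix(recs, structures = dir, n_points = 240L),
    "mismatch"
  )
  expect_s3_class(fm, "feature_matrix")
  expect_equal(nrow(fm), 3L)
  # structural block computed for the matching record only
  expect_equal(fm$OrderpLDDT[1], 1L)
  expect_equal(fm$DisorderpLDDT[1], 0L)
  expect_equal(fm$Helix[1], 1L)
  # reference mismatch (row 2) and missing model (row 3): structural NA,
  # substitution features still present
  expect_true(all(is.na(fm$Helix[2:3])))
  expect_equal(fm$BigToSmall[2], 1L)
  expect_equal(fm$TotalEnergy, c(1L, NA, 0L))
  expect_equal(fm$LessTotalEnergy, c(0L, NA, 1L))
  cells <- as.matrix(as.data.frame(fm)[, feature_registry()])
  expect_true(all(cells %in% c(0L, 1L, NA)))
})

test_that("structural one-hot blocks are exclusive and exhaustive", {
  dir <- withr::local_tempdir()
  coil <- build_extended_chain(12, plddt = 35)
  write_synthetic_model(coil, file.path(dir, "SYNCOIL.pdb"))
  recs <- data.frame(protein_id = "SYNCOIL", position = 3:10, ref_aa = "G",
                     alt_aa = "S", stringsAsFactors = FALSE)
  fm <- build_feature_matrix(recs, structures = dir, n_points = 240L)
  expect_true(all(fm$OrderpLDDT + fm$DisorderpLDDT == 1L))
  expect_true(all(fm$Core + fm$MediumBuried + fm$MediumExposed + fm$Exposed == 1L))
  expect_true(all(fm$Helix + fm$Strand + fm$Loop == 1L))
})

test_that("empty record sets give a header-only matrix and TSV round trip works", {
  fm <- build_feature_matrix(
    data.frame(protein_id = character(), position = integer(),
               ref_aa = character(), alt_aa = character())
  )
  expect_equal(nrow(fm), 0L)
  expect_true(all(feature_registry() %in% names(fm)))

  sim <- simulate_cohort(feature_registry(), 0.5, 0.5, 10, 10, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(sim$pathogenic, f)
  back <- read_feature_matrix(f)
  expect_equal(as.data.frame(back)[feature_registry()],
               as.data.frame(sim$pathogenic)[feature_registry()])
})

test_that("run manifests record thresholds, counts and seed", {
  f <- withr::local_tempfile(fileext = ".json")
  write_run_manifest(f, counts = list(pathogenic = 12L, benign = 30L),
                     thresholds = list(ddg_cutoff = 1.5), seed = 99L)
  man <- jsonlite::read_json(f)
  expect_equal(man$counts$pathogenic, 12L)
  expect_equal(man$seed, 99L)
  expect_equal(man$thresholds$ddg_cutoff, 1.5)
})
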