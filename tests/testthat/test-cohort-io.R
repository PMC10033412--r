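writeFixtureFiles <- function(dir, clinicalExtra = NULL, dropCol = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mut <- data.frame(patient_id = c("P1", "P2", "P3"), gene = "KRAS",
                    gene_role = "oncogene", variant_class = "missense",
                    codon = c(12, 12, 13), aa_change = c("G12D", "G12V", "G13D"),
                    variant_ploidy = c(1.5, 2.0, 1.2), biallelic = FALSE,
                    hotspot_distance = 0, driver_likelihood = 0.99)
  cna <- data.frame(patient_id = "P1", gene = "MYC", gene_copy_number = 8.5,
                    sample_ploidy = 2.0, recurrent_amp = TRUE,
                    recurrent_del = FALSE)
  cli <- data.frame(patient_id = c("P1", "P2", "P3"), endpoint = "OS",
                    time = c(5.5, 8.1, 12.0), event = c(1, 1, 0),
                    arm = "none", ecog = c("0-1", ">=2", "unknown"))
  if (!is.null(clinicalExtra)) cli <- rbind(cli, clinicalExtra)
  if (!is.null(dropCol)) cli[[dropCol]] <- NULL
  paths <- c(mut = file.path(dir, "mut.tsv"), cna = file.path(dir, "cna.tsv"),
             cli = file.path(dir, "cli.tsv"))
  write.table(mut, paths["mut"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cna, paths["cna"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cli, paths["cli"], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}

test_that("a toy TSV triplet round-trips through read with fields intact", {
  p <- writeFixtureFiles(tempfile())
  cg <- suppressMessages(readCohort(p["mut"], p["cna"], p["cli"]))
  expect_s4_class(cg, "ClinicoGenomicCohort")
  expect_equal(nPatients(cg), 3L)
  expect_equal(variantCalls(cg)$aa_change, c("G12D", "G12V", "G13D"))
  expect_equal(variantCalls(cg)$codon, c(12L, 12L, 13L))
  expect_equal(survivalRecords(cg)$time, c(5.5, 8.1, 12.0))
  # unknown covariate level preserved verbatim
  expect_true("unknown" %in% covariateRecords(cg)$ecog)
})

test_that("schema, parse and integrity failures raise one categorized error each", {
  p <- writeFixtureFiles(tempfile(), dropCol = "time")
  expect_error(suppressMessages(readCohort(p["mut"], p["cna"], p["cli"])),
               "time", class = "cs_schema_error")

  p <- writeFixtureFiles(tempfile())
  cli <- read.delim(p["cli"])
  cli$time[2] <- "eight"
  write.table(cli, p["cli"], sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(readCohort(p["mut"], p["cna"], p["cli"])),
               "row 2", class = "cs_parse_error")

  p <- writeFixtureFiles(tempfile())
  cli <- read.delim(p["cli"])
  cli$time[1] <- -1
  write.table(cli, p["cli"], sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(readCohort(p["mut"], p["cna"], p["cli"])),
               class = "cs_integrity_error")

  extra <- data.frame(patient_id = "P1", endpoint = "OS", time = 9, event = 1,
                      arm = "none", ecog = "0-1")
  p <- writeFixtureFiles(tempfile(), clinicalExtra = extra)
  expect_error(suppressMessages(readCohort(p["mut"], p["cna"], p["cli"])),
               "duplicate", class = "cs_integrity_error")
})

test_that("MAF-style headers map through the alias table", {
  dir <- tempfile(); dir.create(dir)
  mut <- data.frame(Tumor_Sample_Barcode = "P1", Hugo_Symbol = "KRAS",
                    gene_role = "oncogene", Variant_Classification = "missense",
                    HGVSp_Short = "p.G12D", hotspot_distance = 0)
  write.table(mut, file.path(dir, "m.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cna <- data.frame(patient_id = character(), gene = character(),
                    gene_copy_number = numeric(), sample_ploidy = numeric())
  write.table(cna, file.path(dir, "c.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cli <- data.frame(patient_id = "P1", endpoint = "OS", time = 4, event = 1)
  write.table(cli, file.path(dir, "k.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cg <- suppressMessages(readCohort(
    file.path(dir, "m.tsv"), file.path(dir, "c.tsv"), file.path(dir, "k.tsv"),
    aliases = c(Tumor_Sample_Barcode = "patient_id", Hugo_Symbol = "gene",
                Variant_Classification = "variant_class",
                HGVSp_Short = "aa_change")))
  expect_equal(variantCalls(cg)$gene, "KRAS")
  # codon derived from the amino-acid change when no codon column exists
  expect_equal(variantCalls(cg)$codon, 12L)
})

test_that("explicit codon disagreeing with the amino-acid change is rejected", {
  p <- writeFixtureFiles(tempfile())
  mut <- read.delim(p["mut"])
  mut$codon[1] <- 13
  write.table(mut, p["mut"], sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(readCohort(p["mut"], p["cna"], p["cli"])),
               class = "cs_integrity_error")
})

test_that("write then read is the identity on random generated cohorts", {
  for (seed in c(2, 23, 101)) {
    cg <- randomCohort(seed)
    d <- tempfile()
    paths <- writeCohort(cg, d)
    cg2 <- suppressMessages(readCohort(paths["mutations"],
                                       paths["copy_numbers"],
                                       paths["clinical"]))
    expect_equal(cg2@patients, cg@patients)
    expect_equal(cg2@variants, cg@variants)
    expect_equal(cg2@copyNumbers, cg@copyNumbers)
    expect_equal(cg2@survival, cg@survival)
    expect_equal(cg2@covariates[order(cg2@covariates$patient_id), ],
                 cg@covariates[order(cg@covariates$patient_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("an empty cohort writes three header-only files", {
  cg <- ClinicoGenomicCohort()
  d <- tempfile()
  paths <- writeCohort(cg, d)
  for (p in paths) {
    expect_true(file.exists(p))
    expect_equal(length(readLines(p)), 1L)
  }
})

test_that("validity catches inconsistent containers", {
  expect_error(ClinicoGenomicCohort(survival = data.frame(
    patient_id = "P1", endpoint = "OS", time = -2, event = 1, arm = "none")),
    "time")
  expect_error(ClinicoGenomicCohort(survival = data.frame(
    patient_id = c("P1", "P1"), endpoint = "OS", time = c(1, 2),
    event = c(1, 0), arm = "none")), "duplicate")
  # aa_change without codon violates the variant invariant
  v <- emptyish <- data.frame(
    patient_id = "P1", gene = "KRAS", gene_role = "oncogene",
    variant_class = "missense", codon = NA_integer_, aa_change = "G12D",
    variant_ploidy = 1, biallelic = FALSE, hotspot_distance = 0,
    repeat_count = NA_real_, driver_likelihood = 0.9)
  v$codon <- NA_integer_
  expect_error(methods::new("ClinicoGenomicCohort",
    patients = data.frame(patient_id = "P1", genomics_available = TRUE),
    variants = v, copyNumbers = codonscreen:::emptyCopyNumbers(),
    survival = codonscreen:::emptySurvival(),
    covariates = data.frame(patient_id = "P1")), "codon")
})
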