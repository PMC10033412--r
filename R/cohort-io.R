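#' Read a cohort from delimited genomic and clinical tables
#'
#' Reads the three-table representation of a cohort (somatic mutations,
#' gene-level copy number, clinical outcomes + covariates) from delimited
#' text files and returns a validated [ClinicoGenomicCohort-class]. Headers
#' are matched case-insensitively against the canonical snake_case schema; an
#' alias map allows MAF-style headers (e.g. `Hugo_Symbol` for `gene`,
#' `HGVSp_Short` for `aa_change`) without format lock-in.
#'
#' The clinical table is long over endpoints: one row per (patient,
#' endpoint) with columns `patient_id`, `endpoint`, `time` (months),
#' `event`, `arm`, optionally `genomics_available`, plus any number of
#' categorical covariate columns (repeated per row; the level `"unknown"` is
#' preserved as such). Rows with an empty `endpoint` carry covariates only.
#'
#' @param mutationFile,cnaFile,clinicalFile paths to the delimited tables.
#' @param delim field delimiter (default tab).
#' @param aliases named character vector mapping file headers to canonical
#'   names (`c(Hugo_Symbol = "gene")`), or the path of a YAML file containing
#'   such a mapping.
#' @return A validated [ClinicoGenomicCohort-class].
#' @section Errors: missing mandatory columns raise a `cs_schema_error`
#'   naming the column; unparseable numeric cells raise a `cs_parse_error`
#'   with the row number; duplicate (patient, endpoint) survival rows,
#'   non-positive times and codon/amino-acid-change mismatches raise a
#'   `cs_integrity_error`.
#' @examples
#' cg <- generateCohort(cohortPreset("discovery_like"), seed = 1)
#' d <- tempfile(); paths <- writeCohort(cg, d)
#' cg2 <- readCohort(paths["mutations"], paths["copy_numbers"], paths["clinical"])
#' nPatients(cg2) == nPatients(cg)
#' @export
readCohort <- function(mutationFile, cnaFile, clinicalFile, delim = "\t",
                       aliases = NULL) {
  aliases <- resolveAliases(aliases)
  mut <- readTable(mutationFile, delim, aliases)
  cna <- readTable(cnaFile, delim, aliases)
  cli <- readTable(clinicalFile, delim, aliases)

  variants <- parseVariants(mut, basename(mutationFile))
  copyNumbers <- parseCopyNumbers(cna, basename(cnaFile))
  clin <- parseClinical(cli, basename(clinicalFile))

  ids <- sort(unique(c(variants$patient_id, copyNumbers$patient_id,
                       clin$survival$patient_id, clin$covariates$patient_id)))
  ga <- clin$genomics_available
  genomic <- ids %in% c(variants$patient_id, copyNumbers$patient_id)
  if (!is.null(ga)) genomic <- genomic | (ids %in% names(ga)[ga])
  patients <- data.frame(patient_id = ids, genomics_available = genomic,
                         stringsAsFactors = FALSE)
  message(sprintf("read cohort: %d patients, %d variants, %d copy-number rows, %d survival rows",
                  length(ids), nrow(variants), nrow(copyNumbers), nrow(clin$survival)))
  methods::new("ClinicoGenomicCohort", patients = patients,
               variants = variants, copyNumbers = copyNumbers,
               survival = clin$survival, covariates = clin$covariates)
}

resolveAliases <- function(aliases) {
  if (is.null(aliases)) return(character())
  if (is.character(aliases) && length(aliases) == 1L && is.null(names(aliases)) &&
      file.exists(aliases)) {
    aliases <- unlist(yaml::read_yaml(aliases))
  }
  stats::setNames(as.character(aliases), tolower(names(aliases)))
}

readTable <- function(path, delim, aliases) {
  if (!file.exists(path)) configError(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, fileEncoding = "UTF-8")
  hdr <- tolower(names(tab))
  hit <- hdr %in% names(aliases)
  hdr[hit] <- unname(aliases[hdr[hit]])
  names(tab) <- tolower(hdr)
  tab
}

requireCols <- function(tab, cols, file) {
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    schemaError(sprintf("missing mandatory column '%s' in %s", miss[1L], file))
}

optCol <- function(tab, col, default = NA_character_) {
  if (col %in% names(tab)) tab[[col]] else rep(default, nrow(tab))
}

parseLogical <- function(x, column, file, default = NA) {
  x <- tolower(trimws(x))
  out <- rep(default, length(x))
  out[x %in% c("true", "1", "yes", "t")] <- TRUE
  out[x %in% c("false", "0", "no", "f")] <- FALSE
  bad <- which(!x %in% c("true", "1", "yes", "t", "false", "0", "no", "f", "", "na"))
  if (length(bad))
    parseError(sprintf("non-logical value '%s' in column '%s' of %s (row %d)",
                       x[bad[1L]], column, file, bad[1L]))
  out
}

#' Parse the codon position out of an amino-acid change string
#'
#' Extracts the residue position from the leading reference-residue + position
#' of an HGVS-style protein change (`"G12D"` or `"p.Thr562Met"` give 12 and
#' 562). Returns NA when the string does not match.
#'
#' @param aa character vector of amino-acid change strings.
#' @return integer vector of codon positions.
#' @examples codonFromAaChange(c("G12D", "p.Thr562Met", "?"))
#' @export
codonFromAaChange <- function(aa) {
  m <- regmatches(aa, regexec("^(?:p\\.)?\\(?([A-Za-z*]{1,3})([0-9]+)", aa))
  vapply(m, function(g) if (length(g) == 3L) as.integer(g[3L]) else NA_integer_,
         integer(1))
}

parseVariants <- function(tab, file) {
  if (nrow(tab) == 0L && ncol(tab) <= 1L) return(emptyVariants())
  requireCols(tab, c("patient_id", "gene", "gene_role", "variant_class"), file)
  aa <- optCol(tab, "aa_change")
  aa[aa == ""] <- NA_character_
  codon <- as.integer(parseNumeric(optCol(tab, "codon"), "codon", file))
  derived <- codonFromAaChange(aa)
  fill <- is.na(codon) & !is.na(derived)
  codon[fill] <- derived[fill]
  clash <- which(!is.na(codon) & !is.na(derived) & codon != derived)
  if (length(clash))
    integrityError(sprintf(
      "codon column (%d) disagrees with aa_change '%s' in %s (row %d)",
      codon[clash[1L]], aa[clash[1L]], file, clash[1L]))
  role <- tolower(tab$gene_role)
  if (any(!role %in% c("oncogene", "tsg")))
    parseError(sprintf("gene_role outside {oncogene, tsg} in %s", file))
  vc <- tolower(tab$variant_class)
  if (any(!vc %in% VARIANT_CLASSES))
    parseError(sprintf("variant_class outside declared levels in %s", file))
  out <- data.frame(
    patient_id = tab$patient_id, gene = tab$gene, gene_role = role,
    variant_class = vc, codon = codon, aa_change = aa,
    variant_ploidy = parseNumeric(optCol(tab, "variant_ploidy"), "variant_ploidy", file),
    biallelic = parseLogical(optCol(tab, "biallelic", "FALSE"), "biallelic", file, FALSE),
    hotspot_distance = parseNumeric(optCol(tab, "hotspot_distance"), "hotspot_distance", file),
    repeat_count = parseNumeric(optCol(tab, "repeat_count"), "repeat_count", file),
    driver_likelihood = parseNumeric(optCol(tab, "driver_likelihood"), "driver_likelihood", file),
    stringsAsFactors = FALSE)
  if (any(out$variant_ploidy < 0, na.rm = TRUE))
    integrityError(sprintf("negative variant_ploidy in %s", file))
  dl <- out$driver_likelihood
  if (any(dl < 0 | dl > 1, na.rm = TRUE))
    integrityError(sprintf("driver_likelihood outside [0,1] in %s", file))
  out
}

parseCopyNumbers <- function(tab, file) {
  if (nrow(tab) == 0L && ncol(tab) <= 1L) return(emptyCopyNumbers())
  requireCols(tab, c("patient_id", "gene", "gene_copy_number", "sample_ploidy"), file)
  gcn <- parseNumeric(tab$gene_copy_number, "gene_copy_number", file)
  gp <- parseNumeric(optCol(tab, "gene_ploidy"), "gene_ploidy", file)
  gp[is.na(gp)] <- gcn[is.na(gp)]
  sp <- parseNumeric(tab$sample_ploidy, "sample_ploidy", file)
  if (any(sp <= 0, na.rm = TRUE))
    integrityError(sprintf("sample_ploidy must be > 0 in %s", file))
  if (any(gcn < 0, na.rm = TRUE))
    integrityError(sprintf("gene_copy_number must be >= 0 in %s", file))
  data.frame(
    patient_id = tab$patient_id, gene = tab$gene, gene_copy_number = gcn,
    gene_ploidy = gp, sample_ploidy = sp,
    recurrent_amp = parseLogical(optCol(tab, "recurrent_amp", "FALSE"),
                                 "recurrent_amp", file, FALSE),
    recurrent_del = parseLogical(optCol(tab, "recurrent_del", "FALSE"),
                                 "recurrent_del", file, FALSE),
    stringsAsFactors = FALSE)
}

parseClinical <- function(tab, file) {
  empty <- list(survival = emptySurvival(),
                covariates = data.frame(patient_id = character()),
                genomics_available = NULL)
  if (nrow(tab) == 0L && ncol(tab) <= 1L) return(empty)
  requireCols(tab, c("patient_id", "time", "event"), file)
  endpoint <- optCol(tab, "endpoint", "OS")
  endpoint[endpoint == ""] <- NA_character_
  isSurv <- !is.na(endpoint)
  time <- parseNumeric(tab$time, "time", file)
  event <- parseNumeric(tab$event, "event", file)
  if (any(isSurv & (is.na(time) | time <= 0)))
    integrityError(sprintf("survival time must be > 0 in %s (row %d)",
                           file, which(isSurv & (is.na(time) | time <= 0))[1L]))
  if (any(isSurv & !event %in% c(0, 1)))
    parseError(sprintf("event must be 0/1 in %s", file))
  canon <- !endpoint %in% ENDPOINTS
  endpoint[isSurv & canon] <- c(os = "OS", pfs = "PFS",
      time_on_treatment = "time_on_treatment",
      tot = "time_on_treatment")[tolower(endpoint[isSurv & canon])]
  if (any(isSurv & is.na(endpoint)))
    parseError(sprintf("unrecognized endpoint in %s", file))
  surv <- data.frame(patient_id = tab$patient_id[isSurv],
                     endpoint = endpoint[isSurv], time = time[isSurv],
                     event = event[isSurv],
                     arm = tolower(optCol(tab, "arm", "none")[isSurv]),
                     stringsAsFactors = FALSE)
  surv$arm[surv$arm == ""] <- "none"
  if (any(!surv$arm %in% ARMS))
    parseError(sprintf("arm outside {treatment, placebo, none} in %s", file))
  if (anyDuplicated(surv[, c("patient_id", "endpoint")])) {
    d <- surv[duplicated(surv[, c("patient_id", "endpoint")]), ]
    integrityError(sprintf("duplicate survival record for patient '%s', endpoint %s in %s",
                           d$patient_id[1L], d$endpoint[1L], file))
  }
  gaCol <- if ("genomics_available" %in% names(tab))
    parseLogical(tab$genomics_available, "genomics_available", file, NA) else NULL
  covCols <- setdiff(names(tab), c("patient_id", "endpoint", "time", "event",
                                   "arm", "genomics_available"))
  cov <- data.frame(patient_id = tab$patient_id, tab[covCols],
                    stringsAsFactors = FALSE, check.names = FALSE)
  cov <- unique(cov)
  if (anyDuplicated(cov$patient_id))
    integrityError(sprintf("inconsistent covariate values across rows of one patient in %s", file))
  ga <- NULL
  if (!is.null(gaCol)) {
    gaTab <- unique(data.frame(id = tab$patient_id, ga = gaCol))
    ga <- stats::setNames(gaTab$ga, gaTab$id)
  }
  list(survival = surv, covariates = cov, genomics_available = ga)
}

#' Write a cohort to its three-table delimited representation
#'
#' Inverse of [readCohort()]: writes `mutations.tsv`, `copy_numbers.tsv` and
#' `clinical.tsv` into `dir`. Missing optional numeric fields are written as
#' empty cells (never 0, since 0 is meaningful e.g. for `hotspot_distance`);
#' `"unknown"` covariate levels are written verbatim. Reading the written
#' files reproduces the cohort field for field.
#'
#' @param cohort a [ClinicoGenomicCohort-class].
#' @param dir output directory (created if needed).
#' @param delim field delimiter (default tab).
#' @return Invisibly, a named character vector of the three paths
#'   (`mutations`, `copy_numbers`, `clinical`).
#' @export
writeCohort <- function(cohort, dir, delim = "\t") {
  stopifnot(methods::is(cohort, "ClinicoGenomicCohort"))
  methods::validObject(cohort)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    csStop("cs_io_error", sprintf("cannot create directory %s", dir))
  paths <- c(mutations = file.path(dir, "mutations.tsv"),
             copy_numbers = file.path(dir, "copy_numbers.tsv"),
             clinical = file.path(dir, "clinical.tsv"))
  writeTab <- function(df, path) {
    utils::write.table(df, path, sep = delim, quote = FALSE, na = "",
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  writeTab(cohort@variants, paths["mutations"])
  writeTab(cohort@copyNumbers, paths["copy_numbers"])

  surv <- cohort@survival
  cov <- cohort@covariates
  clin <- surv
  # carry covariate-only patients as endpoint-less rows so nothing is lost
  extra <- setdiff(cov$patient_id, surv$patient_id)
  if (length(extra))
    clin <- rbind(clin, data.frame(patient_id = extra, endpoint = NA_character_,
                                   time = NA_real_, event = NA_real_,
                                   arm = "none", stringsAsFactors = FALSE))
  if (nrow(cov) > 0 && ncol(cov) > 1L)
    clin <- merge(clin, cov, by = "patient_id", all.x = TRUE, sort = FALSE)
  ga <- genomicsAvailable(cohort)
  if (nrow(clin) > 0)
    clin$genomics_available <- unname(ga[clin$patient_id])
  else clin$genomics_available <- logical()
  clin <- clin[order(clin$patient_id, clin$endpoint), , drop = FALSE]
  writeTab(clin, paths["clinical"])
  invisible(paths)
}
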