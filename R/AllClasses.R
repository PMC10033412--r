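#' Container for a clinically annotated, genomically profiled cohort
#'
#' `ClinicoGenomicCohort` holds the four tables consumed by the biomarker
#' screen and the validation analyses: per-patient somatic small-variant
#' calls, per-patient per-gene copy-number calls, time-to-event outcomes and
#' baseline covariates, together with a patient index that records whether
#' genomic profiling is available for each patient (patients with genomics
#' available but zero calls are distinguishable from patients never
#' profiled).
#'
#' @slot patients data.frame with columns `patient_id` and
#'   `genomics_available` (logical).
#' @slot variants data.frame of somatic small variants: `patient_id`, `gene`,
#'   `gene_role` ("oncogene"/"tsg"), `variant_class` ("missense", "nonsense",
#'   "splice", "frameshift_indel", "inframe_indel"), `codon` (integer or NA),
#'   `aa_change` (e.g. "G12D", or NA), `variant_ploidy` (copies carrying the
#'   variant), `biallelic` (logical), `hotspot_distance` (bases to the
#'   nearest known hotspot, 0 = at a hotspot, NA = unknown), `repeat_count`,
#'   `driver_likelihood` (in [0,1] or NA).
#' @slot copyNumbers data.frame of gene-level copy number: `patient_id`,
#'   `gene`, `gene_copy_number` (absolute minimum copy number),
#'   `gene_ploidy` (gene copy number used by the two-hit sum rule),
#'   `sample_ploidy`, `recurrent_amp`, `recurrent_del` (logical flags for
#'   pan-cancer recurrent amplification/deletion genes).
#' @slot survival data.frame of outcomes: `patient_id`, `endpoint` ("OS",
#'   "PFS" or "time_on_treatment"), `time` (months, > 0), `event` (1 =
#'   death/progression/stop, 0 = censored), `arm` ("treatment", "placebo" or
#'   "none").
#' @slot covariates data.frame with `patient_id` plus categorical baseline
#'   covariates; the level `"unknown"` is carried through explicitly and is
#'   never imputed.
#'
#' @seealso [readCohort()], [writeCohort()], [generateCohort()]
#' @export
setClass("ClinicoGenomicCohort",
  slots = c(
    patients    = "data.frame",
    variants    = "data.frame",
    copyNumbers = "data.frame",
    survival    = "data.frame",
    covariates  = "data.frame"
  )
)

VARIANT_COLS <- c("patient_id", "gene", "gene_role", "variant_class", "codon",
                  "aa_change", "variant_ploidy", "biallelic",
                  "hotspot_distance", "repeat_count", "driver_likelihood")
CN_COLS <- c("patient_id", "gene", "gene_copy_number", "gene_ploidy",
             "sample_ploidy", "recurrent_amp", "recurrent_del")
SURV_COLS <- c("patient_id", "endpoint", "time", "event", "arm")
VARIANT_CLASSES <- c("missense", "nonsense", "splice", "frameshift_indel",
                     "inframe_indel")
ENDPOINTS <- c("OS", "PFS", "time_on_treatment")
ARMS <- c("treatment", "placebo", "none")

setValidity("ClinicoGenomicCohort", function(object) {
  msg <- character()
  pts <- object@patients
  if (!all(c("patient_id", "genomics_available") %in% names(pts)))
    msg <- c(msg, "patients must have columns patient_id, genomics_available")
  else if (anyDuplicated(pts$patient_id))
    msg <- c(msg, "duplicated patient_id in patients")
  ids <- pts$patient_id
  for (slotName in c("variants", "copyNumbers", "survival", "covariates")) {
    tab <- slot(object, slotName)
    if (nrow(tab) > 0 && !all(tab$patient_id %in% ids))
      msg <- c(msg, sprintf("%s refers to patient_id absent from patients", slotName))
  }
  v <- object@variants
  if (nrow(v) > 0) {
    if (!all(VARIANT_COLS %in% names(v)))
      msg <- c(msg, "variants is missing declared columns")
    else {
      if (any(!v$variant_class %in% VARIANT_CLASSES))
        msg <- c(msg, "variants$variant_class outside declared level set")
      if (any(v$variant_ploidy < 0, na.rm = TRUE))
        msg <- c(msg, "variant_ploidy must be >= 0")
      dl <- v$driver_likelihood
      if (any(dl < 0 | dl > 1, na.rm = TRUE))
        msg <- c(msg, "driver_likelihood must lie in [0,1]")
      if (any(!is.na(v$aa_change) & is.na(v$codon)))
        msg <- c(msg, "codon must be present whenever aa_change is present")
    }
  }
  cn <- object@copyNumbers
  if (nrow(cn) > 0 && all(CN_COLS %in% names(cn))) {
    if (any(cn$sample_ploidy <= 0, na.rm = TRUE))
      msg <- c(msg, "sample_ploidy must be > 0")
    if (any(cn$gene_copy_number < 0, na.rm = TRUE))
      msg <- c(msg, "gene_copy_number must be >= 0")
  } else if (nrow(cn) > 0) msg <- c(msg, "copyNumbers is missing declared columns")
  s <- object@survival
  if (nrow(s) > 0) {
    if (!all(SURV_COLS %in% names(s)))
      msg <- c(msg, "survival is missing declared columns")
    else {
      if (any(s$time <= 0, na.rm = TRUE)) msg <- c(msg, "survival time must be > 0")
      if (any(!s$endpoint %in% ENDPOINTS))
        msg <- c(msg, "survival endpoint outside declared level set")
      if (any(!s$arm %in% ARMS)) msg <- c(msg, "survival arm outside declared level set")
      if (any(!s$event %in% c(0, 1))) msg <- c(msg, "survival event must be 0/1")
      if (anyDuplicated(s[, c("patient_id", "endpoint")]))
        msg <- c(msg, "duplicate (patient_id, endpoint) survival record")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ClinicoGenomicCohort
#'
#' Assembles and validates the cohort container from its component tables.
#' Missing tables default to empty; the patient index is derived from the
#' union of patient ids when not given explicitly.
#'
#' @param patients data.frame with `patient_id` and `genomics_available`, or
#'   NULL to derive from the other tables (genomics marked available for
#'   patients appearing in the variant or copy-number tables).
#' @param variants,copyNumbers,survival,covariates component data.frames (see
#'   the class documentation for the schemas); may be omitted.
#' @return A validated [ClinicoGenomicCohort-class] object.
#' @examples
#' cg <- ClinicoGenomicCohort(survival = data.frame(
#'   patient_id = "P1", endpoint = "OS", time = 6.1, event = 1, arm = "none"))
#' nPatients(cg)
#' @export
ClinicoGenomicCohort <- function(patients = NULL,
                                 variants = emptyVariants(),
                                 copyNumbers = emptyCopyNumbers(),
                                 survival = emptySurvival(),
                                 covariates = data.frame(patient_id = character())) {
  variants <- as.data.frame(variants)
  copyNumbers <- as.data.frame(copyNumbers)
  survival <- as.data.frame(survival)
  covariates <- as.data.frame(covariates)
  if (is.null(patients)) {
    ids <- unique(c(variants$patient_id, copyNumbers$patient_id,
                    survival$patient_id, covariates$patient_id))
    ids <- sort(as.character(ids))
    patients <- data.frame(
      patient_id = ids,
      genomics_available = ids %in% c(variants$patient_id, copyNumbers$patient_id),
      stringsAsFactors = FALSE
    )
  }
  methods::new("ClinicoGenomicCohort",
    patients = as.data.frame(patients), variants = variants,
    copyNumbers = copyNumbers, survival = survival, covariates = covariates)
}

emptyVariants <- function() {
  data.frame(patient_id = character(), gene = character(),
             gene_role = character(), variant_class = character(),
             codon = integer(), aa_change = character(),
             variant_ploidy = numeric(), biallelic = logical(),
             hotspot_distance = numeric(), repeat_count = numeric(),
             driver_likelihood = numeric(), stringsAsFactors = FALSE)
}
emptyCopyNumbers <- function() {
  data.frame(patient_id = character(), gene = character(),
             gene_copy_number = numeric(), gene_ploidy = numeric(),
             sample_ploidy = numeric(), recurrent_amp = logical(),
             recurrent_del = logical(), stringsAsFactors = FALSE)
}
emptySurvival <- function() {
  data.frame(patient_id = character(), endpoint = character(),
             time = numeric(), event = numeric(), arm = character(),
             stringsAsFactors = FALSE)
}

#' Driver-classification rule thresholds
#'
#' Thresholds of the somatic driver rules. All printed thresholds are strict
#' inequalities in the printed direction; the tumor-suppressor two-hit ploidy
#' sum uses `>=` against `gene_ploidy - twoHitSlack` by default
#' (`twoHitStrict = TRUE` switches it to `>`).
#'
#' @slot hotspotMaxDistance maximum distance (bases) to a known hotspot for
#'   the oncogene hotspot rule (default 5; the rule tests `<=`).
#' @slot inframeRepeatMax repeat-count bound for oncogene inframe indels
#'   (default 8; the rule tests `<`, i.e. repeat count 8 does not qualify).
#' @slot likelihoodMin driver-likelihood bound (default 0.80; strict `>`).
#' @slot twoHitSlack slack subtracted from the gene ploidy in the
#'   tumor-suppressor two-hit sum rule (default 0.5).
#' @slot twoHitStrict whether the two-hit sum comparison is strict.
#' @slot tsgRequireTwoHit if TRUE (default), a tumor-suppressor mutation is
#'   only a driver when it is biallelic or the two-hit ploidy sum holds; if
#'   FALSE the driver-likelihood criterion alone can qualify it.
#' @slot ampPloidyMultiple amplification threshold as a multiple of sample
#'   ploidy (default 3; strict `>`).
#' @slot delCopyMax homozygous-deletion copy-number bound (default 0.5;
#'   strict `<`).
#' @export
setClass("DriverRuleConfig",
  slots = c(
    hotspotMaxDistance = "numeric", inframeRepeatMax = "numeric",
    likelihoodMin = "numeric", twoHitSlack = "numeric",
    twoHitStrict = "logical", tsgRequireTwoHit = "logical",
    ampPloidyMultiple = "numeric", delCopyMax = "numeric"
  ),
  prototype = list(
    hotspotMaxDistance = 5, inframeRepeatMax = 8, likelihoodMin = 0.80,
    twoHitSlack = 0.5, twoHitStrict = FALSE, tsgRequireTwoHit = TRUE,
    ampPloidyMultiple = 3.0, delCopyMax = 0.5
  )
)

setValidity("DriverRuleConfig", function(object) {
  thr <- c(object@hotspotMaxDistance, object@inframeRepeatMax,
           object@likelihoodMin, object@twoHitSlack,
           object@ampPloidyMultiple, object@delCopyMax)
  if (any(!is.finite(thr)) || any(thr[-4] <= 0) || object@twoHitSlack < 0)
    "all thresholds must be positive (twoHitSlack non-negative)"
  else TRUE
})

#' @rdname DriverRuleConfig-class
#' @param hotspotMaxDistance,inframeRepeatMax,likelihoodMin,twoHitSlack,twoHitStrict,tsgRequireTwoHit,ampPloidyMultiple,delCopyMax see slot documentation.
#' @return A `DriverRuleConfig` object.
#' @examples
#' driverRules(likelihoodMin = 0.9)
#' @export
driverRules <- function(hotspotMaxDistance = 5, inframeRepeatMax = 8,
                        likelihoodMin = 0.80, twoHitSlack = 0.5,
                        twoHitStrict = FALSE, tsgRequireTwoHit = TRUE,
                        ampPloidyMultiple = 3.0, delCopyMax = 0.5) {
  methods::new("DriverRuleConfig",
    hotspotMaxDistance = hotspotMaxDistance,
    inframeRepeatMax = inframeRepeatMax, likelihoodMin = likelihoodMin,
    twoHitSlack = twoHitSlack, twoHitStrict = twoHitStrict,
    tsgRequireTwoHit = tsgRequireTwoHit,
    ampPloidyMultiple = ampPloidyMultiple, delCopyMax = delCopyMax)
}
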