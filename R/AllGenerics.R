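#' @name cohort-accessors
#' @title Accessors for ClinicoGenomicCohort
#' @description Accessor generics for the cohort container. Use these rather
#'   than direct slot access.
#' @param object a [ClinicoGenomicCohort-class].
#' @return The corresponding component data.frame (or character vector of
#'   patient ids / integer count).
#' @examples
#' cg <- generateCohort(cohortPreset("discovery_like"), seed = 1)
#' head(variantCalls(cg))
#' nPatients(cg)
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("patientIds", function(object) standardGeneric("patientIds"))
#' @rdname cohort-accessors
#' @export
setGeneric("nPatients", function(object) standardGeneric("nPatients"))
#' @rdname cohort-accessors
#' @export
setGeneric("variantCalls", function(object) standardGeneric("variantCalls"))
#' @rdname cohort-accessors
#' @export
setGeneric("copyNumberCalls", function(object) standardGeneric("copyNumberCalls"))
#' @rdname cohort-accessors
#' @export
setGeneric("survivalRecords", function(object) standardGeneric("survivalRecords"))
#' @rdname cohort-accessors
#' @export
setGeneric("covariateRecords", function(object) standardGeneric("covariateRecords"))
#' @rdname cohort-accessors
#' @export
setGeneric("genomicsAvailable", function(object) standardGeneric("genomicsAvailable"))

#' @rdname cohort-accessors
setMethod("patientIds", "ClinicoGenomicCohort", function(object)
  object@patients$patient_id)
#' @rdname cohort-accessors
setMethod("nPatients", "ClinicoGenomicCohort", function(object)
  nrow(object@patients))
#' @rdname cohort-accessors
setMethod("variantCalls", "ClinicoGenomicCohort", function(object) object@variants)
#' @rdname cohort-accessors
setMethod("copyNumberCalls", "ClinicoGenomicCohort", function(object)
  object@copyNumbers)
#' @rdname cohort-accessors
setMethod("survivalRecords", "ClinicoGenomicCohort", function(object)
  object@survival)
#' @rdname cohort-accessors
setMethod("covariateRecords", "ClinicoGenomicCohort", function(object)
  object@covariates)
#' @rdname cohort-accessors
setMethod("genomicsAvailable", "ClinicoGenomicCohort", function(object)
  stats::setNames(object@patients$genomics_available, object@patients$patient_id))

setMethod("show", "ClinicoGenomicCohort", function(object) {
  cat("ClinicoGenomicCohort with", nrow(object@patients), "patients\n")
  cat("  genomics available:", sum(object@patients$genomics_available), "\n")
  cat("  somatic variants:  ", nrow(object@variants), "\n")
  cat("  copy-number calls: ", nrow(object@copyNumbers), "\n")
  eps <- table(object@survival$endpoint)
  cat("  survival records:  ", nrow(object@survival),
      if (length(eps)) paste0("(", paste(names(eps), eps, sep = ": ",
                                         collapse = ", "), ")"), "\n")
  cat("  covariates:        ",
      max(0L, ncol(object@covariates) - 1L), "fields\n")
})

setMethod("show", "DriverRuleConfig", function(object) {
  cat("DriverRuleConfig\n")
  cat(sprintf("  oncogene hotspot:      distance <= %g bases\n", object@hotspotMaxDistance))
  cat(sprintf("  oncogene inframe:      repeat count < %g\n", object@inframeRepeatMax))
  cat(sprintf("  driver likelihood:     > %g\n", object@likelihoodMin))
  cat(sprintf("  TSG two-hit sum:       %s gene_ploidy - %g%s\n",
              if (object@twoHitStrict) ">" else ">=", object@twoHitSlack,
              if (object@tsgRequireTwoHit) "  (required for TSG drivers)" else ""))
  cat(sprintf("  amplification:         copy number > %g x sample ploidy\n",
              object@ampPloidyMultiple))
  cat(sprintf("  homozygous deletion:   copy number < %g\n", object@delCopyMax))
})
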