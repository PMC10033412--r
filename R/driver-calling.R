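#' Classify driver status of the mutations in one gene of one patient
#'
#' Applies the somatic mutation driver rules to all small-variant calls of a
#' single (patient, gene) pair and returns at most one mutation driver event.
#' Oncogene rules, in order: (1) a mutation at or within
#' `hotspotMaxDistance` bases of a known hotspot; (2) an inframe indel with
#' repeat count strictly below `inframeRepeatMax`; (3) a sample-specific
#' driver likelihood strictly above `likelihoodMin`. Tumor-suppressor rules:
#' (1) a biallelic nonsense, splice or indel variant (the wild-type allele is
#' lost); (2) two or more mutations whose summed variant ploidies reach the
#' gene ploidy minus `twoHitSlack` (the classical two-hit situation); (3) a
#' driver likelihood above `likelihoodMin`, which by default
#' (`tsgRequireTwoHit = TRUE`) only qualifies when the variant is also
#' biallelic or the two-hit sum holds. When several rules fire, the first in
#' this documented order is recorded as `rule_fired`.
#'
#' @param variants data.frame of variant calls sharing one patient and gene
#'   (schema as in [ClinicoGenomicCohort-class]).
#' @param genePloidy gene ploidy from the matching copy-number record (used
#'   only by the two-hit sum rule; NA disables that rule with a warning when
#'   it would otherwise be evaluated).
#' @param cfg a [DriverRuleConfig-class].
#' @return A one-row data.frame (`patient_id`, `gene`, `event_class`,
#'   `rule_fired`) or NULL when no rule fires.
#' @examples
#' v <- data.frame(patient_id = "P1", gene = "KRAS", gene_role = "oncogene",
#'   variant_class = "missense", codon = 12L, aa_change = "G12D",
#'   variant_ploidy = 1.8, biallelic = FALSE, hotspot_distance = 0,
#'   repeat_count = NA, driver_likelihood = 0.99)
#' classifyMutationDriver(v)
#' @export
classifyMutationDriver <- function(variants, genePloidy = NA_real_,
                                   cfg = driverRules()) {
  if (nrow(variants) == 0L) return(NULL)
  stopifnot(length(unique(variants$patient_id)) == 1L,
            length(unique(variants$gene)) == 1L)
  role <- variants$gene_role[1L]
  lik <- variants$driver_likelihood
  likelihoodHit <- any(!is.na(lik) & lik > cfg@likelihoodMin)
  rule <- NULL
  if (role == "oncogene") {
    hd <- variants$hotspot_distance
    if (any(!is.na(hd) & hd <= cfg@hotspotMaxDistance)) {
      rule <- "oncogene_hotspot"
    } else if (any(variants$variant_class == "inframe_indel" &
                   !is.na(variants$repeat_count) &
                   variants$repeat_count < cfg@inframeRepeatMax)) {
      rule <- "oncogene_inframe_indel"
    } else if (likelihoodHit) {
      rule <- "driver_likelihood"
    }
  } else {
    biallelicLoF <- any(variants$biallelic %in% TRUE &
                        variants$variant_class %in%
                          c("nonsense", "splice", "frameshift_indel", "inframe_indel"))
    twoHit <- FALSE
    if (nrow(variants) >= 2L) {
      vp <- variants$variant_ploidy
      if (anyNA(vp)) {
        warning("two-hit ploidy-sum rule skipped: variant_ploidy absent for ",
                variants$gene[1L], " in patient ", variants$patient_id[1L])
      } else if (!is.na(genePloidy)) {
        s <- sum(vp)
        thr <- genePloidy - cfg@twoHitSlack
        twoHit <- if (cfg@twoHitStrict) s > thr else s >= thr
      }
    }
    if (biallelicLoF) {
      rule <- "tsg_biallelic"
    } else if (twoHit) {
      rule <- "tsg_two_hit_ploidy_sum"
    } else if (likelihoodHit &&
               (!cfg@tsgRequireTwoHit || any(variants$biallelic %in% TRUE))) {
      rule <- "driver_likelihood"
    }
  }
  if (is.null(rule)) return(NULL)
  data.frame(patient_id = variants$patient_id[1L], gene = variants$gene[1L],
             event_class = "mutation", rule_fired = rule,
             stringsAsFactors = FALSE)
}

#' Classify a gene amplification as a driver event
#'
#' A driver amplification requires pan-cancer evidence for recurrent
#' amplification of the gene and a copy number strictly exceeding
#' `ampPloidyMultiple` times the sample ploidy.
#'
#' @param rec one-row data.frame with copy-number schema (see
#'   [ClinicoGenomicCohort-class]).
#' @param cfg a [DriverRuleConfig-class].
#' @return A one-row driver-event data.frame or NULL.
#' @export
classifyAmplification <- function(rec, cfg = driverRules()) {
  if (nrow(rec) == 0L || !isTRUE(rec$recurrent_amp[1L])) return(NULL)
  if (is.na(rec$gene_copy_number[1L]) || is.na(rec$sample_ploidy[1L]) ||
      rec$gene_copy_number[1L] <= cfg@ampPloidyMultiple * rec$sample_ploidy[1L])
    return(NULL)
  data.frame(patient_id = rec$patient_id[1L], gene = rec$gene[1L],
             event_class = "amplification", rule_fired = "amp_threshold",
             stringsAsFactors = FALSE)
}

#' Classify a gene deletion as a driver event
#'
#' A driver deletion requires pan-cancer evidence for recurrent deletion of
#' the gene and a homozygous loss, i.e. absolute gene copy number strictly
#' below `delCopyMax`.
#'
#' @inheritParams classifyAmplification
#' @return A one-row driver-event data.frame or NULL.
#' @export
classifyDeletion <- function(rec, cfg = driverRules()) {
  if (nrow(rec) == 0L || !isTRUE(rec$recurrent_del[1L])) return(NULL)
  if (is.na(rec$gene_copy_number[1L]) ||
      rec$gene_copy_number[1L] >= cfg@delCopyMax)
    return(NULL)
  data.frame(patient_id = rec$patient_id[1L], gene = rec$gene[1L],
             event_class = "deletion", rule_fired = "del_homozygous",
             stringsAsFactors = FALSE)
}

#' Call all driver events in a cohort
#'
#' Applies the mutation, amplification and deletion driver rules across
#' every (patient, gene) combination of the cohort and returns the union of
#' driver events, at most one per (patient, gene, event class), in
#' deterministic (patient, gene, event class) order.
#'
#' @param cohort a [ClinicoGenomicCohort-class].
#' @param cfg a [DriverRuleConfig-class].
#' @return data.frame with columns `patient_id`, `gene`, `event_class`,
#'   `rule_fired`.
#' @examples
#' cg <- generateCohort(cohortPreset("discovery_like"), seed = 1)
#' head(callDrivers(cg))
#' @export
callDrivers <- function(cohort, cfg = driverRules()) {
  stopifnot(methods::is(cohort, "ClinicoGenomicCohort"))
  v <- cohort@variants
  cn <- cohort@copyNumbers
  events <- list()
  if (nrow(v) > 0L) {
    ploidyKey <- paste(cn$patient_id, cn$gene, sep = "\r")
    ploidyMap <- stats::setNames(cn$gene_ploidy, ploidyKey)
    groups <- split(v, paste(v$patient_id, v$gene, sep = "\r"), drop = TRUE)
    events <- c(events, lapply(names(groups), function(k) {
      classifyMutationDriver(groups[[k]],
                             genePloidy = unname(ploidyMap[k])[1L], cfg = cfg)
    }))
  }
  if (nrow(cn) > 0L) {
    for (i in seq_len(nrow(cn))) {
      events <- c(events, list(classifyAmplification(cn[i, , drop = FALSE], cfg)),
                  list(classifyDeletion(cn[i, , drop = FALSE], cfg)))
    }
  }
  events <- events[!vapply(events, is.null, logical(1))]
  if (length(events) == 0L)
    return(data.frame(patient_id = character(), gene = character(),
                      event_class = character(), rule_fired = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, events)
  out <- unique(out)
  out[order(out$patient_id, out$gene, out$event_class), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}
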