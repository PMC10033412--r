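#' Enumerate candidate biomarkers at four levels of specificity
#'
#' Expands driver events into the hierarchical candidate-biomarker table:
#' level 1 gene-level alteration (mutation, amplification or deletion of the
#' gene, e.g. "APC alteration"), level 2 variant class ("APC mutation",
#' "APC deletion"), level 3 codon ("KRAS codon 12 mutation") and level 4
#' amino-acid change ("KRAS p.G12V mutation"). Copy-number events stop at
#' level 2. Codon/amino-acid detail for driver mutations is taken from the
#' variant calls of the corresponding (patient, gene); driver mutations whose
#' variants lack a codon skip levels 3-4 (with a message). Carrier sets are
#' nested: the carriers of a level-k candidate are a subset of the carriers
#' of its level-(k-1) parent.
#'
#' @param events driver events from [callDrivers()].
#' @param variants variant calls providing codon / amino-acid annotation.
#' @return data.frame with columns `label`, `level`, `gene`, `event_class`,
#'   `codon`, `aa_change`, list-column `carriers` and `n_carriers`.
#' @examples
#' cg <- generateCohort(cohortPreset("discovery_like"), seed = 1)
#' head(enumerateCandidates(callDrivers(cg), variantCalls(cg)))
#' @export
enumerateCandidates <- function(events, variants) {
  empty <- data.frame(label = character(), level = integer(),
                      gene = character(), event_class = character(),
                      codon = integer(), aa_change = character(),
                      n_carriers = integer(), stringsAsFactors = FALSE)
  empty$carriers <- list()
  if (is.null(events) || nrow(events) == 0L) return(empty)

  longRow <- function(label, level, gene, eventClass, codon, aa, patient) {
    if (length(label) == 0L)
      return(data.frame(label = character(), level = integer(),
                        gene = character(), event_class = character(),
                        codon = integer(), aa_change = character(),
                        patient_id = character(), stringsAsFactors = FALSE))
    data.frame(label = label, level = level, gene = gene,
               event_class = eventClass, codon = codon, aa_change = aa,
               patient_id = patient, stringsAsFactors = FALSE)
  }
  l1 <- longRow(paste(events$gene, "alteration"), 1L, events$gene,
                NA_character_, NA_integer_, NA_character_, events$patient_id)
  l2 <- longRow(paste(events$gene, events$event_class), 2L, events$gene,
                events$event_class, NA_integer_, NA_character_,
                events$patient_id)
  mut <- events[events$event_class == "mutation", c("patient_id", "gene"),
                drop = FALSE]
  mv <- merge(mut, variants, by = c("patient_id", "gene"))
  noCodon <- tapply(mv$codon, paste(mv$patient_id, mv$gene),
                    function(x) all(is.na(x)))
  for (k in names(noCodon)[noCodon])
    message(sprintf("driver mutation %s has no codon annotation; levels 3-4 skipped", k))
  mv <- mv[!is.na(mv$codon), , drop = FALSE]
  l3 <- longRow(sprintf("%s codon %d mutation", mv$gene, mv$codon), 3L,
                mv$gene, "mutation", mv$codon, NA_character_, mv$patient_id)
  mv4 <- mv[!is.na(mv$aa_change), , drop = FALSE]
  aa4 <- sub("^p\\.", "", mv4$aa_change)
  l4 <- longRow(sprintf("%s p.%s mutation", mv4$gene, aa4), 4L, mv4$gene,
                "mutation", mv4$codon, aa4, mv4$patient_id)
  long <- rbind(l1, l2, l3, l4)
  keyCols <- c("label", "level", "gene", "event_class", "codon", "aa_change")
  key <- do.call(paste, c(long[keyCols], sep = "\r"))
  carrierSets <- lapply(split(long$patient_id, key), function(x) sort(unique(x)))
  meta <- long[!duplicated(key), keyCols, drop = FALSE]
  meta <- meta[match(names(carrierSets), key[!duplicated(key)]), , drop = FALSE]
  out <- meta
  out$carriers <- unname(carrierSets)
  out$n_carriers <- vapply(out$carriers, length, integer(1))
  out <- out[order(out$gene, out$level, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# is candidate `anc` an ancestor of candidate `des` within one gene lineage?
isAncestor <- function(anc, des) {
  if (anc$gene != des$gene || anc$level >= des$level) return(FALSE)
  if (anc$level == 1L) return(TRUE)
  if (anc$level == 2L) return(identical(anc$event_class, des$event_class))
  # level 3 -> 4 within the same codon
  anc$level == 3L && des$level == 4L && identical(anc$codon, des$codon)
}

#' Collapse fully redundant candidate levels
#'
#' When candidates of different levels within one gene lineage have exactly
#' the same carrier set, only the most specific level is informative: e.g.
#' if every alteration of a gene is a mutation, "GENE alteration" and
#' "GENE mutation" are completely redundant and only the latter is kept.
#' Candidates with distinct carrier sets are all retained. The operation is
#' idempotent.
#'
#' @param candidates output of [enumerateCandidates()].
#' @return The candidate table with redundant ancestors removed.
#' @export
collapseRedundant <- function(candidates) {
  n <- nrow(candidates)
  if (n == 0L) return(candidates)
  # carrier sets are stored sorted, so set equality is key equality
  key <- vapply(candidates$carriers, paste, character(1), collapse = "\r")
  lev <- candidates$level; gene <- candidates$gene
  ec <- candidates$event_class; cod <- candidates$codon
  drop <- logical(n)
  for (i in seq_len(n)) {
    for (j in which(gene == gene[i] & lev > lev[i] & key == key[i])) {
      anc <- lev[i] == 1L ||
        (lev[i] == 2L && identical(ec[i], ec[j])) ||
        (lev[i] == 3L && lev[j] == 4L && identical(cod[i], cod[j]))
      if (anc) { drop[i] <- TRUE; break }
    }
  }
  out <- candidates[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter candidates by carrier frequency
#'
#' Keeps candidate biomarkers carried by at least `minCarriers` patients
#' (the discovery screen tests candidates occurring in at least five
#' patients).
#'
#' @param candidates candidate table.
#' @param minCarriers minimum number of carriers (default 5; must be >= 1).
#' @return The filtered candidate table.
#' @export
filterByFrequency <- function(candidates, minCarriers = 5L) {
  if (!is.numeric(minCarriers) || minCarriers < 1)
    configError("minCarriers must be a positive integer")
  out <- candidates[candidates$n_carriers >= minCarriers, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Patients-by-candidates carrier indicator matrix
#'
#' @param candidates candidate table.
#' @param patients character vector of patient ids (row order of the result).
#' @return Binary matrix, rows = patients, columns = candidates in
#'   deterministic label sort order; entry 1 iff the patient carries the
#'   candidate.
#' @export
carrierMatrix <- function(candidates, patients) {
  labs <- sort(candidates$label)
  m <- matrix(0L, nrow = length(patients), ncol = length(labs),
              dimnames = list(patients, labs))
  for (i in seq_len(nrow(candidates))) {
    m[intersect(candidates$carriers[[i]], patients), candidates$label[i]] <- 1L
  }
  m
}
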