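#' Run the genomic-biomarker discovery screen
#'
#' End-to-end discovery screen on one endpoint: driver-event calling
#' ([callDrivers()]), hierarchical candidate enumeration
#' ([enumerateCandidates()]), redundancy collapse ([collapseRedundant()]),
#' the minimum-carrier frequency filter ([filterByFrequency()]), one exact
#' permutation log-rank test per candidate ([exactLogrank()], carriers vs
#' non-carriers among genomically profiled patients) and Benjamini-Hochberg
#' adjustment across all tested candidates ([bhAdjust()]). Candidates are
#' tested marginally, unadjusted. Deterministic given the seed; candidate
#' i's Monte-Carlo stream (when enumeration is infeasible) uses seed + i.
#'
#' @param cohort a [ClinicoGenomicCohort-class] with survival for the
#'   endpoint and genomic calls.
#' @param endpoint "OS", "PFS" or "time_on_treatment".
#' @param rules a [DriverRuleConfig-class].
#' @param minCarriers frequency filter threshold (default 5).
#' @param fdr significance threshold on the adjusted q-value (default 0.05).
#' @param maxEnumeration,mcPermutations,seed exact-test controls, see
#'   [exactLogrank()].
#' @return data.frame of class `screenResult`, one row per tested candidate,
#'   sorted by q then |theta| then label: `label`, `level`, `n_carriers`,
#'   `theta`, `p_exact`, `q_bh`, `significant`, `method`, `endpoint`.
#'   Attributes `n_candidates_tested` and `n_genes_tested` carry both
#'   counting conventions; `fdr` records the threshold.
#' @examples
#' cg <- generateCohort(cohortPreset("discovery_like"), seed = 11)
#' head(runScreen(cg, endpoint = "OS", seed = 11, mcPermutations = 2000))
#' @export
runScreen <- function(cohort, endpoint = "OS", rules = driverRules(),
                      minCarriers = 5L, fdr = 0.05, maxEnumeration = 2e6,
                      mcPermutations = 1e5, seed = NULL) {
  stopifnot(methods::is(cohort, "ClinicoGenomicCohort"))
  surv <- cohort@survival
  surv <- surv[surv$endpoint == endpoint, , drop = FALSE]
  if (nrow(surv) == 0L)
    configError(sprintf("no survival records for endpoint %s", endpoint))
  profiled <- cohort@patients$patient_id[cohort@patients$genomics_available]
  surv <- surv[surv$patient_id %in% profiled, , drop = FALSE]

  events <- callDrivers(cohort, rules)
  candidates <- enumerateCandidates(events, cohort@variants)
  candidates <- collapseRedundant(candidates)
  candidates <- filterByFrequency(candidates, minCarriers)
  emptyRes <- data.frame(label = character(), level = integer(),
                         n_carriers = integer(), theta = numeric(),
                         p_exact = numeric(), q_bh = numeric(),
                         significant = logical(), method = character(),
                         endpoint = character(), stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) {
    warning("no candidate biomarkers remain after the frequency filter")
    return(structure(emptyRes, class = c("screenResult", "data.frame"),
                     n_candidates_tested = 0L, n_genes_tested = 0L, fdr = fdr))
  }
  tests <- lapply(seq_len(nrow(candidates)), function(i) {
    carrier <- surv$patient_id %in% candidates$carriers[[i]]
    lt <- exactLogrank(surv$time, surv$event, carrier,
                       maxEnumeration = maxEnumeration,
                       mcPermutations = mcPermutations,
                       seed = if (!is.null(seed)) seed + i else NULL)
    data.frame(theta = lt$theta, p_exact = lt$p, method = lt$method,
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  res <- data.frame(label = candidates$label, level = candidates$level,
                    n_carriers = candidates$n_carriers,
                    theta = tests$theta, p_exact = tests$p_exact,
                    q_bh = bhAdjust(tests$p_exact),
                    method = tests$method, endpoint = endpoint,
                    stringsAsFactors = FALSE)
  res$significant <- res$q_bh < fdr
  res <- res[order(res$q_bh, -abs(res$theta), res$label), , drop = FALSE]
  rownames(res) <- NULL
  structure(res[, c("label", "level", "n_carriers", "theta", "p_exact",
                    "q_bh", "significant", "method", "endpoint")],
            class = c("screenResult", "data.frame"),
            n_candidates_tested = nrow(res),
            n_genes_tested = length(unique(candidates$gene)), fdr = fdr)
}

#' Write the screen report
#'
#' Writes the ranked screen results as TSV and a theta-versus-FDR scatter
#' (each tested candidate plotted by its standardized exact log-rank
#' statistic and Benjamini-Hochberg FDR, with the significance threshold as
#' a horizontal line) as PDF.
#'
#' @param results a `screenResult` from [runScreen()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths of `screen_results.tsv` and
#'   `screen_volcano.pdf`.
#' @export
screenReport <- function(results, dir) {
  if (is.null(results)) configError("screenReport: results must not be NULL")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    csStop("cs_io_error", sprintf("cannot create directory %s", dir))
  tsv <- file.path(dir, "screen_results.tsv")
  utils::write.table(as.data.frame(results), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fdr <- attr(results, "fdr") %||% 0.05
  pdfPath <- file.path(dir, "screen_volcano.pdf")
  df <- as.data.frame(results)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = theta, y = q_bh)) +
    ggplot2::geom_hline(yintercept = fdr, color = "red", linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(size = n_carriers), alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "exact log-rank statistic (theta)",
                  y = "Benjamini-Hochberg FDR",
                  title = "Candidate biomarker screen") +
    ggplot2::theme_bw()
  if (nrow(df) > 0)
    p <- p + ggplot2::geom_text(ggplot2::aes(label = label), vjust = -0.8,
                                size = 2.6, check_overlap = TRUE)
  grDevices::pdf(pdfPath, width = 7, height = 5)
  print(p)
  grDevices::dev.off()
  invisible(c(results = tsv, volcano = pdfPath))
}
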