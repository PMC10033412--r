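#' Classify patients into codon-specific RAS/RAF groups
#'
#' Assigns each patient exactly one mutually exclusive genotype group from
#' routine-diagnostics-style mutation calls (gene + codon): KRAS G12 and G13
#' both present gives the double-mutant group; otherwise G12; otherwise G13;
#' otherwise any other KRAS mutation; otherwise NRAS; otherwise BRAF;
#' otherwise RAS/RAF wild type. Patients without genomic testing (the
#' `genomics_available` marker is FALSE) are classed `unknown` and are meant
#' to be excluded from analyses. The precedence order is configurable
#' because mutual-exclusivity conventions vary between diagnostic settings.
#'
#' @param cohort a [ClinicoGenomicCohort-class].
#' @param precedence precedence among single-gene groups after the
#'   G12/G13-double check.
#' @return data.frame with `patient_id` and `group` (one row per patient).
#' @examples
#' cg <- generateCohort(cohortPreset("realworld_like"), seed = 5)
#' table(classifyRasRaf(cg)$group)
#' @export
classifyRasRaf <- function(cohort,
                           precedence = c("KRAS_G12", "KRAS_G13",
                                          "KRAS_other", "NRAS_mut",
                                          "BRAF_mut")) {
  stopifnot(methods::is(cohort, "ClinicoGenomicCohort"))
  v <- cohort@variants
  pts <- cohort@patients
  kras <- v[v$gene == "KRAS", , drop = FALSE]
  flagFor <- function(grp) {
    switch(grp,
      KRAS_G12 = unique(kras$patient_id[kras$codon %in% 12]),
      KRAS_G13 = unique(kras$patient_id[kras$codon %in% 13]),
      KRAS_other = unique(kras$patient_id[!kras$codon %in% c(12, 13)]),
      NRAS_mut = unique(v$patient_id[v$gene == "NRAS"]),
      BRAF_mut = unique(v$patient_id[v$gene == "BRAF"]))
  }
  has <- lapply(stats::setNames(nm = precedence), flagFor)
  group <- rep("RAS_RAF_WT", nrow(pts))
  for (grp in rev(precedence))
    group[pts$patient_id %in% has[[grp]]] <- grp
  double <- pts$patient_id %in% has[["KRAS_G12"]] &
            pts$patient_id %in% has[["KRAS_G13"]]
  group[double] <- "KRAS_G12_G13_double"
  group[!pts$genomics_available] <- "unknown"
  data.frame(patient_id = pts$patient_id, group = group,
             stringsAsFactors = FALSE)
}

# assemble the per-patient analysis frame for one endpoint
analysisFrame <- function(cohort, endpoint) {
  surv <- cohort@survival
  surv <- surv[surv$endpoint == endpoint, , drop = FALSE]
  if (nrow(surv) == 0L)
    configError(sprintf("no survival records for endpoint %s", endpoint))
  df <- merge(surv, classifyRasRaf(cohort), by = "patient_id")
  cov <- cohort@covariates
  if (nrow(cov) > 0 && ncol(cov) > 1L)
    df <- merge(df, cov, by = "patient_id", all.x = TRUE)
  df
}

# drop complete-case over "unknown" levels of the used covariates
completeCases <- function(df, covariates) {
  for (cv in covariates) {
    if (!cv %in% names(df))
      schemaError(sprintf("covariate '%s' not present", cv))
    df <- df[!is.na(df[[cv]]) & df[[cv]] != "unknown", , drop = FALSE]
  }
  df
}

adjustmentPreset <- function(preset = c("realworld", "trial")) {
  preset <- match.arg(preset)
  if (preset == "realworld")
    list(strata = "ecog",
         covariates = c("time_since_mets_ge18m", "region", "age_ge65",
                        "sex", "sidedness", "prior_surgery",
                        "peritoneal_disease"))
  else
    list(strata = c("time_since_mets_ge18m", "region"),
         covariates = c("age_ge65", "sex", "ecog", "primary_site",
                        "fluoropyrimidine_refractory", "prior_regorafenib",
                        "n_prior_regimens", "n_met_sites_ge3"))
}

#' Codon-specific subgroup survival analysis
#'
#' For a chosen population and biomarker contrast, computes group-wise
#' Kaplan-Meier estimates (median + 95% CI), the unadjusted (univariate)
#' Cox hazard ratio, the adjusted stratified multivariate Cox hazard ratio
#' using a named adjustment preset, and the Grambsch-Therneau
#' proportional-hazards diagnostic for each fitted model. If the adjusted
#' model violates proportional hazards through one of the adjustment
#' covariates, that categorical term is moved to the stratification factors
#' and the model is refitted (mirroring the analysis convention that
#' categorical covariates are modeled as stratification factors where
#' appropriate). Complete-case analysis over `"unknown"` covariate levels.
#'
#' @param cohort a [ClinicoGenomicCohort-class].
#' @param population "full" (all classified patients), "ras_raf_mut" (any
#'   RAS/RAF mutation) or "kras_exon2" (KRAS codon 12/13 carriers).
#' @param biomarker genotype group(s) defining biomarker-positive patients
#'   (default KRAS G12, including G12/G13 double mutants).
#' @param endpoint survival endpoint.
#' @param preset adjustment preset, "realworld" or "trial" (see the methods
#'   vignette for the covariate sets).
#' @return list with `km` (per-group [kmFit()] results), `unadjusted` and
#'   `adjusted` ([coxFit()]), `ph_unadjusted`, `ph_adjusted`
#'   ([phTest()]), `strata_used`, `n`, `n_biomarker`.
#' @export
runSubgroupOS <- function(cohort, population = c("full", "ras_raf_mut",
                                                 "kras_exon2"),
                          biomarker = c("KRAS_G12", "KRAS_G12_G13_double"),
                          endpoint = "OS",
                          preset = c("realworld", "trial")) {
  population <- match.arg(population)
  adj <- adjustmentPreset(match.arg(preset))
  df <- analysisFrame(cohort, endpoint)
  df <- df[df$group != "unknown", , drop = FALSE]
  keep <- switch(population,
    full = rep(TRUE, nrow(df)),
    ras_raf_mut = df$group != "RAS_RAF_WT",
    kras_exon2 = df$group %in% c("KRAS_G12", "KRAS_G13", "KRAS_G12_G13_double"))
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) configError("empty population after filtering")
  df$biomarker <- as.integer(df$group %in% biomarker)
  if (length(unique(df$biomarker)) < 2L)
    configError("biomarker contrast has no variation in this population")

  km <- lapply(split(df, df$group), function(g) {
    if (nrow(g) == 0L) return(NULL)
    kmFit(g$time, g$event)
  })
  unadj <- coxFit(df, terms = "biomarker")
  phU <- phTest(unadj)

  dfa <- completeCases(df, adj$covariates)
  strata <- adj$strata
  covs <- adj$covariates
  fitA <- coxFit(dfa, terms = c("biomarker", covs), strata = strata)
  phA <- phTest(fitA)
  # move PH-violating categorical covariates to the stratification factors
  for (k in 1:3) {
    if (!phA$violated) break
    perTerm <- phA$table[phA$table$term != "GLOBAL", , drop = FALSE]
    bad <- perTerm$term[which(perTerm$p < 0.05)]
    badCov <- covs[vapply(covs, function(cv) any(startsWith(bad, cv)),
                          logical(1))]
    if (length(badCov) == 0L) break
    strata <- c(strata, badCov[1L])
    covs <- setdiff(covs, badCov[1L])
    fitA <- coxFit(dfa, terms = c("biomarker", covs), strata = strata)
    phA <- phTest(fitA)
  }
  if (!unadj$converged || !fitA$converged)
    warning("a Cox model did not converge; hazard ratios flagged unreliable")
  list(km = km, unadjusted = unadj, adjusted = fitA,
       ph_unadjusted = phU, ph_adjusted = phA,
       strata_used = strata, n = nrow(df), n_biomarker = sum(df$biomarker))
}

#' Treatment-by-genotype interaction analysis for a randomized cohort
#'
#' Tests whether the treatment effect (treatment vs placebo) on the chosen
#' endpoint differs according to a genotype-defined biomarker, via the Wald
#' test of the arm-by-biomarker product term in a Cox model stratified for
#' the trial stratification factors (time since diagnosis of metastases and
#' geographical region). With `adjusted = TRUE` the model additionally
#' adjusts for the eight-covariate trial preset.
#'
#' @param cohort a two-arm [ClinicoGenomicCohort-class].
#' @param biomarker genotype group(s) defining biomarker-positive patients.
#' @param adjusted add the eight trial adjustment covariates.
#' @param endpoint survival endpoint.
#' @return An `interactionResult` (see [interactionTest()]), plus the
#'   per-arm hazard ratio context in its `fit`.
#' @export
runTrialInteraction <- function(cohort, biomarker = c("KRAS_G12",
                                                      "KRAS_G12_G13_double"),
                                adjusted = FALSE, endpoint = "OS") {
  df <- analysisFrame(cohort, endpoint)
  df <- df[df$group != "unknown" & df$arm %in% c("treatment", "placebo"), ,
           drop = FALSE]
  if (length(unique(df$arm)) < 2L)
    configError("interaction analysis needs both treatment and placebo arms")
  adj <- adjustmentPreset("trial")
  df$biomarker <- as.integer(df$group %in% biomarker)
  df$arm_treat <- as.integer(df$arm == "treatment")
  covs <- NULL
  if (adjusted) {
    df <- completeCases(df, adj$covariates)
    covs <- adj$covariates
  }
  df <- completeCases(df, adj$strata)
  interactionTest(df, armCol = "arm_treat", biomarkerCol = "biomarker",
                  covariates = covs, strata = adj$strata)
}

#' Baseline characteristics table with hypothesis tests
#'
#' Per-variable counts (with percentages of each group) and two-group
#' comparison p-values: Fisher's exact test for categorical variables with
#' two levels, the chi-squared test (or Fisher, configurable) for more than
#' two levels, and the normal-approximation Wilcoxon rank-sum test for
#' numeric variables. `"unknown"` levels are shown in the counts but
#' excluded from the tests. Variables with a single observed level are
#' reported without a test.
#'
#' @param cohort a [ClinicoGenomicCohort-class].
#' @param grouping data.frame with `patient_id` and `group` (e.g. from
#'   [classifyRasRaf()]).
#' @param variables covariate names to tabulate (must exist in the cohort's
#'   covariates).
#' @param groups the two group labels to compare; defaults to the two
#'   groups present when exactly two.
#' @param multiLevelTest test for >2-level categorical variables: "chisq"
#'   or "fisher".
#' @return list with `counts` (variable, level, group, n, pct) and `tests`
#'   (variable, test, p, note).
#' @export
baselineTable <- function(cohort, grouping, variables, groups = NULL,
                          multiLevelTest = c("chisq", "fisher")) {
  multiLevelTest <- match.arg(multiLevelTest)
  cov <- cohort@covariates
  miss <- setdiff(variables, names(cov))
  if (length(miss))
    schemaError(sprintf("variable '%s' not present in covariates", miss[1L]))
  df <- merge(grouping, cov, by = "patient_id")
  if (is.null(groups)) {
    groups <- sort(unique(df$group))
    if (length(groups) != 2L)
      configError("specify the two groups to compare")
  }
  df <- df[df$group %in% groups, , drop = FALSE]
  counts <- list(); tests <- list()
  for (v in variables) {
    x <- df[[v]]
    if (is.numeric(x)) {
      for (g in groups) {
        xi <- x[df$group == g]
        counts[[length(counts) + 1L]] <- data.frame(
          variable = v, level = "median (IQR)", group = g,
          n = stats::median(xi, na.rm = TRUE),
          pct = NA_real_, stringsAsFactors = FALSE)
      }
      w <- wilcoxonRankSum(x[df$group == groups[1L]],
                           x[df$group == groups[2L]], mode = "normal_approx")
      tests[[length(tests) + 1L]] <- data.frame(
        variable = v, test = "wilcoxon", p = w$p, note = "",
        stringsAsFactors = FALSE)
      next
    }
    tab <- table(factor(df$group, levels = groups), x)
    for (g in groups) for (lv in colnames(tab)) {
      counts[[length(counts) + 1L]] <- data.frame(
        variable = v, level = lv, group = g, n = as.integer(tab[g, lv]),
        pct = round(100 * tab[g, lv] / sum(tab[g, ]), 1),
        stringsAsFactors = FALSE)
    }
    tTab <- tab[, colnames(tab) != "unknown", drop = FALSE]
    tTab <- tTab[, colSums(tTab) > 0, drop = FALSE]
    if (ncol(tTab) < 2L) {
      tests[[length(tests) + 1L]] <- data.frame(
        variable = v, test = NA_character_, p = NA_real_,
        note = "single observed level; test omitted", stringsAsFactors = FALSE)
    } else if (ncol(tTab) == 2L) {
      tests[[length(tests) + 1L]] <- data.frame(
        variable = v, test = "fisher", p = fisherExact2x2(tTab)$p, note = "",
        stringsAsFactors = FALSE)
    } else {
      p <- if (multiLevelTest == "chisq") chi2Contingency(tTab)$p
           else stats::fisher.test(tTab)$p.value
      tests[[length(tests) + 1L]] <- data.frame(
        variable = v, test = multiLevelTest, p = p, note = "",
        stringsAsFactors = FALSE)
    }
  }
  list(counts = do.call(rbind, counts), tests = do.call(rbind, tests))
}
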