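#' Scenario configuration for synthetic cohort generation
#'
#' Describes the data-generating process the analyses assume: codon-specific
#' genotype frequencies, additional driver-gene alterations, a Weibull
#' baseline hazard with genotype- and treatment-interaction log-hazard
#' effects, independent exponential right-censoring with an administrative
#' cutoff, optional randomized two-arm allocation, and baseline covariate
#' marginals.
#'
#' @param nPatients cohort size.
#' @param groupFreqs named frequencies over the codon-specific genotype
#'   groups (`KRAS_G12`, `KRAS_G13`, `KRAS_G12_G13_double`, `KRAS_other`,
#'   `NRAS_mut`, `BRAF_mut`); the remainder is RAS/RAF wild type. Defaults
#'   follow the population frequencies of KRAS-mutant mCRC (44% KRAS
#'   overall: 28% codon G12, 8% codon G13, 8% other codons).
#' @param extraDrivers data.frame describing additional planted driver genes
#'   with columns `gene`, `kind` ("mutation"/"amplification"/"deletion"),
#'   `role` ("oncogene"/"tsg"), `freq`, `loghr`, `codon`, `aa` (codon/aa may
#'   be NA for copy-number kinds). The generator plants driver *events* and
#'   dresses them with call-level fields chosen so the driver rules fire
#'   deterministically for carriers.
#' @param weibullShape,weibullScale baseline Weibull shape and scale
#'   (months); shape 1 gives an exponential baseline.
#' @param groupLogHR named log hazard ratios per genotype group (reference:
#'   RAS/RAF wild type at 0).
#' @param armRatio treatment:placebo allocation ratio (e.g. 2 for 2:1), or
#'   NA for a single-arm cohort.
#' @param armLogHRByGroup named log hazard ratios of treatment vs placebo
#'   within each genotype group (the genotype-by-treatment interaction
#'   specification); ignored when `armRatio` is NA.
#' @param censorRate rate (per month) of the independent exponential
#'   censoring process.
#' @param adminCutoff administrative censoring time (months).
#' @param covariateMarginals named list; each element is
#'   `list(levels = c(...), probs = c(...))`.
#' @param table1Like if TRUE, G12 carriers get the direction of the printed
#'   baseline imbalances (more right-sided disease, more recent metastases).
#' @param endpoints endpoints to generate ("OS", "PFS",
#'   "time_on_treatment"); non-OS endpoints use shorter scales.
#' @param seed default seed used by [generateCohort()] when none is passed.
#' @return A list of class `ScenarioConfig`.
#' @seealso [cohortPreset()] for study-sized presets.
#' @export
scenarioConfig <- function(nPatients = 960,
                           groupFreqs = c(KRAS_G12 = 0.28, KRAS_G13 = 0.08,
                                          KRAS_G12_G13_double = 0,
                                          KRAS_other = 0.08, NRAS_mut = 0.04,
                                          BRAF_mut = 0.09),
                           extraDrivers = NULL,
                           weibullShape = 1, weibullScale = 9.5,
                           groupLogHR = NULL,
                           armRatio = NA_real_, armLogHRByGroup = NULL,
                           censorRate = 0.02, adminCutoff = 48,
                           covariateMarginals = defaultCovariateMarginals("realworld"),
                           table1Like = FALSE,
                           endpoints = "OS", seed = NULL) {
  allGroups <- c("KRAS_G12", "KRAS_G13", "KRAS_G12_G13_double", "KRAS_other",
                 "NRAS_mut", "BRAF_mut")
  gf <- stats::setNames(rep(0, length(allGroups)), allGroups)
  gf[names(groupFreqs)] <- groupFreqs
  if (any(gf < 0) || sum(gf) > 1)
    configError("groupFreqs must be non-negative and sum to at most 1")
  lh <- stats::setNames(rep(0, length(allGroups) + 1L),
                        c(allGroups, "RAS_RAF_WT"))
  if (!is.null(groupLogHR)) lh[names(groupLogHR)] <- groupLogHR
  alh <- stats::setNames(rep(0, length(allGroups) + 1L),
                         c(allGroups, "RAS_RAF_WT"))
  if (!is.null(armLogHRByGroup)) alh[names(armLogHRByGroup)] <- armLogHRByGroup
  if (!is.na(armRatio) && armRatio <= 0)
    configError("armRatio must be positive")
  stopifnot(weibullShape > 0, weibullScale > 0, censorRate >= 0,
            adminCutoff > 0, nPatients >= 1)
  structure(list(
    nPatients = as.integer(nPatients), groupFreqs = gf,
    extraDrivers = extraDrivers, weibullShape = weibullShape,
    weibullScale = weibullScale, groupLogHR = lh, armRatio = armRatio,
    armLogHRByGroup = alh, censorRate = censorRate,
    adminCutoff = adminCutoff, covariateMarginals = covariateMarginals,
    table1Like = isTRUE(table1Like), endpoints = endpoints, seed = seed
  ), class = "ScenarioConfig")
}

#' @export
print.ScenarioConfig <- function(x, ...) {
  cat(sprintf("ScenarioConfig: n = %d, Weibull(shape %.3g, scale %.3g mo), censor rate %.3g/mo\n",
              x$nPatients, x$weibullShape, x$weibullScale, x$censorRate))
  nz <- x$groupFreqs[x$groupFreqs > 0]
  cat("  genotype freqs:", paste(names(nz), signif(nz, 3), sep = "=", collapse = ", "), "\n")
  if (!is.na(x$armRatio))
    cat(sprintf("  randomized %g:1 treatment:placebo\n", x$armRatio))
  invisible(x)
}

defaultCovariateMarginals <- function(style = c("realworld", "trial")) {
  style <- match.arg(style)
  if (style == "realworld") {
    list(
      age_ge65 = list(levels = c("no", "yes"), probs = c(0.50, 0.50)),
      sex = list(levels = c("female", "male"), probs = c(0.41, 0.59)),
      region = list(levels = c("Italy", "UK"), probs = c(0.86, 0.14)),
      ecog = list(levels = c("0-1", ">=2"), probs = c(0.85, 0.15)),
      primary_site = list(levels = c("colon", "rectum"), probs = c(0.72, 0.28)),
      sidedness = list(levels = c("left", "right"), probs = c(0.69, 0.31)),
      time_since_mets_ge18m = list(levels = c("no", "yes", "unknown"),
                                   probs = c(0.28, 0.71, 0.01)),
      prior_surgery = list(levels = c("no", "yes"), probs = c(0.24, 0.76)),
      peritoneal_disease = list(levels = c("no", "yes"), probs = c(0.63, 0.37)),
      mmr_status = list(levels = c("proficient", "deficient", "unknown"),
                        probs = c(0.59, 0.03, 0.38))
    )
  } else {
    list(
      age_ge65 = list(levels = c("no", "yes"), probs = c(0.56, 0.44)),
      sex = list(levels = c("female", "male"), probs = c(0.39, 0.61)),
      region = list(levels = c("Japan", "Other"), probs = c(0.33, 0.67)),
      ecog = list(levels = c("0", "1"), probs = c(0.57, 0.43)),
      primary_site = list(levels = c("colon", "rectum"), probs = c(0.63, 0.37)),
      time_since_mets_ge18m = list(levels = c("no", "yes"), probs = c(0.21, 0.79)),
      n_prior_regimens = list(levels = c("2", "3", ">=4"),
                              probs = c(0.26, 0.24, 0.50)),
      fluoropyrimidine_refractory = list(levels = c("no", "yes"),
                                         probs = c(0.42, 0.58)),
      prior_regorafenib = list(levels = c("no", "yes"), probs = c(0.84, 0.16)),
      n_met_sites_ge3 = list(levels = c("no", "yes"), probs = c(0.60, 0.40))
    )
  }
}

KRAS_G12_AA <- c(G12D = 0.35, G12V = 0.25, G12C = 0.12, G12A = 0.10,
                 G12R = 0.08, G12S = 0.10)

# one dressed oncogene hotspot variant row
hotspotVariantRow <- function(patient, gene, codon, aa) {
  data.frame(patient_id = patient, gene = gene, gene_role = "oncogene",
             variant_class = "missense", codon = as.integer(codon),
             aa_change = aa, variant_ploidy = round(stats::runif(length(patient), 1.2, 2.6), 3),
             biallelic = FALSE, hotspot_distance = 0,
             repeat_count = NA_real_, driver_likelihood = 0.99,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws a [ClinicoGenomicCohort-class] from a [scenarioConfig()]:
#' genotype-group assignment, genomic tables dressed so that the driver
#' rules fire deterministically for planted carriers, Weibull survival times
#' with group-, planted-driver- and treatment-interaction log-hazard
#' effects, independent exponential right-censoring truncated at the
#' administrative cutoff, and covariates drawn from their marginals. Fully
#' reproducible for a given seed.
#'
#' @param cfg a [scenarioConfig()].
#' @param seed integer seed (mandatory here or in `cfg$seed`).
#' @return A validated [ClinicoGenomicCohort-class].
#' @examples
#' cg <- generateCohort(cohortPreset("discovery_like"), seed = 7)
#' cg
#' @export
generateCohort <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "ScenarioConfig"))
  if (is.null(seed)) configError("generateCohort: a seed is mandatory")
  set.seed(seed)
  n <- cfg$nPatients
  ids <- sprintf("P%05d", seq_len(n))
  groups <- sample(c(names(cfg$groupFreqs), "RAS_RAF_WT"), n, replace = TRUE,
                   prob = c(cfg$groupFreqs, 1 - sum(cfg$groupFreqs)))

  arm <- rep("none", n)
  if (!is.na(cfg$armRatio))
    arm <- sample(c("treatment", "placebo"), n, replace = TRUE,
                  prob = c(cfg$armRatio, 1) / (cfg$armRatio + 1))

  # planted additional driver genes
  xd <- cfg$extraDrivers
  carrierMat <- NULL
  if (!is.null(xd) && nrow(xd) > 0) {
    carrierMat <- vapply(seq_len(nrow(xd)),
                         function(i) stats::rbinom(n, 1, xd$freq[i]),
                         numeric(n))
    colnames(carrierMat) <- xd$gene
  }

  lp <- unname(cfg$groupLogHR[groups])
  if (!is.null(carrierMat)) lp <- lp + drop(carrierMat %*% xd$loghr)
  lp <- lp + (arm == "treatment") * unname(cfg$armLogHRByGroup[groups])

  drawEndpoint <- function(scaleMult, censorMult = 1) {
    u <- stats::runif(n)
    t <- cfg$weibullScale * scaleMult *
      (-log(u) / exp(lp))^(1 / cfg$weibullShape)
    cens <- if (cfg$censorRate > 0)
      pmin(stats::rexp(n, cfg$censorRate * censorMult), cfg$adminCutoff)
    else rep(cfg$adminCutoff, n)
    time <- pmax(pmin(t, cens), 1e-4)
    data.frame(time = round(time, 4), event = as.numeric(t <= cens))
  }
  scaleMult <- c(OS = 1, PFS = 0.55, time_on_treatment = 0.5)
  surv <- do.call(rbind, lapply(cfg$endpoints, function(ep) {
    d <- drawEndpoint(scaleMult[[ep]])
    data.frame(patient_id = ids, endpoint = ep, time = d$time,
               event = d$event, arm = arm, stringsAsFactors = FALSE)
  }))

  # --- genomic dressing -----------------------------------------------------
  vrows <- list()
  addHotspot <- function(pat, gene, codon, aaPool) {
    if (length(pat) == 0L) return()
    aa <- if (length(aaPool) > 1L)
      sample(names(aaPool), length(pat), replace = TRUE, prob = aaPool)
    else rep(names(aaPool), length(pat))
    vrows[[length(vrows) + 1L]] <<- hotspotVariantRow(pat, gene, codon, aa)
  }
  addHotspot(ids[groups %in% c("KRAS_G12", "KRAS_G12_G13_double")], "KRAS",
             12, KRAS_G12_AA)
  addHotspot(ids[groups %in% c("KRAS_G13", "KRAS_G12_G13_double")], "KRAS",
             13, c(G13D = 0.9, G13C = 0.1))
  addHotspot(ids[groups == "KRAS_other"], "KRAS", 61,
             c(Q61H = 0.5, Q61K = 0.3, Q61L = 0.2))
  addHotspot(ids[groups == "NRAS_mut"], "NRAS", 61, c(Q61K = 0.6, Q61L = 0.4))
  addHotspot(ids[groups == "BRAF_mut"], "BRAF", 600, c(V600E = 1))

  cnrows <- list()
  if (!is.null(xd) && nrow(xd) > 0) {
    for (i in seq_len(nrow(xd))) {
      pat <- ids[carrierMat[, i] == 1]
      if (length(pat) == 0L) next
      kind <- xd$kind[i]
      if (kind == "mutation") {
        if (xd$role[i] == "oncogene") {
          addHotspot(pat, xd$gene[i], xd$codon[i],
                     stats::setNames(1, xd$aa[i]))
        } else {
          vrows[[length(vrows) + 1L]] <- data.frame(
            patient_id = pat, gene = xd$gene[i], gene_role = "tsg",
            variant_class = "nonsense", codon = as.integer(xd$codon[i]),
            aa_change = xd$aa[i],
            variant_ploidy = round(stats::runif(length(pat), 0.8, 1.8), 3),
            biallelic = TRUE, hotspot_distance = NA_real_,
            repeat_count = NA_real_, driver_likelihood = 0.95,
            stringsAsFactors = FALSE)
        }
      } else if (kind == "amplification") {
        sp <- round(stats::runif(length(pat), 1.9, 3.2), 3)
        cnrows[[length(cnrows) + 1L]] <- data.frame(
          patient_id = pat, gene = xd$gene[i],
          gene_copy_number = round(sp * 3 + stats::runif(length(pat), 1, 6), 3),
          gene_ploidy = NA_real_, sample_ploidy = sp,
          recurrent_amp = TRUE, recurrent_del = FALSE,
          stringsAsFactors = FALSE)
      } else if (kind == "deletion") {
        cnrows[[length(cnrows) + 1L]] <- data.frame(
          patient_id = pat, gene = xd$gene[i],
          gene_copy_number = round(stats::runif(length(pat), 0, 0.45), 3),
          gene_ploidy = NA_real_,
          sample_ploidy = round(stats::runif(length(pat), 1.9, 3.2), 3),
          recurrent_amp = FALSE, recurrent_del = TRUE,
          stringsAsFactors = FALSE)
      } else configError(sprintf("unknown driver kind '%s'", kind))
    }
  }
  variants <- if (length(vrows)) do.call(rbind, vrows) else emptyVariants()
  copyNumbers <- if (length(cnrows)) do.call(rbind, cnrows) else emptyCopyNumbers()
  if (nrow(copyNumbers))
    copyNumbers$gene_ploidy[is.na(copyNumbers$gene_ploidy)] <-
      copyNumbers$gene_copy_number[is.na(copyNumbers$gene_ploidy)]

  # --- covariates -----------------------------------------------------------
  cov <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (nm in names(cfg$covariateMarginals)) {
    m <- cfg$covariateMarginals[[nm]]
    cov[[nm]] <- sample(m$levels, n, replace = TRUE, prob = m$probs)
  }
  if (cfg$table1Like) {
    g12 <- groups %in% c("KRAS_G12", "KRAS_G12_G13_double")
    if ("sidedness" %in% names(cov)) {
      flip <- g12 & cov$sidedness == "left" & stats::runif(n) < 0.22
      cov$sidedness[flip] <- "right"
    }
    if ("time_since_mets_ge18m" %in% names(cov)) {
      flip <- g12 & cov$time_since_mets_ge18m == "yes" & stats::runif(n) < 0.18
      cov$time_since_mets_ge18m[flip] <- "no"
    }
  }

  patients <- data.frame(patient_id = ids, genomics_available = TRUE,
                         stringsAsFactors = FALSE)
  ord <- order(surv$patient_id, surv$endpoint)
  methods::new("ClinicoGenomicCohort", patients = patients,
               variants = normalizeRows(variants),
               copyNumbers = normalizeRows(copyNumbers),
               survival = normalizeRows(surv[ord, , drop = FALSE]),
               covariates = cov)
}

normalizeRows <- function(df) {
  if (nrow(df)) df <- df[order(df$patient_id, df$gene %||% df$patient_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

defaultExtraDrivers <- function() {
  data.frame(
    gene  = c("APC", "TP53", "PIK3CA", "FBXW7", "SMAD4", "MYC"),
    kind  = c("mutation", "mutation", "mutation", "mutation", "deletion",
              "amplification"),
    role  = c("tsg", "tsg", "oncogene", "tsg", "tsg", "oncogene"),
    freq  = c(0.75, 0.65, 0.18, 0.15, 0.15, 0.15),
    loghr = 0,
    codon = c(1450L, 213L, 545L, 465L, NA, NA),
    aa    = c("R1450*", "R213*", "E545K", "R465C", NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Study-sized scenario presets
#'
#' Returns a [scenarioConfig()] matching one of three study-like designs:
#' \describe{
#'   \item{discovery_like}{n = 37 single-arm whole-genome cohort: 20/37
#'     KRAS G12 carriers, 4/37 other KRAS codons, a panel of common mCRC
#'     driver genes, overall median OS near 6 months, and an elevated G12
#'     hazard (log HR = log 2.5).}
#'   \item{realworld_like}{n = 960 single-arm cohort with genotype-group
#'     expectation proportional to 343 G12 / 86 G13 / 53 other KRAS / 32
#'     BRAF / 61 NRAS / 385 wild type, G12 log HR = log 1.31 and G13 log HR
#'     = log(1.31/1.79) (so the G12:G13 hazard ratio is 1.79), with
#'     baseline-imbalance direction as in the printed baseline table.}
#'   \item{trial_like}{n = 800 randomized 2:1 treatment:placebo with
#'     genotype mix 279 G12 / 60 G13 / 21 G12-G13 double / 7 other / 433
#'     wild type, a worse placebo-arm prognosis for G13 (log HR = log
#'     1.95), and a genotype-specific treatment effect (treatment vs
#'     placebo log HR: G12 log 0.97, G13 log 0.34, wild type log 0.58).}
#' }
#'
#' @param name one of "discovery_like", "realworld_like", "trial_like".
#' @return A `ScenarioConfig`.
#' @export
cohortPreset <- function(name = c("discovery_like", "realworld_like",
                                  "trial_like")) {
  name <- match.arg(name)
  switch(name,
    discovery_like = scenarioConfig(
      nPatients = 37,
      groupFreqs = c(KRAS_G12 = 20 / 37, KRAS_other = 4 / 37),
      extraDrivers = defaultExtraDrivers(),
      # baseline scale calibrated so the genotype mixture (54% of patients
      # at hazard ratio 2.5) has a cohort-level median OS near 6 months
      weibullShape = 1, weibullScale = 14.9,
      groupLogHR = c(KRAS_G12 = log(2.5)),
      censorRate = 0.03, adminCutoff = 30,
      covariateMarginals = defaultCovariateMarginals("realworld"),
      endpoints = c("OS", "time_on_treatment")),
    realworld_like = scenarioConfig(
      nPatients = 960,
      groupFreqs = c(KRAS_G12 = 343, KRAS_G13 = 86, KRAS_other = 53,
                     BRAF_mut = 32, NRAS_mut = 61) / 960,
      weibullShape = 1, weibullScale = 11,
      groupLogHR = c(KRAS_G12 = log(1.31), KRAS_G13 = log(1.31 / 1.79)),
      censorRate = 0.025, adminCutoff = 60,
      covariateMarginals = defaultCovariateMarginals("realworld"),
      table1Like = TRUE,
      endpoints = c("OS", "PFS")),
    trial_like = scenarioConfig(
      nPatients = 800,
      groupFreqs = c(KRAS_G12 = 279, KRAS_G13 = 60,
                     KRAS_G12_G13_double = 21, KRAS_other = 7) / 800,
      weibullShape = 1, weibullScale = 7.6,
      groupLogHR = c(KRAS_G13 = log(1.95)),
      armRatio = 2,
      armLogHRByGroup = c(KRAS_G12 = log(0.97), KRAS_G13 = log(0.34),
                          KRAS_G12_G13_double = log(0.55),
                          KRAS_other = log(0.55), RAS_RAF_WT = log(0.58)),
      censorRate = 0.012, adminCutoff = 24,
      covariateMarginals = defaultCovariateMarginals("trial"),
      endpoints = c("OS", "PFS"))
  )
}
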