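#' Kaplan-Meier estimate with median and confidence interval
#'
#' Product-limit estimator of the survival function with the median survival
#' time (earliest time at which the estimated survival drops to 0.5 or
#' below) and its 95% Brookmeyer-Crowley confidence interval on the log-log
#' scale. Thin wrapper over [survival::survfit()] exposing the fields the
#' screen and subgroup reports consume.
#'
#' @param time positive event/censoring times (months).
#' @param event event indicator (1 = event, 0 = censored).
#' @return A list of class `kmEstimate`: `time`, `surv`, `n_risk`, `n_event`
#'   at the distinct observed times, `median`, `median_ci` (NA when the
#'   curve never reaches 0.5), `n`, `n_events`.
#' @examples
#' kmFit(c(3, 5, 7, 9, 11), c(0, 1, 1, 0, 1))$median
#' @export
kmFit <- function(time, event) {
  if (length(time) == 0L) configError("kmFit: empty input")
  if (any(time <= 0)) integrityError("kmFit: times must be > 0")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  tab <- summary(fit)$table
  # median defined as the earliest time at which the curve reaches 0.5
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else NA_real_
  structure(list(
    time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
    n_event = fit$n.event,
    median = med,
    median_ci = c(lower = unname(tab["0.95LCL"]), upper = unname(tab["0.95UCL"])),
    n = length(time), n_events = sum(event == 1)
  ), class = "kmEstimate")
}

#' @export
print.kmEstimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d\n", x$n, x$n_events))
  cat(sprintf("  median %.3g (95%% CI %.3g-%.3g)\n",
              x$median, x$median_ci[1], x$median_ci[2]))
  invisible(x)
}

#' Log-rank (Peto) scores for a censored sample
#'
#' Per-observation scores of the censored-data linear rank formulation of
#' the log-rank test: an observation with an event at time t scores
#' `1 - sum_{t_j <= t} d_j / n_j` and a censored observation scores
#' `-sum_{t_j <= t} d_j / n_j`, where the sum runs over distinct event
#' times, d_j is the number of events and n_j the number at risk. The scores
#' sum to zero; the exact permutation log-rank test permutes group labels
#' over these fixed pooled-sample scores.
#'
#' @inheritParams kmFit
#' @return Numeric vector of scores, one per observation.
#' @export
logrankScores <- function(time, event) {
  stopifnot(length(time) == length(event))
  n <- length(time)
  if (n == 0L) return(numeric())
  eventTimes <- sort(unique(time[event == 1]))
  d <- vapply(eventTimes, function(t) sum(time == t & event == 1), numeric(1))
  atRisk <- vapply(eventTimes, function(t) sum(time >= t), numeric(1))
  cumHaz <- cumsum(d / atRisk)
  H <- function(t) { # cumulative sum of d_j/n_j over event times <= t
    k <- findInterval(t, eventTimes)
    ifelse(k == 0, 0, cumHaz[pmax(k, 1)])
  }
  ifelse(event == 1, 1 - H(time), -H(time))
}

#' Exact permutation log-rank test
#'
#' Two-sample survival comparison whose null distribution is the exact
#' permutation distribution of the log-rank score sum over all group-label
#' assignments. Log-rank scores are computed once on the pooled sample (see
#' [logrankScores()]); the statistic is the standardized score sum of the
#' biomarker-positive group, `theta = S1 / sd_perm(S1)`, where the
#' permutation variance has the closed form
#' `n1 (n - n1) / (n (n - 1)) * sum(a_i^2)` (the scores have zero mean). The
#' two-sided p-value is the probability under label permutation of a
#' statistic at least as extreme in absolute value. When the number of
#' assignments `choose(n, n1)` does not exceed `maxEnumeration` the
#' distribution is enumerated completely and the p-value is exact;
#' otherwise it is estimated by Monte-Carlo with the observed assignment
#' included in numerator and denominator, so p is never 0.
#'
#' @param time,event pooled survival data.
#' @param group logical (or two-level) vector; TRUE / second level =
#'   biomarker-positive group.
#' @param maxEnumeration largest number of label assignments enumerated
#'   completely (default 2e6).
#' @param mcPermutations Monte-Carlo sample size used beyond the enumeration
#'   cutoff (default 1e5).
#' @param seed integer seed for the Monte-Carlo draw (required there;
#'   recorded in the result).
#' @return A list of class `exactLogrank`: `theta`, `p` (two-sided),
#'   `method` ("enumeration" or "monte_carlo"), `n_permutations`, `seed`,
#'   `n`, `n1`.
#' @examples
#' set.seed(1)
#' exactLogrank(rexp(8), rep(1, 8), rep(c(TRUE, FALSE), each = 4))
#' @export
exactLogrank <- function(time, event, group, maxEnumeration = 2e6,
                         mcPermutations = 1e5, seed = NULL) {
  if (!is.logical(group)) group <- group == sort(unique(group))[2L]
  n <- length(time)
  n1 <- sum(group)
  if (n1 == 0L || n1 == n) configError("exactLogrank: one group is empty")
  a <- logrankScores(time, event)
  s1 <- sum(a[group])
  v <- n1 * (n - n1) / (n * (n - 1)) * sum(a^2)
  theta <- if (v > 0) s1 / sqrt(v) else 0
  tol <- 1e-8 * max(1, abs(s1))
  nComb <- choose(n, n1)
  if (nComb <= maxEnumeration) {
    sums <- combnSums(a, n1)
    p <- sum(abs(sums) >= abs(s1) - tol) / length(sums)
    method <- "enumeration"
    nPerm <- length(sums)
  } else {
    if (is.null(seed)) configError("exactLogrank: seed required for Monte-Carlo")
    stateSaved <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    set.seed(seed)
    sums <- vapply(seq_len(mcPermutations),
                   function(i) sum(a[sample.int(n, n1)]), numeric(1))
    if (!is.null(stateSaved))
      assign(".Random.seed", stateSaved, envir = .GlobalEnv)
    p <- (1 + sum(abs(sums) >= abs(s1) - tol)) / (mcPermutations + 1)
    method <- "monte_carlo"
    nPerm <- mcPermutations
  }
  structure(list(theta = theta, p = p, method = method,
                 n_permutations = nPerm, seed = seed, n = n, n1 = n1),
            class = "exactLogrank")
}

# sums of the scores over all subsets of size k (iterative over utils::combn)
combnSums <- function(a, k) {
  utils::combn(length(a), k, FUN = function(idx) sum(a[idx]))
}

#' @export
print.exactLogrank <- function(x, ...) {
  cat(sprintf("Exact log-rank test (%s, %d assignments): theta = %.3f, p = %.4g\n",
              x$method, x$n_permutations, x$theta, x$p))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted q-values `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1 and
#' mapped back to the input order. Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @examples bhAdjust(c(0.0016, rep(0.5, 9)))[1]
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    configError("bhAdjust: p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Cox proportional-hazards fit with Wald inference
#'
#' Fits a (possibly stratified) Cox model by maximizing the partial
#' likelihood (via [survival::coxph()], Efron ties by default) and returns a
#' per-term coefficient table with hazard ratios, 95% confidence intervals
#' `exp(coef +/- 1.96 se)` and two-sided Wald p-values. Non-convergence and
#' monotone-likelihood (complete separation) are flagged; downstream
#' reporting refuses unconverged fits.
#'
#' @param data data.frame containing the time, event and model columns.
#' @param terms character vector of right-hand-side model terms.
#' @param strata optional character vector of stratification factors.
#' @param timeCol,eventCol names of the time and event columns.
#' @param ties ties method, "efron" (default) or "breslow".
#' @return A list of class `coxFit`: `table` (term, coef, se, hr, lo, hi, z,
#'   p), `loglik`, `converged`, `flags`, `n`, `n_events`, `model` (the
#'   underlying coxph object, kept for residual-based diagnostics).
#' @examples
#' d <- data.frame(time = rexp(100), event = 1, x = rep(0:1, 50))
#' coxFit(d, terms = "x")$table
#' @export
coxFit <- function(data, terms, strata = NULL, timeCol = "time",
                   eventCol = "event", ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  rhs <- terms
  if (length(strata))
    rhs <- c(rhs, sprintf("strata(%s)", paste(strata, collapse = ", ")))
  fml <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s",
                                   timeCol, eventCol,
                                   paste(rhs, collapse = " + ")))
  flags <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties, model = TRUE, x = TRUE),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite|singular",
                conditionMessage(w), ignore.case = TRUE))
        flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sf <- summary(fit)
  co <- sf$coefficients
  if (any(is.na(stats::coef(fit))))
    configError("coxFit: design matrix not full rank (NA coefficient)")
  converged <- fit$iter < 100 && length(flags) == 0L &&
    all(is.finite(co[, "se(coef)"])) && all(abs(co[, "coef"]) < 15)
  tab <- data.frame(
    term = rownames(co), coef = co[, "coef"], se = co[, "se(coef)"],
    hr = exp(co[, "coef"]),
    lo = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    hi = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    z = co[, "z"], p = co[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = fit$loglik[length(fit$loglik)],
                 converged = converged, flags = flags, n = fit$n,
                 n_events = fit$nevent, ties = ties, model = fit),
            class = "coxFit")
}

#' @export
print.coxFit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d%s\n", x$ties, x$n,
              x$n_events, if (!x$converged) "  [NOT CONVERGED]" else ""))
  print(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Treatment-by-biomarker interaction Wald test
#'
#' Fits a Cox model containing the treatment arm, the biomarker and their
#' product term (plus optional covariates and stratification factors) and
#' reports the Wald two-sided p-value of the interaction term — the test of
#' whether the treatment effect differs between biomarker strata (predictive
#' rather than prognostic effect).
#'
#' @param data data.frame with survival columns plus `armCol` and
#'   `biomarkerCol` (binary).
#' @param armCol,biomarkerCol names of the arm and biomarker columns.
#' @param covariates optional additional adjustment covariates.
#' @param strata optional stratification factors.
#' @inheritParams coxFit
#' @return A list of class `interactionResult`: `coef`, `hr_ratio` (ratio of
#'   arm hazard ratios between biomarker groups), `ci`, `p`, `fit` (the full
#'   [coxFit()]).
#' @export
interactionTest <- function(data, armCol = "arm", biomarkerCol = "biomarker",
                            covariates = NULL, strata = NULL,
                            timeCol = "time", eventCol = "event",
                            ties = "efron") {
  for (col in c(armCol, biomarkerCol)) {
    if (length(unique(data[[col]])) < 2L)
      configError(sprintf("interactionTest: '%s' has no variation (design not full rank)", col))
  }
  terms <- c(armCol, biomarkerCol, paste0(armCol, ":", biomarkerCol), covariates)
  fit <- coxFit(data, terms = terms, strata = strata, timeCol = timeCol,
                eventCol = eventCol, ties = ties)
  ia <- grepl(":", fit$table$term)
  row <- fit$table[ia, ][1, ]
  structure(list(coef = row$coef, hr_ratio = row$hr,
                 ci = c(lower = row$lo, upper = row$hi), p = row$p,
                 term = row$term, fit = fit),
            class = "interactionResult")
}

#' @export
print.interactionResult <- function(x, ...) {
  cat(sprintf("Interaction %s: HR ratio = %.3f (95%% CI %.3f-%.3f), Wald p = %.4g\n",
              x$term, x$hr_ratio, x$ci[1], x$ci[2], x$p))
  invisible(x)
}

#' Grambsch-Therneau proportional-hazards diagnostic
#'
#' Tests the proportional-hazards assumption of a fitted Cox model by
#' regressing the scaled Schoenfeld residuals on a transform of the event
#' times ([survival::cox.zph()]); returns per-term and global score tests.
#'
#' @param fit a converged [coxFit()].
#' @param transform time transform: "km" (default), "identity" or "rank".
#' @return A list of class `phTest`: `table` (term, chisq, df, p including a
#'   GLOBAL row), `transform`, `violated` (any p < 0.05).
#' @export
phTest <- function(fit, transform = c("km", "identity", "rank")) {
  transform <- match.arg(transform)
  stopifnot(inherits(fit, "coxFit"))
  if (fit$n_events == 0L) configError("phTest: no events in the fitted model")
  if (!fit$converged) configError("phTest: fit did not converge")
  z <- survival::cox.zph(fit$model, transform = transform, global = TRUE)
  tab <- data.frame(term = rownames(z$table), chisq = z$table[, "chisq"],
                    df = z$table[, "df"], p = z$table[, "p"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, transform = transform,
                 violated = any(tab$p < 0.05, na.rm = TRUE)),
            class = "phTest")
}

#' @export
print.phTest <- function(x, ...) {
  cat(sprintf("Proportional-hazards test (transform = %s)%s\n", x$transform,
              if (x$violated) "  [violation at 0.05]" else ""))
  print(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test with the probability-ordering convention: the
#' p-value sums the hypergeometric probabilities of all tables (at the
#' observed margins) no more probable than the observed one. This is the
#' convention required to reproduce baseline-table p-values; some software
#' defaults (e.g. tail-doubling) differ.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with `p` (two-sided) and `odds_ratio` (conditional MLE).
#' @examples fisherExact2x2(matrix(c(292, 83, 51, 3), 2))$p
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) configError("fisherExact2x2: table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    configError("fisherExact2x2: counts must be non-negative integers")
  ft <- stats::fisher.test(tab)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Pearson chi-squared test for an r x c contingency table
#'
#' Pearson statistic without continuity correction, df = (r-1)(c-1).
#'
#' @param tab matrix of non-negative counts; zero row/column margins are an
#'   error.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi2Contingency <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) configError("chi2Contingency: counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    configError("chi2Contingency: zero margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided two-sample rank-sum test. In `"exact"` mode the p-value comes
#' from the complete enumeration of the rank-sum distribution (twice the
#' smaller tail, capped at 1); ties across the pooled sample force a fall
#' back to the normal approximation with a warning. In `"normal_approx"`
#' mode the z statistic uses the rank-sum mean and variance with no
#' continuity correction.
#'
#' @param x,y non-empty numeric samples.
#' @param mode "exact" or "normal_approx".
#' @return list with `p`, `statistic` (rank-sum based W) and `mode` actually
#'   used.
#' @examples
#' wilcoxonRankSum(1:4, 5:8, mode = "exact")$p          # 2/70
#' wilcoxonRankSum(1:3, 4:7, mode = "normal_approx")$p  # ~0.034
#' @export
wilcoxonRankSum <- function(x, y, mode = c("exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L)
    configError("wilcoxonRankSum: samples must be non-empty")
  if (mode == "exact" && anyDuplicated(c(x, y))) {
    warning("ties present: falling back to normal approximation")
    mode <- "normal_approx"
  }
  wt <- if (mode == "exact")
    stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
  else
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  list(p = wt$p.value, statistic = unname(wt$statistic), mode = mode)
}
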