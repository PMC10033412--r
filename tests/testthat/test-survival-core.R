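test_that("Kaplan-Meier estimate matches the product-limit closed form", {
  # uncensored distinct times: survival drops 1/n per event
  t <- c(2, 4, 6, 8, 10)
  km <- kmFit(t, rep(1, 5))
  expect_equal(km$surv, seq(0.8, 0, by = -0.2))
  expect_equal(km$median, 6)  # earliest time with survival <= 0.5
  # all censored: median undefined
  expect_true(is.na(kmFit(t, rep(0, 5))$median))
  # hand-computed product-limit table for {3+, 5, 7, 9+, 11}
  km <- kmFit(c(3, 5, 7, 9, 11), c(0, 1, 1, 0, 1))
  ev <- km$n_event > 0
  expect_equal(km$surv[ev], c(3 / 4, 3 / 4 * 2 / 3, 0))
  expect_equal(km$median, 7)
  expect_error(kmFit(numeric(), numeric()), class = "cs_config_error")
})

test_that("log-rank scores follow the definition and sum to zero", {
  # single event, n = 1: score 1 - 1 = 0
  expect_equal(logrankScores(5, 1), 0)
  # 4-observation toy, hand-computed: {2, 3+, 4, 5}
  expect_equal(logrankScores(c(2, 3, 4, 5), c(1, 0, 1, 1)),
               c(0.75, -0.25, 0.25, -0.75))
  # scores sum to zero on random censored data (algebraic identity)
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    tm <- round(rexp(n, 0.2) + 0.1, 2)
    evn <- rbinom(n, 1, 0.7)
    a <- logrankScores(tm, evn)
    expect_equal(sum(a), 0, tolerance = 1e-12)
    expect_equal(a, oracleScores(tm, evn))
  }
})

test_that("exact log-rank enumeration equals the brute-force oracle on small data", {
  set.seed(7)
  for (i in 1:12) {
    n <- sample(5:10, 1)
    n1 <- sample(2:(n - 2), 1)
    tm <- round(rexp(n, 0.15) + 0.1, 2)
    evn <- rbinom(n, 1, 0.75)
    grp <- seq_len(n) %in% sample(n, n1)
    res <- exactLogrank(tm, evn, grp)
    expect_equal(res$method, "enumeration")
    expect_equal(res$p, oracleExactLogrankP(tm, evn, grp))
  }
})

test_that("exact log-rank degenerates correctly and Monte-Carlo agrees with enumeration", {
  # identical survival in both equal-sized groups: theta 0, p 1
  tm <- rep(c(1, 2, 3, 4), 2)
  evn <- rep(1, 8)
  res <- exactLogrank(tm, evn, rep(c(TRUE, FALSE), each = 4))
  # groups are exchangeable here; p must be 1 for the all-tied statistic
  expect_equal(res$theta, 0, tolerance = 1e-10)
  expect_equal(res$p, 1)
  expect_error(exactLogrank(tm, evn, rep(TRUE, 8)), class = "cs_config_error")

  set.seed(13)
  tm <- round(rexp(16, 0.2) + 0.1, 2)
  evn <- rbinom(16, 1, 0.8)
  grp <- rep(c(TRUE, FALSE), each = 8)
  exact <- exactLogrank(tm, evn, grp)                       # C(16,8) = 12870
  mc <- exactLogrank(tm, evn, grp, maxEnumeration = 100,
                     mcPermutations = 20000, seed = 99)
  expect_equal(mc$method, "monte_carlo")
  se <- sqrt(exact$p * (1 - exact$p) / 20000)
  expect_lt(abs(mc$p - exact$p), 3 * se + 1 / 20000)
  # same seed reproduces the same p
  mc2 <- exactLogrank(tm, evn, grp, maxEnumeration = 100,
                      mcPermutations = 20000, seed = 99)
  expect_identical(mc$p, mc2$p)
})

test_that("BH adjustment matches the step-up definition and is permutation invariant", {
  set.seed(5)
  for (i in 1:10) {
    p <- runif(sample(3:25, 1))
    expect_equal(bhAdjust(p), oracleBH(p))
    perm <- sample(length(p))
    expect_equal(bhAdjust(p[perm]), bhAdjust(p)[perm])
  }
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.1, 1.2)), class = "cs_config_error")
})

test_that("Cox fit recovers planted effects and matches the log-rank chi-square", {
  set.seed(21)
  # parameter recovery, true log HR = log 2
  b <- replicate(40, {
    n <- 800
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.1 * exp(log(2) * x))
    cns <- rexp(n, 0.025)
    d <- data.frame(time = pmin(t, cns), event = as.numeric(t <= cns), x = x)
    coxFit(d, "x")$table$coef
  })
  expect_lt(abs(mean(b) - log(2)), 0.05)
  # Wald z^2 approximates the asymptotic log-rank chi-square (single binary
  # covariate, no ties)
  n <- 4000
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1 * exp(0.4 * x))
  d <- data.frame(time = t, event = 1, x = x)
  fit <- coxFit(d, "x")
  lr <- survival::survdiff(survival::Surv(time, event) ~ x, data = d)$chisq
  expect_lt(abs(fit$table$z^2 - lr) / lr, 0.10)
  # confidence limits are exp(coef +/- 1.96 se)
  expect_equal(fit$table$lo, exp(fit$table$coef - 1.96 * fit$table$se))
  expect_equal(fit$table$hi, exp(fit$table$coef + 1.96 * fit$table$se))
  # rank deficiency is an error
  d$y <- d$x
  expect_error(coxFit(d, c("x", "y")), class = "cs_config_error")
})

test_that("interaction test finds planted interactions and rejects degenerate designs", {
  set.seed(31)
  # power: arm HR 1.0 in biomarker+, 0.55 in biomarker-, trial-like sizes
  hits <- replicate(20, {
    n <- 800
    bm <- rbinom(n, 1, 0.35)
    arm <- rbinom(n, 1, 2 / 3)
    lp <- ifelse(bm == 1, 0, log(0.55)) * arm
    t <- rexp(n, 0.12 * exp(lp))
    d <- data.frame(time = pmin(t, 24), event = as.numeric(t <= 24),
                    arm = arm, biomarker = bm)
    interactionTest(d)$p < 0.05
  })
  expect_gt(mean(hits), 0.5)
  d <- data.frame(time = rexp(50), event = 1, arm = rbinom(50, 1, 0.5),
                  biomarker = 0)
  expect_error(interactionTest(d), class = "cs_config_error")
})

test_that("proportional-hazards diagnostic flags planted time-varying effects", {
  set.seed(41)
  # planted beta(t) = log(t) violation at n = 500: high rejection rate
  rej <- replicate(25, {
    n <- 500
    x <- rbinom(n, 1, 0.5)
    # hazard h0 * t^x, i.e. beta(t) = log(t): closed-form inversion of the
    # cumulative hazard gives exponential (x = 0) vs Weibull shape 2 (x = 1)
    e <- rexp(n)
    t <- ifelse(x == 1, sqrt(2 * e / 0.08), e / 0.08)
    d <- data.frame(time = t, event = 1, x = x)
    fit <- coxFit(d, "x")
    phTest(fit)$table$p[1] < 0.05
  })
  expect_gt(mean(rej), 0.8)
  # degenerate: no events
  d <- data.frame(time = rexp(10) + 0.1, event = 1, x = rbinom(10, 1, 0.5))
  fit <- coxFit(d, "x")
  fit$n_events <- 0L
  expect_error(phTest(fit), class = "cs_config_error")
})

test_that("Fisher exact equals the hypergeometric probability-ordering oracle", {
  expect_equal(round(fisherExact2x2(matrix(c(292, 83, 51, 3), 2))$p, 4), 0.0031)
  expect_equal(fisherExact2x2(matrix(1, 2, 2))$p, 1.0)
  set.seed(9)
  for (i in 1:25) {
    tab <- matrix(rmultinom(1, sample(8:40, 1), runif(4, 0.05, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisherExact2x2(tab)$p, oracleFisherP(tab), tolerance = 1e-9)
  }
  expect_error(fisherExact2x2(matrix(c(-1, 2, 3, 4), 2)),
               class = "cs_config_error")
})

test_that("chi-squared contingency test matches the hand-computed Pearson statistic", {
  # perfectly proportional table: statistic 0, p 1
  res <- chi2Contingency(matrix(c(10, 20, 5, 10), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # hand-computed 2x3: X^2 = 16/3, df = 2
  tab <- matrix(c(10, 20, 20, 20, 30, 20), 2)
  res <- chi2Contingency(tab)
  expect_equal(res$statistic, 16 / 3)
  expect_equal(res$df, 2)
  # invariance under row permutation
  expect_equal(chi2Contingency(tab[2:1, ])$statistic, res$statistic)
  expect_error(chi2Contingency(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "cs_config_error")
})

test_that("Wilcoxon rank-sum reproduces exact and normal-approximation conventions", {
  # complete separation 4 vs 4: exact two-sided p = 2/70
  expect_equal(wilcoxonRankSum(1:4, 5:8, mode = "exact")$p, 2 / 70)
  # complete separation 3 vs 4, normal approximation: z = -6/sqrt(8)
  res <- wilcoxonRankSum(1:3, 4:7, mode = "normal_approx")
  expect_equal(res$p, 2 * pnorm(-6 / sqrt(8)))
  # identical samples: p = 1
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3),
                               mode = "normal_approx")$p, 1)
  # ties in exact mode fall back with a warning
  expect_warning(res <- wilcoxonRankSum(c(1, 2, 2), c(2, 3, 4), mode = "exact"),
                 "ties")
  expect_equal(res$mode, "normal_approx")
})
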