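# Independent oracles, written from the definitions and kept free of the
# package's own code paths.

# Censored-data log-rank scores computed with an explicit per-observation
# loop straight from the definition (event: 1 - sum_{t_j<=t} d_j/n_j;
# censored: -sum_{t_j<=t} d_j/n_j).
oracleScores <- function(time, event) {
  n <- length(time)
  out <- numeric(n)
  ets <- sort(unique(time[event == 1]))
  for (i in seq_len(n)) {
    h <- 0
    for (t in ets) {
      if (t <= time[i]) {
        d <- sum(time == t & event == 1)
        r <- sum(time >= t)
        h <- h + d / r
      }
    }
    out[i] <- if (event[i] == 1) 1 - h else -h
  }
  out
}

# Brute-force exact permutation log-rank p-value: enumerate every subset of
# size n1 explicitly (recursively, not via the package's combn path) and
# count assignments with |score sum| >= |observed|.
oracleExactLogrankP <- function(time, event, group) {
  a <- oracleScores(time, event)
  n <- length(a)
  n1 <- sum(group)
  sObs <- sum(a[group])
  tol <- 1e-8 * max(1, abs(sObs))
  count <- 0L
  total <- 0L
  subsets <- function(start, left, acc) {
    if (left == 0L) {
      total <<- total + 1L
      if (abs(acc) >= abs(sObs) - tol) count <<- count + 1L
      return(invisible())
    }
    if (start > n) return(invisible())
    for (i in start:(n - left + 1L)) subsets(i + 1L, left - 1L, acc + a[i])
  }
  subsets(1L, n1, 0)
  count / total
}

# Step-up Benjamini-Hochberg from the definition.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Two-sided Fisher p by the probability-ordering hypergeometric sum.
oracleFisherP <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pObs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Tiny hand-assembled cohort used across driver/enumeration tests.
fixtureCohort <- function() {
  variants <- data.frame(
    patient_id = c("A", "A", "B", "B", "C", "D", "E", "F"),
    gene       = c("KRAS", "TP53", "KRAS", "TP53", "KRAS", "APC", "APC", "KRAS"),
    gene_role  = c("oncogene", "tsg", "oncogene", "tsg", "oncogene", "tsg",
                   "tsg", "oncogene"),
    variant_class = c("missense", "nonsense", "missense", "missense",
                      "missense", "missense", "nonsense", "missense"),
    codon      = c(12L, 213L, 12L, 175L, 13L, 1450L, 1450L, 12L),
    aa_change  = c("G12V", "R213*", "G12D", "R175H", "G13D", "T1450M",
                   "R1450*", "G12V"),
    variant_ploidy = c(1.5, 1.0, 2.0, 1.2, 1.4, 1.2, 0.9, 1.1),
    biallelic  = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    hotspot_distance = c(0, NA, 0, NA, 0, NA, NA, 0),
    repeat_count = NA_real_,
    driver_likelihood = c(0.99, 0.95, 0.99, 0.5, 0.99, 0.5, 0.9, 0.99),
    stringsAsFactors = FALSE)
  copyNumbers <- data.frame(
    patient_id = c("C", "D", "A", "B"),
    gene = c("MYC", "SMAD4", "TP53", "TP53"),
    gene_copy_number = c(9.0, 0.2, 2.0, 2.4),
    gene_ploidy = c(9.0, 0.2, 2.0, 2.4),
    sample_ploidy = c(2.0, 2.2, 2.0, 2.0),
    recurrent_amp = c(TRUE, FALSE, FALSE, FALSE),
    recurrent_del = c(FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  survival <- data.frame(
    patient_id = c("A", "B", "C", "D", "E", "F"),
    endpoint = "OS",
    time = c(3.1, 5.2, 7.4, 9.8, 11.0, 2.2),
    event = c(1, 1, 0, 1, 0, 1),
    arm = "none", stringsAsFactors = FALSE)
  covariates <- data.frame(
    patient_id = c("A", "B", "C", "D", "E", "F"),
    ecog = c("0-1", "0-1", ">=2", "0-1", "unknown", "0-1"),
    sex = c("male", "female", "male", "male", "female", "female"),
    stringsAsFactors = FALSE)
  ClinicoGenomicCohort(variants = variants, copyNumbers = copyNumbers,
                       survival = survival, covariates = covariates)
}

# Random small cohort for round-trip property tests.
randomCohort <- function(seed) {
  cfg <- scenarioConfig(nPatients = 12,
                        groupFreqs = c(KRAS_G12 = 0.4, KRAS_G13 = 0.2),
                        extraDrivers = data.frame(
                          gene = "APC", kind = "mutation", role = "tsg",
                          freq = 0.5, loghr = 0, codon = 1450L, aa = "R1450*",
                          stringsAsFactors = FALSE),
                        endpoints = c("OS", "PFS"))
  generateCohort(cfg, seed = seed)
}
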