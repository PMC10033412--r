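oncoVariant <- function(...) {
  base <- data.frame(patient_id = "P1", gene = "KRAS", gene_role = "oncogene",
                     variant_class = "missense", codon = 12L,
                     aa_change = "G12D", variant_ploidy = 1.5,
                     biallelic = FALSE, hotspot_distance = NA_real_,
                     repeat_count = NA_real_, driver_likelihood = NA_real_,
                     stringsAsFactors = FALSE)
  args <- list(...)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  base
}

test_that("oncogene rules fire in documented order with strict printed bounds", {
  ev <- classifyMutationDriver(oncoVariant(hotspot_distance = 0))
  expect_equal(ev$rule_fired, "oncogene_hotspot")
  # within five bases still qualifies; six does not
  expect_equal(classifyMutationDriver(oncoVariant(hotspot_distance = 5))$rule_fired,
               "oncogene_hotspot")
  expect_null(classifyMutationDriver(oncoVariant(hotspot_distance = 6,
                                                 driver_likelihood = 0.5)))
  # inframe indel repeat-count bound is strict (<8)
  ii7 <- oncoVariant(variant_class = "inframe_indel", repeat_count = 7,
                     aa_change = NA_character_, codon = NA_integer_)
  ii8 <- oncoVariant(variant_class = "inframe_indel", repeat_count = 8,
                     aa_change = NA_character_, codon = NA_integer_)
  expect_equal(classifyMutationDriver(ii7)$rule_fired, "oncogene_inframe_indel")
  expect_null(classifyMutationDriver(ii8))
  # likelihood bound is strict (>0.80)
  expect_null(classifyMutationDriver(oncoVariant(driver_likelihood = 0.80)))
  expect_equal(classifyMutationDriver(oncoVariant(driver_likelihood = 0.81))$rule_fired,
               "driver_likelihood")
})

tsgVariant <- function(...) {
  v <- oncoVariant(...)
  v$gene <- "TP53"; v$gene_role <- "tsg"
  v
}

test_that("tumor-suppressor drivers require the biallelic or two-hit condition", {
  # biallelic nonsense is a driver
  ev <- classifyMutationDriver(tsgVariant(variant_class = "nonsense",
                                          biallelic = TRUE))
  expect_equal(ev$rule_fired, "tsg_biallelic")
  # single non-biallelic nonsense with low likelihood is not
  expect_null(classifyMutationDriver(tsgVariant(variant_class = "nonsense",
                                                driver_likelihood = 0.5)))
  # two-hit ploidy sum: 1.2 + 0.9 = 2.1 >= 2.4 - 0.5
  two <- rbind(tsgVariant(variant_ploidy = 1.2),
               tsgVariant(variant_ploidy = 0.9))
  ev <- classifyMutationDriver(two, genePloidy = 2.4)
  expect_equal(ev$rule_fired, "tsg_two_hit_ploidy_sum")
  # at exactly gene_ploidy - 0.5 the default >= fires, the strict variant not
  boundary <- rbind(tsgVariant(variant_ploidy = 1.0),
                    tsgVariant(variant_ploidy = 0.9))
  expect_equal(classifyMutationDriver(boundary, genePloidy = 2.4)$rule_fired,
               "tsg_two_hit_ploidy_sum")
  expect_null(classifyMutationDriver(boundary, genePloidy = 2.4,
                                     cfg = driverRules(twoHitStrict = TRUE)))
  # sum below threshold fails
  expect_null(classifyMutationDriver(rbind(tsgVariant(variant_ploidy = 0.5),
                                           tsgVariant(variant_ploidy = 0.5)),
                                     genePloidy = 2.4))
  # high likelihood alone does not rescue a non-biallelic single TSG mutation...
  expect_null(classifyMutationDriver(tsgVariant(driver_likelihood = 0.95)))
  # ...unless the two-hit requirement is relaxed in the configuration
  ev <- classifyMutationDriver(tsgVariant(driver_likelihood = 0.95),
                               cfg = driverRules(tsgRequireTwoHit = FALSE))
  expect_equal(ev$rule_fired, "driver_likelihood")
  # biallelic missense with high likelihood qualifies via the likelihood rule
  ev <- classifyMutationDriver(tsgVariant(driver_likelihood = 0.95,
                                          biallelic = TRUE))
  expect_equal(ev$rule_fired, "driver_likelihood")
})

test_that("two-hit rule with absent variant ploidy degrades to false with a warning", {
  two <- rbind(tsgVariant(variant_ploidy = NA_real_),
               tsgVariant(variant_ploidy = 0.9))
  expect_warning(ev <- classifyMutationDriver(two, genePloidy = 2.0),
                 "two-hit")
  expect_null(ev)
})

cnRec <- function(copy, ploidy = 2.0, amp = FALSE, del = FALSE) {
  data.frame(patient_id = "P1", gene = "MYC", gene_copy_number = copy,
             gene_ploidy = copy, sample_ploidy = ploidy,
             recurrent_amp = amp, recurrent_del = del, stringsAsFactors = FALSE)
}

test_that("amplification and deletion rules respect strict thresholds and recurrence gates", {
  expect_equal(classifyAmplification(cnRec(7.2, amp = TRUE))$event_class,
               "amplification")
  expect_null(classifyAmplification(cnRec(6.0, amp = TRUE)))   # exactly 3x
  expect_null(classifyAmplification(cnRec(9.0, amp = FALSE)))  # recurrence gate
  expect_equal(classifyDeletion(cnRec(0.3, del = TRUE))$event_class, "deletion")
  expect_null(classifyDeletion(cnRec(0.5, del = TRUE)))        # boundary
  expect_null(classifyDeletion(cnRec(0.1, del = FALSE)))
})

test_that("callDrivers on the fixture cohort matches the hand-derived truth table", {
  cg <- fixtureCohort()
  ev <- callDrivers(cg)
  # hand application of the rules:
  #  A: KRAS hotspot; TP53 biallelic nonsense          -> 2 mutation drivers
  #  B: KRAS hotspot; TP53 single non-biallelic missense (lik 0.5) -> 1
  #  C: KRAS hotspot (G13D); MYC amp 9.0 > 3*2.0       -> 2
  #  D: APC single missense lik 0.5 -> none; SMAD4 del 0.2 < 0.5 -> 1
  #  E: APC biallelic nonsense                          -> 1
  #  F: KRAS hotspot                                    -> 1
  truth <- data.frame(
    patient_id = c("A", "A", "B", "C", "C", "D", "E", "F"),
    gene = c("KRAS", "TP53", "KRAS", "KRAS", "MYC", "SMAD4", "APC", "KRAS"),
    event_class = c("mutation", "mutation", "mutation", "mutation",
                    "amplification", "deletion", "mutation", "mutation"),
    rule_fired = c("oncogene_hotspot", "tsg_biallelic", "oncogene_hotspot",
                   "oncogene_hotspot", "amp_threshold", "del_homozygous",
                   "tsg_biallelic", "oncogene_hotspot"),
    stringsAsFactors = FALSE)
  truth <- truth[order(truth$patient_id, truth$gene, truth$event_class), ]
  rownames(truth) <- NULL
  expect_equal(ev, truth)
  # empty cohort gives an empty event list
  expect_equal(nrow(callDrivers(ClinicoGenomicCohort())), 0L)
})

test_that("tightening thresholds is monotone and rule removal is clean", {
  cg <- generateCohort(cohortPreset("discovery_like"), seed = 3)
  base <- callDrivers(cg)
  cases <- list(
    list(cfg = driverRules(likelihoodMin = 0.999), rule = "driver_likelihood"),
    list(cfg = driverRules(ampPloidyMultiple = 100), rule = "amp_threshold"),
    list(cfg = driverRules(delCopyMax = 1e-6), rule = "del_homozygous"))
  key <- function(d) paste(d$patient_id, d$gene, d$event_class)
  for (cs in cases) {
    restricted <- callDrivers(cg, cs$cfg)
    expect_lte(nrow(restricted), nrow(base))
    # disabling one rule removes only events attributed to that rule
    lost <- base[!key(base) %in% key(restricted), , drop = FALSE]
    expect_true(all(lost$rule_fired == cs$rule))
  }
  # determinism: identical input gives identical output
  expect_identical(callDrivers(cg), base)
})
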