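# enumeration oracle for the exact HWE test: full conditional distribution
# of the heterozygote count given allele counts
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, 2 * n - n_a)
  hets <- seq(rare %% 2, rare, by = 2)
  prob <- vapply(hets, function(h) {
    na2 <- (rare - h) / 2
    nb2 <- n - h - na2
    exp(lgamma(n + 1) - lgamma(na2 + 1) - lgamma(h + 1) - lgamma(nb2 + 1) +
          h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
          lgamma(2 * n + 1))
  }, numeric(1))
  obs <- min(n_ab, rare)
  sum(prob[prob <= prob[match(obs, hets)] + 1e-12]) / sum(prob)
}

test_that("exact HWE test matches full enumeration on n <= 50", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(5:50, 1)
    counts <- as.vector(stats::rmultinom(1, n, c(0.3, 0.45, 0.25)))
    expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]),
                 hwe_oracle(counts[1], counts[2], counts[3]),
                 tolerance = 1e-10)
  }
  # balanced 25/50/25: perfectly HWE-consistent
  expect_gt(hwe_exact_test(25, 50, 25), 0.5)
  # all heterozygotes: extreme excess
  expect_lt(hwe_exact_test(0, 100, 0), 1e-6)
})

test_that("snp_summary computes call rate, MAF and flags", {
  study <- tiny_study()
  s <- snp_summary(study)
  expect_equal(s$call_rate[s$marker_id == "M3"], 8 / 9)
  expect_equal(s$call_rate[s$marker_id == "M1"], 1)
  g <- study$genotypes[, "M1"]
  p_alt <- sum(g, na.rm = TRUE) / (2 * sum(!is.na(g)))
  expect_equal(s$maf[s$marker_id == "M1"], min(p_alt, 1 - p_alt))
  expect_false(any(s$monomorphic))

  # a monomorphic marker: no heterozygous calls
  g2 <- study$genotypes
  g2[, "M2"] <- 0L
  s2 <- snp_summary(genotype_study(study$markers, study$pedigree, g2))
  expect_true(s2$monomorphic[s2$marker_id == "M2"])
  expect_equal(s2$maf[s2$marker_id == "M2"], 0)
})

test_that("Mendelian agreement follows 1 - errors/tested", {
  study <- tiny_study()
  ma <- mendelian_agreement(study)
  expect_true(all(ma$agreement == 1, na.rm = TRUE))
  # dam AA, sire AA, progeny Aa is one error
  g <- study$genotypes
  g["SIRE", "M1"] <- 0L; g["DAM", "M1"] <- 0L
  g[c("P1", "P2", "P3"), "M1"] <- c(1L, 0L, 0L)
  ma2 <- mendelian_agreement(genotype_study(study$markers, study$pedigree, g))
  expect_equal(ma2$n_errors[ma2$marker_id == "M1"], 1)
  expect_equal(ma2$agreement[ma2$marker_id == "M1"], 1 - 1 / 3)
  # direct arithmetic of the agreement formula
  expect_equal(1 - 0 / 100, 1)
  expect_equal(1 - 2 / 200, 0.99)
})

test_that("duplicate detection flags identical columns, not 10% divergent", {
  sim <- small_sim(seed = 21)
  g <- sim$study$genotypes
  g <- cbind(g, DUPLICATE = g[, 1])
  div <- g[, 2]
  flip <- seq(1, nrow(g), by = 10)
  div[flip] <- ifelse(is.na(div[flip]) | div[flip] == 0L, 2L, 0L)
  g <- cbind(g, DIVERGENT = div)
  mk <- rbind(sim$study$markers,
              data.frame(marker_id = c("DUPLICATE", "DIVERGENT"),
                         allele_ref = "A", allele_alt = "B"))
  study <- genotype_study(mk, sim$study$pedigree, g)
  dup <- detect_duplicates(study)
  expect_true(any(dup$marker_a == colnames(g)[1] &
                  dup$marker_b == "DUPLICATE"))
  expect_false("DIVERGENT" %in% c(dup$marker_a, dup$marker_b))
  # a column is never paired with itself
  expect_false(any(dup$marker_a == dup$marker_b))
})

test_that("qc ledger conserves counts and derives the array rates", {
  steps <- c(no_amplify = 539, ambiguous = 1169, monomorphic = 318,
             hwe_deviation = 163, mi_gross = 399, mi_residual = 48,
             low_maf = 42, duplicate = 43, low_call = 140, two_cluster = 50)
  led <- qc_ledger(8967, steps)
  expect_equal(led$n_remaining[nrow(led)], 8967 - sum(steps))
  expect_true(all(diff(led$n_remaining) <= 0))
  r <- qc_rates(led, 8967)
  expect_equal(r$n_genotyped, 7259)
  expect_equal(r$n_final, 6056)
  # all-zero exclusions: rates 100%
  led0 <- qc_ledger(100, setNames(rep(0, length(steps)), names(steps)))
  r0 <- qc_rates(led0, 100)
  expect_equal(r0$conversion_rate, 100)
  expect_equal(r0$validation_rate, 100)
  expect_equal(r0$final_rate, 100)
  expect_error(qc_ledger(10, c(a = 11)), "negative")
})

test_that("apply_qc_pipeline orders exclusions and conserves the ledger", {
  sim <- small_sim(seed = 31, missing_rate = 0.03)
  mk <- sim$study$markers
  mk$flag_ambiguous <- c(TRUE, rep(FALSE, nrow(mk) - 1))
  g <- sim$study$genotypes
  g[, 2] <- 0L                                  # monomorphic
  g[sample(nrow(g), 3), ] <- NA_integer_        # three bad samples
  study <- genotype_study(mk, sim$study$pedigree, g)
  res <- apply_qc_pipeline(study)
  expect_gte(res$n_samples_excluded, 3)
  led <- res$ledger
  expect_equal(sum(led$n_excluded) + led$n_remaining[nrow(led)], nrow(mk))
  expect_gte(led$n_excluded[led$label == "ambiguous"], 1)
  expect_gte(led$n_excluded[led$label == "monomorphic"], 1)
  expect_identical(ncol(res$study$genotypes),
                   as.integer(led$n_remaining[nrow(led)]))
})

test_that("in-silico filter applies each rule and the proximity dialects", {
  cand <- data.frame(
    contig_id = c("c1", "c1", "c2", "c3", "c4", "c5", "c6", "c7", "c8"),
    position = c(100, 140, 50, 50, 50, 50, 50, 50, 50),
    alleles = c("A/C", "A/G", "A/C/G", "A/T", "A/C", "A/C", "A/C", "A/C",
                "A/G"),
    read_depth = c(20, 20, 20, 20, 20, 20, 20, 9, 20),
    minor_allele_reads = c(6, 6, 6, 6, 6, 6, 6, 3, 6),
    maf_insilico = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.2),
    snp_quality = 30, flanking_quality = 30,
    repeat_masked = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                      FALSE),
    adt_score = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.5, 0.9, 0.9, 0.9),
    probe_unique = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  res <- insilico_snp_filter(cand)
  led <- res$ledger
  by_label <- setNames(led$n_excluded, led$label)
  expect_equal(by_label[["quality"]], 2)        # depth 9 and MAF 0.2
  expect_equal(by_label[["multi_allelic"]], 1)
  expect_equal(by_label[["infinium_type_i"]], 1)
  expect_equal(by_label[["repeat_masked"]], 1)
  expect_equal(by_label[["low_adt"]], 1)
  expect_equal(by_label[["probe_not_unique"]], 1)
  # both members of the 40 bp pair on c1 are dropped
  expect_equal(by_label[["flanking_proximity"]], 2)
  expect_identical(nrow(res$survivors), 0L)
  # keep-better retains the higher-quality member
  cand2 <- cand[1:2, ]
  cand2$snp_quality <- c(40, 30)
  res2 <- insilico_snp_filter(cand2, proximity_rule = "keep_better")
  expect_identical(res2$survivors$contig_id, "c1")
  expect_identical(res2$survivors$position, 100)
  expect_equal(sum(res2$ledger$n_excluded) +
                 res2$ledger$n_remaining[nrow(res2$ledger)], 2)
})

test_that("parent reconstruction matches the three-state enumeration", {
  # dam AA, 10 progeny AA -> sire AA with likelihood 1 vs (1/2)^10
  rec <- reconstruct_parent_genotype(0L, matrix(0L, 10, 1))
  expect_identical(rec$ml_genotype, 0L)
  expect_equal(rec$loglik_0, 0)
  expect_equal(rec$loglik_1, 10 * log(0.5))
  expect_true(!is.finite(rec$loglik_2))
  # dam Aa, progeny 5 AA + 5 Aa -> sire AA beats Aa
  rec2 <- reconstruct_parent_genotype(1L, matrix(c(rep(0L, 5), rep(1L, 5)),
                                                 ncol = 1))
  expect_identical(rec2$ml_genotype, 0L)
  expect_equal(rec2$loglik_0, 10 * log(0.5))
  expect_equal(rec2$loglik_1, 5 * log(0.25) + 5 * log(0.5))
  # dam AA with an aa progeny: impossible under every sire genotype
  rec3 <- reconstruct_parent_genotype(0L, matrix(c(0L, 2L), ncol = 1))
  expect_true(rec3$incompatible)
  expect_true(is.na(rec3$ml_genotype))
  # all-missing progeny column flagged undefined
  rec4 <- reconstruct_parent_genotype(0L, matrix(NA_integer_, 4, 1))
  expect_true(rec4$undefined)
})

test_that("masked sires are recovered from >= 10 clean progeny", {
  cfg <- sim_config(n_lgs = 2, markers_per_lg = 15, n_families = 6,
                    progeny_per_family = 12, genotype_error_rate = 0,
                    missing_rate = 0, masked_parent_fraction = 0.5,
                    seed = 44)
  sim <- simulate_study(cfg)
  ped <- sim$study$pedigree
  acc <- c()
  for (m in sim$truth$masked_parents) {
    fam <- ped$family_id[ped$sample_id == m]
    dam <- ped$sample_id[ped$generation == "parent" & ped$sex == "F" &
                         ped$family_id == fam]
    prog <- ped$sample_id[ped$generation == "progeny" &
                          ped$family_id == fam]
    rec <- reconstruct_parent_genotype(sim$study$genotypes[dam, ],
                                       sim$study$genotypes[prog, ])
    truth <- sim$truth$true_genotypes[m, ]
    ok <- !rec$undefined & !rec$incompatible
    expect_false(any(rec$incompatible))
    acc <- c(acc, rec$ml_genotype[ok] == truth[ok])
  }
  expect_gte(mean(acc), 0.99)
})

test_that("injected progeny incompatibility flags the locus", {
  pg <- matrix(c(rep(0L, 9), 2L), ncol = 1)
  rec <- reconstruct_parent_genotype(0L, pg)
  expect_true(rec$incompatible)
})
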