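test_that("EM equals direct gamete counting without double heterozygotes", {
  g1 <- c(rep(0L, 40), rep(0L, 10), rep(2L, 10), rep(2L, 40))
  g2 <- c(rep(0L, 40), rep(2L, 10), rep(0L, 10), rep(2L, 40))
  em <- em_haplotype_freqs(g1, g2)
  expect_equal(unname(em$freq), c(0.4, 0.1, 0.1, 0.4), tolerance = 1e-12)
  st <- ld_pair_stats(em)
  expect_equal(st$D, 0.15, tolerance = 1e-12)
  expect_equal(st$d_prime, 0.6, tolerance = 1e-12)
  expect_equal(st$r2, 0.36, tolerance = 1e-12)
})

test_that("all double heterozygotes converge to the symmetric point", {
  em <- em_haplotype_freqs(rep(1L, 50), rep(1L, 50))
  expect_equal(em$freq[["AB"]], em$freq[["ab"]], tolerance = 1e-8)
  expect_equal(em$freq[["Ab"]], em$freq[["aB"]], tolerance = 1e-8)
  expect_equal(sum(em$freq), 1, tolerance = 1e-12)
})

test_that("EM recovers phased haplotype frequencies from simulated data", {
  sim <- small_sim(seed = 81, genotype_error_rate = 0, missing_rate = 0)
  fd <- simulate_founders(simulate_true_map(
    sim_config(n_lgs = 1, markers_per_lg = 6, n_families = 30,
               n_ancestral_haplotypes = 4, mosaic_switch_rate = 0.02,
               seed = 82)),
    sim_config(n_lgs = 1, markers_per_lg = 6, n_families = 30,
               n_ancestral_haplotypes = 4, mosaic_switch_rate = 0.02,
               seed = 82))
  h <- fd$haplotypes
  # diploids paired from consecutive haplotypes
  odd <- seq(1, nrow(h), by = 2)
  g1 <- h[odd, 1] + h[odd + 1, 1]
  g2 <- h[odd, 2] + h[odd + 1, 2]
  # genotype pair without double heterozygotes -> truth is exact counting
  dh <- g1 == 1 & g2 == 1
  em <- em_haplotype_freqs(g1[!dh], g2[!dh])
  hap1 <- c(h[odd, 1][!dh], h[odd + 1, 1][!dh])
  hap2 <- c(h[odd, 2][!dh], h[odd + 1, 2][!dh])
  truth <- c(mean(hap1 == 0 & hap2 == 0), mean(hap1 == 0 & hap2 == 1),
             mean(hap1 == 1 & hap2 == 0), mean(hap1 == 1 & hap2 == 1))
  expect_equal(unname(em$freq), truth, tolerance = 1e-6)
})

test_that("EM log-likelihood is non-decreasing and converges", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(30:120, 1)
    g1 <- sample(0:2, n, replace = TRUE, prob = c(0.3, 0.45, 0.25))
    g2 <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    em <- em_haplotype_freqs(g1, g2)
    expect_true(all(diff(em$loglik) >= -1e-9))
    expect_true(em$converged)
    expect_equal(sum(em$freq), 1, tolerance = 1e-9)
  }
})

test_that("LD statistics: bounds, complete LD, equilibrium, degeneracy", {
  expect_equal(ld_pair_stats(c(AB = 0.5, Ab = 0, aB = 0, ab = 0.5))$d_prime,
               1)
  expect_equal(ld_pair_stats(c(AB = 0.5, Ab = 0, aB = 0, ab = 0.5))$r2, 1)
  eq <- ld_pair_stats(c(AB = 0.25, Ab = 0.25, aB = 0.25, ab = 0.25))
  expect_equal(eq$D, 0)
  expect_equal(eq$r2, 0)
  mono <- ld_pair_stats(c(AB = 0.7, Ab = 0.3, aB = 0, ab = 0))
  expect_false(mono$defined)
  set.seed(42)
  for (i in 1:100) {
    f <- as.vector(stats::rmultinom(1, 60, runif(4, 0.05, 1)))
    f <- f / sum(f)
    st <- ld_pair_stats(setNames(f, c("AB", "Ab", "aB", "ab")))
    if (!st$defined) next
    expect_gte(st$r2, 0); expect_lte(st$r2, 1 + 1e-12)
    expect_gte(st$d_prime, 0); expect_lte(st$d_prime, 1 + 1e-12)
    expect_lte(st$r2, st$d_prime + 1e-9)
  }
})

test_that("LD decays with map distance under the mosaic model", {
  sim <- medium_sim(seed = 83)
  map <- build_linkage_map(sim$study)
  prof <- ld_decay_profile(sim$study, map, bin_edges = c(0, 3, 6, 12, 25, 50))
  bins <- prof$bins[prof$bins$n_pairs > 5, ]
  mids <- seq_len(nrow(bins))
  rho <- stats::cor.test(mids, bins$mean_r2, method = "spearman",
                         exact = FALSE)
  expect_lt(rho$estimate, 0)
  expect_lt(rho$p.value, 0.05)
  expect_gt(prof$adjacent$mean_r2, bins$mean_r2[nrow(bins)])
})

test_that("single-marker groups contribute no LD pairs", {
  sim <- small_sim(seed = 84)
  tab <- data.frame(marker_id = colnames(sim$study$genotypes)[1:3],
                    lg = c("L1", "L2", "L2"),
                    pos_sexavg = c(0, 0, 5), pos_f = NA, pos_m = NA,
                    method = "linkage", stringsAsFactors = FALSE)
  prof <- ld_decay_profile(sim$study, tab, bin_edges = c(0, 10))
  expect_true(all(prof$pairs$lg == "L2"))
})

test_that("LODE assignment rules: counts, gates, ties", {
  ld <- data.frame(lg = c("LG3", "LG3", "LG3", "LG7"),
                   pos = c(10, 12, 14, 50),
                   r2 = c(0.20, 0.15, 0.12, 0.05))
  pl <- lode_assign_lg(ld)
  expect_identical(pl$assigned_lg, "LG3")
  expect_identical(pl$n_qualifying_pairs, 3L)
  # only two qualifying pairs anywhere -> unassigned
  ld2 <- ld; ld2$r2 <- c(0.2, 0.15, 0.05, 0.04)
  expect_true(is.na(lode_assign_lg(ld2)$assigned_lg))
  expect_match(lode_assign_lg(ld2)$reason, "min_pairs")
  # exact tie between two groups -> unassigned
  ld3 <- data.frame(lg = rep(c("A", "B"), each = 3),
                    pos = c(1, 2, 3, 1, 2, 3),
                    r2 = rep(c(0.3, 0.2, 0.15), 2))
  expect_match(lode_assign_lg(ld3)$reason, "tie")
  # count beats max r2: A has 3 qualifying, B has 2 with a higher max
  ld4 <- data.frame(lg = c("A", "A", "A", "B", "B"),
                    pos = c(1, 2, 3, 1, 2),
                    r2 = c(0.12, 0.11, 0.11, 0.5, 0.4))
  expect_identical(lode_assign_lg(ld4)$assigned_lg, "A")
})

test_that("LODE position is the r2-weighted partner mean", {
  ld <- data.frame(lg = "LG3", pos = c(10, 12, 14), r2 = c(0.4, 0.2, 0.2))
  pl <- lode_assign_lg(ld)
  pl <- lode_position(pl, ld)
  expect_equal(pl$position, 11.5)
  expect_equal(pl$position_max_r2, 10)
  # a dominant partner pulls the estimate to itself
  ld2 <- data.frame(lg = "LG3", pos = c(10, 30, 31), r2 = c(0.9, 0.1, 0.1))
  pl2 <- lode_position(lode_assign_lg(ld2), ld2)
  expect_lt(abs(pl2$position - 10), 6)
})

test_that("lode_place conserves the orphan pool and updates the map", {
  cfg <- sim_config(n_lgs = 2, markers_per_lg = 15, lg_length = 50,
                    n_families = 20, progeny_per_family = 16,
                    n_ancestral_haplotypes = 2, mosaic_switch_rate = 0.1,
                    orphan_holdout_fraction = 0.15, seed = 85)
  sim <- simulate_study(cfg)
  orph <- sim$truth$orphans
  map <- build_linkage_map(sim$study, exclude = orph)
  res <- lode_place(sim$study, map, orphans = orph)
  pl <- res$placements
  expect_identical(nrow(pl), length(orph))
  placed <- pl$marker_id[!is.na(pl$assigned_lg)]
  # placed + unplaced = held out, and the map gained exactly the placed ones
  expect_setequal(c(placed, res$unplaced), orph)
  expect_identical(sum(res$map$table$method == "lode"), length(placed))
  # assignments respect the min-pairs gate
  expect_true(all(pl$n_qualifying_pairs[!is.na(pl$assigned_lg)] >= 3))
  # and are correct w.r.t. truth
  tr <- sim$truth$true_map
  tab <- map$table
  agree <- table(tab$lg, tr$lg[match(tab$marker_id, tr$marker_id)])
  maj <- apply(agree, 1, function(r) colnames(agree)[which.max(r)])
  ok <- maj[pl$assigned_lg[!is.na(pl$assigned_lg)]] ==
    tr$lg[match(placed, tr$marker_id)]
  expect_gte(mean(ok), 0.85)
})

test_that("a monomorphic orphan is never assigned", {
  sim <- medium_sim(seed = 86)
  g <- sim$study$genotypes
  orph <- colnames(g)[5]
  g[, orph] <- 0L
  study <- genotype_study(sim$study$markers, sim$study$pedigree, g)
  map <- build_linkage_map(study, exclude = orph)
  res <- lode_place(study, map, orphans = orph)
  expect_true(is.na(res$placements$assigned_lg[1]))
})
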