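test_that("Kosambi function, inverse, and closed-form values", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.2), 21.18245, tolerance = 1e-5)
  expect_equal(kosambi_inverse(21.18245), 0.2, tolerance = 1e-6)
  expect_true(is.infinite(kosambi(0.5)))
  th <- seq(0.01, 0.49, by = 0.01)
  expect_true(all(abs(kosambi_inverse(kosambi(th)) - th) < 1e-12))
  expect_error(kosambi(-0.1), ">= 0")
  expect_error(kosambi_inverse(-1), ">= 0")
})

test_that("phase deduction on forced, homozygous and ambiguous cases", {
  study <- tiny_study()
  ph <- phase_meioses(study)
  # M1: grandsire BB, granddam AA -> sire's alt allele is grandpaternal;
  # P1 is AA so the sire transmitted A (ref) = grandmaternal haplotype (2)
  row <- which(ph$meioses$parent_id == "SIRE" & ph$meioses$progeny_id == "P1")
  expect_equal(unname(ph$H[row, "M1"]), 2L)
  # P2 is BB: sire transmitted B = grandpaternal haplotype (1)
  row2 <- which(ph$meioses$parent_id == "SIRE" & ph$meioses$progeny_id == "P2")
  expect_equal(unname(ph$H[row2, "M1"]), 1L)
  # M4: both of the sire's grandparents het/uninformative combination
  # (GS1 Aa x GD1 Aa) -> ambiguous -> never informative for the sire
  sire_rows <- ph$meioses$parent_id == "SIRE"
  expect_true(all(is.na(ph$H[sire_rows, "M4"])))
})

test_that("homozygous parents yield no informative meioses", {
  study <- tiny_study()
  g <- study$genotypes
  g["SIRE", ] <- 0L
  g["DAM", ] <- 0L
  expect_error(phase_meioses(genotype_study(study$markers, study$pedigree,
                                            g)),
               "no informative meioses")
})

test_that("two-point estimates match closed forms and flag no-data pairs", {
  H <- h_for_pairs(list(list(a = 1, b = 2, n = 20, r = 0),
                        list(a = 2, b = 3, n = 100, r = 20),
                        list(a = 3, b = 4, n = 20, r = 10)), 5)
  ph <- fake_phased(H)
  tp12 <- twopoint(ph, "M1", "M2")
  expect_equal(tp12$theta, 0)
  expect_equal(tp12$lod, 20 * log10(2), tolerance = 1e-9)
  tp23 <- twopoint(ph, "M2", "M3")
  expect_equal(tp23$theta, 0.2)
  expect_equal(tp23$lod, 8.3707, tolerance = 1e-4)
  tp34 <- twopoint(ph, "M3", "M4")
  expect_equal(tp34$theta, 0.5)
  expect_equal(tp34$lod, 0)
  tp15 <- twopoint(ph, "M1", "M5")
  expect_identical(tp15$n, 0)
  expect_true(is.na(tp15$theta))
})

test_that("theta-hat is the MLE against a grid-search oracle", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    r <- rbinom(1, n, runif(1, 0.05, 0.6))
    theta_hat <- min(r / n, 0.5)
    grid <- seq(0, 0.5, by = 1e-4)
    ll <- vapply(grid, function(t) oracle_ll10(n, r, t), numeric(1))
    expect_lte(max(ll), oracle_ll10(n, r, theta_hat) + 1e-12)
  }
})

test_that("grouping uses transitive closure gated by LOD and distance", {
  # a-b and b-c strongly linked at ~10 cM; a-c weak directly
  H <- rbind(
    h_for_pairs(list(list(a = 1, b = 2, n = 100, r = 10),
                     list(a = 2, b = 3, n = 100, r = 10)), 5),
    h_for_pairs(list(list(a = 1, b = 3, n = 8, r = 4)), 5),
    # d-e: high LOD but at theta 0.302 (~35 cM) -> distance gate blocks
    h_for_pairs(list(list(a = 4, b = 5, n = 500, r = 151)), 5))
  ph <- fake_phased(H)
  tpm <- twopoint_matrices(ph)
  expect_gt(twopoint(tpm, "M4", "M5")$lod, 15)
  grp <- group_markers(tpm, lod_min = 10, dist_max = 30)
  expect_length(grp$groups, 1)
  expect_setequal(grp$groups[[1]], c("M1", "M2", "M3"))
  expect_setequal(grp$orphans, c("M4", "M5"))
})

test_that("simulated linkage groups are recovered pure and complete", {
  sim <- medium_sim(seed = 52, genotype_error_rate = 0, missing_rate = 0)
  ph <- phase_meioses(sim$study)
  grp <- group_markers(twopoint_matrices(ph))
  tr <- sim$truth$true_map
  # every candidate group is pure w.r.t. the true partition (markers from
  # different chromosomes are never joined)
  for (g in grp$groups)
    expect_length(unique(tr$lg[match(g, tr$marker_id)]), 1)
  # the full pipeline (with end-merging and orphan insertion) assigns all
  # markers to pure linkage groups matching the true partition
  map <- insert_orphans(build_linkage_map(sim$study))
  tab <- map$table
  for (lg in unique(tab$lg))
    expect_length(unique(tr$lg[match(tab$marker_id[tab$lg == lg],
                                     tr$marker_id)]), 1)
  expect_gte(nrow(tab), 0.95 * nrow(tr))
})

test_that("a theta chain places the middle marker centrally", {
  H <- h_for_pairs(list(list(a = 1, b = 2, n = 200, r = 10),
                        list(a = 2, b = 3, n = 200, r = 10),
                        list(a = 1, b = 3, n = 200, r = 20)), 3)
  ph <- fake_phased(H)
  tpm <- twopoint_matrices(ph)
  lg <- build_framework(c("M1", "M2", "M3"), tpm)
  expect_identical(lg$markers[2], "M2")
})

test_that("order likelihood is symmetric under reversal", {
  sim <- medium_sim(seed = 61)
  ph <- phase_meioses(sim$study)
  tpm <- twopoint_matrices(ph)
  grp <- group_markers(tpm)
  g <- grp$groups[[1]]
  lg <- build_framework(g, tpm)
  idx_f <- match(lg$markers, tpm$markers)
  C <- lodemap:::.ll10(tpm$N, tpm$R)
  ll_f <- sum(C[cbind(idx_f[-length(idx_f)], idx_f[-1])])
  idx_r <- rev(idx_f)
  ll_r <- sum(C[cbind(idx_r[-length(idx_r)], idx_r[-1])])
  expect_equal(ll_f, ll_r, tolerance = 1e-12)
  expect_equal(lg$loglik, ll_f, tolerance = 1e-9)
})

test_that("small groups are rejected as orphan passthrough", {
  sim <- small_sim(seed = 61)
  tpm <- twopoint_matrices(phase_meioses(sim$study))
  expect_error(build_framework(tpm$markers[1:2], tpm), "orphan passthrough")
})

test_that("map length equals the sum of its interval lengths", {
  sim <- medium_sim(seed = 62)
  map <- build_linkage_map(sim$study)
  for (lg in unique(map$table$lg)) {
    ints <- map$intervals[map$intervals$lg == lg, ]
    pos <- map$table$pos_sexavg[map$table$lg == lg]
    expect_equal(max(pos), sum(ints$d, na.rm = TRUE), tolerance = 1e-9)
    expect_true(all(diff(pos) >= 0))
  }
})

test_that("female and male maps share the locked sex-average order", {
  sim <- medium_sim(seed = 63, female_map_expansion = 1.5)
  map <- build_linkage_map(sim$study)
  map2 <- sex_specific_maps(map)
  expect_identical(map2$table$marker_id, map$table$marker_id)
  for (lg in unique(map2$table$lg)) {
    sel <- map2$table$lg == lg
    expect_true(all(diff(map2$table$pos_f[sel]) >= 0, na.rm = TRUE))
    expect_true(all(diff(map2$table$pos_m[sel]) >= 0, na.rm = TRUE))
  }
  # an interval with zero meioses in a sex stays undefined
  ints <- map2$intervals
  expect_true(all(is.na(ints$d_f[ints$n_f == 0])))
})

test_that("orphan insertion requires support and unique best group", {
  sim <- simulate_study(sim_config(n_lgs = 2, markers_per_lg = 15,
                                   lg_length = 50, n_families = 40,
                                   progeny_per_family = 16, seed = 64))
  tr <- sim$truth$true_map
  # hold out two well-covered interior markers (the reinsertion accuracy
  # claim presumes on the order of 200 informative meioses)
  ph <- phase_meioses(sim$study)
  info <- colSums(!is.na(ph$H))
  interior <- tr$marker_id[!tr$marker_id %in%
                             tr$marker_id[c(1, 15, 16, 30)]]
  held <- interior[order(-info[interior])][1:2]
  expect_gte(min(info[held]), 150)
  map <- build_linkage_map(sim$study, exclude = held)
  before <- nrow(map$table)
  map2 <- insert_orphans(map, orphans = held)
  tab <- map2$table
  errs <- c()
  for (mk in held) {
    expect_true(mk %in% tab$marker_id)
    lg_b <- tab$lg[tab$marker_id == mk]
    mates <- tab$marker_id[tab$lg == lg_b & tab$marker_id != mk]
    expect_identical(unique(tr$lg[match(mates, tr$marker_id)]),
                     tr$lg[tr$marker_id == mk])
    # position error against the true position interpolated onto the
    # built scale (itself noisy at this marker density)
    mk_pos <- tab$pos_sexavg[tab$marker_id == mk]
    tp <- tr$pos[match(mates, tr$marker_id)]
    bp <- tab$pos_sexavg[tab$lg == lg_b][tab$marker_id[tab$lg == lg_b] != mk]
    pred <- stats::approx(tp, bp, xout = tr$pos[tr$marker_id == mk],
                          rule = 2)$y
    errs <- c(errs, abs(mk_pos - pred))
  }
  expect_lt(median(errs), 5)
  expect_gte(nrow(map2$table), before + 2)

  # an orphan genotyped only in grandparents has no informative meioses
  # and stays an orphan
  g <- sim$study$genotypes
  keep <- sim$study$pedigree$sample_id[
    sim$study$pedigree$generation == "grandparent"]
  g[!rownames(g) %in% keep, held[1]] <- NA_integer_
  study2 <- genotype_study(sim$study$markers, sim$study$pedigree, g)
  map3 <- build_linkage_map(study2, exclude = held)
  map4 <- insert_orphans(map3, orphans = held[1])
  expect_true(held[1] %in% map4$orphans)
})

test_that("merge candidates: proposals for a split group, none across LGs", {
  sim <- medium_sim(seed = 65)
  map <- build_linkage_map(sim$study)
  tr <- sim$truth$true_map
  # artificially split the first LG in two at its midpoint
  tab <- map$table
  lg1 <- unique(tab$lg)[1]
  rows <- which(tab$lg == lg1)
  half <- rows[seq_len(floor(length(rows) / 2))]
  tab$lg[half] <- paste0(lg1, "a")
  tab$pos_sexavg[half] <- tab$pos_sexavg[half] - min(tab$pos_sexavg[half])
  rest <- setdiff(rows, half)
  tab$pos_sexavg[rest] <- tab$pos_sexavg[rest] - min(tab$pos_sexavg[rest])
  map$table <- tab[order(tab$lg, tab$pos_sexavg), ]
  prop <- merge_candidates(map, lod_min = 10)
  split_pair <- prop[(prop$lg_a == paste0(lg1, "a") & prop$lg_b == lg1) |
                     (prop$lg_b == paste0(lg1, "a") & prop$lg_a == lg1), ]
  expect_gte(nrow(split_pair), 1)
  expect_gte(max(split_pair$max_lod), 10)
  # no proposals joining markers of different true LGs
  if (nrow(prop)) {
    for (i in seq_len(nrow(prop))) {
      ta <- tr$lg[tr$marker_id == prop$marker_a[i]]
      tb <- tr$lg[tr$marker_id == prop$marker_b[i]]
      expect_identical(ta, tb)
    }
  }
})

test_that("single-LG map yields no merge proposals", {
  sim <- medium_sim(seed = 66)
  map <- build_linkage_map(sim$study)
  map$table <- map$table[map$table$lg == map$table$lg[1], , drop = FALSE]
  expect_identical(nrow(merge_candidates(map)), 0L)
})
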