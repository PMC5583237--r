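# Shared fixture builders. Everything is generated in code; no data files.

# A tiny hand-built study: 2 families, grandparent-traced, 4 markers.
tiny_study <- function() {
  markers <- data.frame(marker_id = paste0("M", 1:4),
                        allele_ref = "A", allele_alt = "B",
                        stringsAsFactors = FALSE)
  ped <- data.frame(
    sample_id = c("GS1", "GD1", "GS2", "GD2", "SIRE", "DAM",
                  "P1", "P2", "P3"),
    sire_id = c(NA, NA, NA, NA, "GS1", "GS2", "SIRE", "SIRE", "SIRE"),
    dam_id = c(NA, NA, NA, NA, "GD1", "GD2", "DAM", "DAM", "DAM"),
    sex = c("M", "F", "M", "F", "M", "F", "U", "U", "U"),
    family_id = "F1",
    generation = c(rep("grandparent", 4), "parent", "parent",
                   rep("progeny", 3)),
    stringsAsFactors = FALSE)
  g <- rbind(
    GS1 = c(2L, 2L, 0L, 1L),
    GD1 = c(0L, 0L, 2L, 1L),
    GS2 = c(0L, 2L, 0L, 0L),
    GD2 = c(2L, 0L, 2L, 2L),
    SIRE = c(1L, 1L, 1L, 1L),
    DAM = c(1L, 1L, 1L, 1L),
    P1 = c(0L, 1L, 1L, 2L),
    P2 = c(2L, 1L, 1L, 0L),
    P3 = c(1L, 2L, NA, 1L))
  colnames(g) <- markers$marker_id
  genotype_study(markers, ped, g)
}

# phased_meioses object built directly from a desired H matrix
fake_phased <- function(H, sex = rep("M", nrow(H)),
                        family = rep("F1", nrow(H))) {
  colnames(H) <- colnames(H, do.NULL = FALSE, prefix = "M")
  structure(list(
    H = H,
    meioses = data.frame(parent_id = paste0("PAR", seq_len(nrow(H))),
                         progeny_id = paste0("PR", seq_len(nrow(H))),
                         parent_sex = sex, family_id = family,
                         stringsAsFactors = FALSE)),
    class = "phased_meioses")
}

# H with prescribed pairwise (N, R) between consecutive markers: each block
# of rows is co-informative at exactly one marker pair
h_for_pairs <- function(pairs, n_markers) {
  # pairs: list of list(a=, b=, n=, r=)
  rows <- list()
  for (p in pairs) {
    blk <- matrix(NA_integer_, p$n, n_markers)
    blk[, p$a] <- 1L
    blk[, p$b] <- c(rep(2L, p$r), rep(1L, p$n - p$r))
    rows[[length(rows) + 1L]] <- blk
  }
  do.call(rbind, rows)
}

# default small simulated study reused across test files (kept modest)
small_sim <- function(seed = 42, ...) {
  simulate_study(sim_config(n_lgs = 2, markers_per_lg = 12, lg_length = 60,
                            n_families = 8, progeny_per_family = 10,
                            seed = seed, ...))
}

# medium study with full-strength meiosis counts, for grouping/ordering tests
medium_sim <- function(seed = 42, ...) {
  simulate_study(sim_config(n_lgs = 2, markers_per_lg = 15, lg_length = 50,
                            n_families = 20, progeny_per_family = 16,
                            seed = seed, ...))
}

# log10 likelihood at theta for (n, r): independent oracle used in several
# tests, written directly from the binomial form
oracle_ll10 <- function(n, r, theta) {
  t1 <- if (r > 0) r * log10(theta) else 0
  t2 <- if (n - r > 0) (n - r) * log10(1 - theta) else 0
  t1 + t2
}
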