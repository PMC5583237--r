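# Two-locus linkage disequilibrium from unphased genotypes and the two-step
# LODE placement of orphan markers (assign a linkage group by counts of
# high-r2 partners, then estimate the position from partner positions).

#' EM estimation of two-locus haplotype frequencies
#'
#' Standard EM for unphased diploid genotype pairs: all gametes are counted
#' directly except the double-heterozygote ambiguity, which is resolved in
#' expectation under the current frequencies. Initialized at linkage
#' equilibrium; the observed-data log-likelihood is non-decreasing over
#' iterations.
#'
#' @param g1,g2 integer genotype vectors (0/1/2/NA) at the two loci.
#' @param tol convergence tolerance on frequency change (default 1e-10).
#' @param max_iter iteration cap (default 1000).
#' @return list of class `ld_em`: `freq` (named `AB, Ab, aB, ab`; `A`/`B`
#'   are the reference alleles), `n` (samples used), `iterations`,
#'   `converged`, `loglik` (trace), `degenerate` (TRUE when a locus is
#'   monomorphic among the used samples — LD undefined).
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-10, max_iter = 1000L) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < 2) stop("need >= 2 samples with both genotypes non-missing")
  counts <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) counts[i + 1, j + 1] <- sum(g1 == i & g2 == j)
  degenerate <- length(unique(g1)) < 2 || length(unique(g2)) < 2

  # fixed gamete counts from unambiguous cells (A = ref at locus 1, B = ref
  # at locus 2); haplotype order AB, Ab, aB, ab
  base <- c(AB = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1],
            Ab = 2 * counts[1, 3] + counts[1, 2] + counts[2, 3],
            aB = 2 * counts[3, 1] + counts[3, 2] + counts[2, 1],
            ab = 2 * counts[3, 3] + counts[3, 2] + counts[2, 3])
  n_dh <- counts[2, 2]

  p_ref1 <- 1 - mean(g1) / 2
  p_ref2 <- 1 - mean(g2) / 2
  p <- c(AB = p_ref1 * p_ref2, Ab = p_ref1 * (1 - p_ref2),
         aB = (1 - p_ref1) * p_ref2, ab = (1 - p_ref1) * (1 - p_ref2))
  if (sum(p) == 0) p <- rep(0.25, 4)
  p <- p / sum(p)

  loglik_of <- function(p) {
    # multinomial over the 9 genotype cells with random haplotype pairing;
    # the double-het cell sums both phasings
    pAB <- p[1]; pAb <- p[2]; paB <- p[3]; pab <- p[4]
    pm <- matrix(c(pAB^2,         2 * pAB * pAb,                 pAb^2,
                   2 * pAB * paB, 2 * pAB * pab + 2 * pAb * paB, 2 * pAb * pab,
                   paB^2,         2 * paB * pab,                 pab^2),
                 3, 3, byrow = TRUE)
    sum(ifelse(counts > 0, counts * log(pm), 0))
  }

  ll <- loglik_of(p)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- p[1] * p[4] + p[2] * p[3]
    cis <- if (denom > 0) p[1] * p[4] / denom else 0.5
    cnt <- base + n_dh * c(cis, 1 - cis, 1 - cis, cis)
    p_new <- cnt / sum(cnt)
    ll <- c(ll, loglik_of(p_new))
    if (max(abs(p_new - p)) < tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
  }
  structure(list(freq = p, n = n, iterations = iter, converged = converged,
                 loglik = ll, degenerate = degenerate),
            class = "ld_em")
}

#' Pairwise LD statistics from haplotype frequencies
#'
#' `D = p_AB - p_A p_B`; `|D'| = |D| / D_max` with the standard bound
#' `D_max = min(p_A p_b, p_a p_B)` for `D > 0` and `min(p_A p_B, p_a p_b)`
#' for `D < 0`; `r2 = D^2 / (p_A p_a p_B p_b)`.
#'
#' @param freq an `ld_em` result or a named frequency vector
#'   `c(AB, Ab, aB, ab)`.
#' @return list: `D`, `d_prime`, `r2`, `p_A`, `p_B`, `defined` (FALSE when
#'   either locus is monomorphic).
#' @export
ld_pair_stats <- function(freq) {
  if (inherits(freq, "ld_em")) {
    if (freq$degenerate)
      return(list(D = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                  p_A = NA_real_, p_B = NA_real_, defined = FALSE))
    freq <- freq$freq
  }
  p_A <- freq[1] + freq[2]; p_B <- freq[1] + freq[3]
  p_a <- 1 - p_A; p_b <- 1 - p_B
  if (min(p_A, p_a, p_B, p_b) <= 0)
    return(list(D = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                p_A = unname(p_A), p_B = unname(p_B), defined = FALSE))
  D <- freq[1] - p_A * p_B
  d_max <- if (D >= 0) min(p_A * p_b, p_a * p_B) else min(p_A * p_B,
                                                          p_a * p_b)
  list(D = unname(D),
       d_prime = unname(if (d_max > 0) abs(D) / d_max else 0),
       r2 = unname(D^2 / (p_A * p_a * p_B * p_b)),
       p_A = unname(p_A), p_B = unname(p_B), defined = TRUE)
}

# samples used for LD estimation
.ld_samples <- function(study, samples = c("parents", "all")) {
  if (is.character(samples) && length(samples) == 1 &&
      samples %in% c("parents", "all")) {
    if (samples == "parents")
      study$pedigree$sample_id[study$pedigree$generation != "progeny"]
    else study$pedigree$sample_id
  } else samples  # explicit sample ids
}

# r2/D' between one marker and a set of markers
.ld_to_set <- function(study, marker, others, sample_ids) {
  g <- study$genotypes[sample_ids, , drop = FALSE]
  g1 <- g[, marker]
  out <- data.frame(marker_b = others,
                    r2 = rep(NA_real_, length(others)),
                    d_prime = rep(NA_real_, length(others)),
                    stringsAsFactors = FALSE)
  for (k in seq_along(others)) {
    ok <- !is.na(g1) & !is.na(g[, others[k]])
    if (sum(ok) < 2) next
    em <- em_haplotype_freqs(g1, g[, others[k]])
    st <- ld_pair_stats(em)
    out$r2[k] <- st$r2
    out$d_prime[k] <- st$d_prime
  }
  out
}

#' LD-decay profile along a map
#'
#' Pairwise within-LG LD among mapped markers, binned by map distance.
#' Related samples inflate LD, so the default sample set is the non-progeny
#' generation.
#'
#' @param study a [genotype_study()].
#' @param map a `genetic_map` or map table.
#' @param bin_edges cM bin edges (default `c(0, 1, 2, 5, 10, 20, 50)`).
#' @param samples `"parents"` (non-progeny, default), `"all"`, or explicit
#'   sample ids.
#' @return list: `bins` (per-bin pair count, mean/median r2, mean |D'|),
#'   `adjacent` (mean/median r2 over adjacent pairs only), `pairs` (the
#'   pair-level table).
#' @export
ld_decay_profile <- function(study, map, bin_edges = c(0, 1, 2, 5, 10, 20,
                                                       50),
                             samples = "parents") {
  tab <- if (inherits(map, "genetic_map")) map$table else as.data.frame(map)
  sample_ids <- .ld_samples(study, samples)
  g <- study$genotypes[sample_ids, , drop = FALSE]
  pairs <- list()
  for (lg in unique(tab$lg)) {
    sel <- tab[tab$lg == lg, , drop = FALSE]
    if (nrow(sel) < 2) next
    cmb <- combn(nrow(sel), 2)
    for (c_i in seq_len(ncol(cmb))) {
      i <- cmb[1, c_i]; j <- cmb[2, c_i]
      dist <- abs(sel$pos_sexavg[j] - sel$pos_sexavg[i])
      if (dist > max(bin_edges)) next
      ok <- !is.na(g[, sel$marker_id[i]]) & !is.na(g[, sel$marker_id[j]])
      if (sum(ok) < 2) next
      em <- em_haplotype_freqs(g[, sel$marker_id[i]], g[, sel$marker_id[j]])
      st <- ld_pair_stats(em)
      if (!st$defined) next
      pairs[[length(pairs) + 1L]] <- data.frame(
        lg = lg, marker_a = sel$marker_id[i], marker_b = sel$marker_id[j],
        adjacent = j == i + 1L, dist = dist, r2 = st$r2,
        d_prime = st$d_prime, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(lg = character(0), marker_a = character(0),
               marker_b = character(0), adjacent = logical(0),
               dist = numeric(0), r2 = numeric(0), d_prime = numeric(0))
  bin <- cut(pairs$dist, bin_edges, include.lowest = TRUE)
  bins <- data.frame(bin = levels(bin),
                     n_pairs = as.integer(table(bin)),
                     mean_r2 = as.numeric(tapply(pairs$r2, bin, mean)),
                     median_r2 = as.numeric(tapply(pairs$r2, bin, median)),
                     mean_d_prime = as.numeric(tapply(pairs$d_prime, bin,
                                                      mean)),
                     stringsAsFactors = FALSE)
  adj <- pairs[pairs$adjacent, , drop = FALSE]
  list(bins = bins,
       adjacent = list(n_pairs = nrow(adj), mean_r2 = mean(adj$r2),
                       median_r2 = median(adj$r2),
                       mean_d_prime = mean(adj$d_prime)),
       pairs = pairs)
}

#' LODE step 1: assign an orphan marker to a linkage group
#'
#' Per linkage group, the number of mapped partners with `r2 >= r2_min` is
#' counted; the orphan is assigned to the group with the most qualifying
#' pairs provided it has at least `min_pairs` of them and strictly beats
#' every other group on (count, then maximum r2). Ties leave the marker
#' unassigned.
#'
#' @param orphan_ld data.frame with columns `lg`, `pos`, `r2` — the
#'   orphan's LD to every mapped marker.
#' @param r2_min qualifying threshold (default 0.1).
#' @param min_pairs minimum qualifying pairs (default 3).
#' @return list of class `lode_placement`: `assigned_lg` (or NA),
#'   `n_qualifying_pairs`, `max_r2`, `reason` for non-assignment.
#' @export
lode_assign_lg <- function(orphan_ld, r2_min = 0.1, min_pairs = 3) {
  ld <- orphan_ld[!is.na(orphan_ld$r2), , drop = FALSE]
  if (!nrow(ld))
    return(structure(list(assigned_lg = NA_character_,
                          n_qualifying_pairs = 0L, max_r2 = NA_real_,
                          reason = "no defined LD"),
                     class = "lode_placement"))
  per_lg <- do.call(rbind, lapply(split(ld, ld$lg), function(d) {
    q <- d$r2 >= r2_min
    data.frame(lg = d$lg[1], n_qual = sum(q),
               max_r2 = if (any(q)) max(d$r2[q]) else max(d$r2),
               stringsAsFactors = FALSE)
  }))
  per_lg <- per_lg[order(-per_lg$n_qual, -per_lg$max_r2), , drop = FALSE]
  best <- per_lg[1, ]
  if (best$n_qual < min_pairs)
    return(structure(list(assigned_lg = NA_character_,
                          n_qualifying_pairs = best$n_qual,
                          max_r2 = best$max_r2,
                          reason = "fewer than min_pairs qualifying pairs"),
                     class = "lode_placement"))
  if (nrow(per_lg) > 1 && per_lg$n_qual[2] == best$n_qual &&
      abs(per_lg$max_r2[2] - best$max_r2) <= 1e-12)
    return(structure(list(assigned_lg = NA_character_,
                          n_qualifying_pairs = best$n_qual,
                          max_r2 = best$max_r2,
                          reason = "tie between linkage groups"),
                     class = "lode_placement"))
  structure(list(assigned_lg = best$lg, n_qualifying_pairs = best$n_qual,
                 max_r2 = best$max_r2, reason = NA_character_),
            class = "lode_placement")
}

#' LODE step 2: estimate an assigned orphan's position
#'
#' Position = r2-weighted mean cM of the qualifying partners on the
#' assigned group; the maximum-r2 partner's position is also reported.
#'
#' @param placement a [lode_assign_lg()] result.
#' @param orphan_ld the same LD table used for assignment.
#' @param r2_min qualifying threshold (default 0.1).
#' @return The placement with `position` (weighted mean), `position_max_r2`
#'   and `support` (qualifying partner table) added.
#' @export
lode_position <- function(placement, orphan_ld, r2_min = 0.1) {
  stopifnot(inherits(placement, "lode_placement"))
  if (is.na(placement$assigned_lg)) stop("orphan is not assigned")
  sup <- orphan_ld[!is.na(orphan_ld$r2) &
                   orphan_ld$lg == placement$assigned_lg &
                   orphan_ld$r2 >= r2_min, , drop = FALSE]
  placement$position <- sum(sup$pos * sup$r2) / sum(sup$r2)
  placement$position_max_r2 <- sup$pos[which.max(sup$r2)]
  placement$support <- sup
  placement
}

#' Place orphan markers on a map by LODE
#'
#' Runs the two LODE steps for each orphan: LD (r2) to every mapped marker
#' is estimated by two-locus EM on the chosen sample set, the orphan is
#' assigned to a linkage group, positioned, and inserted into the map table
#' with `method = "lode"`.
#'
#' @param study a [genotype_study()].
#' @param map a `genetic_map`.
#' @param orphans marker ids to place (default: the map's orphan pool).
#' @param r2_min qualifying threshold (default 0.1).
#' @param min_pairs minimum qualifying pairs (default 3).
#' @param samples LD sample set (see [ld_decay_profile()]).
#' @return list: `placements` (data.frame: `marker_id`, `assigned_lg`,
#'   `n_qualifying_pairs`, `max_r2`, `position`, `position_max_r2`,
#'   `reason`), `map` (with placed orphans added), `unplaced`.
#' @export
lode_place <- function(study, map, orphans = NULL, r2_min = 0.1,
                       min_pairs = 3, samples = "parents") {
  stopifnot(inherits(map, "genetic_map"))
  if (is.null(orphans)) orphans <- map$orphans
  orphans <- intersect(orphans, colnames(study$genotypes))
  sample_ids <- .ld_samples(study, samples)
  tab <- map$table
  out <- list()
  new_rows <- list()
  for (orph in orphans) {
    ld <- .ld_to_set(study, orph, tab$marker_id, sample_ids)
    ld$lg <- tab$lg
    ld$pos <- tab$pos_sexavg
    pl <- lode_assign_lg(ld, r2_min = r2_min, min_pairs = min_pairs)
    row <- data.frame(marker_id = orph, assigned_lg = pl$assigned_lg,
                      n_qualifying_pairs = pl$n_qualifying_pairs,
                      max_r2 = pl$max_r2, position = NA_real_,
                      position_max_r2 = NA_real_, reason = pl$reason,
                      stringsAsFactors = FALSE)
    if (!is.na(pl$assigned_lg)) {
      pl <- lode_position(pl, ld, r2_min = r2_min)
      row$position <- pl$position
      row$position_max_r2 <- pl$position_max_r2
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        marker_id = orph, lg = pl$assigned_lg, pos_sexavg = pl$position,
        pos_f = NA_real_, pos_m = NA_real_, method = "lode",
        tier = NA_character_, co_localised = FALSE, stringsAsFactors = FALSE)
    }
    out[[length(out) + 1L]] <- row
  }
  placements <- if (length(out)) do.call(rbind, out) else
    data.frame(marker_id = character(0), assigned_lg = character(0),
               n_qualifying_pairs = integer(0), max_r2 = numeric(0),
               position = numeric(0), position_max_r2 = numeric(0),
               reason = character(0), stringsAsFactors = FALSE)
  if (length(new_rows)) {
    map$table <- rbind(map$table, do.call(rbind, new_rows))
    map$table <- map$table[order(map$table$lg, map$table$pos_sexavg), ,
                           drop = FALSE]
    rownames(map$table) <- NULL
  }
  placed <- placements$marker_id[!is.na(placements$assigned_lg)]
  map$orphans <- sort(setdiff(map$orphans, placed))
  list(placements = placements, map = map,
       unplaced = setdiff(orphans, placed))
}
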