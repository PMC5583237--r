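# Phase-known two-point linkage analysis and map construction.
#
# The central object is the informative-meiosis matrix H (meioses x markers):
# for each (parent, progeny) meiosis and marker, the grandparental origin of
# the transmitted parental haplotype (1 = grandpaternal, 2 = grandmaternal),
# or NA where phase or transmission cannot be deduced. All two-point
# statistics are counts on pairs of columns of H.

#' Kosambi mapping function
#'
#' Converts a recombination fraction to map distance,
#' `d = 25 * ln((1 + 2*theta) / (1 - 2*theta))` cM. Fractions at or above
#' 0.5 map to `Inf` (unlinked).
#'
#' @param theta recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in cM.
#' @export
kosambi <- function(theta) {
  if (any(theta < 0, na.rm = TRUE))
    stop("theta must be >= 0")
  d <- ifelse(theta >= 0.5, Inf, 25 * log((1 + 2 * theta) / (1 - 2 * theta)))
  d
}

#' Inverse Kosambi mapping function
#'
#' `theta = 0.5 * tanh(2 * d / 100)` for `d` in cM.
#'
#' @param d map distance(s) in cM, `>= 0`.
#' @return Recombination fraction(s).
#' @export
kosambi_inverse <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("d must be >= 0")
  0.5 * tanh(2 * d / 100)
}

# alleles a grandparent genotype can transmit: list of possible alleles
.allele_set <- function(g) {
  if (is.na(g)) return(c(TRUE, TRUE))   # c(can transmit ref, can transmit alt)
  c(g <= 1, g >= 1)
}

#' Derive phase-known informative meioses from a study
#'
#' For every parent that is heterozygous at a marker, a progeny meiosis is
#' informative iff (a) the parent's phase at the marker is deducible from its
#' own sire/dam (grandparent) genotypes and (b) the allele the parent
#' transmitted is deducible from the progeny and other-parent genotypes.
#' Everything else is uninformative (a state, not an error).
#'
#' @param study a [genotype_study()].
#' @return An object of class `phased_meioses`: list with `H` (meioses x
#'   markers matrix over 1 = grandpaternal origin, 2 = grandmaternal, NA) and
#'   `meioses` (data.frame: `parent_id`, `progeny_id`, `parent_sex`,
#'   `family_id`).
#' @export
phase_meioses <- function(study) {
  ped <- study$pedigree
  g <- study$genotypes
  m_ids <- colnames(g)
  parents <- ped[ped$sample_id %in% c(ped$sire_id, ped$dam_id) &
                 ped$generation == "parent", , drop = FALSE]

  rows <- list(); meta <- list()
  for (i in seq_len(nrow(parents))) {
    pid <- parents$sample_id[i]
    gp_s <- parents$sire_id[i]; gp_d <- parents$dam_id[i]
    g_p <- g[pid, ]
    g_gs <- if (!is.na(gp_s)) g[gp_s, ] else rep(NA_integer_, length(m_ids))
    g_gd <- if (!is.na(gp_d)) g[gp_d, ] else rep(NA_integer_, length(m_ids))

    # phase: which grandparent contributed the alternate allele (1 = sire's
    # side / grandpaternal haplotype carries alt, 2 = dam's side), NA if
    # ambiguous. Assignment (ref from GS, alt from GD) is possible iff GS can
    # transmit ref and GD can transmit alt; and symmetrically.
    gs_ref <- is.na(g_gs) | g_gs <= 1; gs_alt <- is.na(g_gs) | g_gs >= 1
    gd_ref <- is.na(g_gd) | g_gd <= 1; gd_alt <- is.na(g_gd) | g_gd >= 1
    alt_from_gs <- gs_alt & gd_ref
    alt_from_gd <- gs_ref & gd_alt
    alt_origin <- rep(NA_integer_, length(m_ids))
    alt_origin[alt_from_gs & !alt_from_gd] <- 1L
    alt_from <- alt_from_gd & !alt_from_gs
    alt_origin[alt_from] <- 2L
    informative <- !is.na(g_p) & g_p == 1L & !is.na(alt_origin)
    if (!any(informative)) next

    prog <- ped[!is.na(ped$sire_id) & !is.na(ped$dam_id) &
                (ped$sire_id == pid | ped$dam_id == pid) &
                ped$generation == "progeny", , drop = FALSE]
    if (!nrow(prog)) next
    for (k in seq_len(nrow(prog))) {
      cid <- prog$sample_id[k]
      other <- if (prog$sire_id[k] == pid) prog$dam_id[k] else prog$sire_id[k]
      g_c <- g[cid, ]
      g_o <- g[other, ]
      # allele transmitted by this parent (0/1/NA)
      t <- rep(NA_integer_, length(m_ids))
      t[!is.na(g_c) & g_c == 0L] <- 0L
      t[!is.na(g_c) & g_c == 2L] <- 1L
      het <- !is.na(g_c) & g_c == 1L
      t[het & !is.na(g_o) & g_o == 0L] <- 1L
      t[het & !is.na(g_o) & g_o == 2L] <- 0L
      h <- rep(NA_integer_, length(m_ids))
      use <- informative & !is.na(t)
      # transmitted alt -> haplotype carrying alt; transmitted ref -> other
      h[use] <- ifelse(t[use] == 1L, alt_origin[use], 3L - alt_origin[use])
      rows[[length(rows) + 1L]] <- h
      meta[[length(meta) + 1L]] <- data.frame(
        parent_id = pid, progeny_id = cid,
        parent_sex = parents$sex[i], family_id = prog$family_id[k],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop("no informative meioses: pedigree lacks grandparent tracing")
  H <- do.call(rbind, rows)
  colnames(H) <- m_ids
  structure(list(H = H, meioses = do.call(rbind, meta)),
            class = "phased_meioses")
}

#' @export
print.phased_meioses <- function(x, ...) {
  cat("phased_meioses:", nrow(x$H), "meioses x", ncol(x$H), "markers;",
      sum(!is.na(x$H)), "informative events\n")
  invisible(x)
}

# log10-likelihood of (N, R) at theta = R/N (0*log(0) := 0)
.ll10 <- function(n, r) {
  theta <- ifelse(n > 0, pmin(r / n, 0.5), NA_real_)
  t1 <- ifelse(r > 0, r * log10(theta), 0)
  t2 <- ifelse(n - r > 0, (n - r) * log10(1 - theta), 0)
  ifelse(n > 0, t1 + t2, 0)
}

#' Pairwise two-point count matrices
#'
#' Computes, for every marker pair, the number of co-informative meioses N
#' and recombinants R (origins differing between the two markers within a
#' meiosis), overall and partitioned by parent sex. All downstream two-point
#' statistics derive from these counts.
#'
#' @param phased a [phase_meioses()] result.
#' @return list of class `twopoint_mats` with matrices `N`, `R`, `N_m`,
#'   `R_m`, `N_f`, `R_f` and the marker ids.
#' @export
twopoint_matrices <- function(phased) {
  count <- function(H) {
    I <- !is.na(H)
    A <- (H == 1L) & I; A[is.na(A)] <- FALSE
    B <- (H == 2L) & I; B[is.na(B)] <- FALSE
    storage.mode(A) <- "numeric"; storage.mode(B) <- "numeric"
    Im <- I; storage.mode(Im) <- "numeric"
    N <- crossprod(Im)
    R <- crossprod(A, B) + crossprod(B, A)
    list(N = N, R = R)
  }
  all_ <- count(phased$H)
  male <- count(phased$H[phased$meioses$parent_sex == "M", , drop = FALSE])
  female <- count(phased$H[phased$meioses$parent_sex == "F", , drop = FALSE])
  structure(list(N = all_$N, R = all_$R,
                 N_m = male$N, R_m = male$R, N_f = female$N, R_f = female$R,
                 markers = colnames(phased$H)),
            class = "twopoint_mats")
}

#' Two-point linkage result for one marker pair
#'
#' Maximum-likelihood recombination fraction `theta = min(R/N, 0.5)` and LOD
#' score `Z = R*log10(theta) + (N-R)*log10(1-theta) - N*log10(0.5)`, with the
#' sex-partitioned counts.
#'
#' @param phased a [phase_meioses()] result (or a `twopoint_mats`).
#' @param marker_a,marker_b marker ids.
#' @return data.frame row: `marker_a, marker_b, n, r, theta, lod, n_m, r_m,
#'   n_f, r_f`. With `n = 0` the estimates are NA (no-data result).
#' @export
twopoint <- function(phased, marker_a, marker_b) {
  tpm <- if (inherits(phased, "twopoint_mats")) phased
         else twopoint_matrices(phased)
  i <- match(marker_a, tpm$markers); j <- match(marker_b, tpm$markers)
  if (is.na(i) || is.na(j)) stop("unknown marker id")
  n <- tpm$N[i, j]; r <- tpm$R[i, j]
  data.frame(marker_a = marker_a, marker_b = marker_b,
             n = n, r = r,
             theta = if (n > 0) min(r / n, 0.5) else NA_real_,
             lod = if (n > 0) .ll10(n, r) + n * log10(2) else NA_real_,
             n_m = tpm$N_m[i, j], r_m = tpm$R_m[i, j],
             n_f = tpm$N_f[i, j], r_f = tpm$R_f[i, j],
             stringsAsFactors = FALSE)
}

.lod_matrix <- function(tpm) {
  n <- tpm$N; r <- tpm$R
  lod <- .ll10(n, r) + n * log10(2)
  lod[n == 0] <- 0
  diag(lod) <- 0
  lod
}

.theta_matrix <- function(tpm) {
  th <- ifelse(tpm$N > 0, pmin(tpm$R / tpm$N, 0.5), NA_real_)
  diag(th) <- 0
  th
}

#' Partition markers into candidate linkage groups
#'
#' Single-linkage transitive closure over marker pairs with
#' `LOD >= lod_min` and Kosambi distance `<= dist_max` cM. Components of one
#' or two markers go to the orphan pool.
#'
#' @param tpm a [twopoint_matrices()] result.
#' @param lod_min LOD threshold for an edge (default 10).
#' @param dist_max Kosambi distance threshold in cM (default 30).
#' @param markers optional subset of marker ids to partition.
#' @return list with `groups` (list of character vectors) and `orphans`.
#' @export
group_markers <- function(tpm, lod_min = 10, dist_max = 30, markers = NULL) {
  ids <- if (is.null(markers)) tpm$markers else intersect(tpm$markers, markers)
  idx <- match(ids, tpm$markers)
  lod <- .lod_matrix(tpm)[idx, idx, drop = FALSE]
  th <- .theta_matrix(tpm)[idx, idx, drop = FALSE]
  d <- suppressWarnings(kosambi(ifelse(is.na(th), 0.5, th)))
  adj <- lod >= lod_min & d <= dist_max
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  groups <- split(ids, comp$membership)
  keep <- lengths(groups) >= 3
  list(groups = unname(groups[keep]),
       orphans = sort(unlist(groups[!keep], use.names = FALSE)))
}

# ---- framework ordering -----------------------------------------------------

.perms_cache <- new.env(parent = emptyenv())
.permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perms_cache[[key]])) return(.perms_cache[[key]])
  p <- if (n == 1) matrix(1L, 1, 1) else {
    sub <- .permutations(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k)
      cbind(k, ifelse(sub >= k, sub + 1L, sub))))
  }
  storage.mode(p) <- "integer"
  .perms_cache[[key]] <- p
  p
}

# Ordering objective: sum over adjacent pairs plus, with weight .LAMBDA2,
# over second-neighbour (skip-one) pairs of the information-balanced LOD.
# Roughly three quarters of meioses are uninformative at any given marker,
# so in the phase-known likelihood a large share of the information about a
# marker's local placement sits in pairs that skip one position; the
# adjacent-only criterion leaves that information on the table and local
# scrambles it cannot see survive refinement. All incremental formulas below
# rely on C being symmetric.
.LAMBDA2 <- 1

# safe pairwise lookup: NA index contributes 0
.cg <- function(C, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  ok <- !is.na(x) & !is.na(y)
  out <- numeric(n)
  if (any(ok)) out[ok] <- C[cbind(x[ok], y[ok])]
  out
}

.order_ll <- function(ord, C, lam = .LAMBDA2) {
  k <- length(ord)
  if (k < 2) return(0)
  tot <- sum(C[cbind(ord[-k], ord[-1])])
  if (lam > 0 && k > 2)
    tot <- tot + lam * sum(C[cbind(ord[1:(k - 2)], ord[3:k])])
  tot
}

# deltas for inserting marker m into ord at slots 1..len+1; slot s places m
# between a = ord[s-1] and b = ord[s] (p, q are their outer neighbours):
# first order gains (a,m), (m,b), loses (a,b); second order gains (p,m),
# (m,q) and (a,b) (now a skip pair), loses (p,b), (a,q)
.insert_deltas <- function(ord, m, C, lam = .LAMBDA2) {
  len <- length(ord)
  pad <- c(NA_integer_, NA_integer_, ord, NA_integer_, NA_integer_)
  s <- seq_len(len + 1L)
  a <- pad[s + 1L]; b <- pad[s + 2L]
  p <- pad[s]; q <- pad[s + 3L]
  ab <- .cg(C, a, b)
  delta <- .cg(C, a, m) + .cg(C, m, b) - ab
  if (lam > 0)
    delta <- delta + lam * (.cg(C, p, m) + .cg(C, m, q) + ab -
                              .cg(C, p, b) - .cg(C, a, q))
  delta
}

# exhaustive permutation of every sliding window ("flips"); candidate
# windows are scored on a slice that includes two fixed flanking markers on
# each side, which covers every first- and second-order pair a window
# permutation can change
.flips_window <- function(ord, C, w = 6L, lam = .LAMBDA2) {
  len <- length(ord)
  w <- min(w, len)
  if (w < 2) return(list(order = ord, improved = FALSE))
  perms <- .permutations(w)
  improved <- FALSE
  i <- 1L
  while (i + w - 1L <= len) {
    lo <- max(1L, i - 2L); hi <- min(len, i + w + 1L)
    left <- if (lo < i) ord[lo:(i - 1L)] else integer(0)
    right <- if (hi > i + w - 1L) ord[(i + w):hi] else integer(0)
    win <- ord[i:(i + w - 1L)]
    base <- .order_ll(c(left, win, right), C, lam)
    best_sc <- base; best_p <- NULL
    for (pi in seq_len(nrow(perms))) {
      sc <- .order_ll(c(left, win[perms[pi, ]], right), C, lam)
      if (sc > best_sc + 1e-9) { best_sc <- sc; best_p <- pi }
    }
    if (!is.null(best_p)) {
      ord[i:(i + w - 1L)] <- win[perms[best_p, ]]
      improved <- TRUE
    }
    i <- i + 1L
  }
  list(order = ord, improved = improved)
}

.polish <- function(ord, C, lam = .LAMBDA2) {
  improved <- FALSE
  k <- 1L
  while (k <= length(ord)) {
    m <- ord[k]
    rest <- ord[-k]
    base <- .order_ll(ord, C, lam)
    delta <- .insert_deltas(rest, m, C, lam)
    ll_rest <- .order_ll(rest, C, lam)
    best <- which.max(delta)
    if (ll_rest + delta[best] > base + 1e-9) {
      ord <- append(rest, m, after = best - 1L)
      improved <- TRUE
    }
    k <- k + 1L
  }
  list(order = ord, improved = improved)
}

# segment-reversal (2-opt) pass: C is symmetric, so reversing ord[i..j]
# changes only pairs that cross the segment boundaries; repairs long
# reversed blocks that bounded-window flips cannot reach
.two_opt <- function(ord, C, lam = .LAMBDA2) {
  k <- length(ord)
  improved <- FALSE
  gidx <- function(t) if (t >= 1L && t <= k) ord[t] else NA_integer_
  repeat {
    best_gain <- 1e-9; best_ij <- NULL
    for (i in seq_len(k - 1L)) {
      p1 <- gidx(i - 1L); p2 <- gidx(i - 2L)
      si <- ord[i]; si1 <- ord[i + 1L]
      for (j in (i + 1L):k) {
        n1 <- gidx(j + 1L); n2 <- gidx(j + 2L)
        sj <- ord[j]; sj1 <- ord[j - 1L]
        gain <- .cg(C, p1, sj) - .cg(C, p1, si) +
          .cg(C, si, n1) - .cg(C, sj, n1)
        if (lam > 0)
          gain <- gain + lam * (.cg(C, p2, sj) - .cg(C, p2, si) +
                                  .cg(C, p1, sj1) - .cg(C, p1, si1) +
                                  .cg(C, si1, n1) - .cg(C, sj1, n1) +
                                  .cg(C, si, n2) - .cg(C, sj, n2))
        if (gain > best_gain) { best_gain <- gain; best_ij <- c(i, j) }
      }
    }
    if (is.null(best_ij)) break
    ord[best_ij[1]:best_ij[2]] <- rev(ord[best_ij[1]:best_ij[2]])
    improved <- TRUE
  }
  list(order = ord, improved = improved)
}

# or-opt pass: relocate (possibly reversed) segments of 2-3 markers; the
# removal delta and the slot-wise insertion deltas (on the reduced order)
# compose exactly
.or_opt <- function(ord, C, seg_lens = 2:3, lam = .LAMBDA2) {
  improved <- FALSE
  repeat {
    k <- length(ord)
    gidx <- function(t) if (t >= 1L && t <= k) ord[t] else NA_integer_
    best_gain <- 1e-9; best_move <- NULL
    for (L in seg_lens) {
      if (k <= L + 1L) next
      for (i in seq_len(k - L + 1L)) {
        e1 <- ord[i]; e2 <- ord[i + L - 1L]
        s2 <- ord[i + 1L]; sl1 <- ord[i + L - 2L]
        u1 <- gidx(i - 1L); u2 <- gidx(i - 2L)
        v1 <- gidx(i + L); v2 <- gidx(i + L + 1L)
        removal <- -.cg(C, u1, e1) - .cg(C, e2, v1) + .cg(C, u1, v1) +
          lam * (-.cg(C, u2, e1) - .cg(C, u1, s2) - .cg(C, sl1, v1) -
                   .cg(C, e2, v2) + .cg(C, u2, v1) + .cg(C, u1, v2))
        rest <- ord[-(i:(i + L - 1L))]
        for (orient in 1:2) {
          if (orient == 1L) { f1 <- e1; f2 <- e2; F2 <- s2; FL1 <- sl1 }
          else { f1 <- e2; f2 <- e1; F2 <- sl1; FL1 <- s2 }
          ins <- .seg_insert_deltas(rest, f1, f2, F2, FL1, C, lam)
          slot <- which.max(ins)
          gain <- removal + ins[slot]
          if (gain > best_gain) {
            best_gain <- gain
            best_move <- list(i = i, L = L, orient = orient, slot = slot)
          }
        }
      }
    }
    if (is.null(best_move)) break
    seg <- ord[best_move$i:(best_move$i + best_move$L - 1L)]
    if (best_move$orient == 2L) seg <- rev(seg)
    rest <- ord[-(best_move$i:(best_move$i + best_move$L - 1L))]
    ord <- append(rest, seg, after = best_move$slot - 1L)
    improved <- TRUE
  }
  list(order = ord, improved = improved)
}

# slot-wise deltas for inserting a fixed segment (entering end f1, leaving
# end f2, second element F2, penultimate FL1) into ord
.seg_insert_deltas <- function(ord, f1, f2, F2, FL1, C, lam = .LAMBDA2) {
  len <- length(ord)
  pad <- c(NA_integer_, NA_integer_, ord, NA_integer_, NA_integer_)
  s <- seq_len(len + 1L)
  a <- pad[s + 1L]; b <- pad[s + 2L]
  p <- pad[s]; q <- pad[s + 3L]
  delta <- .cg(C, a, f1) + .cg(C, f2, b) - .cg(C, a, b)
  if (lam > 0)
    delta <- delta + lam * (.cg(C, p, f1) + .cg(C, a, F2) + .cg(C, FL1, b) +
                              .cg(C, f2, q) - .cg(C, p, b) - .cg(C, a, q))
  delta
}

.refine <- function(ord, C, max_sweeps = 20L) {
  for (s in seq_len(max_sweeps)) {
    f <- .flips_window(ord, C)
    t2 <- .two_opt(f$order, C)
    o3 <- .or_opt(t2$order, C)
    p <- .polish(o3$order, C)
    ord <- p$order
    if (!f$improved && !t2$improved && !o3$improved && !p$improved) break
  }
  ord
}

#' Order a candidate linkage group into a framework map
#'
#' Hierarchical incremental insertion: the most strongly linked pair seeds
#' the order; each remaining marker is inserted at its best position when the
#' order log10-likelihood margin over the second-best position meets the
#' current tier threshold (default tiers 3, 2, then "best" = 0). After each
#' tier the order is refined by exhaustive permutation of every sliding
#' window of six markers ("flips 6") and by remove-and-reinsert of every
#' marker ("polish"), repeated to a fixed point, accepting only likelihood
#' improvements. The order likelihood is the sum over adjacent pairs of
#' `R*log10(theta) + (N-R)*log10(1-theta)` at each pair's own MLE
#' (complete-data factorization over phase-known meioses). At the final tier
#' an exact positional tie is resolved to the lower coordinate and the marker
#' is recorded as co-localised.
#'
#' @param markers marker ids of one candidate group (>= 3).
#' @param tpm a [twopoint_matrices()] result.
#' @param tiers numeric margin thresholds, loosest last (default `c(3, 2,
#'   0)`).
#' @param max_sweeps refinement sweep cap per tier.
#' @return list of class `linkage_group`: `markers` (ordered), `tier`
#'   (placement tier per marker: `"lod3"`, `"lod2"`, `"best"`),
#'   `co_localised`, `intervals` (adjacent n, r, theta, cM), `length`,
#'   `loglik`.
#' @export
build_framework <- function(markers, tpm, tiers = c(3, 2, 0),
                            max_sweeps = 20L) {
  if (length(markers) < 3)
    stop("group smaller than 3 markers: orphan passthrough")
  idx <- match(markers, tpm$markers)
  if (anyNA(idx)) stop("unknown marker id in group")
  lod <- .lod_matrix(tpm)[idx, idx, drop = FALSE]
  # ordering objective: sum over adjacent pairs of the information-balanced
  # LOD, lod / (N + n0). Relative to the raw adjacent log-likelihood this
  # (a) subtracts each pair's theta = 0.5 baseline, so data-free adjacencies
  # score worst rather than best, and (b) rescales to per-meiosis support
  # with a small-sample shrinkage constant, so the heterogeneous numbers of
  # co-informative meioses across pairs cannot pull distant but well-counted
  # pairs next to each other. Placement-confidence margins (the LOD3/LOD2
  # tiers) stay in raw LOD units.
  C <- lod / (tpm$N[idx, idx, drop = FALSE] + 10)
  k <- length(idx)
  tier_names <- c("lod3", "lod2", "best")[seq_along(tiers)]
  tier_of <- setNames(rep(NA_character_, k), markers)
  co_loc <- setNames(rep(FALSE, k), markers)

  # seed with the most-informative (highest-LOD) pair
  seed <- which(lod == max(lod), arr.ind = TRUE)[1, ]
  ord <- as.integer(seed)
  tier_of[markers[ord]] <- tier_names[1]
  remaining <- setdiff(seq_len(k), ord)
  info <- colSums(tpm$N[idx, idx, drop = FALSE])

  for (t in seq_along(tiers)) {
    tier <- tiers[t]
    repeat {
      placed_any <- FALSE
      for (m in remaining[order(-info[remaining])]) {
        delta <- .insert_deltas(ord, m, C)
        o <- order(-delta)
        best <- o[1]
        delta_raw <- .insert_deltas(ord, m, lod)
        margin <- delta_raw[best] - max(delta_raw[-best])
        last_tier <- t == length(tiers)
        if (margin < tier && !last_tier) next
        tied <- abs(delta[o[1]] - delta[o[2]]) <= 1e-9
        if (tied && !last_tier) next  # defer exact ties to a looser tier
        if (tied) {                    # final tier: lowest coordinate wins
          best <- min(which(abs(delta - delta[o[1]]) <= 1e-9))
          co_loc[markers[m]] <- TRUE
        }
        ord <- append(ord, m, after = best - 1L)
        tier_of[markers[m]] <- tier_names[t]
        remaining <- setdiff(remaining, m)
        placed_any <- TRUE
      }
      if (!placed_any || !length(remaining)) break
    }
    ord <- .refine(ord, C, max_sweeps)
    if (!length(remaining)) break
  }

  # canonical orientation (order likelihood is reversal-symmetric)
  if (markers[ord[length(ord)]] < markers[ord[1]]) ord <- rev(ord)

  ordered <- markers[ord]
  gi <- idx[ord]
  n_adj <- tpm$N[cbind(gi[-k], gi[-1])]
  r_adj <- tpm$R[cbind(gi[-k], gi[-1])]
  theta <- ifelse(n_adj > 0, pmin(r_adj / n_adj, 0.4999999), NA_real_)
  d <- .wls_interval_lengths(gi, tpm$N, tpm$R)
  intervals <- data.frame(marker_a = ordered[-k], marker_b = ordered[-1],
                          n = n_adj, r = r_adj, theta = theta, d = d,
                          stringsAsFactors = FALSE)
  Cll <- .ll10(tpm$N, tpm$R)[idx, idx, drop = FALSE]
  structure(list(markers = ordered, tier = tier_of[ordered],
                 co_localised = co_loc[ordered], intervals = intervals,
                 length = sum(d, na.rm = TRUE),
                 loglik = .order_ll(ord, Cll, lam = 0)),
            class = "linkage_group")
}

# ---- interval length estimation --------------------------------------------

# Interval lengths by weighted least squares over spanning pairs. Each
# marker pair within max_idx_span order positions contributes one
# observation: its two-point distance modelled as the sum of the adjacent
# intervals it spans, weighted by co-informative meioses. Pooling across
# spans removes the downward selection bias of taking each adjacent pair's
# own (noisy, order-selected) estimate. Three numerical points:
#   * the fit is done in Haldane scale, which is exactly additive across
#     intervals under independent per-interval recombination, with a
#     second-order Taylor correction for the convexity bias of the
#     transform at finite N; fitted intervals are converted back to Kosambi
#     cM individually (the two scales agree closely at interval size);
#   * negative intervals (local ordering noise) are pinned to zero by
#     backward-elimination non-negative least squares;
#   * the non-negative solution is rescaled so its total matches the
#     signed-solution total, which telescopes to the end-to-end span and is
#     therefore robust to local order scrambles that the pinning would
#     otherwise silently delete.
# Positions remain cumulative sums of the estimated intervals, so
# map-length additivity holds by construction.
.wls_interval_lengths <- function(idx, Nmat, Rmat, max_idx_span = 12L,
                                  n_min = 5, theta_cap = 0.4) {
  k <- length(idx)
  if (k < 2) return(numeric(0))
  rows <- list(); y <- numeric(0); w <- numeric(0)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):min(k, i + max_idx_span)) {
      n <- Nmat[idx[i], idx[j]]; r <- Rmat[idx[i], idx[j]]
      if (n < n_min) next
      th <- min(r / n, 0.4999999)
      if (th >= theta_cap) next
      a <- numeric(k - 1L); a[i:(j - 1L)] <- 1
      rows[[length(rows) + 1L]] <- a
      z <- -50 * log(1 - 2 * th) -
        200 * th * (1 - th) / (n * (1 - 2 * th)^2)
      y <- c(y, max(z, 0)); w <- c(w, n)
    }
  }
  z_est <- rep(NA_real_, k - 1L)
  if (length(rows)) {
    A <- do.call(rbind, rows)
    cf_raw <- stats::lm.fit(A * sqrt(w), y * sqrt(w))$coefficients
    cf_raw[is.na(cf_raw)] <- 0
    span_total <- sum(cf_raw)
    active <- seq_len(ncol(A))
    pinned <- integer(0)
    cf <- rep(NA_real_, ncol(A))
    repeat {
      if (!length(active)) break
      fit <- stats::lm.fit(A[, active, drop = FALSE] * sqrt(w), y * sqrt(w))
      cf_a <- fit$coefficients
      neg <- which(!is.na(cf_a) & cf_a < -1e-12)
      if (!length(neg)) { cf[active] <- cf_a; break }
      pinned <- c(pinned, active[neg])
      active <- active[-neg]
    }
    z_est <- cf
    z_est[pinned] <- 0
    z_est[!is.na(z_est) & z_est < 0] <- 0
    tot <- sum(z_est, na.rm = TRUE)
    if (tot > 0 && span_total > 0) {
      s <- span_total / tot
      z_est <- z_est * min(max(s, 0.5), 3)
    }
  }
  d <- kosambi(0.5 * (1 - exp(-2 * pmax(z_est, 0) / 100)))
  # intervals with no spanning data: fall back on the direct adjacent pair
  for (i in which(is.na(d))) {
    n <- Nmat[idx[i], idx[i + 1L]]; r <- Rmat[idx[i], idx[i + 1L]]
    d[i] <- if (n > 0) kosambi(min(r / n, 0.4999999)) else NA_real_
  }
  unname(d)
}

# ---- map assembly -----------------------------------------------------------

.lg_positions <- function(intervals, col = "d") {
  d <- intervals[[col]]
  cumsum(c(0, ifelse(is.na(d), 0, d)))
}

.empty_map_table <- function() {
  data.frame(marker_id = character(0), lg = character(0),
             pos_sexavg = numeric(0), pos_f = numeric(0),
             pos_m = numeric(0), method = character(0), tier = character(0),
             co_localised = logical(0), stringsAsFactors = FALSE)
}

.assemble_map <- function(lgs, tpm, orphans) {
  if (!length(lgs))
    return(structure(list(table = .empty_map_table(),
                          intervals = NULL, loglik = numeric(0),
                          orphans = orphans),
                     class = "genetic_map"))
  # order linkage groups by total sex-average length, longest first
  lens <- vapply(lgs, `[[`, numeric(1), "length")
  lgs <- lgs[order(-lens)]
  tab <- list(); ints <- list()
  for (i in seq_along(lgs)) {
    lg_id <- sprintf("LG%02d", i)
    lg <- lgs[[i]]
    sexint <- .sex_intervals(lg, tpm)
    pos <- .lg_positions(sexint, "d")
    pos_f <- .lg_positions(sexint, "d_f")
    pos_m <- .lg_positions(sexint, "d_m")
    tab[[i]] <- data.frame(
      marker_id = lg$markers, lg = lg_id,
      pos_sexavg = pos, pos_f = pos_f, pos_m = pos_m,
      method = "linkage", tier = unname(lg$tier),
      co_localised = unname(lg$co_localised),
      stringsAsFactors = FALSE)
    sexint$lg <- lg_id
    ints[[i]] <- sexint
  }
  structure(list(table = do.call(rbind, tab),
                 intervals = do.call(rbind, ints),
                 loglik = setNames(vapply(lgs, `[[`, numeric(1), "loglik"),
                                   sprintf("LG%02d", seq_along(lgs))),
                 orphans = orphans),
            class = "genetic_map")
}

# per-interval sex-specific counts and Kosambi lengths for an ordered LG,
# under the locked sex-average order; interval lengths use the same
# spanning-pair estimator as the sex-average map, but an interval with zero
# direct co-informative meioses in a sex stays undefined (never imputed)
.sex_intervals <- function(lg, tpm) {
  mk <- lg$markers
  k <- length(mk)
  out <- lg$intervals
  gi <- match(mk, tpm$markers)
  ii <- cbind(gi[-k], gi[-1])
  n_f <- tpm$N_f[ii]; r_f <- tpm$R_f[ii]
  n_m <- tpm$N_m[ii]; r_m <- tpm$R_m[ii]
  theta_f <- ifelse(n_f > 0, pmin(r_f / n_f, 0.4999999), NA_real_)
  theta_m <- ifelse(n_m > 0, pmin(r_m / n_m, 0.4999999), NA_real_)
  d_f <- .wls_interval_lengths(gi, tpm$N_f, tpm$R_f)
  d_m <- .wls_interval_lengths(gi, tpm$N_m, tpm$R_m)
  d_f[n_f == 0] <- NA_real_
  d_m[n_m == 0] <- NA_real_
  out$n_f <- n_f; out$r_f <- r_f; out$theta_f <- theta_f; out$d_f <- d_f
  out$n_m <- n_m; out$r_m <- r_m; out$theta_m <- theta_m; out$d_m <- d_m
  out
}

#' Recalculate sex-specific interval lengths under the locked sex-average
#' order
#'
#' The marker order is never re-estimated: female and male maps share the
#' sex-average order exactly, with per-interval recombination fractions
#' recomputed from female- and male-parent informative meioses separately.
#' Intervals with zero meioses in a sex are reported as missing, never
#' imputed; totals are over defined intervals only.
#'
#' @param map a [genetic_map] (from [build_linkage_map()]).
#' @param tpm the two-point count matrices to recalculate from (default:
#'   the map's own).
#' @return The map with refreshed `intervals` and female/male positions.
#' @export
sex_specific_maps <- function(map, tpm = map$tpm) {
  stopifnot(inherits(map, "genetic_map"))
  ints <- map$intervals
  for (lg in unique(ints$lg)) {
    sel <- ints$lg == lg
    mk <- c(ints$marker_a[sel], tail(ints$marker_b[sel], 1))
    fake_lg <- list(markers = mk, intervals = ints[sel, seq_len(6)])
    new_int <- .sex_intervals(fake_lg, tpm)
    for (col in c("n_f", "r_f", "theta_f", "d_f",
                  "n_m", "r_m", "theta_m", "d_m"))
      ints[sel, col] <- new_int[[col]]
    rows <- map$table$lg == lg
    map$table$pos_f[rows] <- .lg_positions(new_int, "d_f")
    map$table$pos_m[rows] <- .lg_positions(new_int, "d_m")
  }
  map$intervals <- ints
  map
}

#' Build a genetic map from a study
#'
#' End-to-end linkage stage: phase meioses, compute all-pairs two-point
#' counts, partition markers into linkage groups, order each group into a
#' framework and recalculate sex-specific interval lengths. Markers in
#' `exclude` (e.g. held-out orphans) are kept out of grouping but remain
#' available for later insertion.
#'
#' @param study a [genotype_study()].
#' @param lod_group LOD threshold for grouping (default 10).
#' @param dist_max distance threshold for grouping, cM (default 30).
#' @param tiers ordering margin tiers (default `c(3, 2, 0)`).
#' @param exclude marker ids to withhold from grouping.
#' @param merge_lod after ordering, end-to-end merge proposals (the maximum
#'   two-point LOD among the five distal markers of each end pair) at or
#'   above this LOD are applied greedily, strongest first, re-ordering each
#'   merged group; `NA` disables merging. The default (7) sits between the
#'   grouping threshold and the orphan-insertion threshold: a genuine
#'   junction between two fragments of one chromosome typically shows
#'   distal support around LOD 6-13 at moderate meiosis counts, while
#'   chance support between unlinked groups stays well below it.
#' @return A `genetic_map`: list with `table` (one row per mapped marker:
#'   positions, method, tier), `intervals` (per adjacent interval: sexed
#'   counts and cM), per-LG `loglik`, `orphans`, plus the `phased` meioses
#'   and `tpm` count matrices used.
#' @export
build_linkage_map <- function(study, lod_group = 10, dist_max = 30,
                              tiers = c(3, 2, 0), exclude = NULL,
                              merge_lod = 7) {
  phased <- phase_meioses(study)
  tpm <- twopoint_matrices(phased)
  use <- setdiff(tpm$markers, exclude)
  grp <- group_markers(tpm, lod_min = lod_group, dist_max = dist_max,
                       markers = use)
  lgs <- lapply(grp$groups, build_framework, tpm = tpm, tiers = tiers)
  if (!is.na(merge_lod) && length(lgs) > 1)
    lgs <- .apply_merges(lgs, tpm, tiers, lod_min = merge_lod)
  map <- .assemble_map(lgs, tpm, grp$orphans)
  map$phased <- phased
  map$tpm <- tpm
  map
}

# greedy end-to-end merging of ordered groups: strongest distal-pair LOD
# first, re-ordering each merged group, until no proposal reaches lod_min
.apply_merges <- function(lgs, tpm, tiers, lod_min, k_distal = 5) {
  lodm <- .lod_matrix(tpm)
  end_lod <- function(a, b) {
    ea <- c(head(a$markers, k_distal), tail(a$markers, k_distal))
    eb <- c(head(b$markers, k_distal), tail(b$markers, k_distal))
    max(lodm[match(unique(ea), tpm$markers),
             match(unique(eb), tpm$markers), drop = FALSE])
  }
  repeat {
    if (length(lgs) < 2) break
    best <- c(NA, NA); best_lod <- -Inf
    for (i in seq_along(lgs)) for (j in seq_along(lgs)) {
      if (j <= i) next
      l <- end_lod(lgs[[i]], lgs[[j]])
      if (l > best_lod) { best_lod <- l; best <- c(i, j) }
    }
    if (best_lod < lod_min) break
    merged <- build_framework(c(lgs[[best[1]]]$markers,
                                lgs[[best[2]]]$markers),
                              tpm, tiers = tiers)
    lgs <- c(lgs[-best], list(merged))
  }
  lgs
}

#' @export
print.genetic_map <- function(x, ...) {
  n_lg <- length(unique(x$table$lg))
  cat("genetic_map:", nrow(x$table), "markers in", n_lg, "linkage groups;",
      length(x$orphans), "orphans\n")
  tot <- tapply(x$table$pos_sexavg, x$table$lg, max)
  cat("  total sex-average length:", round(sum(tot), 2), "cM\n")
  invisible(x)
}

#' Insert orphan markers by two-point linkage
#'
#' Each orphan is tested by two-point against all mapped markers. It is
#' inserted (placement tier "best") when its strongest two-point LOD reaches
#' `lod_min` on exactly one linkage group; ties between groups leave it an
#' orphan. Within the group it is placed at the position maximizing the
#' order likelihood; positional ties go to the lower coordinate and are
#' recorded as co-localised.
#'
#' @param map a `genetic_map` carrying `phased`/`tpm` (as returned by
#'   [build_linkage_map()]).
#' @param orphans marker ids to try (default: the map's orphan pool).
#' @param lod_min minimum supporting LOD (default 3).
#' @return The updated map; residual orphans remain in `map$orphans`.
#' @export
insert_orphans <- function(map, orphans = NULL, lod_min = 3) {
  stopifnot(inherits(map, "genetic_map"))
  tpm <- map$tpm
  if (is.null(orphans)) orphans <- map$orphans
  orphans <- intersect(orphans, tpm$markers)
  lodm <- .lod_matrix(tpm)
  placed <- character(0)
  for (orph in orphans) {
    oi <- match(orph, tpm$markers)
    lgs <- unique(map$table$lg)
    best_lod <- vapply(lgs, function(lg) {
      mi <- match(map$table$marker_id[map$table$lg == lg], tpm$markers)
      max(lodm[oi, mi])
    }, numeric(1))
    top <- max(best_lod)
    if (top < lod_min) next
    if (sum(abs(best_lod - top) <= 1e-9) > 1) next  # ambiguous between LGs
    lg <- lgs[which.max(best_lod)]
    mk <- map$table$marker_id[map$table$lg == lg]
    idx <- match(c(mk, orph), tpm$markers)
    C <- lodm[idx, idx, drop = FALSE] /
      (tpm$N[idx, idx, drop = FALSE] + 10)
    k <- length(mk)
    delta <- .insert_deltas(seq_len(k), k + 1L, C)
    o <- order(-delta)
    slot <- o[1]
    co <- FALSE
    if (abs(delta[o[1]] - delta[o[2]]) <= 1e-9) {
      slot <- min(which(abs(delta - delta[o[1]]) <= 1e-9))
      co <- TRUE
    }
    new_order <- append(mk, orph, after = slot - 1L)
    map <- .replace_lg_order(map, lg, new_order, orph, co)
    placed <- c(placed, orph)
  }
  map$orphans <- sort(setdiff(union(map$orphans, orphans),
                              c(placed, map$table$marker_id)))
  map
}

# rebuild one LG's rows after a marker insertion, preserving tiers
.replace_lg_order <- function(map, lg, new_order, new_marker, co_localised) {
  tpm <- map$tpm
  k <- length(new_order)
  gi <- match(new_order, tpm$markers)
  n_adj <- tpm$N[cbind(gi[-k], gi[-1])]
  r_adj <- tpm$R[cbind(gi[-k], gi[-1])]
  theta <- ifelse(n_adj > 0, pmin(r_adj / n_adj, 0.4999999), NA_real_)
  d <- .wls_interval_lengths(gi, tpm$N, tpm$R)
  ints <- data.frame(marker_a = new_order[-k], marker_b = new_order[-1],
                     n = n_adj, r = r_adj, theta = theta, d = d,
                     stringsAsFactors = FALSE)
  sexint <- .sex_intervals(list(markers = new_order, intervals = ints),
                           tpm)
  sexint$lg <- lg

  old_rows <- map$table[map$table$lg == lg, , drop = FALSE]
  tier <- setNames(old_rows$tier, old_rows$marker_id)[new_order]
  meth <- setNames(old_rows$method, old_rows$marker_id)[new_order]
  colo <- setNames(old_rows$co_localised, old_rows$marker_id)[new_order]
  tier[new_order == new_marker] <- "best"
  meth[new_order == new_marker] <- "linkage"
  colo[new_order == new_marker] <- co_localised
  new_tab <- data.frame(
    marker_id = new_order, lg = lg,
    pos_sexavg = .lg_positions(sexint, "d"),
    pos_f = .lg_positions(sexint, "d_f"),
    pos_m = .lg_positions(sexint, "d_m"),
    method = unname(meth), tier = unname(tier),
    co_localised = unname(colo), stringsAsFactors = FALSE)
  map$table <- rbind(map$table[map$table$lg != lg, , drop = FALSE], new_tab)
  map$table <- map$table[order(map$table$lg, map$table$pos_sexavg), ,
                         drop = FALSE]
  rownames(map$table) <- NULL
  map$intervals <- rbind(map$intervals[map$intervals$lg != lg, , drop = FALSE],
                         sexint)
  rownames(map$intervals) <- NULL
  map
}

#' Propose linkage-group merges from distal two-point linkage
#'
#' For every ordered pair of linkage groups and every end orientation, the
#' maximum two-point LOD among the `k_distal` x `k_distal` distal marker
#' pairs is computed; combinations reaching `lod_min` are reported as merge
#' candidates. Groups with fewer than `k_distal` markers use all their
#' markers.
#'
#' @param map a `genetic_map` carrying `tpm`.
#' @param k_distal distal markers per end (default 5).
#' @param lod_min reporting threshold (default 10).
#' @return data.frame: `lg_a, lg_b, end_a, end_b, max_lod, marker_a,
#'   marker_b`, one row per end combination that reaches `lod_min`.
#' @export
merge_candidates <- function(map, k_distal = 5, lod_min = 10) {
  stopifnot(inherits(map, "genetic_map"))
  tpm <- map$tpm
  lodm <- .lod_matrix(tpm)
  lgs <- unique(map$table$lg)
  if (length(lgs) < 2)
    return(data.frame(lg_a = character(0), lg_b = character(0),
                      end_a = character(0), end_b = character(0),
                      max_lod = numeric(0), marker_a = character(0),
                      marker_b = character(0), stringsAsFactors = FALSE))
  ends <- function(lg) {
    mk <- map$table$marker_id[map$table$lg == lg]
    kk <- min(k_distal, length(mk))
    list(head = head(mk, kk), tail = tail(mk, kk))
  }
  out <- list()
  for (i in seq_along(lgs)) for (j in seq_along(lgs)) {
    if (j <= i) next
    ea <- ends(lgs[i]); eb <- ends(lgs[j])
    for (na in c("head", "tail")) for (nb in c("head", "tail")) {
      ia <- match(ea[[na]], tpm$markers); ib <- match(eb[[nb]], tpm$markers)
      sub <- lodm[ia, ib, drop = FALSE]
      mx <- max(sub)
      if (mx >= lod_min) {
        w <- which(sub == mx, arr.ind = TRUE)[1, ]
        out[[length(out) + 1L]] <- data.frame(
          lg_a = lgs[i], lg_b = lgs[j], end_a = na, end_b = nb,
          max_lod = mx, marker_a = ea[[na]][w[1]], marker_b = eb[[nb]][w[2]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(lg_a = character(0), lg_b = character(0),
                      end_a = character(0), end_b = character(0),
                      max_lod = numeric(0), marker_a = character(0),
                      marker_b = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
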