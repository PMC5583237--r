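# Heterogeneity and segregation-distortion statistics.
#
# All heterogeneity tests compare a free-parameter log10-likelihood against
# the pooled-estimate likelihood and scale by 2*ln(10) to a chi-squared
# statistic. .ll10() (linkage.R) evaluates R*log10(theta) + (N-R)*
# log10(1-theta) at theta = R/N; the -N*log10(0.5) LOD reference cancels in
# every difference.

#' Sex-heterogeneity goodness-of-fit test for a marker interval
#'
#' Tests whether male- and female-parent recombination fractions differ on
#' an interval: `X^2 = 2*ln(10) * [Z(theta_m, theta_f) - Z(theta, theta)]`,
#' with one degree of freedom, where the first term is the joint
#' sex-specific likelihood at the per-sex MLEs and the second the likelihood
#' with a common pooled fraction.
#'
#' @param n_m,r_m male-parent co-informative meioses and recombinants
#'   (vectorized).
#' @param n_f,r_f female-parent counts.
#' @return data.frame: `chi2`, `df` (= 1), `p`. Rows with a sex at zero
#'   meioses are flagged `skipped` and carry NA statistics.
#' @export
sex_heterogeneity_test <- function(n_m, r_m, n_f, r_f) {
  ok <- n_m >= 1 & n_f >= 1
  free <- .ll10(n_m, r_m) + .ll10(n_f, r_f)
  pooled <- .ll10(n_m + n_f, r_m + r_f)
  chi2 <- ifelse(ok, pmax(0, 2 * log(10) * (free - pooled)), NA_real_)
  data.frame(chi2 = chi2, df = 1L,
             p = ifelse(ok, pchisq(chi2, 1, lower.tail = FALSE), NA_real_),
             skipped = !ok)
}

#' Sex-heterogeneity scan over all map intervals
#'
#' Applies [sex_heterogeneity_test()] to every adjacent interval of a built
#' map and adds a Benjamini-Hochberg q-value within the scan.
#'
#' @param map a `genetic_map` (with sexed intervals).
#' @return data.frame: interval ids, counts, `chi2`, `df`, `p`, `fdr_q`.
#' @export
map_sex_heterogeneity <- function(map) {
  ints <- map$intervals
  res <- sex_heterogeneity_test(ints$n_m, ints$r_m, ints$n_f, ints$r_f)
  out <- cbind(ints[, c("lg", "marker_a", "marker_b",
                        "n_m", "r_m", "n_f", "r_f")], res)
  out$fdr_q <- NA_real_
  out$fdr_q[!out$skipped] <- bh_fdr(out$p[!out$skipped])
  out
}

#' Family-heterogeneity M-test
#'
#' Tests homogeneity of a recombination fraction across families:
#' `X^2 = 2*ln(10) * [sum_i Z_i(theta_i) - Z(theta)]` with
#' `df = #contributing families - 1`; families with zero co-informative
#' meioses are dropped from both terms.
#'
#' @param n,r per-family co-informative meioses and recombinants.
#' @return list: `chi2`, `df`, `p`, `n_families`, `skipped` (fewer than two
#'   contributing families).
#' @export
family_heterogeneity_mtest <- function(n, r) {
  keep <- n >= 1
  n <- n[keep]; r <- r[keep]
  if (length(n) < 2)
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                n_families = length(n), skipped = TRUE))
  chi2 <- max(0, 2 * log(10) * (sum(.ll10(n, r)) - .ll10(sum(n), sum(r))))
  df <- length(n) - 1L
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       n_families = length(n), skipped = FALSE)
}

#' Per-family two-point counts for a marker pair
#'
#' @param phased a [phase_meioses()] result.
#' @param marker_a,marker_b marker ids.
#' @return data.frame: `family_id`, `n`, `r`.
#' @export
twopoint_by_family <- function(phased, marker_a, marker_b) {
  h1 <- phased$H[, marker_a]; h2 <- phased$H[, marker_b]
  co <- !is.na(h1) & !is.na(h2)
  rec <- co & h1 != h2
  fam <- phased$meioses$family_id
  fams <- sort(unique(fam))
  data.frame(family_id = fams,
             n = vapply(fams, function(f) sum(co[fam == f]), integer(1)),
             r = vapply(fams, function(f) sum(rec[fam == f]), integer(1)),
             stringsAsFactors = FALSE)
}

#' Log-likelihood-ratio (G) goodness-of-fit test
#'
#' `G = 2 * sum O * ln(O / E)` against expected class ratios, with
#' `df = #classes - 1`; zero observed cells contribute nothing.
#'
#' @param observed observed class counts.
#' @param expected_ratio expected ratios (normalized internally).
#' @return list: `G`, `df`, `p`, `observed`, `expected`.
#' @export
g_test <- function(observed, expected_ratio) {
  stopifnot(length(observed) == length(expected_ratio))
  expected <- expected_ratio / sum(expected_ratio) * sum(observed)
  terms <- ifelse(observed > 0, observed * log(observed / expected), 0)
  g <- 2 * sum(terms)
  df <- length(observed) - 1L
  list(G = g, df = df, p = pchisq(g, df, lower.tail = FALSE),
       observed = observed, expected = expected)
}

#' Segregation-distortion test at one marker for one informative parent
#'
#' Progeny genotype classes and Mendelian expectations follow the cross
#' type: het x hom gives two classes at 1:1, het x het gives the three
#' genotype classes at 1:2:1. Progeny whose genotype is impossible for the
#' cross are excluded from the counts (they are inheritance errors, not
#' segregation), and reported.
#'
#' @param study a [genotype_study()].
#' @param marker marker id.
#' @param parent sample id of the heterozygous (informative) parent.
#' @return list of class `distortion_result`: `marker`, `parent`,
#'   `cross` (`"het_x_homref"`, `"het_x_het"`, `"het_x_homalt"`),
#'   `observed`, `expected`, `G`, `df`, `p`, `n_excluded`, `skipped`.
#' @export
segregation_distortion <- function(study, marker, parent) {
  ped <- study$pedigree
  g <- study$genotypes
  gp <- g[parent, marker]
  if (is.na(gp) || gp != 1L)
    return(list(marker = marker, parent = parent, cross = NA_character_,
                skipped = TRUE, reason = "parent not heterozygous"))
  prog <- ped[!is.na(ped$sire_id) & !is.na(ped$dam_id) &
              (ped$sire_id == parent | ped$dam_id == parent), , drop = FALSE]
  if (!nrow(prog))
    return(list(marker = marker, parent = parent, cross = NA_character_,
                skipped = TRUE, reason = "no progeny"))
  others <- ifelse(prog$sire_id == parent, prog$dam_id, prog$sire_id)
  go <- g[cbind(others, marker)]
  # the test requires one well-defined cross type: use progeny whose other
  # parent genotype is non-missing and constant
  ok <- !is.na(go)
  if (!any(ok) || length(unique(go[ok])) != 1L)
    return(list(marker = marker, parent = parent, cross = NA_character_,
                skipped = TRUE, reason = "other-parent genotype unusable"))
  other_g <- unique(go[ok])
  gc <- g[prog$sample_id[ok], marker]
  gc <- gc[!is.na(gc)]
  if (!length(gc))
    return(list(marker = marker, parent = parent, cross = NA_character_,
                skipped = TRUE, reason = "no genotyped progeny"))
  spec <- switch(as.character(other_g),
    "0" = list(classes = c(0L, 1L), ratio = c(1, 1), cross = "het_x_homref"),
    "1" = list(classes = c(0L, 1L, 2L), ratio = c(1, 2, 1),
               cross = "het_x_het"),
    "2" = list(classes = c(1L, 2L), ratio = c(1, 1), cross = "het_x_homalt"))
  obs <- vapply(spec$classes, function(cl) sum(gc == cl), integer(1))
  names(obs) <- spec$classes
  n_excl <- length(gc) - sum(obs)
  gt <- g_test(obs, spec$ratio)
  structure(list(marker = marker, parent = parent, cross = spec$cross,
                 observed = obs, expected = gt$expected,
                 G = gt$G, df = gt$df, p = gt$p,
                 n_excluded = n_excl, skipped = FALSE),
            class = "distortion_result")
}

#' Segregation-distortion scan
#'
#' Runs [segregation_distortion()] for every marker x informative parent
#' combination (each informative parent tested separately) and applies a
#' Benjamini-Hochberg correction within the scan.
#'
#' @param study a [genotype_study()].
#' @param markers marker subset (default all).
#' @param parents parent subset (default all F1 parents with progeny).
#' @return data.frame: `marker`, `parent`, `cross`, `G`, `df`, `p`, `fdr_q`.
#' @export
segregation_scan <- function(study, markers = NULL, parents = NULL) {
  ped <- study$pedigree
  if (is.null(markers)) markers <- study$markers$marker_id
  if (is.null(parents))
    parents <- ped$sample_id[ped$generation == "parent" &
                             ped$sample_id %in% c(ped$sire_id, ped$dam_id)]
  out <- list()
  for (mk in markers) for (p in parents) {
    if (is.na(study$genotypes[p, mk]) || study$genotypes[p, mk] != 1L) next
    res <- segregation_distortion(study, mk, p)
    if (isTRUE(res$skipped)) next
    out[[length(out) + 1L]] <- data.frame(
      marker = mk, parent = p, cross = res$cross, G = res$G, df = res$df,
      p = res$p, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(marker = character(0), parent = character(0),
                      cross = character(0), G = numeric(0), df = integer(0),
                      p = numeric(0), fdr_q = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$fdr_q <- bh_fdr(res$p)
  res
}

#' Female-to-male map-distance ratios
#'
#' `R = X_f / X_m` per interval, per linkage group and over the whole map.
#' The genome scope reports both the ratio of totals and the mean of per-LG
#' ratios. Undefined where the male length is zero or missing.
#'
#' @param map a `genetic_map` with sexed intervals.
#' @return data.frame: `scope` (`"interval"`, `"lg"`, `"genome"`), `id`,
#'   `x_f`, `x_m`, `ratio`. The genome rows have ids `"ratio_of_totals"` and
#'   `"mean_of_lg_ratios"`.
#' @export
fm_ratios <- function(map) {
  ints <- map$intervals
  if (is.null(ints) || !nrow(ints))
    return(data.frame(scope = character(0), id = character(0),
                      x_f = numeric(0), x_m = numeric(0),
                      ratio = numeric(0), stringsAsFactors = FALSE))
  ratio <- ifelse(!is.na(ints$d_m) & ints$d_m > 0 & !is.na(ints$d_f),
                  ints$d_f / ints$d_m, NA_real_)
  per_int <- data.frame(scope = "interval",
                        id = paste(ints$marker_a, ints$marker_b, sep = "--"),
                        x_f = ints$d_f, x_m = ints$d_m, ratio = ratio,
                        stringsAsFactors = FALSE)
  lgs <- unique(ints$lg)
  per_lg <- do.call(rbind, lapply(lgs, function(lg) {
    sel <- ints$lg == lg & !is.na(ints$d_f) & !is.na(ints$d_m)
    xf <- sum(ints$d_f[sel]); xm <- sum(ints$d_m[sel])
    data.frame(scope = "lg", id = lg, x_f = xf, x_m = xm,
               ratio = if (xm > 0) xf / xm else NA_real_,
               stringsAsFactors = FALSE)
  }))
  ok <- !is.na(ints$d_f) & !is.na(ints$d_m)
  xf <- sum(ints$d_f[ok]); xm <- sum(ints$d_m[ok])
  genome <- data.frame(
    scope = "genome",
    id = c("ratio_of_totals", "mean_of_lg_ratios"),
    x_f = c(xf, NA), x_m = c(xm, NA),
    ratio = c(if (xm > 0) xf / xm else NA_real_,
              mean(per_lg$ratio, na.rm = TRUE)),
    stringsAsFactors = FALSE)
  rbind(per_int, per_lg, genome)
}

#' Genome-wide recombination sex ratio from informative-event counts
#'
#' Counts grandparental-origin switches between consecutive informative
#' markers along the map order, per meiosis, and forms the female:male
#' ratio of per-meiosis switch rates. Because it pools whole meioses rather
#' than per-interval estimates it is robust to local ordering noise, and
#' isolated origin flips (a marker disagreeing with both tight flankers —
#' the signature of a genotyping or phasing error rather than a true double
#' crossover) are masked by default.
#'
#' @param map a `genetic_map` carrying `phased`.
#' @param method `"mle"` (default) fits, per sex, a single multiplicative
#'   map-scale factor by maximum likelihood: each gap between consecutive
#'   informative markers contributes a Bernoulli observation with success
#'   probability `kosambi_inverse(scale * gap)`; the ratio of the fitted
#'   female and male scales estimates the genome-wide expansion.
#'   `"density"` reports observed switches per 100 sex-average cM over gaps
#'   at most `gap_cap_cm` wide (wider gaps hide even crossover numbers,
#'   which would shrink the longer female map more than the male one).
#' @param gap_cap_cm gap cap in sex-average cM (default 30 for `"mle"`
#'   where wide gaps carry little information anyway; use about 12 for
#'   `"density"`).
#' @param drop_singletons mask isolated single-marker origin flips
#'   (default TRUE).
#' @param singleton_max_gap_cm a flip is masked only when both flanking
#'   informative gaps are at most this wide, so that a genuine double
#'   crossover (probability about the product of the two gap recombination
#'   fractions) is an implausible explanation (default 8 cM).
#' @return list: `ratio` (female:male), `scale_f`/`scale_m` (mle) or
#'   `density_f`/`density_m` (switches per 100 cM), `n_switches_f`,
#'   `n_switches_m`, `n_gaps_f`, `n_gaps_m`.
#' @export
sex_recombination_ratio <- function(map, method = c("mle", "density"),
                                    gap_cap_cm = 30,
                                    drop_singletons = TRUE,
                                    singleton_max_gap_cm = 8) {
  stopifnot(inherits(map, "genetic_map"))
  method <- match.arg(method)
  ph <- map$phased
  tab <- map$table[order(map$table$lg, map$table$pos_sexavg), , drop = FALSE]
  tab <- tab[tab$marker_id %in% colnames(ph$H), , drop = FALSE]
  H <- ph$H[, tab$marker_id, drop = FALSE]
  pos <- tab$pos_sexavg
  lg <- tab$lg
  sex <- ph$meioses$parent_sex
  dat <- list(M = list(d = numeric(0), s = logical(0)),
              F = list(d = numeric(0), s = logical(0)))
  for (i in seq_len(nrow(H))) {
    h <- H[i, ]
    inf <- which(!is.na(h))
    if (length(inf) < 2) next
    hv <- h[inf]; lgv <- lg[inf]; pv <- pos[inf]
    if (drop_singletons && length(hv) >= 3) {
      mid <- 2:(length(hv) - 1L)
      bad <- mid[hv[mid] != hv[mid - 1L] & hv[mid - 1L] == hv[mid + 1L] &
                   lgv[mid - 1L] == lgv[mid + 1L] &
                   pv[mid] - pv[mid - 1L] <= singleton_max_gap_cm &
                   pv[mid + 1L] - pv[mid] <= singleton_max_gap_cm]
      if (length(bad)) hv[bad] <- hv[bad - 1L]
    }
    gaps <- diff(pv)
    use <- lgv[-1] == lgv[-length(lgv)] & gaps > 0 & gaps <= gap_cap_cm
    if (!any(use)) next
    s <- sex[i]
    dat[[s]]$d <- c(dat[[s]]$d, gaps[use])
    dat[[s]]$s <- c(dat[[s]]$s, (hv[-1] != hv[-length(hv)])[use])
  }
  sw <- vapply(dat, function(x) sum(x$s), numeric(1))
  ng <- vapply(dat, function(x) length(x$s), numeric(1))
  if (method == "mle") {
    fit_scale <- function(d, s) {
      if (!length(d) || !any(s)) return(NA_real_)
      nll <- function(logx) {
        p <- pmin(pmax(kosambi_inverse(exp(logx) * d), 1e-9), 0.5 - 1e-9)
        -sum(ifelse(s, log(p), log(1 - p)))
      }
      exp(stats::optimize(nll, c(-3, 3))$minimum)
    }
    scale_f <- fit_scale(dat$F$d, dat$F$s)
    scale_m <- fit_scale(dat$M$d, dat$M$s)
    list(ratio = scale_f / scale_m, scale_f = scale_f, scale_m = scale_m,
         n_switches_f = sw[["F"]], n_switches_m = sw[["M"]],
         n_gaps_f = ng[["F"]], n_gaps_m = ng[["M"]])
  } else {
    density_f <- 100 * sw[["F"]] / sum(dat$F$d)
    density_m <- 100 * sw[["M"]] / sum(dat$M$d)
    list(ratio = density_f / density_m,
         density_f = density_f, density_m = density_m,
         n_switches_f = sw[["F"]], n_switches_m = sw[["M"]],
         n_gaps_f = ng[["F"]], n_gaps_m = ng[["M"]])
  }
}

#' Benjamini-Hochberg step-up false-discovery-rate adjustment
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values in the input order (empty input gives empty output).
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}
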