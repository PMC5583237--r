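# Genome-coverage estimation and cross-map synteny comparison.

#' Expected linkage-group genome length
#'
#' `Ge = L * (m + 1) / (m - 1)` for a group of observed length `L` cM
#' carrying `m` loci (co-localised markers all count).
#'
#' @param length_cm observed LG length(s), cM.
#' @param n_markers marker count(s) `m`; values below 2 are rejected, `m =
#'   2` is computed but flagged by [expected_genome_length()].
#' @return Expected length(s), cM.
#' @export
lg_expected_length <- function(length_cm, n_markers) {
  if (any(n_markers < 2)) stop("Ge needs m >= 2 loci")
  length_cm * (n_markers + 1) / (n_markers - 1)
}

#' Genome-coverage report for a map
#'
#' Per linkage group: observed length `L` (sex-average by default), marker
#' count `m` and expected length `Ge = L*(m+1)/(m-1)`; totals `Goa` (sum of
#' observed) and `Ge_total`. Groups with fewer than 2 markers are excluded
#' and flagged; `m = 2` rows are flagged but kept.
#'
#' @param map a `genetic_map`, a map table (data.frame with `lg` and
#'   `pos_sexavg`), or a data.frame with columns `lg`, `length_cm`,
#'   `n_markers` (pre-aggregated).
#' @return data.frame of class `coverage_report`: `lg`, `length_cm`, `m`,
#'   `ge`, `flag`; attributes `goa` and `ge_total`.
#' @export
expected_genome_length <- function(map) {
  tab <- if (inherits(map, "genetic_map")) map$table else as.data.frame(map)
  if (all(c("length_cm", "n_markers") %in% names(tab))) {
    agg <- data.frame(lg = tab$lg, length_cm = tab$length_cm,
                      m = tab$n_markers, stringsAsFactors = FALSE)
  } else {
    agg <- do.call(rbind, lapply(split(tab, tab$lg), function(d)
      data.frame(lg = d$lg[1],
                 length_cm = max(d$pos_sexavg) - min(d$pos_sexavg),
                 m = nrow(d), stringsAsFactors = FALSE)))
  }
  flag <- ifelse(agg$m < 2, "excluded_m_lt_2",
                 ifelse(agg$m == 2, "m_eq_2", ""))
  keep <- agg$m >= 2
  ge <- rep(NA_real_, nrow(agg))
  ge[keep] <- lg_expected_length(agg$length_cm[keep], agg$m[keep])
  out <- data.frame(lg = agg$lg, length_cm = agg$length_cm, m = agg$m,
                    ge = ge, flag = flag, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("coverage_report", "data.frame"),
            goa = sum(agg$length_cm[keep]), ge_total = sum(ge[keep]))
}

#' Genome coverage from a coverage report
#'
#' `Coa = Goa / Ge_total`, reported as a percentage.
#'
#' @param report a [expected_genome_length()] result, or a list with
#'   elements `goa` and `ge_total`.
#' @return list: `goa`, `ge_total`, `coverage_pct`.
#' @export
genome_coverage <- function(report) {
  if (inherits(report, "coverage_report")) {
    goa <- attr(report, "goa"); ge_total <- attr(report, "ge_total")
  } else {
    goa <- report$goa; ge_total <- report$ge_total
  }
  if (is.null(ge_total) || ge_total == 0) stop("Ge total is zero/undefined")
  list(goa = goa, ge_total = ge_total,
       coverage_pct = 100 * goa / ge_total)
}

#' Oxford grid of shared markers across two maps
#'
#' Contingency matrix of shared-marker counts indexed by (linkage group in
#' map A) x (linkage group in map B). A marker is concordant iff its map-B
#' group is the majority map-B group of its map-A group.
#'
#' @param correspondence data.frame with columns `marker_a, marker_b, lg_a,
#'   pos_a, lg_b, pos_b` ([read_correspondence()] output). When `map_a` /
#'   `map_b` are supplied the lg/pos columns are (re)resolved from them and
#'   unresolvable rows are skipped with a count.
#' @param map_a,map_b optional `genetic_map`s or map tables.
#' @return list of class `oxford_grid`: `grid` (count matrix), `markers`
#'   (per-marker rows with `concordant`), `discordant` (marker_a ids),
#'   `n_skipped`.
#' @export
oxford_grid <- function(correspondence, map_a = NULL, map_b = NULL) {
  co <- as.data.frame(correspondence)
  n_skipped <- 0L
  resolve <- function(map, ids) {
    tab <- if (inherits(map, "genetic_map")) map$table else as.data.frame(map)
    idx <- match(ids, tab$marker_id)
    list(lg = tab$lg[idx], pos = tab$pos_sexavg[idx])
  }
  if (!is.null(map_a)) {
    ra <- resolve(map_a, co$marker_a)
    co$lg_a <- ra$lg; co$pos_a <- ra$pos
  }
  if (!is.null(map_b)) {
    rb <- resolve(map_b, co$marker_b)
    co$lg_b <- rb$lg; co$pos_b <- rb$pos
  }
  bad <- is.na(co$lg_a) | is.na(co$lg_b)
  if (any(bad)) {
    n_skipped <- sum(bad)
    warning(n_skipped, " correspondence row(s) unresolvable; skipped")
    co <- co[!bad, , drop = FALSE]
  }
  if (!nrow(co)) {
    return(structure(list(grid = matrix(0L, 0, 0), markers = co,
                          discordant = character(0), n_skipped = n_skipped),
                     class = "oxford_grid"))
  }
  grid <- table(lg_a = co$lg_a, lg_b = co$lg_b)
  majority_b <- apply(grid, 1, function(r) colnames(grid)[which.max(r)])
  co$concordant <- co$lg_b == majority_b[co$lg_a]
  structure(list(grid = unclass(grid), markers = co,
                 discordant = co$marker_a[!co$concordant],
                 n_skipped = n_skipped),
            class = "oxford_grid")
}

#' @export
print.oxford_grid <- function(x, ...) {
  cat("oxford_grid:", sum(x$grid), "shared markers;",
      length(x$discordant), "discordant;", x$n_skipped, "skipped\n")
  invisible(x)
}

#' Match linkage groups across two maps from an Oxford grid
#'
#' Majority-rule matching per map-A group (a match requires at least half
#' of that group's shared markers), with merge flags (two or more map-B
#' groups each placing `min_support` or more markers on one map-A group)
#' and the symmetric split flags.
#'
#' @param grid an [oxford_grid()] result.
#' @param min_support markers required from each side group for a
#'   merge/split flag (default 2).
#' @return list of class `lg_match_report`: `matches` (per map-A LG:
#'   `matched_lg_b`, `n_support`, `n_discordant`, `matched`), `merges`
#'   (map-A LG with the map-B groups involved), `splits`.
#' @export
lg_match <- function(grid, min_support = 2) {
  g <- if (inherits(grid, "oxford_grid")) grid$grid else as.matrix(grid)
  if (!length(g))
    return(structure(list(matches = data.frame(), merges = data.frame(),
                          splits = data.frame()), class = "lg_match_report"))
  matches <- do.call(rbind, lapply(rownames(g), function(a) {
    row <- g[a, ]
    best <- which.max(row)
    data.frame(lg_a = a, matched_lg_b = colnames(g)[best],
               n_support = as.integer(row[best]),
               n_discordant = as.integer(sum(row) - row[best]),
               matched = row[best] >= sum(row) / 2,
               stringsAsFactors = FALSE)
  }))
  merges <- do.call(rbind, lapply(rownames(g), function(a) {
    contrib <- colnames(g)[g[a, ] >= min_support]
    if (length(contrib) < 2) return(NULL)
    data.frame(lg_a = a, lgs_b = paste(contrib, collapse = "+"),
               stringsAsFactors = FALSE)
  }))
  splits <- do.call(rbind, lapply(colnames(g), function(b) {
    contrib <- rownames(g)[g[, b] >= min_support]
    if (length(contrib) < 2) return(NULL)
    data.frame(lg_b = b, lgs_a = paste(contrib, collapse = "+"),
               stringsAsFactors = FALSE)
  }))
  empty <- function(x, cols) if (is.null(x))
    as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                  stringsAsFactors = FALSE) else x
  structure(list(matches = matches,
                 merges = empty(merges, c("lg_a", "lgs_b")),
                 splits = empty(splits, c("lg_b", "lgs_a"))),
            class = "lg_match_report")
}
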