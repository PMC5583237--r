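# Pedigree/genotype simulator with known truth.
#
# Study design emulated: independent full-sib families, each with four
# genotyped grandparents, two F1 parents (one meiosis each from their own
# sire and dam, so parental phase is known by construction) and a set of
# full-sib progeny. Founder chromosomes are mosaics of a small ancestral
# haplotype panel, which induces linkage disequilibrium that decays with map
# distance. Meioses walk adjacent map intervals with independent
# recombination probability given by the inverse Kosambi function; female
# meioses may use multiplicatively expanded interval lengths.

#' Simulation configuration
#'
#' Collects and validates all generator parameters. The defaults describe a
#' mapping design of 5 linkage groups of 40 markers over 100 cM each,
#' genotyped in 20 full-sib families of 16 progeny with grandparent tracing —
#' a desk-scale analogue of a multi-family SNP-array mapping study.
#'
#' @param n_lgs number of linkage groups.
#' @param markers_per_lg markers per linkage group.
#' @param lg_length true length of each linkage group, cM.
#' @param n_families number of full-sib families (each with 4 grandparents,
#'   2 parents and `progeny_per_family` progeny).
#' @param progeny_per_family full-sib progeny per family.
#' @param n_ancestral_haplotypes size of the ancestral haplotype panel that
#'   founder chromosomes are copied from (smaller = stronger founder LD).
#' @param mosaic_switch_rate expected ancestral-donor switch events per cM in
#'   founder mosaics (larger = faster LD decay).
#' @param genotype_error_rate per-cell probability that an observed genotype
#'   is flipped to a uniformly chosen different state.
#' @param missing_rate per-cell missingness probability.
#' @param female_map_expansion multiplier applied to interval cM in female
#'   meioses (1 = no sex difference).
#' @param distortion_loci data.frame with columns `marker_id` and `s`:
#'   viability selection against the alternate allele. A progeny's survival
#'   is multiplied by `1 - s` for each alternate allele it inherited from a
#'   heterozygous parent, so an Aa x aa cross is thinned to 1 : (1-s) and an
#'   Aa x Aa cross to 1 : 2(1-s) : (1-s)^2.
#' @param orphan_holdout_fraction fraction of markers flagged as orphans:
#'   genotyped, but excluded from the truth handed to the linkage stage.
#' @param masked_parent_fraction fraction of families whose sire genotypes
#'   are deleted (for parent-reconstruction tests).
#' @param spacing `"even"` or `"random"` marker spacing along each LG.
#' @param maf_range range of ancestral allele frequencies markers are drawn
#'   from.
#' @param seed integer seed; mandatory, all stages derive their streams from
#'   it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_lgs = 5, markers_per_lg = 40, lg_length = 100,
                       n_families = 20, progeny_per_family = 16,
                       n_ancestral_haplotypes = 4, mosaic_switch_rate = 0.05,
                       genotype_error_rate = 0.001, missing_rate = 0.01,
                       female_map_expansion = 1, distortion_loci = NULL,
                       orphan_holdout_fraction = 0,
                       masked_parent_fraction = 0,
                       spacing = c("even", "random"),
                       maf_range = c(0.25, 0.5), seed) {
  spacing <- match.arg(spacing)
  if (missing(seed) || is.null(seed)) stop("config error: seed is mandatory")
  if (n_lgs < 1 || markers_per_lg < 1)
    stop("config error: need at least one LG and one marker per LG")
  if (markers_per_lg > 1 && lg_length <= 0)
    stop("config error: lg_length must be > 0 with >1 marker per LG",
         " (tied truth positions are disallowed)")
  if (n_families < 1 || progeny_per_family < 1)
    stop("config error: family size must be >= 1")
  if (n_ancestral_haplotypes < 2)
    stop("config error: need >= 2 ancestral haplotypes")
  rates <- c(genotype_error_rate, missing_rate, orphan_holdout_fraction,
             masked_parent_fraction)
  if (any(rates < 0 | rates > 1))
    stop("config error: rates must be in [0, 1]")
  if (mosaic_switch_rate < 0)
    stop("config error: mosaic_switch_rate must be >= 0")
  if (female_map_expansion <= 0)
    stop("config error: female_map_expansion must be > 0")
  if (!is.null(distortion_loci)) {
    distortion_loci <- as.data.frame(distortion_loci)
    if (!all(c("marker_id", "s") %in% names(distortion_loci)))
      stop("config error: distortion_loci needs marker_id and s columns")
    if (any(distortion_loci$s < 0 | distortion_loci$s > 1))
      stop("config error: selection coefficients must be in [0, 1]")
  }
  structure(list(
    n_lgs = n_lgs, markers_per_lg = markers_per_lg, lg_length = lg_length,
    n_families = n_families, progeny_per_family = progeny_per_family,
    n_ancestral_haplotypes = n_ancestral_haplotypes,
    mosaic_switch_rate = mosaic_switch_rate,
    genotype_error_rate = genotype_error_rate, missing_rate = missing_rate,
    female_map_expansion = female_map_expansion,
    distortion_loci = distortion_loci,
    orphan_holdout_fraction = orphan_holdout_fraction,
    masked_parent_fraction = masked_parent_fraction,
    spacing = spacing, maf_range = maf_range, seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a true genetic map
#'
#' @param config a [sim_config()].
#' @return A `true_map`: data.frame with `marker_id`, `lg`, `pos` (true
#'   sex-average cM, strictly increasing within LG) and `freq` (ancestral
#'   alternate-allele frequency).
#' @export
simulate_true_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  m <- config$markers_per_lg
  rows <- lapply(seq_len(config$n_lgs), function(i) {
    pos <- if (m == 1) 0 else if (config$spacing == "even")
      seq(0, config$lg_length, length.out = m)
    else sort(c(0, runif(m - 2, 0, config$lg_length), config$lg_length))
    while (m > 1 && any(diff(pos) <= 0))  # no tied truth positions
      pos <- sort(c(0, runif(m - 2, 0, config$lg_length), config$lg_length))
    data.frame(
      marker_id = sprintf("LG%02d_M%03d", i, seq_len(m)),
      lg = sprintf("TLG%02d", i), pos = pos,
      freq = runif(m, config$maf_range[1], config$maf_range[2]),
      stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("true_map", "data.frame"))
}

# one mosaic haplotype across one LG: donor switches at Poisson(rate * d)
.mosaic_hap <- function(panel, pos, rate) {
  m <- length(pos)
  if (m == 1) return(panel[sample.int(nrow(panel), 1L), , drop = TRUE])
  switches <- rpois(m - 1, rate * diff(pos)) > 0
  seg <- cumsum(c(1L, as.integer(switches)))
  donors <- sample.int(nrow(panel), max(seg), replace = TRUE)
  panel[cbind(donors[seg], seq_len(m))]
}

#' Simulate founder haplotypes as mosaics of an ancestral panel
#'
#' Each grandparent receives two haplotypes copied segment-wise from a small
#' ancestral panel, with donor switches arising at `mosaic_switch_rate` per
#' cM, so pairwise r-squared among founders decays with map distance down to
#' a sampling floor.
#'
#' @param true_map from [simulate_true_map()].
#' @param config a [sim_config()].
#' @return A `haplotype_panel`: list with `ancestral` (panel x markers 0/1
#'   matrix) and `haplotypes` (founder haplotypes x markers; two consecutive
#'   rows per grandparent, `4 * n_families` grandparents).
#' @export
simulate_founders <- function(true_map, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  m_total <- nrow(true_map)
  k <- config$n_ancestral_haplotypes
  # the panel realizes each marker's target frequency exactly (array markers
  # are ascertained polymorphic, so monomorphic ancestral columns would be
  # unrealistic): round(freq * k) alternate copies, at least one of each
  ancestral <- matrix(0L, k, m_total,
                      dimnames = list(NULL, true_map$marker_id))
  n_alt <- pmin(pmax(round(true_map$freq * k), 1L), k - 1L)
  for (j in seq_len(m_total))
    ancestral[sample.int(k, n_alt[j]), j] <- 1L
  n_haps <- 8L * config$n_families  # 4 grandparents x 2 haplotypes / family
  haps <- matrix(0L, n_haps, m_total,
                 dimnames = list(NULL, true_map$marker_id))
  lgs <- unique(true_map$lg)
  for (lg in lgs) {
    idx <- which(true_map$lg == lg)
    pos <- true_map$pos[idx]
    for (h in seq_len(n_haps))
      haps[h, idx] <- .mosaic_hap(ancestral[, idx, drop = FALSE], pos,
                                  config$mosaic_switch_rate)
  }
  structure(list(ancestral = ancestral, haplotypes = haps,
                 true_map = true_map), class = "haplotype_panel")
}

# gamete from a diploid (2 x markers haplotype matrix); returns alleles and
# the per-marker parental-haplotype origin (1 or 2)
.meiosis <- function(hap_pair, true_map, expansion) {
  m <- nrow(true_map)
  origin <- integer(m)
  for (lg in unique(true_map$lg)) {
    idx <- which(true_map$lg == lg)
    d <- diff(true_map$pos[idx]) * expansion
    theta <- kosambi_inverse(d)
    rec <- rbinom(length(theta), 1L, theta)
    o <- cumsum(c(sample(1:2, 1L), rec)) %% 2L
    origin[idx] <- o + 1L  # back to 1/2 labels
  }
  list(alleles = hap_pair[cbind(origin, seq_len(m))], origin = origin)
}

#' Simulate genotyped families with full truth
#'
#' Builds the pedigree (grandparents, F1 parents, full-sib progeny), runs
#' meioses under the inverse-Kosambi model with optional female map
#' expansion, applies viability selection at distortion loci, genotyping
#' error and missingness, holds out orphan markers and masks selected sire
#' genotypes.
#'
#' @param true_map from [simulate_true_map()].
#' @param founders from [simulate_founders()].
#' @param config a [sim_config()].
#' @return list with `study` (a [genotype_study()]) and `truth` — a list
#'   holding the true map, parent haplotypes (`parent_haps`), per-meiosis
#'   transmitted-haplotype origins (`origins`, meioses x markers, 1 =
#'   grandpaternal), true unobserved genotypes, orphan marker ids, masked
#'   sire ids and the distortion table.
#' @export
simulate_families <- function(true_map, founders, config) {
  stopifnot(inherits(config, "sim_config"),
            inherits(founders, "haplotype_panel"))
  set.seed(config$seed + 3L)
  nf <- config$n_families
  np <- config$progeny_per_family
  m_total <- nrow(true_map)
  exp_f <- config$female_map_expansion

  dist_idx <- integer(0); dist_s <- numeric(0)
  if (!is.null(config$distortion_loci)) {
    dist_idx <- match(config$distortion_loci$marker_id, true_map$marker_id)
    if (anyNA(dist_idx))
      stop("config error: distortion marker not in true map")
    dist_s <- config$distortion_loci$s
  }

  ped <- list(); geno <- list()
  parent_haps <- list()
  origins <- list(); origin_meta <- list()

  for (f in seq_len(nf)) {
    fam <- sprintf("F%02d", f)
    gp_ids <- paste0(fam, "_", c("GS1", "GD1", "GS2", "GD2"))
    gp_haps <- lapply(seq_len(4), function(g)
      founders$haplotypes[(f - 1L) * 8L + (g - 1L) * 2L + 1:2, , drop = FALSE])
    names(gp_haps) <- gp_ids

    # F1 parents: sire from GS1 x GD1, dam from GS2 x GD2; haplotype 1 is
    # always the grandpaternal gamete, so parental phase is known in truth
    sire_id <- paste0(fam, "_SIRE"); dam_id <- paste0(fam, "_DAM")
    sire_haps <- rbind(.meiosis(gp_haps[[1]], true_map, 1)$alleles,
                       .meiosis(gp_haps[[2]], true_map, exp_f)$alleles)
    dam_haps <- rbind(.meiosis(gp_haps[[3]], true_map, 1)$alleles,
                      .meiosis(gp_haps[[4]], true_map, exp_f)$alleles)
    parent_haps[[sire_id]] <- sire_haps
    parent_haps[[dam_id]] <- dam_haps

    ped[[length(ped) + 1L]] <- data.frame(
      sample_id = c(gp_ids, sire_id, dam_id),
      sire_id = c(rep(NA, 4), gp_ids[1], gp_ids[3]),
      dam_id = c(rep(NA, 4), gp_ids[2], gp_ids[4]),
      sex = c("M", "F", "M", "F", "M", "F"),
      family_id = fam,
      generation = c(rep("grandparent", 4), "parent", "parent"),
      stringsAsFactors = FALSE)
    for (g in seq_len(4))
      geno[[gp_ids[g]]] <- colSums(gp_haps[[g]])
    geno[[sire_id]] <- colSums(sire_haps)
    geno[[dam_id]] <- colSums(dam_haps)

    sire_het <- geno[[sire_id]][dist_idx] == 1L
    dam_het <- geno[[dam_id]][dist_idx] == 1L

    for (p in seq_len(np)) {
      pid <- sprintf("%s_P%02d", fam, p)
      for (attempt in seq_len(1000L)) {
        gs <- .meiosis(sire_haps, true_map, 1)
        gd <- .meiosis(dam_haps, true_map, exp_f)
        if (length(dist_idx)) {
          # disfavoured alternate alleles inherited from heterozygous parents
          n_bad <- (gs$alleles[dist_idx] == 1L) * sire_het +
                   (gd$alleles[dist_idx] == 1L) * dam_het
          surv <- prod((1 - dist_s)^n_bad)
          if (surv < 1 && runif(1) > surv) next
        }
        break
      }
      if (attempt == 1000L)
        stop("viability selection rejected 1000 consecutive meioses")
      geno[[pid]] <- gs$alleles + gd$alleles
      ped[[length(ped) + 1L]] <- data.frame(
        sample_id = pid, sire_id = sire_id, dam_id = dam_id, sex = "U",
        family_id = fam, generation = "progeny", stringsAsFactors = FALSE)
      origins[[length(origins) + 1L]] <- gs$origin
      origin_meta[[length(origin_meta) + 1L]] <-
        data.frame(parent_id = sire_id, progeny_id = pid,
                   stringsAsFactors = FALSE)
      origins[[length(origins) + 1L]] <- gd$origin
      origin_meta[[length(origin_meta) + 1L]] <-
        data.frame(parent_id = dam_id, progeny_id = pid,
                   stringsAsFactors = FALSE)
    }
  }

  pedigree <- do.call(rbind, ped)
  true_geno <- do.call(rbind, geno)
  storage.mode(true_geno) <- "integer"
  rownames(true_geno) <- names(geno)
  colnames(true_geno) <- true_map$marker_id

  obs <- true_geno
  masked <- character(0)
  if (config$masked_parent_fraction > 0) {
    sires <- pedigree$sample_id[pedigree$generation == "parent" &
                                pedigree$sex == "M"]
    n_mask <- round(config$masked_parent_fraction * length(sires))
    if (n_mask > 0) {
      masked <- sample(sires, n_mask)
      obs[masked, ] <- NA_integer_
    }
  }
  if (config$genotype_error_rate > 0) {
    flip <- which(!is.na(obs) &
                  matrix(runif(length(obs)) < config$genotype_error_rate,
                         nrow(obs)))
    if (length(flip)) {
      old <- obs[flip]
      obs[flip] <- vapply(old, function(g)
        sample(setdiff(0:2, g), 1L), integer(1))
    }
  }
  if (config$missing_rate > 0)
    obs[matrix(runif(length(obs)) < config$missing_rate, nrow(obs))] <-
      NA_integer_

  orphans <- character(0)
  if (config$orphan_holdout_fraction > 0) {
    n_orph <- round(config$orphan_holdout_fraction * m_total)
    if (n_orph > 0) orphans <- sort(sample(true_map$marker_id, n_orph))
  }

  markers <- data.frame(marker_id = true_map$marker_id,
                        allele_ref = "A", allele_alt = "B",
                        stringsAsFactors = FALSE)
  study <- genotype_study(markers, pedigree, obs,
                          metadata = list(seed = config$seed,
                                          generator = "lodemap::simulate"))
  origin_mat <- do.call(rbind, origins)
  colnames(origin_mat) <- true_map$marker_id
  truth <- list(true_map = true_map,
                parent_haps = parent_haps,
                origins = origin_mat,
                origin_meta = do.call(rbind, origin_meta),
                true_genotypes = true_geno,
                orphans = orphans,
                masked_parents = masked,
                distortion_loci = config$distortion_loci)
  list(study = study, truth = truth)
}

#' Run the full simulator
#'
#' Convenience wrapper: [simulate_true_map()], [simulate_founders()],
#' [simulate_families()] under one config.
#'
#' @param config a [sim_config()].
#' @return As [simulate_families()].
#' @export
simulate_study <- function(config) {
  tm <- simulate_true_map(config)
  fd <- simulate_founders(tm, config)
  simulate_families(tm, fd, config)
}
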