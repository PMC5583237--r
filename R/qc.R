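# Marker/sample quality control: per-SNP summaries, Mendelian agreement,
# duplicate detection, the array QC exclusion ledger, the in-silico SNP
# discovery filter ledger, and ML reconstruction of an ungenotyped parent.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the allele counts, sums the probabilities of
#' all heterozygote counts whose conditional probability does not exceed the
#' observed one.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom-ref, het, hom-alt).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(NA_real_)
  n_a <- 2 * n_aa + n_ab          # minor/major labelling is irrelevant
  rare <- min(n_a, 2 * n - n_a)
  hets <- seq(rare %% 2, rare, by = 2)
  # log conditional probability of each possible het count
  logp <- vapply(hets, function(h) {
    na2 <- (rare - h) / 2
    nb2 <- n - h - na2
    lgamma(n + 1) - lgamma(na2 + 1) - lgamma(h + 1) - lgamma(nb2 + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs_het <- min(n_ab, rare)
  p_obs <- prob[match(obs_het, hets)]
  min(1, sum(prob[prob <= p_obs + 1e-12]))
}

#' Per-marker summary statistics
#'
#' Call rate, minor-allele frequency, heterozygote frequency, exact-test HWE
#' p-value (computed on non-progeny samples only, so family structure does
#' not masquerade as disequilibrium), Mendelian agreement and QC flags.
#'
#' @param study a [genotype_study()].
#' @param hwe_alpha significance level for the `hwe_fail` flag (default
#'   1e-4).
#' @param maf_min polymorphism threshold for the `low_maf` flag (default
#'   0.01).
#' @param mi_min Mendelian-agreement threshold for the `mi_fail` flag
#'   (default 0.99).
#' @param call_min call-rate threshold for the `low_call` flag (default
#'   0.90).
#' @return data.frame, one row per marker: `marker_id`, `call_rate`, `maf`,
#'   `het_frequency`, `hwe_p`, `n_mendelian_errors`, `mendelian_agreement`
#'   and logical flag columns (`no_amplify`, `monomorphic`, `hwe_fail`,
#'   `mi_fail`, `low_maf`, `low_call`).
#' @export
snp_summary <- function(study, hwe_alpha = 1e-4, maf_min = 0.01,
                        mi_min = 0.99, call_min = 0.90) {
  g <- study$genotypes
  if (!nrow(g)) stop("study has no samples")
  founders <- study$pedigree$sample_id[
    study$pedigree$generation != "progeny"]
  gf <- g[founders, , drop = FALSE]

  call_rate <- colMeans(!is.na(g))
  n_alt <- colSums(g, na.rm = TRUE)
  n_called <- colSums(!is.na(g))
  p_alt <- ifelse(n_called > 0, n_alt / (2 * n_called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  het <- ifelse(n_called > 0,
                colSums(g == 1L, na.rm = TRUE) / n_called, NA_real_)
  hwe_p <- vapply(seq_len(ncol(gf)), function(j) {
    x <- gf[, j]
    hwe_exact_test(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
                   sum(x == 2L, na.rm = TRUE))
  }, numeric(1))

  ma <- mendelian_agreement(study)
  out <- data.frame(
    marker_id = colnames(g),
    call_rate = unname(call_rate), maf = unname(maf),
    het_frequency = unname(het), hwe_p = unname(hwe_p),
    n_mendelian_errors = ma$n_errors,
    mendelian_agreement = ma$agreement,
    stringsAsFactors = FALSE)
  out$no_amplify <- out$call_rate == 0
  out$monomorphic <- !out$no_amplify &
    colSums(g == 1L, na.rm = TRUE) == 0    # no heterozygous calls
  out$hwe_fail <- !is.na(out$hwe_p) & out$hwe_p < hwe_alpha
  out$mi_fail <- !is.na(out$mendelian_agreement) &
    out$mendelian_agreement < mi_min
  out$low_maf <- !is.na(out$maf) & out$maf < maf_min
  out$low_call <- out$call_rate < call_min
  out
}

# progeny genotype impossible given available parent genotypes?
.mendel_error_matrix <- function(study) {
  ped <- study$pedigree
  g <- study$genotypes
  prog <- ped[ped$generation == "progeny" &
              (!is.na(ped$sire_id) | !is.na(ped$dam_id)), , drop = FALSE]
  err <- tested <- matrix(FALSE, nrow(prog), ncol(g),
                          dimnames = list(prog$sample_id, colnames(g)))
  for (i in seq_len(nrow(prog))) {
    gc_ <- g[prog$sample_id[i], ]
    gs <- if (!is.na(prog$sire_id[i])) g[prog$sire_id[i], ] else
      rep(NA_integer_, ncol(g))
    gd <- if (!is.na(prog$dam_id[i])) g[prog$dam_id[i], ] else
      rep(NA_integer_, ncol(g))
    has_parent <- !is.na(gs) | !is.na(gd)
    tested[i, ] <- !is.na(gc_) & has_parent
    # single-parent violations: hom parent cannot give opposite hom child
    e <- (!is.na(gs) & ((gs == 0L & gc_ == 2L) | (gs == 2L & gc_ == 0L))) |
         (!is.na(gd) & ((gd == 0L & gc_ == 2L) | (gd == 2L & gc_ == 0L)))
    # both-parents violations: child het requires different transmittable
    # alleles; both parents hom-same cannot give het
    both <- !is.na(gs) & !is.na(gd)
    e <- e | (both & gs == 0L & gd == 0L & gc_ != 0L) |
             (both & gs == 2L & gd == 2L & gc_ != 2L) |
             (both & ((gs == 0L & gd == 2L) | (gs == 2L & gd == 0L)) &
                gc_ != 1L)
    e[is.na(e)] <- FALSE
    err[i, ] <- e & tested[i, ]
  }
  list(errors = err, tested = tested)
}

#' Per-marker Mendelian agreement
#'
#' `agreement = 1 - n_errors / n_loci_tested`, where an error is a progeny
#' genotype impossible given the available parent genotypes and a test is a
#' genotyped progeny with at least one genotyped parent.
#'
#' @param study a [genotype_study()].
#' @return data.frame: `marker_id`, `n_errors`, `n_tested`, `agreement`
#'   (NA where zero loci were tested).
#' @export
mendelian_agreement <- function(study) {
  mm <- .mendel_error_matrix(study)
  n_err <- colSums(mm$errors)
  n_test <- colSums(mm$tested)
  data.frame(marker_id = colnames(study$genotypes),
             n_errors = unname(n_err), n_tested = unname(n_test),
             agreement = ifelse(n_test > 0, 1 - n_err / n_test, NA_real_),
             stringsAsFactors = FALSE)
}

#' Detect duplicated markers by genotype concordance
#'
#' Marker pairs whose concordance over jointly non-missing samples reaches
#' the threshold; the later-listed member of each pair is the one flagged.
#'
#' @param study a [genotype_study()].
#' @param concordance_threshold default 0.995.
#' @param min_overlap minimum jointly called samples for a comparison
#'   (default 10).
#' @return data.frame: `marker_a`, `marker_b` (flagged duplicate),
#'   `concordance`, `n_overlap`.
#' @export
detect_duplicates <- function(study, concordance_threshold = 0.995,
                              min_overlap = 10) {
  g <- study$genotypes
  if (ncol(g) < 2) stop("need >= 2 markers")
  out <- list()
  for (j in seq_len(ncol(g) - 1L)) for (k in (j + 1L):ncol(g)) {
    both <- !is.na(g[, j]) & !is.na(g[, k])
    n <- sum(both)
    if (n < min_overlap) next
    conc <- mean(g[both, j] == g[both, k])
    if (conc >= concordance_threshold)
      out[[length(out) + 1L]] <- data.frame(
        marker_a = colnames(g)[j], marker_b = colnames(g)[k],
        concordance = conc, n_overlap = n, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(marker_a = character(0), marker_b = character(0),
                      concordance = numeric(0), n_overlap = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Build a QC exclusion ledger from a starting count and step counts
#'
#' The primitive behind both QC pipelines: an ordered sequence of labelled
#' exclusion steps with running remaining counts. Conservation (exclusions +
#' final remaining = start) holds by construction.
#'
#' @param total starting count.
#' @param steps named numeric vector of per-step exclusion counts, in order.
#' @return data.frame of class `qc_ledger`: `step`, `label`, `n_excluded`,
#'   `n_remaining`.
#' @export
qc_ledger <- function(total, steps) {
  if (any(steps < 0)) stop("exclusion counts must be >= 0")
  remaining <- total - cumsum(steps)
  if (any(remaining < 0)) stop("ledger would go negative")
  structure(data.frame(step = seq_along(steps), label = names(steps),
                       n_excluded = unname(steps),
                       n_remaining = unname(remaining),
                       stringsAsFactors = FALSE),
            class = c("qc_ledger", "data.frame"))
}

#' Array-performance rates from a QC ledger
#'
#' Conversion rate = SNPs producing genotypes / total; validation rate =
#' polymorphic / genotyped; the minimal-error and final rates also use the
#' genotyped count as denominator. Steps are identified by label.
#'
#' @param ledger a [qc_ledger()] whose labels include `no_amplify`,
#'   `ambiguous` and `monomorphic` (the array pipeline's ordering).
#' @param total the starting count the ledger was built from.
#' @return list: `conversion_rate`, `validation_rate`, `minimal_error_rate`,
#'   `final_rate` (all percentages) and the underlying counts.
#' @export
qc_rates <- function(ledger, total) {
  lab <- ledger$label
  after <- function(l) ledger$n_remaining[match(l, lab)]
  genotyped <- after("ambiguous")
  polym <- after("monomorphic")
  minimal <- after("mi_gross")
  final <- ledger$n_remaining[nrow(ledger)]
  list(conversion_rate = 100 * genotyped / total,
       validation_rate = 100 * polym / genotyped,
       minimal_error_rate = 100 * minimal / genotyped,
       final_rate = 100 * final / genotyped,
       n_genotyped = genotyped, n_polymorphic = polym,
       n_minimal_error = minimal, n_final = final)
}

#' Apply the array QC pipeline to a study
#'
#' Exclusion steps in the array accounting order: low-call-rate samples are
#' dropped first, then markers by no-amplification, ambiguous clusters
#' (annotation flag), monomorphism, HWE deviation, Mendelian-inheritance
#' failure (two passes: gross and residual < 0.01 error), low MAF,
#' duplication, low call rate and two-cluster annotation. Cluster-shape
#' flags (`flag_ambiguous`, `flag_two_cluster`) are consumed from the marker
#' table when present — they come from array intensity review and cannot be
#' recomputed from genotypes.
#'
#' @param study a [genotype_study()].
#' @param sample_call_rate sample inclusion threshold (default 0.90).
#' @param marker_call_rate marker call-rate threshold (default 0.90).
#' @param maf_min polymorphism threshold (default 0.01).
#' @param hwe_alpha HWE exclusion level (default 1e-4).
#' @param mi_gross agreement below this is a gross MI failure (default
#'   0.95).
#' @param mi_min residual MI agreement threshold (default 0.99).
#' @param duplicate_threshold concordance for duplicates (default 0.995).
#' @return list: `study` (filtered), `ledger` (a [qc_ledger()]), `rates`
#'   (from [qc_rates()]), `n_samples_excluded`.
#' @export
apply_qc_pipeline <- function(study, sample_call_rate = 0.90,
                              marker_call_rate = 0.90, maf_min = 0.01,
                              hwe_alpha = 1e-4, mi_gross = 0.95,
                              mi_min = 0.99, duplicate_threshold = 0.995) {
  scall <- rowMeans(!is.na(study$genotypes))
  keep_samples <- scall >= sample_call_rate
  n_samp_excl <- sum(!keep_samples)
  if (n_samp_excl) {
    ped <- study$pedigree[keep_samples, , drop = FALSE]
    drop_ids <- study$pedigree$sample_id[!keep_samples]
    ped$sire_id[ped$sire_id %in% drop_ids] <- NA
    ped$dam_id[ped$dam_id %in% drop_ids] <- NA
    study <- genotype_study(study$markers, ped,
                            study$genotypes[keep_samples, , drop = FALSE],
                            study$metadata)
  }

  s <- snp_summary(study, hwe_alpha = hwe_alpha, maf_min = maf_min,
                   mi_min = mi_min, call_min = marker_call_rate)
  flag_col <- function(nm) {
    if (nm %in% names(study$markers))
      as.logical(study$markers[[nm]]) else rep(FALSE, nrow(s))
  }
  ambiguous <- flag_col("flag_ambiguous")
  two_cluster <- flag_col("flag_two_cluster")

  alive <- rep(TRUE, nrow(s))
  steps <- numeric(0)
  take <- function(label, cond) {
    hit <- alive & cond
    alive <<- alive & !hit
    steps <<- c(steps, setNames(sum(hit), label))
  }
  take("no_amplify", s$no_amplify)
  take("ambiguous", ambiguous)
  take("monomorphic", s$monomorphic)
  take("hwe_deviation", s$hwe_fail)
  take("mi_gross", !is.na(s$mendelian_agreement) &
         s$mendelian_agreement < mi_gross)
  take("mi_residual", s$mi_fail)
  take("low_maf", s$low_maf)
  dup <- detect_duplicates(
    genotype_study(study$markers[alive, , drop = FALSE], study$pedigree,
                   study$genotypes[, alive, drop = FALSE], study$metadata),
    concordance_threshold = duplicate_threshold)
  take("duplicate", s$marker_id %in% dup$marker_b)
  take("low_call", s$low_call)
  take("two_cluster", two_cluster)

  ledger <- qc_ledger(nrow(s), steps)
  filtered <- genotype_study(study$markers[alive, , drop = FALSE],
                             study$pedigree,
                             study$genotypes[, alive, drop = FALSE],
                             study$metadata)
  list(study = filtered, ledger = ledger,
       rates = tryCatch(qc_rates(ledger, nrow(s)), error = function(e) NULL),
       n_samples_excluded = n_samp_excl)
}

#' In-silico SNP discovery filter
#'
#' Sequential candidate-SNP filtering in the discovery order: read-level
#' quality (in-silico MAF, read depth, minor-allele reads, SNP and flanking
#' qualities), multi-allelic sites, sites needing Infinium type I probes
#' (A/T or C/G), repeat-masked probes, low assay-design (ADT) score,
#' non-unique probes, and finally proximity — any two surviving candidates
#' on the same contig closer than `flank_bp` are both removed (symmetric
#' rule; set `proximity_rule = "keep_better"` to retain the higher-quality
#' member).
#'
#' @param candidates data.frame with columns `contig_id`, `position`,
#'   `alleles` (string, e.g. `"A/T"`), `read_depth`, `minor_allele_reads`,
#'   `maf_insilico`, `snp_quality`, `flanking_quality`, `repeat_masked`,
#'   `adt_score`, `probe_unique`.
#' @param maf_min minimum in-silico MAF (default 0.25).
#' @param depth_min minimum read depth (default 10).
#' @param minor_reads_min minimum minor-allele reads (default 2).
#' @param snp_quality_min minimum SNP mapping quality (default 25).
#' @param flank_quality_min minimum flanking-sequence quality (default 25).
#' @param adt_min minimum ADT score (default 0.7; scores are consumed, never
#'   computed).
#' @param flank_bp proximity exclusion window, bp (default 50).
#' @param proximity_rule `"drop_both"` (default) or `"keep_better"`.
#' @return list: `survivors` (filtered candidate table), `ledger` (a
#'   [qc_ledger()]).
#' @export
insilico_snp_filter <- function(candidates, maf_min = 0.25, depth_min = 10,
                                minor_reads_min = 2, snp_quality_min = 25,
                                flank_quality_min = 25, adt_min = 0.7,
                                flank_bp = 50,
                                proximity_rule = c("drop_both",
                                                   "keep_better")) {
  proximity_rule <- match.arg(proximity_rule)
  cand <- as.data.frame(candidates)
  if (any(cand$minor_allele_reads > cand$read_depth))
    stop("minor_allele_reads exceeds read_depth")
  alive <- rep(TRUE, nrow(cand))
  steps <- numeric(0)
  take <- function(label, cond) {
    hit <- alive & cond
    alive <<- alive & !hit
    steps <<- c(steps, setNames(sum(hit), label))
  }
  n_alleles <- vapply(strsplit(cand$alleles, "/", fixed = TRUE), length,
                      integer(1))
  type_i <- cand$alleles %in% c("A/T", "T/A", "C/G", "G/C")
  take("quality", cand$maf_insilico < maf_min |
         cand$read_depth < depth_min |
         cand$minor_allele_reads < minor_reads_min |
         cand$snp_quality < snp_quality_min |
         cand$flanking_quality < flank_quality_min)
  take("multi_allelic", n_alleles > 2)
  take("infinium_type_i", type_i)
  take("repeat_masked", as.logical(cand$repeat_masked))
  take("low_adt", cand$adt_score < adt_min)
  take("probe_not_unique", !as.logical(cand$probe_unique))
  # proximity among survivors, per contig
  prox <- rep(FALSE, nrow(cand))
  for (ct in unique(cand$contig_id[alive])) {
    sel <- which(alive & cand$contig_id == ct)
    if (length(sel) < 2) next
    pos <- cand$position[sel]
    o <- order(pos)
    close_next <- diff(pos[o]) < flank_bp
    hit <- rep(FALSE, length(sel))
    hit[o][which(close_next)] <- TRUE
    hit[o][which(close_next) + 1L] <- TRUE
    if (proximity_rule == "keep_better") {
      # within each run of close candidates keep the highest snp_quality
      runs <- split(o[hit[o]], cumsum(!c(FALSE, close_next))[hit[o]])
      hit <- rep(FALSE, length(sel))
      for (rn in runs) {
        worst <- rn[-which.max(cand$snp_quality[sel][rn])]
        hit[worst] <- TRUE
      }
    }
    prox[sel[hit]] <- TRUE
  }
  take("flanking_proximity", prox)
  list(survivors = cand[alive, , drop = FALSE],
       ledger = qc_ledger(nrow(cand), steps))
}

#' Maximum-likelihood reconstruction of an ungenotyped parent
#'
#' Per locus, the likelihood of the progeny genotype counts is evaluated
#' under each of the three candidate genotypes for the unknown parent, with
#' the known parent's genotype fixed and Mendelian transmission assumed
#' (loci treated independently; no linkage information is used — a
#' deliberate simple stand-in, flagged in the result metadata).
#'
#' @param known_parent_genotypes integer vector (0/1/2/NA) per locus for the
#'   genotyped parent.
#' @param progeny_genotypes matrix progeny x loci (0/1/2/NA).
#' @return data.frame of class `reconstructed_genotype`: per locus
#'   `ml_genotype`, `loglik_0`, `loglik_1`, `loglik_2`, `incompatible`
#'   (TRUE when no candidate explains the progeny), `undefined` (no
#'   genotyped progeny). Attribute `method = "per_locus_ml"`.
#' @export
reconstruct_parent_genotype <- function(known_parent_genotypes,
                                        progeny_genotypes) {
  pg <- as.matrix(progeny_genotypes)
  n_loci <- ncol(pg)
  stopifnot(length(known_parent_genotypes) == n_loci)
  ll <- matrix(NA_real_, n_loci, 3)
  ml <- rep(NA_integer_, n_loci)
  incompatible <- undefined <- rep(FALSE, n_loci)
  for (j in seq_len(n_loci)) {
    counts <- tabulate(pg[, j] + 1L, nbins = 3L)
    if (sum(counts) == 0 || is.na(known_parent_genotypes[j])) {
      undefined[j] <- TRUE
      next
    }
    p_known <- known_parent_genotypes[j] / 2
    for (g_cand in 0:2) {
      p_c <- g_cand / 2
      probs <- c((1 - p_known) * (1 - p_c),
                 p_known * (1 - p_c) + (1 - p_known) * p_c,
                 p_known * p_c)
      ll[j, g_cand + 1L] <- sum(ifelse(counts > 0, counts * log(probs), 0))
    }
    if (all(!is.finite(ll[j, ]))) incompatible[j] <- TRUE
    else ml[j] <- which.max(ll[j, ]) - 1L
  }
  structure(data.frame(ml_genotype = ml,
                       loglik_0 = ll[, 1], loglik_1 = ll[, 2],
                       loglik_2 = ll[, 3],
                       incompatible = incompatible, undefined = undefined),
            class = c("reconstructed_genotype", "data.frame"),
            method = "per_locus_ml")
}
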