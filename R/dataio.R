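# Data input/output: genotype studies (PED/MAP and TSV dialects), genetic-map
# tables and marker-correspondence tables.
#
# Genotypes are stored unphased as counts of the alternate allele:
# 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
# NA = missing. Phase is derived downstream from the pedigree.

VALID_SEX <- c("M", "F", "U")
VALID_GENERATION <- c("grandparent", "parent", "progeny")
MAP_COLUMNS <- c("marker_id", "lg", "pos_sexavg", "pos_f", "pos_m", "method")
CORR_COLUMNS <- c("marker_a", "marker_b", "lg_a", "pos_a", "lg_b", "pos_b")

#' Assemble and validate a genotype study
#'
#' Bundles a marker table, a pedigree and a genotype matrix into a single
#' validated object, the working set of the whole pipeline.
#'
#' @param markers data.frame with columns `marker_id`, `allele_ref`,
#'   `allele_alt` and optionally `source_contig`, `lg_hint`, `pos_hint` plus
#'   free annotation columns (e.g. array QC flags).
#' @param pedigree data.frame with columns `sample_id`, `sire_id`, `dam_id`
#'   (NA = unknown), `sex` (`"M"`, `"F"` or `"U"`), `family_id`, `generation`
#'   (`"grandparent"`, `"parent"` or `"progeny"`).
#' @param genotypes integer matrix, samples x markers, values 0/1/2/NA
#'   (alternate-allele counts). Row and column names must match the pedigree
#'   and marker table.
#' @param metadata free-form named list (seed, provenance, ...).
#' @return An object of class `genotype_study`.
#' @export
genotype_study <- function(markers, pedigree, genotypes, metadata = list()) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  pedigree <- as.data.frame(pedigree, stringsAsFactors = FALSE)
  if (!"marker_id" %in% names(markers))
    stop("marker table needs a 'marker_id' column")
  if (anyDuplicated(markers$marker_id))
    stop("integrity error: duplicated marker_id: ",
         paste(unique(markers$marker_id[duplicated(markers$marker_id)]),
               collapse = ", "))
  if (!all(c("allele_ref", "allele_alt") %in% names(markers))) {
    markers$allele_ref <- if ("allele_ref" %in% names(markers))
      markers$allele_ref else "A"
    markers$allele_alt <- if ("allele_alt" %in% names(markers))
      markers$allele_alt else "B"
  }
  if (any(markers$allele_ref == markers$allele_alt))
    stop("integrity error: marker with identical ref/alt allele codes")

  need <- c("sample_id", "sire_id", "dam_id", "sex", "family_id", "generation")
  miss <- setdiff(need, names(pedigree))
  if (length(miss))
    stop("pedigree is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(pedigree$sample_id))
    stop("integrity error: duplicated sample_id in pedigree")
  if (!all(pedigree$sex %in% VALID_SEX))
    stop("pedigree sex must be one of ", paste(VALID_SEX, collapse = "/"))
  if (!all(pedigree$generation %in% VALID_GENERATION))
    stop("pedigree generation must be one of ",
         paste(VALID_GENERATION, collapse = "/"))
  for (col in c("sire_id", "dam_id")) {
    known <- !is.na(pedigree[[col]])
    bad <- known & !(pedigree[[col]] %in% pedigree$sample_id)
    if (any(bad))
      stop("integrity error: ", col, " not present as a sample: ",
           paste(unique(pedigree[[col]][bad]), collapse = ", "))
    if (any(known & pedigree[[col]] == pedigree$sample_id))
      stop("integrity error: sample listed as its own parent")
  }
  .check_no_ancestor_cycles(pedigree)

  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(rownames(genotypes)) || is.null(colnames(genotypes)))
    stop("genotype matrix needs sample row names and marker column names")
  if (!identical(sort(rownames(genotypes)), sort(pedigree$sample_id)))
    stop("format error: genotype rows do not match pedigree sample_ids")
  if (!identical(sort(colnames(genotypes)), sort(markers$marker_id)))
    stop("format error: genotype columns do not match marker table")
  genotypes <- genotypes[pedigree$sample_id, markers$marker_id, drop = FALSE]
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("format error: genotype values must be 0, 1, 2 or NA")

  structure(list(markers = markers, pedigree = pedigree,
                 genotypes = genotypes, metadata = metadata),
            class = "genotype_study")
}

.check_no_ancestor_cycles <- function(ped) {
  # every sample must have a finite ancestor chain
  parent_of <- rbind(
    data.frame(s = ped$sample_id, p = ped$sire_id, stringsAsFactors = FALSE),
    data.frame(s = ped$sample_id, p = ped$dam_id, stringsAsFactors = FALSE))
  parent_of <- parent_of[!is.na(parent_of$p), , drop = FALSE]
  if (!nrow(parent_of)) return(invisible(TRUE))
  for (s0 in unique(parent_of$s)) {
    frontier <- s0
    seen <- character(0)
    while (length(frontier)) {
      nxt <- parent_of$p[parent_of$s %in% frontier]
      if (s0 %in% nxt)
        stop("integrity error: sample ", s0, " is its own ancestor")
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
  }
  invisible(TRUE)
}

#' @export
print.genotype_study <- function(x, ...) {
  cat("genotype_study:", nrow(x$pedigree), "samples x",
      nrow(x$markers), "markers\n")
  gen <- table(x$pedigree$generation)
  cat("  generations:",
      paste(names(gen), as.integer(gen), sep = "=", collapse = ", "), "\n")
  cat("  missing genotype cells:", sum(is.na(x$genotypes)), "\n")
  invisible(x)
}

#' Read a genotype study from disk
#'
#' Two dialects are supported. `"ped_map"` reads a space-delimited PLINK-style
#' PED/MAP pair: 6 leading PED columns (family, sample, sire, dam, sex,
#' phenotype) then two allele codes per marker, `0` meaning a missing allele;
#' the MAP file holds 3 or 4 columns (chromosome/linkage-group hint, marker
#' id, cM position and optionally bp). `"tsv"` reads a tab-separated genotype
#' table (`sample_id` + one 0/1/2/NA column per marker) together with a
#' pedigree TSV.
#'
#' @param path for `"ped_map"`, the file prefix (or the `.ped` file itself);
#'   for `"tsv"`, the genotype table.
#' @param dialect `"ped_map"` or `"tsv"`.
#' @param pedigree_path pedigree TSV (required for `"tsv"`; columns
#'   `sample_id, sire_id, dam_id, sex, family_id, generation`).
#' @param metadata passed through to [genotype_study()].
#' @return A validated [genotype_study()].
#' @export
read_genotypes <- function(path, dialect = c("ped_map", "tsv"),
                           pedigree_path = NULL, metadata = list()) {
  dialect <- match.arg(dialect)
  if (dialect == "ped_map") {
    prefix <- sub("\\.ped$", "", path)
    ped_file <- paste0(prefix, ".ped")
    map_file <- paste0(prefix, ".map")
    if (!file.exists(ped_file)) stop("format error: missing ", ped_file)
    if (!file.exists(map_file)) stop("format error: missing ", map_file)
    .read_ped_map(ped_file, map_file, metadata)
  } else {
    if (is.null(pedigree_path))
      stop("tsv dialect requires pedigree_path")
    .read_tsv_study(path, pedigree_path, metadata)
  }
}

.read_ped_map <- function(ped_file, map_file, metadata) {
  map <- read.table(map_file, header = FALSE, stringsAsFactors = FALSE)
  if (!ncol(map) %in% 3:4)
    stop("format error: MAP file must have 3 or 4 columns, found ", ncol(map))
  names(map)[1:3] <- c("lg_hint", "marker_id", "pos_hint")
  if (anyDuplicated(map$marker_id))
    stop("integrity error: duplicated marker_id in MAP file")
  ped <- read.table(ped_file, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  n_mark <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_mark)
    stop("format error: PED has ", ncol(ped), " columns; expected ",
         6 + 2 * n_mark, " for ", n_mark, " markers")
  if (anyDuplicated(ped[[2]]))
    stop("integrity error: duplicated sample_id in PED file")

  geno <- matrix(NA_integer_, nrow(ped), n_mark,
                 dimnames = list(ped[[2]], map$marker_id))
  allele_ref <- character(n_mark)
  allele_alt <- character(n_mark)
  for (j in seq_len(n_mark)) {
    a1 <- ped[[6 + 2 * j - 1]]
    a2 <- ped[[6 + 2 * j]]
    ok <- a1 != "0" & a2 != "0"
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    if (length(alleles) > 2)
      stop("format error: marker ", map$marker_id[j],
           " has >2 allele codes in PED")
    if (length(alleles) == 0) alleles <- c("A", "B")
    if (length(alleles) == 1) alleles <- c(alleles, setdiff(c("A", "B"),
                                                            alleles)[1])
    allele_ref[j] <- alleles[1]
    allele_alt[j] <- alleles[2]
    geno[ok, j] <- (a1[ok] == alleles[2]) + (a2[ok] == alleles[2])
  }

  sex <- c(`1` = "M", `2` = "F")[ped[[5]]]
  sex[is.na(sex)] <- "U"
  pedigree <- data.frame(
    sample_id = ped[[2]],
    sire_id = ifelse(ped[[3]] == "0", NA_character_, ped[[3]]),
    dam_id = ifelse(ped[[4]] == "0", NA_character_, ped[[4]]),
    sex = unname(sex),
    family_id = ped[[1]],
    stringsAsFactors = FALSE)
  pedigree$generation <- .infer_generation(pedigree)

  markers <- data.frame(marker_id = map$marker_id,
                        allele_ref = allele_ref, allele_alt = allele_alt,
                        lg_hint = as.character(map$lg_hint),
                        pos_hint = as.numeric(map$pos_hint),
                        stringsAsFactors = FALSE)
  genotype_study(markers, pedigree, geno, metadata)
}

# grandparent = founders of parents; parent = has offspring; progeny = leaf
.infer_generation <- function(ped) {
  is_parent <- ped$sample_id %in% c(ped$sire_id, ped$dam_id)
  offspring_of <- function(id)
    ped$sample_id[!is.na(ped$sire_id) & ped$sire_id == id |
                  !is.na(ped$dam_id) & ped$dam_id == id]
  gen <- ifelse(is_parent, "parent", "progeny")
  for (i in which(is_parent)) {
    kids <- offspring_of(ped$sample_id[i])
    if (any(kids %in% ped$sample_id[is_parent])) gen[i] <- "grandparent"
  }
  gen
}

.read_tsv_study <- function(geno_path, ped_path, metadata) {
  g <- read.table(geno_path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE, check.names = FALSE)
  if (names(g)[1] != "sample_id")
    stop("format error: genotype TSV must start with a sample_id column")
  mk <- names(g)[-1]
  if (anyDuplicated(mk))
    stop("integrity error: duplicated marker column: ",
         paste(unique(mk[duplicated(mk)]), collapse = ", "))
  if (anyDuplicated(g$sample_id))
    stop("integrity error: duplicated sample_id in genotype TSV")
  geno <- as.matrix(g[, -1, drop = FALSE])
  rownames(geno) <- g$sample_id
  suppressWarnings(storage.mode(geno) <- "integer")
  ped <- read.table(ped_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = c("NA", "", "0"))
  markers <- data.frame(marker_id = mk, allele_ref = "A", allele_alt = "B",
                        stringsAsFactors = FALSE)
  genotype_study(markers, ped, geno, metadata)
}

#' Write a genotype study to disk
#'
#' Inverse of [read_genotypes()]; the write/read roundtrip is the identity on
#' genotype values and missing cells.
#'
#' @param study a [genotype_study()].
#' @param path file prefix (`ped_map`) or genotype TSV path (`tsv`).
#' @param dialect `"ped_map"` or `"tsv"`.
#' @param pedigree_path pedigree TSV path (`tsv` dialect only).
#' @export
write_genotypes <- function(study, path, dialect = c("ped_map", "tsv"),
                            pedigree_path = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "ped_map") {
    prefix <- sub("\\.ped$", "", path)
    g <- study$genotypes
    mk <- study$markers
    ped6 <- data.frame(
      fam = study$pedigree$family_id,
      id = study$pedigree$sample_id,
      sire = ifelse(is.na(study$pedigree$sire_id), "0",
                    study$pedigree$sire_id),
      dam = ifelse(is.na(study$pedigree$dam_id), "0", study$pedigree$dam_id),
      sex = c(M = "1", F = "2", U = "0")[study$pedigree$sex],
      pheno = "-9", stringsAsFactors = FALSE)
    allele_cols <- vector("list", nrow(mk))
    for (j in seq_len(nrow(mk))) {
      a <- matrix("0", nrow(g), 2)
      gt <- g[, j]
      a[!is.na(gt) & gt == 0, ] <- mk$allele_ref[j]
      a[!is.na(gt) & gt == 2, ] <- mk$allele_alt[j]
      het <- !is.na(gt) & gt == 1
      a[het, 1] <- mk$allele_ref[j]
      a[het, 2] <- mk$allele_alt[j]
      allele_cols[[j]] <- a
    }
    out <- cbind(ped6, do.call(cbind, allele_cols))
    write.table(out, paste0(prefix, ".ped"), quote = FALSE, sep = " ",
                row.names = FALSE, col.names = FALSE)
    map <- data.frame(
      lg = if ("lg_hint" %in% names(mk) && !all(is.na(mk$lg_hint)))
        ifelse(is.na(mk$lg_hint), "0", mk$lg_hint) else "0",
      marker_id = mk$marker_id,
      cm = if ("pos_hint" %in% names(mk) && !all(is.na(mk$pos_hint)))
        ifelse(is.na(mk$pos_hint), 0, mk$pos_hint) else 0)
    write.table(map, paste0(prefix, ".map"), quote = FALSE, sep = " ",
                row.names = FALSE, col.names = FALSE)
    invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
  } else {
    g <- as.data.frame(study$genotypes)
    g <- cbind(sample_id = rownames(study$genotypes), g)
    write.table(g, path, quote = FALSE, sep = "\t", row.names = FALSE)
    if (!is.null(pedigree_path)) {
      ped <- study$pedigree
      write.table(ped, pedigree_path, quote = FALSE, sep = "\t",
                  row.names = FALSE, na = "NA")
    }
    invisible(path)
  }
}

.validate_map_table <- function(tab) {
  miss <- setdiff(MAP_COLUMNS, names(tab))
  if (length(miss))
    stop("format error: map table missing column(s): ",
         paste(miss, collapse = ", "))
  pos <- tab$pos_sexavg
  if (any(!is.na(pos) & pos < 0))
    stop("integrity error: negative map position")
  for (lg in unique(tab$lg)) {
    p <- pos[tab$lg == lg]
    p <- p[!is.na(p)]
    if (is.unsorted(p))
      stop("integrity error: positions not non-decreasing within LG ", lg)
  }
  invisible(TRUE)
}

#' Write a genetic-map table as TSV
#'
#' Columns are written in the fixed order
#' `marker_id, lg, pos_sexavg, pos_f, pos_m, method`; positions must be
#' non-negative and non-decreasing within each linkage group.
#'
#' @param map a [genetic_map] object or a data.frame with the map columns.
#' @param path output path.
#' @export
write_map <- function(map, path) {
  tab <- if (inherits(map, "genetic_map")) map$table else as.data.frame(map)
  .validate_map_table(tab)
  write.table(tab[, MAP_COLUMNS], path, quote = FALSE, sep = "\t",
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a genetic-map table written by [write_map()]
#' @param path TSV path.
#' @return data.frame with the six fixed map columns, validated.
#' @export
read_map <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "numeric", "numeric", "character"))
  .validate_map_table(tab)
  tab
}

#' Read a marker-correspondence table
#'
#' Six named TSV columns: `marker_a, marker_b, lg_a, pos_a, lg_b, pos_b` —
#' the product of an orthology/identity match between two maps.
#'
#' @param path TSV path.
#' @return data.frame preserving row order.
#' @export
read_correspondence <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  miss <- setdiff(CORR_COLUMNS, names(tab))
  if (length(miss))
    stop("format error: correspondence table missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("pos_a", "pos_b")) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (any(is.na(vn) & !is.na(v)))
        stop("format error: non-numeric cM in column ", col)
      tab[[col]] <- vn
    }
  }
  tab[, CORR_COLUMNS]
}

#' Write a marker-correspondence table
#' @param tab data.frame with the six correspondence columns.
#' @param path output path.
#' @export
write_correspondence <- function(tab, path) {
  miss <- setdiff(CORR_COLUMNS, names(tab))
  if (length(miss))
    stop("format error: correspondence table missing column(s): ",
         paste(miss, collapse = ", "))
  write.table(tab[, CORR_COLUMNS], path, quote = FALSE, sep = "\t",
              row.names = FALSE)
  invisible(path)
}
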