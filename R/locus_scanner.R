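#' Loci fixed for the alternate allele within one population
#'
#' A locus qualifies when every counted individual of the population is
#' homozygous for the scanned allele and the missing-data policy holds.
#' The default policy counts every individual (zero missing tolerated:
#' "fixed in all individuals"); `min_called_frac < 1` relaxes this to
#' "at least that fraction called, and all called individuals homozygous".
#'
#' @param gm a [genotype_matrix()].
#' @param pm popmap (sample -> population).
#' @param population population label to scan.
#' @param min_called_frac minimum fraction of the population's
#'   individuals that must be called (1 = none missing).
#' @param allele `"alt"` (default; hom-alt fixation relative to the
#'   reference) or `"ref"` for completeness.
#' @return Object of class `fixed_locus_set`: list with `population`,
#'   `idx` (locus column indices) and `loci` (their metadata rows).
#' @export
fixed_loci <- function(gm, pm, population, min_called_frac = 1,
                       allele = c("alt", "ref")) {
  allele <- match.arg(allele)
  pm <- align_popmap(gm, pm)
  if (!population %in% pm) stop("unknown population: ", population)
  idx <- fixed_idx(gm, names(pm)[pm == population], min_called_frac, allele)
  structure(list(population = population, idx = idx,
                 loci = gm$loci[idx, , drop = FALSE], allele = allele),
            class = "fixed_locus_set")
}

#' @export
print.fixed_locus_set <- function(x, ...) {
  cat(sprintf("fixed_locus_set: %d loci fixed (%s) in %s\n",
              length(x$idx), x$allele, x$population))
  invisible(x)
}

# vectorized fixation test: columns where all called members have the
# homozygous code and the called fraction satisfies the policy
fixed_idx <- function(gm, members, min_called_frac, allele) {
  g <- gm$geno[members, , drop = FALSE]
  target <- if (allele == "alt") 2L else 0L
  n_called <- colSums(!is.na(g))
  all_target <- colSums(g == target, na.rm = TRUE) == n_called
  ok <- n_called >= min_called_frac * length(members) & n_called > 0L & all_target
  which(ok)
}

#' Population-specific (private fixed) loci
#'
#' The core diagnostic scan. In `strict-private` mode (default), a locus
#' is specific to population P when P is fixed for the scanned allele and
#' no called individual outside P carries that allele at all. In
#' `upset-unique` mode, a locus is specific to P when it is in P's fixed
#' set and in no other population's fixed set (the singleton cells of the
#' UpSet intersection diagram) — a weaker condition that tolerates
#' carriers outside P as long as no other population is fixed.
#'
#' @param gm a [genotype_matrix()].
#' @param pm popmap.
#' @param mode `"strict-private"` or `"upset-unique"`.
#' @param min_called_frac missing policy within the focal population
#'   (see [fixed_loci()]).
#' @param allele scanned allele, `"alt"` (default) or `"ref"`.
#' @return Named list (one element per population) of marker data.frames
#'   with columns `chrom`, `pos`, `ref`, `alt`, `population`,
#'   `diagnostic_allele`, sorted by (chrom, pos).
#' @export
specific_loci <- function(gm, pm, mode = c("strict-private", "upset-unique"),
                          min_called_frac = 1, allele = c("alt", "ref")) {
  mode <- match.arg(mode)
  allele <- match.arg(allele)
  pm <- align_popmap(gm, pm)
  pops <- sort(unique(pm))
  if (length(pops) < 2L) stop("need at least 2 populations")
  fixed <- lapply(pops, function(p) {
    fixed_idx(gm, names(pm)[pm == p], min_called_frac, allele)
  })
  names(fixed) <- pops
  out <- vector("list", length(pops))
  names(out) <- pops
  for (p in pops) {
    idx <- fixed[[p]]
    if (mode == "strict-private") {
      others <- names(pm)[pm != p]
      g_out <- gm$geno[others, idx, drop = FALSE]
      carried <- if (allele == "alt") {
        colSums(g_out > 0L, na.rm = TRUE) > 0L
      } else {
        colSums(g_out < 2L, na.rm = TRUE) > 0L
      }
      idx <- idx[!carried]
    } else {
      other_fixed <- unique(unlist(fixed[setdiff(pops, p)], use.names = FALSE))
      idx <- setdiff(idx, other_fixed)
    }
    loci <- gm$loci[idx, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
    loci$population <- rep(p, nrow(loci))
    loci$diagnostic_allele <- if (allele == "alt") loci$alt else loci$ref
    rownames(loci) <- NULL
    out[[p]] <- loci
  }
  out
}

#' UpSet-style intersection counts of fixed-locus sets
#'
#' For every nonempty subset S of populations, counts the loci fixed in
#' exactly the populations of S. The counts over all subsets sum to the
#' size of the union.
#'
#' @param fixed named list of `fixed_locus_set` objects (or plain vectors
#'   of locus identifiers).
#' @return data.frame with `combination` (labels joined by `&`),
#'   `degree`, and `count`, over all nonempty subsets.
#' @export
intersection_counts <- function(fixed) {
  sets <- lapply(fixed, function(x) {
    if (inherits(x, "fixed_locus_set")) locus_id(x$loci) else as.character(x)
  })
  pops <- names(sets)
  if (is.null(pops) || any(!nzchar(pops))) stop("sets must be named")
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1L, function(row) {
    paste(pops[row], collapse = "&")
  })
  tallies <- table(pattern)
  combos <- unlist(lapply(seq_along(pops), function(k) {
    apply(utils::combn(pops, k), 2L, paste, collapse = "&")
  }))
  out <- data.frame(
    combination = combos,
    degree = lengths(strsplit(combos, "&", fixed = TRUE)),
    count = as.integer(ifelse(combos %in% names(tallies),
                              tallies[combos], 0L)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Restrict markers to selected target genes: the diagnostic panel
#'
#' Keeps markers whose locus lies within a selected gene span (1-based
#' inclusive) and annotates the housing gene, producing the deliverable
#' panel.
#'
#' @param markers named list of marker data.frames from [specific_loci()]
#'   (or a single combined data.frame).
#' @param genes selected gene table (e.g. from [select_target_genes()]):
#'   columns `gene_id`, `chrom`, `start`, `end`.
#' @param provenance optional list of scan settings recorded on the panel.
#' @return Object of class `diagnostic_panel`: a data.frame of markers
#'   with a `gene_id` column, canonically sorted by (population, chrom,
#'   pos), with attributes `provenance` and `summary` (per-population
#'   marker counts and genes hit).
#' @export
restrict_to_genes <- function(markers, genes, provenance = list()) {
  if (is.data.frame(markers)) markers <- list(markers)
  tab <- do.call(rbind, unname(markers))
  if (is.null(tab) || nrow(tab) == 0L) {
    tab <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      population = character(0),
                      diagnostic_allele = character(0))
  }
  gene_of <- rep(NA_character_, nrow(tab))
  for (k in seq_len(nrow(genes))) {
    hit <- tab$chrom == genes$chrom[k] &
      tab$pos >= genes$start[k] & tab$pos <= genes$end[k] & is.na(gene_of)
    gene_of[hit] <- genes$gene_id[k]
  }
  tab$gene_id <- gene_of
  tab <- tab[!is.na(tab$gene_id), , drop = FALSE]
  tab <- tab[order(tab$population, tab$chrom, tab$pos), , drop = FALSE]
  if (anyDuplicated(tab[, c("chrom", "pos", "population")])) {
    tab <- tab[!duplicated(tab[, c("chrom", "pos", "population")]), ]
  }
  rownames(tab) <- NULL
  smry <- list(
    markers_per_population = table(tab$population),
    genes_hit = length(unique(tab$gene_id))
  )
  structure(tab, class = c("diagnostic_panel", "data.frame"),
            provenance = provenance, summary = smry)
}

#' @export
print.diagnostic_panel <- function(x, ...) {
  cat(sprintf("diagnostic_panel: %d markers, %d populations, %d genes\n",
              nrow(x), length(unique(x$population)),
              length(unique(x$gene_id))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a diagnostic panel as TSV (and optionally BED)
#'
#' @param panel a `diagnostic_panel`.
#' @param path TSV output path.
#' @param bed_path optional BED path; coordinates convert to 0-based
#'   half-open at this boundary only.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, bed_path = NULL) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = panel$chrom, start = panel$pos - 1L,
                      end = panel$pos,
                      name = paste(panel$population, panel$gene_id, sep = "|"))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a diagnostic panel TSV back
#' @param path TSV written by [write_panel()].
#' @return A `diagnostic_panel`.
#' @export
read_panel <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  structure(tab, class = c("diagnostic_panel", "data.frame"),
            provenance = list(source = path))
}
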