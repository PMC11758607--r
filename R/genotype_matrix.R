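#' Genotype matrix of biallelic SNP calls
#'
#' Container for diploid genotype calls at SNP loci: an integer matrix of
#' samples (rows) by loci (columns) holding the count of alternate alleles
#' (0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing), plus per-locus
#' metadata (contig, 1-based position, ref and alt allele).
#'
#' @param geno integer matrix, samples x loci, values in \{0, 1, 2, NA\}.
#'   Row names are sample ids.
#' @param loci data.frame with one row per locus and columns `chrom`,
#'   `pos` (1-based), `ref`, `alt`; optional columns `qual`, `filter`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `geno` (the call matrix), `loci` (locus metadata, with added logical
#'   columns `is_snp` and `is_biallelic`), and `samples`.
#' @examples
#' gm <- genotype_matrix(
#'   matrix(c(0L, 2L, 1L, NA), 2, 2, dimnames = list(c("s1", "s2"), NULL)),
#'   data.frame(chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = c("G", "T"))
#' )
#' gm
#' @export
genotype_matrix <- function(geno, loci) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  colnames(geno) <- NULL
  if (is.null(rownames(geno))) stop("geno must have sample ids as row names")
  if (anyDuplicated(rownames(geno))) stop("duplicate sample ids")
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(loci))) {
    stop("loci must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(loci) != ncol(geno)) stop("loci rows must match geno columns")
  if (any(loci$pos < 1L)) stop("positions must be 1-based (>= 1)")
  if (is.null(loci$qual)) loci$qual <- NA_real_
  if (is.null(loci$filter)) loci$filter <- "PASS"
  bases <- c("A", "C", "G", "T")
  loci$is_snp <- loci$ref %in% bases &
    !grepl(",", loci$alt, fixed = TRUE) &
    nchar(loci$alt) == 1L & loci$alt %in% c(bases, ".")
  loci$is_biallelic <- !grepl(",", loci$alt, fixed = TRUE) & loci$alt != "."
  if (any(loci$is_snp & loci$ref == loci$alt)) stop("ref == alt at a SNP locus")
  bad <- geno[!is.na(geno) & !(geno %in% 0:2)]
  if (length(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  rownames(loci) <- NULL
  structure(
    list(geno = geno, loci = loci, samples = rownames(geno)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d loci (%d contigs, %.1f%% missing)\n",
    n_samples(x), n_loci(x), length(unique(x$loci$chrom)),
    100 * mean(is.na(x$geno))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param x a `genotype_matrix`.
#' @param i sample index (ids, logical or integer).
#' @param j locus index (logical or integer).
#' @param ... ignored.
#' @return A `genotype_matrix` with the selected samples and loci, in the
#'   requested order.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  genotype_matrix(x$geno[i, j, drop = FALSE], x$loci[j, , drop = FALSE])
}

n_samples <- function(gm) nrow(gm$geno)
n_loci <- function(gm) ncol(gm$geno)

locus_id <- function(loci) paste(loci$chrom, loci$pos, sep = ":")

#' Alternate-allele frequency per locus
#'
#' @param gm a `genotype_matrix`.
#' @param samples optional subset of sample ids over which to count.
#' @return Numeric vector of alt-allele frequencies computed from called
#'   genotypes only; `NaN` where no genotype is called.
#' @export
alt_freq <- function(gm, samples = NULL) {
  g <- gm$geno
  if (!is.null(samples)) g <- g[samples, , drop = FALSE]
  colSums(g, na.rm = TRUE) / (2 * colSums(!is.na(g)))
}
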