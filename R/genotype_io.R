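#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses the GT field of a VCF (v4.2) into alternate-allele dosage codes.
#' Non-SNP and multiallelic records are retained but flagged
#' (`is_snp`/`is_biallelic` columns of the locus table) so that
#' [filter_sites()] can remove them; genotype phase is ignored and diploid
#' half-calls (e.g. `0/.`) are treated as missing.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param region optional region filter, either `"chrom"` or a list
#'   `list(chrom =, start =, end =)` with a 1-based inclusive interval.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF parse error in ", path, ": ", conditionMessage(e))
  )
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (ncol(v@gt) < 2L) stop("VCF has no sample columns: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  # dosage codes; anything other than two called alleles -> NA
  code_one <- function(s) {
    al <- strsplit(gsub("|", "/", s, fixed = TRUE), "/", fixed = TRUE)
    vapply(al, function(a) {
      if (length(a) != 2L || any(a == ".") || any(!grepl("^[0-9]+$", a))) {
        return(NA_integer_)
      }
      sum(as.integer(a) > 0L)
    }, integer(1))
  }
  codes <- apply(gt, 2L, code_one)
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1, dimnames = dimnames(gt))
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  loci <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    qual = qual, filter = ifelse(is.na(fix[, "FILTER"]), ".", fix[, "FILTER"]),
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(t(codes), loci)
  if (!is.null(region)) {
    if (is.character(region)) region <- list(chrom = region)
    keep <- gm$loci$chrom == region$chrom
    if (!is.null(region$start)) keep <- keep & gm$loci$pos >= region$start
    if (!is.null(region$end)) keep <- keep & gm$loci$pos <= region$end
    gm <- gm[, keep]
  }
  gm
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits plain-text VCF with unphased diploid GT fields; QUAL and FILTER
#' come from the locus metadata. Reading the file back with [read_vcf()]
#' reproduces the genotype codes and locus metadata exactly.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=poptrace",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  ), con)
  gt_str <- c("0/0", "0/1", "1/1")
  g <- gm$geno
  m <- matrix("./.", nrow(g), ncol(g))
  ok <- !is.na(g)
  m[ok] <- gt_str[g[ok] + 1L]
  qual <- ifelse(is.na(gm$loci$qual), ".", format(gm$loci$qual, trim = TRUE))
  rows <- paste(gm$loci$chrom, gm$loci$pos, ".", gm$loci$ref, gm$loci$alt,
                qual, gm$loci$filter, ".", "GT", sep = "\t")
  body <- apply(m, 2L, paste, collapse = "\t")
  writeLines(paste(rows, body, sep = "\t"), con)
  invisible(path)
}

#' Filter SNP sites on missingness, quality, allele count and MAF
#'
#' Site-level screen in the style of VCFtools: retain sites whose missing
#' fraction is at most `max_missing_frac` (VCFtools `--max-missing 0.9`
#' means at least 90\% called, i.e. `max_missing_frac = 0.1`), whose QUAL
#' is at least `min_qual`, which are biallelic SNPs, and (optionally)
#' whose minor allele frequency over called genotypes is at least
#' `maf_min`. Retained loci and samples keep their order, so the filter
#' is idempotent.
#'
#' @param gm a `genotype_matrix`.
#' @param max_missing_frac maximum per-site fraction of missing genotypes.
#' @param min_qual minimum QUAL; sites with missing QUAL (`.`) pass.
#' @param biallelic_only drop non-SNP and multiallelic records.
#' @param maf_min optional minimum minor allele frequency; a site whose
#'   MAF equals `maf_min` is retained (`>=`), invariant sites (MAF 0) are
#'   removed.
#' @param pass_only if `TRUE`, drop sites whose FILTER column is neither
#'   `PASS` nor `.` (upstream hard-filter verdicts are honored this way).
#' @return The filtered `genotype_matrix`.
#' @export
filter_sites <- function(gm, max_missing_frac = 0.1, min_qual = 20,
                         biallelic_only = TRUE, maf_min = NULL,
                         pass_only = FALSE) {
  if (n_loci(gm) == 0L) stop("empty genotype matrix")
  if (max_missing_frac < 0 || max_missing_frac > 1) {
    stop("max_missing_frac must be in [0, 1]")
  }
  miss <- colMeans(is.na(gm$geno))
  keep <- miss <= max_missing_frac
  keep <- keep & (is.na(gm$loci$qual) | gm$loci$qual >= min_qual)
  if (biallelic_only) keep <- keep & gm$loci$is_snp & gm$loci$is_biallelic
  if (pass_only) keep <- keep & gm$loci$filter %in% c("PASS", ".")
  if (!is.null(maf_min)) {
    f <- alt_freq(gm)
    maf <- pmin(f, 1 - f)
    keep <- keep & !is.na(maf) & maf >= maf_min & maf > 0
  }
  gm[, keep]
}

#' Read a sample-to-population map
#'
#' @param path TSV with two columns: sample id and population label
#'   (no header, or a header line starting with `sample`).
#' @return Named character vector mapping sample id to population label.
#'   A sample listed twice with the same population is accepted with a
#'   warning; conflicting assignments are an error.
#' @export
read_popmap <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("sample", "population"))
  if (nrow(tab) && tolower(tab$sample[1]) == "sample") tab <- tab[-1, ]
  dup <- duplicated(tab$sample)
  if (any(dup)) {
    for (s in unique(tab$sample[dup])) {
      pops <- unique(tab$population[tab$sample == s])
      if (length(pops) > 1L) {
        stop("sample ", s, " assigned to conflicting populations: ",
             paste(pops, collapse = ", "))
      }
    }
    warning("duplicate sample rows collapsed: ",
            paste(unique(tab$sample[dup]), collapse = ", "))
    tab <- tab[!dup, ]
  }
  stats::setNames(tab$population, tab$sample)
}

#' Write a population map
#' @param pm named character vector (sample -> population).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pm, path) {
  utils::write.table(data.frame(sample = names(pm), population = unname(pm)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export genotype codes as TSV
#'
#' Samples x loci table of codes (columns named `chrom:pos`); missing
#' genotypes are written as `NA`.
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geno_tsv <- function(gm, path) {
  m <- gm$geno
  colnames(m) <- locus_id(gm$loci)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

# restrict a popmap to the samples of a matrix, warning on strays
align_popmap <- function(gm, pm) {
  stray <- setdiff(names(pm), gm$samples)
  if (length(stray)) {
    warning("popmap samples absent from matrix: ", paste(stray, collapse = ", "))
  }
  missing <- setdiff(gm$samples, names(pm))
  if (length(missing)) {
    stop("matrix samples missing from popmap: ", paste(missing, collapse = ", "))
  }
  pm[gm$samples]
}
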