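#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper around [ape::nj()] that validates the input and clamps
#' negative branch lengths to zero. Three taxa give the unique unrooted
#' star topology.
#'
#' @param d symmetric nonnegative distance matrix with zero diagonal and
#'   at least 3 labelled taxa.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(d))) stop("distance matrix must have taxon labels")
  if (!isTRUE(all.equal(d, t(d), check.attributes = FALSE))) {
    stop("distance matrix is not symmetric")
  }
  if (any(d < 0) || any(diag(d) != 0)) {
    stop("distances must be nonnegative with zero diagonal")
  }
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# nontrivial splits of an unrooted tree, canonicalized: each split is the
# sorted leaf subset on the side NOT containing the first label
# (alphabetically), serialized for set comparison
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  anchor <- tips[1]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character(0)
  for (p in parts) {
    side <- labs[p]
    if (anchor %in% side) side <- setdiff(tips, side)
    k <- length(side)
    if (k >= 2L && k <= n - 2L) out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Robinson-Foulds distance between two unrooted topologies
#'
#' Size of the symmetric difference between the sets of nontrivial
#' bipartitions of the two trees, which is 0 for identical topologies and
#' `2*(n-3)` for maximally different bifurcating trees.
#'
#' @param t1,t2 [ape::phylo] trees over the same leaf set.
#' @return List with `rf` (the count) and `normalized`
#'   (`rf / (2*(n-3))`, `NA` for fewer than 4 leaves).
#' @export
rf_distance <- function(t1, t2) {
  l1 <- sort(t1$tip.label)
  l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    diffs <- c(setdiff(l1, l2), setdiff(l2, l1))
    stop("leaf sets differ: ", paste(diffs, collapse = ", "))
  }
  if (length(l1) < 3L) stop("RF needs at least 3 leaves")
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  rf <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  n <- length(l1)
  list(rf = rf, normalized = if (n >= 4L) rf / (2 * (n - 3)) else NA_real_)
}

#' Build per-gene NJ trees from genotype data
#'
#' For each gene, subsets the loci falling inside the gene span, computes
#' the pairwise allele-sharing distance
#' \eqn{d(i,j) = \mathrm{mean}_{\ell}\,|g_{i\ell} - g_{j\ell}|/2} over loci
#' called in both samples, and runs [nj_tree()]. Genes with fewer than 4
#' informative sites (sites variable among called samples), or with a
#' sample pair sharing no called locus, are marked untreeable.
#'
#' @param gm a [genotype_matrix()].
#' @param genes gene table from [read_gff_genes()] (columns `gene_id`,
#'   `chrom`, `start`, `end`).
#' @param collapse_to optional popmap; when given, samples are averaged
#'   into per-population distance entries before NJ (trees then have one
#'   leaf per population).
#' @return List with `trees` (gene_id -> `phylo` or `NULL` if untreeable)
#'   and `genes` (input table with added `n_informative_sites` and
#'   `untreeable` columns).
#' @export
gene_trees_from_matrix <- function(gm, genes, collapse_to = NULL) {
  trees <- vector("list", nrow(genes))
  names(trees) <- genes$gene_id
  n_inf <- integer(nrow(genes))
  untree <- logical(nrow(genes))
  for (k in seq_len(nrow(genes))) {
    in_gene <- gm$loci$chrom == genes$chrom[k] &
      gm$loci$pos >= genes$start[k] & gm$loci$pos <= genes$end[k]
    sub <- gm$geno[, in_gene, drop = FALSE]
    informative <- apply(sub, 2L, function(col) {
      length(unique(col[!is.na(col)])) > 1L
    })
    n_inf[k] <- sum(informative)
    if (n_inf[k] < 4L) {
      untree[k] <- TRUE
      next
    }
    d <- allele_sharing_dist(sub[, informative, drop = FALSE])
    if (!is.null(collapse_to)) {
      pm <- align_popmap(gm, collapse_to)
      pops <- sort(unique(pm))
      dp <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
      for (a in seq_along(pops)) {
        for (b in seq_along(pops)) {
          if (a < b) {
            dp[a, b] <- dp[b, a] <-
              mean(d[names(pm)[pm == pops[a]], names(pm)[pm == pops[b]]])
          }
        }
      }
      d <- dp
    }
    if (anyNA(d) || nrow(d) < 3L) {
      untree[k] <- TRUE
      next
    }
    trees[[k]] <- nj_tree(d)
  }
  genes$n_informative_sites <- n_inf
  genes$untreeable <- untree
  list(trees = trees, genes = genes)
}

# mean |code_i - code_j| / 2 over loci called in both samples
allele_sharing_dist <- function(geno) {
  n <- nrow(geno)
  d <- matrix(0, n, n, dimnames = list(rownames(geno), rownames(geno)))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      ok <- !is.na(geno[a, ]) & !is.na(geno[b, ])
      d[a, b] <- d[b, a] <- if (any(ok)) {
        mean(abs(geno[a, ok] - geno[b, ok]) / 2)
      } else {
        NA_real_
      }
    }
  }
  d
}

#' Attach RF distances to a gene table
#'
#' @param gt result of [gene_trees_from_matrix()].
#' @param species_tree [ape::phylo] species tree over the same leaf set
#'   as the gene trees.
#' @return The gene table with an `rf` column (`NA` for untreeable genes).
#' @export
gene_rf <- function(gt, species_tree) {
  genes <- gt$genes
  genes$rf <- vapply(seq_len(nrow(genes)), function(k) {
    tr <- gt$trees[[genes$gene_id[k]]]
    if (is.null(tr)) return(NA_real_)
    rf_distance(tr, species_tree)$rf
  }, numeric(1))
  genes
}

#' Pearson correlation between RF distance and gene length
#'
#' @param genes gene table with `rf` and `length` columns; rows with `NA`
#'   rf are dropped.
#' @return List with `r`, `p` (two-sided), `n`; `r` is `NA` with a note
#'   when either variable has zero variance.
#' @export
rf_length_correlation <- function(genes) {
  ok <- !is.na(genes$rf) & !is.na(genes$length)
  x <- genes$length[ok]
  y <- genes$rf[ok]
  if (length(x) < 3L) stop("need at least 3 genes with defined rf")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                note = "zero variance: correlation undefined"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Rank genes by species-tree concordance and select targets
#'
#' Drops exons shorter than `min_exon_len` from the gene models, keeps
#' genes whose span length exceeds `min_gene_len`, sorts by (rf
#' ascending, length ascending, gene_id) and returns the first
#' `n_targets` — the genes most concordant with the species phylogeny
#' and short enough to amplify across.
#'
#' @param genes gene table with `rf`, `length`, and (optionally) an
#'   `exons` list-column of 2-column start/end matrices.
#' @param min_gene_len minimum span length in bp (strict `>`).
#' @param min_exon_len exons shorter than this are removed from the model.
#' @param n_targets number of genes to return.
#' @param length_mode `"span"` (default) ranks on genomic span length;
#'   `"exon"` ranks on summed exon length after the exon filter.
#' @return The selected gene table, ranked, with a `rank` column.
#' @export
select_target_genes <- function(genes, min_gene_len = 2000, min_exon_len = 15,
                                n_targets = 300,
                                length_mode = c("span", "exon")) {
  length_mode <- match.arg(length_mode)
  if (!is.null(genes$exons)) {
    genes$exons <- lapply(genes$exons, function(ex) {
      if (is.null(ex) || nrow(ex) == 0L) return(ex)
      ex[(ex[, 2] - ex[, 1] + 1) >= min_exon_len, , drop = FALSE]
    })
  }
  genes$length <- genes$end - genes$start + 1L
  rank_len <- if (length_mode == "exon" && !is.null(genes$exons)) {
    vapply(genes$exons, function(ex) {
      if (is.null(ex) || nrow(ex) == 0L) 0L else sum(ex[, 2] - ex[, 1] + 1L)
    }, integer(1))
  } else {
    genes$length
  }
  keep <- genes$length > min_gene_len & !is.na(genes$rf)
  genes <- genes[keep, , drop = FALSE]
  rank_len <- rank_len[keep]
  ord <- order(genes$rf, rank_len, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes <- utils::head(genes, n_targets)
  genes$rank <- seq_len(nrow(genes))
  rownames(genes) <- NULL
  genes
}

#' Read gene models from a GFF3 file
#'
#' @param path GFF3 path; `gene` features define spans, `exon` features
#'   are attached to their gene via the `Parent`/`ID` attributes (or
#'   containment within the span as a fallback).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `length` and an `exons` list-column of start/end matrices.
#' @export
read_gff_genes <- function(path) {
  g <- ape::read.gff(path)
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
  }
  genes <- g[g$type == "gene", ]
  ids <- attr_field(genes$attributes, "ID")
  ids[is.na(ids)] <- sprintf("gene%d", which(is.na(ids)))
  exons <- g[g$type == "exon", ]
  parent <- attr_field(exons$attributes, "Parent")
  out <- data.frame(gene_id = ids, chrom = as.character(genes$seqid),
                    start = genes$start, end = genes$end,
                    strand = as.character(genes$strand),
                    stringsAsFactors = FALSE)
  out$length <- out$end - out$start + 1L
  out$exons <- lapply(seq_len(nrow(out)), function(k) {
    mine <- if (all(is.na(parent))) {
      exons$seqid == out$chrom[k] & exons$start >= out$start[k] &
        exons$end <= out$end[k]
    } else {
      !is.na(parent) & parent == out$gene_id[k]
    }
    cbind(start = exons$start[mine], end = exons$end[mine])
  })
  out
}
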