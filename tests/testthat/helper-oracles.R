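# Shared fixtures and independent oracles used across the suite.

# small genotype matrix from a samples x loci code matrix
make_gm <- function(codes, chrom = "c1", pos = NULL, ref = "A", alt = "G",
                    qual = 100) {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes))) {
    rownames(codes) <- sprintf("s%d", seq_len(nrow(codes)))
  }
  n <- ncol(codes)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  genotype_matrix(codes, data.frame(
    chrom = rep_len(chrom, n), pos = pos,
    ref = rep_len(ref, n), alt = rep_len(alt, n), qual = rep_len(qual, n),
    stringsAsFactors = FALSE
  ))
}

write_toy_vcf <- function(path, body, samples = c("s1", "s2")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body
  ), path)
  path
}

# random unrooted tree over a fixed label set
random_tree <- function(labels) {
  tr <- ape::rtree(length(labels), rooted = FALSE)
  tr$tip.label <- sample(labels)
  tr
}

# RF oracle: splits found by deleting each internal edge of the tree
# graph and reading connected components (igraph mechanics, independent
# of the package's traversal)
oracle_splits <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  tips <- tree$tip.label
  n <- length(tips)
  anchor <- sort(tips)[1]
  out <- character(0)
  for (k in seq_len(nrow(tree$edge))) {
    g2 <- igraph::delete_edges(g, k)
    comp <- igraph::components(g2)$membership
    tip_ids <- as.character(seq_len(n)) # phylo tips are nodes 1..n
    side <- tips[comp[tip_ids] == comp[[as.character(1)]]]
    if (!anchor %in% side) side <- setdiff(tips, side)
    other <- setdiff(tips, side)
    if (length(other) >= 2 && length(other) <= n - 2) {
      out <- c(out, paste(sort(other), collapse = "|"))
    }
  }
  unique(out)
}

oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1)
  s2 <- oracle_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# exhaustive minimum-spanning-tree weight by leaf decomposition:
# every spanning tree of S has a leaf v whose removal leaves a spanning
# tree of S \ v, so W(S) = min over (v, u) of W(S \ v) + w(u, v)
oracle_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(0)
  W <- rep(Inf, 2^n)
  for (v in seq_len(n)) W[bitwShiftL(1L, v - 1L) + 1L] <- 0
  subsets <- order(vapply(0:(2^n - 1), function(s) sum(bitwAnd(s, 2^(0:(n - 1))) > 0), numeric(1)))
  for (s in subsets - 1L) {
    members <- which(bitwAnd(s, 2^(0:(n - 1))) > 0)
    if (length(members) < 2L) next
    best <- Inf
    for (v in members) {
      rest <- s - 2^(v - 1)
      wrest <- W[rest + 1L]
      if (!is.finite(wrest)) next
      for (u in setdiff(members, v)) {
        best <- min(best, wrest + d[u, v])
      }
    }
    W[s + 1L] <- best
  }
  W[2^n]
}

# plain combinatorial brute force over edge subsets (cross-check of the
# oracle itself, small n only)
bruteforce_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(0)
  pairs <- utils::combn(n, 2)
  best <- Inf
  picks <- utils::combn(ncol(pairs), n - 1)
  for (k in seq_len(ncol(picks))) {
    e <- pairs[, picks[, k], drop = FALSE]
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (j in seq_len(ncol(e))) {
      ra <- find(e[1, j]); rb <- find(e[2, j])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (ok) best <- min(best, sum(d[t(e)]))
  }
  best
}

# per-locus re-scan of strict-private specific loci, written as a plain
# double loop so it shares no code with the scanner
oracle_strict_private <- function(gm, pm) {
  pops <- sort(unique(pm))
  out <- list()
  for (j in seq_len(ncol(gm$geno))) {
    col <- gm$geno[, j]
    for (p in pops) {
      mine <- col[names(pm)[pm == p]]
      rest <- col[names(pm)[pm != p]]
      if (!anyNA(mine) && length(mine) > 0 && all(mine == 2L) &&
          all(rest[!is.na(rest)] == 0L)) {
        out[[length(out) + 1L]] <- data.frame(
          pos = gm$loci$pos[j], population = p, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(pos = integer(0), population = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$population, res$pos), ]
}

marker_key <- function(df) sort(paste(df$population, df$pos))
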