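#' Collapse an alignment into haplotypes
#'
#' Groups identical aligned sequences into haplotypes. With the default
#' `mask-columns` policy, every alignment column containing a gap (`-`)
#' or an ambiguous base (anything outside A/C/G/T) in any sequence is
#' excluded from all comparisons, so sequences differing only at masked
#' columns merge.
#'
#' @param alignment a named character vector of equal-length sequences, a
#'   `Biostrings::DNAStringSet`, or a path to an aligned FASTA file.
#' @param ambiguous_policy `"mask-columns"` (default) or `"strict"`
#'   (compare full sequences verbatim).
#' @return Object of class `haplotype_table`: list with `haplotypes`
#'   (named character vector of representative full-length sequences),
#'   `members` (haplotype -> sample ids), `frequency`, and `kept_columns`
#'   (indices of unmasked columns, used for distances).
#' @export
collapse_haplotypes <- function(alignment, ambiguous_policy = c("mask-columns", "strict")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  seqs <- as_seq_vector(alignment)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences differ in length: align them first")
  }
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  keep <- if (ambiguous_policy == "mask-columns") {
    apply(chars, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  } else {
    rep(TRUE, ncol(chars))
  }
  key <- apply(chars[, keep, drop = FALSE], 1L, paste, collapse = "")
  groups <- split(names(seqs), key)
  # stable naming: order of first appearance
  ord <- order(vapply(groups, function(g) match(g[1], names(seqs)), integer(1)))
  groups <- groups[ord]
  hap_ids <- sprintf("H%d", seq_along(groups))
  reps <- vapply(groups, function(g) seqs[[g[1]]], character(1))
  structure(
    list(
      haplotypes = stats::setNames(unname(reps), hap_ids),
      members = stats::setNames(unname(groups), hap_ids),
      frequency = stats::setNames(lengths(groups), hap_ids),
      kept_columns = which(keep)
    ),
    class = "haplotype_table"
  )
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d haplotypes over %d samples (%d/%d columns compared)\n",
              length(x$haplotypes), sum(x$frequency),
              length(x$kept_columns), nchar(x$haplotypes[1])))
  invisible(x)
}

#' Pairwise Hamming distances between haplotypes
#'
#' Substitution counts on the unmasked alignment columns.
#' @param ht a `haplotype_table`.
#' @return Symmetric integer matrix of substitution counts.
#' @export
haplotype_distances <- function(ht) {
  chars <- do.call(rbind, strsplit(ht$haplotypes, ""))
  chars <- chars[, ht$kept_columns, drop = FALSE]
  n <- nrow(chars)
  d <- matrix(0L, n, n, dimnames = list(names(ht$haplotypes), names(ht$haplotypes)))
  if (n > 1L) {
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        d[a, b] <- d[b, a] <- sum(chars[a, ] != chars[b, ])
      }
    }
  }
  d
}

#' Build a minimum-spanning haplotype network
#'
#' Kruskal's algorithm on pairwise substitution distances with
#' deterministic tie-breaking by (weight, lexicographic node pair). Edges
#' not in the spanning tree are retained as `alternative` edges when they
#' join, at their own weight level, two components that were still
#' separate when that weight level was reached — the usual
#' minimum-spanning-network extension of an MST.
#'
#' @param ht a `haplotype_table` from [collapse_haplotypes()].
#' @param method currently only `"mst"`.
#' @param populations optional named vector (sample -> population) used
#'   to annotate nodes with their population composition.
#' @return Object of class `haplotype_network`: list with `nodes`
#'   (data.frame: haplotype, frequency, composition) and `edges`
#'   (data.frame: from, to, weight, alternative).
#' @export
build_network <- function(ht, method = "mst", populations = NULL) {
  method <- match.arg(method, "mst")
  ids <- names(ht$haplotypes)
  comp <- rep(NA_character_, length(ids))
  if (!is.null(populations)) {
    comp <- vapply(ht$members, function(g) {
      tb <- table(populations[g])
      paste(sprintf("%s:%d", names(tb), tb), collapse = ",")
    }, character(1))
  }
  nodes <- data.frame(haplotype = ids, frequency = as.integer(ht$frequency),
                      composition = comp, stringsAsFactors = FALSE)
  n <- length(ids)
  if (n == 1L) {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = integer(0), alternative = logical(0))
    return(structure(list(nodes = nodes, edges = edges),
                     class = "haplotype_network"))
  }
  d <- haplotype_distances(ht)
  cand <- which(upper.tri(d), arr.ind = TRUE)
  ework <- data.frame(from = ids[cand[, 1]], to = ids[cand[, 2]],
                      weight = d[cand], stringsAsFactors = FALSE)
  swap <- ework$from > ework$to
  tmp <- ework$from[swap]; ework$from[swap] <- ework$to[swap]; ework$to[swap] <- tmp
  ework <- ework[order(ework$weight, ework$from, ework$to), ]
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  in_mst <- logical(nrow(ework))
  alt <- logical(nrow(ework))
  for (w in unique(ework$weight)) {
    grp <- which(ework$weight == w)
    # component membership at the start of this weight level
    comp_at <- vapply(ids, find, character(1))
    joins <- comp_at[ework$from[grp]] != comp_at[ework$to[grp]]
    for (k in grp) {
      ra <- find(ework$from[k])
      rb <- find(ework$to[k])
      if (ra != rb) {
        in_mst[k] <- TRUE
        parent[[ra]] <- rb
      }
    }
    alt[grp] <- joins & !in_mst[grp]
  }
  keep <- in_mst | alt
  edges <- ework[keep, , drop = FALSE]
  edges$alternative <- alt[keep]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d nodes, %d edges (%d alternative), MST weight %d\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$alternative),
              sum(x$edges$weight[!x$edges$alternative])))
  invisible(x)
}

#' Connected clusters after cutting long edges
#'
#' Removes all edges with weight greater than `cut` and returns the
#' connected components — the operation behind "does the network separate
#' population X into its own cluster".
#'
#' @param net a `haplotype_network`.
#' @param cut maximum edge weight to keep.
#' @return List of character vectors of haplotype ids, one per cluster.
#' @export
network_clusters <- function(net, cut) {
  ids <- net$nodes$haplotype
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  e <- net$edges[net$edges$weight <= cut, , drop = FALSE]
  for (k in seq_len(nrow(e))) {
    ra <- find(e$from[k]); rb <- find(e$to[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(ids, find, character(1))
  unname(split(ids, roots))
}

#' Write a haplotype network as TSV edge list and GraphML
#'
#' @param net a `haplotype_network`.
#' @param edges_path TSV edge-list path (`from`, `to`, `weight`,
#'   `alternative`).
#' @param graphml_path optional GraphML XML output path.
#' @param members_path optional haplotype-membership TSV (haplotype,
#'   sample); needs `ht`.
#' @param ht the `haplotype_table` (for membership export).
#' @return `edges_path`, invisibly.
#' @export
write_network <- function(net, edges_path, graphml_path = NULL,
                          members_path = NULL, ht = NULL) {
  utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="freq" for="node" attr.name="frequency" attr.type="int"/>',
      '  <key id="w" for="edge" attr.name="weight" attr.type="int"/>',
      '  <graph edgedefault="undirected">',
      sprintf('    <node id="%s"><data key="freq">%d</data></node>',
              net$nodes$haplotype, net$nodes$frequency),
      sprintf('    <edge source="%s" target="%s"><data key="w">%d</data></edge>',
              net$edges$from, net$edges$to, net$edges$weight),
      "  </graph>", "</graphml>"
    )
    writeLines(lines, graphml_path)
  }
  if (!is.null(members_path)) {
    if (is.null(ht)) stop("membership export needs the haplotype_table")
    mem <- data.frame(
      haplotype = rep(names(ht$members), lengths(ht$members)),
      sample = unlist(ht$members, use.names = FALSE)
    )
    utils::write.table(mem, members_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(edges_path)
}

# accept DNAStringSet, named character vector, or FASTA path
as_seq_vector <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    return(stats::setNames(as.character(x), names(x)))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    return(stats::setNames(as.character(ss), names(ss)))
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("seq%d", seq_along(x))
    return(x)
  }
  stop("cannot interpret sequences: pass a DNAStringSet, named vector, or FASTA path")
}
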