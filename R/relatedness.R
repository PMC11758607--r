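#' KING-robust kinship coefficient for one sample pair
#'
#' Allele-frequency-free estimator of pairwise kinship from biallelic
#' genotypes, computed over the sites called in both samples:
#' \deqn{\phi = \frac{N_{het,het} - 2\,N_{opp.hom}}{N_{het}(i) + N_{het}(j)}}
#' where \eqn{N_{het,het}} counts sites where both samples are
#' heterozygous, \eqn{N_{opp.hom}} counts opposite homozygotes, and
#' \eqn{N_{het}(\cdot)} are the per-sample heterozygote counts over the
#' shared sites. Duplicates/monozygotic twins give \eqn{\phi = 0.5}
#' exactly, first-degree relatives about 0.25, unrelated pairs about 0.
#'
#' @param gm a [genotype_matrix()].
#' @param i,j sample ids.
#' @return A one-row data.frame with `sample_i`, `sample_j`, `phi`,
#'   `n_het_het`, `n_opp_hom`, `n_het_i`, `n_het_j`, `n_shared`. `phi` is
#'   `NA` (with everything else reported) when neither sample has a
#'   heterozygous call over the shared sites.
#' @export
king_kinship <- function(gm, i, j) {
  gi <- gm$geno[i, ]
  gj <- gm$geno[j, ]
  ok <- !is.na(gi) & !is.na(gj)
  if (!any(ok)) stop("no sites called in both samples")
  gi <- gi[ok]
  gj <- gj[ok]
  n_hh <- sum(gi == 1L & gj == 1L)
  n_opp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  n_hi <- sum(gi == 1L)
  n_hj <- sum(gj == 1L)
  denom <- n_hi + n_hj
  phi <- if (denom > 0L) (n_hh - 2 * n_opp) / denom else NA_real_
  data.frame(sample_i = i, sample_j = j, phi = phi,
             n_het_het = n_hh, n_opp_hom = n_opp,
             n_het_i = n_hi, n_het_j = n_hj, n_shared = sum(ok),
             stringsAsFactors = FALSE)
}

#' KING-robust kinship for all sample pairs
#'
#' @param gm a [genotype_matrix()].
#' @param pm optional popmap; with `within_population_only = TRUE`, only
#'   pairs from the same population are computed.
#' @param within_population_only restrict to within-population pairs.
#' @return data.frame of per-pair kinship rows (see [king_kinship()]).
#' @export
king_pairs <- function(gm, pm = NULL, within_population_only = !is.null(pm)) {
  ids <- gm$samples
  if (length(ids) < 2L) {
    return(king_kinship(gm, ids[1], ids[1])[0, ])
  }
  if (!is.null(pm)) pm <- align_popmap(gm, pm)
  pairs <- utils::combn(ids, 2L)
  res <- vector("list", ncol(pairs))
  k <- 0L
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]
    b <- pairs[2, p]
    if (within_population_only && !is.null(pm) && pm[[a]] != pm[[b]]) next
    k <- k + 1L
    res[[k]] <- king_kinship(gm, a, b)
  }
  do.call(rbind, res[seq_len(k)])
}

#' Flag duplicate / first-degree pairs and propose exclusions
#'
#' Flags all pairs with kinship above `threshold` (default 0.354, the
#' duplicate/first-degree boundary \eqn{2^{-3/2}} rounded as commonly
#' printed) and proposes a minimal-effort exclusion set: within each
#' connected component of the flagged-pair graph, greedily remove the
#' individual with the most flagged partners (ties broken by lexicographic
#' sample id) until no flagged pair remains.
#'
#' @param gm a [genotype_matrix()].
#' @param pm optional popmap (sample -> population).
#' @param threshold kinship cutoff; pairs with `phi > threshold` are flagged.
#' @param within_population_only only test within-population pairs.
#' @return List with `pairs` (all computed pairs with a logical `flagged`
#'   column) and `exclude` (character vector of proposed removals).
#' @export
flag_relatives <- function(gm, pm = NULL, threshold = 0.354,
                           within_population_only = !is.null(pm)) {
  pairs <- king_pairs(gm, pm, within_population_only)
  pairs$flagged <- !is.na(pairs$phi) & pairs$phi > threshold
  edges <- pairs[pairs$flagged, c("sample_i", "sample_j")]
  exclude <- character(0)
  while (nrow(edges) > 0L) {
    deg <- sort(table(c(edges$sample_i, edges$sample_j)), decreasing = TRUE)
    top <- names(deg)[deg == max(deg)]
    victim <- sort(top)[1]
    exclude <- c(exclude, victim)
    edges <- edges[edges$sample_i != victim & edges$sample_j != victim, ]
  }
  list(pairs = pairs, exclude = exclude)
}
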