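#' Patterson's D (ABBA-BABA) with block-jackknife significance
#'
#' Frequency-weighted four-taxon test for gene flow. Sites are polarized
#' so that the outgroup major allele is ancestral; with \eqn{f_k} the
#' derived-allele frequency in group \eqn{k}, each site contributes
#' \deqn{ABBA \mathrel{+}= (1-f_1) f_2 f_3 (1-f_O), \quad
#'       BABA \mathrel{+}= f_1 (1-f_2) f_3 (1-f_O)}
#' and \eqn{D = (ABBA - BABA)/(ABBA + BABA)}. Under a strict bifurcating
#' history of ((P1,P2),P3) the two discordant patterns are equally
#' frequent and D is 0; introgression between P3 and P2 pushes D
#' positive. A standard error comes from a delete-one jackknife over
#' contiguous blocks of `block_size` loci, giving `z = d / se`.
#'
#' Sites where the outgroup is polymorphic at more than
#' `outgroup_poly_max` minor frequency, or where any group has no called
#' genotype, are skipped.
#'
#' @param gm a [genotype_matrix()].
#' @param pm popmap (sample -> population).
#' @param p1,p2,p3,outgroup population labels.
#' @param block_size loci per jackknife block.
#' @param outgroup_poly_max maximum tolerated outgroup minor-allele
#'   frequency.
#' @return List of class `dstat` with `populations`, `d`, `abba`, `baba`,
#'   `z`, `se`, `n_blocks`, `n_sites_used`. `d` and `z` are `NA`
#'   (flagged via `note`) when `abba + baba` is zero.
#' @export
patterson_d <- function(gm, pm, p1, p2, p3, outgroup, block_size = 1000,
                        outgroup_poly_max = 0.10) {
  pm <- align_popmap(gm, pm)
  labs <- c(p1, p2, p3, outgroup)
  absent <- setdiff(labs, unique(pm))
  if (length(absent)) stop("populations not in popmap: ", paste(absent, collapse = ", "))
  f <- vapply(labs, function(p) alt_freq(gm, names(pm)[pm == p]),
              numeric(n_loci(gm)))
  if (n_loci(gm) == 1L) f <- matrix(f, nrow = 1)
  fo_alt <- f[, 4]
  use <- rowSums(is.na(f)) == 0L & pmin(fo_alt, 1 - fo_alt) <= outgroup_poly_max
  # polarize: outgroup major allele is ancestral
  flip <- fo_alt > 0.5
  fd <- f
  fd[flip, ] <- 1 - f[flip, ]
  f1 <- fd[, 1]; f2 <- fd[, 2]; f3 <- fd[, 3]; fo <- fd[, 4]
  abba_s <- ifelse(use, (1 - f1) * f2 * f3 * (1 - fo), 0)
  baba_s <- ifelse(use, f1 * (1 - f2) * f3 * (1 - fo), 0)
  abba <- sum(abba_s)
  baba <- sum(baba_s)
  out <- list(populations = c(P1 = p1, P2 = p2, P3 = p3, Outgroup = outgroup),
              abba = abba, baba = baba, n_sites_used = sum(use))
  if (abba + baba == 0) {
    out$d <- NA_real_; out$z <- NA_real_; out$se <- NA_real_
    out$n_blocks <- 0L
    out$note <- "no informative sites: d undefined"
    class(out) <- "dstat"
    return(out)
  }
  out$d <- (abba - baba) / (abba + baba)
  blk <- ceiling(seq_len(n_loci(gm)) / block_size)
  ab_b <- tapply(abba_s, blk, sum)
  ba_b <- tapply(baba_s, blk, sum)
  informative <- (ab_b + ba_b) > 0
  B <- sum(informative)
  out$n_blocks <- B
  if (B >= 2L) {
    d_del <- (abba - ab_b[informative] - (baba - ba_b[informative])) /
      (abba - ab_b[informative] + (baba - ba_b[informative]))
    var_j <- (B - 1) / B * sum((d_del - mean(d_del))^2)
    out$se <- sqrt(var_j)
    out$z <- if (out$se > 0) out$d / out$se else NA_real_
  } else {
    out$se <- NA_real_
    out$z <- NA_real_
    out$note <- "fewer than 2 informative blocks: no jackknife z"
  }
  class(out) <- "dstat"
  out
}

#' @export
print.dstat <- function(x, ...) {
  cat(sprintf("Patterson's D: (((%s,%s),%s),%s)\n", x$populations[1],
              x$populations[2], x$populations[3], x$populations[4]))
  cat(sprintf("  D = %.4f  (ABBA %.1f, BABA %.1f, %d sites)\n",
              x$d, x$abba, x$baba, x$n_sites_used))
  cat(sprintf("  z = %.2f  (%d jackknife blocks)\n", x$z, x$n_blocks))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Run Patterson's D over a table of trios
#'
#' @param gm a [genotype_matrix()].
#' @param pm popmap.
#' @param trios data.frame with columns `p1`, `p2`, `p3`, `outgroup`.
#' @param ... passed to [patterson_d()].
#' @return data.frame with one row per trio: populations, D, Z, ABBA,
#'   BABA, sites used.
#' @export
dstat_table <- function(gm, pm, trios, ...) {
  rows <- lapply(seq_len(nrow(trios)), function(k) {
    r <- patterson_d(gm, pm, trios$p1[k], trios$p2[k], trios$p3[k],
                     trios$outgroup[k], ...)
    data.frame(P1 = trios$p1[k], P2 = trios$p2[k], P3 = trios$p3[k],
               Outgroup = trios$outgroup[k], D = r$d, Z = r$z,
               ABBA = r$abba, BABA = r$baba, n_sites = r$n_sites_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
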