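#' Primer design constraints
#'
#' Defaults are the Primer3 settings used throughout: primer size
#' 20/22/26 (min/opt/max), Tm 52/56/62 degC, GC 30/50/70 %, product size
#' 850-950 bp.
#'
#' @param size_min,size_opt,size_max primer length bounds (nt).
#' @param tm_min,tm_opt,tm_max melting temperature bounds (degC).
#' @param gc_min,gc_opt,gc_max GC content bounds (%).
#' @param product_min,product_max amplicon length bounds (bp).
#' @return List of class `primer_constraints`.
#' @export
primer_constraints <- function(size_min = 20, size_opt = 22, size_max = 26,
                               tm_min = 52, tm_opt = 56, tm_max = 62,
                               gc_min = 30, gc_opt = 50, gc_max = 70,
                               product_min = 850, product_max = 950) {
  pc <- list(size_min = size_min, size_opt = size_opt, size_max = size_max,
             tm_min = tm_min, tm_opt = tm_opt, tm_max = tm_max,
             gc_min = gc_min, gc_opt = gc_opt, gc_max = gc_max,
             product_min = product_min, product_max = product_max)
  for (base in c("size", "tm", "gc")) {
    v <- unlist(pc[paste0(base, c("_min", "_opt", "_max"))])
    if (is.unsorted(v)) stop(base, " bounds must satisfy min <= opt <= max")
  }
  if (product_min > product_max) stop("product bounds inverted")
  structure(pc, class = "primer_constraints")
}

#' Extract flanking sequence around a locus
#'
#' Returns the reference slice `[pos - flank, pos + flank]` (1-based
#' inclusive; 1801 bp for the default 900 bp flank at an interior locus),
#' clamped at contig ends with the locus offset updated accordingly.
#'
#' @param reference a `Biostrings::DNAStringSet`, named character vector
#'   of contigs, or FASTA path.
#' @param locus list or one-row data.frame with `chrom` and `pos`.
#' @param flank bases on each side of the locus.
#' @return List with `sequence`, `offset` (1-based position of the locus
#'   within the slice), `chrom`, `start`, `end`.
#' @export
extract_flank <- function(reference, locus, flank = 900) {
  ref <- as_seq_vector(reference)
  chrom <- as.character(locus$chrom)
  pos <- as.integer(locus$pos)
  flank <- as.integer(flank)
  if (!chrom %in% names(ref)) stop("contig not in reference: ", chrom)
  contig <- ref[[chrom]]
  if (pos < 1L || pos > nchar(contig)) {
    stop("locus position ", pos, " beyond contig ", chrom,
         " (length ", nchar(contig), ")")
  }
  start <- max(1L, pos - flank)
  end <- min(nchar(contig), pos + flank)
  list(sequence = substr(contig, start, end), offset = pos - start + 1L,
       chrom = chrom, start = start, end = end)
}

#' Oligo melting temperature
#'
#' `nn` (default): nearest-neighbor thermodynamics with the SantaLucia
#' 1998 unified parameter set, entropy salt correction
#' `0.368 * (N-1) * ln[Na+]` at 50 mM monovalent salt, and 250 nM of each
#' strand (two-state model, `C_T/4`). `wallace`: the rule of thumb
#' `2*(A+T) + 4*(G+C)`.
#'
#' @param oligo sequence over A/C/G/T, length >= 8.
#' @param method `"nn"` or `"wallace"`.
#' @param na_molar monovalent cation concentration (mol/L).
#' @param oligo_molar concentration of each strand (mol/L).
#' @return Melting temperature in degC.
#' @export
melting_temp <- function(oligo, method = c("nn", "wallace"),
                         na_molar = 0.05, oligo_molar = 250e-9) {
  method <- match.arg(method)
  oligo <- toupper(oligo)
  b <- strsplit(oligo, "")[[1]]
  if (length(b) < 8L) stop("oligo too short (need >= 8 nt)")
  if (any(!b %in% c("A", "C", "G", "T"))) {
    stop("ambiguous base in oligo: ", oligo)
  }
  if (method == "wallace") {
    return(2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C")))
  }
  nn <- paste0(b[-length(b)], b[-1])
  dH <- sum(.nn_dH[nn]) + .nn_init_dH[b[1]] + .nn_init_dH[b[length(b)]]
  dS <- sum(.nn_dS[nn]) + .nn_init_dS[b[1]] + .nn_init_dS[b[length(b)]]
  dS <- dS + 0.368 * (length(b) - 1) * log(na_molar)
  unname(dH * 1000 / (dS + 1.987 * log(oligo_molar / 2)) - 273.15)
}

# SantaLucia (1998) unified NN parameters, kcal/mol and cal/(mol K)
.nn_dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
.nn_init_dH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.nn_init_dS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Design primer pairs around a target locus
#'
#' Enumerates every (forward window, reverse window) pair on the template
#' that meets the size, Tm and GC bounds, whose product length falls in
#' the product range, and whose product contains the target position at
#' least `min_target_dist` bp away from each primer's 3' end (so a Sanger
#' read from either primer covers the diagnostic base cleanly). Pairs are
#' ranked by
#' `|Tm-opt|_fwd + |Tm-opt|_rev + 0.2*(|GC-opt|_fwd + |GC-opt|_rev) +
#'  0.1*|size-opt|_fwd + 0.1*|size-opt|_rev + |pair dTm|`,
#' a Tm-dominated penalty in the spirit of Primer3's defaults.
#'
#' @param template template sequence (e.g. from [extract_flank()]).
#' @param target_offset 1-based position of the diagnostic base within
#'   the template.
#' @param constraints a [primer_constraints()] object.
#' @param n_return maximum number of pairs to return.
#' @param tm_method passed to [melting_temp()] (the `nn` path is computed
#'   with the same thermodynamics, vectorized).
#' @param min_target_dist minimum distance (bp) between the target and
#'   each primer's 3' end.
#' @return data.frame of ranked pairs: `fwd`, `rev` (reverse primer given
#'   5'->3' on the minus strand), `fwd_start`, `fwd_tm`, `rev_tm`,
#'   `fwd_gc`, `rev_gc`, `product_start`, `product_end`, `product_len`,
#'   `penalty`. Empty (zero rows) with attribute `failure_tally` when no
#'   pair satisfies the constraints.
#' @export
design_primers <- function(template, target_offset, constraints = primer_constraints(),
                           n_return = 5, tm_method = "nn", min_target_dist = 30) {
  pc <- constraints
  L <- nchar(template)
  if (L < pc$product_min) stop("template shorter than the minimum product size")
  b <- strsplit(toupper(template), "")[[1]]
  if (any(!b %in% c("A", "C", "G", "T"))) {
    stop("template contains ambiguous bases")
  }
  win <- enumerate_windows(b, pc, tm_method)
  tally <- attr(win, "failure_tally")
  # forward windows must end >= min_target_dist before the target;
  # reverse windows must start >= min_target_dist after it
  fwd <- win[win$end <= target_offset - min_target_dist, , drop = FALSE]
  rev_ <- win[win$start >= target_offset + min_target_dist, , drop = FALSE]
  pairs <- NULL
  if (nrow(fwd) && nrow(rev_)) {
    # rank on numeric vectors over the full cross, materialize only the best
    fi <- rep(seq_len(nrow(fwd)), times = nrow(rev_))
    ri <- rep(seq_len(nrow(rev_)), each = nrow(fwd))
    plen <- rev_$end[ri] - fwd$start[fi] + 1L
    ok <- plen >= pc$product_min & plen <= pc$product_max
    tally["product_size"] <- tally["product_size"] + sum(!ok)
    fi <- fi[ok]; ri <- ri[ok]; plen <- plen[ok]
    if (length(fi)) {
      penalty <- abs(fwd$tm[fi] - pc$tm_opt) + abs(rev_$tm[ri] - pc$tm_opt) +
        0.2 * (abs(fwd$gc[fi] - pc$gc_opt) + abs(rev_$gc[ri] - pc$gc_opt)) +
        0.1 * abs(fwd$size[fi] - pc$size_opt) +
        0.1 * abs(rev_$size[ri] - pc$size_opt) +
        abs(fwd$tm[fi] - rev_$tm[ri])
      top <- utils::head(order(penalty, fwd$start[fi]), n_return)
      f <- fwd[fi[top], ]
      r <- rev_[ri[top], ]
      pairs <- data.frame(
        fwd = f$seq, rev = vapply(r$seq, revcomp, character(1)),
        fwd_start = f$start, fwd_len = f$size, rev_len = r$size,
        fwd_tm = f$tm, rev_tm = r$tm, fwd_gc = f$gc, rev_gc = r$gc,
        product_start = f$start, product_end = r$end,
        product_len = plen[top], penalty = penalty[top],
        stringsAsFactors = FALSE
      )
      rownames(pairs) <- NULL
    }
  }
  if (is.null(pairs)) {
    pairs <- data.frame(fwd = character(0), rev = character(0),
                        fwd_start = integer(0), fwd_len = integer(0),
                        rev_len = integer(0), fwd_tm = numeric(0),
                        rev_tm = numeric(0), fwd_gc = numeric(0),
                        rev_gc = numeric(0), product_start = integer(0),
                        product_end = integer(0), product_len = integer(0),
                        penalty = numeric(0))
  }
  attr(pairs, "failure_tally") <- tally
  pairs
}

# all windows of allowed sizes passing Tm and GC bounds; O(L) via
# cumulative sums of per-step NN enthalpy/entropy and GC counts
enumerate_windows <- function(b, pc, tm_method) {
  L <- length(b)
  gc_cum <- cumsum(b %in% c("G", "C"))
  nn <- paste0(b[-L], b[-1])
  dH_cum <- cumsum(c(0, .nn_dH[nn]))
  dS_cum <- cumsum(c(0, .nn_dS[nn]))
  out <- list()
  fail <- c(tm = 0L, gc = 0L, product_size = 0L)
  for (size in pc$size_min:pc$size_max) {
    starts <- seq_len(L - size + 1L)
    ends <- starts + size - 1L
    gc_n <- gc_cum[ends] - c(0, gc_cum)[starts]
    gc_pct <- 100 * gc_n / size
    if (tm_method == "nn") {
      dH <- dH_cum[ends] - dH_cum[starts] +
        .nn_init_dH[b[starts]] + .nn_init_dH[b[ends]]
      dS <- dS_cum[ends] - dS_cum[starts] +
        .nn_init_dS[b[starts]] + .nn_init_dS[b[ends]] +
        0.368 * (size - 1) * log(0.05)
      tm <- dH * 1000 / (dS + 1.987 * log(250e-9 / 2)) - 273.15
    } else {
      at_n <- size - gc_n
      tm <- 2 * at_n + 4 * gc_n
    }
    ok_tm <- tm >= pc$tm_min & tm <= pc$tm_max
    ok_gc <- gc_pct >= pc$gc_min & gc_pct <= pc$gc_max
    fail["tm"] <- fail["tm"] + sum(!ok_tm)
    fail["gc"] <- fail["gc"] + sum(ok_tm & !ok_gc)
    keep <- which(ok_tm & ok_gc)
    if (length(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        start = starts[keep], end = ends[keep], size = size,
        tm = tm[keep], gc = gc_pct[keep],
        seq = vapply(keep, function(k) {
          paste(b[starts[k]:ends[k]], collapse = "")
        }, character(1)),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(start = integer(0), end = integer(0), size = integer(0),
               tm = numeric(0), gc = numeric(0), seq = character(0))
  }
  attr(res, "failure_tally") <- fail
  res
}

#' In-silico PCR
#'
#' Finds occurrences of the forward primer on the plus strand and of the
#' reverse-complemented reverse primer downstream within `max_product`
#' bp, and reports the implied amplicons (first base of the forward site
#' through last base of the reverse site, primers included). With
#' `max_mismatch > 0`, mismatches are allowed anywhere except the 3
#' terminal 3'-end bases of either primer. Multi-mapping primer pairs
#' yield multiple amplicons (reported, not suppressed).
#'
#' @param template a `DNAStringSet`, named character vector, or FASTA path.
#' @param fwd,rev primer sequences (5'->3'; `rev` on the minus strand),
#'   >= 15 nt.
#' @param max_product maximum amplicon length (bp).
#' @param max_mismatch tolerated mismatches per primer site.
#' @return data.frame of amplicons: `template_id`, `start`, `end`
#'   (1-based inclusive), `length`, `sequence`. Zero rows when no site
#'   pairs up.
#' @export
insilico_pcr <- function(template, fwd, rev, max_product = 2000,
                         max_mismatch = 0) {
  seqs <- as_seq_vector(template)
  fwd <- toupper(fwd)
  rev <- toupper(rev)
  if (nchar(fwd) < 15L || nchar(rev) < 15L) stop("primers must be >= 15 nt")
  rev_site <- revcomp(rev)
  out <- list()
  for (id in names(seqs)) {
    subj <- Biostrings::DNAString(seqs[[id]])
    fhits <- primer_sites(subj, fwd, max_mismatch, three_prime = "right")
    rhits <- primer_sites(subj, rev_site, max_mismatch, three_prime = "left")
    for (fs in fhits) {
      for (rs in rhits) {
        rend <- rs + nchar(rev) - 1L
        plen <- rend - fs + 1L
        if (rs > fs && plen >= nchar(fwd) + nchar(rev) && plen <= max_product) {
          out[[length(out) + 1L]] <- data.frame(
            template_id = id, start = fs, end = rend, length = plen,
            sequence = substr(seqs[[id]], fs, rend),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      sequence = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# start positions of primer occurrences; 3'-terminal 3 bases must match
# exactly ("right" = 3' end at the right edge of the site)
primer_sites <- function(subject, pattern, max_mismatch, three_prime) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                   max.mismatch = max_mismatch)
  starts <- Biostrings::start(hits)
  if (max_mismatch > 0 && length(starts)) {
    n <- nchar(pattern)
    keep <- vapply(seq_along(starts), function(k) {
      site <- as.character(hits[[k]])
      idx <- if (three_prime == "right") (n - 2):n else 1:3
      substr(site, idx[1], idx[3]) == substr(pattern, idx[1], idx[3])
    }, logical(1))
    starts <- starts[keep]
  }
  starts
}

#' Design and validate primers for every marker of a panel
#'
#' Convenience wrapper: for each marker, extract the flank, design the
#' best primer pair, and validate it by in-silico PCR against the full
#' reference, recording the amplicon and whether the diagnostic base is
#' contained.
#'
#' @param panel a `diagnostic_panel`.
#' @param reference the reference sequences (DNAStringSet, named vector,
#'   or FASTA path).
#' @param flank flank size in bp.
#' @param constraints a [primer_constraints()] object.
#' @param ... passed to [design_primers()].
#' @return data.frame with one row per marker: marker coordinates,
#'   designed pair (or NAs), `n_amplicons`, `amplicon_len`,
#'   `contains_target`.
#' @export
design_panel_primers <- function(panel, reference, flank = 900,
                                 constraints = primer_constraints(), ...) {
  ref <- as_seq_vector(reference)
  rows <- lapply(seq_len(nrow(panel)), function(k) {
    locus <- panel[k, ]
    fl <- extract_flank(ref, locus, flank)
    pr <- design_primers(fl$sequence, fl$offset, constraints, n_return = 1, ...)
    base <- data.frame(chrom = locus$chrom, pos = locus$pos,
                       population = locus$population,
                       diagnostic_allele = locus$diagnostic_allele,
                       stringsAsFactors = FALSE)
    if (nrow(pr) == 0L) {
      return(cbind(base, data.frame(fwd = NA_character_, rev = NA_character_,
                                    product_len = NA_integer_,
                                    penalty = NA_real_,
                                    n_amplicons = 0L,
                                    amplicon_len = NA_integer_,
                                    contains_target = FALSE)))
    }
    amp <- insilico_pcr(ref, pr$fwd[1], pr$rev[1])
    hit <- amp[amp$template_id == locus$chrom &
                 amp$start <= locus$pos & amp$end >= locus$pos, , drop = FALSE]
    cbind(base, data.frame(fwd = pr$fwd[1], rev = pr$rev[1],
                           product_len = pr$product_len[1],
                           penalty = pr$penalty[1],
                           n_amplicons = nrow(amp),
                           amplicon_len = if (nrow(amp)) amp$length[1] else NA_integer_,
                           contains_target = nrow(hit) > 0L))
  })
  do.call(rbind, rows)
}
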