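#' Read the bases observed at panel loci for one query sample
#'
#' VCF mode (`query` is a [genotype_matrix()]): the genotype at each
#' panel locus is translated to observed bases (`"A"` for a homozygote,
#' `"A/G"` for a heterozygote); markers absent from the query are
#' missing. Amplicon mode (`query` is a set of sequences): each marker's
#' flank anchors the read — an exact seed match of the `seed` bases
#' immediately 5' and 3' of the locus locates the diagnostic base in the
#' amplicon (both orientations are tried); markers whose seeds do not
#' match are reported unreadable, not an error.
#'
#' @param query a `genotype_matrix` (VCF mode) or amplicon sequences
#'   (named character vector / `DNAStringSet` / FASTA path).
#' @param panel a `diagnostic_panel`.
#' @param sample sample id (VCF mode with a multi-sample matrix).
#' @param flanks named list of [extract_flank()] results keyed by
#'   `chrom:pos` (amplicon mode only).
#' @param seed seed length on each side of the locus (amplicon mode).
#' @return Named character vector, one element per panel marker
#'   (`chrom:pos` names): observed base(s), or `NA` if
#'   uncovered/unreadable.
#' @export
genotype_at_panel <- function(query, panel, sample = NULL, flanks = NULL,
                              seed = 20) {
  ids <- paste(panel$chrom, panel$pos, sep = ":")
  obs <- stats::setNames(rep(NA_character_, nrow(panel)), ids)
  if (inherits(query, "genotype_matrix")) {
    if (is.null(sample)) {
      if (n_samples(query) != 1L) stop("multi-sample query: give `sample`")
      sample <- query$samples[1]
    }
    qid <- locus_id(query$loci)
    for (k in seq_len(nrow(panel))) {
      j <- match(ids[k], qid)
      if (is.na(j)) next
      g <- query$geno[sample, j]
      if (is.na(g)) next
      obs[k] <- switch(as.character(g),
        "0" = query$loci$ref[j],
        "1" = paste(sort(c(query$loci$ref[j], query$loci$alt[j])), collapse = "/"),
        "2" = query$loci$alt[j]
      )
    }
    return(obs)
  }
  amps <- as_seq_vector(query)
  if (is.null(flanks)) stop("amplicon mode requires marker flanks for anchoring")
  for (k in seq_len(nrow(panel))) {
    fl <- flanks[[ids[k]]]
    if (is.null(fl)) next
    left <- substr(fl$sequence, fl$offset - seed, fl$offset - 1L)
    right <- substr(fl$sequence, fl$offset + 1L, fl$offset + seed)
    if (nchar(left) < seed || nchar(right) < seed) next
    for (a in amps) {
      for (s in c(a, revcomp(a))) {
        hit <- regexpr(left, s, fixed = TRUE)
        if (hit > 0L) {
          at <- hit + seed
          after <- substr(s, at + 1L, at + seed)
          if (after == right) {
            obs[k] <- substr(s, at, at)
            break
          }
        }
      }
      if (!is.na(obs[k])) break
    }
  }
  obs
}

#' Assign a sample to a population from its panel bases
#'
#' For each population, the match fraction is the number of readable
#' markers whose observed base(s) contain the diagnostic allele, divided
#' by the readable markers of that population. A sample is assigned to P
#' only under unanimity: P's fraction is 1.0 with at least `min_markers`
#' readable markers, and no other population also reaches 1.0. Two
#' populations at 1.0 give an ambiguous verdict; when the full diagnostic
#' sets of two populations are matched simultaneously (as in an F1
#' hybrid carrying both), a hybrid note is attached. Heterozygous
#' observations containing the diagnostic allele count as matches but
#' are flagged as possible hybridity.
#'
#' @param obs observed bases from [genotype_at_panel()].
#' @param panel a `diagnostic_panel`.
#' @param min_markers minimum readable markers required to assign.
#' @return Object of class `assignment_report`: list with `markers`
#'   (per-marker table), `populations` (per-population readable/matched/
#'   fraction), `verdict` (`"assigned"`, `"ambiguous"` or
#'   `"unassigned"`), `population` (when assigned), `notes`.
#' @export
assign_sample <- function(obs, panel, min_markers = 2) {
  if (nrow(panel) == 0L) stop("empty panel")
  ids <- paste(panel$chrom, panel$pos, sep = ":")
  observed <- unname(obs[ids])
  matched <- mapply(function(o, a) {
    if (is.na(o)) NA else a %in% strsplit(o, "/", fixed = TRUE)[[1]]
  }, observed, panel$diagnostic_allele)
  het <- !is.na(observed) & grepl("/", observed, fixed = TRUE)
  markers <- data.frame(
    chrom = panel$chrom, pos = panel$pos, population = panel$population,
    diagnostic_allele = panel$diagnostic_allele, observed = observed,
    readable = !is.na(observed), matched = matched, het = het,
    stringsAsFactors = FALSE
  )
  pops <- sort(unique(panel$population))
  readable <- vapply(pops, function(p) sum(markers$readable[markers$population == p]), integer(1))
  nmatch <- vapply(pops, function(p) {
    sum(markers$matched[markers$population == p], na.rm = TRUE)
  }, integer(1))
  frac <- ifelse(readable > 0L, nmatch / readable, NA_real_)
  poptab <- data.frame(population = pops, readable = readable,
                       matched = nmatch, fraction = frac,
                       stringsAsFactors = FALSE)
  full <- !is.na(frac) & frac == 1
  eligible <- full & readable >= min_markers
  notes <- character(0)
  pops_with_match <- pops[nmatch > 0L]
  if (length(pops_with_match) >= 2L) {
    notes <- c(notes, paste0(
      "diagnostic alleles of multiple populations observed (",
      paste(pops_with_match, collapse = ", "), "): possible hybrid"
    ))
  }
  if (any(markers$het & !is.na(markers$matched) & markers$matched)) {
    notes <- c(notes, "diagnostic allele observed in heterozygous state: possible hybrid")
  }
  if (sum(full) >= 2L) {
    verdict <- "ambiguous"
    population <- NA_character_
  } else if (sum(eligible) == 1L && sum(full) == 1L) {
    verdict <- "assigned"
    population <- pops[eligible]
  } else {
    verdict <- "unassigned"
    population <- NA_character_
    if (all(nmatch == 0L)) notes <- c(notes, "no diagnostic allele matched")
    else notes <- c(notes, "decision rule not satisfied (partial panel or conflict)")
  }
  structure(list(markers = markers, populations = poptab, verdict = verdict,
                 population = population, notes = notes,
                 min_markers = min_markers),
            class = "assignment_report")
}

#' @export
print.assignment_report <- function(x, ...) {
  cat("assignment_report:", x$verdict,
      if (!is.na(x$population)) paste0("-> ", x$population) else "", "\n")
  print(x$populations, row.names = FALSE)
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Trace every sample of a query matrix against a panel
#'
#' @param query a `genotype_matrix` of query samples.
#' @param panel a `diagnostic_panel`.
#' @param min_markers passed to [assign_sample()].
#' @return data.frame with one row per query sample: `sample`, `verdict`,
#'   `population`, `notes`.
#' @export
trace_samples <- function(query, panel, min_markers = 2) {
  rows <- lapply(query$samples, function(s) {
    rep_ <- assign_sample(genotype_at_panel(query, panel, sample = s),
                          panel, min_markers)
    data.frame(sample = s, verdict = rep_$verdict,
               population = rep_$population,
               notes = paste(rep_$notes, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
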