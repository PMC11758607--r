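#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a desk-scale study emulating the structure the
#' scanner assumes: 3 populations of 8 diploid samples, 20,000 biallelic
#' SNPs on a 2 Mb contig with Balding-Nichols drift (F = 0.1), 10
#' planted private-fixed loci per population (half inside gene spans),
#' 40 gene models of 2-6 kb, and no missing data.
#'
#' @param n_populations number of populations.
#' @param n_per_pop samples per population.
#' @param n_loci background + planted loci in total.
#' @param fst Balding-Nichols drift parameter F, recycled per population
#'   (`F in [0, 1)`; 0 = no drift).
#' @param clades optional list of integer vectors partitioning the
#'   populations into clades; clade allele frequencies are drawn from
#'   the ancestral frequency with drift `fst_clade`, and population
#'   frequencies from their clade's frequency, giving the cohort a true
#'   hierarchical topology (used to test gene-tree/species-tree
#'   concordance).
#' @param fst_clade drift of the clade frequencies around the ancestral
#'   frequency (only with `clades`).
#' @param planted_per_pop private-fixed diagnostic loci planted per
#'   population.
#' @param planted_in_gene_frac fraction of planted loci placed inside
#'   gene spans.
#' @param admixed data.frame (`source`, `target`, `alpha`, `n`) of
#'   admixed individuals to append to `target`: each allele copies the
#'   `source` population with probability `alpha`, `alpha in (0, 1)`.
#' @param relatives data.frame (`pop`, `relationship`, `n`) of related
#'   pairs to append; relationship `"duplicate"` or `"parent-offspring"`.
#' @param missing_rate per-genotype missingness probability.
#' @param contig_length reference contig length (bp).
#' @param contig_name reference contig name.
#' @param n_genes,gene_len_range gene models placed on the contig.
#' @param seed RNG seed (keep below 2^31).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_populations = 3, n_per_pop = 8, n_loci = 20000,
                       fst = 0.1, clades = NULL, fst_clade = 0.15,
                       planted_per_pop = 10,
                       planted_in_gene_frac = 0.5,
                       admixed = NULL, relatives = NULL, missing_rate = 0,
                       contig_length = 2e6, contig_name = "ctg1",
                       n_genes = 40, gene_len_range = c(2001, 6000),
                       seed = 1) {
  if (n_populations * planted_per_pop >= n_loci) {
    stop("planted loci exceed n_loci")
  }
  fst <- rep_len(fst, n_populations)
  if (any(fst < 0 | fst >= 1)) stop("F must be in [0, 1)")
  if (!is.null(clades) &&
      !setequal(unlist(clades), seq_len(n_populations))) {
    stop("clades must partition the populations")
  }
  if (!is.null(admixed) && any(admixed$alpha <= 0 | admixed$alpha >= 1)) {
    stop("alpha must be in (0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a multi-population cohort with planted diagnostic loci
#'
#' Background loci follow the Balding-Nichols model: ancestral frequency
#' `p ~ Uniform(0.05, 0.95)`, per-population frequency
#' `Beta(p (1-F)/F, (1-p)(1-F)/F)` (frequency = `p` when `F = 0`), and
#' diploid genotypes `Binomial(2, freq)`. Planted loci are fixed for the
#' alternate allele in their focal population (frequency 1) and absent
#' elsewhere (frequency 0), positioned inside or outside gene spans as
#' configured. Admixed individuals draw each allele from the source
#' population with probability `alpha`, else from the target. Relatives
#' are built by Mendelian transmission from simulated parents. The
#' reference carries the ref allele at every locus. Deterministic under a
#' fixed seed.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory; when given, writes
#'   `cohort.vcf`, `popmap.tsv`, `reference.fa`, `genes.gff3` and
#'   `truth.json`.
#' @return List with `gm` ([genotype_matrix()]), `popmap` (named
#'   vector), `reference` (named character vector), `genes` (gene table
#'   with `exons` list-column), and `truth` (list: `planted`,
#'   `relatives`, `admixed`).
#' @export
simulate_cohort <- function(cfg = sim_config(), dir = NULL) {
  set.seed(cfg$seed)
  pops <- sprintf("pop%s", LETTERS[seq_len(cfg$n_populations)])
  # gene models first, so planted loci can be placed relative to them
  genes <- place_genes(cfg)
  in_gene <- rep(FALSE, cfg$contig_length)
  for (k in seq_len(nrow(genes))) in_gene[genes$start[k]:genes$end[k]] <- TRUE
  # flank-safe interior region so every planted locus supports 900 bp flanks
  interior <- c(rep(FALSE, 1000), rep(TRUE, cfg$contig_length - 2000),
                rep(FALSE, 1000))
  n_planted <- cfg$n_populations * cfg$planted_per_pop
  n_in <- round(cfg$planted_per_pop * cfg$planted_in_gene_frac)
  pos_pool_in <- which(in_gene & interior)
  pos_pool_out <- which(!in_gene & interior)
  planted_pos <- integer(0)
  planted_pop <- character(0)
  planted_ingene <- logical(0)
  for (p in pops) {
    pin <- sample(pos_pool_in, n_in)
    pout <- sample(pos_pool_out, cfg$planted_per_pop - n_in)
    pos_pool_in <- setdiff(pos_pool_in, pin)
    pos_pool_out <- setdiff(pos_pool_out, pout)
    planted_pos <- c(planted_pos, pin, pout)
    planted_pop <- c(planted_pop, rep(p, cfg$planted_per_pop))
    planted_ingene <- c(planted_ingene, rep(c(TRUE, FALSE), c(length(pin), length(pout))))
  }
  bg_pos <- sample(setdiff(seq_len(cfg$contig_length), planted_pos),
                   cfg$n_loci - n_planted)
  pos <- c(planted_pos, bg_pos)
  ord <- order(pos)
  pos <- pos[ord]
  is_planted <- c(rep(TRUE, n_planted), rep(FALSE, length(bg_pos)))[ord]
  planted_of <- c(planted_pop, rep(NA_character_, length(bg_pos)))[ord]
  ingene_of <- c(planted_ingene, rep(NA, length(bg_pos)))[ord]

  # per-population allele frequencies
  n_loci <- cfg$n_loci
  p_anc <- stats::runif(n_loci, 0.05, 0.95)
  bn_draw <- function(p, F) {
    if (F == 0) p else {
      stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
    }
  }
  p_base <- matrix(rep(p_anc, cfg$n_populations), n_loci)
  if (!is.null(cfg$clades)) {
    for (cl in cfg$clades) {
      p_cl <- bn_draw(p_anc, cfg$fst_clade)
      p_base[, cl] <- p_cl
    }
  }
  freq <- matrix(0, n_loci, cfg$n_populations, dimnames = list(NULL, pops))
  for (k in seq_len(cfg$n_populations)) {
    freq[, k] <- bn_draw(p_base[, k], cfg$fst[k])
    freq[is_planted, k] <- ifelse(planted_of[is_planted] == pops[k], 1, 0)
  }

  # genotypes: base cohort
  samples <- unlist(lapply(pops, function(p) sprintf("%s_s%d", p, seq_len(cfg$n_per_pop))))
  popmap <- stats::setNames(rep(pops, each = cfg$n_per_pop), samples)
  geno <- matrix(NA_integer_, length(samples), n_loci,
                 dimnames = list(samples, NULL))
  for (k in seq_len(cfg$n_populations)) {
    members <- names(popmap)[popmap == pops[k]]
    geno[members, ] <- matrix(
      stats::rbinom(length(members) * n_loci, 2, rep(freq[, k], each = length(members))),
      length(members), n_loci
    )
  }

  truth_adm <- data.frame(sample = character(0), source = character(0),
                          target = character(0), alpha = numeric(0))
  if (!is.null(cfg$admixed)) {
    for (r in seq_len(nrow(cfg$admixed))) {
      src <- cfg$admixed$source[r]
      tgt <- cfg$admixed$target[r]
      alpha <- cfg$admixed$alpha[r]
      for (m in seq_len(cfg$admixed$n[r])) {
        id <- sprintf("%s_adm%d_%d", tgt, r, m)
        take_src <- matrix(stats::runif(2 * n_loci) < alpha, 2, n_loci)
        al <- vapply(1:2, function(h) {
          ifelse(take_src[h, ],
                 stats::rbinom(n_loci, 1, freq[, src]),
                 stats::rbinom(n_loci, 1, freq[, tgt]))
        }, integer(n_loci))
        geno <- rbind(geno, matrix(as.integer(rowSums(al)), 1, n_loci,
                                   dimnames = list(id, NULL)))
        popmap[id] <- tgt
        truth_adm <- rbind(truth_adm, data.frame(sample = id, source = src,
                                                 target = tgt, alpha = alpha))
      }
    }
  }

  truth_rel <- data.frame(sample_i = character(0), sample_j = character(0),
                          relationship = character(0))
  if (!is.null(cfg$relatives)) {
    for (r in seq_len(nrow(cfg$relatives))) {
      p <- cfg$relatives$pop[r]
      rel <- cfg$relatives$relationship[r]
      for (m in seq_len(cfg$relatives$n[r])) {
        anchor <- names(popmap)[popmap == p][m]
        id <- sprintf("%s_%s%d", anchor, substr(rel, 1, 3), m)
        g_new <- if (rel == "duplicate") {
          geno[anchor, ]
        } else { # parent-offspring: one allele transmitted, one from the pool
          transmitted <- ifelse(geno[anchor, ] == 1L,
                                stats::rbinom(n_loci, 1, 0.5),
                                geno[anchor, ] / 2L)
          as.integer(transmitted + stats::rbinom(n_loci, 1, freq[, p]))
        }
        geno <- rbind(geno, matrix(as.integer(g_new), 1, n_loci,
                                   dimnames = list(id, NULL)))
        popmap[id] <- p
        truth_rel <- rbind(truth_rel, data.frame(sample_i = anchor,
                                                 sample_j = id,
                                                 relationship = rel))
      }
    }
  }

  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(length(geno)) < cfg$missing_rate,
                   nrow(geno), ncol(geno))
    geno[drop] <- NA_integer_
  }

  # reference sequence and alleles
  bases <- c("A", "C", "G", "T")
  ref_seq <- sample(bases, cfg$contig_length, replace = TRUE)
  ref_al <- ref_seq[pos]
  alt_al <- vapply(ref_al, function(r) sample(setdiff(bases, r), 1), character(1))
  loci <- data.frame(chrom = cfg$contig_name, pos = pos, ref = ref_al,
                     alt = alt_al, qual = 100, filter = "PASS",
                     stringsAsFactors = FALSE)
  gm <- genotype_matrix(geno, loci)

  truth_planted <- data.frame(
    chrom = rep(cfg$contig_name, sum(is_planted)), pos = pos[is_planted],
    ref = ref_al[is_planted], alt = alt_al[is_planted],
    population = planted_of[is_planted], in_gene = ingene_of[is_planted],
    stringsAsFactors = FALSE
  )
  truth_planted <- truth_planted[order(truth_planted$population, truth_planted$pos), ]
  rownames(truth_planted) <- NULL
  reference <- stats::setNames(paste(ref_seq, collapse = ""), cfg$contig_name)
  out <- list(gm = gm, popmap = popmap, reference = reference, genes = genes,
              truth = list(planted = truth_planted, relatives = truth_rel,
                           admixed = truth_adm))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(gm, file.path(dir, "cohort.vcf"))
    write_popmap(popmap, file.path(dir, "popmap.tsv"))
    writeLines(c(paste0(">", cfg$contig_name), chunk_seq(reference[[1]])),
               file.path(dir, "reference.fa"))
    write_gff3(genes, file.path(dir, "genes.gff3"))
    jsonlite::write_json(out$truth, file.path(dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  out
}

# nonoverlapping gene spans with 2-4 exons of >= 20 bp each
place_genes <- function(cfg) {
  lens <- sample(cfg$gene_len_range[1]:cfg$gene_len_range[2], cfg$n_genes,
                 replace = TRUE)
  slot <- floor((cfg$contig_length - 4000) / cfg$n_genes)
  if (max(lens) + 200 > slot) stop("contig too short for the gene models")
  starts <- 2000 + (seq_len(cfg$n_genes) - 1) * slot +
    sample(100, cfg$n_genes, replace = TRUE)
  ends <- starts + lens - 1
  exons <- lapply(seq_len(cfg$n_genes), function(k) {
    nex <- sample(2:4, 1)
    cuts <- sort(sample(seq(starts[k] + 50, ends[k] - 50, by = 25), 2 * nex))
    cbind(start = cuts[seq(1, 2 * nex, 2)], end = cuts[seq(2, 2 * nex, 2)])
  })
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(cfg$n_genes)),
                      chrom = cfg$contig_name, start = starts, end = ends,
                      strand = "+", length = lens, stringsAsFactors = FALSE)
  genes$exons <- exons
  genes
}

write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (k in seq_len(nrow(genes))) {
    lines <- c(lines, sprintf("%s\tpoptrace\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              genes$chrom[k], genes$start[k], genes$end[k],
                              genes$strand[k], genes$gene_id[k]))
    ex <- genes$exons[[k]]
    for (e in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf("%s\tpoptrace\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                                genes$chrom[k], ex[e, 1], ex[e, 2],
                                genes$strand[k], genes$gene_id[k], e,
                                genes$gene_id[k]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

chunk_seq <- function(s, width = 70) {
  starts <- seq(1, nchar(s), by = width)
  substring(s, starts, pmin(starts + width - 1, nchar(s)))
}

#' Simulate aligned mitochondrial haplotypes
#'
#' Emulates the maternal structure where one population is reciprocally
#' distinct while the others share haplotypes: a random root sequence;
#' the designated population's haplotypes carry at least `k` private
#' substitutions from the root; the remaining populations draw from a
#' shared pool of near-root haplotypes (each 1-3 substitutions from the
#' root, at sites disjoint from the private set). The alignment is
#' gap-free and equal-length.
#'
#' @param n_pops number of populations (>= 2).
#' @param n_per_pop samples per population.
#' @param seq_length alignment length (bp).
#' @param designated index of the population to make distinct.
#' @param k private substitutions separating the designated population.
#' @param pool_size shared haplotype pool size for the other populations.
#' @param seed RNG seed.
#' @return List with `alignment` (named character vector) and
#'   `populations` (named vector sample -> population).
#' @export
simulate_mito <- function(n_pops = 3, n_per_pop = 8, seq_length = 1000,
                          designated = 1, k = 10, pool_size = 5, seed = 1) {
  if (n_pops < 2L) stop("need at least 2 populations")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, seq_length, replace = TRUE)
  mutate <- function(seq, sites) {
    seq[sites] <- vapply(seq[sites], function(x) sample(setdiff(bases, x), 1),
                         character(1))
    seq
  }
  private_sites <- sample(seq_length, k)
  shared_sites <- setdiff(seq_len(seq_length), private_sites)
  designated_base <- mutate(root, private_sites)
  pool <- lapply(seq_len(pool_size), function(i) {
    mutate(root, sample(shared_sites, sample(1:3, 1)))
  })
  pops <- sprintf("pop%s", LETTERS[seq_len(n_pops)])
  aln <- character(0)
  labels <- character(0)
  for (pi in seq_len(n_pops)) {
    for (s in seq_len(n_per_pop)) {
      id <- sprintf("%s_m%d", pops[pi], s)
      seq <- if (pi == designated) {
        # small within-population variation on top of the private backbone
        if (stats::runif(1) < 0.5) designated_base else {
          mutate(designated_base, sample(shared_sites, 1))
        }
      } else {
        pool[[sample(pool_size, 1)]]
      }
      aln[id] <- paste(seq, collapse = "")
      labels[id] <- pops[pi]
    }
  }
  list(alignment = aln, populations = labels)
}
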