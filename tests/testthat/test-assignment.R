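# panel of 2 markers per population over 2 populations
toy_panel <- function() {
  restrict_to_genes(
    data.frame(chrom = "c1", pos = c(150L, 160L, 170L, 180L),
               ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"),
               population = rep(c("P", "Q"), each = 2),
               diagnostic_allele = c("G", "T", "A", "C"),
               stringsAsFactors = FALSE),
    data.frame(gene_id = "g1", chrom = "c1", start = 100L, end = 200L)
  )
}

# query matrix at the panel loci: codes per sample
query_gm <- function(codes_by_sample) {
  codes <- do.call(rbind, codes_by_sample)
  make_gm(codes, pos = c(150L, 160L, 170L, 180L),
          ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"))
}

test_that("VCF-mode readout reports diagnostic and heterozygous bases", {
  panel <- toy_panel()
  gm <- query_gm(list(pp = c(2L, 2L, 0L, 0L), ht = c(1L, 0L, NA, 0L)))
  obs <- genotype_at_panel(gm, panel, sample = "pp")
  expect_equal(unname(obs), c("G", "T", "G", "T"))
  obs2 <- genotype_at_panel(gm, panel, sample = "ht")
  expect_equal(unname(obs2[1]), "A/G")
  expect_true(is.na(obs2[3]))
})

test_that("amplicon-mode readout anchors on the flank and reports unreadable loci", {
  set.seed(83)
  ref <- c(c1 = paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = ""))
  panel <- toy_panel()[1, , drop = FALSE]
  class(panel) <- c("diagnostic_panel", "data.frame")
  fl <- extract_flank(ref, panel, flank = 100)
  flanks <- setNames(list(fl), paste(panel$chrom, panel$pos, sep = ":"))
  # amplicon = the flank with the diagnostic base substituted at the locus
  amp <- fl$sequence
  substr(amp, fl$offset, fl$offset) <- "G"
  obs <- genotype_at_panel(c(q = amp), panel, flanks = flanks)
  expect_equal(unname(obs), "G")
  # reverse-complemented amplicon still reads out
  obs_rc <- genotype_at_panel(c(q = poptrace:::revcomp(amp)), panel, flanks = flanks)
  expect_equal(unname(obs_rc), "G")
  # locus deleted -> unreadable, not an error
  broken <- paste0(substr(amp, 1, fl$offset - 1), substr(amp, fl$offset + 1, nchar(amp)))
  expect_true(is.na(genotype_at_panel(c(q = broken), panel, flanks = flanks)))
})

test_that("unanimity rule assigns pure samples and never assigns F1 hybrids", {
  panel <- toy_panel()
  gm <- query_gm(list(
    pureP = c(2L, 2L, 0L, 0L),
    pureQ = c(0L, 0L, 2L, 2L),
    f1 = c(1L, 1L, 1L, 1L),          # carries both diagnostic sets, het
    blank = c(NA, NA, NA, NA),
    partial = c(2L, NA, 0L, 0L)       # only 1 readable P marker
  ))
  reports <- lapply(gm$samples, function(s) {
    assign_sample(genotype_at_panel(gm, panel, sample = s), panel)
  })
  names(reports) <- gm$samples
  expect_equal(reports$pureP$verdict, "assigned")
  expect_equal(reports$pureP$population, "P")
  expect_equal(reports$pureQ$population, "Q")
  expect_equal(reports$f1$verdict, "ambiguous")
  expect_true(any(grepl("hybrid", reports$f1$notes)))
  expect_equal(reports$blank$verdict, "unassigned")
  expect_equal(reports$partial$verdict, "unassigned")  # below min_markers
  expect_equal(assign_sample(genotype_at_panel(gm, panel, sample = "partial"),
                             panel, min_markers = 1)$population, "P")
})

test_that("the verdict is invariant to marker order", {
  panel <- toy_panel()
  gm <- query_gm(list(pureP = c(2L, 2L, 0L, 0L)))
  obs <- genotype_at_panel(gm, panel, sample = "pureP")
  perm <- sample(nrow(panel))
  panel_shuffled <- panel[perm, ]
  class(panel_shuffled) <- c("diagnostic_panel", "data.frame")
  a <- assign_sample(obs, panel)
  b <- assign_sample(obs[perm], panel_shuffled)
  expect_equal(a$verdict, b$verdict)
  expect_equal(a$population, b$population)
})

test_that("trace_samples summarises a query matrix against a panel", {
  panel <- toy_panel()
  gm <- query_gm(list(pureP = c(2L, 2L, 0L, 0L), f1 = c(1L, 1L, 1L, 1L)))
  tab <- trace_samples(gm, panel)
  expect_equal(tab$verdict, c("assigned", "ambiguous"))
  expect_equal(tab$population[1], "P")
})

test_that("panel TSV round-trip preserves markers", {
  panel <- toy_panel()
  path <- tempfile(fileext = ".tsv")
  bed <- tempfile(fileext = ".bed")
  write_panel(panel, path, bed)
  back <- read_panel(path)
  expect_equal(as.data.frame(back), as.data.frame(panel), ignore_attr = TRUE)
  bedtab <- read.delim(bed, header = FALSE)
  expect_equal(bedtab$V2, panel$pos - 1L)   # 0-based half-open at the boundary
  expect_equal(bedtab$V3, panel$pos)
})
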