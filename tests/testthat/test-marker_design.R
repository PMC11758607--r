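# build a template with engineered primer sites of moderate GC around a target
engineered_template <- function(seed = 71) {
  set.seed(seed)
  fwd <- "GACTGCATTACGGATCAACGTT"    # 22-mer, 45% GC
  rev_site <- "CCATGTTAGCAACGGTATCAGT" # appears on the plus strand
  filler <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  # fwd at 301..322, rev site ends at 301 + 900 - 1 = 1200 -> 900 bp product
  template <- paste0(filler(300), fwd, filler(900 - 44), rev_site, filler(601))
  list(template = template, fwd = fwd, rev = poptrace:::revcomp(rev_site),
       target = 301 + 450)
}

test_that("primer constraint triples are validated", {
  pc <- primer_constraints()
  expect_equal(c(pc$size_min, pc$size_opt, pc$size_max), c(20, 22, 26))
  expect_equal(c(pc$tm_min, pc$tm_opt, pc$tm_max), c(52, 56, 62))
  expect_equal(c(pc$gc_min, pc$gc_opt, pc$gc_max), c(30, 50, 70))
  expect_equal(c(pc$product_min, pc$product_max), c(850, 950))
  expect_error(primer_constraints(tm_opt = 80), "min <= opt <= max")
})

test_that("flank extraction returns 1801 bp interior slices and clamps at contig ends", {
  set.seed(73)
  ref <- c(ctg = paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = ""))
  fl <- extract_flank(ref, list(chrom = "ctg", pos = 2500L), flank = 900)
  expect_equal(nchar(fl$sequence), 1801L)
  expect_equal(fl$offset, 901L)
  expect_equal(substr(fl$sequence, 901, 901), substr(ref[[1]], 2500, 2500))
  # re-slicing the reference at the reported interval reproduces the sequence
  expect_identical(substr(ref[[1]], fl$start, fl$end), fl$sequence)
  edge <- extract_flank(ref, list(chrom = "ctg", pos = 10L), flank = 900)
  expect_equal(edge$start, 1L)
  expect_equal(nchar(edge$sequence), 910L)
  expect_equal(edge$offset, 10L)
  zero <- extract_flank(ref, list(chrom = "ctg", pos = 42L), flank = 0)
  expect_equal(zero$sequence, substr(ref[[1]], 42, 42))
  expect_error(extract_flank(ref, list(chrom = "ctg", pos = 9999L)), "beyond contig")
  expect_error(extract_flank(ref, list(chrom = "nope", pos = 1L)), "not in reference")
})

test_that("Wallace melting temperatures follow 2AT + 4GC", {
  expect_equal(melting_temp("GCGCGCGCGCATATATATAT", method = "wallace"), 60)
  expect_equal(melting_temp(strrep("A", 20), method = "wallace"), 40)
  expect_error(melting_temp("ACGTNACGTACGT"), "ambiguous")
  expect_error(melting_temp("ACGT"), "too short")
})

test_that("nearest-neighbor Tm reproduces the frozen SantaLucia-1998 fixture", {
  # independently computed once from the published unified NN tables at
  # 50 mM Na+, 250 nM per strand, and frozen
  expect_equal(melting_temp("ACGTTGCAATGCCGTAAGGCTT", method = "nn"),
               60.928, tolerance = 1e-3)
  # published primer pairs land near their low-50s annealing design
  tab <- read.delim(system.file("extdata", "table1_primers.tsv",
                                package = "poptrace"))
  tms <- c(vapply(tab$forward, melting_temp, numeric(1)),
           vapply(tab$reverse, melting_temp, numeric(1)))
  expect_true(all(tms > 45 & tms < 65))
})

test_that("design_primers returns in-bound pairs on an engineered template", {
  fix <- engineered_template()
  pr <- design_primers(fix$template, fix$target, n_return = 20)
  expect_gt(nrow(pr), 0)
  expect_true(all(pr$product_len >= 850 & pr$product_len <= 950))
  expect_true(all(pr$fwd_gc >= 30 & pr$fwd_gc <= 70))
  expect_true(all(pr$fwd_tm >= 52 & pr$fwd_tm <= 62))
  expect_true(all(nchar(pr$fwd) >= 20 & nchar(pr$fwd) <= 26))
  # target sits >= 30 bp inside the product from both 3' ends
  expect_true(all(pr$fwd_start + nchar(pr$fwd) - 1 <= fix$target - 30))
  expect_true(all(pr$product_end - nchar(pr$rev) + 1 >= fix$target + 30))
})

test_that("a homopolymer template yields no primers with the GC bound cited", {
  pr <- design_primers(strrep("A", 1000), 500,
                       primer_constraints(product_min = 300, product_max = 400))
  expect_equal(nrow(pr), 0L)
  tally <- attr(pr, "failure_tally")
  expect_gt(tally[["tm"]] + tally[["gc"]], 0)
})

test_that("every returned pair re-amplifies exactly its own product in silico", {
  fix <- engineered_template()
  pr <- design_primers(fix$template, fix$target, n_return = 5)
  for (k in seq_len(nrow(pr))) {
    amp <- insilico_pcr(c(tpl = fix$template), pr$fwd[k], pr$rev[k])
    expect_equal(nrow(amp), 1L)
    expect_equal(amp$length, pr$product_len[k])
    expect_true(amp$start <= fix$target && amp$end >= fix$target)
  }
})

test_that("in-silico PCR finds constructed amplicons and respects the 3' rule", {
  set.seed(79)
  fwd <- "GACTGCATTACGGATCAACGTT"
  rev <- "ACTGATACCGTTGCTAACATGG"
  filler <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
  tpl <- paste0(fwd, filler, poptrace:::revcomp(rev))
  amp <- insilico_pcr(c(t1 = tpl), fwd, rev)
  expect_equal(amp$length, nchar(fwd) + 800L + nchar(rev))
  expect_equal(amp$sequence, tpl)
  # absent reverse site -> nothing
  expect_equal(nrow(insilico_pcr(c(t1 = paste0(fwd, filler)), fwd, rev)), 0L)
  # one internal mismatch tolerated with max_mismatch = 1, not at the 3' end
  fwd_mid <- fwd
  substr(fwd_mid, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(fwd, 5, 5))[1]
  expect_equal(nrow(insilico_pcr(c(t1 = tpl), fwd_mid, rev)), 0L)
  expect_equal(nrow(insilico_pcr(c(t1 = tpl), fwd_mid, rev, max_mismatch = 1)), 1L)
  fwd_3p <- fwd
  substr(fwd_3p, 22, 22) <- setdiff(c("A", "C", "G", "T"), substr(fwd, 22, 22))[1]
  expect_equal(nrow(insilico_pcr(c(t1 = tpl), fwd_3p, rev, max_mismatch = 1)), 0L)
})
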