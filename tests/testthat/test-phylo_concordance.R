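test_that("nj_tree recovers an additive 4-taxon topology and validates input", {
  true <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):1);")
  d <- ape::cophenetic.phylo(true)[c("A", "B", "C", "D"), c("A", "B", "C", "D")]
  tr <- nj_tree(d)
  expect_equal(rf_distance(tr, true)$rf, 0)   # AB|CD recovered
  bad <- d
  bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(d[1:2, 1:2]), "3 taxa")
})

test_that("three taxa give the unique unrooted star and RF to self is 0", {
  d <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(d) <- 0
  tr <- nj_tree(d)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(rf_distance(tr, tr)$rf, 0)
})

test_that("RF distance matches hand-enumerable cases", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1)$rf, 0)
  r <- rf_distance(t1, t2)
  expect_equal(r$rf, 2)                       # the two 4-taxon topologies
  expect_equal(r$normalized, 1)
  cat6 <- ape::read.tree(text = "(((((A,B),C),D),E),F);")
  nni <- ape::read.tree(text = "(((((A,C),B),D),E),F);")
  expect_equal(rf_distance(cat6, nni)$rf, 2)  # one NNI
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(rf_distance(t1, t3), "leaf sets differ")
})

test_that("RF agrees with an edge-deletion oracle and phangorn on random trees", {
  set.seed(41)
  labels8 <- LETTERS[1:8]
  for (r in 1:40) {
    n <- sample(4:8, 1)
    labs <- labels8[1:n]
    t1 <- random_tree(labs)
    t2 <- random_tree(labs)
    got <- rf_distance(t1, t2)
    expect_equal(got$rf, oracle_rf(t1, t2))
    expect_equal(got$rf, phangorn::RF.dist(t1, t2))
    expect_true(got$normalized >= 0 && got$normalized <= 1)
  }
})

test_that("RF is a metric: symmetry, identity, triangle inequality", {
  set.seed(43)
  labs <- LETTERS[1:7]
  for (r in 1:15) {
    a <- random_tree(labs); b <- random_tree(labs); c_ <- random_tree(labs)
    dab <- rf_distance(a, b)$rf
    expect_equal(dab, rf_distance(b, a)$rf)
    expect_equal(rf_distance(a, a)$rf, 0)
    expect_lte(dab, rf_distance(a, c_)$rf + rf_distance(c_, b)$rf)
  }
})

test_that("gene trees use allele-sharing distances and flag untreeable genes", {
  # two populations fixed at opposite alleles at 5 loci inside one gene
  codes <- rbind(a1 = rep(2L, 5), a2 = rep(2L, 5),
                 b1 = rep(0L, 5), b2 = rep(0L, 5))
  gm <- make_gm(codes, pos = c(110L, 120L, 130L, 140L, 150L))
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "c1",
                      start = c(100L, 1000L), end = c(200L, 2000L),
                      stringsAsFactors = FALSE)
  gt <- gene_trees_from_matrix(gm, genes)
  d <- poptrace:::allele_sharing_dist(gm$geno)
  expect_equal(d["a1", "a2"], 0)
  expect_equal(d["a1", "b1"], 1)
  expect_false(gt$genes$untreeable[1])
  expect_true(gt$genes$untreeable[2])        # no loci in span
  expect_null(gt$trees[["g2"]])
})

test_that("genes simulated on a clade topology are concordant with the species tree", {
  sim <- simulate_cohort(sim_config(
    n_populations = 6, n_per_pop = 6, n_loci = 15000, contig_length = 1e6,
    clades = list(c(1, 2), c(3, 4), c(5, 6)), fst = 0.08, fst_clade = 0.2,
    n_genes = 30, planted_per_pop = 0, seed = 13
  ))
  pm <- sim$popmap
  pops <- sort(unique(pm))
  f <- vapply(pops, function(p) alt_freq(sim$gm, names(pm)[pm == p]),
              numeric(ncol(sim$gm$geno)))
  dpop <- matrix(0, 6, 6, dimnames = list(pops, pops))
  for (a in 1:5) for (b in (a + 1):6) {
    dpop[a, b] <- dpop[b, a] <- mean(abs(f[, a] - f[, b]))
  }
  species <- nj_tree(dpop)
  # the species tree itself reflects the clade structure
  expect_equal(rf_distance(species, ape::read.tree(
    text = "((popA,popB),(popC,popD),(popE,popF));"))$rf, 0)
  gt <- gene_trees_from_matrix(sim$gm, sim$genes, collapse_to = pm)
  genes <- gene_rf(gt, species)
  informative <- genes[!genes$untreeable & genes$n_informative_sites >= 50, ]
  expect_gte(nrow(informative), 20)
  expect_equal(median(informative$rf), 0)
})

test_that("rf_length_correlation matches the textbook Pearson formula", {
  genes <- data.frame(gene_id = letters[1:5], length = 2:6,
                      rf = c(4, 4, 2, 2, 0))
  r <- rf_length_correlation(genes)
  expect_equal(r$r, cor(2:6, c(4, 4, 2, 2, 0)))
  expect_equal(round(r$r, 4), -0.9449)
  lin <- data.frame(length = 1:6, rf = 12 - 2 * (1:6))
  expect_equal(rf_length_correlation(lin)$r, -1)
  flat <- data.frame(length = 1:6, rf = rep(3, 6))
  expect_true(is.na(rf_length_correlation(flat)$r))
  expect_match(rf_length_correlation(flat)$note, "zero variance")
})

test_that("select_target_genes applies length and exon filters and ranks rf-first", {
  genes <- data.frame(
    gene_id = c("short", "concordant", "discordant"),
    chrom = "c1", start = c(1L, 1L, 1L), end = c(1500L, 9000L, 2500L),
    rf = c(0, 0, 2), stringsAsFactors = FALSE
  )
  genes$exons <- list(cbind(100L, 400L), cbind(c(100L, 500L), c(109L, 900L)),
                      cbind(100L, 400L))
  sel <- select_target_genes(genes, n_targets = 1)
  expect_equal(sel$gene_id, "concordant")         # rf-first beats shorter length
  expect_false("short" %in% sel$gene_id)          # 1500 bp excluded
  sel2 <- select_target_genes(genes, n_targets = 10)
  expect_equal(nrow(sel2), 2L)
  # the 10 bp exon was dropped from the retained gene's model
  expect_equal(nrow(sel2$exons[[which(sel2$gene_id == "concordant")]]), 1L)
  # determinism
  expect_identical(sel2, select_target_genes(genes, n_targets = 10))
})

test_that("read_gff_genes assembles spans and exons", {
  sim <- simulate_cohort(sim_config(n_loci = 500, contig_length = 1e5,
                                    n_genes = 6, planted_per_pop = 3,
                                    seed = 19), dir = td <- tempfile())
  genes <- read_gff_genes(file.path(td, "genes.gff3"))
  expect_equal(genes$gene_id, sim$genes$gene_id)
  expect_equal(genes$start, sim$genes$start)
  expect_equal(vapply(genes$exons, nrow, integer(1)),
               vapply(sim$genes$exons, nrow, integer(1)))
  unlink(td, recursive = TRUE)
})
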