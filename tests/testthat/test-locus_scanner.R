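# 2 populations x 4 samples; columns engineered per case
scan_pm <- c(p1 = "P", p2 = "P", p3 = "P", p4 = "P",
             q1 = "Q", q2 = "Q", q3 = "Q", q4 = "Q")

scan_gm <- function(p_codes, q_codes) {
  make_gm(rbind(
    matrix(p_codes, 4, length(p_codes) / 4,
           dimnames = list(names(scan_pm)[1:4], NULL)),
    matrix(q_codes, 4, length(q_codes) / 4,
           dimnames = list(names(scan_pm)[5:8], NULL))
  ))
}

test_that("fixation requires every counted individual hom-alt under the missing policy", {
  gm <- scan_gm(c(2L, 2L, 2L, 2L,   2L, 2L, 2L, 1L,   2L, 2L, 2L, NA),
                rep(0L, 12))
  fx <- fixed_loci(gm, scan_pm, "P")
  expect_equal(fx$idx, 1L)                       # het breaks col 2, NA breaks col 3
  fx75 <- fixed_loci(gm, scan_pm, "P", min_called_frac = 0.75)
  expect_equal(fx75$idx, c(1L, 3L))              # 3/4 called, all hom-alt
  expect_error(fixed_loci(gm, scan_pm, "nope"), "unknown population")
})

test_that("strict-private and upset-unique modes differ exactly on outside carriers", {
  # col 1: P fixed, Q all hom-ref       -> specific in both modes
  # col 2: P fixed, one Q heterozygote  -> upset-unique only
  # col 3: fixed in both populations    -> specific to neither
  gm <- scan_gm(c(rep(2L, 4), rep(2L, 4), rep(2L, 4)),
                c(rep(0L, 4), 1L, 0L, 0L, 0L, rep(2L, 4)))
  strict <- specific_loci(gm, scan_pm, mode = "strict-private")
  upset <- specific_loci(gm, scan_pm, mode = "upset-unique")
  expect_equal(strict$P$pos, 10L)
  expect_equal(upset$P$pos, c(10L, 20L))
  expect_equal(nrow(strict$Q), 0L)
  expect_equal(nrow(upset$Q), 0L)
  expect_equal(strict$P$diagnostic_allele, "G")  # the alt base
})

test_that("strict-private is nested in upset-unique, which is nested in fixed", {
  set.seed(53)
  for (r in 1:5) {
    gm <- make_gm(matrix(sample(c(0:2, NA), 8 * 300, TRUE, prob = c(5, 2, 3, 1)),
                         8, 300, dimnames = list(names(scan_pm), NULL)))
    fx <- fixed_loci(gm, scan_pm, "P")
    strict <- specific_loci(gm, scan_pm, "strict-private")$P$pos
    upset <- specific_loci(gm, scan_pm, "upset-unique")$P$pos
    expect_true(all(strict %in% upset))
    expect_true(all(upset %in% fx$loci$pos))
  }
})

test_that("scanner output is invariant to sample and locus order", {
  set.seed(59)
  gm <- make_gm(matrix(sample(c(0:2), 8 * 200, TRUE, prob = c(5, 2, 3)),
                       8, 200, dimnames = list(names(scan_pm), NULL)))
  base <- specific_loci(gm, scan_pm)
  perm <- gm[sample(8), sample(200)]
  shuffled <- specific_loci(perm, scan_pm)
  for (p in names(base)) {
    expect_equal(shuffled[[p]]$pos, sort(base[[p]]$pos))
    expect_equal(shuffled[[p]], base[[p]][order(base[[p]]$pos), ],
                 ignore_attr = TRUE)
  }
})

test_that("intersection counts tally exact membership patterns and conserve the union", {
  disjoint <- intersection_counts(list(A = c("x", "y", "z"), B = c("u", "v")))
  expect_equal(disjoint$count[disjoint$combination == "A"], 3L)
  expect_equal(disjoint$count[disjoint$combination == "B"], 2L)
  expect_equal(disjoint$count[disjoint$combination == "A&B"], 0L)
  nested <- intersection_counts(list(A = c("x", "y"), B = "y"))
  expect_equal(nested$count[nested$combination == "A"], 1L)
  expect_equal(nested$count[nested$combination == "A&B"], 1L)
  expect_equal(nested$count[nested$combination == "B"], 0L)
  set.seed(61)
  for (r in 1:20) {
    k <- sample(2:5, 1)
    sets <- setNames(lapply(1:k, function(i) {
      sample(letters[1:10], sample(0:8, 1))
    }), LETTERS[1:k])
    tab <- intersection_counts(sets)
    expect_equal(sum(tab$count), length(unique(unlist(sets))))
    # brute-force per-element membership tally
    elements <- unique(unlist(sets))
    patt <- vapply(elements, function(el) {
      paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
            collapse = "&")
    }, character(1))
    expected <- table(patt)
    for (i in seq_len(nrow(tab))) {
      want <- if (tab$combination[i] %in% names(expected)) {
        as.integer(expected[[tab$combination[i]]])
      } else 0L
      expect_identical(tab$count[i], want)
    }
  }
})

test_that("restrict_to_genes keeps in-span markers inclusively and annotates genes", {
  markers <- data.frame(chrom = "c1", pos = c(150L, 99L, 200L),
                        ref = "A", alt = "G", population = "P",
                        diagnostic_allele = "G", stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = "g1", chrom = "c1", start = 100L, end = 200L)
  panel <- restrict_to_genes(list(P = markers), genes)
  expect_equal(panel$pos, c(150L, 200L))          # 99 < start dropped, end kept
  expect_equal(unique(panel$gene_id), "g1")
})

test_that("planted in-gene markers are exactly the panel on simulated data", {
  sim <- simulate_cohort(sim_config(n_loci = 5000, contig_length = 5e5,
                                    n_genes = 20, planted_per_pop = 8,
                                    seed = 67))
  sp <- specific_loci(sim$gm, sim$popmap)
  panel <- restrict_to_genes(sp, sim$genes)
  planted_in <- sim$truth$planted[sim$truth$planted$in_gene, ]
  expect_equal(marker_key(panel), marker_key(planted_in))
})
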