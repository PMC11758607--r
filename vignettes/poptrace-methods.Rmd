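---
title: "Population-diagnostic SNP markers and sample traceability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-diagnostic SNP markers and sample traceability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `poptrace`, in the spirit of a methods supplement: what
each stage assumes, which knobs matter, and what the simulation-based tests
do and do not establish about real data.

## Problem setting

Geographic traceability asks: given DNA from an unknown wildlife sample,
which population did it come from? The approach implemented here relies on
*population-specific fixed loci* — biallelic SNPs at which one population is
homozygous for an allele that other populations do not carry. Such loci
arise by drift in small, isolated populations (snub-nosed monkey populations
are an extreme case: tiny effective sizes, strong geographic isolation,
lowest heterozygosity among primates), and make ideal forensic markers
because a single Sanger-readable base is decisive. No adaptive
interpretation is attached to them; drift alone is the expected source, and
the package deliberately computes no selection statistics.

The pipeline is: curate samples (relatedness, gene flow) → choose target
genes (phylogenetic concordance) → scan for diagnostic loci → design and
validate primers → assign unknowns.

## Sample curation

**Kinship.** Duplicated accessions and close relatives distort fixation
scans (a duplicated individual double-counts its genotypes). We use the
KING-robust estimator in its symmetric form,
$$\phi = \frac{N_{\text{het,het}} - 2N_{\text{opp.hom}}}{N_{\text{het}}(i) + N_{\text{het}}(j)},$$
over the sites called in both samples. It needs no population allele
frequencies, returns exactly 0.5 for duplicates and approximately 0.25 for
first-degree pairs, and degrades gracefully with missing data because the
site set is the per-pair intersection. The default exclusion threshold is
0.354 (the conventional rounding of $2^{-3/2}$, the geometric midpoint
between duplicate and first-degree expectations); the exact value is a
parameter. The estimator is undefined when neither sample has a heterozygous
call over shared sites; that case is reported as `NA`, not an error. Since
only which individuals to drop is needed (not a pedigree), exclusions are
proposed greedily: within each connected component of the flagged-pair
graph, remove the individual with most flagged partners (ties broken by
sample id) until no flagged pair remains — a standard vertex-cover
heuristic that removes 2 of 3 mutual duplicates, as it should.

**Gene flow.** Admixed individuals carry another population's alleles and
would erase genuine diagnostics from the scan (the allele is "carried
outside" the focal population). Patterson's D is computed with
frequency-weighted site patterns,
$ABBA = \sum (1-f_1) f_2 f_3 (1-f_O)$ and
$BABA = \sum f_1 (1-f_2) f_3 (1-f_O)$, after polarizing each site so the
outgroup's major allele is ancestral. Sites where the outgroup minor-allele
frequency exceeds 10% are skipped — polarization is unreliable there; the
cutoff is exposed as `outgroup_poly_max`. Significance comes from a
delete-one jackknife over contiguous blocks of 1,000 loci (`block_size`);
blocks are equal-sized by construction, so the plain $(B-1)/B$ jackknife
variance is used without block-size weighting. Blocks proxy for linkage
structure; on real data the block size should be chosen so blocks exceed LD
range. Which trios to test and the $|z|$ cutoff for calling a hybrid are
left to the analyst (the package reports, it does not decide).

## Target genes by phylogenetic concordance

Primers must sit in regions whose local genealogy matches the population
tree, otherwise a marker may reflect incomplete lineage sorting rather than
population membership. Gene trees are built per gene by neighbor-joining on
allele-sharing distances $d(i,j) = \mathrm{mean}_\ell |g_{i\ell} -
g_{j\ell}|/2$ (optionally averaged to one leaf per population), and
compared to the species tree by unrooted Robinson–Foulds distance — the
size of the symmetric difference of nontrivial bipartition sets, computed on
canonicalized splits. NJ distance trees stand in for maximum-likelihood
trees here as a deliberate design choice: they are deterministic,
dependency-free, and concordance ranking only needs topology; an
external-newick import path (any `ape::read.tree` result) lets users
substitute ML trees. Genes with fewer than 4 informative sites are
"untreeable" and excluded from ranking.

Selection then drops exons shorter than 15 bp from the gene models, keeps
genes with genomic span > 2,000 bp (span, not summed exon length, is the
default "gene length" since the span is what a primer pair must bracket;
`length_mode = "exon"` switches), sorts by (RF ascending, length ascending,
gene id) and keeps the first `n_targets` (default 300). The rf-then-length
order and the id tie-break make the ranking deterministic.

## The diagnostic scan

"Fixed" is defined on the alternate allele: every counted individual of the
population is hom-alt. Scanning alt-fixation (with `allele = "ref"`
available for completeness) reflects that the reference genome is typically
conspecific with one population, making hom-ref fixation uninformative.
The default missing policy is *zero missing within the focal population* —
"fixed in all individuals" taken literally; `min_called_frac` relaxes it for
degraded data.

Two specificity modes are provided because set-difference-of-fixed-sets (the
UpSet workflow) and true privacy differ exactly on outside carriers:

* `strict-private` (default): the population is fixed for the allele **and**
  the allele count outside the population is zero. Diagnostic in the
  forensic sense — observing the allele implies the population.
* `upset-unique`: fixed in this population's set and no other's. A
  heterozygous carrier elsewhere does not disqualify the locus.

For every population subset, `intersection_counts()` tallies loci fixed in
exactly that subset; counts sum to the union size (a conservation law the
tests enforce against a per-locus oracle). Markers are then restricted to
the selected genes (1-based inclusive span containment) to form the panel.
Scanner output is canonically sorted, so it is invariant to sample and locus
order.

## Primer design and in-silico PCR

A 900 bp flank on each side of the marker gives a 1,801 bp template with the
diagnostic base at offset 901 (clamped at contig ends, with the offset
adjusted). Candidate windows of 20–26 nt are enumerated at every position
(O(length) via cumulative dinucleotide sums), filtered by Tm 52–62 °C and
GC 30–70 %, and paired so the product is 850–950 bp and contains the target
at least 30 bp from each primer's 3' end — far enough that a Sanger read
from either primer covers the diagnostic base cleanly past its noisy start.

Melting temperatures default to nearest-neighbor thermodynamics with the
SantaLucia 1998 unified parameter set, entropy salt correction
$0.368\,(N-1)\ln[\mathrm{Na}^+]$ at 50 mM monovalent cation, 250 nM of each
strand, and the two-state $C_T/4$ term — fixed, documented conditions, since
typical PCR buffers vary and only the relative ranking matters here. The
Wallace rule ($2AT + 4GC$) is available as a fast alternative, but note it
systematically overshoots this window for 22-mers of moderate GC. Pairs are
ranked by
$|T_m - 56|_{fwd} + |T_m - 56|_{rev} + 0.2(|GC-50|_{fwd} + |GC-50|_{rev}) +
0.1|s-22|_{fwd} + 0.1|s-22|_{rev} + |\Delta T_m|$ — invented weights chosen
so Tm deviation dominates, mirroring the spirit of Primer3's defaults.

In-silico PCR finds the forward primer on the plus strand and the
reverse-complemented reverse primer downstream within `max_product` bp; the
amplicon runs from the first base of the forward site to the last base of
the reverse site. Mismatches (when allowed) are forbidden in the three
terminal 3' bases of either primer, where polymerase extension is most
sensitive. Multi-mapping pairs are reported rather than suppressed — a
multi-hit primer is a design failure the analyst must see. Published primer
sets can violate the product window (one known set amplifies 817 bp against
an 850–950 specification); such violations are reported, not silently
accepted.

## Assignment

The decision rule is unanimity, not majority: a sample is assigned to P only
if *every* readable marker of P matches, at least `min_markers = 2` markers
are readable (two SNPs suffice to distinguish each population in the
motivating system, hence the default), and no second population also reaches
a full match. Because diagnostics are fixed differences, any conflict
signals error or hybridity, and an F1 hybrid — heterozygous at both parents'
markers — matches both parental sets and is deliberately reported
*ambiguous with a hybrid note* rather than assigned. A heterozygous
observation containing the diagnostic allele counts as a match but is
flagged, since hybrid misidentification is the known failure mode of
fixed-difference panels. Amplicon-mode readout anchors each marker by exact
20 bp seed matches flanking the locus (both orientations tried); markers
whose seeds fail to anchor are "unreadable" and simply reduce the readable
count.

## The simulator

`simulate_cohort()` generates the statistical structure the method assumes,
plus a truth set for scoring: ancestral frequencies $p \sim U(0.05, 0.95)$;
population frequencies Balding–Nichols,
$\mathrm{Beta}\!\left(p\frac{1-F}{F}, (1-p)\frac{1-F}{F}\right)$; genotypes
$\mathrm{Binomial}(2, f)$. Balding–Nichols was chosen over coalescent
simulation because it directly parameterizes the drift/fixation behavior the
scanner exploits; testing set logic does not require coalescent fidelity.
Planted diagnostic loci are fixed (frequency 1) in the focal population and
absent (0) elsewhere, placed inside or outside gene spans as configured;
admixed individuals draw each allele from the source population with
probability $\alpha$; relatives arise by Mendelian transmission; the
reference carries the ref allele at every site. An optional clade structure
(populations nested in clades with their own drift level) gives the cohort a
true topology for concordance testing.

The reference study conditions — used by the test suite and the acceptance
script — are 3 populations × 8 diploid samples, 20,000 loci on a 2 Mb
contig, $F = 0.1$, 10 planted markers per population (half in genes), no
missingness. These sizes keep every property checkable in seconds while
leaving room for incidental drift-driven fixation to occur and be handled.
The D-statistic runs use 4 populations with outgroup drift $F = 0.3$ (an
outgroup is by construction the most diverged lineage; higher drift also
gives it the near-fixed sites that polarization needs). Concordance runs use
6 populations in 3 clades ($F_{clade} = 0.2$, $F_{pop} = 0.08$) and, for the
RF-versus-length correlation, gene spans of 0.5–6 kb so that short genes
genuinely carry too few sites to resolve the topology — which is exactly the
mechanism the negative RF–length correlation reflects.

What the simulations do **not** emulate: linkage disequilibrium (loci are
independent, so jackknife blocks are a formality in simulation), sequencing
and genotyping error, reference bias, selection, and realistic site
frequency spectra at the rare end (ancestral frequencies below 0.05 are not
generated). Passing tests therefore establish the *set logic, estimators and
numerics*, not robustness to caller artifacts; on real data the upstream
hard filters (honored via the VCF FILTER column) carry that burden.

Mitochondrial alignments are simulated with one designated population
carrying $k \ge 10$ private substitutions while the others draw from a
shared haplotype pool — the "one population maternally distinct, two
sharing" structure that motivates falling back to nuclear markers.

## Numerical conventions and edge cases

* Coordinates are 1-based inclusive everywhere; only BED export converts to
  0-based half-open.
* VCF QUAL is the site-quality filter ("minQ"-style); caller-specific
  annotations are honored only through the FILTER column (`pass_only`).
  Half-calls (`0/.`) and non-diploid GTs are missing. VCFtools'
  `--max-missing 0.9` convention maps to `max_missing_frac = 0.1`.
* A MAF threshold is applied with `>=` (a site at exactly the threshold is
  retained); invariant sites never pass the MAF screen.
* NJ branch lengths are clamped at zero from below; RF on trees with < 4
  leaves has no nontrivial splits and normalized RF is `NA` there.
* The minimum-spanning network uses Kruskal with deterministic
  (weight, lexicographic pair) tie-breaking; same-weight edges that join
  components still separate at the start of their weight level are kept as
  `alternative` edges. The statistical-parsimony connection limit of TCS is
  not implemented — the topology, not the limit, carries the population
  signal.
* Degenerate inputs favored over crashes: zero-het kinship pairs,
  zero-numerator D, all-masked alignment columns, primer searches with no
  feasible pair (returned empty with a per-constraint failure tally), and
  unreadable amplicon markers are all reported states.

## Known limitations

Diagnostic panels inherit the weaknesses of fixed differences: new sampling
can reveal carriers that break privacy; hybrids and backcrosses beyond F1
may pass the unanimity rule on one parent's panel; heavily processed samples
defeat PCR itself. The gene-tree stage uses distance trees, adequate for
ranking but not for publication-grade phylogenies. The D-statistic module
computes one statistic per trio and its z-score; genome-scanning variants
(f-branch, windowed f4) are out of scope.
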