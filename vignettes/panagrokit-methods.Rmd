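---
title: "Methods and modelling choices in panagrokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in panagrokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

panagrokit implements the comparative-genomic inferences used to
characterise parthenogenetic, cryptobiotic panagrolaimid nematodes:
ploidy inference from variant-frequency spectra, Alien-Index screening
for horizontal gene transfer (HGT) with a contamination and integration
evidence cascade, Dollo-parsimony reconstruction of HGT-family gain and
loss on a species tree, duplication-loss gene-tree reconciliation to
discriminate allo- from autopolyploid origin of duplicated gene copies,
distance-based divergence dating rescaled by generation time, and the
supporting enrichment and contingency statistics. This vignette explains
each model, its assumptions, the tunable parameters, and the design
choices made where the design was genuinely open. Every quantitative
statement here is computed by the package's test suite or the
`scripts/acceptance.R` script; none is asserted from memory.

## Ploidy from variant-frequency spectra

**Model.** Map RNA-seq (or genomic) reads to a collapsed reference and
call variants. At a site where the alternative allele is carried by *k*
of *m* genome copies, the alternative-read fraction concentrates around
*k/m*: a diploid heterozygote reads at 1/2; a triploid with a collapsed
reference reads at 1/3 (variant on one copy) or 2/3 (variant on two
copies); a homozygous genome yields no coherent mode. The spectrum of
per-site fractions `f = alt/(ref+alt)` therefore carries the ploidy
signature in its peak structure.

**Folding.** Whether a divergent triploid site reads at 1/3 or 2/3
depends only on which allele the collapsed reference happens to carry,
so `f` and `1-f` are equivalent evidence. Spectra are folded
(`min(f, 1-f)`, support `(0, 0.5]`) by default, which unifies the two
triploid modes into one peak at 1/3. Folding is idempotent, and the
diploid window is capped at 0.50 because folded support ends there.

**Parameters.** All are exposed and none is inferred from data:

* `min_depth = 20` reads — below this the binomial noise on `f` blurs
  1/3 vs 1/2 badly (sd of `f` at depth 20 is about 0.11).
* `trim = (0.05, 0.95)` — near-fixed sites carry no heterozygosity
  signal and are dominated by sequencing error.
* `bin_width = 0.02` — 25 folded bins; fine enough to separate 0.33 from
  0.50 by eight bins, coarse enough that a 5,000-site sample fills bins.
* smoothing: centred 5-bin moving average (shrinking at the edges).
* `flatness_threshold = 1.5` on peak prominence
  (`max(smoothed)/median(smoothed)`); a perfectly uniform spectrum has
  prominence 1.
* windows: triploid `[0.28, 0.40]`, diploid `[0.44, 0.50]` on the folded
  scale; a peak elsewhere yields `ambiguous`.
* `min_variants = 200` — below this a call is `ambiguous` regardless of
  shape.

**Between-sample comparison** uses a two-sample Kolmogorov–Smirnov test
implemented in the package: `D` is the supremum ECDF distance; for
pooled sizes `n1 + n2 <= 12` the p value is exact by enumeration of all
`choose(n1+n2, n1)` assignments (ties handled naturally); otherwise the
asymptotic Kolmogorov distribution is used with effective size
`n1 n2/(n1 + n2)` and `lambda = sqrt(n_eff) D` (no small-sample
continuity correction; the exact branch covers the region where the
limit is poor). `stats::ks.test` is used only as an independent oracle
in the tests.

**What the generator emulates — and does not.** `simulate_variants`
draws per-site depth as Poisson(mean depth) floored at 1 (a neutral
coverage model), and alternative counts as Binomial(depth, p') with
`p' = p(1-e) + (1-p)e` folding in a symmetric error rate `e`; `p` is 0,
1/2, or 1/3 vs 2/3 per ploidy class, with a default 10% of triploid
sites at 2/3 (a collapsed reference mostly carries the majority allele).
It does not model mapping bias, allele-specific expression, or residual
population polymorphism. The last omission matters for the homozygous
class: an error-only homozygous sample leaves almost no variants inside
the trim window (about 15 of 5,000 sites at depth 50, error 0.005), so
the classifier reports `ambiguous` — correctly flagging that there is no
spectrum to classify — rather than `homozygous_flat`. Flat spectra in
real homozygous samples come from rare segregating variants spread
across frequencies, which the generator deliberately does not add.
Passing tests therefore demonstrate recovery of the triploid and diploid
signatures and honest abstention on error-only input; they do not
demonstrate recovery of a flat spectrum from residual polymorphism.

## Alien-Index HGT screen

For each gene, let `E_m` and `E_n` be the best (smallest) BLAST-style
e-values among metazoan and non-metazoan subjects respectively, with a
missing hit encoded as `E = 1` and values capped at 1. The Alien Index
is

    AI = ln(E_m + e^-200) - ln(E_n + e^-200)

The `e^-200` floor bounds `|AI|` by `200 + ln 2` and keeps zero e-values
finite. `AI > 0` means the non-metazoan hit is better; `AI > 30`
corresponds to an e-value advantage of more than `e^30` and marks strong
candidates. Best hits are chosen deterministically: lowest e-value, ties
by highest bitscore, then lexicographic subject id.

The screen then applies, in order:

1. **Contamination rule (wins over everything):** `AI > 0` and identity
   to the best non-metazoan protein `> 70%` flags a likely contaminant —
   a genuinely transferred gene has had time to diverge from its donor.
2. **High confidence:** `AI > 30`, at least one spliceosomal intron, and
   expression `> 100` TPM — a transferred gene that gained introns and
   is expressed is domesticated in the host genome.
3. Otherwise `candidate_ai30` (`AI > 30`) or `candidate_ai0`
   (`0 < AI <= 30`).

"Neighbours hitting Metazoa" is operationalised as: another gene on the
same contig with `AI < 0`. The taxonomic self-exclusion set (hits to the
query's own lineage) is delegated to the partition map at read time.
Codon-usage screening is not implemented: no statistic or cut-off is
defined for it here, and it is orthogonal to the evidence the package
models. The `tier_report` feature counts (contigs, neighbours, introns,
TPM tiers, Pfam domains) are computed over strong (`AI > 30`)
non-contaminant candidates.

## Dollo reconstruction of HGT gains and losses

Families of horizontally acquired genes observed in two or more species
are assumed to have been acquired once — multiple independent
acquisitions of the same family are less parsimonious — and possibly
lost repeatedly afterwards. Under this Dollo model the gain node of a
family is the MRCA of the species carrying it, and the minimal loss set
is the set of root edges of the maximal subtrees under the gain node
that contain no carrier (both facts are verified against brute-force
enumeration in the tests). Per node the package reports families gained,
families lost on the edge above the node (losses are attributed to the
child node of the lost edge), and cumulative families present, with the
additivity identity `cum(n) = cum(parent) + gains(n) - losses(n)`.
Families observed in a single species are allowed (gain at the leaf).
Probabilistic (ML) reconstruction and gain/loss cost weighting are out
of scope: plain parsimony is the stated model.

Recovery behaviour: without losses, gain-node recovery from simulated
matrices is exact. With losses the inferred gain node can only move
*tipward* of the truth (losses prune carriers; the MRCA of a subset is
never above the MRCA of the full set) — the tests assert this direction.
At a 10% per-edge loss rate on a 10-leaf tree the expected recovery is
about 91%, so the test suite pools ten replicate 200-family simulations
before asserting the 90% recovery floor, keeping Monte-Carlo noise
(about 2 percentage points per single draw) out of the assertion.

## Allo- vs autopolyploidy by donor-graft reconciliation

The two hypotheses for the parthenogens' extra gene copies make opposite
topological predictions: under autopolyploidy each extra copy is sister
to its own species' copy; under allopolyploidy the extra copies form
their own clade descending from a donor lineage outside the sampled
species. The package reduces full multi-labelled-tree reconciliation to
a one-parameter family of hypotheses: a single `DONOR` leaf grafted
midway on each edge of the species tree (terminal edges included). For
each graft, each gene tree is reconciled by standard LCA duplication-loss
mapping with the extra copies (copy index >= 2 in designated
parthenogen species) re-assigned to `DONOR`, at cost
`duplications + losses`, unweighted. An internal gene node is a
duplication iff its LCA image equals the image of one of its children;
losses are counted per child edge as `depth(M(c)) - depth(M(v)) - 1`,
plus one when the node is a duplication and the child maps strictly
below, floored at zero. The brute-force minimum over all valid
internal-node mappings equals the LCA mapping's cost on every enumerated
small case in the tests.

The graft edge minimising the summed cost gives the verdict. Edges are
classed by their child node: inside the parthenogen clade (including
parthenogen terminal edges) = `auto`; outside the congener clade, or the
congener stem edge itself = `allo`; edges within the congener clade but
outside the parthenogen clade form a third class, and a minimum there —
or a tie spanning classes — yields `ambiguous`. The congener set (the
parthenogens plus their sexual sister species) defaults to the tips
below the parent of the parthenogens' MRCA, and can be given explicitly.
This single-donor reduction cannot represent multiple simultaneous
hybridisations; it is sufficient to separate the two competing origins,
which is its only job here.

Unrooted input gene trees are rooted on the species tree's
earliest-diverging outgroup (the smaller side of its root split); a tree
with no outgroup leaf, or with no extra copies, is skipped with a
warning. With 100 simulated gene trees per replicate and one random NNI
perturbation per tree, the verdict is recovered with positive margin in
at least 95 of 100 seeded replicates for both scenarios (measured in the
test suite; typical runtime about half a second per replicate).

## Divergence dating

Genome-wide distances (e.g. from an alignment-free estimator, consumed
as a PHYLIP or TSV matrix) are converted to ages by linear calibration:

    age(i,j) = cal_age * d(i,j) / d(cal_pair) * (gen_target / gen_cal)

Age is linear in distance (a molecular clock on the calibrated scale)
and linear in generation time: with the number of elapsed generations
fixed by the distance, halving the generations per year doubles the
calendar age. This is the minimal model consistent with reporting the
same splits under alternative generation times — an 8-day laboratory
generation time versus a conservative 50-day field value gives exactly a
6.25-fold age ratio, e.g. 1.3 Myr becomes 8.125 Myr. No confidence
intervals are produced: the inputs are point distances and a point
calibration. For testing, Jukes–Cantor distances
(`d = -3/4 ln(1 - 4p/3)`, gap/N columns dropped, error at `p >= 0.75`)
on synthetic alignments stand in for the alignment-free estimator, which
is not re-implemented.

## Enrichment and contingency statistics

Domain overrepresentation uses one-sided (greater) Fisher exact tests on
per-domain 2x2 tables (proteins carrying the domain vs not, foreground
vs background — presence counting keeps the margins well defined), with
Benjamini–Hochberg step-up correction across domains. P values are
computed directly from the hypergeometric distribution (this is what the
Fisher exact test is; the vectorised form also keeps the 1,000-replicate
FDR simulation in the tests fast), and `stats::fisher.test` serves as
the independent oracle. The odds ratio reported is the sample ratio
`ad/bc`, infinite when `bc = 0`. The 2x2 chi-square test is Pearson's
with 1 df via `stats::chisq.test`, optional Yates correction, and an
explicit error (advising Fisher) when an expected cell is zero.

## Numerical conventions

* Coordinates are 1-based inclusive on I/O (GFF3, VCF); no 0-based
  representation leaks across module boundaries.
* Histogram bins are half-open `[a, b)` with the last bin closed, so
  `f = 0.5` lands in the final folded bin.
* Internal nodes without labels are auto-named `N<k>` by postorder
  index; edges are identified by the label of their child node.
* All generators are pure functions of their spec (seed included):
  byte-identical outputs across runs.
* Missing best hits are encoded as e-value 1 and e-values above 1 are
  capped, bounding the Alien Index.
* Ties in best-hit selection, modal-bin selection and graft scoring are
  broken deterministically (bitscore then subject id; first bin;
  lexicographic edge id — with cross-class cost ties reported as
  `ambiguous` rather than silently resolved).

## Problem sizes used by the tests

The suite exercises: 5,000-site spectra at depth 50 (error 0.005) for
the headline ploidy calls and 50 seeds per class for recovery; 2,000
frequencies per sample for the KS separation; exhaustive Dollo
enumeration on trees of up to 6 leaves and reconciliation enumeration on
gene trees of up to 4 leaves (complete) and 5 leaves (sampled); 100
replicates of 100 gene trees for each polyploidy scenario; ten pooled
200-family matrices for lossy gain-node recovery; and 1,000 null
replicates of 100 domains for FDR control. These sizes make every
stochastic assertion a property of the method rather than of a lucky
seed while keeping the full suite in the minutes range.

## Known limitations

* The HGT screen consumes best-hit tables; it does not run the homology
  search, and its verdicts inherit any taxon-sampling bias of the
  underlying database.
* The homozygous ploidy class is only identifiable as honest abstention
  under the error-only generator (see above).
* The donor-graft reduction considers one donor lineage; reticulate
  histories with several donors are out of scope.
* Dating assumes strict linearity in distance and generation time;
  saturation, rate variation and calibration uncertainty are not
  modelled.
* The Dollo model forbids regain; a family lost and re-acquired would be
  mis-dated rootward.
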