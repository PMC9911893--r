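---
title: "Methods: WGD detection and duplicate retention in wgdretain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WGD detection and duplicate retention in wgdretain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records how each stage of the pipeline is defined, which
parameters matter, and where the design was genuinely open — in enough
detail that a reader could re-derive every number the package produces.

## The analysis model

A whole-genome duplication leaves two coupled signatures. First, duplicate
gene pairs born at the same event share a divergence time, so their
synonymous substitution rate Ks (substitutions per synonymous site, a
clock-like proxy because synonymous changes are nearly neutral) clusters
around a common value; two nested WGDs give a bimodal Ks distribution.
Second, WGD duplicates — unlike tandem or dispersed duplicates — preserve
neighbourhood: runs of homologous gene pairs in conserved order (collinear
or syntenic blocks). The pipeline exploits both: Ks dates the duplicates,
synteny certifies their WGD origin, and gene trees identify which modern
genes descend from a duplication node at all.

The stages run in dependency order:

1. **Ks estimation** for every within-genome homolog pair of the focal
   species (codon alignment → counting estimator).
2. **Tandem flagging and block chaining** over the ranked gene order.
3. **Peak fitting**: the Ks values of in-block anchor pairs are split at
   the inter-peak trough and one Gaussian is fitted per side.
4. **Duplication events**: species-overlap calls on gene trees, filtered,
   and assigned to the younger (σ) or older (ρ) WGD via the Ks class of
   the block containing a cross-child anchor pair.
5. **TF-family statistics** and **GO over-representation** of the retained
   sets.

## Ks estimators

`ng86()` implements the classic counting estimator: for each codon, each
of the nine single-nucleotide neighbours is classified synonymous or
nonsynonymous under the standard genetic code (changes to stop codons are
excluded and the per-position site normalised over the remaining
alternatives, so S + N = 3 per counted codon exactly); differences between
codons separated by more than one change are averaged over all
substitution orders, skipping pathways through stop codons; proportions
are corrected with d = −3/4 · ln(1 − 4p/3). A proportion above 3/4 makes
the logarithm undefined — such estimates are returned with
`valid = FALSE` rather than clamped, because silently clamping saturated
pairs at an arbitrary ceiling would distort the upper tail of the Ks
distribution that the mixture fit consumes.

`yn00()` follows the same counting skeleton but removes the two biases
NG86 is known for: transition/transversion inequality and codon usage.
Codon frequencies come from the F3×4 model (position-specific nucleotide
frequencies of the aligned pair); κ is estimated from fourfold-degenerate
third positions with a two-parameter (K80) correction, falling back to 2
(a typical plant nuclear value) when fewer than 10 such sites exist; site
counts weight each possible change by κ^[transition] times the frequency
of the target codon; and multi-hit pathways are weighted by
κ^[transitions] · ω^[nonsynonymous steps], with ω updated from the
current Ka/Ks until the difference counts change by less than 1e-6
(relative), at most 100 iterations. Distances are corrected with the same
JC-style formula as NG86; the refinement of correcting transition and
transversion fractions separately is deliberately omitted — at the
divergences this pipeline retains (Ks < 1.5) its effect is far smaller
than the sampling noise of a single gene pair, and the simpler correction
keeps the two estimators exactly comparable in the κ = 1, uniform-usage
limit (a property the test suite checks). Alignments with fewer than 10
counted codons are refused; the method is unstable below that.

Columns containing a gap, an ambiguous base (N), or a stop codon in
either sequence are excluded from counting. Pairs of equal-length CDS are
aligned by trivial back-translation; anything else requires an external
protein alignment threaded through `backthread_codon_alignment()`
(pal2nal-style), because protein alignment itself is outside the
package's scope.

The pipeline's default estimator is YN00; NG86 is retained as a
cross-check mode (`ks_method = "NG86"`), and as the target of an exact
enumeration oracle in the tests.

## Ks filters and the ortholog exception

Paralog Ks values are kept only in the exclusive window (0.05, 1.50):
below 0.05 the signal is dominated by alleles, recent tandems and
annotation artifacts; above 1.50 saturation makes the correction
unreliable. The interspecies single-copy-ortholog workflow, however,
measures a divergence (Ks ≈ 0.02 between close sister species) that sits
*below* the paralog lower bound, so `single_copy_ortholog_ks()` takes its
own bounds with default (0, 1.5) — applying the paralog filter there
would delete the very peak the comparison needs.

## Synteny

Anchors (homolog pairs with gene ranks on both axes) are chained by
dynamic programming within each chromosome pair: a successor must
increase the rank on the A axis and move monotonically on the B axis
(increasing for same-orientation blocks, decreasing for inverted ones),
with both rank gaps in (0, 25]. The chain score is the anchor count —
not a bitscore-weighted sum — which matches the "minimum number of gene
pairs" framing of block definitions and keeps the brute-force oracle
exact. Chains are extracted greedily, best first; ties prefer the same
orientation and then the lexicographically smallest anchor sequence in
canonical (rank_a, rank_b) order, making the output deterministic.
Chains shorter than 5 anchors are discarded; tandem-flagged anchors and
self-pairs are removed before chaining. The maximum rank gap of 25 is a
convention of collinearity tools rather than a published constant; it is
exposed in the config.

A block's age class is the median Ks of its anchors with valid
estimates: *young* in (0.05, 0.6), *old* in [0.6, 1.5) — the trough value
0.6 itself classifies old (left-closed convention, asserted by a test).
Two simplifications are deliberate: the block-similarity ("homo") index
used by some collinearity tools is not reimplemented (median Ks alone
separates the two age classes cleanly on data with two distinct peaks),
and no block-level significance p-value is computed (blocks are filtered
only by the five-anchor minimum). Both are documented choices, not
omissions.

## Trough-split Gaussian fitting

The two-WGD Ks distribution is split at a fixed trough (default 0.6,
chosen by inspection of the valley between the peaks; an automatic mode —
the minimum of a kernel-smoothed density between the two largest modes —
is opt-in via `trough = "auto"`). Each subset gets its own 200-bin
density histogram over its own range, and a three-parameter Gaussian
curve (location, scale, amplitude) is fitted by least squares
(Nelder–Mead, relative tolerance 1e-10), with the location initialized at
the subset median ("median mode") and the scale at half the interquartile
range — both robust to the truncation the split introduces. The fitted
location is the reported peak. Fitting a plain Gaussian to a
trough-clipped sample incurs a small truncation bias; it is accepted
rather than corrected because the fitted peak, not the full density, is
the quantity of interest, and the amplitude being free absorbs most of
the clipping. Subsets below 50 values are refused — a 200-bin density on
fewer points is mostly empty bins and the fit is unstable; the error
message advises pooling data or lowering the bin count.

## Duplication events and retention assignment

A node of a rooted gene tree is a *duplication* iff the species sets of
its two child clades intersect (species overlap) — the same criterion
orthology pipelines use, and the one the downstream filters are designed
around. Full duplication-transfer-loss reconciliation is out of scope.
Candidates then pass four filters, each recording a terminal status so
that accepted + rejected always equals candidates:

* composition: the orthogroup has ≥ 4 genes, contains at least one
  non-ingroup gene, both children carry a focal-species gene, and the
  node is binary (polytomies are rejected — a duplication call on an
  unresolved node is not interpretable as one event);
* support: branch support ≥ 0.5 on the 0–1 scale (values read as
  percentages are divided by 100 first); exactly 0.5 is kept;
* tandem: any focal cross-child pair within 5 gene ranks on one
  chromosome rejects the event ("within the range of five genes" is read
  as rank distance ≤ 5, inclusive and strand-agnostic; the alternative
  reading — five intervening genes — would shift the window by one);
* Ks: the arithmetic mean over valid cross-child focal pair Ks must lie
  in (0.05, 1.50).

Surviving events are assigned σ if a cross-child pair is an anchor of a
young block and ρ for an old block; with hits in both classes, the class
of the anchor whose Ks is nearest the event mean wins (whether such
double hits occur at all depends on the chaining; the tiebreak makes the
rule total). Events with no anchored pair are `rejected_nonsyntenic` —
without synteny there is no evidence the duplicates are WGD-derived.
Retained gene sets are unions of focal genes over accepted events per
WGD; a gene can legitimately appear in both the σ and ρ sets, so raw and
deduplicated union counts are both reported. Reported percentages use
round-half-up at one decimal throughout (`summary_percentages()`), the
convention under which published count/total pairs reproduce exactly.

## TF-family screening

The family × species count matrix is screened before any z-score:
families with fewer than 10 members in *any* species are dropped (small
counts make the normality assumption meaningless), and the remaining
families must pass a Shapiro–Wilk normality test at α = 0.05 (the α is
not prescribed anywhere authoritative; 0.05 is the default and
configurable). A zero-variance family is screened out as non-normal
rather than producing an infinite z. The z-score uses the sample (n−1)
standard deviation — the population convention is a config switch, since
the formula z = (x−μ)/σ does not specify — and z > 1.5 flags enlarged
families. Shapiro–Wilk is delegated to `stats::shapiro.test`.

## Enrichment

Over-representation only (one-sided hypergeometric upper tail, computed
by `stats::phyper`), BH-adjusted. The background is the *annotated*
focal genome: genes without any GO term are excluded from N, because an
unannotatable gene can never contribute a success and would deflate every
p-value. The q-value cutoff of clusterProfiler-style interfaces is
approximated by the BH-adjusted p itself (π₀ = 1) — a deliberate,
conservative surrogate that avoids estimating π₀, which nothing in this
analysis constrains. True-path propagation of annotations to ancestor
terms is applied when a parent-edge table is supplied and skipped
otherwise (both conventions exist in the wild; the choice is explicit,
not hidden).

## The simulator

`simulate_genome()` generates the statistical structure the analysis
assumes, with ground truth attached: an ancestral gene order on
`n_chromosomes` × `genes_per_chromosome` genes; one duplication of every
chromosome per WGD event (the duplicate appended as a new chromosome,
lost genes removed, ranks recomputed — which yields the clean 2:1
dot-plot structure real paleopolyploid genomes show in their
least-rearranged regions); retention probabilities per duplicate,
elevated for designated TF families; tandem duplicates inserted adjacent
to their source gene; a close sister species sharing both WGDs
(orthologs at Ks ≈ 0.02) and an unduplicated outgroup (Ks ≈ 1.3, beyond
the old WGD but below saturation). Codon sequences evolve along the true
gene tree: synonymous and nonsynonymous substitution counts per branch
are Poisson with means ds·S and dn·N (S, N the κ-weighted site counts of
each codon), applied as κ-biased single-nucleotide changes that never
create stop codons. This parameterisation — counts drawn to match the
target rather than an acceptance ratio ω on proposals — realises the
same mutation–selection process but guarantees the property the
estimator tests need: realised dS equals its target in expectation.
Targets at or above 3 substitutions per site are refused as saturated.
Branch supports are drawn in [0.5, 1] with a configurable fraction
(default 0.15) in [0, 0.5) to exercise the support filter.

Default conditions are the study conditions: two WGDs at Ks depths 0.27
and 0.97 with background retention 0.25 and 0.10, TF retention 0.5, 5
chromosomes × 120 genes, 3 species, tandem rate 0.05 at Ks 0.10,
ortholog Ks 0.02, κ = 2, ω = 0.2, CDS lengths 150–250 codons. A WGD
depth must exceed the ortholog divergence: the simulator's event order
(WGDs before speciation) cannot express a duplication younger than the
species split, so a near-zero WGD depth is simulated with a
correspondingly smaller ortholog divergence.

What the simulator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: genome rearrangement after
WGD (blocks are maximally clean), gene loss biased by dosage rather than
i.i.d. retention draws, rate variation among genes and lineages, indels
(all family members keep equal length, so alignment error is absent),
annotation error, and assembly artifacts. Recovery rates on simulated
data are upper bounds on real-data performance.

## Numerical and testing choices

Determinism: one seed fixes the whole dataset byte-for-byte; the
pipeline itself is deterministic given its inputs, so rerunning a config
reproduces every output file. All randomness in tests is seeded.

Problem sizes in the test suite are chosen for desk-scale runs: the
shared end-to-end fixture uses the default 600-family genome once per
test run (~30 s); estimator-recovery tests use 300–500 codons and tens
of replicates; oracle-equivalence tests run exact comparisons on ≤ 20
codons, ≤ 8 anchors, and N ≤ 30 hypergeometric grids, where exhaustive
enumeration is feasible. The enrichment null-calibration test uses
K/N = 0.2, n = 200 — parameters where the discrete hypergeometric's
achievable significance level is close to nominal, so the empirical
rejection rate is a meaningful check of calibration rather than of
discreteness.

## Known limitations

Only counting estimators are provided (no codeml-style ML); the number
of WGDs is an input (two subsets from one trough), not model-selected;
block detection has no significance model; the retention assignment
trusts block classification, so a misclassified block propagates; and
the q-value surrogate makes the `q_cutoff` redundant with `p_adj_cutoff`
unless a true π₀ estimator is substituted.
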