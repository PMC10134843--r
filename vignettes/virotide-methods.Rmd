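---
title: "Methods: viral community dynamics across a macroalgal bloom"
author: "virotide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viral community dynamics across a macroalgal bloom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virotide)
```

## Scope and model of the data

`virotide` implements the computational chain used in time-series viral
metagenomics of coastal bloom systems: assembled contigs are screened for
viral origin with a rule over upstream tool scores, dereplicated into viral
operational taxonomic units (vOTUs), quantified as transcripts per million
(TPM), classified by the temporal shape of their abundance, linked to
candidate hosts through three independent evidence channels, and placed in
gene-sharing and co-occurrence networks. The sampling design the package
emulates is three coastal stations (ZQ, MS, XG) sampled on six Julian days
(165, 181, 193, 208, 243, 271) spanning the arrival and demise of an *Ulva
prolifera* green tide, with one of the eighteen libraries missing
(seventeen libraries in total).

Heavy upstream steps — read QC, assembly, read mapping, and the scoring
tools themselves (VirFinder-, VirSorter-, CAT-style classifiers, BLAST,
ARAGORN, CRISPR detection, protein clustering) — are consumed as tables.
The package implements the decisions *over* those tables, plus the
sequence-level primitives (dereplication alignment, spacer matching) that
define its core statistics.

## Viral identification

A contig (minimum 3 kb, enforced) is called viral when any of four
criteria holds: (i) VirFinder-style score ≥ 0.9 with p < 0.05;
(ii) VirSorter-style category in {1, 2, 4, 5}; (iii) score ≥ 0.7 with
p < 0.05 and category in {1..6}; (iv) a CAT-style annotator calls it a
virus. Comparisons are `>=` for scores and strictly `<` for p-values,
exactly as the thresholds are conventionally printed. A missing field
fails every clause that uses it rather than erroring, since the upstream
tools do not score every contig; category 6 can only contribute through
criterion iii. The call is by construction the OR of the four criteria
evaluated independently, and the test suite checks this against a
separate per-criterion evaluation on a dense grid of inputs.

## Dereplication into vOTUs

Contigs are clustered greedily, longest first (ties broken by id): each
contig joins the first established representative it matches at ≥ 95%
nucleotide identity over ≥ 80% of the shorter sequence, else founds a new
vOTU. This mirrors the first-fit semantics of greedy incremental
clusterers such as CD-HIT rather than best-fit assignment.

The pairwise comparison is a native banded local aligner: exact shared
15-mers seed a diagonal band (densest window of 200 diagonals, padded by
48, capped at 1024), and a Smith–Waterman pass restricted to the band
(match +1, mismatch −1, linear gap −2) yields the best local alignment.
Two definitions are pinned for testability:

* **identity** = matching columns / all aligned columns, gaps included in
  the denominator;
* **coverage** = aligned span on the *shorter* sequence / its length.

Both orientations are tried, since assembly orientation is arbitrary. A
pair sharing no 15-mer is reported as unaligned; at dereplication-grade
similarity (≥ 90% identity over ≥ 2.4 kb) a shared exact 15-mer is
effectively certain, so the prefilter only prunes hopeless pairs and
cannot split a mergeable pair. The aligner is validated against a full
dynamic-programming local-alignment oracle (same scoring) on planted
pairs, and whole greedy partitions are compared against a brute-force
oracle that applies the same greedy rule to exact DP alignments.

## Abundance, diversity, AMGs

Per sample, counts are divided by vOTU length and rescaled to sum to one
million (TPM); each column with any mapped reads sums to 1e6 to within
1e-9 relative tolerance, and TPM is invariant to rescaling a sample's
counts. Alpha diversity uses the natural logarithm: Shannon H, richness
S, and Pielou J = H/ln S (undefined at S = 1), computed through the
standard `vegan` routines and pinned by closed-form tests.

The abundance of an auxiliary metabolic gene (AMG) family in a sample is
the sum over its ORFs of the TPM of the vOTU encoding each ORF. The
upstream phrase "normalizing to the abundance of the vOTUs in which it
was encoded" admits other readings (dividing by vOTU count or length);
inheritance of the parent vOTU's TPM is the reading adopted here because
it keeps ORF abundance on the same scale as the community matrix and
makes the family-level sum a plain weighted ORF count. Families with no
ORFs are absent rows, not zeros.

## Peak typology

For each vOTU and station, a day belongs to a peak when that day's TPM is
strictly greater than the vOTU's own mean over the days with data. The
boolean pattern over the six days is labelled:

* `single1`–`single3`: exactly one above-mean day, in day group
  G1 = {165, 181}, G2 = {193, 208}, or G3 = {243, 271};
* `single4`: exactly the pattern {165, 271} — one peak at each end;
* `wide1`–`wide3`: one contiguous run of 2–3 consecutive *sampled* days,
  subtyped by the group containing the run's first day;
* `several`: all other patterns (non-contiguous sets other than
  {165, 271}, and runs of ≥ 4 days);
* `flat`: no above-mean day — a constant series. The strict inequality
  forces this class to exist mathematically even though bloom-affected
  communities rarely realize it.

Open choices resolved here, configurable in principle but fixed for
reproducibility: adjacency is defined on consecutive sampled days, not
calendar gaps; "wide" means runs of exactly 2–3 days so that wide stays
narrower than most of the series; a run starting at day 165 or 181 is
`wide1` (the G4 = {165, 271} group only ever labels the two-day single4
pattern, so a `wide4` label is reachable only under alternative rule
sets); classification is per station, matching per-station composition
summaries, with a pooled mode behind a flag. The classifier is a total
function on the 64 possible patterns and is tested exhaustively against
an independently written decision table.

## Ordination

PCA is the column-centered SVD of the sample × vOTU matrix after a
Hellinger transform (square root of sample relative abundances), the
standard variance-stabilizing choice for compositional community data;
axis proportions are squared singular values over their total. CCA is the
textbook chi-square formulation — chi-square standardized community
matrix, weighted least-squares projection onto the environmental
variables, eigen-analysis of the fitted matrix — computed through
`vegan::cca()`. Descriptions of "CCA based on Bray–Curtis
dissimilarities" in the field literature are internally unusual (CCA is
chi-square-based by definition); this package implements the textbook
form and records that choice here. Both ordinations are verified against
dense (generalized) eigen-decomposition oracles to 1e-8.

## Virus–host linkage

Three evidence channels, each with the thresholds fixed:

* **homology**: hits from vOTUs ≥ 5 kb kept when query coverage ≥ 75%,
  identity ≥ 70%, bit score ≥ 50 and E ≤ 1e-5, all simultaneously;
* **tRNA**: reciprocal best alignment between a viral and a host tRNA
  covering ≥ 90% of both sequences at ≥ 90% identity;
* **CRISPR spacer**: a full-length occurrence of the spacer on either
  strand of the vOTU with at most one substitution. Matching is an exact
  scan without indels; at spacer lengths (20–60 nt) the conventional
  E-value screen is subsumed by the mismatch bound, and the scan is
  verified against an offset-by-offset sliding-window oracle.

Evidence is unioned per vOTU; a vOTU linked to ≥ 2 distinct host classes
is labelled `broad`, otherwise `narrow`. How conflicting channels should
be reconciled is not standardized; unioning is the minimal choice and is
recorded on each link (channels and classes are both reported).

## Networks

The gene-sharing similarity of two genomes with protein-cluster (PC)
sets A and B in a universe of N PCs is the exact upper hypergeometric
tail P(X ≥ |A∩B|), and the edge score is −log10(p × number of pairwise
comparisons), floored at zero. The tail is computed exactly (no normal
approximation) and matched against explicit binomial-coefficient
enumeration for every configuration with N ≤ 30. Viral clusters (VCs)
are connected components of the thresholded graph: the upstream
convention runs a dedicated graph clusterer (ClusterONE/MCL) here, but
only the similarity score is actually specified by the method; components
are deterministic, testable, and a pluggable interface is left for
alternatives. The drawing threshold (default score ≥ 1) is a documented
choice. Genomes under 10 kb are excluded when lengths are supplied.

VC–host co-occurrence uses Pearson correlation over shared samples with
the two-sided p-value from t = r √((n−2)/(1−r²)) on n−2 degrees of
freedom; edges require |r| > 0.8 AND p < 0.05 (strict, as printed), carry
their sign, and receive no multiple-testing correction — deliberately
mirroring common practice in this literature; treat the edge lists as
exploratory.

## The synthetic scenario generator

Every input the pipeline consumes can be generated with planted ground
truth, so each stage is testable closed-loop without any download.

**Abundance.** Each vOTU draws a peak class from a configurable mixture
and a matching above-mean day set; its true trajectory is a lognormal
baseline (sdlog 0.5) plus a 3× bump on the peak days. Trajectories are
defined at the TPM (length-normalized) scale and renormalized per day.
Because relative abundances are compositional, one vOTU's bump perturbs
every other vOTU's trajectory; amplitudes are therefore boosted
iteratively until, noise-free, every strictly-above-mean day set equals
its class definition. In very small communities (tens of vOTUs) a few
intended patterns can be mutually unplantable under closure; those vOTUs
are relabelled with the class their realized noise-free trajectory
actually has, so the recorded truth always describes the generated data.
Two consequences of closure are worth noting: a `flat` trajectory cannot
be planted at all (a constant-count vOTU still inherits the day-to-day
variation of the denominator), so the mixture excludes it; and the
default mixture (singles 0.47, wides 0.43, several 0.10) makes ~90% of
vOTUs single- or wide-peaked, the regime the typology was designed for.

Counts are drawn per sample by multinomial sampling of `read_depth`
reads (default 1e5, a desk-scale stand-in for real virome libraries)
with probabilities proportional to composition × vOTU length, so TPM
computed from counts consistently estimates the true composition.
Multiplicative lognormal noise with coefficient of variation `noise_cv`
(default 0.2) acts on compositions before sampling — a standard
overdispersion stand-in. At the planted 3× amplitude, class recovery is
100% noise-free and ≈ 91% at cv 0.2; recovery checks use the complete
18-sample design, since with the default missing library (XG, day 243) a
vOTU whose single planted peak falls on the missing day is genuinely
unrecoverable at that station — an instructive property of the design,
not a defect of the classifier.

**Sequences.** Contigs are uniform-random ACGT (3–15 kb by default; no
ambiguity codes, keeping identity unambiguous), including parent–child
pairs planted by substitution at 90/94/96/99% identity with full and
partial (50%, 85%) overlap of the shorter member, children
reverse-complemented with probability 1/2. Tool scores are constructed
so the four-way rule recovers the planted viral flag exactly. Host
artifacts embed exactly one detectable signal per planted link —
a passing homology hit, an identical shared tRNA, or a spacer copied
with 0–1 substitutions — alongside decoys that must not link (hits
failing one threshold, tRNA pairs at 85% identity, spacers with two
substitutions). Environmental series follow the bloom shapes (NH4, SiO3,
NO2 maximal on day 208; NO3 rising to day 271; chlorophyll *a* higher
post-bloom, minimal on day 193) with small fixed station offsets.

**What the generator does not emulate**: real sequence composition
(k-mer structure, repeats), assembly artifacts and chimeras, shared gene
content between unrelated viruses, uneven library sizes, or genuine
ecological covariance between vOTUs beyond the planted classes. Passing
closed-loop tests therefore demonstrates correctness of the decision
rules and statistics, not robustness to every artifact of real viromes.

## Numerical choices and problem sizes

Alignment scoring (match +1, mismatch −1, linear gap −2) is fixed
identically in the implementation and the DP oracle so identities are
comparable; ties between co-optimal alignments may differ by under one
percentage point, hence the 1-point identity / 2-point coverage test
tolerances. Degenerate inputs are defined: all-zero count columns give
all-zero TPM with a warning; single-taxon samples give J = NA;
zero-variance series are skipped in correlation with a warning; constant
environmental columns are an error, collinear ones are dropped with a
warning.

Default test problem sizes were chosen for fast desk-scale runs while
keeping every check meaningful: 300 vOTUs × 3 stations for class
recovery, 50 contigs (2–4 kb) for the clustering-oracle comparison,
100 vOTUs × 20 hosts for the linkage closed loop, ~1e5 null pairs for
the correlation-rate check, all hypergeometric configurations to N = 30.

## Known limitations

The aligner assumes a single dominant alignment diagonal (appropriate
for dereplication, not for rearranged genomes). VCs from connected
components can chain distinct clusters through intermediate genomes in
dense graphs. The correlation network inherits the uncorrected p < 0.05
convention. The peak typology is tied to the six-day design; other
designs need their own day groups. Lifestyle (lytic/lysogenic) calls and
cross-habitat comparisons are out of scope.
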