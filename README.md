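# virotide

Viral community dynamics across a macroalgal bloom: an R toolkit for
time-series viral metagenomics of coastal waters.

When a massive green tide arrives and decays, the bacterial community
turns over and the viruses that prey on it follow. Quantifying that
succession from shotgun viromes takes a chain of small, threshold-dense
decisions between "assembled contigs" and "ecological conclusions", and
each one is easy to get silently wrong. `virotide` implements that chain
as tested, reusable functions:

* **Viral identification** — a contig is viral if any of four criteria
  over upstream tool scores holds: VirFinder-style score ≥ 0.9 with
  p < 0.05; VirSorter-style category ∈ {1, 2, 4, 5}; score ≥ 0.7 with
  p < 0.05 and category ∈ {1..6}; or a CAT-style virus call.
* **Dereplication** — greedy longest-first clustering into vOTUs at
  ≥ 95% nucleotide identity over ≥ 80% of the shorter contig, with a
  native banded local aligner (seeded by shared 15-mers, both strands).
* **Abundance** — TPM per sample (counts / length, rescaled to 1e6),
  Shannon H, richness S, Pielou J = H/ln S.
* **Temporal typology** — each vOTU's above-mean day pattern is labelled
  `single1–4` / `wide1–3` / `several` / `flat` over the six sampled
  Julian days (165–271); per-station class composition tables.
* **Ordination** — Hellinger PCA and textbook chi-square CCA against
  environmental variables, both oracle-tested to 1e-8.
* **Virus–host linkage** — homology hits (coverage ≥ 75%, identity
  ≥ 70%, bits ≥ 50, E ≤ 1e-5, vOTUs ≥ 5 kb), reciprocal-best tRNA
  matches (≥ 90% length, ≥ 90% identity), and CRISPR spacers (≤ 1
  substitution, either strand), unioned into links with narrow/broad
  host-range labels.
* **Networks** — gene-sharing edges scored as
  −log10(P(X ≥ k) × n_comparisons) with an exact hypergeometric tail;
  viral clusters as connected components; VC–host co-occurrence edges at
  |r| > 0.8 and p < 0.05 with sign.
* **Synthetic scenario generator** — every input above can be generated
  with planted ground truth (peak classes, boundary contig pairs,
  host links with decoys, bloom-shaped environmental series), so the
  whole pipeline is testable closed-loop with no external data.

See `vignettes/virotide-methods.Rmd` for the model, the resolved
ambiguities, and the generator's design.

## Worked example

Simulate the bloom design (3 stations × 6 Julian days, one library
missing), normalize, and classify every vOTU's temporal pattern:

```r
library(virotide)
cfg <- scenario_config(n_votus = 200, seed = 1)
g   <- generate_abundance(cfg)
ab  <- tpm(g$counts, g$lengths)
head(round(ab[, 1:4], 1), 3)
#>            MS_165  MS_181  MS_193  MS_208
#> vOTU_0001 15196.3 11592.5  2511.5  3729.1
#> vOTU_0002  1671.6  1257.8   935.9  1923.6
#> vOTU_0003  5111.2  7169.4 29532.7 23081.0
```

Every column sums to one million: TPM is a composition. Peak classes per
station, and how well they recover the planted truth:

```r
pk <- peak_classes(ab, g$samples)
head(pk, 3)
#>     votu_id station   label     pattern
#> 1 vOTU_0001      MS   wide1     165;181
#> 2 vOTU_0002      MS single3         243
#> 3 vOTU_0003      MS   wide2 193;208;243
mean(pk$label == g$truth$votu_peak_class[pk$votu_id])
#> [1] 0.855
```

`vOTU_0002` peaks after the bloom (day 243, `single3`); `vOTU_0003`
rises with the bloom's demise (`wide2`). Recovery is 85.5% here because
the default design drops the XG day-243 library — a vOTU whose only peak
falls on the missing day cannot be recovered at that station — and
because multiplicative noise (cv 0.2) flips a few patterns; it is 100%
on the complete noise-free design. Diversity per sample:

```r
head(diversity_table(ab), 3)
#>   sample        H         J   S
#> 1 MS_165 4.927020 0.9299217 200
#> 2 MS_181 4.884682 0.9219308 200
#> 3 MS_193 4.909567 0.9266276 200
```

The gene-sharing score for two genomes sharing 2 of their 3 and 4
protein clusters in a universe of 10:

```r
hypergeom_score(c("a","b","c"), c("a","b","d","e"), N = 10,
                n_comparisons = 1)
#> $k       2
#> $p_hyper 0.3333333   # exact tail, equals [C(3,2)C(7,2)+C(3,3)C(7,1)]/C(10,4)
#> $score   0.4771213
```

The full pipeline — simulate → identify → cluster → abundance →
dynamics → hosts → networks — runs with one call and writes plain-text
tables plus a manifest with per-stage counts and output hashes:

```r
run_pipeline(scenario_config(seed = 1), "out/")
```

A thin command-line front end with per-stage subcommands is installed at
`inst/cli/virotide.R`:

```sh
Rscript inst/cli/virotide.R run-all --dir out --seed 1
Rscript inst/cli/virotide.R simulate --dir out --n-votus 300
Rscript inst/cli/virotide.R identify --dir out
```

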