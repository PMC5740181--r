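---
title: "Pooled-sequencing BSA for quantitative traits: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-sequencing BSA for quantitative traits: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

## The problem and the statistic

Cocoon shell weight (CSW) in the silkworm is the standard proxy for a
strain's capacity to synthesise silk proteins. It is a quantitative trait,
and one productive way to map its loci is bulked segregant analysis (BSA)
of a backcross: cross a low-silk inbred line to a high-silk line, backcross
the F1 males to the low parent, phenotype the BC1 males, and sequence two
DNA pools made from the phenotypic extremes. At a marker linked to a CSW
locus the two pools differ in allele representation; at an unlinked marker
they do not.

In a BC1 every individual is either homozygous for the recurrent-parent
allele (`aa`) or heterozygous (`ab`). Pooled sequencing of a marker yields
four depth counts: `Maa`, `Mab` for the low pool and `Paa`, `Pab` for the
high pool. The scan statistic is built from the *SNP-index* of each
genotype channel,

$$\mathrm{SNP\_index}(aa) = \frac{M_{aa}}{P_{aa}+M_{aa}}, \qquad
  \mathrm{SNP\_index}(ab) = \frac{M_{ab}}{P_{ab}+M_{ab}},$$

and their contrast
$\Delta = \mathrm{SNP\_index}(aa) - \mathrm{SNP\_index}(ab)$. Both indices
are the *low pool's share* of a channel's total depth, so an unlinked
marker has both indices near 0.5 and $\Delta$ near 0, while at a marker
linked to a CSW locus the low pool is enriched for the recurrent
homozygote and depleted of heterozygotes, pushing $\Delta$ positive. Each
marker's $\Delta$ is standardised against the genome-wide location and
spread,

$$Z_i = \frac{\Delta_i - \mu_0}{\text{scale}}, \qquad
  \mu_0 = \overline{\Delta},$$

converted to a normal upper-tail p-value ($p = 1-\Phi(Z)$ for the scan),
adjusted for multiple testing, and called linked below an adjusted-value
threshold of 0.05.

## Two standardisation scales, and why the default pipeline uses "classic"

`z_scores()` offers two scalings. The verbatim form divides by
$S/\sqrt{n}$, with $S$ the spread of all $\Delta$ and $n$ the number of
markers — a one-sample Z-test form in which $|Z|$ grows with the marker
count: with thousands of markers, half the genome becomes "significant".
It is retained (`z_mode = "verbatim"`) because published scan tables were
produced with this family of formulas and the package must reproduce their
arithmetic. The ordinary standardisation (`z_mode = "classic"`, divide by
$S$) makes null Z scores approximately standard normal, and is the default
everywhere the package does inference on simulated data. The scan object
records which was used.

Two details are deliberate:

* **S is the sample standard deviation.** The source methodology calls $S$
  "the variance" while writing the standard-error form $S/\sqrt{n}$; only
  the standard deviation gives a dimensionally consistent z-like score, so
  that is what the package computes.
* **The two-sided p is uncapped.** Confirmation-stage p-values are
  $2(1-\Phi(Z))$ with no folding through $|Z|$ and no cap at 1, so a
  negative Z yields $p > 1$. This odd-looking convention is exactly what
  published confirmation tables print (values like 1.82), it preserves
  $p(z) + p(-z) = 2$, and the classification rule below only ever compares
  p-values with each other.

## Multiple testing: "Bonferroni" that is arithmetically BH

The methodology this package follows *names* Bonferroni, but its published
outcome — 14 markers called at 0.05 whose largest raw p is
$7.03\times10^{-5}$ among 9,143 tests — is impossible under Bonferroni
($7.03\times10^{-5} \times 9143 = 0.64$) and exact under Benjamini–Hochberg
step-up ($7.03\times10^{-5} \times 9143/14 = 0.046$). The package therefore
defaults to BH with an explicit `n_tests` (supporting p-value lists that
are only the smallest few of a larger scan), keeps Bonferroni available,
and prints the discrepancy in every scan summary and in `table1_demo()`
rather than resolving it silently. Adjusted values are left uncapped; the
linked call uses a strict `fdr < threshold`.

```{r}
demo <- table1_demo()
demo
```

## Confirmation by individual genotyping

Pooled sequencing can mis-state allele frequency (unequal DNA contribution
per individual, depth sampling), so each putative linked marker is
confirmed by genotyping an Indel within ±15 kb in every pooled individual.
The four counts are now *individuals*, not reads; the same index/Z/p
machinery applies, with a two-sided p. A marker is confirmed **positive**
iff its Indel p is strictly smaller than its scan p — the only decision
rule that reproduces the published 8-positive/6-false-discovery split
(plain thresholds fail on rows where both p-values are small). Ties go to
false discovery; printed zeros in the worked example are treated as
underflow ($p < 5\times10^{-10}$) and compared on the computed float.

One genuinely open choice is which $\mu_0$ and $S$ the Indel Z should be
standardised against. `indel_index_test()` self-standardises over the
supplied Indel set by default, but `confirm_markers()` — the
pipeline-facing wrapper — standardises against the *scan's* $\mu_0$ and
$S$ (`reference = "scan"`). Two reasons. First, the published numbers are
magnitude-consistent with exactly this: the 14 tabulated BSA Z values
(3.9–4.9) span precisely the range of the top order statistics of 9,143
standard normals, and Indel deltas near 1 over a scan-level spread of
~0.06 give the tabulated Indel Z of 10–12. Second, self-standardisation
degenerates when the confirmed set is homogeneous — if every supplied
Indel sits on the same true QTL, their deltas are all large and similar,
$\mu_0$ swallows the signal, and the stage would reject exactly the
markers it should confirm. Judging each Indel delta against the
genome-wide null spread is the comparison the stage is for. The same
logic applies to `flank_support()`, which standardises over the full
genotyped Indel table before reporting the flanking subset.

## The synthetic BC1 generator

`cross_design()` + `simulate_bc1()` generate the data structure the
analysis assumes, at the study's own scale by default:

| parameter | default | meaning |
|---|---|---|
| `n_families` | 7 | single-pair matings ("moth areas") |
| `family_size_range` | 127–174 | BC1 males per family |
| `pool_fraction` | 0.10 | per-tail selection fraction, per family |
| `mean_depth` | 245 | pooled reads per marker per pool (Poisson) |
| `phenotype_noise_sd` | 0.05 g | residual CSW noise |
| `baseline_csw` | 0.35 g | recurrent-parent mean CSW |
| `n_chromosomes`, `chrom_length_cm` | 28, 50 cM | map geometry |
| `marker_spacing_cm` | 5 cM | marker grid |
| `bp_per_cm` | 300 kb | physical scale |

Gametes follow a Markov chain along each chromosome with Haldane
recombination fractions $r = \tfrac12(1-e^{-2d/100})$; QTLs may sit
between markers (simulated as hidden loci). Phenotype is baseline plus an
additive shift per heterozygous QTL genotype plus Gaussian noise. The
defaults for the map and phenotype scale are choices, not published
values: 28 chromosomes of 50 cM at the 300 kb/cM conversion give a genome
of the right order (~420 Mb), a 0.35 g baseline with 0.05 g noise puts CSW
in the range silkworm strains actually span, and the "2 SD" planted QTL
used in calibration studies is then a 0.1 g effect.

Pool selection is per family (removing between-family phenotype shifts),
takes exactly `floor(fraction * n)` individuals per tail (minimum 1), and
orders by (phenotype, index) — a stable order whose first and last blocks
are the two tails, so fraction 0.5 partitions a family and all-equal
phenotypes degrade to index order.

**Read-assignment conventions.** Published pool depths are labelled by
genotype (`aa`/`ab` channels), which is ambiguous for reads. The default
`"allele"` convention observes alleles only: `aa` individuals emit `a`
reads, heterozygotes emit `a` and `b` equally, `a` reads land in the `aa`
channel. Its signature limit: perfect selection drives $\Delta$ to $2/3$,
not 1, because the high pool's heterozygotes still emit `a` alleles
($\mathrm{index}(aa) = D/(D + D/2) = 2/3$, $\mathrm{index}(ab) = 0$). The
alternative `"dosage"` convention attributes reads to the emitting
genotype class, splitting heterozygote reads half-and-half
deterministically (odd read to `aa`). For BC1 pools the `aa`-channel mean
is the same under both; only heterozygote sampling noise differs. Note
that *individual genotype counts* (the confirmation stage) are not
subject to the 2/3 cap — a perfectly selected marker has delta 1 — which
is precisely the asymmetry that lets confirmation beat the scan's p-value
at a true locus.

**What the generator does not emulate:** restriction-site marker ascertainment
and its uneven genome coverage, unequal per-individual DNA contribution to
pools, sequencing error beyond a symmetric per-read flip, overdispersed
depth (the Poisson default is deliberately the simplest model),
segregation distortion, and epistasis. Passing calibration tests on this
generator therefore show the *statistics* behave as designed, not that
real pooled SLAF data meet the assumptions.

## Cluster statistics

Differentially expressed genes are tested for genomic clustering against
a uniform-placement null. Adjacent-gene intervals are computed per
chromosome on sorted midpoints; the expectation is `genome_size /
n_genes` (genome-wide, verbatim from the methodology); ratios below 1 and
below 0.1 are reported with strict inequalities. A cluster is a maximal
run of ≥3 consecutive genes whose every adjacent interval is strictly
below the threshold. Two threshold conventions circulate for the same
analysis — 30 kb absolute (roughly the average silkworm gene interval)
and 10% of the expected interval — so `cluster_report()` computes both
and flags disagreement instead of picking one silently.
`cluster_null_test()` formalises "more clustered than expected" by
re-placing the observed per-chromosome gene counts uniformly and reporting
seeded empirical p-values with the +1 correction. Under uniform placement
spacings are approximately exponential, so the below-0.1 fraction tends to
$1 - e^{-0.1} \approx 0.095$ — a closed-form oracle the test suite checks
at $10^5$ genes.

## Expression–phenotype association

With 12 strains and a handful of instar days, distributional assumptions
are hard to defend, so permutation tests are the default inferential
engine (10,000 label permutations, seeded, +1-corrected), with the
classical statistics (Pearson/Spearman correlation, Welch t) reported as
the test statistics. Temporal association correlates expression with
daily gland-volume increments and with their negative (both
growth-tracking and anti-tracking patterns occur among real candidates);
strain association offers a Spearman-correlation mode and a median-split
mode, the split falling back to correlation when all phenotype values tie.
The published analysis reports significance without naming a test or its
grouping, so both the engine and the median split are package choices.

## Numerical conventions, in one place

* Coordinates are 1-based inclusive throughout; conversion to BED's
  0-based half-open happens only at the file boundary (`export_bed()`).
* Coverage filter: total depth strictly greater than `min_coverage`
  (default 5), per "more than 5×".
* Markers with a zero-depth channel are excluded with a logged reason,
  never imputed, and never enter $\mu_0$, $S$ or $n$.
* Candidate regions are ±150 kb windows (300 kb total, ~1 cM) centred on
  confirmed markers, clipped at 1 and at the chromosome end when lengths
  are known, merged when overlapping or exactly adjacent.
* Gene-in-region membership is any-overlap (≥1 bp), not containment.
* EST screening requires count > 0 in *every* required tissue; a missing
  tissue key counts as 0; an empty requirement set is vacuous.
* All thresholds (`fdr < t`, interval `< threshold`, ratio `< 0.1`) are
  strict.
* One master seed per design; every stochastic stage derives a child seed
  deterministically, so pipeline reruns are byte-identical.

## Problem sizes used by the checks

The calibration and recovery studies run at the design defaults (7
families of 127–174 males, ~1,000 individuals, 308 markers, 245× depth):
100 replicates for the null type-I check, 50 for QTL recovery, $10^5$
genes for the spacing oracle and $10^4$ for the brute-force cluster
comparison. These sizes make the Monte-Carlo error small relative to the
margins being asserted while keeping a full run in the tens of seconds.

## Known limitations

* The verbatim `verbatim` scaling is reproduced, not endorsed; it has no null
  calibration and the package will not use it for simulation-based
  inference unless asked.
* The published BSA p-value column of the worked example is *not* a
  monotone function of its BSA Z column, so no single Z→p rule can
  reproduce it; only the Indel confirmation column reproduces exactly,
  and the package asserts only that.
* Published genome-wide cluster figures (77.8% of pairs closer than
  expected, 114 clusters) depend on a specific DEG compilation and
  annotation build that are not distributable inputs; the pipeline
  computes the same summaries for any user-supplied DEG list, and its
  correctness is asserted against closed-form and brute-force oracles
  instead.
* No sliding-window smoothing of $\Delta$; the methodology tests single
  markers, and so does the package.
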