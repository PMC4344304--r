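---
title: "Methods: MEM-based miRNA quantification and m6A motif discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEM-based miRNA quantification and m6A motif discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memir)
```

## The analysis

memir implements the computational arm of an m6A (N6-methyladenosine) survey
of mature microRNAs. The experimental design it serves has two branches:

* **Knockdown branch.** Cells depleted of an m6A demethylase (three
  knockdown/scrambled-control pairs) are profiled by small-RNA sequencing;
  miRNAs that lose expression after knockdown are candidates for
  methylation-dependent regulation.
* **RIP branch.** RNA immunoprecipitated with an anti-m6A antibody versus an
  IgG isotype control (three replicate pairs) identifies miRNAs whose
  molecules carry the mark.

Both branches reduce to the same computational chain: adapter removal,
assignment of short reads to a mature-miRNA catalog, reads-per-million
normalization, threshold calls, and finally a discriminative motif search
that asks whether the immunoprecipitated miRNAs share a sequence context —
the methyltransferase consensus RRACH (R = A/G, H = A/C/U) and its core RAC
being the expected answer.

Because no raw sequencing data accompanies the study this package serves, a
first-class synthetic-data generator reproduces the statistical structure the
analysis assumes, and every stage is validated against it plus independent
brute-force oracles.

## Adapter trimming

Mature miRNAs (19–27 nt) are shorter than the 50-bp reads, so each miRNA read
runs into the 3' adapter `TGGAATTCTCGGGTGCCAAGG`. `trim_adapter()` considers,
for every read position p:

* the **full adapter** starting at p with the trailing read free, and
* every **adapter prefix** of length ℓ ≥ `min_overlap` (default 4) flush with
  the read's 3' end.

A placement is admissible when its unit-cost edit distance e (substitutions,
insertions, deletions) satisfies e ≤ floor(`max_error_rate` × aligned adapter
length), with the default rate 0.20 — so up to floor(0.2 × 21) = 4 errors for
the full adapter. The error budget is *floored* at fractional products; 4/21
(19%) is admissible, 5/21 (23.8%) is not. Among admissible placements the one
with the most matched bases wins, ties going to fewer errors and then to the
smallest start. Selecting on matched bases rather than on the leftmost
admissible start is deliberate: with free leading insertions an exact adapter
occurrence would otherwise lose to a noisy placement a few bases earlier, and
matched-base maximisation is also how the standard 3'-trimming tools resolve
the same ambiguity.

One boundary effect is worth knowing: when the adapter's first base is
sequenced wrongly and the insert happens to end with that same base, the
insert's final base and the adapter's first are genuinely indistinguishable,
and the trimmer (like any edit-distance trimmer) may shift the boundary by
one. The recovery tests therefore plant errors strictly inside the adapter.

Trimmed reads shorter than 16 bp are discarded (`too_short`); reads of
16–28 bp are `candidate` mature-miRNA reads; anything longer — including
untrimmed 50-bp reads — is `too_long` and excluded from counting.

## The reference catalog

`parse_mature_fasta()` reads a miRBase-style mature FASTA (uppercased, T→U,
order preserved). `collapse_identical()` merges entries with byte-identical
sequences into one entry named after the lexicographically smallest member,
retaining full membership — the catalog therefore contains pairwise-distinct
sequences. `add_spikes()` appends the three knockdown siRNAs, their reverse
complements, and the scrambled control with its reverse complement, flagged
`is_spike`, so that siRNA-derived reads are captured by a reference of their
own and kept out of the miRNA totals. The catalog is stored in the RNA
alphabet; matching canonicalises U→T so DNA reads compare directly.

## Read assignment by maximal exact matches

A **MEM** of a read r against a reference s is an interval [p, p+L) of r
whose substring occurs in s while neither the left- nor the right-extended
substring does. Assignment uses two thresholds: each MEM must have L ≥ 7, and
the union of qualifying MEM intervals must cover ≥ 17 bp of the read for a
reference to be eligible. Among eligible references the one with the most
matching basepairs (the same union size) wins; residual ties go to the
lexicographically smallest reference name and are flagged. A 16-bp read is a
legal candidate yet can never reach 17 bp of coverage; such reads are
reported unassigned, keeping both stated rules intact.

The implementation seeds candidate references through a shared-7-mer index
and computes MEMs from longest-match arrays in C++; its contract is exact
equality with a brute-force oracle that enumerates every (interval,
occurrence, extension) triple, which the test suite checks on 1,000 random
read/reference pairs (twice — once per module suite, once in the acceptance
properties).

## Normalization and threshold calls

Counts are normalized to **reads per million mapped miRNA reads**: each
sample's cells are scaled by 10⁶ over the per-sample sum of *non-spike*
rows; spike rows are scaled by the same denominator but never contribute to
it. Whenever any non-spike reads were mapped, the non-spike RPM column sums
to 10⁶ exactly.

Calls follow the protocol thresholds literally, with "at least" rules
inclusive (≥) and fold-change rules strict (> or <):

* **expressed** — ≥ 15 RPM in every scrambled-control sample;
* **down** — controls ≥ 15 RPM in all three pairs and mean fold change
  (knockdown/control, mean of the three per-pair ratios) strictly below 0.5;
* **up** — knockdowns ≥ 15 RPM everywhere and mean fold change above 2
  (status is also reported at the secondary 1.5-fold setting, where "down"
  uses the reciprocal bound 1/1.5);
* **methylated** — every m6A-IP replicate ≥ 100 RPM and mean per-replicate
  enrichment (IP + 1)/(IgG + 1) ≥ 2, reported sorted by mean enrichment with
  its standard deviation.

Two numerical choices deserve a note. Fold changes are **means of per-pair
ratios** (reported with SD), not ratios of means. The 1-RPM pseudocount is
applied unconditionally inside the RIP enrichment ratio, but in the
knockdown ratio only when the control is zero — this keeps a knockdown pair
at exactly half its control at a mean fold change of exactly 0.5, which the
strict "fewer than 50%" rule then correctly declines to call down.

## Discriminative motif search

The motif spaces are parameterised as **k-x-y-n**: length-k strings over the
15-letter IUPAC alphabet with at most x twofold-degenerate characters
(R,Y,K,M,W,S), at most y threefold characters (B,D,H,V) and at most n Ns.
`enumerate_motif_space()` generates each admissible string exactly once in
lexicographic order. Direct enumeration of the three scanned forms gives
2464 (3-2-2-0), 37248 (4-2-2-1) and 571904 (5-3-2-1) — each exactly two
below the previously published sizes (2466/37250/571906); the difference is
below 0.1% and the inclusion–exclusion closed form confirms the enumeration,
so the two extra patterns in the original counts remain unexplained here.

Each motif is scored on per-sequence **containment** (occurrence
multiplicity is ignored) in the immunoprecipitated set versus the remaining
set, forming a 2×2 table. Two p-values are attached:

* **Fisher exact, two-sided (point-probability method)** — the sum of
  hypergeometric probabilities of all tables with the observed margins that
  do not exceed the observed table's probability (relative tolerance 1e-7),
  Bonferroni-corrected by the size of the scanned space. This is the
  acceptance-bearing statistic.
* **Background-model p-value** — an order-(k−1) Markov text model is
  estimated from the background set's k-mers with add-one smoothing;
  for each IP sequence the probability of ≥ 1 motif occurrence is computed
  exactly by dynamic programming over (position, last k−1 bases), and the
  upper tail of the resulting Poisson-binomial count (by convolution,
  grouped by sequence length) gives the p-value. This is a deliberately
  transparent surrogate for the compound-distribution machinery of the
  original motif-discovery software, which is documented only by citation;
  the two rankings agree closely in practice and only the Fisher ranking is
  relied upon.

For throughput, a scan precomputes each sequence's k-mer presence set once;
a motif's containment vector is the union of the presence columns of its
concrete expansions (at most 2^x·3^y·4^n of them), obtained as one matrix
product per chunk of motifs, and Fisher p-values are cached per distinct
table since the margins are fixed across a scan.

## The synthetic experiment

`sim_config()` pins the simulated study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_refs` | 300 | catalog size |
| `ref_len_range` | 19–27 nt | mature miRNA lengths, uniform |
| `methylated_fraction` | 0.25 | references flagged methylated |
| `planted_motif` | `GGACU` | RRACH instance written into methylated refs |
| `motif_plant_rate_ip` | 0.6 | fraction of methylated refs carrying it |
| `ip_enrichment_fold` | 8 | m6A-IP weight multiplier for methylated refs |
| `kd_down_fold` | 0.4 | knockdown weight multiplier for methylated refs |
| abundance | log-normal, meanlog log(100), sdlog 1.5 | per-ref base weight |
| `reads_per_sample` | 50,000 | multinomial draws per sample |
| `error_rate` | 0.005/base | substitution-only sequencing error |
| `no_adapter_rate` | 0.02 | fully random 50-bp reads |

Reads are built as insert (U→T) + adapter + random padding to 50 bp with a
constant quality string. All distributional choices are inventions — the
study deposited no raw data — chosen as a scientist would parameterise a
plausible small-RNA library: log-normal abundances spanning ~3 orders of
magnitude, error rates typical of modern short-read chemistry, a small
adapter-free fraction standing in for junk reads. One global seed derives a
deterministic substream per sample, so a run is byte-reproducible.

What the simulation does *not* model: indel sequencing errors, quality-score
structure, isomiR end-heterogeneity, sequence-composition biases of ligation
and PCR, and catalog cross-homology (real miRNA families share seeds;
random 19–27-mers rarely collide). Passing the recovery tests therefore
demonstrates the pipeline's internal correctness under its own assumptions,
not its field performance on real libraries.

At the default scale, one pipeline run (12 samples × 50,000 reads, 300
references) takes about two minutes on one CPU; the test suite runs the full
default-scale recovery once and scales everything else down (40 references,
~2,500 reads) to keep iteration fast. On the default conditions the planted
methylated set is recovered with sensitivity ≥ 0.9 at a false-discovery
proportion ≤ 0.1, and a 3-2-2-0 scan of the called set ranks the planted
motif's core (GAC, typically as itself or a matching generalization such as
RAC/GWC) first with Bonferroni-significant p.

## Downstream statistics

`pearson_r()` provides the product-moment correlation with the
ordinary-least-squares line for the log2(enrichment) versus
log2(knockdown fold change) scatter; `shapiro_wilk()` wraps the Royston
algorithm of `stats::shapiro.test()`. The reference analysis's headline numbers
on these axes (a near-zero correlation, a strongly non-normal
fold-change distribution, ~92% of methylated miRNAs down after knockdown)
depend on the unreleased sequencing data; the package demonstrates the same
qualitative behaviour on synthetic data (the correlate stage reports the
fraction down, the correlation and both test statistics) but asserts no
numeric reproduction.

## Degenerate inputs and tie rules, collected

* All-zero sample → all-zero RPM column plus a warning, never NaN.
* Zero IgG RPM → finite enrichment through the pseudocount.
* Collapsed catalog entries take the lexicographically smallest member name.
* Assignment ties take the lexicographically smallest reference name and are
  flagged; the rule is order-free, so catalog permutations cannot change a
  call.
* Motif ranking sorts by ascending Fisher p, ties by ascending pattern.
* A motif longer than a sequence never matches; an empty IP set is an error,
  not an empty report.

## Known limitations

* The two-pattern discrepancy in the published motif-space sizes is
  documented, not resolved.
* The background-model p-value is a surrogate, not a reimplementation, of
  the original compound-Poisson machinery.
* Motif scans with k > 5 are outside the supported envelope (space growth is
  exponential; the chunked scanner keeps memory flat but time grows with the
  space).
* Real-data effects listed under the simulation's non-goals are untested by
  construction.
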