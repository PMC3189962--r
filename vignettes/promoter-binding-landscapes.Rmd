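---
title: "Promoter binding landscapes: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter binding landscapes: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promobind)
```

# The analysis in one paragraph

`promobind` characterizes where two transcription factors bind relative to
transcription start sites (TSSs) in promoter-array (ChIP-on-chip style)
data. The motivating biology is a pair of factors with qualitatively
different binding geometry: an OTX2-like homeodomain factor whose aggregate
binding is *bimodal* around the TSS (an upstream mode near −250 bp and a
downstream mode near +650 bp, with many promoters carrying two or more
peaks), and a MYC-like factor with the classical single TSS-centered mode.
The package builds TSS-anchored aggregate profiles, classifies promoters by
single/multiple binding and co-binding, tests whether the two factors' peak
centers sit closer together than a randomization null predicts, scans
binding motifs (TAATCC family; E-box) against soft-masked genome sequence,
and relates the binding classes to gene expression.

# Coordinate and binning conventions

Everything is 0-based, half-open (BED convention); a TSS position is the
first transcribed base. Offsets are strand-aware and negative upstream: on
the plus strand `offset = center − tss`, on the minus strand
`offset = tss − center`. Peak centers are `floor((start + end)/2)`; the
floor makes even-width peaks deterministic.

Profile bins are half-open `[x, x + 50)` labeled by their center
`x + 25`; offset 0 lies in bin `[0, 50)`. This convention is arbitrary but
unambiguous, and every binning routine is pinned against brute-force
double-loop oracles in the test suite. Aggregate mean-signal profiles pool
all (probe, promoter) pairs per bin; an alternative that first averages
within promoters is available via `per_promoter_first = TRUE`.

A promoter is *bound* by a factor when at least one peak center has offset
in `[−2000, +2000]` — inclusive at both endpoints, since the window is
stated as a closed range of distances; the boundary behavior is pinned by
tests either way. Multiple-TSS genes are pre-filtered with
`filter_tss()`: scanning each gene's TSSs in genomic order, a TSS closer
than 150 bp to the previously *retained* TSS of that gene is discarded.

# The synthetic generator

Real promoter-array peak calls for this design are not redistributable, so
the package ships a generator (`synthetic_config()`, `generate_dataset()`)
whose defaults encode the study conditions the analyses assume:

| parameter | default | origin |
|---|---|---|
| promoters | 25,064 | size of the emulated promoter array |
| P(OTX2-bound) | 0.454 | reported bound fraction |
| P(multiple \| bound) | 0.402 | reported multi-peak fraction |
| OTX2 offset law | mixture, means −250 / +650 bp | reported profile modes |
| mixture sds / weights | 200 bp / 0.5, 0.5 | chosen; see below |
| MYC offset law | Gaussian, mean 0, sd 150 bp | TSS-centered single mode |
| P(MYC \| multiple) | 0.638 | reported co-binding rate |
| P(MYC \| single) | 0.487 | reported co-binding rate |
| P(MYC) marginal | 0.515 | reported MYC-bound fraction |
| extra peaks on multi promoters | geometric(0.5), ≤ 5 total | chosen; see below |
| peak width | 300 bp | typical called-peak width on tiling arrays |

`P(MYC | no OTX2)` is not free: it is solved from the law of total
probability so the marginal comes out at 0.515 (≈ 0.488 at the defaults);
an infeasible combination fails fast before any data are produced.

Values marked *chosen* are not determined by the emulated study and were
fixed once on field-plausibility grounds: mixture sds of 200 bp keep the
two modes well separated yet produce realistic overlap in the valley;
equal weights reflect that neither mode visibly dominates; the
single-parameter truncated geometric is the simplest heavy-ish tail for a
peak count that the study only ever dichotomizes as single vs multiple.

Layout: 1,000 promoters per synthetic chromosome, TSSs every 10,200 bp so
that −5000..+3000 windows never overlap regardless of strand (strands are
random). An option (`close_tss_fraction`) plants extra same-gene TSSs
closer than 150 bp to exercise the spacing filter.
`otx2_offset_law = "uniform"` replaces the mixture with the uniform law
over ±2000 bp — exactly the law the distance-randomization null assumes —
which is what a calibration run needs. `myc_coupling_sd` moves MYC peaks
next to the first OTX2 peak (e.g. sd 150 bp) to plant genuine proximity.

Sequence is generated per promoter window: uniform ACGT background;
TAATCC-family motifs planted at 1.2/kb far from the TSS, ramping linearly
to zero inside ±500 bp (the planted depletion); E-boxes at
Poisson(0.6)/promoter placed N(0, 150 bp) around the TSS (the planted
enrichment); Alu-like 300 bp soft-masked (lowercase) insertions at
0.5/promoter, each carrying three TAATCC copies, which inflate unmasked
family counts the way genuine Alu repeats do.

What the generator deliberately does **not** model: probe-level array
noise structure beyond additive Gaussian noise, any linkage between the
planted sequence motifs and where peaks are planted, overlapping promoter
windows (except via the close-TSS option), and copy-number or mappability
artifacts. Passing tests therefore demonstrate correctness of the
*computations* under the stated statistical structure, not robustness to
every artifact of real array data.

Determinism: each component (core/peaks, signal, expression, sequence)
draws from a sub-seed derived from the master seed, so e.g. peaks are
byte-identical whether or not the (expensive) sequence is generated. The
`what =` argument materializes only what a caller needs; sequence for the
full 25,064-promoter design is ~200 Mb and rarely required.

# Mode detection

`find_profile_modes()` reports strict local maxima with *topographic*
prominence: a candidate's prominence is its height above the higher of the
key saddles separating it from higher terrain (for the global maximum, its
height above the profile minimum). The default threshold is 10% of the
profile range. Plateaus resolve to the bin nearest the TSS; boundary bins
count as maxima against their single neighbor.

`principal_modes()` answers the practical question "where are the upstream
and downstream modes?". The raw argmax bin of a percent-bound profile is a
noisy location estimate: with ~3–4% bin values over 25,064 promoters the
per-bin counting noise (~0.12 percentage points) is comparable to the
curvature of the flat-topped mixture peaks, and in simulation the argmax
bin lands up to two bins from the planted mode. The default estimator is
therefore the value-weighted centroid of the contiguous bins above half
the mode height — the center of mass of the full-width-at-half-maximum
support, a standard peak-location estimator — snapped back to the nearest
bin center. In a 50-seed simulation study at the default conditions this
reduced the worst-case location error from 75 bp (argmax) to under one
bin. `refine_frac = NULL` restores the raw argmax.

# Enrichment and distance statistics

**Hypergeometric co-binding enrichment.** `hypergeometric_enrichment()`
computes the exact upper tail P(X ≥ k), including the observed count (the
standard one-sided enrichment convention), as a log-space sum of
`lchoose` terms so that tails around 1e−80 retain full relative precision.
The test suite checks it against both `phyper` and a direct choose()-sum
oracle over the entire N ≤ 60 space. The published framing of the
co-binding test this reproduces is loose about the exact 2×2
configuration; the package keeps the literal upper-tail reading and the
acceptance test asserts the order of magnitude rather than forcing a
digit-for-digit match.

**Distance null.** For promoters with a single OTX2 peak plus MYC binding,
the observed statistic is the distance from the OTX2 center to the
*nearest* MYC center (the conservative proximity measure when several MYC
peaks are assigned). The null redraws each OTX2 offset uniformly over the
±2000 bp binding window, keeps MYC fixed and per-promoter peak counts
intact, and pools R = 3 randomizations by default; expected percentages
are averaged over the individual randomizations. Per half-open distance
range (default breaks 0, 200, 400, 800, 1600 bp), a 2×2 table of observed
vs null counts — the null column scaled to the observed total and rounded
so the table is integer — is tested with the two-sided Fisher exact test
(sum-of-smaller-probabilities rule, as in `stats::fisher.test`). Whether
the original randomization also moved peaks outside ±2000 bp is not
documented anywhere; re-drawing within the binding window is this module's
declared null.

# Motif machinery

Scanning is exact substring matching, both strands by default, with
reverse-strand hits mapped to the forward coordinate of their first base
and palindromes counted once per position. Soft-masking (lowercase) is the
only repeat-mask representation: with `respect_softmask = TRUE` a match
overlapping any lowercase base is skipped. "E-box" defaults to the
canonical CACGTG with the CANNTG expansion available
(`ebox_motifs(extended = TRUE)`); the OTX2 family is TAATCC, TAAGCC,
TAATCT.

The iterative enrichment (`kmer_enrichment_iterative()`) emulates the
common mask-and-repeat motif-discovery loop: per round, count every 6-,
7- and 8-mer exhaustively on both strands in foreground and background,
report the k-mer maximizing the pseudocounted log2 relative-frequency
ratio, replace its occurrences (and its reverse complement's) in the
foreground with N, and repeat (15 rounds by default). Exhaustive
enumeration is exact at these lengths, so no heuristic inner search is
needed. Two counting details matter: palindromic k-mers are counted once
per physical site (otherwise they enjoy a spurious two-fold advantage),
and reverse-complement pairs — which necessarily tie on the score — are
represented by the member with more forward-strand foreground
occurrences, then lexicographically. Scores of k-mers of different
lengths are compared directly as relative-frequency ratios; this favors
longer k-mers when the background is sparse, which is why the discovery
tests construct backgrounds genuinely free of the planted motif.

# Expression integration

Genes are split into five rank-quantile categories by log2 expression
(fixed cut-offs are not reproducible across datasets; ranks are). Ties
keep their stable-sort category; sizes differ by at most one, remainder to
the lower categories. Per category and co-binding class the bound
percentage is a plain ratio. Class-wise expression differences use the
Welch t-test by default (the robust choice when the original report says
only "t-test"; pooled variance via `var_equal = TRUE`), comparing the
multi+MYC reference class against each other class separately *and*
against all others pooled — the original description is ambiguous between
the two, so both are reported and neither is claimed to be "the" original
test. Genes without expression measurements are excluded with a message,
never imputed.

# Numerical and degenerate-input choices

* Window widths must be multiples of the bin width (hard error).
* Bins with no data are `NA` in mean-signal profiles and excluded from
  mode detection; a profile with no informative bins is an error.
* The heatmap-style `promoter_matrix()` keeps promoters with strictly
  more than 100 informative bins (the stated filter is strict), sorts by
  descending key with stable ties, and drops promoters with missing keys
  with a message.
* `fisher.test` may return p marginally above 1 in floating point; the
  distance module clamps to 1.
* Degenerate Welch comparisons (zero variance in both samples) report
  `NA` statistics instead of failing.
* The k-mer loop stops early with a warning when the foreground is
  exhausted (all N).

# Problem sizes used by the test suite

The suite exercises the full default design (25,064 promoters) for
classification and profile-mode checks, ~22,000 promoters for the
bimodal-recovery check (≈10,000 bound), 5,000 promoters for the
distance-power check with coupling sd 150 bp, 100 replicates of 400
promoters for null calibration and p-value uniformity, 600 promoters of
generated sequence for the motif-density curves, and brute-force oracles
on instances of tens of promoters. These sizes were chosen so that each
check has comfortable statistical resolution while the whole suite runs
in about a minute.

# Known limitations

* Peaks are consumed as called intervals; no peak calling or array
  normalization is provided.
* Only two factors are modeled in the co-binding classes (the data model
  itself does not care how many peak tables exist).
* Motif analysis is exact-match only — no position-weight matrices and no
  genome-wide FDR for matches.
* The randomization null and the binding definition share the ±2000 bp
  window by construction; conclusions about distances beyond that window
  are outside the model.
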