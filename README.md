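# promobind

Promoter binding landscapes for paired transcription-factor ChIP data.

## The problem

Aggregate ChIP profiles around transcription start sites (TSSs) usually
show a single TSS-centered peak. Some factors deviate: an OTX2-like
homeodomain factor binds promoters with a **bimodal** aggregate profile —
an upstream mode near −250 bp and a downstream mode near +650 bp — with a
large fraction of promoters carrying two or more peaks, while a MYC-like
factor retains the classical TSS-centered mode. `promobind` is for
analysts who have promoter-array (ChIP-on-chip style) peak calls, probe
signal, TSSs, expression and genome sequence for such a pair of factors
and want to quantify:

* **TSS-anchored profiles** — mean log2 signal and percent-of-promoters-
  bound per 50 bp bin over −5000..+3000 bp, with mode detection and
  heatmap-style per-promoter matrices;
* **co-binding classes** — promoters bound within ±2000 bp of the TSS,
  split into single/multiple binding of the first factor crossed with
  binding of the second, with the hypergeometric enrichment
  P(X ≥ k) = Σᵢ C(K,i)·C(N−K,n−i)/C(N,n) computed in log space;
* **peak–peak proximity** — observed OTX2→nearest-MYC center distances
  against a null that redraws OTX2 offsets uniformly over the ±2000 bp
  window (R randomizations), with two-sided Fisher exact tests per
  distance range;
* **motif geography** — exact scanning of TAATCC-family and E-box motifs
  against soft-masked FASTA, density vs TSS or peak center, motif
  frequency vs expression in 400-peak bins, and iterative exhaustive
  k-mer enrichment (count, report best log2 frequency-ratio k-mer, mask,
  repeat);
* **expression integration** — five rank-quantile expression categories,
  percent-bound curves per class, and Welch t-tests of the multi+MYC
  class against the others.

A synthetic-data generator (`generate_dataset()`) emulates the whole
statistical structure — bimodal offsets, peak multiplicity, co-binding
coupling, class-dependent expression, motif-depleted/-enriched sequence
with soft-masked repeats — so the entire pipeline is testable without any
external download.

## Worked example

```r
library(promobind)

cfg <- synthetic_config(n_promoters = 5000, seed = 42)
ds  <- generate_dataset(cfg, what = c("peaks", "expression"))

oa <- assign_binding(ds$otx2_peaks, ds$tss)   # ±2000 bp center rule
ma <- assign_binding(ds$myc_peaks,  ds$tss)
cl <- classify_promoters(oa, ma, ds$tss)
cl$class_table
#> Promoter co-binding class table
#>            total       otx2_bound           single         multiple
#>             5000             2245             1330              915
#>        myc_bound          cobound   myc_and_single myc_and_multiple
#>             2587             1249              666              583
#> percent:
#> otx2_bound_of_total     single_of_bound   multiple_of_bound        myc_of_total
#>                44.9                59.2                40.8                51.7
#>    cobound_of_total    myc_given_single  myc_given_multiple
#>                25.0                50.1                63.7
#> enrichment P(X >= k) = 4.76e-16
```

44.9% of promoters carry ≥1 OTX2-like peak, 40.8% of those carry several,
and MYC-like binding is markedly enriched among the multiple-bound class
(63.7% vs 51.7% overall; upper-tail hypergeometric p ≈ 5e−16 at this
sample size).

```r
prof <- peak_frequency_profile(ds$otx2_peaks, ds$tss)   # % bound per 50 bp bin
principal_modes(prof)
#> $upstream
#> [1] -225
#> $downstream
#> [1] 675
```

The percent-bound profile is bimodal with modes one bin from the planted
−250/+650 bp.

```r
obs <- observed_distances(cl$summaries, oa, ma, ds$otx2_peaks, ds$myc_peaks)
nl  <- randomized_null(cl$summaries, oa, ma, ds$otx2_peaks, ds$myc_peaks,
                       R = 3, seed = 1)
range_enrichment(obs, nl)
#> <distance_result> n=666 observed distances
#>       range observed observed_pct expected expected_pct      p_value
#>     [0,200)      143     21.47147       66      9.95996 7.472836e-09
#>   [200,400)      139     20.87087       66      9.95996 3.479727e-08
#>   [400,800)      272     40.84084      132     19.76977 6.909586e-17
#>  [800,1600)      112     16.81682      261     39.13914 7.115805e-20
#>  [1600,Inf)        0      0.00000      141     21.17117 1.777717e-46
```

On single-OTX2/MYC-bound promoters the two factors' peak centers sit far
closer than the uniform randomization null expects — 42% of observed
distances fall within 400 bp versus 20% expected.

```r
cats <- expression_categories(ds$expression, n = 5)
tab  <- percent_bound_by_category(cl$summaries, cats, stratify_by = "cobind_class")
round(tab$percent[tab$stratum == "multi+MYC"], 1)
#> [1]  1.2  3.4  6.7 13.4 33.6
```

The multi+MYC class climbs steeply across the five expression quintiles —
the planted coupling between co-binding and high expression.

See the vignette (`vignettes/promoter-binding-landscapes.Rmd`) for the
models, parameter defaults and the reasoning behind the numerical
conventions.

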