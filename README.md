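# m6Amir

Does N6-methyladenosine (m6A) on a target mRNA enhance miRNA-mediated
repression? `m6Amir` is an R package for analysts of epitranscriptomic and
post-transcriptional regulation data who want to ask that question — and
stress-test the answer — from four kinds of evidence:

* **Regulation.** Transcripts with a canonical 7mer/8mer seed site are
  split into m6A+ (≥ 1 mapped single-nucleotide m6A site) and m6A−
  groups, plus an "Others" background, and compared on log2 fold change
  under miRNA overexpression or knockout with two-sample
  Kolmogorov–Smirnov (KS) tests.
* **Conservation.** miRNA-binding sites overlapping an m6A position are
  compared with non-overlapping sites on mean per-nucleotide conservation,
  for predicted seed sites and for sites located inside CLASH chimeric
  fragments (including seedless sites).
* **Structure.** 3'-UTR GC content per group, and a site-accessibility
  measure ΔG_total = ΔG_hybrid + ΔG_open: the minimum free energy of the
  miRNA:target duplex plus the cost of opening the target's local
  secondary structure (ΔG_open ≥ 0; higher ΔG_total = less accessible).
  Both energies come from a reduced nearest-neighbor model — stacking
  energies with linear loop penalties and affine multiloops — implemented
  as exact dynamic programs (Rcpp) and certified against exhaustive
  enumeration in the test suite.
* **Confounders.** Six re-analyses: m6A-to-site distance, UTR length with
  500-nt bin-matched resampling, relative site location, basal
  expression, seed-type proportions, and proximal-but-non-overlapping
  m6A.

A built-in generator produces complete synthetic cohorts (UTR FASTA, m6A
BED, expression TSV, conservation bedGraph, CLASH-style chimera TSV) with
planted, configurable effect structure, so every stage runs and is
validated with no downloads. The methods vignette
(`vignettes/m6a-mirna-regulation.Rmd`) documents the model, conventions
and design choices.

## Worked example

```r
library(m6Amir)

cohort <- generate_cohort(synth_config(n_transcripts = 800, rng_seed = 7))
analysis <- analyze_cohort(cohort, energy = "hybrid", dg_threshold = "none")
print(analysis)
#> m6A/miRNA regulation analysis
#>   transcripts: 800; binding sites: 661
#>   groups: m6A+ 216, m6A- 191, Others 393 (excluded 6mer: 0)
#>   comparisons:
#>     log2fc                   m6a_pos vs m6a_neg: D=0.149, p=0.0216
#>     log2fc                   m6a_pos vs others: D=0.250, p=5.29e-08
#>     log2fc                   m6a_neg vs others: D=0.168, p=0.00143
#>     site_conservation        m6a_pos_sites vs m6a_neg_sites: D=0.881, p=2.23e-308
#>     gc_content               m6a_pos vs m6a_neg: D=0.807, p=2.23e-308
#>     clash_site_conservation  m6a_pos_sites vs m6a_neg_sites: D=0.917, p=2.23e-308
```

Reading this: of 800 transcripts, 407 carry a 7mer/8mer seed site for the
perturbed miRNA (216 methylated, 191 not). The planted m6A enhancement
(an extra −0.3 log2FC on methylated targets) shows up as the m6A+ group
being down-regulated more than the m6A− group (D = 0.149, p = 0.022);
both target groups respond more than the untargeted "Others". The
conservation and GC comparisons recover the generator's planted +0.2
conservation elevation at methylated sites and +5-point GC shift on
methylated transcripts.

The confounder battery for the same run:

```r
analysis$confounders[, c("confounder", "n_a", "n_b", "statistic", "p_value")]
#>                  confounder n_a n_b statistic  p_value
#> 1   m6a_distance_regulation 113 103    0.1010 6.41e-01
#> 2                utr_length 216 191    0.3782 5.14e-13
#> 3 regulation_length_matched 134 134    0.1716 3.86e-02
#> 4         relative_location 216 191    0.0492 9.67e-01
#> 5          basal_expression 216 191    0.1164 1.28e-01
#> 6       eightmer_proportion 216 191    4.6032 3.19e-02
#> 7  proximal_only_regulation  90 191    0.1469 1.43e-01
```

The m6A+ group has longer UTRs (row 2 — the generator couples methylation
odds to length, as real maps do), yet the regulation difference survives
length-matched resampling (row 3): the signal is not a length artifact.

Site-level energetics are available directly:

```r
delta_g_total(paste0(strrep("A", 40), "CUACCUCA", strrep("A", 40)),
              start = 40, end = 48, mirna_seq = "UGAGGUAGUAGGUUGUAUAGUU")
#> $dg_hybrid  -17.7
#> $dg_open      0
#> $dg_total   -17.7
```

A command-line front end covering simulate / run-all / sites / energy
lives at `inst/scripts/m6amir.R`.

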