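---
title: "Does m6A on target mRNAs enhance miRNA-mediated repression? Methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Does m6A on target mRNAs enhance miRNA-mediated repression? Methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Amir)
```

## The question and the analysis

N6-methyladenosine (m6A) is the most prevalent internal mRNA modification,
enriched in 3'-UTRs — the same region where microRNAs bind. `m6Amir`
implements a comparative analysis that asks whether the presence of m6A on a
target mRNA is associated with stronger miRNA-mediated repression, and
whether that association survives a battery of confounder controls.

The pipeline has five stages:

1. **Classification.** A transcript is *m6A+* if it carries at least one
   mapped single-nucleotide m6A site, *m6A−* otherwise; a miRNA-binding
   site is *m6A+* if an m6A position falls inside its half-open interval.
2. **Site identification.** Canonical seed sites on each 3'-UTR: 6mer
   (Watson–Crick match to miRNA positions 2–7), 7mer-m8 (2–8), 7mer-A1
   (2–7 plus a target adenosine opposite position 1), and 8mer (2–8 plus
   the A1 adenosine). In CLASH chimeric fragments, sites without a seed
   match are located as the 10-nt window with the strongest intermolecular
   duplex energy (*seedless* sites).
3. **Energetics.** For each representative site, the hybridization energy
   ΔG_hybrid of the miRNA:target duplex, the opening energy ΔG_open needed
   to expose the site, and the accessibility measure
   ΔG_total = ΔG_hybrid + ΔG_open. A higher ΔG_total means lower
   accessibility.
4. **Group comparisons.** Expressed transcripts are divided into m6A+
   seed targets, m6A− seed targets, and "Others"; groups are compared on
   log2 fold change under miRNA perturbation, site conservation, GC
   content, and ΔG_total with two-sample Kolmogorov–Smirnov (KS) tests.
5. **Confounder battery.** Six re-analyses probing whether the group
   difference could be carried by m6A-to-site distance, UTR length,
   site location, basal expression, seed-type composition, or proximal
   (non-overlapping) m6A.

Every stage runs on synthetic cohorts from the built-in generator, so the
whole analysis is reproducible and testable offline.

## Site identification conventions

All coordinates are 0-based, half-open, in transcript-local (3'-UTR)
space; BED and bedGraph inputs already use this convention. Seed matching
is Watson–Crick only — G·U wobbles never count as seed matches, although
they are allowed in folding and duplexes.

All occurrences of the four patterns are reported, including overlapping
occurrences at different offsets, with one exception: a match whose
interval is contained in a strictly longer match is suppressed
(longest-match-wins), so a single 8mer locus is not additionally counted
as the 7mers and 6mer nested inside it.

When one transcript carries several sites, a single **representative
site** stands for it in per-target statistics: an 8mer is preferred over
either 7mer type (the two 7mers form one width class); among equals the
most negative ΔG_hybrid wins; remaining ties go to the smallest start.
6mer-only transcripts never represent seed targets — they either stay in
"Others" or, if their representative 6mer looks like a confident target
(ΔG_total at or below a threshold), are excluded entirely. The published
analyses used a trained site-confidence model for this exclusion; that
model's parameters are not public, so the package uses a configurable
ΔG_total threshold (default: the cohort median over 6mer-only
representatives) and flags it as a proxy in its outputs.

## The reduced thermodynamic model

Folding and hybridization use a reduced nearest-neighbor model, chosen so
that an exhaustive enumeration oracle can certify the dynamic programs
exactly:

* sequence-dependent stacking energies over the pairs AU, UA, CG, GC,
  GU, UG (defaults of Turner-rule magnitude, symmetric under duplex
  reversal; see `default_stack_table()`);
* linear loop penalties `base + per_nt × size` for hairpin
  (3.5 + 0.3/nt), internal (2.0 + 0.35/nt) and bulge loops
  (3.0 + 0.35/nt), all in kcal/mol;
* affine multiloops `a + b × branches + c × unpaired`
  (3.4 + 0.4/branch + 0.1/nt), branches counting the closing pair;
* minimum hairpin size 3; interior loops capped at 30 unpaired
  nucleotides (the usual computational cap — irrelevant at oracle sizes);
* no dangles, no coaxial stacking, no lone-pair prohibition, no special
  hairpin sequences.

Parameters live in a YAML file (`system.file("extdata",
"energy_params.yaml", package = "m6Amir")`), so a fuller parameterization
can be swapped in without code changes.

`duplex_energy()` is the intermolecular analog (stacks plus linear
bulge/internal penalties; no intramolecular pairs or branching), in the
spirit of hybrid-MFE tools. A lone base pair scores 0, and a window with
no allowed pair at all returns the sentinel `+Inf`, which propagates to
ΔG_total. `fold_mfe()` is a Zuker-style MFE fold supporting hard
unpaired constraints, and

```
ΔG_open(site) = E_MFE(window | site unpaired) − E_MFE(window)  ≥ 0
```

over a local window of the site ± `flank` (default 100 nt). ΔG_hybrid is
computed against the site extended `hyb_flank` (default 15 nt) toward the
UTR 5' end, where miRNA 3'-end pairing lands. The 100-nt flank keeps the
cubic-time fold local; 15 nt covers the miRNA 3' span.

Two deliberate simplifications, and their consequences:

* **MFE rather than ensemble.** The cited accessibility method uses
  ensemble (partition-function) disruption energies; the MFE variant here
  is deterministic and oracle-checkable, at the cost of ignoring
  suboptimal structure. Relative group comparisons are insensitive to
  this choice in the synthetic studies; absolute ΔG values are not
  comparable across the two definitions.
* **Representative sites only.** Opening energies cost two window folds
  per site, so they are computed for representative sites (one per
  transcript), which carry all downstream accessibility statistics.
  `delta_g_total()` remains available for any individual site.

The sign convention ΔG_total = ΔG_hybrid + ΔG_open with ΔG_open ≥ 0 is
fixed by the requirement that a *higher* ΔG_total indicate *lower*
accessibility.

There are no thermodynamic parameters for modified nucleotides in this
model: all energies describe the unmodified sequence, so accessibility
results read as "accessibility before any effect of the modification".

## Statistics

All distributional comparisons are two-sided, two-sample KS tests on raw
(uncorrected) p-values, matching the reporting style of the analyses this
package reproduces; whether the original tests were one- or two-sided is
not stated anywhere, so two-sided is used and recorded in output
metadata. For `min(n, m) ≤ 10` the exact conditional null distribution is
used. Knockout experiments reverse the expected direction of regulation,
so in knockout mode only up-regulated transcripts (log2FC > 0) enter the
comparison.

The UTR-length control uses 500-nt bins (0,500], (500,1000], …,
(4500,5000], (5000,∞) — a boundary length of exactly 500 lands in exactly
one bin — and draws `min(size, n+ in bin, n− in bin)` transcripts per bin
without replacement from each group (default size 3000). The published
description does not say what happens when a bin is smaller than the
sampling size; per-bin balance is the property the control needs, so the
min rule is used. After sampling, the pooled length distributions are
bin-balanced by construction.

Other conventions: m6A-to-site distance is 0 on overlap, otherwise the
nucleotide gap to the nearest site nucleotide, with the shortest distance
used when a UTR has several m6A sites; the distance split puts the
boundary (d = 100) in the "longer" subset, while the proximal-m6A window
(d ≤ 200) is inclusive. Site conservation is the mean of available
per-nucleotide scores; track gaps are missing data, not zeros, and a site
with fewer than half its positions scored has no score. The seed-type
composition check is a two-proportion chi-square test on the 8mer share
among representative sites (no test is named in the published analysis).

## The synthetic-data generator

`generate_cohort()` emulates the statistical structure of the study
inputs; its defaults are the package's reference conditions:

| parameter | default | emulates |
|---|---|---|
| `n_transcripts` | 4000 | desk-scale transcriptome |
| UTR length | lognormal(6.5, 0.9), clipped [50, 20000] | median ≈ 665 nt |
| `gc_base`, `gc_m6a_shift` | 0.45, +0.05 | higher GC on methylated targets |
| `p_methylated`, `meth_length_slope` | 0.5, 0.8 | methylation odds rising with UTR length |
| `m6a_per_tx_mean` | 2 | sites per methylated transcript |
| `p_target`, `site_type_mix` | 0.6; 8mer .30 / 7mer-A1 .25 / 7mer-m8 .25 / 6mer .20 | planted seed sites |
| `p_site_overlap_m6a` | 0.3 | m6A inside the binding site |
| `delta_target`, `delta_m6a` | −0.2, −0.3 | targeting effect and its m6A enhancement |
| `noise_sigma` | 0.5 | expression noise |
| conservation | Beta(2, 5) per nt, +0.2 at m6A+ site footprints | elevated conservation at methylated sites |
| `basal` | lognormal(5, 1) | control-sample expression |
| `n_chimeras` | 300 | CLASH-style fragments |

Planted sites are substituted into the background sequence (never
truncated), so generator truth is exactly recoverable; if the random
flanking base would extend a planted site into a wider type (a 6mer
followed by a chance A reads as a 7mer-A1), the flank is adjusted
deterministically. Chance background seed matches elsewhere are expected
and allowed. m6A positions are always placed on adenosines. All
randomness flows from one seed through per-stage substreams, so
identical configurations give byte-identical output files.

What the generator does **not** model: m6A thermodynamic effects (no
such parameters exist — the GC shift encodes the structural-stability
observation instead), realistic transcript annotation, read-level noise,
or inter-site correlation along a UTR. Passing tests on these cohorts
therefore certify the machinery — calibration, power at planted effect
sizes, confounder control — not any claim about real data.

## Validation design and problem sizes

The test suite validates each layer against an independent oracle:

* duplex and fold energies against exhaustive enumeration (200 random
  instances each, miRNA ≤ 10 nt / target ≤ 14 nt, folds ≤ 22 nt, with
  and without unpaired constraints, |Δ| ≤ 1e-6);
* opening-energy positivity and constraint monotonicity on 500 random
  UTR/site instances, with poly-A controls at exactly 0;
* the seed scanner against a substring-scan oracle on 1000 random UTRs
  (50–3000 nt) plus 100% recovery of planted sites in two cohorts;
* KS D and exact p against full labeling enumeration for every sample
  size pair with n + m ≤ 12;
* calibration: 200 null cohorts (`delta_m6a = 0`, n = 800) with the
  rejection rate at α = 0.05 required inside [0.02, 0.09];
* power: 100 cohorts at the scale of the largest published group sizes
  (~1500 vs ~1350 seed targets; n = 5400), requiring p < 0.001 in ≥ 95%;
* confounder control: 100 length-confounded cohorts
  (`delta_length_per_kb = −0.25`, `meth_length_slope = 1.2`, n = 2500,
  no m6A effect) must show raw significance and lose it after
  bin-matched resampling (p > 0.05 in ≥ 80%), while 100 cohorts with a
  genuine `delta_m6a = −0.3` must retain it (p < 0.01 in ≥ 90%);
* conservation: a +0.2 planted elevation detected at 500 sites/group in
  ≥ 95 of 100 cohorts, and a zero-shift arm calibrated as above;
* end-to-end determinism: `run_all()` twice on one configuration gives
  byte-identical tables.

The length-confounded scenario's parameters were fixed from a small
design pilot before the thresholds were frozen; they encode "an effect
carried by length, with methylation merely correlated with length", the
situation the bin-matched control exists to catch.

## Known limitations

* Transcriptome-wide *seedless* site prediction is out of scope; seedless
  sites are located only inside CLASH fragments, and the trained
  confidence model behind the published "Others" construction is replaced
  by the ΔG_total threshold proxy described above.
* The thermodynamic model is reduced; absolute energies are not
  Turner-complete, and ΔG_open is MFE-based rather than ensemble-based.
* m6A status is binary per transcript/site; stoichiometry, cell-type
  specificity and reader-protein binding are not modeled.
* Conservation input is a per-nucleotide track in transcript coordinates;
  genome-coordinate liftover is out of scope.
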