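---
title: "Quantifying DNA-mediated cooperativity of Sox and Pax factors"
author: "tfcoop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA-mediated cooperativity of Sox and Pax factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcoop)
```

## The problem

Sox and Pax transcription factors co-select composite enhancer elements in
which a canonical *sox* half-site sits immediately next to a degenerate,
low-affinity *pax* half-site. On such elements the two factors bind far more
strongly together than the product of their individual affinities predicts —
the hallmark of cooperativity — and the effect is thought to be transmitted
through DNA structure rather than through a protein–protein interface.
`tfcoop` implements the quantitative machinery needed to dissect this system
at the desk: an equilibrium model of the four probe microstates, the
cooperativity statistic estimated from quantified gel bands, composite-motif
scanning with rigid spacing, ChIP-seq peak intersection, and weighted NMR
chemical-shift-perturbation mapping, together with synthetic-data generators
that stand in for the wet-lab inputs.

## The four-microstate equilibrium model

A DNA probe `D` incubated with a Sox protein `S` and a Pax protein `P`
partitions into four microstates — free DNA, `SD`, `PD` and the ternary
complex `SPD` — which migrate as four distinct bands in an EMSA lane. At
equilibrium the complexes obey

$$[SD] = \frac{[S][D]}{K_S}, \qquad
  [PD] = \frac{[P][D]}{K_P}, \qquad
  [SPD] = \omega\,\frac{[S][P][D]}{K_S K_P},$$

where $K_S$ and $K_P$ are the monomeric dissociation constants (nM) and
$\omega$ is the cooperativity factor: the ratio of the ternary-complex
equilibrium constant to the product of the monomeric ones. $\omega > 1$ is
cooperative, $\omega = 1$ additive (independent binding), $\omega < 1$
competitive.

`solve_equilibrium()` solves this system under full mass conservation of all
three species. No trace-probe approximation is made, because the
experimental regime of interest deliberately uses probe concentrations
(100–300 nM) comparable to or above the protein concentrations. The solver
eliminates free DNA analytically (the DNA balance is linear in `[D]` once
`[S]` and `[P]` are fixed) and finds the two free protein concentrations by
nested bracketed root finding on `[0, total]`; each bracket provably
contains the physical root because the residual is negative at 0 and
non-negative at the total. A damped fixed-point polish then pushes all three
mass balances below `rel_tol` (default `1e-10`, iteration cap 10 000);
failure to converge is an error naming the parameter set, never a silent
return. Derivative-free bracketed iteration was chosen over Newton-type
methods because it cannot leave the physical domain and needs no Jacobian;
the test suite cross-checks it against an independent multivariate Newton
solve on random parameter sets.

Two exact consequences of the model anchor the tests:

* **Round trip**: the plug-in statistic
  $(f_{dimer} f_{free})/(f_{Sox} f_{Pax})$ of the solved fractions equals
  the input $\omega$ identically, for every parameter set.
* **Factorisation**: at $\omega = 1$,
  $f_{dimer} f_{free} = f_{Sox} f_{Pax}$.

`solve_two_probe()` extends the same construction to two probes competing
for shared protein pools — the dual-label experiment in which a cooperative
low-affinity element and an additive high-affinity element are offered to
the same proteins simultaneously. Both probes see the same free `[S]` and
`[P]`; each probe's DNA balance holds separately.

## The cooperativity statistic

Quantified band intensities from one lane are normalised to fractions
(`normalize_lane()`), and the cooperativity factor is estimated as

$$\hat\omega = \frac{f_{dimer}\; f_{free}}{f_{Sox}\; f_{Pax}}.$$

Because $\hat\omega$ is a ratio of ratios it is invariant to lane exposure
and to the normalisation constant.

**Detectability rule.** A band below the threshold `epsilon` (default 0.01,
i.e. 1 % of the lane signal) cannot be quantified reliably on a gel image.
`estimate_omega()` therefore flags estimates rather than dropping them:
a sub-threshold monomer band gives reason *monomer band below
detectability*, a sub-threshold ternary band — the typical competitive
element phenotype — gives *ternary band barely detectable*. A zero
denominator at `epsilon = 0` yields `Inf`, never an exception. The 1 %
default encodes "barely detectable" as a reproducible rule; it is
configurable.

**Sign convention.** Competitive binding is sometimes described as
"negative" cooperativity; a ratio of non-negative fractions cannot be
negative, so this is interpreted on the log scale: `log2_omega < 0` for
$\omega < 1$. Both $\omega$ and $\log_2\omega$ are reported.

**Replicates.** `summarize_replicates()` aggregates reliable estimates only;
the median and IQR are the primary summary (boxplot convention) with mean ±
SD alongside (barplot convention). Whether published point values are means
or medians of replicates is generally unstated; the median is used because
it is robust to the occasional band misquantification and matches the
boxplot presentation. Replicate counts of ~10 per element are typical for
this assay and are the default in the simulation layer.

**Affinity fits.** `fit_kd()` fits the single-site isotherm
$b = P/(P + K_d)$ to a titration by least squares under the trace-probe
assumption (this is the one place the approximation is appropriate: affinity
titrations use trace labelled probe). The objective is minimised over
$\log_{10} K_d$ by bracketed golden-section search on $[10^{-3}, 10^9]$ nM —
one parameter, no start values, no divergence.

## Composite motif scanning

Composite sites are represented as a *sox* word + fixed gap + *pax* word
over the 15-letter IUPAC alphabet, in fixed order on the same strand
(`composite_motif()`). Scanning (`scan_composite()`) reports all and only
the positions where both words match with exactly the specified spacing;
whole-motif matches on the minus strand are reported with `strand = "-"`.
Conventions, fixed once and used everywhere:

* Coordinates are 0-based half-open on the forward strand; `offset` is the
  forward-strand coordinate of the first base of the sox word as read on its
  own strand. Half-site switch positions facing the user are 1-based (the
  conventional T3/G8/C9/T11-style labels).
* Matching is case-insensitive; soft-masked lowercase bases match by default
  and are excluded with `respect_mask = TRUE`.
* Negative gaps (overlapping half-sites) are a construction-only concept for
  the spacer series; they are never a scanning state, because contracted
  spacing abolishes cooperative binding and a well-defined overlap semantics
  does not exist for degenerate words.
* Flipped mode (`build_flipped_composite()`) reverse-complements only the
  pax word, modelling elements that encode the pax consensus on the opposite
  strand with unchanged sox architecture.

`enumerate_spacer_variants()` builds the ±spacing series by inserting
user-supplied bases at the sox-word/spacer junction or deleting spacer bases
adjacent to it; deletions into a half-site are refused, and there is *no*
default insert sequence — the historically used inserted bases are not part
of the packaged annotation, so silent defaults would fabricate data.
`enumerate_switch_mutants()` emits all subsets (up to a chosen order) of the
switch positions converted from the degenerate half-site toward the
consensus, labelled consensus-base+position (`G8C9`, `T3G8C9`, ...).

`high_ic_deviations()` connects the two: positions whose PFM information
content ($2 + \sum_b f_b \log_2 f_b$ bits, pseudocount-smoothed) reaches a
threshold *and* whose degenerate-half-site base is not a majority base of
the column are the candidate switches. The default pseudocount is 0.25 per
base for real matrices and 0 for exact toy arithmetic. The PFM shipped under
`inst/extdata/pax6_like_synthetic.pfm` is a *constructed stand-in* (its
filename and header say so): no matrix counts are redistributable inside
this package, so a synthetic matrix was built whose high-information
deviating positions against the packaged degenerate half-site are exactly
positions 3, 8, 9 and 11.

The half-site boundaries of the packaged native-element annotation (sox
`CATTGT` at offset 2 of the 31-mer duplex, pax `TGTTGC` immediately
adjacent, gap 0) are figure-derived rather than printed text, and the
default scanning word set in `inst/extdata/dc5_like_words.yaml` is likewise
a package reconstruction — both files are labelled accordingly.

## Peak intersection

`intersect_peaks()` defines a co-bound region as the *intersection span* of
every cross-factor peak pair overlapping by at least `min_overlap` bp
(default 1), with overlapping or touching spans merged afterwards. The
intersection-span convention is the conservative choice — every reported
region is a subset of both factors' evidence — and is stated here
prominently because published co-bound region counts rarely state theirs.
Chromosome names match by exact string equality; `normalize_chr = TRUE`
opts into `chr`-prefix normalisation. BED input is parsed with
line-numbered errors; intervals are 0-based half-open at the interface and
GRanges-backed internally.

## Chemical-shift perturbation

`weighted_csp()` implements
$\Delta\delta = \sqrt{(\Delta\delta_{HN})^2 + (0.1\,\Delta\delta_N)^2}$
in ppm. The nitrogen weight is fixed at exactly 0.1 (the common alternative
0.154 is deliberately not the default, but the weight is configurable).
`compare_states()` matches two peak lists by residue index, reports deltas
as state B − state A, and emits unmatched residues with a missing status
instead of dropping them; `classify_perturbed()` thresholds the weighted CSP
(default 0.1 ppm, the conventional large-perturbation line). Peak-intensity
attenuation and line-broadening analysis are out of scope — only shift
positions are modelled.

## Synthetic data: what it emulates and what it does not

* `simulate_gel_replicates()` draws lanes from the equilibrium model and
  multiplies each band by an independent lognormal factor with median 1 and
  CV `noise_cv` (default 0.1). Multiplicative noise reflects densitometry's
  intensity-proportional error; median-1 noise makes the ratio statistic
  median-unbiased (verified empirically at 10 000 replicates in the test
  calibration). Not modelled: band overlap, background subtraction error,
  gel smearing, pipetting error correlated across bands.
* `plant_composite_motifs()` plants concrete realisations of the degenerate
  words into uniform-composition background and then *post-corrects*:
  sequences are exhaustively re-scanned and accidental background matches
  are destroyed by point mutation, so the truth table equals the scanner
  output exactly. Real genomes have repeat structure, GC heterogeneity and
  motif clustering that uniform background does not reproduce — passing
  recovery tests shows scanner correctness, not genomic realism (a GC
  parameter exists for mild composition shifts).
* `simulate_peak_lists()` draws state-A amide positions uniformly from
  1H 6–10 ppm / 15N 100–135 ppm and applies specified deltas plus Gaussian
  jitter for state B. Peak overlap and missing assignments must be injected
  explicitly.

### Element presets

`preset_registry()` fixes the simulation conditions for the studied
elements: native cooperative elements DC5 ($\omega = 25$) and N3
($\omega = 50$) within the published 20–50 range; the consensus element
DC5con at $\omega = 1$ (additive); the competitive element LE9 at
$\omega = 0.2$ with a weak pax site (Kd 8 µM) so that at the standard
300/300/300 nM condition its ternary band sits below the 1 % detectability
line — reproducing the known phenotype that its cooperativity cannot be
reliably determined; contracted spacers at $\omega = 0.3$ and expanded
spacers at $\omega = 2$, an order of magnitude below the native element.
Absolute Kd values for these elements are not published; the preset
magnitudes (Kd$_S$ = 100 nM, degenerate-pax Kd$_P$ = 1000 nM, consensus-pax
Kd$_P$ = 100 nM) were chosen once so that at 300/300/300 nM all four bands
of the quantifiable elements are visible — the stated experimental
quantifiability condition — and every preset's `note` field marks the Kd
values as package choices.

## Problem sizes and numerical choices

The test suite runs the solver-vs-oracle comparison on 100 random parameter
sets ($\omega \in [0.1, 100]$, Kd $\in [10, 10^4]$ nM, totals
$\in [10, 1000]$ nM), the scanner against a character-level exhaustive
oracle on 1000 + 500 random sequences (lengths 12–60 bp), and the peak
intersection against a quadratic all-pairs oracle on 1000 random interval
sets (up to 20 intervals per set); these sizes give dense coverage of the
branch structure while keeping the default suite fast. Fraction tolerances
are `1e-6` against oracles and `1e-10` relative on mass balances.
Monte-Carlo acceptance bounds (median $\hat\omega$ over 10 replicates at
CV 0.1 within [20, 31]; Kd recovery within 10 % at CV 0.05) were calibrated
by 10 000-draw simulation of the respective estimators before being frozen
into the tests.

## Known limitations

* The model covers exactly two proteins and one or two probes; no kinetics,
  no DNA bending energetics, no structure-based prediction of $\omega$.
* Composite scanning is word-based by design; probabilistic (log-odds)
  scoring of composite sites and de novo motif discovery are out of scope.
* The packaged element annotation and scanning words are reconstructions
  (see above); analyses that depend on the exact historical sequences should
  supply their own.
* `fit_kd()` assumes trace probe and a single site; it is not suitable for
  the high-probe regime of the cooperativity gels (use the full solver
  there).
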