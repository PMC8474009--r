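---
title: "Methods: design and quantification of targeted phosphopeptide MRM assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design and quantification of targeted phosphopeptide MRM assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmassay)
```

# The problem

Multiplexed targeted mass spectrometry (MRM/SRM) can quantify hundreds of
phosphosites across signaling pathways in a single run, provided three
things are engineered carefully: (i) a panel of proteotypic tryptic
phosphopeptides that actually carry the nominated sites and behave well on
LC-MS; (ii) an instrument method — transitions, collision energies,
retention-time schedule, peptide mixtures — built around stable-isotope-
labeled (SIL) internal standards; and (iii) a statistical pipeline that
copes with the left-censored missingness targeted phospho data always has.
`mrmassay` implements all three stages plus a synthetic-data module that
generates proteomes, evidence tables and chromatograms with known ground
truth, so the full pipeline is testable without instrument data.

# Panel design

**Digestion.** `digest()` cleaves C-terminal to K/R with *no* proline
suppression by default. This is deliberate: the short fully cleaved forms
that motivate the missed-cleavage rescue rule (e.g. a `D(pS)LQK` followed by
proline) only exist under unconditional K/R cleavage. The classical
suppressed rule is available via `proline_rule = TRUE`. The missed-cleavage
ceiling is 2, which is exactly what the rescue forms spanning two internal
cleavage points require.

**Selection rules** (`select_peptide()`), in order:

1. forms longer than 40 residues are dropped (all too long → reject);
2. forms shorter than 6 residues are dropped; they survive only through a
   6–40-residue missed-cleaved *rescue* form. If no in-range form exists the
   site is rejected `too_short_no_rescue` — a selected entry must always be
   6–40 residues, so an observed-but-short form cannot be selected either;
3. the most frequently observed form wins; ties prefer fewer missed
   cleavages, then shorter length;
4. a winner with zero observations is rejected for nominated sites unless
   explicitly exempted (`include_unobserved`, modeling panels that retain
   biologically critical but never-observed peptides); discovery-derived
   sites are observed by construction;
5. singly phosphorylated forms are preferred over doubly phosphorylated
   ones unless the doubly form is at least `prevalence_factor` (default 3)
   times more frequently observed. The literature states only "much more
   prevalent"; the factor 3 is this package's operationalization and is
   configurable. Triply phosphorylated forms are never generated.

**Uniqueness and conservation** are exact substring searches of the
unmodified peptide against a proteome, with no I/L folding — a deliberate
conservative choice, since an I/L-folded match would still produce a
different precursor mass only when other residues differ.

**Routing.** pS/pT-only peptides go to IMAC; pY-containing peptides go to
the pY-antibody route unless prior evidence shows detection under both
enrichments, in which case they enter the combined IMACpY pool usable with
either method.

**Heavy labels** sit on the C-terminal K/R; protein-C-terminal peptides
fall back to an N-terminal K/R, then an internal L or P — mirroring SIL
synthesis practice.

# Masses and transitions

All masses derive from one table (`mass_constants()`): monoisotopic residue
masses, proton 1.0072765 Da, water 18.0105646 Da, phospho +79.9663305 Da,
and full ¹³C/¹⁵N label deltas (K +8.01420, R +10.00827, L +7.01723,
P +6.01385). Exported m/z values are formatted to 5 decimals. Phospho
neutral-loss transitions are not generated: ranking draws on b/y series
only.

`rank_transitions()` replaces the manual transition-picking step with a
deterministic tier sort: (1) y-ions above the precursor m/z, (2) remaining
site-determining ions, (3) remaining y-ions, (4) b-ions; within tiers by
library intensity, ties broken by higher product m/z, y before b, lower
index. Between 3 and 6 transitions are returned. A fragment is
*site-determining* when it contains the phosphosite or its boundary
separates the phosphosite from an alternative S/T/Y acceptor.

Collision energy is the standard triple-quadrupole linear form
`CE = slope·(m/z) + intercept` per charge (defaults 0.0339/2.3597 for 2+,
0.0295/2.4141 for 3+). These coefficients are instrument-specific and
config-overridable; the schedule logic, not the constants, is the tested
content. CE optimization tests the calculated value plus 5 below and 5
above in 2 eV steps (11 values, clipped at 0; duplicate zeros retained —
an instrument export may de-duplicate).

Monitored charge states default to 2+, adding 3+ for peptides with two or
more internal basic residues, since the literature does not state a
per-peptide policy.

**Methods and mixtures.** The IMAC method runs 160 min with a 3.0-s cycle,
the pY method 120 min with 1.5 s; both use Q1 0.4 / Q3 0.7 FWHM and a
10-min RT scheduling window. `build_method()` clips windows to the gradient
and reports the maximum concurrent-transition count on a 0.1-min grid as a
feasibility diagnostic. `assemble_mixtures()` sorts each route
alphabetically by gene and partitions contiguously into the minimum number
of mixtures within the route's size bounds (IMAC 43–50, pY 31–40, IMACpY a
single pool) with sizes differing by at most one, at 2 pmol/µl equimolar.

# Quantification

The spiked heavy standard defines the integration window: the apex of the
summed heavy profile, ± 1.5 × its FWHM (half-max crossings linearly
interpolated). The same window is applied to light and heavy — the software
analogue of "equal integration of light and heavy". Areas are trapezoidal
with no baseline subtraction by default (synthetic baselines are flat; a
linear-baseline option exists).

The reporting transition must be interference-free: each transition's
relative-contribution fraction is computed separately in the heavy and
light channels, and a transition whose fractions disagree by more than 0.2
(configurable) is flagged; among clean transitions the largest heavy area
reports. This absolute-deviation criterion is inspired by fragment-pattern
dot-product practice; the underlying requirement is only qualitative.

Detection requires light signal on *every* monitored transition (nonzero
integrated area — the package's operationalization of per-transition
signal) plus a minimal apex height of the reporting transition: more than
250 counts for pY-antibody samples and 300 counts for IMAC, compared on
raw, unsmoothed traces. Category 1 = confident; category 2 = present but
below threshold (values are kept as measured); category 3 = no signal on at
least one transition (missing, to be imputed). The light/heavy peak-area
ratio (PAR) on the reporting transition is the quantitative readout.

# Statistics

PARs are log2-transformed. **Imputation**: category-3 cells are drawn from
`Normal(mu − shift·sd, sd)` where `mu`/`sd` come from the category-2 values
(quantified but below threshold) and `shift` defaults to 1 — the down-shift
makes imputed values resemble ratios below the detection limit. Parameters
pool per dataset × enrichment route (pass the corresponding sub-matrix);
per-sample pooling is a documented alternative the package does not take,
because the censoring mechanism is a property of the enrichment/run, not of
individual samples. Imputation is seeded and bit-reproducible, and an audit
table of drawn values is attached.

**Moderated t-tests.** The per-row variance is squeezed toward a prior
estimated across rows under the scaled-F model `s² ~ s0²·F(d, d0)`;
hyperparameters come from the method of moments on `log s²` (closed-form
digamma/trigamma moments; the trigamma inversion takes a few Newton
steps). The statistic uses the posterior variance
`s̃² = (d0·s0² + d·s²)/(d0 + d)` and gains `d0` degrees of freedom. With
`d0 = 0` the test reduces exactly to the ordinary Student t (a tested
identity); with `d0 = ∞` every row uses the common variance. The literature
names the moderated test without formulas; empirical-Bayes variance
shrinkage is the standard interpretation, and the implementation is
cross-checked against an independent empirical-Bayes fit in the test suite.
Two-sided p-values are Benjamini–Hochberg adjusted; default significance
levels are 0.05 for cell-line contrasts and 0.1 for tissue/xenograft
contrasts, both exposed as configuration.

**ANOVA/Tukey** uses the standard single-factor decomposition per row with
Tukey HSD pairwise comparisons, BH-adjusted across all comparisons.
**Median-MAD normalization** is the robust row z-score; the MAD carries no
1.4826 consistency factor (matching the robust z-score convention of
heat-map tooling; configurable). **Sample clustering** is complete-linkage
on `1 − Spearman` over pairwise-complete rows (≥ 3 shared observations per
pair); columns are ordered lexicographically first so equal-height merges
resolve deterministically. Constant columns are an error naming the sample,
since their correlation is undefined.

# The synthetic-data module

`make_proteome()` embeds one motif per scenario class into random
tryptic-looking backbones (K/R every 10 residues): a well-behaved site, a
sub-6-residue fully cleaved form rescued by an observed 2-missed-cleavage
form, a peptide duplicated verbatim across two genes, a site trapped in a
K/R-free stretch longer than 40 residues, pY sites with and without
dual-route evidence, and a site whose doubly phosphorylated form dominates
its evidence 8-fold. `simulate_chromatograms()` produces Gaussian elution
peaks (σ = 0.1 min on a 0.05-min grid), per-transition relative intensities
shared between labels, heavy apex calibrated to 10,000 counts at the
default 30-fmol spike, additive truncated-normal noise (default 5% of the
heavy apex), and a censoring floor below which the light trace is flat
zero. `simulate_study()` draws log2 ratios directly for power/type-I work.

What the generators emulate: linear apex-to-amount response, matched
light/heavy fragmentation, co-elution of the SIL standard, left-censored
missingness, additive detector noise. What they do not: enrichment
chemistry yields, retention-time drift between runs, Poisson counting
statistics, peak tailing, or correlated interferences. Passing tests
therefore demonstrate the correctness of the bookkeeping, integration and
statistics — not robustness to chromatographic pathology.

# Numerical choices and degenerate inputs

* Trapezoid integration interpolates the boundary points; refining the
  grid changes a smooth Gaussian's area by well under 0.5%.
* A flat heavy profile yields the full trace window with a warning; an
  all-zero heavy profile is an error ("internal standard not detected").
* If every transition is interference-flagged, the least-deviating one
  reports with a warning; if the light channel is entirely empty there is
  nothing to cross-check and the strongest heavy transition reports.
* Zero-variance rows in the one-sample test stay finite through the
  shrunk variance; zero-effect zero-variance rows get t = 0, p = 1.
* Variances are floored at 1e-12 inside the hyperparameter fit only.
* Configuration files are YAML (structured text with defaults applied and
  unknown keys rejected by name).

# Problem sizes

The test-suite and acceptance-script simulations use: 9 peptides across a
100-fold ratio range for noise-free PAR recovery; 50 peptides × 3
replicates at 5% noise for the %CV summary; ≥ 10,000 imputation draws for
the calibration check; 2,000 null rows for type-I calibration; and 500
rows at 10% true effects for the power summaries. These sizes give Monte
Carlo standard errors comfortably inside the asserted tolerances while
keeping the whole suite fast on a single CPU.

# Known limitations

* No vendor/mzML ingestion; chromatograms enter as long-format TSV.
* No RT alignment across runs — the heavy standard defines per-run windows.
* Isoform resolution stops at exact-substring gene lists.
* The power attainable by the moderated test at 2 + 2 replicates with a
  1 log2-unit effect and 0.5 within-group sd is ≈ 50% per row before
  multiplicity adjustment; after BH at 10% prevalence few rows survive.
  The acceptance summary reports both raw and adjusted recovery so the
  operating characteristics are visible rather than implied.
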