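---
title: "Covalent TCR-pMHC recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covalent TCR-pMHC recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cysbond)
```

Most T cell receptors engage peptide-MHC through transient noncovalent
contacts. A CDR3 loop that places a cysteine near its apex, opposite a
cysteine in the bound peptide, can instead form a disulfide bond and convert
a fleeting encounter into a long-lived covalent complex. `cysbond`
implements the quantitative machinery for studying this mode of
recognition on three fronts: a repertoire statistic that measures how often
apex-proximal cysteines occur across T cell lineages, a two-phase binding
kinetics model for surface plasmon resonance (SPR) and tetramer-decay data,
and four-parameter logistic dose-response fitting for T cell activation
assays. Every component has a seeded synthetic-data generator, so the whole
pipeline is testable without instrument data.

## The cysteine index

A *clone* is a unique combination of a V gene and a CDR3 nucleotide
sequence within one sample; a *clonotype* is a unique (V gene, CDR3 amino
acid) pair. Clone tables arrive as AIRR Rearrangement TSVs
(`parse_airr()`), are deduplicated by `(v_gene, cdr3_nt)` with detection
counts summed over merged rows, and are productivity-filtered: junctions
whose nucleotide length is not a multiple of three, or whose translation
contains a stop codon, are dropped. CDR3 sequences use the IMGT convention,
which strips the conserved N-terminal Cys and C-terminal Trp/Phe from the
junction.

For a CDR3 of $n$ amino acids the *apex* is the residue at the largest
position not greater than $n/2 + 1$, i.e. $\lfloor n/2 \rfloor + 1$
(1-based). The **cysteine index** of a sample is the percentage of clones
with a Cys within two positions of the apex — a five-residue window,
clipped at the CDR3 boundaries. Each clone counts once regardless of its
detection count. Two exclusion rules apply to both numerator and
denominator:

* clones detected only once or twice in the sample are excluded (they are
  the most likely artifacts of sequencing error);
* beta-chain *Trbv1* clones with a CDR3 shorter than 8 amino acids are
  excluded, because *Trbv1* can contribute a germline-encoded Cys at CDR3
  position 2, and position 2 lies inside the apex window exactly when
  $n \le 7$ (for $n \ge 8$, $|\,2 - (\lfloor n/2\rfloor + 1)\,| > 2$). The
  boundary is a property of the apex rule, and the test suite asserts it
  for all lengths 4–20.

If no eligible clone carries an apex Cys the index falls back to the
reciprocal of the eligible-clone count, expressed as a percentage, so the
statistic is always strictly positive (a sample of 40 Cys-free clones
scores 2.5%). We interpret "the number of clones in the sample" in this
fallback as the post-exclusion eligible count, since excluded clones never
enter the calculation; this is a declared convention. Likewise the
five-residue window reads "within 2 positions" as inclusive distance
$\le 2$, which is the only reading consistent with the length-8 *Trbv1*
boundary. The *Trbv1* rule is applied to beta chains only, and alpha and
beta indices are always computed per chain, never pooled.

## Reference catalogs and clonotype distributions

For lineage-tracing questions we aggregate all clones detected across the
samples of a lineage into a *reference catalog* — deliberately without
cross-sample deduplication, so a clonotype found in two mice contributes
two clones ("aggregating all clones detected" is read literally; the
alternative reading would discard recurrence information). A clonotype's
*intra-lineage frequency* in a catalog is the number of clones encoding it
divided by the catalog's total clone count; its *distribution* across the
four catalogs is these frequencies normalized to sum to 100%. The
distribution is therefore invariant under uniform replication of all
catalogs, and neither the detection-count filter nor the *Trbv1* rule is
applied here (the catalog procedure defines no such filters).

## The synthetic repertoire generator

`generate_sample()` draws clones with: CDR3 length from a discretized
normal over 4–20 (mode 11, matching typical murine CDR3 length profiles);
residues i.i.d. from a background table; an engineered apex-window Cys with
probability `apex_cys_prob`, placed uniformly in the clipped window; a
germline position-2 Cys for *Trbv1* clones; a random codon back-translation
providing the nucleotide clone key (so distinct clones can encode one
clonotype); and a heavy-tailed detection count with configurable
singleton/doubleton mass (default 20%, so the count filter is exercised;
the remaining mass sits at 3 plus a geometric tail).

Defaults encode the wild-type study conditions: apex-Cys probabilities of
0.08 for CD8aa intestinal intraepithelial lymphocytes (the enriched,
agonist-selected lineage, consistent with the reported 6–10% range), 0.03
for preselection thymocytes, and 0.01 for conventional CD4/CD8 T cells;
attenuated-signaling and MHC-deficient genotypes flatten every lineage to
the preselection probability. Background residue frequencies are uniform
with Cys down-weighted to 1%, so the measured index is dominated by the
engineered probability plus a small, oracle-countable leakage (a 1% per
residue chance across a five-residue window adds roughly 4–5 percentage
points uniformly across lineages; parameter-recovery tests set the
background Cys frequency to zero to remove it).

The generator emulates the clone-table structure the statistic consumes —
not V(D)J recombination biology. It has no junctional insertion/deletion
model, no V–J pairing structure, no shared public clonotypes beyond codon
coincidences, and lineage labels are exact. Passing tests therefore
demonstrate the statistic's correctness and calibration on its stated
input model, not robustness to the full complexity of real repertoires.

## Two-phase binding kinetics

The binding model couples a reversible noncovalent complex $B_{nc}$ to an
irreversible covalent complex $B_{cov}$ (response units, RU):

$$\frac{dB_{nc}}{dt} = k_{on} C (R_{max} - B_{nc} - B_{cov})
  - (k_{off} + k_{cov}) B_{nc}, \qquad
  \frac{dB_{cov}}{dt} = k_{cov} B_{nc},$$

with analyte concentration $C$ piecewise-constant over an injection
schedule and state carried across segments without reset (matching a
sequential titration). The noncovalent affinity is
$K_{eq} = k_{off}/k_{on}$. Assumptions: no analyte depletion or mass
transport limitation; covalent complexes never dissociate (a reducing
agent such as DTT is modelled as $k_{cov} = 0$, which abolishes the
persistent phase entirely — in the model this is an exact equivalence, not
an approximation); monomeric 1:1 binding only. Any steric or rotameric
restriction on disulfide formation is represented only implicitly through
a small $k_{cov}$.

`simulate_sensorgram()` integrates the system with `deSolve`'s adaptive
stiff solver (lsoda, relative tolerance $10^{-9}$); the `dt` argument sets
only the reporting grid. The test suite checks the simulator against the
exact piecewise matrix-exponential solution of the augmented linear system
over a $3\times3\times3$ grid of $(k_{on}, k_{off}, k_{cov})$ to within
$10^{-3} R_{max}$ — the oracle lives in the tests and shares no code with
the simulator.

Derived quantities:

* **Persistent fraction.** At injection end, the fraction of bound
  receptors that will never release is
  $(B_{cov} + B_{nc}\,k_{cov}/(k_{off}+k_{cov})) / (B_{nc}+B_{cov})$ — the
  covalent pool plus the share of the noncovalent pool destined to convert
  rather than dissociate. It is zero iff $k_{cov} = 0$ and strictly
  increasing in injection duration otherwise; with a sub-second
  noncovalent half-life and $k_{cov} \sim 10^{-3}\,s^{-1}$ the per-event
  conversion probability $k_{cov}/(k_{off}+k_{cov})$ is only
  $\sim 1.4\times10^{-3}$, yet persistence accumulates to tens of percent
  over 20-minute injections.
* **Steady-state fitting.** `fit_steady_state()` fits the 1:1 Langmuir
  isotherm $R_{eq} = R_{max} C/(K_{eq} + C)$ by nonlinear least squares
  (`minpack.lm::nlsLM`, starts: $R_{max}$ at 1.5 times the largest
  response, $K_{eq}$ at the median concentration). Flat responses are
  flagged `degenerate` without fitting; fits whose $R_{max}$ standard
  error exceeds half the estimate, or whose largest response is below half
  the fitted plateau, are flagged `non_saturating` — in both cases with a
  warning rather than an error, since a flagged estimate is still a lower
  bound worth reporting.
* **Occupancy normalization.** To compare surfaces with different
  immobilization levels, the equilibrium response of a control analyte at
  concentration $C$ is scaled by $(K_{eq}+C)/C$ to the response at 100%
  occupancy (at $K_{eq} = 64.1\,\mu M$ and $C = 100\,\mu M$ the factor is
  1.641).
* **Dissociation decomposition.** `decompose_dissociation()` fits
  $R(t) = A e^{-\lambda (t - t_0)} + P$ on the post-injection window,
  separating the fast noncovalent decay (half-life $\ln 2/\lambda$; the
  fitted $\lambda$ estimates $k_{off}+k_{cov}$) from the persistent
  covalent plateau. A non-monotone window (rises above 2% of the signal
  range) triggers a quality warning.
* **Tetramer decay.** With rebinding blocked there is no association term
  and the bound pool either releases at $k_{off}$ or converts at
  $k_{cov}$:
  $\mathrm{remaining}(t) = 100\,[f_{cov} + (1-f_{cov})e^{-(k_{off}+k_{cov})t}
  + (1-f_{cov})\tfrac{k_{cov}}{k_{off}+k_{cov}}(1 - e^{-(k_{off}+k_{cov})t})]$,
  where $f_{cov}$ is the covalent fraction at blocker addition. Conversion
  strictly raises the curve above pure exponential decay at every
  timepoint, and $f_{cov}$ is a floor on the asymptote.

Rate constants are free parameters of the simulations (no instrument data
ship with the package); defaults are chosen so the noncovalent half-life is
below one second while covalent accumulation spans minutes, the regime the
two-phase interpretation describes.

## Dose-response fitting

`fit_4pl()` fits $Y = bottom + (top - bottom)/(1 + (EC_{50}/X)^h)$ by
least squares, parameterized internally on $\log EC_{50}$ for optimizer
stability and reported on the linear scale. Zero-dose control wells are
excluded (log dose undefined) but reported alongside. Starting values come
from the response range and the dose nearest the half-range.

Confidence intervals use a seeded parametric bootstrap (default 1000
resamples) rather than asymptotic Wald intervals — a deliberate,
reproducibility-motivated deviation from the commercial-package
convention. The bootstrap resamples responses from the fitted curve with
*multiplicative* lognormal noise at the coefficient of variation estimated
from relative residuals (on points above 2% of the fitted span):
immunoassay noise scales with the signal, and a homoscedastic Gaussian
bootstrap measurably undercovers the EC50 under constant-CV noise, while
the constant-CV bootstrap holds 95% intervals at nominal coverage in the
package's Monte Carlo checks (200 simulated assays).

A curve counts as having reached its plateau when the bootstrap CI width
of $top$ is below half the fitted $top$ *and* the mean response at the
highest dose is at least 90% of the fitted $top$. Otherwise the EC50 is
reported as a minimum estimate (`ec50_is_minimum_estimate = TRUE`). The
numeric thresholds are declared conventions — the underlying idea, that a
dilution series truncated below saturation can only bound the EC50 from
below, is standard; no canonical cutoff exists.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed, and one root seed
deterministically derives all per-stage seeds, so studies, bootstraps and
Monte Carlo checks are bit-reproducible. The shipped tests and the
acceptance script use: 100 random fixtures of up to 50 clones for the
index-oracle equivalence; samples of 5000 clones and 3 mice per lineage
for study-level calibration (group-mean gaps assessed in units of the
binomial standard error of the pooled apex-Cys rate); a 27-point rate grid
for the kinetics oracle; 200 replicates for the noisy $K_{eq}$ recovery
(2% multiplicative noise on the 1.5–120 µM series); and 200 simulated
assays with 200 bootstrap resamples each for EC50 coverage.

## Limitations

* The repertoire generator's simplifications (above) mean calibration
  results speak to the statistic, not to biological variation in real
  repertoires; real samples also carry V-call ambiguity and sequencing
  error upstream of this package's scope.
* The kinetics model omits analyte depletion, mass transport, bulk
  refractive-index shifts, surface heterogeneity and any reverse covalent
  rate; it is a model of the idealized two-phase mechanism, suitable for
  simulation, decomposition and steady-state analysis, not for fitting
  raw drift-contaminated sensorgrams.
* Group-level hypothesis testing (ANOVA and multiple-comparison
  procedures) is left to standard R routines on the tidy tables this
  package emits.
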