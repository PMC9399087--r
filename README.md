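# cysbond

Analysis toolkit for **covalent T cell antigen recognition** — T cell
receptors (TCRs) whose CDR3 loop places a cysteine near its apex and can
form a disulfide bond with a cysteine in the bound peptide-MHC, converting
a sub-second noncovalent encounter into a long-lived covalent complex. The
package is aimed at immunologists analysing TCR repertoire sequencing,
surface plasmon resonance (SPR) and T cell activation data around this
mechanism.

Three components, each with a seeded synthetic-data generator:

1. **Cysteine index** (repertoire statistic). For a CDR3 of *n* amino
   acids (CDR3-IMGT, conserved flanks removed) the apex is position
   ⌊*n*/2⌋ + 1; the index is the percentage of clones with a Cys within 2
   positions of the apex. Clones are unique (V gene, CDR3 nucleotide)
   pairs counted once each; clones detected only once or twice are
   excluded, as are *Trbv1* beta clones with CDR3 < 8 aa (whose
   germline position-2 Cys would otherwise sit inside the apex window);
   samples with zero apex-Cys clones score 100/*n*<sub>clones</sub> %.
   Clone tables are read and written as AIRR Rearrangement TSV.
   Reference-catalog clonotype distributions (per-lineage aggregation,
   intra-lineage frequencies normalized to 100%) are included.
2. **Two-phase binding kinetics.** dB<sub>nc</sub>/dt =
   k<sub>on</sub>C(R<sub>max</sub> − B<sub>nc</sub> − B<sub>cov</sub>) −
   (k<sub>off</sub> + k<sub>cov</sub>)B<sub>nc</sub>;
   dB<sub>cov</sub>/dt = k<sub>cov</sub>B<sub>nc</sub>, with
   piecewise-constant injections. Sensorgram simulation, 1:1 Langmuir
   steady-state fitting (K<sub>eq</sub> = k<sub>off</sub>/k<sub>on</sub>),
   occupancy normalization, exponential-plus-plateau dissociation
   decomposition, persistent-fraction analysis and tetramer-decay curves
   with rebinding blocked.
3. **Dose-response fitting.** Four-parameter logistic
   Y = bottom + (top − bottom)/(1 + (EC₅₀/X)^h) with seeded parametric
   bootstrap confidence intervals and a minimum-estimate convention for
   curves that never reach a plateau.

## Worked example

```r
library(cysbond)

# a synthetic CD8aa-IEL-like repertoire: 2000 clones, 8% engineered
# apex-window Cys, 20% singleton/doubleton mass
p <- lineage_profile(lineage = "CD8aaIEL", n_clones = 2000, apex_cys_prob = 0.08)
s <- generate_sample(p, seed = 42)
cysteine_index(s)
#> <cys_index_result> synthetic (beta): 13.873% (221/1593 apex-Cys; excluded 394 low-count, 13 Trbv1-short)
```

394 low-count clones and 13 short *Trbv1* clones were excluded; of the
1593 eligible clones, 221 carry an apex-window Cys. The index (13.9%)
exceeds the engineered 8% because the 1% background Cys frequency leaks
~5% into the five-residue window — measurable by the same count.

```r
# two-phase kinetics: sub-second noncovalent half-life, slow conversion
kp <- kinetic_params(kon = 1e4, koff = 0.7, kcov = 1e-3, rmax = 100)
vapply(c(60, 300, 1200), persistent_fraction, numeric(1),
       params = kp, concentration = 100e-6)
#> [1] 0.0583599 0.2477166 0.6358520
```

Although only ~0.14% of individual binding events convert
(k<sub>cov</sub>/(k<sub>off</sub>+k<sub>cov</sub>)), persistent binding
grows from 6% to 64% of the end-of-injection signal as the injection
lengthens from 1 to 20 minutes — the covalent pool accumulates while the
noncovalent pool turns over.

```r
# occupancy normalization: Keq = 64.1 uM control analyte at 100 uM
normalized_ru(50, keq_ref = 64.1e-6, concentration = 100e-6)$factor
#> [1] 1.641
```

## Analysis workflow

Numbered drivers under `analysis/` run the full set of studies and write
tables to `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_repertoire.R` | wild-type and attenuated-signaling synthetic cohorts as AIRR TSVs |
| `02_cysteine_index.R` | per-sample indices and lineage group means from the files on disk |
| `03_catalog_distribution.R` | four lineage catalogs and clonotype distribution table |
| `04_spr_kinetics.R` | titration sensorgrams ± covalent conversion, steady-state and dissociation fits, tetramer decay |
| `05_dose_response.R` | 4PL fits of high- and low-sensitivity simulated assays |

Run them in order with `Rscript analysis/01_simulate_repertoire.R` etc.

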