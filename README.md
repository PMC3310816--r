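# spotms

Multiple-Site ensemble models for SPOT peptide-array binding data.

## The problem

SH3 domains and similar peptide-binding modules recognize short proline-rich
motifs (the classic `PxxP` core) weakly and transiently.  SPOT-synthesis
arrays quantify this binding for thousands of 13–14-residue peptides as
light intensities (BLU), converted to pseudo-binding free energies
`G = -ln(BLU)` in RT units.  Because the recognition core spans only 4–8
residues, each array peptide contains several overlapping candidate docking
sites, and a transiently bound domain samples all of them — so attributing
the whole spot signal to one fixed site misestimates the site energies.

spotms is for anyone fitting position-specific energy models to peptide
arrays (or scanning proteomes with them) who wants the ensemble physics
handled correctly.

## The models

Every contiguous window σᵢ of size S has an additive energy
`G_P(σᵢ) = Σₛ J_{s,aₛ}` (one reference residue per position carries J = 0).

* **MS (Multiple-Site) model** — the peptide-level energy is the
  Boltzmann-weighted ensemble over all N−S+1 windows:

  `G = α − ln Σᵢ exp(−G_P(σᵢ))`

  fitted by bounded Levenberg–Marquardt least squares with random restarts
  (`ms_fit()`); α is an additive offset absorbing the imperfect
  intensity-to-energy conversion.

* **SS (Single-Site) baseline** — ordinary linear regression on one fixed
  representative window (`ss_fit()`).

* **MLP (maximum local population)** — the largest Boltzmann occupancy
  among a peptide's windows (`mlp()`): 1 means fully localized binding,
  0.5 means two sites share the domain equally.

The evaluation protocol (`crossval()`, `scan_windows()`,
`compare_models()`) is 10-fold cross-validation with std-normalized RMSE, a
median-α refit pass for the MS model, per-size scans, and the fold-paired
percent error decrease of MS relative to SS.  `simulate_spot_array()`
generates study-condition datasets with known ground truth;
`read_spot_table()` / `scan_fasta()` / `write_model_json()` handle IO.

## Worked example

```r
library(spotms)

sim <- simulate_spot_array(n_peptides = 150, lengths = 9, window_size = 3,
                           noise_sd = 0.1, seed = 42)
fit <- ms_fit(sim$records, window_size = 3, profile = "fixed_alanine",
              n_restarts = 3, seed = 1)
fit
#> Multiple-Site (MS) model fit
#>   n = 150 peptides (0 skipped), S = 3, profile 'fixed_alanine'
#>   alpha = 5.0240 RT
#>   SSE = 0.733423 RT^2  (best of 3 restarts, #2, converged)

correlate(coef(fit)[-1], coef(sim$truth)[-1])
#> [1] 0.9876015
```

The fitted α is within 0.03 RT of the generator's 5.0, the residual SSE of
0.73 RT² over 150 spots is below the injected noise budget (150 × 0.1² =
1.5, part of which the 58 fitted parameters absorb), and the fitted J
table correlates at r = 0.988 with the generating one.  The MLP view of
the first few peptides:

```r
mlp(fit, sim$records$sequence[1:3])
#>   peptide_id  sequence   energy       mlp argmin_start n_windows
#> 1    pep0001 NEWGPWEPM 1.167825 0.9193939            5         7
#> 2    pep0002 PWIPLMKMC 1.969961 0.6342490            1         7
#> 3    pep0003 PAIPMCICW 2.854307 0.5778667            5         7
```

`pep0001` binds almost entirely through the window at 0-based offset 5
(MLP 0.92); `pep0003` splits its bound population across windows
(MLP 0.58).

A command-line front end over the same functions ships at
`inst/cli/spotms.R` (subcommands `simulate`, `fit`, `predict`, `crossval`,
`mlp`, `scan-fasta`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","spotms.R",package="spotms"))')" \
  simulate --n 500 --window 6 --seed 7 --out spots.tsv
```

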