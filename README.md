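# fxivar

Structural census analysis of coagulation Factor XI (FXI) variants, for
haemostasis researchers and structural bioinformaticians who maintain or
consume FXI deficiency variant resources.

FXI is a 625-residue precursor (18-residue signal peptide + 607-residue
zymogen) of four Apple domains (Ap1–Ap4) and a serine protease (SP)
domain, circulating as a disulfide-linked homodimer. Variants of the
*F11* gene cause FXI deficiency: Type I (CRM⁻) variants lower both
coagulant activity (FXI:C) and antigen (FXI:Ag), Type II (CRM⁺)
variants lower activity only (FXI:C/FXI:Ag < 0.7). `fxivar`
re-implements the quantitative analyses behind a structural census of
such variants:

* **Census model and tabulation** — HGVS protein-change parsing with
  derived effects, HGVS↔legacy numbering (offset 18), phenotype
  classification from FXI:C/FXI:Ag, allele-frequency rarity filtering,
  and counts/percentages by event, effect, phenotype and domain.
* **Substitution analyses** — single-nucleotide reachability under the
  standard genetic code, the 20×20 substitution grid, and a
  from-scratch Grantham matrix
  *D*ᵢⱼ = ρ·[α(cᵢ−cⱼ)² + β(pᵢ−pⱼ)² + γ(vᵢ−vⱼ)²]^½, normalised to mean
  100 over the 190 amino-acid pairs (range 5–215 after rounding).
* **Solvent accessibility** — deterministic sphere-point (golden
  spiral) SASA with a 1.4 Å probe; percent accessibility relative to
  theoretical sidechain maxima; decile bins, buried = bin ≤ 1.
* **Domains and the dimer** — per-residue accessibility change upon
  domain separation (always ≥ 0), interface residues by buried surface
  area (BSA > 5 Å²), geometric disulfide detection (Sγ–Sγ ≤ 2.3 Å) and
  rigid-body dimer assembly.
* **Consensus Apple domain** — Cys-anchored alignment of Ap1–Ap4 with
  per-column variant tallies and dominant phenotypes.
* **Synthetic ground truth** — toy helices, packed pairs with designed
  contact sets, and censuses with exact requested marginals, so the
  whole pipeline tests without downloads.

A 272-variant census fixture transcribed from the published lists and
tallies is bundled, together with the curated 17-bridge disulfide table
and a clearly labelled *synthetic* FXI-like sequence.

## Worked example

```r
library(fxivar)

s <- tabulate_census(fxi_census())
s$by_event
#>       category count percent
#>          point   200   73.53
#>       deletion    19    6.99
#>      insertion     4    1.47
#>    duplication     4    1.47
#>   polymorphism    45   16.54
#>      undefined     0    0.00

rarity_filter(fxi_census(), 0.01)[c("n_common", "n_rare")]
#> $n_common  [1] 9
#> $n_rare    [1] 108

cc <- cys_census(fxi_census())
c(cc$n_cys_loss, cc$n_cys_loss_apple, cc$n_cys_loss_sp, cc$n_cys_gain)
#> [1] 28 20  8 13

G <- grantham_matrix()
c(G["Leu", "Ile"], G["Cys", "Trp"])   # closest and most radical pairs
#> [1]   5 215

hgvs_to_legacy(c(575, 135))           # catalytic Ser; founder Glu135*
#> [1] 557 117
```

Of the 272 census variants, 73.53% are point variants (77.00% of them
missense), 9 of the 117 with a gnomAD frequency are common at
AF > 0.01, and the 28 cysteine-loss plus 13 cysteine-gain variants
split 20 Apple / 8 SP, reflecting the load that disulfide-breaking
substitutions place on the FXI fold.

The numbered scripts under `analysis/` run the full study:
`01_simulate_census.R` (generator reproducing the published marginals),
`02_census_tabulation.R`, `03_substitution_grid.R`,
`04_structure_toys.R`, `05_consensus.R` and `06_report_bundle.R`, each
writing its tables under `results/`. Script 06 uses a synthetic toy
assembly unless the 6I58 crystal structure is supplied at
`data/6i58.pdb`, in which case the same structural reports are produced
for the real zymogen.

## Documentation

The methods vignette (`vignettes/fxi-variant-analysis.Rmd`) describes
the models, conventions (binning, numbering, max-ASA tables, anchors),
the design decisions taken where the source left choices open, and what
the synthetic fixtures do and do not establish about real data.
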