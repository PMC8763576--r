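---
title: "Methods: structural census analysis of Factor XI variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural census analysis of Factor XI variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fxivar)
```

# The problem

Coagulation Factor XI (FXI) is a 607-residue plasma zymogen preceded by
an 18-residue signal peptide, folded into four Apple (Ap1--Ap4) domains
and a C-terminal serine protease (SP) domain, and circulating as a
disulfide-linked homodimer. Genetic variants of the *F11* gene cause
FXI deficiency, a bleeding disorder in which Type I (CRM^-^) variants
depress both coagulant activity (FXI:C) and antigen level (FXI:Ag) --
typically through misfolding and degradation -- while Type II (CRM^+^)
variants depress activity but leave antigen normal, indicating a
functional defect in a normally secreted protein.

`fxivar` implements the quantitative backbone of a structural census of
such variants: a census data model and tabulations, substitution
analyses (genetic-code reachability and Grantham distances), solvent
accessibility and burial classification on protein structures, domain
separation and dimer-interface analysis, disulfide detection, and a
consensus Apple-domain projection. Synthetic generators supply toy
structures and censuses with known ground truth so that every stage is
testable without downloading coordinates.

# The census model

A census is a table of unique variants. Per-variant rows carry an
HGVS-style protein change (`Cys56Arg`, `Glu135*`); aggregate rows
(`aggregate = TRUE`, weight `count`) stand for groups of variants whose
individual identities are not recorded in the transcription, and enter
every tabulation with their weight. The effect of a parsed change is
derived, never trusted: a stop replacement is nonsense, identity is
silent, anything else missense, and a contradictory stated effect is an
error naming the row. Polymorphism status is a curated label (event
type and phenotype must agree); it is never inferred from allele
frequency.

Two residue numbering schemes coexist in the FXI literature.
`hgvs_to_legacy()` and `legacy_to_hgvs()` interconvert with the fixed
offset of 18 (the signal peptide), and refuse signal-peptide residues,
which have no legacy number.

Phenotype classification from laboratory values follows the ratio
rule: FXI:C within the 70--150 IU/dL normal range is unaffected; below
it, FXI:C/FXI:Ag < 0.7 is Type II, otherwise Type I; a missing antigen
measurement leaves the phenotype unknown.

```{r}
classify_phenotype(c(30, 30, 100), c(100, 35, 100))
```

Percentages in summaries are rounded half-up to two decimals, matching
the printed style of the source tallies (e.g. 73.53% point variants).

## The bundled fixture

`fxi_census()` ships a 272-variant table transcribed from printed lists
and marginal tallies. Everything individually named in the source is a
per-variant row; the remainder (e.g. most of the missense identities)
is carried by aggregate rows so that the marginals are exact. Two
kinds of entries are constructions of this package rather than
transcriptions, and are treated as such in tests: the substitution
identities at the Thr51 and Gly97 hotspot residues (the source counts
variants per residue without printing each substitution; we chose
plausible single-nucleotide changes), and the two silent variants'
identities. The 31.5 kb deletion that spans several domains is stored
without a residue position and tabulates as domain-unassigned, as do
all aggregate rows.

```{r}
s <- tabulate_census(fxi_census())
s$by_event
```

# Substitution analyses

Single-nucleotide reachability is computed from the standard nuclear
genetic code: two residues (or a residue and stop) are reachable when
some pair of their codons differs at exactly one position; identity is
reachable through synonymous codons. The 20x20 substitution grid
counts distinct missense variants per (reference, alternate) cell and
flags -- but keeps -- any record in an unreachable cell, since a
correctly transcribed census should contain none.

The Grantham distance is rebuilt from the 1974 composition, polarity
and molecular-volume properties:

$$D_{ij} = \rho\,\bigl[\alpha\,(c_i-c_j)^2 + \beta\,(p_i-p_j)^2 +
\gamma\,(v_i-v_j)^2\bigr]^{1/2}$$

with $\alpha = 1.833$, $\beta = 0.1018$, $\gamma = 0.000399$ and $\rho$
fixed so the mean over the 190 unordered pairs is 100. Integer
rounding gives the familiar published matrix: minimum 5 (Leu--Ile),
maximum 215 (Cys--Trp), zero diagonal.

```{r}
G <- grantham_matrix()
c(min(G[upper.tri(G)]), max(G))
```

# Solvent accessibility

SASA is computed by deterministic sphere-point sampling: `n_points`
(default 960) golden-section spiral points on each atom's
solvent-accessible sphere (van der Waals radius + 1.4 A water probe)
are tested against all neighbouring accessible spheres; the free
fraction times the sphere area is the atom's SASA. The spiral lattice
replaces random sampling so results are reproducible without a seed;
the default point count keeps per-residue areas within 2% of a
10,000-point reference on the toy structures used in the tests. Van
der Waals radii are the fixed element set C 1.70, N 1.55, O 1.52,
S 1.80 A. Coincident atom centres are rejected rather than silently
deduplicated.

Relative accessibility divides the sidechain SASA of each residue by a
theoretical per-residue-type maximum (`max_asa_sidechain()`, a
Gly-X-Gly extended-tripeptide-style table). Published maxima differ by
a few percent between sources and the exact table behind the original
analysis is not identifiable from the text; since the analysis
consumes decile bins rather than absolute areas, the table is
configurable and the default is documented data, not a fitted
quantity. Glycine, lacking a sidechain, is represented by its
C$\alpha$ (a common convention) with a small maximum of 25 A^2^.
Percentages above 100 can occur in extended conformations and are
allowed; the bin is capped: bin = floor(min(percent, 99.9)/10), buried
means bin 0 or 1, exposed bins 2--9. Variants at residues absent from
a structure are reported "not classified", never silently dropped.

For the synthetic helices the sidechain is a single 1.9 A pseudo-sphere
whose theoretical maximum is its own isolated-sphere area;
`max_asa_pseudo_sidechain()` supplies that table so toy percentages
stay on the 0--100 scale the bins assume.

# Domains, separation and the dimer interface

The default domain map -- signal 1--18, Ap1 19--108, Ap2 109--198, Ap3
199--288, Ap4 289--379, SP 380--625 -- brackets each Apple domain's
disulfide span (Ap1 Cys20--Cys103 ... Ap4 Cys291--Cys374) and places
the SP boundary at Cys380, upstream of the Arg387-Ile388 activation
site. The exact Ap4/SP split is not printed in the source; every
result in this package is insensitive to moving it within 375--415,
and the map is a plain argument everywhere.

Separation analysis recomputes accessibility for each domain in
isolation: removing atoms can only uncover surface, so the per-residue
bin delta (isolated - intact) is non-negative everywhere -- asserted,
not assumed -- and residues with delta >= 1 bin (ten percentage
points) are reported as interdomain contacts.

Interface analysis uses per-residue buried surface area, BSA =
SASA(monomer alone) - SASA(assembly), all atoms, with the 5 A^2^
cut-off used for the published 17-residue Ap4 dimer interface.
Disulfides are detected geometrically as S$\gamma$ pairs within 2.3 A
(covalent bonds refine near 2.05 A; 2.3 tolerates refinement noise and
excludes van der Waals contacts), resolved nearest-first so each
cysteine joins at most one bridge, with interchain pairs flagged. The
dimer itself is built from a stored rigid-body transform rather than
recomputed interface significance, avoiding any dependency on an
assembly server.

# Consensus Apple domain

The source derived its consensus Apple domain by structural
superposition. This package substitutes a cysteine-anchored sequence
alignment: the six conserved cysteines of each domain (C1..C6, forming
the C1-C6, C2-C5, C3-C4 bridges) are forced into common columns, and
the inter-anchor segments are aligned to Ap2 -- the domain
conventionally taken to represent the consensus -- by global alignment
with BLOSUM62 and affine gaps (configurable). Anchor columns are
identical to the superposition's by construction; gap placement
between anchors may differ, so the consensus length is reported, not
asserted (the bundled sequence yields 95 columns against the published
87). Variants project onto columns with per-column tallies and a
modal dominant phenotype (ties reported unknown).

# Synthetic data: what it does and does not emulate

`make_helix()` builds ideal helices (1.5 A rise, 100 degrees per
residue) with single-sphere pseudo-sidechains -- deliberately not
biophysical, but fully analytic. `make_packed_pair()` packs two
helices to a controlled surface gap and returns the designed contact
set: sidechains within gap + 2 A of the partner surface, and empty by
construction once the gap exceeds the 2.8 A water-probe diameter,
beyond which nothing can be buried. `make_census()` generates censuses
whose marginals reproduce requested counts exactly, drawing
substitutions from the bundled sequence under single-nucleotide
reachability, reproducibly under a seed.

Passing tests on these toys demonstrates that the machinery --
sampling geometry, bin bookkeeping, interface recovery, alignment
anchoring -- is correct on known ground truth. It does not demonstrate
biophysical realism: real sidechains are multi-atom and flexible, real
interfaces are irregular, and the bundled 625-residue sequence is a
synthetic stand-in (all residue identities named in the source placed
at their HGVS positions, deterministic filler elsewhere, with a filler
period of 15 chosen to divide the 90-residue Apple spacing so the four
domain stand-ins are near-identical off the constrained positions,
emulating the true paralogy of the Apple domains). Results that
depend on the true F11 translation or the 6I58 crystal coordinates --
per-residue bins of real residues, the exact 17-residue interface list
-- require those inputs, which `analysis/06_report_bundle.R` accepts
when present.

# Numerical choices and problem sizes

Defaults: probe 1.4 A, 960 sample points per atom, BSA cut-off 5 A^2^,
disulfide cut-off 2.3 A, allele-frequency cut-off 0.01 (0.001 as the
stricter alternative), contact threshold 1 bin. Tests run toys of 7--24
residues and dense cross-checks at 10,000 points, sizes at which the
whole suite completes in well under a minute of SASA time while the
sampling error stays far from every asserted tolerance. Degenerate
inputs are defined behaviour: empty censuses tabulate to empty
summaries, a single-chain assembly has an empty interface, an empty
coordinate file is rejected, and infeasible generator marginals are
errors rather than best-effort output.

# Known limitations

* Secondary structure is never computed; a classic DSSP output reader
  is provided for comparison only.
* PolyPhen-2, SIFT and PROVEAN scores are pass-through annotations.
* The consensus alignment is sequence-based; against structure-based
  superposition the anchor columns agree but inter-anchor gaps may
  not.
* Aggregate census rows carry no residue, so domain tabulations list
  them as unassigned rather than guessing.
* The sphere-sampling BSA and any PISA-style area calculation can
  disagree near the 5 A^2^ boundary; on real structures the interface
  list is best-effort at borderline residues.
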