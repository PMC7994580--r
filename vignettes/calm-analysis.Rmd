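---
title: "Methods: conservation mapping, superposition, binding surfaces and split motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation mapping, superposition, binding surfaces and split motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calmscape)
```

calmscape implements the computational core of a CALM-domain
characterisation: red algal phycobilisomes carry "lone" phycoerythrin β
subunits that are not part of a conventional αβ protomer, and the
scaffolding proteins that stabilise them do so through a small, flat
β-ribbon-plus-helix domain (the cryptophyte-α-like motif, CALM) that
binds a conserved, hydrophobic groove on PE β. Establishing that picture
requires four quantitative analyses — conservation of the binding
surface, structural similarity of the domains, hydrophobicity and burial
of the interface, and the repeat architecture of the motif — and this
vignette documents how each is modelled here, which parameters matter,
and where genuine design choices were made.

## Per-site conservation as Shannon entropy

For each alignment column the entropy in bits is

$$H = -\sum_{i=\mathrm{Ala}}^{\mathrm{Tyr}} \frac{n_i}{N}\log_2\frac{n_i}{N},$$

with $n_i$ the count of amino acid $i$ and $N$ the total count. $H = 0$
means the site is invariant; the maximum $\log_2 20 \approx 4.32$ bits
means all twenty residues are equally likely. A column with one residue
at 97 % and the rest uniform sits at $\approx 0.32$ bits, which is why
the conventional display cap of $H < 0.3$ (strict) reads as "roughly
97 % identity or better". `identity_for_entropy()` makes that reading
exact by inverting $H(p)$ for the majority-plus-uniform-remainder family
with monotone root finding on $p \in [1/20, 1]$.

**Gaps and nonstandard residues.** Published descriptions of this
calculation typically start from complete, fragment-free sequences, so
the treatment of gaps is left unstated. Two conventions are defensible
and both are implemented: the default (`gaps = "exclude"`) sets
$N = \sum_i n_i$, excluding gaps and nonstandard residues (B, Z, X, U,
O) from numerator and denominator alike so that the probabilities
normalise and $H$ remains a true entropy; `gaps = "count"` uses the
literal row count as $N$, which deflates probabilities at gappy columns.
A column with no standard residue at all gets `H = NA` with an
`undefined` flag — never a silent zero, since zero means "perfectly
conserved".

**Painting onto structures.** `map_entropy_to_bfactors()` writes each
column's entropy into the B-factor of every atom of the corresponding
residue (PDB field `%6.2f`, so values round-trip at two decimals;
$\log_2 20$ prints as `4.32`). Residues outside the correspondence get
the sentinel 99.99 — the largest visually distinct printable value —
and are excluded, and reported, by `classify_conserved()`. The
column-to-residue correspondence either follows residue numbering or is
derived by global alignment (BLOSUM62, gap open 10, extend 0.5) of the
chain's one-letter sequence against a chosen alignment row; alignment
gaps simply leave residues unmapped. Author residue numbering is always
preserved; structures are never renumbered.

## Superposition with iterative outlier rejection

`kabsch()` computes the least-squares proper rotation by SVD of the
cross-covariance matrix, with the usual determinant correction so that
reflections are never returned. `superpose()` wraps it in
refinement-with-rejection cycles: fit, compute per-pair deviations,
discard pairs deviating by more than `reject_factor` (default 2.0)
times the current RMSD, and repeat until nothing is rejected, fewer
than three pairs would remain, or `max_cycles` (default 5) fits have
run. The reported RMSD is over retained pairs only, with the retained
count alongside — the same convention as the familiar
"0.744 Å over 172 atoms" style of reporting.

Default atom selection is the backbone (N, CA, C, O): for CALM-sized
domains of 40–50 residues this yields the atom counts (~170–210) that
published comparisons of such domains quote; Cα-only and all-atom
selections are available.

**Rejection granularity.** The deviations that matter in domain
comparison are residue-level displacements, while coordinate noise is
atom-level. Rejecting individual atom pairs at `2 × RMSD` clips the
tail of the noise distribution (for Gaussian noise a few tenths of a
percent of atoms exceed the cutoff each cycle, so some clean atoms
would always be nibbled away), whereas a residue's *RMS* deviation over
its four backbone atoms concentrates sharply around the noise level and
crosses the cutoff essentially only when the residue as a whole has
moved. The default therefore rejects whole residues by their RMS
deviation (`reject_by = "residue"`); `reject_by = "atom"` gives the
classical per-pair behaviour. With the default, a pair carrying two
residues displaced by 10 Å under 0.1 Å coordinate noise yields exactly
the planted residues rejected, reproducibly across seeds.

**Structure-based sequence alignment.** After the fit, residues are
paired greedily by Cα distance: closest pair first, each residue used
once, pairs beyond `pair_cutoff` (default 4.0 Å) discarded, crossings
forbidden so sequence order is preserved, and ties broken towards the
lower mobile residue number for determinism. Greedy order-preserving
pairing is adequate for homologous globular domains; a
dynamic-programming pairing would be the natural extension if
significantly diverged topologies were in scope.

## Solvent accessibility, buried area and hydrophobic patches

`sasa()` is a Shrake–Rupley implementation: each atom's sphere (van der
Waals radius + 1.4 Å probe) is sampled with a deterministic Fibonacci
lattice of 960 points, and a point is buried when it lies *strictly*
inside a neighbouring expanded sphere — so a point exactly on a
neighbour's surface counts accessible, which makes coincident-sphere
cases deterministic. Radii are by element (C 1.70, N 1.55, O 1.52,
S 1.80, H 1.20, P 1.80, default 1.80 Å), hydrogens are ignored by
default (cryo-EM and crystallographic models usually omit them), and
doubling the point count changes totals by well under half a percent on
the test structures. An independent reference implementation (biotite's
Shrake–Rupley, called through Python) agrees within 2 % on fixtures; it
is used only as a test oracle, never at runtime.

Buried surface area is the standard half-sum
$\mathrm{BSA} = (\mathrm{SASA}_A + \mathrm{SASA}_B -
\mathrm{SASA}_{AB})/2$; interface residues are those losing more than
1.0 Å² of SASA on complexation, and the hydrophobic fraction of that
set is computed under the ɸ scheme (A, V, L, I, M, F, W, C, Y
hydrophobic; Ω = Y/F/W aromatic), with Kyte–Doolittle > 0 as an
alternative. Hydrophobic surface patches are connected components of
exposed hydrophobic residues (relative SASA above 0.05 against
Gly-X-Gly theoretical maxima) linked when their closest atoms are
within 4.5 Å, reported largest summed SASA first. All thresholds are
arguments.

## Split-motif models and repeat counting

CALM repeats present as a three-part split motif: ordered segments
separated by variable-length spacers, 2–5 copies per scaffolding
protein. Discovery from scratch is out of scope (that is a job for EM
or Gibbs samplers); instead the package builds per-segment PSSMs from a
seed alignment of motif instances,

$$s_{c,a} = \log_2\frac{n_{c,a} + q\,b_a}{(N+q)\,b_a},$$

with total pseudocount $q = 1$ distributed by the background $b$
(uniform by default). `scan_split()` finds candidate windows per
segment, assembles them left to right into triples whose spacers fall
inside the model's ranges, scores a triple as the sum of its segment
scores (spacers contribute nothing), and prunes overlaps greedily —
best score first, ties to the leftmost placement. Nonstandard positions
(X and friends) score zero per column, i.e. they neither support nor
penalise a match. Coordinates are 1-based inclusive throughout, matching
how domain boundaries are quoted in figures.

Thresholds default to 60 % of each segment's maximum achievable score —
a simple, scale-free choice — but the calibrated alternative is
preferred for recovery work: `calibrate_thresholds()` scans seeded
uniform-background null sequences and returns the per-segment null
maximum plus a 1-bit margin, which by construction yields no
background hits while keeping sensitivity. The GP-rich N-terminal motif
is handled as an ordinary single-segment PSSM of width 37.

## The synthetic-data generators

The generators exist so every stage runs against known ground truth
without downloads, and their defaults encode the study conditions the
analyses are meant for:

- `simulate_msa()`: columns follow the majority-plus-uniform-remainder
  model; the interesting regimes are 83 rows at 97 % identity (the
  depth and conservation level of a red algal PE β alignment) and 2000
  rows at 1/20 identity, where the empirical mean column entropy lands
  within 0.05 bits of the analytic $\log_2 20$.
- `simulate_structure_pair()`: an idealised helical backbone (Cα
  spacing 3.8 Å, N/C/O placed in each residue's local frame — realistic
  spacing without a forcefield) transformed by a known rotation and
  translation, plus Gaussian coordinate noise and optionally displaced
  outlier residues.
- `simulate_complex()`: two flat Cα sheets facing each other across a
  plane, residue identities hydrophobic with a planted probability; at
  100 Å spacing the chains are non-contacting (BSA exactly 0), at 4 Å a
  planar interface forms.
- `simulate_split_motifs()`: plants 0–5 motif copies per sequence with
  per-position consensus match probability `conservation`. Default
  segment widths 9/13/10 and spacer ranges (3, 8) and (4, 9) put a full
  instance at ~40–50 residues, the span of a CALM domain; the first
  segment's consensus is aromatic-biased, mirroring the aromatic-rich
  leading segment of real repeats. Widths and ranges are parameters
  because the real segment boundaries are figure-level knowledge, not
  constants.

Each generator call runs on its own RNG stream seeded from its `seed`
argument, so identical seeds give byte-identical outputs and calls do
not disturb the caller's RNG. What the generators deliberately do *not*
model: phylogenetic correlation between sequences (columns are i.i.d.
across rows), side-chain packing, chromophores, and realistic amino
acid composition. Passing tests therefore demonstrate algorithmic
correctness against controlled truth, not performance on the quirks of
real alignments or cryo-EM models.

## Problem sizes, pipelines and limitations

The checked quantities use deliberately modest sizes — 200 random
instances of up to 50 points for the superposition oracle comparison
(agreement with the independent quaternion method to 1e−8), 30-residue
chains for outlier recovery, 32-residue complexes for interface
analysis, and six sequences per copy-number condition (2–5 copies at
conservation 0.9) for motif recovery — chosen so the whole suite runs
in seconds while leaving the statistical margins wide.

The file-level drivers `run_entropy_map()`, `run_compare()` and
`run_interface()` chain the stages on FASTA/PDB inputs, write fixed-name
outputs, and record a manifest (input hashes, all parameters, package
version); reruns on identical inputs are byte-identical. They are plain
R functions rather than a shell entry point: in a tibble-first package
the functions themselves are the scripting interface, and the manifest
carries the reproducibility burden a CLI would otherwise hold.

Known limitations: PDB fixed-column format only (no mmCIF); the initial
atom correspondence for superposition comes from residue
numbering/naming, not from sequence- or secondary-structure-independent
search; no motif E-value statistics (thresholds are calibrated on
nulls instead); no electrostatics or binding-energy estimation; and
reproducing published RMSD values for specific deposited structures
requires those coordinate files as local inputs — the algorithms
support it, but no downloads happen here.
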