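---
title: "Structural statistics of protein conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural statistics of protein conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strucstats)
```

## The problem

Comparing an ensemble of protein structures — crystal structures of the
same protein in different ligation states, NMR models, homologues —
requires a common coordinate system in two senses: a *residue*
correspondence (which residue of structure A matches which residue of
structure B) and, for Cartesian measures, a *spatial* superposition.
Once both are in place, the ensemble can be summarized position by
position: how much does each part of the chain move, in Cartesian space
and in the internal (torsion-angle) coordinates, and do the conformers
fall into discrete states?

`strucstats` implements this pipeline: PDB input under explicit policies,
alignment-position mapping, Kabsch superposition, per-position Cartesian
and circular (dihedral) statistics, and complete-linkage clustering of
conformers in dihedral space.

## Input policies

PDB files are parsed from their fixed columns; only `ATOM` records are
used (`HETATM` are ignored), only the *first model* of multi-model files
is read, and when an atom has alternate locations only the *first one in
file order* is kept — deliberately not the highest-occupancy one, so the
rule is order-deterministic.  Chain selection mirrors common ensemble
usage: `"first"` (default) autodetects the chain of the first `ATOM`
record, `"*"` keeps all chains, `"_"` selects a blank chain id, any other
character matches exactly.  Hydrogens are retained on input but excluded
from the statistics groups (X-ray ensembles rarely carry them; mixing
protonated and unprotonated structures would bias fluctuations).  Records
ending before the B-factor column get `b = 0` with a warning.

An ensemble is described by a *Structure list* (basename, optional chain
spec, optional family label per line) and optionally a *Position list*
(alignment-position ranges plus dihedral names) restricting clustering
and distribution summaries.

## Residue correspondence

Two routes build the alignment:

* **Numbering-based** (`align_by_numbering()`): columns are the sorted
  union of residue keys (number + insertion code; the chain id enters the
  key only when a structure carries several chains, so multi-chain
  ensembles cannot collide numbers across chains).  This is exact and
  fast but *assumes consistent numbering* across the ensemble.
* **User-supplied MSA** (`read_alignment()`): aligned FASTA or CLUSTAL.
  Rows are matched to structures by label (basename, optionally
  `label:CHAIN`), never by file order — order-only files are rejected so
  rows cannot silently bind to the wrong structure.  Each row, degapped,
  must equal the structure's extracted sequence exactly.

Computing alignments de novo is out of scope; outputs of standard MSA
programs are accepted instead, which keeps the package self-contained
and testable offline.  Positions are numbered from 1 by default and can
be shifted (`renumber()`) to match a reference numbering such as a
kinase's conventional residue numbers.

## Superposition

`superpose_ensemble()` fits every structure onto a reference (the first
structure unless specified) with the closed-form Kabsch solution: SVD of
the cross-covariance of the matched, centered point sets, with the
reflection branch corrected so the rotation is proper.  Matched atoms
are those of the chosen set (backbone N, CA, C, O by default — robust to
sidechain differences across sequences; `calpha` as the lighter option)
present in both structures at mutually non-gap columns.  This is a
single-pass least-squares optimum: no iterative outlier trimming and no
maximum-likelihood covariance weighting — the well-defined reference
behaviour for a superposition stage that is in principle pluggable.

Properties the tests enforce: the optimum never increases the
matched-atom RMSD, re-superposing a superposed ensemble is a fixed point
(transforms within 1e-6 of identity), and the result matches a
brute-force rotation search (Euler-angle grid plus local refinement) to
1e-3 Å on small point sets.

## Cartesian statistics

For each alignment position and atom group (backbone = N, CA, C, O;
sidechain = all other heavy atoms, OXT in neither), each atom name
present in at least two structures contributes a population
root-mean-square fluctuation
$f_a = \sqrt{\tfrac{1}{N_a}\sum_s \lVert r_{s,a} - \bar r_a\rVert^2}$,
and the position reports $\sqrt{\operatorname{mean}_a f_a^2}$
(RMS-combining; averaging inside the square root rather than of the
roots is a documented convention choice).  The population ($1/N$) form
is used rather than the sample ($1/(N{-}1)$) form, matching the RMSF
convention; for two points this gives half their separation.  Atoms seen
in only one structure still enter the B-factor average (which is a plain
arithmetic mean over all contributing group atoms) but cannot contribute
a fluctuation.  Glycine-only positions therefore report sidechain
fluctuation 0 with zero contributing atoms — the expected zero points in
sidechain fluctuation profiles.  Note the B-factor column may carry
other quantities in non-crystallographic files.

## Torsion angles and their undefined values

`torsion_angle()` uses the IUPAC sign convention (planar *cis* = 0°,
*trans* = 180°), values in (−180°, 180°].  Under this convention a
dihedral is invariant under reversing the four points and changes sign
under mirror reflection — both are property-tested, as is agreement with
an independent implementation.

Backbone angles follow φ(i) = C(i−1)–N(i)–CA(i)–C(i),
ψ(i) = N(i)–CA(i)–C(i)–N(i+1), ω(i) = CA(i)–C(i)–N(i+1)–CA(i+1) (ω
attributed to residue i).  φ is undefined at the N-terminal side of a
contiguous stretch, ψ and ω at the C-terminal side.  *Contiguous* is
operationalized as a peptide C(i)–N(i+1) distance below 2.5 Å within the
same chain — the standard bond-distance criterion; a gap in the model
(or an engineered 4 Å break in a test fixture) severs the angles that
span it.  Missing atoms make the affected angle undefined rather than
raising an error.

χ1–χ4 follow the standard heavy-atom quadruple table (χ1 ends at CG, or
CG1 for Ile/Val, OG for Ser, OG1 for Thr, SG for Cys; Pro has χ1/χ2
only; Ala and Gly none).  Values of 2-fold-degenerate terminal dihedrals
(Phe/Tyr χ2, Asp χ2, Glu χ3) are reported raw, without symmetry folding;
any folding rule would halve their apparent spread, so the choice is
documented and left to the interpretation stage.

## Circular statistics

Torsions live on the circle, so per-position summaries use the vector
resultant: the mean is the direction of the resultant (undefined when
its length is numerically zero, e.g. an antipodal pair — an error, not a
silent 0), and the dispersion is Mardia's circular standard deviation
$s = \sqrt{-2\ln\bar R}$ reported in degrees.  This estimator is one
documented choice among several (the arc-based deviation being the main
alternative) and is isolated behind `circular_sd()` so it can be
swapped; for tightly clustered samples it agrees with the linear
standard deviation to well below 0.01°, which the tests assert.
Summaries are computed globally and, when the Structure list assigns
families, per family.

## Clustering

The conformer metric is the circular distance between selected dihedral
angles: for a pair of structures, distances are taken over all selected
(position, angle) variables where *both* have a defined value, and
aggregated by arithmetic mean (default).  The mean keeps the pair
distance in degrees on the same scale as a single angle and hence
directly comparable to the cluster radius; RMS and maximum are provided
as alternatives since the aggregation is a genuine design choice.  Pairs
compared over very different variable counts (min < 50% of max) trigger
a warning; a pair with no shared variables is an error naming the pair.

Agglomeration is complete ("maximum") linkage, implemented directly
(naive O(n³), ample for ensembles of tens to hundreds of conformers)
with a deterministic tie-break towards the smallest leaf indices; merge
heights are checked in the tests against an independent complete-linkage
implementation and are monotone by construction.  The flat cut applies
every merge *strictly below* the radius and refuses the rest, so the
radius (default 60°) is literally the minimum complete-linkage distance
allowed between surviving clusters: a merge at exactly the radius is
refused.  Cluster ids are 1-based in decreasing size order.  The tree is
written as ultrametric Newick with node depths equal to merge heights,
and a regenerated Structure list with cluster ids in the family column
lets a clustering seed a second, family-stratified run.

## The synthetic builder

`build_chain()` constructs peptide chains from torsion targets by
sequential NeRF placement with idealized geometry (N–CA 1.458 Å,
CA–C 1.525 Å, C–N 1.329 Å; backbone angles 111°/117°/121°), including
sidechain atoms along the χ chains.  Because each torsion is recomputed
from exactly the quadruple used to place the fourth atom, the
build→measure round trip is exact to numerical precision (< 1e-6°),
which anchors the torsion tests.  `build_ensemble()` adds family torsion
offsets and wrapped-normal noise *in torsion space* — never Cartesian —
so family separation is controlled exactly where the clustering metric
lives, and is bit-reproducible for a fixed seed.

What the generator emulates: multi-state ensembles with localized
torsion variability and optional chain breaks.  What it does not:
realistic sidechain rotamer coupling, sterics, correlated backbone
motions, crystallographic noise, missing density, or alternate
conformations.  Passing tests therefore demonstrate the statistics and
clustering machinery, not robustness to the full messiness of deposited
PDB entries.

### Study conditions used in the test suite

The recurring fixture is a 12-residue chain with two families whose φ/ψ
centers differ by 120° over positions 4–9, within-family wrapped-normal
noise of 5°, and 10 structures per family; clustering over φ/ψ of
positions 4–9 at the default 60° radius then recovers the two states at
100% purity.  These sizes mirror, at desk scale, the two-state
(inactive/active) structure ensembles this kind of analysis is used for,
with a between-state separation far exceeding within-state spread.

## Numerical choices and degenerate inputs

* Angles are stored in degrees throughout; trigonometry converts
  locally.  Values are wrapped into (−180°, 180°].
* Torsions with coincident or collinear consecutive points raise errors;
  within structures, missing atoms yield `NA` instead.
* `kabsch()` requires ≥ 3 point pairs and rejects (near-)collinear
  configurations, where the rotation is not identifiable.
* The circular mean/sd treat resultant lengths below 1e-12 as undefined.
* All pipeline outputs are written with fixed-format numbers, so
  repeated runs are byte-identical — there is no hidden nondeterminism
  to average away.

## Known limitations

* Numbering-based alignment trusts the deposited numbering; it cannot
  detect consistent-but-wrong numbering.
* mmCIF, gzipped input and PDB-code download are out of scope, as are
  external MSA/superposition programs (their output files are accepted).
* The circular-sd estimator and the pair-distance aggregation are
  documented defaults, not the only defensible choices; both are isolated
  behind single functions/arguments for exactly that reason.
* A repeated chain id interleaved with other chains is treated as one
  chain (records grouped by id, chains ordered by first appearance).
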