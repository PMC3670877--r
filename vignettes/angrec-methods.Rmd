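---
title: "Methods: comparative analysis of the Ang peptide receptors"
author: "angrec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of the Ang peptide receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angrec)
```

# Scope and model

The renin–angiotensin system signals through three class-A GPCRs — AT1
and AT2 (angiotensin II receptors) and MAS (the Ang-(1–7) receptor).
The three receptors bind closely related angiotensin peptides yet
trigger different, sometimes opposing, responses, and comparative
sequence/structure analysis is the standard way to ask *which residues
make the difference*.  `angrec` implements that comparison as a
reusable pipeline:

1. **Family alignments and percent identity** (`pairwise_global_align`,
   `build_msa`, `percent_identity`),
2. **Residue-class consensus symbols** per aligned column
   (`consensus_sequence`),
3. **Helix-based consensus numbering** and **cross-family conservation
   categories** (`assign_consensus_numbers`, `classify_position`,
   `divergence_report`),
4. **Structural mapping** of categories onto receptor models
   (`kabsch_superpose`, `pocket_residues`, `annotate_structure`),
5. **Docking-pose scoring and ranking** with a simplified nonbonded
   energy, cross-receptor rescoring, and distance-constrained rigid
   placement (`binding_energy`, `rank_and_select`, `cross_rescore`,
   `generate_constrained_poses`),
6. **Trajectory statistics** (`ca_rmsd_series`, `per_residue_rmsf`,
   `average_structure`, `residue_distance_series`),
7. A **synthetic-data module** that generates every input with planted,
   recoverable structure, and
8. A config-driven **pipeline** (`run_pipeline`) with manifest and
   per-stage resume.

Homology modelling, molecular-dynamics *production* (we analyse
trajectories, we do not generate physics), AutoDock pose generation and
full structural alignment (MUSTANG-style) are deliberately out of
scope; where those tools' outputs are needed, they are inputs.

# Sequence stage

**Pairwise alignment.** Global Needleman–Wunsch alignment with affine
gaps stands in for the ClustalW pairwise step; it is delegated to
`Biostrings::pairwiseAlignment` with ClustalW-like defaults (BLOSUM62,
gap open 10, gap extend 0.5; a gap of length $L$ costs
$10 + 0.5L$).  The test suite checks the optimal score against an
independent full Gotoh dynamic-programming oracle on hundreds of random
pairs.  Traceback tie-breaking is whatever Biostrings does —
deterministic, but not configurable; every quantity we derive from an
alignment (score, percent identity, merged gap patterns) is invariant
to the tie choice.

**Percent identity.**  The published pairwise "% sequence homology"
numbers for these receptors never state the aligner or the denominator.
We use the most common convention: columns in which *both* sequences
carry a residue form the denominator, identical letters the numerator.
Exact reproduction of a published percentage therefore depends on the
original tool's gap placement; agreement should be expected to a couple
of percentage points, not to the printed decimals.

**Multiple alignment.**  `build_msa` is a center-star progressive
merger: the center is the sequence with the highest summed pairwise
identity; every other member is pairwise-aligned to the center and the
gap patterns merged under "once a gap, always a gap".  This preserves
each pairwise alignment against the center exactly, never produces an
all-gap column, and is adequate for the near-gapless within-family
alignments this analysis works on.  It is *not* a ClustalW
re-implementation (no guide tree, no profile–profile step); externally
computed alignments (Clustal `.aln` or aligned FASTA) can be supplied
through `read_alignment` and bypass it.

# Consensus symbols

Each aligned column is summarised by one symbol
(`residue_class_scheme`):

| symbol | class | residues |
|---|---|---|
| a letter | 100% identical column | that letter |
| β | polar acidic | D, E |
| µ | polar basic | K, R, H |
| ∞ | hydroxyl | S, T |
| π | aromatic | F, W, H, Y |
| α | hydrophobic | A, V, L, I, F, W, M, P |
| . | no conservation | — |

The classes overlap on purpose (H is basic *and* aromatic; F and W
hydrophobic *and* aromatic).  The scheme's source never states which
symbol wins when a column satisfies two classes, so we declare a
precedence — smaller, more specific class first:
**β > µ > ∞ > π > α** — and make it configurable
(`residue_class_scheme(precedence = ...)`).  A column containing any
gap is annotated "." : within-family alignments here are near-gapless,
and a gapped column carries no positional conservation signal.

# Consensus numbering and conservation categories

Transmembrane positions are labelled $100h + k$: helix number $h$ in
the hundreds place, $k$ the 1-based offset within the helix, so 101 is
the first residue of helix 1 and 512 the twelfth residue of helix 5.
Loop residues carry no number.  Helix boundaries are an *input*
(`helix_annotation`, TSV): they were chosen by the original modelling
work and never published, so the package ships only a synthetic fixture
annotation and treats real boundaries as user data.  Consequently the
package can reproduce the numbering *scheme* exactly but not the
original paper-specific numbers unless the same boundaries are
supplied.

Each aligned position is then placed in one of five categories, in
priority order: `gpcr_common` (membership in a user-supplied list of
class-A motif positions — the list is configuration, not inference),
`all_conserved` (shared by AT1, AT2, MAS and the outgroup, typically
rhodopsin), `trio_conserved` (the three receptor families only),
`pair_conserved` (AT1 and AT2 only), else `unconserved`.  Two symbols
"share" conservation when they are equal letters, letters of one common
class, equal class symbols — or a class symbol with a letter of that
class, a natural extension we adopt so that a family conserved *as a
class* can match a family fixed at one residue of that class.

`divergence_report` joins the categories with each receptor's native
numbering and a curated functional-residue table, and flags positions
aromatic in AT1/AT2 but not MAS — the pattern behind the differential
handling of the C-terminal Phe of Ang II (consensus 621), which MAS
(Met) cannot stabilise.

# Structural mapping

Superposition is least-squares rigid-body fitting (Kabsch, via SVD) of
matched CA atoms, where the residue matching comes from the sequence
alignment — we do not re-derive it from structure.  Tests verify
machine-precision recovery of planted rigid transforms and agreement
with an independent quaternion-eigendecomposition oracle to $10^{-6}$ Å.
Binding-pocket residues are those with any heavy atom within a cutoff
(default 6 Å — a conventional contact-shell radius; the choice is a
parameter, not a claim) of a probe ligand or point.  Conservation
categories are painted into the B-factor column with a fixed code table
(`category_codes`: unmapped 0, gpcr_common 1, all_conserved 2,
trio_conserved 3, pair_conserved 4, unconserved 5) so the annotated PDB
is bit-stable and renders directly in any molecular viewer's B-factor
coloring.

# Pose scoring, ranking, constraints

The original docking analysis scored AMBER03/YASARA energies; those
magnitudes are not reproducible outside that stack.  `angrec` instead
uses a deliberately simple pairwise nonbonded energy,

$$E = \sum_{i<j} 4\varepsilon_{ij}\left[\left(\tfrac{\sigma_{ij}}{r_{ij}}\right)^{12} - \left(\tfrac{\sigma_{ij}}{r_{ij}}\right)^{6}\right] + \frac{332.06\, q_i q_j}{D(r_{ij})\, r_{ij}},$$

with Lorentz–Berthelot mixing, distance-dependent dielectric
$D(r) = 4r$, and a 10 Å cutoff.  Only *orderings and signs* of the
resulting energies are meaningful; absolute values are not comparable
with a full force field.  Note the potential energies are plain vacuum
nonbonded sums with no bonded-pair exclusions, so the intra-molecular
PE of a covalently bonded ligand is large and constant across rigid
poses; it cancels exactly in the binding energy.

The binding energy is $BE = E_{rec} + E_{lig} - E_{complex}$; with a
pairwise-additive energy this equals minus the receptor–ligand
cross-interaction energy, an identity the tests assert to $10^{-9}$.
**Sign convention: more positive = more favourable**, matching the
"highest binding energy is best" usage of the original ranking macros.
`rank_and_select` ranks an ensemble's poses by BE descending and keeps
the best $k$ (default 3, mirroring the top-10 → top-3 treatment); ties
break by ascending pose index.  The ranking source text is ambiguous
about whether all four reported metrics or only BE are rank-compiled;
we rank by BE only, which is the only reading that makes the
"three lowest rank values" selection well defined with a single score.

`rigid_minimize` is a deterministic pattern search over the six
rigid-body degrees of freedom (±translations, ±rotations about the
centroid, step halving on failure); ligands are rigid throughout —
internal flexibility belongs to the out-of-scope docking engine.
`cross_rescore` re-scores top poses against other receptors after
(optionally) minimizing on each; receptors must share the pose frame,
or per-receptor rigid transforms (from `kabsch_superpose`) must be
supplied.

Mutagenesis and photolabeling data enter as *distance constraints*
(`check_constraints`): e.g. the ligand C-terminal carboxylate within
5 Å of the basic residue at consensus 512 plus the residue-8 ring
within 6 Å of the aromatic residue at consensus 621 ("initial"
binding), or the C-terminus within 5 Å of consensus 725 (AT1) / 336
(AT2) ("buried" binding).  The shipped JSON files encode these as
conventions — the distances are package choices, the experimental
literature gives none.  `generate_constrained_poses` rejection-samples
uniformly random rigid placements around the constraint anchor until
all constraints hold and the pose is clash-free; 20 placements per set
by default, mirroring a twenty-fold manual docking, all reproducible
from one seed.

# Trajectory statistics

Trajectories are multi-model PDB (binary MD formats are out of scope).
Per-frame CA RMSD and per-residue RMSF are computed after superposing
every frame onto the *initial* frame (frame-1 RMSD is 0 by definition);
the RMSF here is the RMS deviation of each CA from its initial
position — "averaged movement from the starting structure" — not the
deviation from the time-mean.  The average structure is the per-atom
mean after the same fitting.  Distance series are computed without
superposition, since interatomic distances are frame-invariant.

# Synthetic data: the study conditions

The generators plant exactly the structure the analyses are supposed to
recover, so every stage has a ground truth:

* `gen_family_alignment` — families sized like the species panels the
  comparison was built on (AT1 14 species, AT2 4, MAS 8), gapless,
  with a per-column planted symbol; sampling pools are chosen so a
  noise-free column classifies to exactly the planted symbol under the
  default precedence (e.g. planted α avoids F/W, which would classify
  as π).  Substitution noise is i.i.d. per cell from outside the
  planted class.
* `gen_7tm_bundle` — seven ideal α-helical CA traces (1.5 Å rise,
  100°/residue, 2.3 Å helix radius, consecutive CA ≈ 3.8 Å) on a
  circle, 24 residues per helix by default (a typical TM helix
  length), with short interpolated loops and the matching helix
  annotation.
* `gen_pose_set` — rigid ligand copies along the outward axis through
  the receptor's most exposed atom, first pose at 5.5 Å separation and
  0.55 Å per rank step: beyond the LJ minimum the attraction decays
  monotonically, so the planted rank order is realized; the generator
  *verifies* this after scoring and refuses geometries that cannot
  realize it.
* `gen_trajectory` — frame 1 is the base structure; later frames add
  i.i.d. Gaussian jitter (per-atom σ allowed, so a mobile loop can sit
  against rigid helices) and optionally displace one residue along the
  axis to a second residue so their distance grows linearly by a
  planted amount (3 Å by default, the magnitude of the helix-stretch
  signal the trajectory analysis is meant to detect).

What the synthetic data does **not** emulate: real substitution
processes (no phylogeny), real protein geometry beyond CA traces, and
real force-field energetics.  Passing tests therefore demonstrate that
the *computations* are correct and recover planted signal, not that the
biology of any particular receptor is reproduced; real-data conclusions
still require real alignments, models and trajectories as inputs.

# Numerical choices

* Kabsch via LAPACK SVD with the determinant sign correction; matched
  sets must have ≥ 3 non-collinear CA pairs.
* Interatomic distances below $10^{-6}$ Å raise a clash error rather
  than returning an astronomically large energy.
* All RNG flows through explicit integer seeds; generators save and
  restore the caller's RNG state (`with_seed`), so library calls never
  perturb a session's random stream.
* Pipeline TSV numbers are written with fixed 10-significant-digit
  formatting so reruns are byte-identical; the manifest records MD5
  checksums per output file plus all stage seeds.
* Problem sizes used by the shipped checks (default bundle ≈ 190
  residues, 2000-frame trajectories for fluctuation recovery, 200
  random alignment pairs, 500 ranking ensembles) were chosen as the
  smallest sizes at which the statistical recoveries are comfortably
  inside their tolerances.

# Known limitations

* Published identity percentages depend on unstated aligner choices
  (see above); published model-vs-model RMSDs and absolute energies
  are not reproducible because the models, ensembles and trajectories
  behind them were never deposited.
* The consensus-numbering scheme needs helix boundaries as input; with
  different boundaries the same residue gets a different number.
* The energy model has no solvation, polarization or bonded terms; use
  it to rank and compare, never to report kcal/mol against experiment.
* `build_msa` is quadratic in family size and intended for the small
  (≤ ~20 member) families this analysis uses.
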