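---
title: "Methods: a desk-scale ML-enhanced virtual screen for degradation-site binders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale ML-enhanced virtual screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wasscreen)
```

# The screening problem

WASp, the actin nucleation-promoting factor of hematopoietic cells, is
degraded after ubiquitylation of two lysines (K76/K81) on its WH1
domain; in the resting complex that surface is shielded by the
chaperone WIP. A small molecule that binds the WH1 surface next to
those lysines can promote WASp degradation selectively in
hematopoietic (including malignant) cells. `wasscreen` implements the
computational arm of such a campaign: prepare a surrogate receptor
model from a homolog structure, generate ligand conformers, dock them
rigidly into the targeted site, convert each docking model into an
interaction fingerprint, score it with a random-forest binder
classifier, and keep only candidates whose pose lies within 5 Å of the
degradation-site lysines, with a SwissADME-style drug-likeness panel
for the survivors. The closed-form assay models used to characterize a
hit (binding isotherm, FRET efficiency, degradation and tumor metrics)
are included as well.

# Stage-by-stage model

## Receptor preparation

Structures are flat atom tables parsed from PDB (via bio3d; alternate
locations other than blank/'A' are dropped). A surrogate receptor is
produced by virtual point mutagenesis, e.g. the set V71A, A72V, L74F,
R81K in the structure's own numbering: backbone atoms (N, CA, C, O and
CB where the target has one) are never moved; the side chain beyond CB
is rebuilt from an idealized internal-coordinate template (single
canonical rotamer, chi angles trans) anchored on the residue's own
N/CA/CB frame. Truncating mutations reduce to atom deletion, so a
mutation followed by its reverse restores the residue exactly.
Component deletion (`delete_components`) removes, e.g., the chaperone
peptide; the removed atoms are retained as the reference set for the
interface clash check of final candidates.

## Conformers

Heavy-atom conformers are laid out along a BFS spanning tree with
ideal bond lengths (covalent-radius sums scaled by bond order) and
hybridization-dependent angles; rotatable-bond torsions come from the
staggered set {180°, +60°, -60°}, the first conformer being all-trans.
Each candidate is minimized under a Dreiding-style objective: harmonic
bonds (k = 300), 1-3 distance restraints standing in for angle bending
(k = 60), planarity restraints across aromatic six-rings (k = 30) and
12-6 nonbonded terms (eps = 0.1, r_min = 0.85 x Bondi sum) between
atoms three or more bonds apart. Minimization is L-BFGS with an
analytic gradient and never returns a higher energy than its input;
symmetric saddle traps in fused-ring layouts are broken by up to two
seeded jitter restarts. Conformers are deduplicated greedily
(lowest energy first) at 0.5 Å superposition RMSD (Kabsch, no
atom-symmetry correction) and capped at 10 per molecule by default.
Bonded atoms must end 0.9-1.9 Å apart (2.1 Å for bonds to Br/I, whose
equilibrium lengths exceed 1.9 Å).

## Docking

Poses are the cross product of seeded uniform random rotations
(Shoemake quaternions; the first is the identity) and translations on
a 1 Å lattice inside the site sphere. Scoring is geometric: contacts
are receptor-ligand heavy-atom pairs with distance in [3.0, 4.5] Å,
clashes are pairs below the Bondi van-der-Waals sum minus 0.4 Å, and
the composite is `contacts - 5 x clashes`. Poses cluster greedily,
best score first, at 4 Å ligand-RMSD in the common receptor frame (no
re-superposition; poses are alternatives at one site). When refinement
is enabled, local rigid-body (6-DOF) searches minimize a smooth 12-6
interaction energy from two kinds of starts: the top cluster
representatives by score, and a deterministic orientation covering —
the ligand's first conformer placed at the site centroid under the 24
rotations of the chiral octahedral group. The covering matters in snug
pockets: the near-native basin is reachable only from approximately
the right orientation, and sampled poses near it carry clashes that
rank them last by score, so score-ranked starts alone miss it and
recovery would depend on the random rotation draw. A refined pose
replaces its start only if its composite does not drop, and a penalty
keeps the ligand centroid within site radius + 2 Å.

## Features and classifier

Each docking model becomes a fixed 65-entry fingerprint: 60 contact
counts binned by receptor atom class {C,N,O,S,other} x ligand atom
class {C,N,O,other} x distance shell {[0,2.5), [2.5,3.5), [3.5,4.5)},
plus H-bond pairs (N/O vs N/O within 3.5 Å), hydrophobic C-C contacts
within 4.5 Å, the buried-ligand fraction, the composite score and the
ligand heavy-atom count. The classifier is a bagged-CART random
forest: 500 trees by default, Gini impurity, ceiling(sqrt(F))
candidate features per split, trees grown to purity, deterministic for
a fixed seed, serializable to versioned JSON with identical
predictions after a round trip. The binder score of a model is the
fraction of trees voting the positive class. Positive training
examples are redocked cognate complexes; negatives are a seeded
derangement of the same ligands over non-cognate receptors, giving
exact class balance.

## Site filter and ranking

A candidate passes iff the minimum distance from its best pose's heavy
atoms to any atom of the tagged site residues is at most 5.0 Å —
inclusive at the boundary, matching a discard rule stated as "farther
than 5 Å". Passing candidates are ranked by classifier score with
deterministic tie-breaks (higher contact count, then lexicographic
id); failures are retained, flagged and logged with the rule that
removed them.

## Descriptor panel

Molecular weight uses IUPAC 2021 atomic weights (3 decimals) over
heavy atoms plus implicit hydrogens. TPSA is the Ertl
fragment-contribution sum over N/O/S/P environments; an environment
missing from the table falls back to the generic N (3.24) or O (9.23)
contribution with a warning. H-bond donors are N/O atoms bearing
hydrogen; acceptors are all O plus N excluding amide/imide N and
pyrrole-type aromatic N — the rule that reproduces an acceptor count
of 4 for a C28H35N3O3 compound with two imide N, one amine N, two
carbonyl O and one ether O. logP is the single Wildman-Crippen atomic
model (a web-tool consensus of several models will differ; the panel
treats published consensus values as a +-1.5 sanity band only). logS
is Delaney's ESOL. Rotatable bonds are non-ring single bonds between
heavy atoms of degree >= 2, excluding amide C-N. The Abbott
bioavailability score follows Martin's rule table: anionic at pH 7
(formal charge or carboxylic/sulfonic/phosphoric acid) is bucketed by
TPSA (> 150: 0.11; 75-150: 0.56; < 75: 0.85), otherwise 0.55 with at
most one Lipinski violation and 0.17 with two or more. The radar axes
use the SwissADME default ranges stored in `RADAR_RANGES`.

## Assay models

Titrations follow the ligand-excess 1:1 hyperbola
`S(c) = S_u + (S_b - S_u) c/(c + Kd)`; the titrated compound is in
vast excess over the fluorescent protein, so the ligand-depletion
quadratic is unnecessary. A two-fold serial dilution of 18 points from
200 uM ends at 1.5 nM, the span used for MST-style curves. `fit_kd`
runs Levenberg-Marquardt least squares from seven log-spaced Kd starts
and reports the linearized standard error from the fit covariance;
flat curves and sub-4-point designs are rejected as unidentifiable.
FRET efficiency, percent gelatin degradation, ellipsoidal tumor
volume, the TD50 from a linear viability trend and the plasma-protein
binding percentage are direct formula implementations with input
validation.

# The synthetic benchmark: what it emulates and what it does not

No public set of validated complexes ships with the package; instead
the generators build a fully synthetic, seeded benchmark:

* **Receptors** are pseudo-atom constructs: either a lattice shell
  with a concave pocket (`make_toy_receptor`) or a shape-complementary
  wall built around a planted ligand pose
  (`make_complementary_receptor`), with two rim pseudo-residues tagged
  as degradation-site lysines 76 and 81. Walls sit at the low edge of
  the contact shell (3.1-3.35 Å from their anchor atom, no closer than
  3.02 Å to any other ligand atom): the planted pose is then both
  clash-free and contact-optimal, so the composite-score landscape
  genuinely peaks at the planted register. Wall atoms anchored at
  ligand N/O atoms are typed N or O, emulating the favorable polar
  contacts of a cognate complex.
* **Cognate ligands** are acyclic branched C/N/O molecules
  (`make_branched_ligand`, 9-16 heavy atoms, 2-4 polar atoms, at least
  two branch points). Acyclic branched skeletons are strongly
  shape-asymmetric, so redocking recovers the planted orientation;
  ring systems with near-symmetric silhouettes would flip in a purely
  geometric score and blur the training labels.
* **Decoys** come from a fragment grammar of drug-like cores and
  substituents (`make_decoy_library`). The decoy library plays the
  role of the fixed external screening collection, so it is seeded
  independently of the master seed.
* **The screen benchmark** (`make_screen_benchmark`) builds 11
  training and 8 held-out cognate complexes with ligand sizes
  interleaved across the splits, trains the forest on redocked
  positives versus deranged negatives, evaluates held-out AUC, and
  screens the first held-out receptor's cognate ligand (the planted
  binder) against 99 decoys.

Default desk-scale problem sizes: 1 conformer per benchmark molecule,
24 docking orientations per grid point, a 2 Å translation-grid radius,
0.03 Å receptor jitter and 500 trees. These sizes keep a full 10-seed
benchmark run to minutes while exercising every stage; they are
deliberately far smaller than a production screen of hundreds of
thousands of compounds.

What passing the synthetic benchmark does **not** show: pseudo-atom
pockets have no real side-chain chemistry, electrostatics or
flexibility; the polar-contact signal is a geometric emulation of
hydrogen bonding, not an energy model; decoys and binders are far
smaller than typical screening hits; and the classifier is trained on
tens, not thousands, of complexes. Results on this benchmark validate
the machinery (determinism, scoring, learning, filtering), not
prospective enrichment on real targets.

# Numerical choices and degenerate inputs

* Clash tolerance 0.4 Å (the common crystallographic convention);
  Bondi radii in `BONDI_RADII`.
* The site-proximity comparison is inclusive at exactly 5.0 Å; a
  candidate at 4.9 Å passes and one at 5.1 Å fails.
* Pose sampling returns an empty list (with a warning) only when every
  sampled pose clashes *and* none achieves a positive composite —
  near-native poses in snug cavities often carry one resolvable clash,
  and discarding them would void docking exactly where it matters.
* `fit_kd` refuses flat curves (signal SD ~ 0) and designs with fewer
  than four points; `td50_linear` requires the fitted line to cross
  50% viability inside the dose range.
* Empty molecules give a molecular weight of 0 and an empty formula;
  single-atom molecules embed trivially.
* All randomness is drawn through a private RNG scope (`with_seed`),
  so library code never perturbs the caller's RNG state, and master
  seeds map to per-component child seeds through a fixed integer
  schedule, so adding a fixture never changes an existing one.

# Known limitations

* The SMILES dialect is the organic subset plus bracket
  charges/H-counts; stereochemistry is parsed but ignored.
* Side-chain templates cover the 16 amino acids without rings in the
  chi-1+ path (no HIS/TRP/PRO rebuild targets); a single canonical
  rotamer is used, adequate for the coarse downstream scoring.
* The docking score is purely geometric; no electrostatics, solvation
  or torsional strain. Patch-style shape complementarity is emulated
  with a simple contact/clash count, not a production docking engine.
* The forest uses axis-aligned splits on raw counts; with the small
  training sets of the synthetic benchmark its variance is visible in
  the out-of-bag estimate.
* The Kd standard error is the linearized (Jacobian-based) estimate; a
  bootstrap is straightforward but not built in.
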