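---
title: "Profiling immunoglobulin:pMHC interfaces: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling immunoglobulin:pMHC interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmhcprofiler)
```

## The problem

T-cell receptors (TCRs) recognise short peptides presented in the groove of
Major Histocompatibility Complex molecules (pMHC); TCR-mimetic antibodies
(TCRms) are engineered to do the same. Whether a given antibody engages a
pMHC "like a TCR" is a structural and energetic question: how much surface
it buries on the peptide versus the MHC helices, which CDR loops do the
work, at what angle and polarity it sits over the groove, and where its
binding energy concentrates. `pmhcprofiler` computes these quantities from
coordinates plus a chain-role/numbering annotation, so that any
immunoglobulin:pMHC complex can be scored against the conventions observed
in TCRs.

The pipeline has five analysis stages — surface burial, interface
interaction typing, binding geometry, dataset curation, and binding-energy
decomposition statistics — plus deterministic synthetic-fixture generators
that let every stage be tested without structure downloads.

## Data model

A complex is loaded from PDB or mmCIF (via bio3d) and sanitized: hydrogens,
waters, heteroatoms and alternate locations are removed (altlocs resolve to
the highest-occupancy record, ties to the first). Roles
(HEAVY/LIGHT/TCR_BETA/TCR_ALPHA/MHC_ALPHA/MHC_BETA/B2M/PEPTIDE) and IMGT or
renumbered-MHC numbers come from a TSV sidecar; the sidecar always wins
over any heuristic, because curation must be deterministic. Numbering is
consumed, not computed: assigning IMGT numbers to sequences is a solved
problem with dedicated tools, and this package only requires their output.

CDR loops are delimited on IMGT numbers: CDR1 27–38, CDR2 56–65, CDR3
105–117, identically for heavy/light/beta/alpha chains; everything else in
a variable domain is framework. Antibody heavy and TCR beta chains are both
V(D)J-recombined, light and alpha chains VJ-recombined, which is the
pairing used whenever heavy-vs-beta or light-vs-alpha quantities are
compared. MHC helix windows are configurable and default to renumbered
50–86 (α1) and 138–176 (α2) on the class-I α chain; for class II the
second window is looked up on the β chain. The renumbering scheme itself is
supplied by the user through the sidecar, since conventions differ between
pipelines.

## Buried surface area

Solvent-accessible surface area uses the Shrake–Rupley construction: each
atom's sphere is expanded by the probe radius (1.4 Å, a water molecule) and
covered with a deterministic golden-spiral lattice; a lattice point is
accessible iff it lies outside every other atom's expanded sphere. We chose
a deterministic lattice over random sampling so results are bit-reproducible
at any point count; the default of 960 points puts the isolated-sphere
error well below 0.5% and agrees with an independent dense (10^5-point)
sampler to within 2% on multi-atom fixtures (both checked in the test
suite). Neighbour search uses a cell grid whose cells equal the largest
expanded diameter; the tests assert it returns exactly the all-pairs
neighbour set.

Van der Waals radii are pinned (C 1.70, N 1.55, O 1.52, S 1.80 Å) and an
unknown element is an error, never a silent default, because the radius
table scales every downstream number. Different published radius tables and
point counts shift absolute SASA values at the percent level, which is the
expected magnitude of disagreement when comparing against other
implementations.

Burial is apo-minus-complex: each partner's SASA is recomputed with the
other partner's coordinates deleted, and the per-residue difference is its
buried surface area (BSA). Because the identical lattice is used in both
states, occlusion can only remove accessible points, so ΔSASA ≥ 0 holds
exactly and the interface BSA decomposes exactly into the immunoglobulin
and antigen sides. A residue counts as "buried" when its ΔSASA exceeds
0.01 Å² — a strict "decreased at all" test on floating point would be
noise-sensitive at exactly-zero differences. Aggregates follow the
profiling conventions: per-CDR fractions of immunoglobulin BSA, the
VDJ-chain CDR3 share of the CDR3-pair BSA, the peptide share of pMHC BSA
(peptide_bsa / (peptide_bsa + mhc_bsa)), and the buried-peptide-residue
count.

## Interface interactions

Four attractive interaction types are assigned from heavy-atom geometry:

* hydrophobic — apolar-carbon pairs ≤ 4.5 Å (apolar = carbons not bonded
  to N/O, from a per-residue atom-name table);
* aromatic — ring-centroid distance ≤ 5.0 Å for Phe/Tyr/Trp/His rings;
* hydrogen bond — donor heavy atom to acceptor ≤ 3.5 Å with an
  antecedent–donor–acceptor angle ≥ 90°; geometries failing the angle test
  are never emitted, so "weak" distance-only hydrogen bonds do not appear;
* salt-bridge candidate — Asp/Glu carboxylate oxygen to Lys NZ, Arg
  NH1/NH2/NE or His ND1/NE2 ≤ 4.0 Å. His is treated as positively charged
  by default (there is no protonation model); this is configurable.

These cutoffs live in a criteria object so users can tune them to match an
external contact-typing tool, and an importer accepts externally produced
contact tables in a documented TSV layout.

Atom contacts consolidate to residue-pair interactions: multiple
hydrophobic (or aromatic) atom contacts collapse to one interaction of that
type; a pair may carry both, reflecting their different physical origins.
Salt-bridge candidates are resolved so that each positive/negative charge
pairing yields exactly one salt bridge, assigned greedily to the residue
pair with the closest atom–atom distance (ties break to the
lexicographically smaller pair, for determinism); candidates that lose are
recorded as hydrogen bonds. In region-level summaries, a pair carrying both
a hydrophobic and an aromatic interaction counts twice, once per type —
totals are cardinalities of (residue pair, type) entries. This is an
interpretation choice: the alternative (counting such pairs once) would
lower total interaction counts slightly.

## Binding geometry

The groove frame consists of an axis, an origin and a platform-plane
normal. The axis is either the principal component of the Cα atoms of both
helix windows (`helix_axis`) or the vector through the peptide anchor Cα
atoms (`anchor_ca`, anchors defaulting to position 2 and the C-terminus),
oriented N→C along the peptide. The platform normal is the best-fit plane
through helix Cα atoms. By default both helices contribute: the Cα cloud of
one straight helix is nearly cylindrically symmetric about its own axis, so
a single-helix best-fit plane is numerically ill-conditioned, whereas the
two-helix platform is well-determined. An α1-only window remains available
for users who want the literal single-helix construction.

The docking/crossing angle is measured between the groove axis and the line
connecting the conserved centres of the two variable domains, both
projected into the platform plane (projection makes the angle well-defined
for binders approaching at different elevations). Each domain centre is the
midpoint of the Cα atoms of its conserved IMGT-23 and IMGT-104 cysteines —
the disulfide that anchors every immunoglobulin variable domain — exposed
as a parameter so alternative anchor sets can be supplied. The inter-domain
vector points from the VJ-chain centre to the VDJ-chain centre, so
canonically docked TCRs fall in the 30–60° band and reverse-polarity
binders near the supplement; relabelling the chains maps θ to 180 − θ.

Polarity is called by assignment cost: canonical iff placing the VDJ domain
over the α1-helix C-terminal-half centroid and the VJ domain over the α2
C-terminal-half centroid gives a smaller total distance than the swapped
assignment. Diagonality folds angles to min(θ, 180 − θ) before comparing
against the inclusive range of a reference cohort, since canonical and
reverse binders with the same degree of diagonality are pooled on absolute
angle. The arginine guanidino tilt — used to distinguish extended,
protruding Arg side chains from ones lying along the helix — is the angle
between the best-fit plane of NE/CZ/NH1/NH2 and the platform plane, folded
to [0°, 90°].

## Dataset curation

Representative non-redundant sets are built in two greedy clustering
rounds, in the style of cd-hit: records are first quality-filtered (X-ray,
resolution ≤ 2.5 Å); concatenated CDR sequences cluster at 80% identity
into paratope clusters; within each paratope cluster, concatenated antigen
sequences (descending length; the presented peptide for TCRs) cluster at
80% identity with a minimum alignment coverage of only 20% of the shorter
sequence, so a truncated antigen construct groups with its full-length
parent rather than counting as a new target. One representative survives
per (paratope, antigen) cluster: best resolution, ties to the
lexicographically smaller identifier — the representative rule is this
package's own convention, as greedy-clustering tools do not fix one.

Identity is computed from an exact global alignment scoring match +1,
mismatch 0 and gaps 0 (so the optimum maximises matched columns), with
identity = matches / alignment columns after stripping terminal-gap
columns and coverage = that span / shorter-sequence length. This is a
documented substitute for cd-hit's internal short-vs-representative word
heuristics; at desk scale, exactness is worth more than speed. One caveat
is inherent to gapped identity: co-optimal alignments can differ in span,
so identities for very dissimilar pairs are alignment-dependent —
irrelevant near the 0.8 threshold, where alignments are essentially
ungapped. Clustering seeds by descending length (ties by identifier), so
results are independent of input file order.

## Energy-decomposition statistics

The molecular-dynamics/MMGBSA machinery that produces per-residue energy
decompositions is out of scope; this package consumes its output tables
(TSV: chain, resnum, icode, energy_kcal_mol; negative = attractive). When
an ensemble of per-frame tables is supplied they are averaged per residue
first, so hotspots are called on ensemble means.

Hotspots are residues contributing −7 kcal/mol or stronger; semi-hotspots
lie in (−7, −4]. Boundaries are inclusive towards the stronger category and
calling is monotone in energy. Regional fractions divide the attractive
magnitude of each of peptide / α1 helix / α2 helix by their total — the
normalisation is pinned to those three regions only, a documented
assumption since other pMHC surface could in principle be included; a
repulsive (net-positive) region is clipped to zero and flagged. CDR energy
fractions divide each loop's sum by the total over all six loops; loops
with repulsive sums are passed to zero after normalisation, so unclipped
fractions sum to exactly one while clipped fractions sum to one plus the
clipped amount.

## What the synthetic fixtures do and do not emulate

The groove generator builds two idealised poly-Ala α-helices (2.3 Å radius,
1.5 Å/residue rise, 100°/residue) flanking an extended Cα-only peptide,
plus a two-domain binder whose conserved-cysteine anchors realise a
requested docking angle and whose CDR3 pseudo-atoms hang 5.2 Å above each
requested peptide position — close enough to occlude that residue's
expanded sphere, far enough (≥ 6.2 Å centre distance) not to touch its
neighbours, so planted burial counts are recovered exactly. In this
scaffold angle and polarity are coupled (below 90° canonical, above 90°
reverse, with reverse poses mirrored across the groove axis), and poses
near 90° are excluded from test sampling because polarity is undefined when
the inter-domain line is perpendicular to the groove. Generators use a
pinned xorshift PRNG, so outputs are byte-stable across platforms and never
touch R's global RNG.

These fixtures are deliberately not physical: no realistic immunoglobulin
fold, no side chains beyond what the contact typing needs, no
peptide–groove packing. Passing tests therefore demonstrate the
correctness of the geometry, burial, counting and clustering machinery —
not that any particular biological cohort statistic will be reproduced,
which additionally depends on the input structures, the radius table and
the numbering quality. The decomposition generator plants exact hotspot
energies over a truncated Gaussian background (mean −1, sd 0.5 kcal/mol,
values above zero rejected), chosen so that spurious background hotspots
are effectively impossible while the background remains attractive on
average, as per-residue decompositions of a stable interface typically
are.

## Problem sizes and runtime choices

The shipped tests run the SASA oracle comparison on 3-atom fixtures with a
10^5-point dense sampler, burial invariants on 100 random two-sided
fixtures (240-point lattice; the lattice count does not affect the exact
invariants being checked), geometry recovery on 50 random poses under
random rigid-body transforms, clustering recovery on 15–20 sequence sets of
length 50–60, and all planted-hotspot patterns. The whole suite completes
in well under a minute on a single CPU; the acceptance script recomputes
the same headline quantities from scratch in comparable time.

## Known limitations

* Rigid-structure analysis only: no induced fit in either the SASA or the
  energy post-processing.
* Identity under zero-cost gaps is alignment-dependent for very dissimilar
  sequence pairs (co-optimal spans differ).
* The hydrogen-bond model is heavy-atom geometric; protonation states
  (notably His) are conventions, not chemistry.
* The docking-angle convention (disulfide midpoints, platform-plane
  projection) reproduces its literature lineage only up to those two
  choices; both are configurable for calibration against other
  implementations.
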