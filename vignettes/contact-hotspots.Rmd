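---
title: "Contact co-occurrence and the hot-spot model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact co-occurrence and the hot-spot model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotRF)
```

## The problem

A binding hot spot is an interfacial residue whose mutation to alanine
raises the binding free energy change of a protein-protein complex by at
least 2 kcal/mol. Experimentally these are found by alanine scanning;
computationally, hotspotRF regresses the per-mutation ddG (kcal/mol) from
a structural descriptor of the mutation's atomic environment and calls
hot spots by thresholding the prediction. The descriptor is built from
three ingredients: *beta contacts* across and around the interface,
*co-occurrence* of contact pairs linked by short covalent paths, and
*normalized crystallographic B factors* that weight every contact by
local rigidity.

## Beta contacts

Two atoms i and j are in beta contact when

* `dist(i, j) <= td_factor * (vdw_i + vdw_j)` with `td_factor = 1.25`, and
* no third atom k sees the pair under an angle `>= 85` degrees
  (`angle(i, k, j)` measured at k). The angle criterion is the
  beta-skeleton "forbidden region" condition: a large angle at k means k
  sits between i and j and physically interrupts the contact.

Geometric choices worth stating explicitly:

* Interrupters are tested at atom centers only; interrupter radii do not
  inflate the forbidden region. This is an assumption -- the original
  skeleton construction admits either convention -- and a configuration
  switch is reserved for the alternative.
* Pairs within 2 covalent-bond steps are never counted as contacts: a
  1-2 pair is a bond and a 1-3 pair is angle-coupled through its middle
  atom (which also interrupts it under the 85-degree rule in ideal
  geometry). Without this rule bonded neighbours at 1.5 A would dominate
  every contact vector.
* Aromatic rings (PHE, TYR, HIS, both TRP rings) are augmented with two
  pseudo-atoms 0.5 A above and below the ring centroid along the
  least-squares plane normal. Pseudo-atoms can *be* endpoints (pi
  contacts) but never interrupt -- they are bookkeeping, not matter. They
  carry the ring's mean B factor, the aromatic-carbon van der Waals
  radius, and are treated as one covalent step from every ring atom so
  that nearby-atom semantics reach pi contacts.
* A crystallographic water joins the graph only when it is buried
  (solvent-accessible surface area below 1 square Angstrom in the
  complex, waters included as occluders) and makes at least three beta
  contacts with donor or acceptor atoms (protein N or O); water-water
  contacts are never counted.

The interface graph is assembled in three layers: *interfacial* atoms
have at least one cross-interface beta contact; *supporting* atoms
contact an interfacial atom; the *neighborhood* adds every non-backbone
atom within 3 covalent-bond steps of either. All contacts touching the
neighborhood form the graph. Covalent bonds themselves are inferred by
distance (1.9 A heavy-heavy, 2.2 A when sulfur is involved, peptide
C-N bonds between consecutive residues) rather than residue templates,
which keeps the rule robust on idealized synthetic fixtures.

## The 143-element descriptor

Each alanine mutation is described by 143 features, in this order:

| block | length | content |
|---|---|---|
| dASA | 2 | `ln(dASA + 1)` and `dASA / ASA_unbound` of the mutated residue |
| B factor | 8 | `(Bavg, Bdif)` in the slot pair of the residue's amino-acid group |
| mutated contacts | 14 | per-type sums over contacts touching mutated atoms |
| neighborhood | 14 | per-type sums over cross-interface contacts in the mutation's neighborhood |
| co-occurrence | 105 | per-type-pair sums over co-occurring contact pairs |

The compact label of feature k is `Vk`; e.g. V14 is the mutated
hydrophobic-contact element and V84 the co-occurrence of hydrophobic and
pi contacts. *Mutated atoms* are the side-chain heavy atoms beyond CB --
the atoms an X-to-Ala substitution removes -- plus the residue's ring
pseudo-atoms; this set is the standard alanine-scanning convention and is
stated here because the choice is not forced by the model.

B factors are normalized per complex: after sorting, the lowest 1% and
highest 9% of atomic B factors are dropped (guarding deposited zeros and
outliers; fractions are applied with `floor`, population standard
deviation is used), then `B_norm = (B - mean) / (1.645 * sd)` maps the
90% confidence interval to [-1, 1], and the working value is
`(B_norm - 1)` clamped to [-2, 0]: an atom at the complex mean scores -1,
a rigid atom -2, a flexible one 0 ("-2 or 0, whichever is closer" for
values outside the interval). Every contact carries the
weight `(B_i + B_j) / 2` of its endpoints' clamped values, so all
contact-derived features are non-positive and more negative means more,
and more rigid, contacts.

Two contacts *co-occur* when an endpoint of one is within 3
covalent-bond steps (including 0, a shared atom) of an endpoint of the
other. The co-occurrence block sums, for each unordered pair of the 14
contact types, the combined weights of qualifying pairs in which at
least one member is a mutated contact; each unordered pair contributes
exactly once.

Atom typing uses 10 groups and contact typing 14 types, shipped as
editable TSVs under `extdata/`. No complete reference partition is
available for either, so the bundled tables are *reconstructions*
anchored on the well-established type semantics (hydrogen
bonds, C_c/C_on carbon split by covalent topology, pi contacts,
acceptor-acceptor, salt bridges), with the remaining groups (sulfur,
water, donor-donor splits) filled to total exactly 10 and 14. Models
trained with a different completion of the tables will differ in detail
but not in structure.

ASA is computed by the Shrake-Rupley construction (default 960
golden-spiral points per atom, probe 1.4 A; neither value is prescribed
by the method, both are the field's conventional defaults). The dASA
features use `ln(dASA + 1)`: the natural log with a +1 guard against
zero burial, a choice the code documents and isolates. The unbound
reference is each side's atoms
alone; waters are excluded from the protein ASA tables and included only
for the water-burial rule.

## The regressor

A randomForest regression with 500 trees and a minimum terminal node of
3 mutations, `mtry` one third of the retained features (the regression
convention; the method prescribes only the first two values). Features
with 3 or fewer non-zero values are dropped *inside each training fold*
-- the alternative, filtering once on the full data, leaks test-fold
information, and the defensible fold-local choice is used throughout.
Evaluation is leave-complex-out: all mutations of one complex are held
out together, so homologous neighbours never split across folds.
Permutation importance is reported as %IncMSE -- the relative increase
in out-of-bag mean squared error after permuting one feature, averaged
over 5 repeats -- computed from the forest's per-tree in-bag records.

Classification metrics (precision, recall, F1, accuracy, specificity,
negative precision) use inclusive thresholds: observed ddG >= 2 kcal/mol
defines a true hot spot ('Strong' for categorically labeled data --
'Intermediate' is *not* positive, which the bundled three-complex
benchmark confirms arithmetically), and predicted ddG >= 1.5 kcal/mol
defines a predicted one, compensating the regressor's compression of
extreme ddG values. Undefined ratios (empty denominator) are reported as
`NA`, never as 0.

## The synthetic study system

Real training corpora for this method require curated alanine-scanning
databases and PDB downloads; the package instead ships a generator of
idealized two-chain complexes so that every claim is testable
hermetically.

Chains are straight strands with 2.77 A residue spacing; side chains
are rigid ideal-geometry templates pointing at the partner chain on
alternating positions, and each facing pair is placed tip-to-tip across
a gap drawn from [3.3, 3.7] A (within every heavy-atom contact cutoff at
`td_factor = 1.25`). B factors are Gaussian (per-complex mean 20-55 A^2,
sd 6-16, truncated at 1). The default study set is 20 complexes of 12+12
residues with up to 15 mutations each (about 300 mutations), sized so
the full generate-extract-crossvalidate cycle runs in minutes on one
CPU. ddG is a planted linear signal over the extracted features --
concentrated on the hydrophobic, hydrogen-bond and pi contact classes
the method emphasizes, with weights calibrated once so hot-spot
prevalence lands near the 10-35% range of curated datasets -- plus
Gaussian noise at signal-to-noise 2:1. Dedicated fixtures plant a
hydrogen-bond network with exactly counted co-occurrences (an arginine
donating to 1-3 serine acceptors placed along ideal donor directions)
and a buried-water icosahedral cage that switches the water rule on and
off.

What the generator does *not* emulate: side-chain rotamers, backbone
curvature, crystallographic disorder, correlated B factors, or physical
energetics -- the planted ddG is linear by construction. Green tests
therefore certify the machinery (geometry, typing, bookkeeping,
learning, validation), not predictive accuracy on real complexes, which
depends on the unavailable published typing tables and curated data.

## Numerical conventions

* Feature sums are accumulated in value-sorted order, so descriptors are
  bit-identical under any permutation of the input atom order.
* Alternate locations resolve to the highest occupancy, ties to file
  order; hydrogens are discarded; only the first NMR model is read;
  non-standard residues are skipped with a warning; a missing B factor
  is fatal (the method requires them).
* Gly-to-Ala mutations are rejected (backbone reconfiguration risk), as
  are mutations of alanine itself.
* All randomness (forest, permutations, generators) flows from a single
  integer seed; equal seeds give byte-identical fixtures and
  predictions.

## Known limitations

* The 10-group/14-type tables are reconstructions (see above); exact
  reproduction of the published importance ranking is out of reach and
  out of scope.
* The Shrake-Rupley ASA is numeric; analytic surface areas and
  solvent-excluded surfaces are not provided.
* mmCIF input and hydrogen placement are unsupported.
* The interruption test is centers-only; an interrupter-radius variant
  is a planned configuration switch.
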