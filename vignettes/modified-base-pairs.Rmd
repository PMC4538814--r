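---
title: "Classifying and modelling modified RNA base pairs with modbp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and modelling modified RNA base pairs with modbp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modbp)
```

## The problem

Posttranscriptional modifications enlarge the chemical alphabet of RNA, and a
large fraction of the modified nucleobases seen in crystal structures are
hydrogen-bonded to another base. `modbp` provides the machinery to study such
*modified base pairs*: it detects hydrogen bonds in 3D structures, assigns an
extended Leontis--Westhof geometry label to each H-bonded pair, aggregates
annotations into an occurrence atlas with best-resolution representatives,
builds capped, hydrogen-completed model fragments ready for external
quantum-chemistry engines, generates unmodified counterparts that preserve
the H-bonding pattern, and implements the bookkeeping of counterpoise-corrected
interaction energies

$$E_\mathrm{int} = E_\mathrm{BP} - (E_\mathrm{B1} + E_\mathrm{B2}) + \mathrm{BSSE}$$

and of the *modification energy*

$$E_\mathrm{Mod} = E_\mathrm{int}(\text{modified pair}) -
                   E_\mathrm{int}(\text{unmodified pair}),$$

where a negative $E_\mathrm{Mod}$ means the modification stabilizes the pair.
Quantum chemistry itself is out of scope: any function mapping a fragment to
an energy can be plugged in, and the packaged toy backend exists only to
exercise the pipeline (its numbers are not physical).

## The chemistry dictionary

The heart of the package is a plain-text dictionary
(`inst/extdata/nucleobase_dictionary.txt`) describing the four canonical
ribonucleosides, eleven natural modifications (m1A, m66A, m1G, m2G, m22G,
m7G, m5C, m5U, s4U, H2U and pseudouridine) and three non-natural halogenated
pyrimidines (5BrC, 5BrU, 5IU). For each residue it stores idealized
heavy-atom coordinates in a standard frame, covalent topology, implicit
hydrogen counts, H-bond donor/acceptor roles, and the Leontis--Westhof edge
of every atom. The geometries were generated once with a molecular-mechanics
optimization (MMFF94) and the base flattened onto its best plane; they are
idealized templates, not experimental coordinates.

Three choices deserve comment:

* **Boundary atoms.** Atoms such as N6 of adenine, O6 of guanine, N4 of
  cytosine and O2/O4 of uracil sit between two H-bonding faces. A strict
  one-atom-one-edge vote is not robust for them: with equal-length H-bonds a
  shortest-bond tie break flips under tiny coordinate changes. The dictionary
  therefore stores a primary and a secondary edge for such atoms, and each
  contact is resolved by the direction of the partner atom in the base's own
  plane. The majority vote and the shortest-bond tie break then apply.
* **Dihydrouridine** is intrinsically non-planar; its template is a
  half-chair with ring dihedrals N1-C6-C5-C4 of about $-50^\circ$ and
  N1-C2-N3-C4 of about $-10^\circ$, and it is exempt from the planarity
  invariant.
* **m2G methyl orientation.** Whether the single N2 methyl blocks the
  Watson--Crick or the sugar edge is a per-instance conformational fact. The
  template stores the *anti* rotamer (methyl on the sugar side), which is the
  conformation required by the frequent regular m2G:C Watson--Crick pair; the
  dictionary lists both W and S as potentially affected edges.

Pseudouridine is attached to the ribose through C5 rather than N1, so its
edges follow the *structural* ring correspondence with uridine
(C5→N1, C4→C2, O4→O2, N3→N3, C2→C4, O2→O4, N1→C5, C6→C6), obtained by
walking both rings from the glycosidic attachment in the same rotational
sense. The same map is used when superposing Ψ-containing fragments onto
their uridine counterparts, and it is the RMSD-optimal ring walk (the test
suite verifies this against the alternative walk).

## Hydrogen-bond detection

X-ray structures usually lack hydrogens, so detection works on heavy atoms:

* donor--acceptor distance between 2.4 and 3.5 Å (configurable),
* approach angle (covalent neighbour)--donor--acceptor of at least 90°,
* donor capability limited to the number of hydrogens the donor carries
  (an imino nitrogen donates once, an amino nitrogen at most twice),
* C--H donors excluded by default.

The source study inherited its criteria from an external annotation tool and
does not state them; the defaults above are conventions. The angle default is
90° rather than a more common 100° for one specific reason: the bifurcated
Ψ:G pair, in which both N1--H and N2--H of guanine reach the same O4 acceptor,
has an intrinsic donor angle of ≈96° at N2 for any sensible distance
combination — at a 100° cutoff the published bifurcated pattern would be
undetectable. Since weak C--H donors are excluded anyway, the looser angle
does not flood the output with spurious contacts.

Waters (HOH/WAT/H2O) are never counted as direct pair bonds; a water whose
oxygen lies within the H-bond distance of base atoms of *both* residues is
reported as a bridge and sets the `(w)` flag.

## The extended label

A label such as `tS(w)S(r)` is read: *trans* orientation, sugar edge of the
first (modified) base — with a cross-edge note `(w)` meaning the partner's
ribose additionally binds this base's Watson--Crick edge — sugar edge of the
second base, whose own 2'-OH takes part (`(r)`). A trailing `1` marks a pair
held by a single H-bond; the count includes ribose contacts and
water-mediated links, which reproduces every printed label in the packaged
atlas (a pair with one direct bond plus a bridging water is *not* written
with a `1`). Cross-edge notes are emitted for the leading (modified) base
only, which is how the published atlas itself behaves.

Orientation is the pseudo-torsion C1'--glycosidic--glycosidic--C1', cis when
its magnitude is below 90° and trans otherwise (the boundary maps to trans).
Pairing plausibility requires an interplane angle of at most 70° and rejects
stacked geometries: near-parallel planes (interplane < 30°) displaced by more
than 2.5 Å along the normal. The displacement alone is deliberately not
sufficient for rejection, because ribose-mediated pairs can be strongly
inclined with a large centroid offset while being genuine pairs.

## The synthetic-structure generator

`generate_pair()` realizes any of the 36 atlas pair types as an idealized
structure: base 1 fixed in its template frame, base 2 posed so that the
recipe's donor--acceptor distances are satisfied (within 0.05 Å for the
primary bonds) with the bases coplanar; auxiliary soft constraints keep
approach angles realistic and a steric term keeps the optimizer out of
overlapped minima. Recipes that involve a ribose 2'-OH gain the glycosidic
torsion of that sugar as an extra degree of freedom. Two published types are
handled by a deterministic enumeration instead of the smooth optimizer: the
strained H2U:G trans W/S pair, and the 5BrU:A ribose-mediated pair, which is
intrinsically non-coplanar and is posed by anchoring the two bonded atoms
directly.

Every solved pose is self-checked: running the package's own H-bond detection
and classifier on the generated structure must reproduce exactly the recipe's
bond set and geometry string. Poses are solved once and cached; noise trials
(seeded Gaussian displacement of heavy atoms) reuse the cached pose.

Bond-distance targets are 2.9 Å by default, with per-bond values where
published pair geometry or template feasibility dictates (e.g. 2.91/2.98/2.86
for the three G:C Watson--Crick bonds, 3.3 Å to a thioketone sulfur). The
synthetic data emulate idealized, noise-controlled geometries of every pair
type; they do not emulate crystallographic context (neighbouring residues,
backbone, alternate conformations, crystal contacts), so passing round-trip
tests demonstrate internal consistency of generator and classifier, not
performance on experimental files — which the structure readers accept, but
for which no ground truth ships with the package.

### One contradictory published type

For the aptamer pair `5BrU:A cW(r)S` no physically realizable H-bond pattern
classifies as *cis* W(r)S under the rules above: the only sugar-edge-capable
adenine acceptor is N3, the 5BrU imino and 2'-OH donor cones cannot chelate
two nearby adenine atoms, and every realizable W(r)S arrangement has a
pseudo-torsion magnitude of at least ≈130°, i.e. solidly trans. The published
label also disagrees with the H-bond atoms printed alongside it. The
generator therefore realizes this type as `tW(r)S`, and the package reports
the classification round-trip as 35 of 36 exact rather than forcing
agreement. All other 35 types round-trip exactly.

## Fragments and counterparts

Base-only residues are truncated at C1', kept as a methyl carbon; riboses are
retained when their 2'-OH participates in the pair, in which case the 5'
side becomes a methyl (phosphate and O5' removed) and the 3' side is capped
by deleting O3' and saturating C3' — the published wording ("replaced by a
methyl group") is ambiguous for the 3'-OH, so the alternative reading
(O3' replaced by a carbon) is available as a configuration. Hydrogens are
placed at idealized geometry (N--H 1.01 Å, O--H 0.96 Å, C--H 1.09 Å, sp²/sp³
angles); bridging-water hydrogens point at the bridged acceptors.

Counterpart generation replaces each modified base by its parent while
preserving the H-bonding pattern: mapped atoms keep their coordinates exactly
(zero RMSD over the correspondence set before any optimization), removed
substituents disappear, S4→O4 keeps the bond direction rescaled to the
parent's C4=O4 template length, and hydrogens are rebuilt. For dihydrouridine
the heavy-atom coordinates are kept as they are — including the residual ring
pucker — restoring only the sp² hydrogen count; planarization is left to the
downstream geometry optimization, because flattening would contradict the
zero-RMSD guarantee on mapped atoms. RMSD comparisons between modified and
unmodified fragments use only atoms present in both bases (element
replacements such as S4/O4 are excluded), with the structural ring map for
pseudouridine.

## Energies

`interaction_energy()` and `modification_energy()` implement the two
equations above, with hartree inputs converted at 627.5095 kcal/mol. BSSE is
an input, not computed; `write_counterpoise_inputs()` emits the two
monomer-in-dimer-basis geometries for an external counterpoise run. The
packaged reference energy table reproduces its printed modification-energy
column from the two interaction-energy columns within 0.01 kcal/mol for all
rows, which also settles the question of rounding order (the printed values
were rounded after subtraction).

## Problem sizes

The test suite and the acceptance script solve each of the 36 recipe poses
once (cached thereafter), run 20--25 noise trials per type at σ = 0.05 Å, 100
random instances for the superposition oracle, and an end-to-end set of 14
structures across six types. These sizes keep a full run in the minutes
range on a single core while exercising every pair type and every flag of the
extended nomenclature.

## Known limitations

* H-bond criteria are conventions, not fitted to the source data; the atlas
  census ships as packaged data, so census numbers do not depend on them.
* The generator's recipes pin one idealized realization per pair type; real
  instances vary in bond lengths, propeller twist and context.
* Counterpart geometries are starting points for external optimization, not
  optimized structures; the published optimized-versus-experimental RMSD
  values are not reproducible without the optimized coordinates.
* The census counts each observed instance separately, including
  crystallographic copies within one asymmetric unit, matching the published
  occurrence counts.
* The Ψ occurrence discrepancy in the source (139 in the table versus 149 in
  the text) is preserved as printed in the table and documented, not
  resolved.
* The reference energy table's adenine-side row for the doubly modified
  m1A:m5U pair prints a modification energy that does not follow from its own
  interaction-energy columns (−22.54 − (−15.79) = −6.75, printed −6.35); the
  unmodified reference cross-checks against the table's own A:m5U entry, so
  the printed E_Mod is a misprint. The fixture keeps the printed values and
  the tests assert the deviation explicitly.
* The occurrence and energy tables disagree on which of the two m5U:G rows is
  the single-H-bond tWH1 and which the wobble cWW (ids 16/17 are swapped
  between them). Both fixtures keep their printed content; all joins are by
  (bases, geometry) key, which is unambiguous.
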