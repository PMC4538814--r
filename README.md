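# modbp — modified RNA base pairs: annotation, atlas and energetics

A significant fraction of the modified nucleobases observed in experimental
RNA structures are hydrogen-bonded to another base. `modbp` is an R toolkit
for studying these *modified base pairs*:

* **Detection and classification.** Hydrogen bonds are detected from heavy
  atoms (donor–acceptor distance 2.4–3.5 Å, approach angle ≥ 90°, donors
  limited by their hydrogen count), and every H-bonded pair of nucleotides is
  assigned an extended Leontis–Westhof label: `c`/`t` for the cis/trans
  orientation of the glycosidic bonds, `W`/`H`/`S` for the Watson–Crick,
  Hoogsteen and sugar edges, `Bs` for bifurcated pairs sharing a sugar-side
  keto/amino group, `(r)` when a ribose 2'-OH takes part, `(w)` for a
  bridging water, and a trailing `1` for single-H-bond pairs
  (e.g. `tHW(w)`, `cS(r)W`, `tBsW`, `cWW1`).
* **Atlas building.** Annotations from many structures are aggregated into
  unique (base combination, geometry) types with occurrence counts and a
  best-resolution representative. A packaged machine-readable reference
  atlas (36 types, 27 natural) and reference interaction-energy table ship
  with the package.
* **QM model fragments.** For any annotated pair the package builds a capped,
  hydrogen-completed fragment (bases truncated at C1' as a methyl; riboses
  retained and capped when their 2'-OH pairs; bridging waters included) and
  its unmodified counterpart, replacing each modified base by its parent
  while preserving the H-bonding pattern — pseudouridine through its
  structural ring map C5→N1, C4→C2, O4→O2, N3→N3, C2→C4, O2→O4, N1→C5,
  C6→C6.
* **Energy bookkeeping.** `E_int = E_BP − (E_B1 + E_B2) + BSSE` and
  `E_Mod = E_int(modified) − E_int(unmodified)` in kcal/mol, with an
  external-backend contract for the actual quantum chemistry and emission of
  counterpoise monomer geometries.
* **Superposition.** Kabsch least-squares fitting with proper-rotation
  enforcement, cross-checked against an independent quaternion solution, and
  correspondence-aware RMSDs between modified and unmodified fragments.
* **Synthetic structures.** A generator realizes every atlas pair type as an
  idealized structure (target H-bond distances satisfied within 0.05 Å,
  self-checked against the package's own classifier), with seeded coordinate
  noise — the test bed for the whole pipeline.

## A worked example

```r
library(modbp)

# generate an idealized 5-methylcytosine : guanine Watson-Crick pair
st <- generate_pair("m5C:G cWW")
hb <- find_hbonds(st)
nrow(hb)
#> [1] 3
ann <- classify_pair(st, "A|1|", "A|2|", hbonds = hb)
ann
#> m5C:G cWW  (A|1| | A|2|)  3 H-bond(s), torsion 4 deg, C1'-C1' 10.9 A

# a QM-ready fragment and its unmodified counterpart
frag <- build_pair_model(ann, st)
frag
#> Fragment m5C:G cWW: 38 atoms (16 H), charge +0
cp <- make_unmodified_counterpart(frag)
rmsd_pairs(frag, cp, mode = "common_atoms")   # methyl excluded, mapped atoms kept
#> [1] 9.08434e-16

# the packaged reference tables and their headline statistics
atlas_stats(load_paper_atlas())
#> Atlas census:
#>   573 base-pair occurrences (424 natural)
#>   443 naturally modified nucleobases in pairs
#>   by parent base: A 66, G 82, C 60, U (non-Psi) 96, Psi 139
#>   36 unique types (27 natural; 15 trans, 8 strict cWW among natural)

ex <- energy_extremes(load_paper_energies())
ex$strongest$key;  ex$strongest$E_int
#> [1] "m7G:C cWW"
#> [1] -37.17
ex$E_Mod_min$E_Mod; ex$E_Mod_max$E_Mod
#> [1] -15.12
#> [1] 9.42
```

The census numbers summarize the packaged occurrence table: 573 observed
modified-base-pair instances, 424 of them involving natural modifications
(with one doubly modified type, so 443 naturally modified nucleobases sit in
pairs), and 36 unique types of which 27 are natural — 15 of those trans and
8 strict Watson–Crick. The energy extremes identify the strongest pair (the
positively charged m7G:C Watson–Crick pair at −37.17 kcal/mol), and the
modification-energy range from −15.12 (m7G:G, strongly stabilized by the
positive charge) to +9.42 kcal/mol (the single-H-bond m2G:C pair).

A shell entry point wrapping the same functions is installed at
`inst/exec/modbp` (`scan`, `atlas`, `model`, `energy`, `compare`, `synth`,
`tables` subcommands).

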