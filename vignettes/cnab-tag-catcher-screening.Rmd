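---
title: "Screening CnaB-type domains for covalent tag/catcher design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening CnaB-type domains for covalent tag/catcher design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnasplit)
```

## The problem

CnaB domains are small bacterial Ig-like β-sandwiches (seven conserved
β-strands) whose first and last strands pair in parallel and are locked
together by an intramolecular isopeptide bond: the NZ amine of a
reactive lysine attacks the side-chain carbon (CG) of an asparagine or
aspartate, with a neighbouring glutamate/aspartate shuttling protons.
Splitting such a domain between its last two strands yields a *catcher*
(the folded body, carrying the lysine and the catalytic residue) and a
short *tag* peptide (carrying the acceptor). When the two parts meet,
they reconstitute the fold and form the bond *inter*-molecularly —
giving a genetically encodable covalent connector, the design behind
SpyTag/SpyCatcher.

`cnasplit` implements the computational half of a screening protocol
for deriving new tag/catcher pairs from candidate CnaB domains:

1. **sequence screen** — candidates must be mutually divergent
   (pairwise identity below 30 %),
2. **triad detection** — the structure must contain the reactive
   Lys–Asn/Asp pair plus the catalytic residue in bonding geometry,
3. **split validation and construct building** — residue-range splits
   with derived deleted linkers, capping, variants, point mutants and
   expression fusions,
4. **stability read-outs on MD trajectories** — core-region backbone
   RMSD, tag↔catcher van der Waals energy, β-sheet hydrogen-bond
   distances and a contact-based dissociation monitor, compared between
   the intact domain and the split system.

The toolkit does not run molecular dynamics; it emits a preparation
recipe (`emit_md_recipe()`) and analyses trajectories supplied as
multi-model PDB.

## Data model

A structure is an atom-level tibble (`cna_structure`) with author
numbering preserved exactly as deposited — all residue ranges
throughout the package are 1-based, inclusive, author-numbered, because
every documented split boundary and active-site residue is quoted in
that numbering. A trajectory (`cna_trajectory`) is a topology plus an
`n_frames × n_atoms × 3` coordinate array. Metric series are tibbles
with `glance()`/`tidy()`/`autoplot()` methods.

## The four candidate systems

```{r}
cna_systems()
```

Catcher/tag boundaries, rigid-core windows and the active-site numbers
of the two functional systems (`4oq1`: K155/N252/E222; `3kptC`:
K417/N512/E472) are taken from the published construct designs;
`triad_source = "stand-in"` marks the two systems whose triad numbering
is not on record — there the detector's job is precisely to report it
from a real structure, and the numbers in this table only parameterise
the synthetic scaffolds.

The deleted linker range is always *derived* from a split
specification, never user-supplied, so there is a single source of
truth:

```{r}
spec <- system_split_spec("4oq1")
deleted_range(spec)
```

## Synthetic stand-ins instead of bundled coordinates

The package bundles no crystal structures. `make_synthetic_domain()`
builds, per system, a geometric stand-in with the documented numbering:
an ideal parallel two-strand sheet pairing the first catcher residues
with the tag strand, a coil carrying the remaining residues, and a
planted triad at the documented (or stand-in) active-site numbers.
Fixture backbones use ideal internal coordinates (N–CA 1.458 Å,
CA–C 1.525 Å, C–N 1.329 Å; φ/ψ = −119°/113°); planted side chains are
deterministic geometric scaffolds, *not* minimised conformers.

What passing tests on these fixtures demonstrates: the bookkeeping
(ranges, deleted regions, triad placement, sequence reconstruction) and
the measurement code (distances, energies, superpositions) are correct.
What they do **not** demonstrate: anything about the real folds —
strand counts, loop structure, sheet content or sequence identities of
the deposited entries are properties of real coordinates, and the
corresponding checks (`screen_reference_entries()`) run only when the
four deposited entries are available locally or via a connection.

```{r}
dom <- make_synthetic_domain("4oq1")
detect_isopeptide(dom)
```

## Triad detection

Detection is purely geometric, on heavy atoms (crystal structures lack
hydrogens): every Lys NZ within `proximal_max` (default 4 Å) of an
Asn/Asp CG is reported with its nearest acceptor; a Glu CD / Asp CG
within `catalytic_max` (5 Å) of NZ is attached as catalytic. The bond
state is `covalent` at or below `covalent_max` (default 1.8 Å —
deposited isopeptide bonds sit around 1.3–1.4 Å, van der Waals contact
well above 2.5 Å, so the two regimes separate cleanly) and `proximal`
otherwise. All three cutoffs are user-configurable
(`detection_params()`); ties break deterministically toward the lower
residue number.

## Split validation and construct building

`make_split()` enforces the tag-carries-the-acceptor topology: reactive
Lys and catalytic residue in the catcher range, acceptor in the tag
range, no triad member in the deleted linker. The mirrored topology
(acceptor in the catcher, as in Snoop-like designs split after the
first strand) is rejected with an explicit message rather than modelled
— all four systems here follow the Spy-like split.

For simulation preparation, the *original* domain termini are capped
(acetyl/N-methyl) while the newly created split termini stay ionic;
`cap_termini()` places cap heavy atoms from ideal internal coordinates
(C–N 1.335 Å) so outputs are deterministic and testable rather than
delegated to an external prep tool. The default `prep_protocol()`
records the simulation constants the recipe carries: TIP3P water,
10 Å margin, neutralising counter-ions, three restrained heating stages
(5 kcal mol⁻¹ Å⁻² all-protein 0.1 ns, CA-only 0.4 ns, free 0.5 ns) to
310 K, then 200 ns NPT with a 2 fs step and hydrogen bond-length
constraints. Split systems are prepared *without* the isopeptide bond —
the recipe flags this — because the relevant question is whether the
tag stays bound in the reaction-competent pose before the bond forms.

Variants are encoded against author numbering (N-terminal extensions
may be given as parent residue ranges) or as literal sequence edits.
One documented conflict is deliberately left literal: the two-residue
N-extension of the `3kptC` tag is described with inconsistent residue
numbers in different places in the source material, so the variant is
encoded as the literal sequence `"NQ"`. Similarly, the expression
linker is `GSGSGSG` by default with `GSGESG` also shipped, because the
construct documentation uses both.

## Fusion parts and masses

`fusion_part_library()` loads editable FASTA parts. His6, HA
(`YPYDVPDYA`), both linkers and the pQE-9 vector-encoded leader
(`MRGSHHHHHHGS`) are exact public sequences; the MBP and mCherry
entries are **synthetic stand-ins** — random compositions constrained
to the documented length and average mass of the real parts (370 aa /
≈40.71 kDa; 236 aa / ≈26.72 kDa) — because the exact construct
sequences live in supplementary material not shipped here. Masses are
average (not monoisotopic), matching gel-based size estimates, and
reports echo per-part checksums so edited libraries are identifiable.
With these parts the assembled tag–MBP, His6–catcher–HA and
mCherry–catcher fusions come out at ≈44, ≈12.5 and ≈39.7 kDa; the
package's own checks compare these to the reported gel values (44, 13,
40 kDa) at ±1 kDa, the realistic read-off precision of a Coomassie
gel.

## Trajectory metrics

```{r}
prox <- make_synthetic_domain("4oq1", triad_nz_cg = 3.4)
cs <- make_split(prox, spec, detect_isopeptide(prox)[1, ])
split_top <- new_structure(rbind(as.data.frame(cs$catcher),
                                 as.data.frame(cs$tag)))
traj <- make_jitter_trajectory(split_top, n_frames = 40, sigma = 0.25,
                               seed = 42)
glance(core_rmsd_series(traj, 183, 223))
```

* **Core RMSD** — frame 1 is the reference; each frame is superposed on
  the core backbone (`N, CA, C, O`; the backbone set is pinned here
  because "backbone" is ambiguous) with a Kabsch (SVD) fit constrained
  to proper rotations, then the RMSD over the same atoms is taken. The
  rigid-core windows per system (e.g. 183–223 for `4oq1`) are built in
  as `core_regions()`.
* **Tag↔catcher vdW energy** — the plain 12-6 sum
  `Σ ε_ij[(R_ij/r)¹² − 2(R_ij/r)⁶]` over cross-pairs, no cutoff,
  deterministic summation order. The shipped parameter table is a
  generic element-keyed one; a force-field table can be supplied, and
  every report names the table used. Absolute energies therefore are
  not comparable to any particular force field — the screening use is
  the *within-toolkit* comparison of domain versus split. For the
  intact domain, cross-pairs within 3 covalent bonds of the
  tag/catcher junction are excluded (bonds inferred from reference
  distances); 1-4 pairs are kept at full weight, and this choice is
  fixed and stated rather than configurable.
* **β-sheet hydrogen bonds** — backbone N···O pairs across the
  tag/catcher interface at ≤3.5 Å in the reference structure (nearest
  wins, each atom once per direction), then per-frame distances and
  per-pair means over the trajectory.
* **Contact fraction** — fraction of frames whose minimum inter-group
  heavy-atom distance is ≤4.5 Å; the dissociation proxy.

Secondary structure (`assign_secondary_structure()`) follows the
Kabsch–Sander electrostatic model,
`E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol with the
amide hydrogen rebuilt from ideal geometry and a −0.5 kcal/mol bond
threshold; bridges grow into ladders (label `E`), consecutive
(i, i+4) bonds give helices (`H`), the rest is coil. Sheet content is
reported as an integer percent, matching the granularity of
experimental secondary-structure estimates. Which assignment convention
the original analyses used is not on record; Kabsch–Sander is this
package's declared convention and any comparison of sheet-content
values carries that caveat.

## Verdicts

```{r}
screen_thresholds()
```

The published screen judged stability qualitatively ("similar RMSD, no
dissociation"). To make the verdict reproducible the package uses
explicit stand-in thresholds, echoed in every report: a split system is
`dissociated` when its contact fraction drops below 0.95, else
`destabilized` when its mean core RMSD exceeds the domain's by more
than 1.0 Å or it retains less than half of the domain's tag binding
energy, else `comparable`. Precedence is total
(dissociated > destabilized > comparable), and thresholds are pure
configuration — changing them never changes a metric value.

```{r, fig.width = 6, fig.height = 3}
dt <- make_jitter_trajectory(dom, 40, 0.25, seed = 1)
dr <- make_drift_trajectory(split_top, "B", c(0, 0, 0.6), 40,
                            sigma = 0.1, seed = 2)
cfg <- tibble::tibble(label = c("bound", "drifting"),
                      parent = list(dom, dom), chain = "A",
                      catcher_first = 146L, catcher_last = 240L,
                      tag_first = 246L, tag_last = 259L,
                      core_first = 183L, core_last = 223L,
                      domain_traj = list(dt, dt),
                      split_traj = list(traj, dr))
rep <- run_screen(cfg)
tidy(rep)[, c("system", "deleted", "contact", "verdict")]
```

## Numerical choices and degenerate inputs

* Superposition requires ≥3 non-collinear points; reflections are
  excluded by construction (determinant +1); agreement with an
  independent quaternion-method implementation is part of the test
  suite (≤1e−8 Å on random point sets).
* Altloc policy on reading: highest occupancy wins, ties go to the
  alphabetically first conformer. Files with several `MODEL` blocks are
  trajectories; `read_structure()` takes the first model only.
* A lysine without its NZ atom is skipped with a warning, not an error
  — truncated side chains are common in deposited models.
* Zero interatomic distance in the energy sum, empty residue ranges,
  wild-type mismatches in point mutations, and frame/topology atom
  mismatches all fail fast with messages naming the offender.
* Fixture randomness is local: generators take explicit seeds and
  restore the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
fixtures: strands of 8–14 residues, domains of ~110 residues,
trajectories of 30–200 frames, oracle batches of 100 random systems.
These sizes were chosen as the smallest at which every code path and
statistical property under test is clearly exercised; all functions
scale to real trajectories (thousands of frames) without modification.

## Known limitations

* The synthetic domains are scaffolds, not folds: they support
  bookkeeping and measurement tests, never structural biology claims.
* The LJ table is generic; absolute energies differ from any specific
  force field.
* Ester/thioester-bonded domains and Snoop-like (N-terminal tag)
  splits are out of scope by design.
* Checks that need the deposited entries (mutual sequence identity
  <30 %, pairwise backbone RMSD 1.8–2.2 Å, seven template strands, 43 %
  catcher sheet content) require those files; offline, with no cache,
  they report failure rather than silently passing on stand-ins.
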