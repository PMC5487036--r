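# cnasplit

Design and *in silico* screening of covalent tag/catcher split-protein
systems derived from CnaB-type domains.

## What it is for

CnaB domains are bacterial Ig-like β-sandwiches whose first and last
β-strands pair in parallel and are locked by an autocatalytic
intramolecular isopeptide bond: Lys-NZ attacks the side-chain carbon of
an Asn/Asp, assisted by a catalytic Glu/Asp. Cutting such a domain
between its last two strands yields a folded **catcher** (with the Lys
and the catalytic residue) and a short peptide **tag** (with the
acceptor); on mixing, the parts reconstitute and form the bond
*between* molecules — a genetically encodable covalent connector (the
SpyTag/SpyCatcher principle).

`cnasplit` is a toolkit for protein engineers screening candidate CnaB
domains for this kind of splitting:

* **detect** reactive triads geometrically in a structure
  (`detect_isopeptide()`): every Lys-NZ within 4 Å of an Asn/Asp CG,
  state `covalent` (≤1.8 Å) or `proximal`, plus the nearest catalytic
  carboxylate within 5 Å;
* **screen sequences** for mutual divergence
  (`screen_candidates()`, Needleman–Wunsch/BLOSUM62, pass = identity
  < 30 %);
* **build constructs** from residue-range splits
  (`split_spec()`, `make_split()`): derived deleted linkers, validation
  of triad placement, acetyl/N-methyl capping, length/sequence variants,
  point mutants, fusion assembly with mass bookkeeping, and a
  machine-readable MD-preparation recipe;
* **score stability** on trajectories (multi-model PDB), intact domain
  versus split system:
  * core-region backbone RMSD after Kabsch superposition,
  * tag↔catcher van der Waals energy
    `E = Σ ε_ij[(R_min,ij/r)¹² − 2(R_min,ij/r)⁶]`,
  * β-sheet hydrogen-bond N···O distance persistence,
  * contact fraction as a dissociation monitor,
  and fold them into a verdict
  (`comparable` / `destabilized` / `dissociated`);
* **generate synthetic fixtures** (`make_two_strand_parallel()`,
  `plant_triad()`, `make_jitter_trajectory()`,
  `make_drift_trajectory()`, `make_synthetic_domain()`): seedable
  structures and trajectories with planted, exactly-known geometry, so
  the whole pipeline is testable without downloading anything.

Everything is tidyverse-shaped: structures and metric series are
tibbles, results have `tidy()` / `glance()` / `autoplot()` methods, and
a thin CLI (`exec/cnasplit`) wraps the main steps for shell use.

## Worked example

```r
library(cnasplit)

dom <- make_synthetic_domain("4oq1")   # stand-in parent, author numbering
detect_isopeptide(dom)
#> # A tibble: 1 × 9
#>   chain lys_res acceptor_res acceptor_name catalytic_res catalytic_name ...
#> 1 A         155          252 ASN                     222 GLU
```

The detector finds one triad: Lys155 bonded to Asn252 (state
`covalent`, NZ–CG = 1.33 Å) with Glu222 in catalytic range — the
active-site residues of the 4oq1 system.

```r
spec <- system_split_spec("4oq1")      # catcher 146-240 / tag 246-259
cs <- make_split(dom, spec, detect_isopeptide(dom)[1, ])
cs
#> <cna_constructs> catcher 146-240 (95 aa), tag 246-259 (14 aa),
#>   deleted {241,242,243,244,245}
```

Splitting validates the triad placement (Lys+Glu in the catcher, Asn in
the tag) and derives the deleted linker 241–245. Stability read-outs on
a trajectory:

```r
tr <- make_jitter_trajectory(dom, 50, 0.25, seed = 1)
glance(core_rmsd_series(tr, 183, 223))
#> # A tibble: 1 × 5
#>   label              n_frames  mean     sd unit
#> 1 core backbone RMSD       50 0.418 0.0623 Angstrom
```

i.e. a mean backbone RMSD of 0.42 Å over the rigid core 183–223,
relative to the first frame. Fusion constructs and their masses:

```r
lib <- fusion_part_library()
assemble_fusion(c("pqe9_his6_leader", "mbp_standin", "gs_linker",
                  cs$tag_seq), lib)
#> <cna_fusion> 403 aa, 44.1 kDa
```

— the tag-MBP expression construct comes out at ≈44 kDa. (MBP and
mCherry ship as length- and mass-matched synthetic stand-in sequences;
see the vignette.)

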