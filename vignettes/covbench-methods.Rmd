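---
title: "Evaluating covalent docking tools: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating covalent docking tools: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covbench)
```

## The problem

Covalent inhibitors carry an electrophilic warhead that reacts with a
nucleophilic residue of the target — in the systems this package covers, a
cysteine thiol (SG) or a serine hydroxyl (OG). Covalent docking programs
sample ligand conformations under the constraint of that predefined bond, but
their scoring functions largely ignore the energetics of bond formation, so
their reliability varies strongly with target class and warhead chemistry.
No single tool dominates; the practical question is *which tool to trust for
a given system*. covbench implements an evaluation protocol for answering
that question against a curated benchmark of covalent co-crystal structures.

## Benchmark curation

Candidate complexes pass through an ordered, auditable filter pipeline
(`run_curation()`):

1. **Resolution** — strictly below 3.0 Å (missing resolution fails, reason
   `"no resolution"`).
2. **Nucleic acids** — complexes containing DNA/RNA chains are excluded.
3. **Anchor** — the covalent linkage must be to Cys-SG or Ser-OG.
4. **Single linkage** — exactly one covalent bond between ligand and
   receptor.
5. **Cofactor proximity** — any non-buffer heterogroup heavy atom within
   8.0 Å of a ligand heavy atom excludes the complex. This scan runs on the
   *deposited* structure, before waters/metals/cofactors are stripped from
   the receptor; running it after stripping would make the rule vacuous, so
   the entry object retains the full deposited content in its `context`
   table. The buffer/crystallisation-agent dictionary is an editable YAML
   file (`inst/extdata/buffer_agents.yaml`).
6. **Ligand size** — at least 5 heavy atoms and strictly fewer than 30
   rotatable bonds.

A *rotatable bond* is defined as a single, acyclic bond between two heavy
atoms each bearing at least one further heavy neighbour, excluding amide C–N
bonds. This is the common strict convention; since no normative definition
accompanies the size rule, the bound is configurable. The count is taken on
the **pre-reaction** ligand — the species that is actually docked — a
deliberate call where either form could be argued.

The retained *set* is order-insensitive (filters are independent predicates);
the *attribution* of an exclusion to the first filter that fired follows the
pipeline order above. Covalent linkages are read from LINK/struct_conn
records when present; otherwise a distance rule declares a linkage when a
ligand heavy atom lies within 2.0 Å of an SG or 1.8 Å of an OG (covalent
S–C ≈ 1.8 Å and O–C ≈ 1.4 Å, plus tolerance). Deposited files frequently
omit the records, so the fallback is essential in practice.

## Warhead taxonomy

Ligands are classified into 15 warhead classes spanning 7 reaction types
(nucleophilic addition by Cys/Ser, nucleophilic substitution by Cys/Ser, ring
opening by Cys/Ser, disulfide formation). The class definitions are *data*,
not code: `inst/extdata/warhead_taxonomy.yaml` lists one rule per class with
its anchor, priority, and one or more core patterns given as explicit
element/bond-order graphs (a SMARTS string is carried as annotation). The
matcher supports wildcard atoms (`*`), a halogen class (`X`), and per-atom
degree caps — the degree cap is what distinguishes an aldehyde or ketone
carbon from amide/ester carbons without hydrogen bookkeeping.

Priorities encode specificity: ring-opening cores (lactam before lactone
before epoxide/aziridine) rank above boronic acid and phosphonyl, then
nitriles before alkynes, the activated-halide pattern above generic
carbonyls, Michael-acceptor alkenes above carbonyls, and the `Others`
substitution catch-all last. Classification picks the highest-priority rule
whose anchor matches and whose pattern occurs; among several embeddings of
the winning rule, the core whose link atom is nearest the anchor nucleophile
is reported. Every class ships with an example chemotype
(`warhead_example_ligand()`), and the suite asserts 15/15 self-recognition —
each example matches its own class and no higher-priority one.

Reaction templates are MDL RXN files, one per reaction variant, with the
anchor nucleophile represented as a mapped single-atom fragment (atom-map
99). `apply_reaction()` is a generic graph rewrite driven by the mapping:
bond-order changes, template leaving groups, nucleophile attachment, and a
reverse mode that restores the pre-reaction ligand. Templates without
leaving groups round-trip to a graph isomorphic to the input; this is
asserted for the twelve round-trippable templates.

## Pose accuracy

Docking accuracy is the **no-fit** heavy-atom RMSD between a docked pose and
the crystallographic ligand: both are expressed in the receptor frame and no
superposition is performed, because a perfectly shaped pose in the wrong
place is a wrong pose. Hydrogens are excluded throughout. Atom
correspondence is established by graph isomorphism on the heavy-atom skeleton
(element and bond order, stereo ignored), since different engines renumber
atoms freely. With symmetry correction on (the default), the RMSD is
minimised over the ligand's graph automorphisms, so a flipped
para-disubstituted ring scores 0 rather than a spurious 2–3 Å; automorphism
enumeration is capped at 10 000 mappings, beyond which the identity mapping
is used with a warning. Whether published covalent-docking RMSDs are
symmetry-corrected is generally unstated, so both modes are exposed
(`symmetry = FALSE` gives the raw fixed-correspondence value; the
symmetry-on value is never larger).

Per complex and tool, `evaluate_run()` reports S₁ (Best Scored Pose: RMSD of
the rank-1 pose), S₂ (Best Sampled Pose: minimum over all retained poses),
Smax (maximal deviated pose, taken over the retained run), the P-deviation
S₁ − S₂, and two flags at the near-native threshold τ = 2.0 Å: *success*
(S₁ ≤ τ; a pose at exactly 2.0 Å counts) and *failure* (S₁ > τ **and**
S₂ > τ). Success and failure are intentionally non-complementary: a run
whose scorer missed but whose sampler found a near-native pose is neither,
and that asymmetry is what the P-deviation and the profiling counts measure.

## Selection criteria

**Precision** P(i, x) is the median over classes of the within-class median
RMSD for tool *i* under measurement *x*. The two-stage median makes rare
classes (one or two structures) count as much as classes with a hundred —
deliberately: a tool should not look "precise" merely because it is good at
the most common chemistry. Even-length medians are the mean of the two
central values. Empty classes are dropped from the outer median with a
warning. Note on the shipped summary tables: for one tool/measurement the
outer median of the distributed per-warhead medians (2.44 Å) differs from the
bottom line printed in the same distributed table (2.53 Å); the
implementation follows the definition literally and reproduces the four
bottom lines that are consistent.

**Generality** follows the mark-counting formulation: within every (class,
subgroup) cell, the tool(s) attaining the minimum median RMSD are marked; all
minimisers are marked on exact ties (no fractional splitting, keeping marks
integer and interpretable). The integer total `marks` is reported alongside
the per-class normalised score G(i, x) = Σ_j (marks_j / N_{i,j}) × 100, with
N_{i,j} the number of structures of class *j* evaluated by tool *i*. N is
per-tool, and tools evaluated on different entry sets are an error — a
comparison across unequal benchmarks is invalid rather than silently
reweighted.

**Robustness** is the sample standard deviation (n − 1) of a tool's RMSDs
over all complexes.

**Profiling** counts, per tool: successes, failures, S-Only / F-Only
(entries where only this tool succeeded / failed) and S ≥ 2 / F ≥ 2 (this
tool plus at least one other). Pairwise tool comparisons use the two-sided,
tie-corrected Mann–Whitney test (normal approximation with continuity
correction); degenerate all-equal samples return p = 1 with a warning, and
Holm-adjusted p-values are reported alongside the raw ones.

`select_tool()` computes everything for both measurements, recommends the
Best Scored Pose report as primary — scoring accuracy is what a prospective
user experiences; sampling differences between modern engines are smaller —
and names the winner per criterion, flagging disagreement rather than
resolving it.

## Anchor-site descriptors

Anchor flexibility is summarised by two descriptors. The **SASA** of the
anchor residue is computed on the ligand-free receptor by rolling-probe point
sampling: each atom's sphere at (vdW + probe) radius is covered with a
deterministic golden-spiral lattice (960 points/atom by default) and the
accessible fraction counted against neighbouring spheres. The radius table
(Bondi-type values) and the 1.4 Å probe ship as an editable YAML file; since
published SASA values depend on the radius set of the tool used, absolute
agreement with other software is expected only to a few Å². Computing on the
ligand-free receptor is a declared choice — the descriptor is meant to
measure the pocket a docking tool faces. The **dihedral** is the signed
IUPAC torsion N–CA–CB–SG (Cys) or N–CA–CB–OG (Ser) in (−180°, 180°], the
−180° boundary reported as +180°; collinear geometry is an error, not NaN.
`accuracy_by_feature()` bins per-tool median S₁ by SASA (10 Å² bins),
dihedral (30° bins, matching the granularity at which anchor rotamers are
usually discussed) or a categorical kinase-domain label; empty bins are
reported as missing, never as zero.

## The synthetic benchmark generator

The generator fabricates everything the pipeline consumes: five-residue
peptide stubs carrying the anchor, ligands built from each warhead class's
example core placed at covalent-bond distance from the nucleophile
(1.81 Å to SG, 1.42 Å to OG), and docking runs constructed from **rigid
translations** of the reference ligand. Translations make the planted
accuracy analytic: the no-fit RMSD of a pure translation equals the
translation norm under the identity mapping, and no automorphism can do
better (the mean displacement over any atom permutation is the translation
vector, so by convexity every mapping's RMSD is at least the norm). Planted
(S₁, S₂, Smax) are therefore recovered to numerical precision — the
end-to-end closure observed is at the 1e-15 Å level — independent of the
symmetry setting.

Defaults mirror the curated study conditions: 330 entries distributed over
the 15 warhead classes in the benchmark's published proportions, four mock
tools, 10 retained poses per run, and per-tool accuracy profiles
(μ 1.9–2.5 Å, σ 0.9–1.3 Å) spanning the range of the published per-tool
precision values; the score–RMSD agreement parameter ρ = 0.7 makes the
top-scored pose the best sampled one in about 70% of runs, creating the
Best-Scored ≠ Best-Sampled regime that the P-deviation diagnostics target.

What the generator does *not* emulate: real binding-site geometry, scoring
energetics, pose clustering, or the heavy right tail of real failure modes.
Because each run's poses are independent draws and S₂ is a minimum of ten,
the synthetic best-sampled success rate (≈ 0.99 at the defaults) is higher
than real benchmarks show, and the best-scored rate (≈ 0.8) sits above the
0.45–0.57 range seen with commercial engines on curated data. Passing the
closure and ranking-recovery tests therefore demonstrates that the
*measurement machinery* is correct — not that any docking tool behaves like
the mock profiles.

## Numerical and interface choices

* Molecular graphs are heavy-atom-only throughout; proton bookkeeping in
  reactions reduces to bond-order edits.
* Coordinates stay in the deposited receptor frame; residue numbering is
  as-deposited (author numbering). Alternate location A is kept; occupancy
  is ignored.
* Score orientation is declared per run (`lower_better` / `higher_better`);
  rank 1 always means best by the producing tool's own convention, and
  scores pass through unmodified.
* PDB serialisation of entries includes LINK and CONECT records so curation
  round-trips; PDB's 3-decimal coordinate field bounds that round-trip at
  1e-3 Å, while SDF pose files round-trip at 1e-4 Å or better.
* Generality ties are resolved by marking all minimisers; heat-map colours
  interpolate linearly in RGB between the 1 Å (deep green) and 5 Å (deep
  red) anchors and clamp outside.
* Median convention everywhere: even-length lists give the mean of the two
  central values (`stats::median`).

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data: the
closure check uses 200 entries × 4 tools × 10 poses; ranking recovery uses 60
entries × 4 tools; the rank-test calibration uses 200 replicates at n = 100
per arm; brute-force automorphism cross-checks use ligands of up to 8 atoms.
These sizes give sampling error comfortably below the assertion tolerances
while keeping a full run in the order of a minute or two.

## Known limitations

* mmCIF support is thinner than PDB: coordinates parse, but covalent-linkage
  records are scanned with the same fixed-column text rule as PDB LINK
  records.
* The taxonomy's pattern library is intentionally compact; exotic warheads
  (e.g. nitro-displacement chemistry) fall into `Others` or come back
  `"unclassified warhead"` — which is a value, not an exception, so pipelines
  can triage rather than crash.
* Kinase-domain labels are consumed from metadata; no structural domain
  assignment is attempted.
* Bond orders read from PDB CONECT records default to single; classification
  of a complex read back from a stripped PDB should use the accompanying SDF
  ligand file, which preserves orders.
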