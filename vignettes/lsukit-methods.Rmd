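---
title: "Modeling LSU coiled-coil dimers and scoring their interactomes"
author: "lsukit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling LSU coiled-coil dimers and scoring their interactomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsukit)
```

## The problem

The four Arabidopsis thaliana LSU (RESPONSE TO LOW SULFUR) proteins -- LSU1
(At3g49580), LSU2 (At5g24660), LSU3 (At3g49570), LSU4 (At5g24655) -- are
~100-residue, almost entirely alpha-helical proteins with predicted parallel
coiled-coil regions, strongly induced by sulfur starvation and repeatedly
flagged as stress-related interaction hubs. Their structures are unsolved and
their molecular function unknown. Three computational questions arise around
them, and this package implements one tested pipeline for all three:

1. **Dimer geometry.** Which homo- and heterodimers can the four monomers
   form as parallel two-stranded coiled coils, and at which relative register
   of the two helices is the leucine zipper best formed?
2. **Candidate partners from TAP-MS.** Given tandem-affinity-purification
   mass-spectrometry intensity tables for the four TAP-tagged baits across
   growth conditions, which co-purifying proteins are enriched enough over a
   tag-only control to count as candidate partners?
3. **Interactome hubs.** In the network of known and newly found LSU
   interactors, which nodes are *specifically* enriched in LSU-interactome
   neighbors, rather than merely well connected?

Because the raw plant material, MS runs, and full-length sequences are not
part of the package, a synthetic-data module generates inputs whose structure
matches each stage's assumptions, with known ground truth, so every stage is
testable end to end.

## Dimer modeling

### The ideal template

Models are built by threading sequence pairs onto a fixed two-helix backbone.
Rather than shipping an experimental structure, `build_ideal_template()`
generates an ideal two-stranded, parallel, left-handed coiled coil from the
Crick parameterization: two alpha-helices of radius $R_1 = 2.26$ Å wound on a
superhelix of radius $R_0 = 4.9$ Å and pitch $150$ Å, axial rise $1.51$
Å/residue, $3.62$ residues per helical turn, and the two helices $180°$ apart
in superhelical phase. These are standard literature values for two-stranded
coiled coils; all are arguments. With them, consecutive CA–CA distances land
in 3.77–3.79 Å and the minor-helix phase advances ~102.9°/residue in the
interface frame, which is what makes the heptad repeat (abcdefg, core at a/d)
a stationary pattern along the seam. The default heptad phase of slot 0 is
$\pi/7$, placing the 'a' and 'd' positions symmetrically either side of the
dimer interface.

Each residue slot carries backbone N/CA/C/O coordinates plus a side-chain
anchor: the CB direction extended radially from the local helix axis. Scoring
uses only the anchors; the backbone exists for PDB export and for round-trip
through `load_template_pdb()`, which can also ingest a real two-chain
parallel coiled-coil PDB structure (CB rebuilt from backbone geometry where
missing, chain breaks > 4.5 Å CA–CA rejected, antiparallel chains rejected).

### Register-shift scanning and the zipper score

`thread_dimer()` places residue `start + k` of each chain at template slot
`k + shift` of its helix -- one integer shift per helix, no gaps, residues
shifted past the template ends dropped. `scan_register_shifts()` evaluates
the full grid of shift combinations $(s_A, s_B) \in [-W, W]^2$; the default
half-width $W = 25$ gives 51 registers per helix and $51^2 = 2{,}601$ models
per pair, about half a supercoil turn. Each model's score is the number of
leucine side chains (over both chains) whose anchor lies within a cutoff of
at least one leucine anchor on the opposite chain -- a count of leucines that
could engage in an intermolecular leucine zipper. The cutoff default is 8.0
Å: CB–CB distances of packed core leucines in two-stranded coiled coils fall
well under 8 Å on this template (4.5–7.7 Å for a/d pairings) while the
nearest non-core pairings exceed 10 Å, so the score is insensitive to the
exact value over roughly 8 ± 1 Å.

`select_best()` returns every model attaining the maximal score, ordered by
$|\Delta s| = |s_A - s_B|$ ascending, then lexicographically -- a
deterministic tie-break -- and reports the set of optimal $\Delta s$ values
(the register-shift series). Models with fewer than 7 placed residues (one
heptad) on either helix are degenerate and excluded. On synthetic LSU-like
sequences the odd–odd and even–even pairs produce symmetric series (e.g.
{-1, 0, 1}) while odd–even pairs are skewed ({0, 1} or {-1, 0}); the
characteristic register offsets of the real proteins depend on their full
sequences, which are not bundled, so no specific offset value is asserted.

A deliberately qualitative `interface_energy_proxy()` is also provided: -1
per hydrophobic–hydrophobic anchor contact, ±0.5 per charged contact (lower
is better). It is a deterministic heuristic for comparing models of the same
pair, not an energy function, and nothing in the pipeline depends on it.

### Mutation-effect prediction

`predict_mutation_effect()` combines two terms:

* **zipper_delta** -- best attainable zipper score of the mutant dimer
  (over the full grid) minus the wild type's. Because a Leu→X substitution
  can only remove leucines, the mutant grid is pointwise ≤ the wild-type
  grid, and losing a core leucine shows up as a strict drop.
* **electro_delta** -- intra-helical charge pairs at the helical contact
  spacings $(i, i\pm3)$ and $(i, i\pm4)$ involving the mutated position:
  +1 per like-charge pair created or opposite-charge pair removed
  (destabilizing for the helix), -1 for the converse. D/E count as negative,
  K/R as positive.

The verdict rule is: destabilizing if `zipper_delta < 0`, stabilizing if
`> 0`; only at `zipper_delta == 0` does the electrostatic sign decide; both
zero is neutral. Letting the zipper term dominate is this package's design
choice: the zipper term reflects the dimer interface directly, while the
electrostatic term is a single-helix stability heuristic. For an LSU1-like
homodimer (E51, C54, L60 at a core position) this yields C54A neutral, C54E
destabilizing (new E51–E54 $(i, i+3)$ repulsion), C54R stabilizing (new
E51–R54 attraction), and L60A destabilizing with a weaker effect when only
one chain of a heterodimer is mutated -- the directions expected for these
replacements.

## TAP-MS scoring

The design has 4 baits (LSU1-TAP..LSU4-TAP) × 4 conditions (4 or 10 days,
normal or deficient sulfur: 4d_nS, 4d-S, 10d_nS, 10d-S) = 16 datasets, plus
a tag-only control line per condition; LSU1-TAP and the control run in
triplicate, the others in duplicate. Two statistics are computed per protein
group and dataset:

* **abundance** = mean intensity over the dataset's replicates / molecular
  weight (kDa);
* **relative specificity** = $\log_{10}(\mathrm{median(probe)} /
  \mathrm{median(control)})$, with the control median replaced by the
  arbitrary background level 1 when the protein is undetected in the
  control. Undetected replicates enter the medians as observed zeros (they
  are measured absences, not missing values); a protein undetected in all
  probe replicates gets an NA sentinel and can never be a candidate. The
  background rule is applied whenever the control median is ≤ 0, which also
  covers the corner case of a control detected in fewer than half its
  replicates (median 0) that would otherwise divide by zero.

A **candidate partner** is a group with relative specificity strictly
greater than 1 (the wording "higher than one" makes the boundary value 1.0 a
non-candidate). Medians are taken within one (bait, condition) dataset --
pooling across conditions is not done by default. Detections of an LSU in
its own bait line are flagged as bait and excluded from partner incidence;
`incidence()` counts, per group, the number of the 16 datasets in which it
was a candidate, and `bait_detection_report()` tabulates which LSUs appear
in which lines, expanding ambiguous groups ("LSU2/LSU4", trailing "s"
family names) under each member with an ambiguity flag. Intensities are in
arbitrary MaxQuant-style units; no cross-run normalization is applied (none
is part of the statistic), which is why the documented scaling property
holds: multiplying one dataset's probe intensities by $c$ shifts every
defined relative specificity by exactly $\log_{10} c$.

## Interactome hubs

The network stage operates on a simple undirected graph (interaction assays
give no reliable direction; duplicates and self-loops are collapsed) with
two designated node sets: the four LSU baits and the LSU partner set. For
every non-isolated, non-bait node, `hub_scores()` computes `degree_total`,
`degree_lsu` (neighbors inside the partner set) and their ratio.
`rank_hubs()` filters to `degree_lsu >= 10` (the default floor for calling
something a hub at all), selects the top k = 9 by ratio, and *orders* the
selection by `degree_lsu` descending -- selection-by-enrichment but
reporting-by-LSU-degree, with both criteria available as pure modes. All
ties break by node id, so rankings are permutation-invariant.
`hub_membership_counts()` then counts, per partner, how many selected hubs
touch it, the quantity that reveals partners shared by many hubs.
Exports are GraphML (node attributes: degree_total, degree_lsu, ratio) and
SIF, both loadable by Cytoscape.

## The synthetic-data generator

`make_lsu_like_sequences()` encodes what *is* published about the four
sequences: leucines exactly at the landmark positions (L18, L29, L53, L57,
L60, L65, L78 in all four; L25 in LSU1/LSU3; L37 and L82 in LSU2/LSU4; L85
in LSU1–3), E51 and C54, an initiator methionine, length 100. Background
positions are helix-favoring residues (A/E/K/Q/R), restricted to uncharged
A/Q within ±4 of any landmark so that no accidental charge pairs or
hydrophobic contacts contaminate the mutation and zipper analyses. The
generator is deterministic per seed.

`simulate_tapms()` reproduces the study's design frame (16 datasets, the
3/2/3 replicate pattern) with multiplicative log-normal noise (sd in log10
units, default 0.2 -- a typical replicate scatter for label-free
intensities), planted partners at a fold-enrichment of 100 by default (the
threshold statistic sits at 10-fold, so planted partners are clearly but not
absurdly enriched), molecular weights uniform on 10–150 kDa, and optional
Bernoulli dropout (default 0; 0.2 in robustness tests). Each LSU protein is
planted only in its own line; cross-line LSU detections (heterodimer
carry-over) are not simulated, keeping ground truth unambiguous.

`simulate_network()` plants hubs that attach to each partner with
probability 0.85 and to background with 0.02, over an Erdős–Rényi background
at 0.05, sized 150 background nodes / 25 partners / 5 hubs. At these sizes a
background node essentially never reaches 10 partner neighbors, so recovery
failures reflect the ranking logic, not freak topology.

What the generators deliberately do **not** emulate: real sequence
divergence outside the landmarks, correlated MS noise, match-between-runs
artifacts, contaminant profiles, or literature-curation bias in the network.
Passing the recovery tests therefore demonstrates that the statistics and
rankings behave correctly on data satisfying their assumptions -- not that
those assumptions hold for any particular real dataset.

## Numerical and scale choices

* Residue numbering is 1-based from the initiator methionine everywhere,
  matching labels like L18 and C54; the modeled span defaults to residues
  7–65 (the predicted coiled-coil region; configurable).
* The register grid is exact integer arithmetic; scores are integers; the
  only floating-point tolerance in scoring is a $10^{-9}$ slack on the
  squared-distance cutoff so boundary contacts are stable across platforms.
* All stochastic stages consume an explicit integer seed and restore the
  caller's RNG state, so `run_all()` reruns are byte-identical.
* Test problem sizes: oracle-equivalence runs use a 30-slot template with
  half-width 3 over 100 random pairs; recovery suites use 20 TAP-MS seeds
  and 50 network seeds with the default generator sizes. These sizes give
  each property enough repetitions to be meaningful while keeping the whole
  suite fast.

## Known limitations

* The zipper contact rule (CB-anchor distance ≤ 8 Å) is this package's
  operationalization; crystallographic knobs-into-holes assignments are more
  restrictive, and an experimentally derived template may shift absolute
  scores (the grid arithmetic and selection logic are unaffected).
* The energy proxy is qualitative by construction and should never be
  compared across different sequence pairs.
* Whether published candidate counts are reproduced depends on reprocessing
  the deposited raw MS data against a dated proteome release, which is out
  of scope; the recovery suites on planted ground truth stand in for that
  check.
* The mutation rule treats electrostatics at the single-helix level only;
  inter-chain charge interactions are visible to the energy proxy but do
  not enter the verdict.
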