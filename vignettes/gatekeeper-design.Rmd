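---
title: "Designing inhibitor-resistant gatekeeper mutants from close-contact ensembles"
author: "gatekeepR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing inhibitor-resistant gatekeeper mutants from close-contact ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatekeepR)
```

## The problem

An inhibitor-resistant but catalytically active kinase mutant is the
cleanest way to show that a compound's cellular activity is mediated by
its nominal target. The mutation must satisfy two opposed constraints:
it has to disrupt inhibitor binding while leaving nucleotide binding and
catalysis intact. gatekeepR operationalizes this as a differential
close-contact analysis over conformational ensembles, followed by a
staged exclusion of residues that cannot satisfy one of the constraints.

## The contact model

Both enzyme and ligand are flexible, so single structures misrepresent
the interaction surface; the unit of analysis is therefore the
*conformational ensemble*: a set of frames of the same ligand--protein
complex, typically extracted from molecular-dynamics trajectories, with
identical topology across frames. For a frame, a **close contact** is a
ligand-atom/protein-atom pair with Euclidean distance strictly below a
cutoff; the default is 4.5 Å, a conventional envelope for van der Waals
plus weak polar interactions. Strict `<` is used, so a pair at exactly
the cutoff is not a contact. Counting is purely combinatorial — no
distance weighting, no interaction typing — which keeps the metric
robust and cheap over tens of thousands of frames.

Contacts are aggregated per protein residue into
`total = backbone + sidechain` pair-frame counts, the frame occupancy
(fraction of frames with at least one contact), and the per-frame mean.
Means, not totals, are compared between the inhibitor-bound and
nucleotide-bound ensembles, which makes unequal frame counts harmless.
The backbone set is N, CA, C, O, OXT plus their attached hydrogens (H,
H1--H3, HA, and HA2/HA3 for glycine); everything else is side chain.
All atoms present in the input participate by default, including
hydrogens — MD-derived frames normally contain them, and the pair count
is defined over all atom pairs. `heavyOnly = TRUE` restricts counting
(or parsing) to heavy atoms for inputs without reliable hydrogens;
restricting atoms can only ever decrease counts.

## The five triage stages

Writing `mean_I(r)` and `mean_N(r)` for a residue's per-frame mean
contacts with inhibitor and nucleotide, and
`Δ(r) = mean_I(r) − mean_N(r)`:

| stage | rule | default | why |
|---|---|---|---|
| proximal | occupancy ≥ `minOccupancy` | 0.05 | one contacting frame in a long ensemble is noise; 5% retains any persistently contacting residue |
| structural_ok | backbone fraction < `backboneFractionThreshold`, not annotated critical | 0.75 | mostly-backbone contacts survive any side-chain substitution; critical residues (e.g. the catalytic lysine or the DFG aspartate) would destroy activity |
| differential_positive | `Δ(r) > 0`, strict | — | a tie offers no selectivity between inhibitor and nucleotide |
| sufficient_contact | `mean_I(r) ≥ minMeanContacts` | 1.0 contact/frame | removing a side chain that barely touches the inhibitor cannot block binding |
| family_invariant | alignment column of `r` identical in all homologs | — | if the family already varies at the position (gaps included), the side chain evidently does not discriminate ligands |

Each set is a subset of the previous one by construction. Survivors are
ranked by `Δ(r)` descending (ties broken by residue number ascending)
and annotated with a substitution to `substitutionTarget`, glycine by
default: removing the entire side chain switches off all of its
favorable van der Waals contacts with the inhibitor. A candidate that
already is the target residue is flagged rather than suggested.

The occupancy, backbone-fraction and low-contact thresholds are genuine
design choices — the qualitative rules ("close proximity",
"interact via backbone atoms", "very few contacts overall") do not fix
numerical values — so all three are exposed in `triageConfig()` and
recorded in every report. Critical residues are user-supplied
annotations, not inferred: which residues are indispensable is domain
knowledge, not something a contact count can decide.

### Fixture mode

`runTriageFixture()` executes the same stage logic from a transcribed
per-residue table (flags `critical`, `backbone_mediated`, `low_contact`
plus the two means) instead of raw ensembles. Explicit flags take
precedence over thresholds, so a published worked example is
reproducible exactly even though the underlying trajectories are not
distributed. The bundled MERTK/MRX-2843 fixture encodes the 19-residue
case; its flags are the published facts, while its numeric means are
illustrative values chosen to be consistent with the published
qualitative statements (they determine only the ranking magnitudes, not
the stage memberships).

```{r fixture}
extdata <- system.file("extdata", package = "gatekeepR")
fam <- readMsa(file.path(extdata, "tam_family_synthetic.fasta"),
               file.path(extdata, "tam_family_numbering.tsv"))
runTriageFixture(file.path(extdata, "mertk_worked_example.tsv"),
                 fam, "MERTK")
```

## Residue identity, numbering, alignment

Residues are identified by chain, author residue number, insertion code
and residue name — all four compared, because author numbering alone is
not unique across chains or insertions. Author numbering is kept
throughout (kinase literature numbers residues by the full-length
protein, e.g. Leu593), so the family alignment carries a per-sequence
first-residue offset in a sidecar TSV; `mapPosition()` maps an author
number to a 1-based alignment column by skipping gaps, and
`columnVaries()` reports any inter-homolog difference at the column,
case-insensitively, with gaps counting as differences. The bundled
TAM-family alignment is a synthetic fragment constructed to encode the
published positional correspondence (MERTK Ile650 ↔ TYRO3 Ala581 ↔ AXL
Met599); it makes no claim about the true full-length alignment.

## Parsing choices and degenerate inputs

- Multi-model PDB files or directories of single-model PDB files are
  accepted; in a directory, lexicographic file order defines frame
  order, for determinism.
- Alternate locations resolve to the highest-occupancy record, ties to
  altLoc `A` — the common convention; the choice is immaterial for
  ensemble counting.
- Inconsistent atom counts across models, ligand selections matching
  nothing, and topologies without protein atoms are errors, not
  warnings.
- Ensembles are assumed imaged and whole. There is no periodic-boundary
  handling: frames must be post-processed so that ligand and pocket are
  not split across box images.
- A residue with zero contacts over the whole ensemble is simply absent
  from the profile; differential tables fill absent sides with zero.
- An empty natural-ligand baseline is legal: every structurally
  acceptable residue with sufficient inhibitor contacts then survives
  the differential stages.

## The synthetic generator

`generateEnsembles()` builds matched toy ensembles for testing: pseudo
residues (4 backbone + 2 side-chain atoms with legal PDB names) on a
ring of radius `pocketRadius` (12 Å) around a central single-atom
ligand. Per frame and residue, `floor(p)` routed atoms — side-chain, or
backbone for backbone-routed residues — are placed ~3 Å from the
ligand, plus one more with probability `p − floor(p)`; every coordinate
then receives Gaussian jitter (`jitterSd`, default 0.3 Å). The expected
mean contacts/frame therefore equals the planted propensity `p`
exactly, integer propensities are deterministic in the noise-free
limit, and the 1.5 Å margin between planted positions and the 4.5 Å
shell makes jitter-induced boundary crossings rare at the default
noise. The default plan draws propensities uniformly on [0, 1.5], routes
~20% of residues through their backbone, flags two residues critical,
and plants one gatekeeper at propensities 1.8 (inhibitor) versus 0.2
(nucleotide), so its differential exceeds any unplanted residue's range
by construction — recovering it is a correctness check of the pipeline,
not a hard statistical task.

What the generator does *not* emulate: autocorrelated dynamics (frames
are independent), realistic geometry and chemistry, competing binding
modes, or contact counts that covary between residues. Passing the
recovery tests therefore demonstrates that the counting and triage
machinery is correct, not that the procedure will single out the right
residue on real trajectories, where the signal is weaker and the noise
structured.

## Problem sizes and determinism

The test-suite and acceptance computations use desk-scale ensembles —
50 residues (301 atoms) × 200 frames for recovery runs, 100 seeds per
condition, 500 frames for calibration — sizes at which the exhaustive
double-loop oracles used for verification remain practical. All
randomness flows through a single seeded stream per generator call;
identical seeds reproduce ensembles, files and JSON reports
byte-for-byte (reports deliberately carry no timestamps).

## Limitations

- Contact counting is the only signal: no energetics, no
  hydrogen-bond/π-stacking typing, no estimate of whether a mutation
  preserves folding or catalysis. Candidates are hypotheses for
  experimental validation (activity assay of the mutant plus inhibitor
  challenge), not predictions of mutant viability.
- Docking and MD themselves are out of scope; the package starts from
  ensembles.
- The conservation rule is binary (any variation excludes); it does not
  weigh conservative substitutions differently.
- mmCIF and compressed trajectory formats are not read; convert to
  multi-model PDB first.
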