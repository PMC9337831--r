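# gatekeepR

Contact-based design of inhibitor-resistant, catalytically active
"gatekeeper" kinase mutants.

When a small-molecule inhibitor shows activity in cells, one of the
strongest on-target controls is a kinase mutant that can no longer bind
the inhibitor but still binds its natural nucleotide and retains
catalytic activity. gatekeepR implements the in-silico side of designing
such a mutant from conformational ensembles (for example snapshots
extracted from molecular-dynamics trajectories) of the same kinase bound
to (a) the inhibitor and (b) the nucleotide.

The metric is the **close-contact count**: for every frame, all
ligand-atom/protein-atom pairs with interatomic distance *d* < 4.5 Å are
counted and aggregated per residue *r* into

- `total(r)` — atom-pair-per-frame contacts over the whole ensemble,
  split into backbone and side-chain contacts,
- `occupancy(r)` — fraction of frames with ≥ 1 contact,
- `mean(r)` = `total(r) / n_frames` — the per-frame mean, comparable
  across ensembles of different size,
- `Δ(r)` = `mean_inhibitor(r) − mean_nucleotide(r)` — the differential
  contact.

Residues are then triaged in five nested stages:

1. **proximal** — occupancy ≥ 5 % against the inhibitor;
2. **structural_ok** — drop residues that contact the inhibitor mostly
   through backbone atoms (backbone fraction ≥ 0.75; a side-chain
   substitution cannot remove those contacts) and residues annotated as
   critical for the integrity of the enzyme;
3. **differential_positive** — keep residues with `Δ(r) > 0` (strict);
4. **sufficient_contact** — drop residues with
   `mean_inhibitor(r) < 1` contact/frame;
5. **family_invariant** — drop positions whose alignment column varies
   across the kinase family (gaps count as variation): the family
   already tolerates different side chains there.

Survivors are ranked by `Δ(r)` and reported with a suggested
substitution, glycine by default, since removing the whole side chain
switches off its van der Waals contacts with the inhibitor.

## Worked example

The package bundles the MERTK/MRX-2843 worked example as a transcribed
per-residue fixture (flags plus illustrative contact means) and a small
synthetic TAM-family (TYRO3/AXL/MERTK) alignment fragment:

```r
library(gatekeepR)
extdata <- system.file("extdata", package = "gatekeepR")
fam <- readMsa(file.path(extdata, "tam_family_synthetic.fasta"),
               file.path(extdata, "tam_family_numbering.tsv"))
tr <- runTriageFixture(file.path(extdata, "mertk_worked_example.tsv"),
                       fam, "MERTK")
tr
#> TriageResult
#>   proximal               19 residue(s)
#>   structural_ok          8 residue(s)
#>   differential_positive  5 residue(s)
#>   sufficient_contact     3 residue(s)
#>   family_invariant       2 residue(s)
#>   candidates:
#>  suggestion delta
#>       L593G   3.7
#>       L671G   1.9
```

Of 19 residues near the inhibitor, 8 survive the backbone/critical
exclusion, 5 contact the inhibitor more than the nucleotide, 3 of those
have enough contacts to matter (Leu671, Leu593, Ile650), and Ile650 is
removed because its column varies across the TAM family (Ala in TYRO3,
Met in AXL) — leaving L593G and L671G, with L593G ranked first by
differential contact.

The same pipeline runs on raw ensembles:

```r
lig <- ligandSpec("LIG")
inh <- readEnsemble("inhibitor.pdb", lig)   # multi-model PDB or directory
nat <- readEnsemble("natural.pdb", lig)
runTriage(inh, nat, annotations = readAnnotations("critical.tsv"),
          family = fam, targetId = "MERTK")
```

and from the shell via `inst/scripts/gatekeepr.R`
(`profile | triage | synth | fixture` subcommands).

A seeded synthetic-ensemble generator (`generatorConfig()`,
`generateEnsembles()`) plants per-residue contact propensities,
backbone-vs-side-chain routing and a designated gatekeeper residue, so
every stage is testable without trajectories.

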