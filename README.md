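# ptmdimer

Contact, persistence and buried-surface analysis of variably modified
peptide dimers, with the histone H3 N-terminal tail as the motivating
system.

## The problem

Histone tails are intrinsically disordered regions whose
post-translational modifications (PTMs) tune chromatin behaviour.
Phosphorylation acts as a charge rheostat: the unmodified H3(1–12) tail
is strongly basic, every phosphate subtracts two charge units, and a
fully modified tail is an exactly neutral polyampholyte. Whether and how
two such tails associate is studied with two-chain simulation
trajectories, summarized by a small set of statistics:

* the formal net charge of each annotated peptide
  (e.g. `ART[ph]K[me3]QTAR[me2]KSTG-NME` → +3);
* **N<sub>cc</sub>** — the time-averaged number of inter-chain heavy-atom
  pairs closer than 4 Å (strict inequality, hydrogens excluded);
* the **persistence** of each residue pair — the fraction of frames in
  which at least one heavy-atom pair of the two residues is within 4 Å —
  reported above a 10% threshold and typed as salt bridges when a
  phosphorylated Ser/Thr meets an Arg/Lys side chain;
* **ΔA = ⟨A₁ + A₂ − A₁₂⟩** — the buried solvent-accessible surface area,
  where A₁₂ is the Shrake–Rupley SASA of the dimer frame and A₁, A₂ the
  SASA of each chain with its partner deleted (probe 1.4 Å, time average
  over the trajectory).

`ptmdimer` implements all of these for two-chain trajectories stored as
multi-model PDB files, plus a synthetic trajectory generator that
produces two-chain systems with *exactly known* contact schedules, so
every stage of the pipeline is validated against ground truth rather
than against another implementation.

## Worked example

Generate a study-scale synthetic dimer — two H3(1–12) chains carrying
the mitotic phospho-T3/trimethyl-K4/dimethyl-R8 mark set, 200 frames,
with four scheduled inter-chain contacts at persistences 98/94/64/19% —
and run the full analysis:

```r
library(ptmdimer)

fix   <- h3_dimer_fixture("extended", n_frames = 200, seed = 101)
paths <- write_fixture(fix, "results/fixtures", name = "p1m2_dimer_extended",
                       label = "P1M2/P1M2", conformation = "extended")
bundle <- run_analysis(run_config(paths$pdb, paths$topology,
                                  out_dir = "results/p1m2_dimer_extended"))
bundle
#> <report_bundle> P1M2/P1M2 (extended): N_cc = 8.4, dA = 238 A^2, n_inter = 4 (200 frames)
```

The persistence map (`interaction_map.tsv`) recovers the scheduled
ladder exactly, with the phospho-T3/dimethyl-R8 pair typed as an
arginine–phosphothreonine salt bridge with a methylated donor:

```
pair     scope           persistence  category         donor_modified
A:3-B:8  intermolecular  0.98         R_pT_saltbridge  TRUE
A:2-B:9  intermolecular  0.94         other_contact    FALSE
A:2-B:8  intermolecular  0.64         other_contact    FALSE
A:3-B:9  intermolecular  0.19         K_pT_saltbridge  FALSE
```

N<sub>cc</sub> = 8.4 says that, averaged over the trajectory, about
eight heavy-atom pairs bridge the two chains; ΔA = 238 Å² is the surface
each frame buries in the interface, and it drops to 0 (within the
0.1 Å² lattice resolution) for an association-free control. The charge
model prints the four built-in study peptides at +5, +4, +3 and 0:

```r
vapply(builtin_peptides(), compute_formal_charge, integer(1))
#> P0M0_ala P0M0_ace     P1M2     P2M4
#>        5        4        3        0
```

## Analysis workflow

The `analysis/` directory holds the narrative drivers, each a thin
script over the package functions, writing under `results/`:

1. `01_peptide_charges.R` — charge table of the four study peptides.
2. `02_generate_fixtures.R` — study-scale synthetic trajectories
   (extended and helical starting geometry).
3. `03_contacts_persistence.R` — full pipeline runs and persistence
   maps, checked against the generator ground truth.
4. `04_sasa_burial.R` — buried-surface summary plus an association-free
   control.
5. `05_compare_dimers.R` — a ten-system panel (five dimer compositions ×
   two conformations) assembled into one N<sub>cc</sub>/ΔA/n comparison
   table.

The methods vignette (`vignettes/dimer-analysis-methods.Rmd`) documents
the models, conventions, the generator's noise-proof separation margins,
and what the synthetic fixtures do and do not validate.

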