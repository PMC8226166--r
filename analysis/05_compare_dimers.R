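#!/usr/bin/env Rscript
# Synthetic dimer panel: association strength across modification states
# and starting conformations.
#
# Builds the five dimer combinations of the study peptides in both
# starting geometries, each with a scheduled number of persistent
# intermolecular interactions that follows the ordering observed for the
# real systems (sparse association for unmodified or fully neutralized
# pairs, dense association when phosphorylated and unmodified tails
# meet), and assembles the N_cc / dA / n comparison table. The generator
# realizes at most four simultaneous rigid contacts in the extended
# geometry and two in the helical one, so denser schedules are capped
# there; this panel exercises the pipeline ordering, not the original
# trajectory values.

suppressPackageStartupMessages(library(ptmdimer))

peps <- builtin_peptides()
ladder <- c(0.98, 0.94, 0.64, 0.19)

# interface residues: basic/phospho cluster near each terminus; 11-mer
# chains (acetyl-capped) have everything shifted one position down
iface <- function(spec) {
  if (length(spec) == 12L) list(a = c(3L, 2L, 2L, 3L), b = c(8L, 9L, 8L, 9L))
  else list(a = c(2L, 1L, 1L, 2L), b = c(7L, 8L, 7L, 8L))
}

panel <- list(
  list(label = "P0M0_ala/P0M0_ala", a = "P0M0_ala", b = "P0M0_ala",
       n = c(helical = 0L, extended = 1L)),
  list(label = "P1M2/P0M0_ala", a = "P1M2", b = "P0M0_ala",
       n = c(helical = 2L, extended = 4L)),   # observed 3 / 4
  list(label = "P1M2/P1M2", a = "P1M2", b = "P1M2",
       n = c(helical = 2L, extended = 4L)),   # observed 2 / 6
  list(label = "P0M0_ace/P2M4", a = "P0M0_ace", b = "P2M4",
       n = c(helical = 2L, extended = 4L)),   # observed 4 / 7
  list(label = "P2M4/P2M4", a = "P2M4", b = "P2M4",
       n = c(helical = 1L, extended = 0L))    # observed 1 / 0
)

dir.create("results/panel", recursive = TRUE, showWarnings = FALSE)
bundles <- list()
seed <- 200
for (entry in panel) {
  for (conf in c("helical", "extended")) {
    seed <- seed + 1L
    n_epi <- entry$n[[conf]]
    spec_a <- peps[[entry$a]]; spec_b <- peps[[entry$b]]
    ia <- iface(spec_a); ib <- iface(spec_b)
    ep <- data.frame(res_a = ia$a, res_b = ib$b,
                     fraction = ladder)[seq_len(n_epi), , drop = FALSE]
    sched <- association_schedule(ep, n_frames = 100, seed = seed)
    cat(sprintf("%-18s %-8s n=%d ... ", entry$label, conf, n_epi))
    fix <- generate_dimer_trajectory(spec_a, spec_b, conf, sched)
    name <- sprintf("%s_%s", gsub("/", "_", entry$label), conf)
    paths <- write_fixture(fix, "results/panel", name = name,
                           label = entry$label, conformation = conf)
    b <- run_analysis(run_config(paths$pdb, paths$topology,
                                 n_points = 240))
    stopifnot(b$n_intermolecular == n_epi)
    bundles[[name]] <- b
    cat(sprintf("N_cc %.1f, dA %.0f, n %d\n", b$mean_ncc, b$delta_A,
                b$n_intermolecular))
  }
}

cmp <- compare_runs(bundles)
write.table(cmp, "results/dimer_comparison.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nComparison table (results/dimer_comparison.tsv):\n")
print(cmp, right = FALSE)

# ordering check: within each conformation N_cc rises with the scheduled
# interaction count, and surface is buried exactly when interactions are
# scheduled (dA across different peptide lengths is not comparable,
# since an 11-mer interface buries less area than a 12-mer one)
for (conf in c("helical", "extended")) {
  sub <- cmp[cmp$conformation == conf, ]
  ord <- order(sub$n_intermolecular)
  stopifnot(!is.unsorted(round(sub$N_cc[ord], 6)),
            all(sub$delta_A[sub$n_intermolecular > 0] > 10),
            all(abs(sub$delta_A[sub$n_intermolecular == 0]) < 0.1))
}
cat("\nN_cc tracks scheduled interaction density; dA is positive exactly for associating dimers\n")
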