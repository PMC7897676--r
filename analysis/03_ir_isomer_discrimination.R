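#!/usr/bin/env Rscript
# Step 3: positional-isomer discrimination by solid-deposition GC-FTIR
# library search. A synthetic library (three positional isomers sharing 80%
# of their bands, the distinguishing bands in the fingerprint region, plus
# 20 decoy compounds) is searched with noisy queries of each isomer; the
# first-derivative correlation QMF must rank the true isomer first with a
# large margin over the wrong isomers, mirroring the separations achievable
# on real solid-phase spectra.

suppressPackageStartupMessages(library(npsid))
dir.create("results", showWarnings = FALSE)

sim <- simulate_ir_library(ir_sim_config(seed = 42))
cat(sprintf("library: %d entries (%d isomers, %d decoys)\n",
            length(sim$library), sim$config$n_isomers, sim$config$n_decoys))

all_hits <- NULL
for (nm in names(sim$queries)) {
  hits <- rank_library(sim$queries[[nm]], sim$library)
  wrong <- hits[grepl("^isomer", hits$name) & hits$name != nm, ]
  cat(sprintf(
    "\nquery %s: Hit #1 = %s (QMF %.1f); best wrong isomer %s at Hit #%d (QMF %.1f); gap %.1f\n",
    nm, hits$name[1], hits$qmf[1], wrong$name[1], wrong$rank[1],
    wrong$qmf[1], hits$qmf[1] - wrong$qmf[1]))
  print(head(hits, 5), row.names = FALSE)
  all_hits <- rbind(all_hits, cbind(query = nm, hits))
}
write.csv(all_hits, "results/ir_hit_lists.csv", row.names = FALSE)
cat("\nwrote results/ir_hit_lists.csv\n")
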