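#!/usr/bin/env Rscript
# Cis-regulatory motif discovery in the module promoters: word census, greedy
# IUPAC generalization and PWM EM, filtered by the cascade (length >= 7,
# <= 3 uncharacterized positions, p < 1e-5, >= 2 algorithms) and merged into
# IUPAC consensuses.

suppressMessages(library(yapmod))
proms <- read_fasta("results/data/promoters.fasta")
m <- read_module_json("results/module.json")

module_ids <- intersect(m$members, names(proms))
mod <- proms[module_ids]
bg <- proms[setdiff(names(proms), module_ids)]
res <- discover_motifs(mod, bg, seed = 61)
write_motif_report(res$candidates, "results/motif_candidates.tsv")
write_motif_report(res$retained, "results/motifs_retained.tsv")

summ <- lapply(res$consensus, function(cm)
  list(consensus = cm$consensus, n_members = nrow(cm$members),
       p = cm$p, coverage_pct = 100 * cm$coverage))
jsonlite::write_json(summ, "results/motif_consensus.json",
                     auto_unbox = TRUE, digits = NA)

cat("Motifs:", nrow(res$candidates), "candidates ->", nrow(res$retained),
    "retained ->", length(res$consensus), "consensus group(s)\n")
for (cm in res$consensus)
  cat(sprintf("  %s  p = %.3g, present in %.0f%% of module promoters\n",
              cm$consensus, cm$p, 100 * cm$coverage))
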