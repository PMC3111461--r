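#!/usr/bin/env Rscript
# Generate every synthetic input for the workflow, with ground truth on disk.
# Conditions: ~5000-gene matrices with 7 arrays per group, 5000 IP/INPUT
# probes from the two-component regression mixture, 2000 promoters of 800 nt
# with a YRE-like element planted in the module promoters.

suppressMessages(library(yapmod))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1)
write_run_config(run_config(sim = cfg), "results/data/run_config.json")

ben <- gen_expression(cfg, "benomyl")
write_expression_tsv(ben$dataset, "results/data/expr_benomyl.tsv")
mut <- gen_expression(cfg, "mutant")
write_expression_tsv(mut$dataset, "results/data/expr_mutant.tsv")

chip <- gen_chip(cfg)
write_probe_tsv(chip$probes, "results/data/chip_probes.tsv")

universe <- rownames(ben$dataset$mat)
prom_ids <- universe[seq_len(cfg$n_promoters)]
truth_module <- intersect(ben$truth$de_genes, mut$truth$de_genes)
module_ids <- intersect(truth_module, prom_ids)
prom <- gen_promoters(cfg, motif = "TTASTAA", module_ids = module_ids,
                      ids = prom_ids)
write_fasta(prom$promoters, "results/data/promoters.fasta")

pro <- gen_proteomes(cfg, n_families = 100, rewire_fraction = 0.1)
write_fasta(pro$proteome_a, "results/data/proteome_a.fasta")
write_fasta(pro$proteome_b, "results/data/proteome_b.fasta")

truth <- list(de_genes = ben$truth$de_genes,
              tf_dependent_genes = mut$truth$de_genes,
              bound_promoters = chip$truth$bound_promoters,
              module_ids = module_ids,
              planted_motif = "TTASTAA",
              ortholog_pairs = pro$truth$ortholog_pairs)
jsonlite::write_json(truth, "results/data/truth.json", auto_unbox = TRUE)

cat("Simulated:", length(universe), "genes,",
    length(unique(chip$probes$probe)), "probes,",
    length(prom$promoters), "promoters (module:", length(module_ids), "),",
    length(pro$proteome_a), "+", length(pro$proteome_b), "proteins\n")
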