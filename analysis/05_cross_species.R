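#!/usr/bin/env Rscript
# Cross-species comparison: thresholded homology links (E < 1e-2, aligned
# length > 100 aa, identity > 25%), reciprocal-best-hit orthologs, module
# overlap against the shuffled-modules null, and the FP/FN rates of
# transferring a module by homology alone.

suppressMessages(library(yapmod))
pa <- read_fasta("results/data/proteome_a.fasta")
pb <- read_fasta("results/data/proteome_b.fasta")
truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)

links <- homology_links(pa, pb)
utils::write.table(links, "results/homology_links.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
orthos <- rbh_orthologs(links)
utils::write.table(orthos, "results/orthologs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
tp <- truth$ortholog_pairs
rec <- mean(paste(tp$a, tp$b) %in% paste(orthos$a, orthos$b))

# module in species A vs its orthologous image in species B, minus rewired
ma <- tp$a[1:20]
mb <- tp$b[tp$a %in% ma][1:14]   # partial conservation
ov <- module_overlap(ma, mb, orthos, names(pa), names(pb),
                     n_perm = 1e4, seed = 51)
tr <- transfer_error_rates(ma, links, mb, names(pb))
jsonlite::write_json(list(n_links = nrow(links), n_orthologs = nrow(orthos),
                          ortholog_recovery = rec, overlap = ov,
                          transfer = tr[c("fp_rate", "fn_rate",
                                          "fp_rate_refdenom")]),
                     "results/xspecies.json", auto_unbox = TRUE, digits = NA)

cat("Homology:", nrow(links), "links,", nrow(orthos),
    "one-to-one orthologs (recovery", round(rec, 3), ")\n")
cat("Module overlap:", ov$count, "ortholog pairs (",
    round(ov$percent), "% of the smaller module ), p_perm =",
    signif(ov$p_perm, 3), ", p_hyper =", signif(ov$p_hyper, 3), "\n")
cat("Annotation transfer: FP", round(tr$fp_rate, 1), "% , FN",
    round(tr$fn_rate, 1), "%\n")
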