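#!/usr/bin/env Rscript
# Step 4: integrate the three evidence streams. A gene joins the module iff
# it is up-regulated (step 1) AND either TF-dependent (step 2) or TF-bound
# (step 3).

suppressMessages(library(yapmod))
step1 <- readLines("results/step1_genes.txt")
step2 <- readLines("results/step2_genes.txt")
step3 <- readLines("results/step3_genes.txt")
ds <- read_expression_tsv("results/data/expr_benomyl.tsv")
truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)

m <- build_btm(step1, step2, step3, rownames(ds$mat),
               species = "synthetic", tf = "AP1")
write_module_json(m, "results/module.json")
rep <- module_report(m)
print(rep$counts)

truth_module <- intersect(truth$de_genes,
                          union(truth$tf_dependent_genes,
                                truth$bound_promoters))
tp <- length(intersect(m$members, truth_module))
f1 <- 2 * tp / (length(m$members) + length(truth_module))
cat("Module:", length(m$members), "genes; planted-truth F1 =",
    round(f1, 3), "\n")
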