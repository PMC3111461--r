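test_that("expression generator plants the configured number of genes", {
  cfg <- sim_config(seed = 1, n_genes = 1000, de_fraction = 0.05,
                    n_samples_per_group = 4)
  out <- gen_expression(cfg, "benomyl")
  expect_length(out$truth$de_genes, 50L)
  expect_equal(dim(out$dataset$mat), c(1000L, 8L))
  expect_true(all(out$truth$de_genes %in% rownames(out$dataset$mat)))
  expect_error(sim_config(n_genes = 0), "positive")
})

test_that("generators are pure functions of the config (bit-identical reruns)", {
  cfg <- sim_config(seed = 7, n_genes = 300, n_probes = 200, n_promoters = 60,
                    promoter_length = 120, n_samples_per_group = 3)
  expect_identical(gen_expression(cfg, "benomyl"), gen_expression(cfg, "benomyl"))
  expect_identical(gen_chip(cfg), gen_chip(cfg))
  expect_identical(gen_promoters(cfg, "TTACTAA"), gen_promoters(cfg, "TTACTAA"))
  expect_identical(gen_proteomes(cfg, n_families = 10),
                   gen_proteomes(cfg, n_families = 10))
  # and the benomyl / mutant designs differ
  expect_false(identical(gen_expression(cfg, "benomyl")$dataset$mat,
                         gen_expression(cfg, "mutant")$dataset$mat))
})

test_that("zero effect size leaves planted genes indistinguishable", {
  cfg <- sim_config(seed = 3, n_genes = 1000, de_fraction = 0.5,
                    effect_size = 0, n_samples_per_group = 4)
  out <- gen_expression(cfg, "benomyl")
  planted <- out$dataset$mat[out$truth$de_genes, ]
  rest <- out$dataset$mat[setdiff(rownames(out$dataset$mat), out$truth$de_genes), ]
  ks <- suppressWarnings(stats::ks.test(as.vector(planted), as.vector(rest)))
  expect_gt(ks$p.value, 0.01)
})

test_that("chip generator honours the mixing weight", {
  cfg0 <- sim_config(seed = 2, n_probes = 500, pi_bound = 0, n_replicates = 1)
  out0 <- gen_chip(cfg0)
  expect_length(out0$truth$bound_probes, 0L)
  cfg <- sim_config(seed = 2, n_probes = 5000, pi_bound = 0.2, n_replicates = 1)
  out <- gen_chip(cfg)
  phat <- length(out$truth$bound_probes) / 5000
  expect_lt(abs(phat - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))
  expect_error(sim_config(pi_bound = 1.2), "proportion")
  expect_error(sim_config(b0 = 2, b1 = 1), "steeper")
})

test_that("with vanishing noise the component is recoverable by nearest line", {
  cfg <- sim_config(seed = 4, n_probes = 400, sigma = 1e-4, n_replicates = 1,
                    a0 = 0, b0 = 1, a1 = 2, b1 = 1.6, pi_bound = 0.3)
  out <- gen_chip(cfg)
  r0 <- abs(out$probes$ip - (0 + 1 * out$probes$input))
  r1 <- abs(out$probes$ip - (2 + 1.6 * out$probes$input))
  lab <- out$probes$probe[r1 < r0]
  expect_setequal(lab, out$truth$bound_probes)
})

test_that("promoter generator plants resolvable sites where it says it does", {
  cfg <- sim_config(seed = 5, n_promoters = 200, de_fraction = 0.25,
                    promoter_length = 400, motif_prob_in_module = 1)
  out <- gen_promoters(cfg, motif = "ATTACTAA")
  sites <- out$truth$motif_sites
  expect_setequal(unique(sites$seq_id), out$module_ids)
  # truth consistency: the recorded word is really at the recorded offset
  for (i in seq_len(nrow(sites))) {
    s <- substr(out$promoters[[sites$seq_id[i]]], sites$offset[i],
                sites$offset[i] + nchar(sites$word[i]) - 1L)
    expected <- if (sites$strand[i] == "+") sites$word[i]
                else iupac_revcomp(sites$word[i])
    expect_identical(s, expected)
  }
  # scanning recovers at least 95% of recorded sites
  hits <- iupac_sites(out$promoters, "ATTACTAA")
  found <- paste(hits$seq_id, hits$offset)
  expect_gte(mean(paste(sites$seq_id, sites$offset) %in% found), 0.95)
  expect_error(gen_promoters(sim_config(promoter_length = 5), "ATTACTAA"),
               "longer")
})

test_that("background nucleotide composition follows the GC setting", {
  cfg <- sim_config(seed = 6, n_promoters = 200, de_fraction = 0,
                    promoter_length = 800, gc_content = 0.5)
  out <- gen_promoters(cfg, motif = "TTACTAA", module_ids = character(0))
  freq <- table(strsplit(paste(out$promoters, collapse = ""), "")[[1]])
  expect_true(all(abs(freq / sum(freq) - 0.25) < 0.02))
})

test_that("proteome generator records exact ortholog truth", {
  cfg <- sim_config(seed = 8)
  full <- gen_proteomes(cfg, n_families = 30, rewire_fraction = 0)
  expect_equal(nrow(full$truth$ortholog_pairs), 30L)
  ident <- gen_proteomes(cfg, n_families = 10, rewire_fraction = 0,
                         mutation_rate = 0)
  expect_identical(unname(ident$proteome_a), unname(ident$proteome_b))
  rew <- gen_proteomes(cfg, n_families = 30, rewire_fraction = 0.3)
  expect_equal(nrow(rew$truth$ortholog_pairs), 21L)
  expect_length(rew$proteome_b, 21L)
})

test_that("toy complex generator validates geometry and rejects clashes", {
  expect_error(gen_complex(data.frame(resname = "ARG", atom = "NH1",
                                      dna_atom = "OP1", distance = 0.5,
                                      class = "salt_bridge")), "clash")
  expect_error(gen_complex(data.frame(resname = "ALA", atom = "CB",
                                      dna_atom = "OP1", distance = 3,
                                      class = "salt_bridge")), "salt bridge")
  expect_error(gen_complex(data.frame(resname = "GLN", atom = "NE2",
                                      dna_atom = "N7", distance = 4.2,
                                      class = "hydrogen_bond")), "2.4")
})
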