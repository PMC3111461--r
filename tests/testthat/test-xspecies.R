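test_that("homology links enforce all three thresholds", {
  set.seed(31)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  long_seq <- paste(sample(aa, 150, replace = TRUE), collapse = "")
  short_seq <- paste(sample(aa, 80, replace = TRUE), collapse = "")
  links <- homology_links(c(q1 = long_seq), c(s1 = long_seq))
  expect_equal(nrow(links), 1L)
  expect_equal(links$pident, 100)
  expect_equal(links$length, 150L)
  # identical but too short: the length > 100 rule removes it
  expect_equal(nrow(homology_links(c(q1 = short_seq), c(s1 = short_seq))), 0L)
  expect_error(homology_links(c(q1 = "MKV1"), c(s1 = long_seq)), "symbol")
})

test_that("vectorized link search equals a per-pair alignment oracle", {
  cfg <- sim_config(seed = 32)
  pro <- gen_proteomes(cfg, n_families = 20, rewire_fraction = 0.1,
                       mutation_rate = 0.05)
  links <- homology_links(pro$proteome_a, pro$proteome_b)
  got <- sort(paste(links$a, links$b))
  want <- character(0)
  tot_n <- sum(nchar(pro$proteome_b))
  for (a in names(pro$proteome_a)) for (b in names(pro$proteome_b)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(pro$proteome_a[[a]]),
      Biostrings::AAString(pro$proteome_b[[b]]),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    ev <- 0.041 * nchar(pro$proteome_a[[a]]) * tot_n *
      exp(-0.267 * Biostrings::score(aln))
    len <- nchar(as.character(Biostrings::pattern(aln)))
    ok <- ev < 1e-2 && len > 100 && Biostrings::pid(aln, "PID1") > 25
    if (ok) want <- c(want, paste(a, b))
  }
  expect_identical(got, sort(want))
})

test_that("reciprocal best hits form a one-to-one matching", {
  links <- data.frame(a = c("a1", "a1", "a2", "a3"),
                      b = c("b1", "b2", "b1", "b3"),
                      score = c(90, 50, 95, 70))
  # a1's best is b1 but b1's best is a2 -> a1 unpaired; a2-b1 and a3-b3 pair
  out <- rbh_orthologs(links)
  expect_identical(out$a, c("a2", "a3"))
  expect_identical(out$b, c("b1", "b3"))
  sym <- data.frame(a = c("a1", "a2"), b = c("b1", "b2"), score = c(80, 85))
  expect_equal(nrow(rbh_orthologs(sym)), 2L)
  set.seed(33)
  for (i in 1:10) {
    rnd <- data.frame(a = sample(sprintf("a%d", 1:6), 12, replace = TRUE),
                      b = sample(sprintf("b%d", 1:6), 12, replace = TRUE),
                      score = runif(12, 40, 100))
    rnd <- rnd[!duplicated(rnd[, c("a", "b")]), ]
    out <- rbh_orthologs(rnd)
    expect_false(anyDuplicated(out$a) > 0)
    expect_false(anyDuplicated(out$b) > 0)
  }
})

test_that("orthology recovers the planted pairs at study-like divergence", {
  cfg <- sim_config(seed = 34)
  pro <- gen_proteomes(cfg, n_families = 100, rewire_fraction = 0.1,
                       mutation_rate = 0.05)
  links <- homology_links(pro$proteome_a, pro$proteome_b)
  orthos <- rbh_orthologs(links)
  truth <- paste(pro$truth$ortholog_pairs$a, pro$truth$ortholog_pairs$b)
  expect_gte(mean(truth %in% paste(orthos$a, orthos$b)), 0.95)
})

test_that("module overlap counts ortholog pairs across modules", {
  orthos <- data.frame(a = sprintf("a%d", 1:10), b = sprintf("b%d", 1:10))
  ua <- sprintf("a%d", 1:20); ub <- sprintf("b%d", 1:20)
  mirror <- module_overlap(sprintf("a%d", 1:5), sprintf("b%d", 1:5), orthos,
                           ua, ub, n_perm = 100, seed = 1)
  expect_equal(mirror$count, 5L)
  expect_equal(mirror$percent, 100)
  disj <- module_overlap(sprintf("a%d", 11:15), sprintf("b%d", 11:15), orthos,
                         ua, ub, n_perm = 100, seed = 1)
  expect_equal(disj$count, 0L)
  none <- module_overlap("a1", "b1", orthos[0, ], ua, ub)
  expect_equal(none$count, 0L)
  expect_equal(none$p_perm, 1)
})

test_that("overlap count is invariant under gene relabeling", {
  set.seed(35)
  orthos <- data.frame(a = sprintf("a%d", 1:15), b = sprintf("b%d", 1:15))
  ua <- sprintf("a%d", 1:15); ub <- sprintf("b%d", 1:15)
  ma <- sample(ua, 6); mb <- sample(ub, 6)
  base <- module_overlap(ma, mb, orthos, ua, ub, n_perm = 50, seed = 1)$count
  perm <- sample(15)
  relab <- setNames(sprintf("z%d", perm), ua)
  o2 <- data.frame(a = relab[orthos$a], b = orthos$b)
  got <- module_overlap(relab[ma], mb, o2, unname(relab[ua]), ub,
                        n_perm = 50, seed = 1)$count
  expect_equal(got, base)
})

test_that("annotation-transfer error rates match their constructions", {
  links <- data.frame(a = c("a1", "a2", "a3"), b = c("b1", "b2", "b3"),
                      score = 1)
  ub <- sprintf("b%d", 1:10)
  perfect <- transfer_error_rates(c("a1", "a2"), links, c("b1", "b2"), ub)
  expect_equal(perfect$fp_rate, 0); expect_equal(perfect$fn_rate, 0)
  wrong <- transfer_error_rates(c("a1", "a2"), links, c("b9", "b10"), ub)
  expect_equal(wrong$fp_rate, 100); expect_equal(wrong$fn_rate, 100)
  nothing <- transfer_error_rates("a9", links, "b1", ub)
  expect_true(is.na(nothing$fp_rate))
  # rewiring fraction r with perfect homology gives FN = r exactly here:
  # transfer from the rewired proteome back to the full one misses exactly
  # the families whose counterpart was lost
  cfg <- sim_config(seed = 36)
  pro <- gen_proteomes(cfg, n_families = 100, rewire_fraction = 0.3,
                       mutation_rate = 0)
  back_links <- data.frame(a = pro$truth$ortholog_pairs$b,
                           b = pro$truth$ortholog_pairs$a, score = 1)
  src <- names(pro$proteome_b)            # module in the rewired species
  ref <- names(pro$proteome_a)            # reference module: all 100 families
  tr <- transfer_error_rates(src, back_links, ref, ref)
  expect_equal(tr$fn_rate, 30)
  expect_equal(tr$fp_rate, 0)
  expect_equal(length(tr$predicted), 70L)
})
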