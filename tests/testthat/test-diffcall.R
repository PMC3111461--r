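test_that("moderated t handles degenerate genes by construction", {
  ds <- tiny_dataset(list(c(1, 2, 3, 1, 2, 3),      # identical groups
                          c(2, 2, 2, 0, 0, 0),      # zero variance, shifted
                          c(0.1, -0.2, 0.3, 0.2, -0.1, 0),
                          c(1, 1.1, 0.9, 0.2, 0.1, 0.3)))
  tb <- moderated_t(ds)
  expect_equal(tb$statistic[1], 0)
  expect_equal(tb$p[1], 1)
  expect_true(is.finite(tb$statistic[2]))  # shrinkage prevents 0/0
  expect_true(tb$call[2])
  expect_true(all(tb$p >= 0 & tb$p <= 1, na.rm = TRUE))
})

test_that("moderated t agrees with an independent empirical-Bayes fit", {
  cfg <- sim_config(seed = 10, n_genes = 500, n_samples_per_group = 4,
                    de_fraction = 0.1)
  ds <- gen_expression(cfg, "benomyl")$dataset
  ours <- moderated_t(ds)
  design <- cbind(1, as.integer(ds$groups == levels(ds$groups)[1]))
  fit <- limma::eBayes(limma::lmFit(ds$mat, design))
  expect_gt(cor(ours$statistic, fit$t[, 2]), 0.99)
  expect_gt(cor(ours$p, fit$p.value[, 2]), 0.99)
})

test_that("permutation d ranks strongly planted genes on top", {
  cfg <- sim_config(seed = 11, n_genes = 1000, de_fraction = 0.05,
                    noise_sd = 0.25, effect_size = 1, n_samples_per_group = 7)
  out <- gen_expression(cfg, "benomyl")
  tb <- permutation_d(out$dataset, n_perm = 100, seed = 1)
  top <- tb$gene[order(-tb$statistic)][seq_along(out$truth$de_genes)]
  expect_gte(mean(out$truth$de_genes %in% top), 0.9)
  expect_error(permutation_d(out$dataset, n_perm = 5), "n_perm")
})

test_that("constant data yields zero d and no calls", {
  mat <- matrix(1, 20, 6, dimnames = list(sprintf("g%02d", 1:20), NULL))
  ds <- expression_dataset(mat, factor(rep(c("treated", "reference"), each = 3),
                                       levels = c("treated", "reference")))
  tb <- permutation_d(ds, n_perm = 20, seed = 1)
  expect_true(all(tb$statistic == 0, na.rm = TRUE))
  expect_false(any(tb$call))
})

test_that("permutation FDR is monotone non-increasing in the |d| threshold", {
  cfg <- sim_config(seed = 12, n_genes = 300, de_fraction = 0.1,
                    n_samples_per_group = 4)
  tb <- permutation_d(gen_expression(cfg, "benomyl")$dataset,
                      n_perm = 50, seed = 2)
  ord <- order(abs(tb$statistic), decreasing = TRUE)
  # brute force over the threshold grid given by the observed |d| values
  expect_false(is.unsorted(tb$fdr[ord]))
})

test_that("the per-group caller agrees with moderated t on equal-variance data", {
  cfg <- sim_config(seed = 13, n_genes = 800, de_fraction = 0.05,
                    n_samples_per_group = 5)
  ds <- gen_expression(cfg, "benomyl")$dataset
  a <- moderated_t(ds); b <- groupwise_variance_t(ds)
  expect_gte(mean(a$call == b$call), 0.9)
})

test_that("a huge-variance zero-shift gene is not called", {
  set.seed(99)
  rows <- c(list(c(30, -30, 25, 0.01, -0.02, 0.03)),
            replicate(30, rnorm(6, sd = 0.3), simplify = FALSE))
  ds <- tiny_dataset(rows)
  tb <- groupwise_variance_t(ds)
  expect_false(tb$call[1])
})

test_that("consensus voting applies the at-least-two rule", {
  mk <- function(genes, calls, dirs) data.frame(
    gene = genes, statistic = 1, p = 0.01, fdr = 0.01, call = calls,
    direction = dirs, caller = "x", stringsAsFactors = FALSE)
  t1 <- mk(c("A", "B", "C"), c(TRUE, TRUE, TRUE), c(1, 1, 1))
  t2 <- mk(c("A", "B", "C"), c(TRUE, FALSE, TRUE), c(1, 1, 1))
  t3 <- mk(c("A", "B", "C"), c(FALSE, FALSE, TRUE), c(1, 1, 1))
  expect_setequal(consensus_vote(list(t1, t2, t3), 2, "up")$genes, c("A", "C"))
  none <- mk(c("A", "B"), c(FALSE, FALSE), c(1, 1))
  expect_length(consensus_vote(list(none, none), 2, "up")$genes, 0L)
})

test_that("voting equals brute-force enumeration on random call tables", {
  set.seed(42)
  genes <- sprintf("g%02d", 1:15)
  for (rep in 1:20) {
    tables <- lapply(1:3, function(i) data.frame(
      gene = genes, statistic = rnorm(15), p = runif(15), fdr = runif(15),
      call = runif(15) < 0.4, direction = sample(c(-1, 1), 15, replace = TRUE),
      caller = paste0("c", i), stringsAsFactors = FALSE))
    for (dir in c("up", "down", "both")) {
      got <- consensus_vote(tables, 2, dir)$genes
      want <- Filter(function(g) {
        votes <- sum(vapply(tables, function(tb) {
          row <- tb[tb$gene == g, ]
          row$call && switch(dir, up = row$direction > 0,
                             down = row$direction < 0, both = TRUE)
        }, logical(1)))
        votes >= 2
      }, genes)
      expect_setequal(got, want)
    }
  }
  # consensus shrinks weakly as min_agree grows
  tbs <- lapply(1:3, function(i) data.frame(
    gene = genes, statistic = 1, p = 0.01, fdr = 0.01,
    call = runif(15) < 0.5, direction = 1, caller = paste0("c", i),
    stringsAsFactors = FALSE))
  sizes <- vapply(1:3, function(m) length(consensus_vote(tbs, m, "up")$genes),
                  numeric(1))
  expect_false(is.unsorted(rev(sizes)))
})

test_that("one-sample consensus behaves at the degenerate extremes", {
  zeros <- matrix(0, 20, 4)
  expect_length(call_onesample(zeros, n_perm = 20, seed = 1)$consensus$genes, 0L)
  expect_error(call_onesample(matrix(0, 5, 1)), "replicates")
})
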