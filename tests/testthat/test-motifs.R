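test_that("hypergeometric tail equals exact enumeration on a full grid", {
  # every consistent (N, n, K, k) with N <= 12, in exact rational arithmetic
  for (N in c(5L, 8L, 12L)) for (n in 0:N) for (K in 0:N) {
    for (k in 0:min(n, K)) {
      if (n - k > N - K) next
      expect_equal(hypergeom_enrichment(k, n, K, N),
                   hyper_tail_oracle(k, n, K, N), tolerance = 1e-12)
    }
  }
  expect_equal(hypergeom_enrichment(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(0, 6, 10, 20), 1)
  expect_equal(hypergeom_enrichment(4, 6, 10, 20),
               hyper_tail_oracle(4, 6, 10, 20), tolerance = 1e-12)
  expect_error(hypergeom_enrichment(7, 6, 10, 20), "inconsistent")
  expect_error(hypergeom_enrichment(2, 6, 25, 20), "inconsistent")
})

test_that("word census ranks a planted word first", {
  cfg <- sim_config(seed = 40, n_promoters = 600, de_fraction = 100 / 600,
                    motif_prob_in_module = 0.6, promoter_length = 500)
  pr <- gen_promoters(cfg, motif = "ATTACTAA", background_motif_prob = 0.01)
  mod <- pr$promoters[pr$module_ids]
  bg <- pr$promoters[setdiff(names(pr$promoters), pr$module_ids)]
  words <- discover_words(mod, bg, k = 8)
  expect_identical(words$motif[1], "ATTACTAA")
  expect_lt(words$p[1], 1e-10)
  expect_error(discover_words(mod, bg, k = 3), "4, 12")
})

test_that("word-census p-values are calibrated on a null module", {
  # a module drawn at random from the background: per-word p-values must be
  # (conservatively) uniform, so the fraction below any alpha stays at or
  # below alpha up to Monte-Carlo slack
  for (s in 1:3) {
    cfg <- sim_config(seed = 400 + s, n_promoters = 2100,
                      de_fraction = 100 / 2100, motif_prob_in_module = 0)
    pr <- gen_promoters(cfg, motif = "ATTACTAA")  # nothing actually planted
    mod <- pr$promoters[pr$module_ids]
    bg <- pr$promoters[setdiff(names(pr$promoters), pr$module_ids)]
    w <- discover_words(mod, bg, k = 8, max_candidates = Inf)
    n_words <- length(unique(yapmod:::.kmer_presence(c(mod, bg), 8L)$canon))
    # conservative per-word calibration: at most alpha of all scored words
    # can sit below alpha
    expect_lte(sum(w$p < 0.01) / n_words, 0.01)
    # and nothing reaches the cascade operating point of 1e-5
    expect_equal(sum(w$p < 1e-5), 0L)
  }
})

test_that("greedy generalization merges equally planted variants", {
  # the two planted variants TTACTAA / TTAATAA are not reverse complements,
  # so only the degenerate code TTAMTAA covers both
  cfg <- sim_config(seed = 41, n_promoters = 500, de_fraction = 0.2,
                    promoter_length = 400, motif_prob_in_module = 1)
  pr <- gen_promoters(cfg, motif = "TTAMTAA")
  mod <- pr$promoters[pr$module_ids]
  bg <- pr$promoters[setdiff(names(pr$promoters), pr$module_ids)]
  out <- discover_degenerate(mod, bg, seeds = "TTACTAA")
  expect_identical(out$motif, "TTAMTAA")
  seed_p <- yapmod:::.motif_enrichment("TTACTAA", mod, bg)$p
  expect_lte(out$p, seed_p)
  # an already optimal seed is returned unchanged
  opt <- discover_degenerate(mod, bg, seeds = "TTAMTAA")
  expect_identical(opt$motif, "TTAMTAA")
  expect_lte(iupac_n_ambiguous(out$motif), 3L)
})

test_that("reverse-complement variants are already one canonical motif", {
  # TTACTAA and TTAGTAA are reverse complements: strand-collapsed counting
  # makes them the same motif, so generalizing one gains nothing
  cfg <- sim_config(seed = 46, n_promoters = 300, de_fraction = 0.2,
                    promoter_length = 300, motif_prob_in_module = 1)
  pr <- gen_promoters(cfg, motif = "TTASTAA")
  mod <- pr$promoters[pr$module_ids]
  bg <- pr$promoters[setdiff(names(pr$promoters), pr$module_ids)]
  pc <- yapmod:::.motif_enrichment("TTACTAA", mod, bg)
  ps <- yapmod:::.motif_enrichment("TTASTAA", mod, bg)
  expect_equal(pc$k, ps$k)
  expect_equal(pc$p, ps$p)
})

test_that("PWM EM recovers a strongly planted motif", {
  cfg <- sim_config(seed = 42, n_promoters = 600, de_fraction = 50 / 600,
                    motif_prob_in_module = 1)
  pr <- gen_promoters(cfg, motif = "ATTACTAA")
  mod <- pr$promoters[pr$module_ids]
  bg <- pr$promoters[setdiff(names(pr$promoters), pr$module_ids)]
  out <- discover_pwm(mod, bg, width = 8, seed = 1)
  mm <- motifs_match(out$motif, "ATTACTAA", min_overlap = 6)
  expect_true(mm$match)
  expect_gte(mm$overlap, 6)
  expect_false(is.unsorted(attr(out, "loglik_trace")))
  expect_identical(discover_pwm(mod, bg, width = 8, seed = 1)$motif, out$motif)
})

test_that("the filter cascade applies each rule and is idempotent", {
  cand <- rbind(
    .row <- data.frame(motif = "TTACTA", algorithm = "words",
                       algorithms = "words", p = 1e-9, k_module = 10,
                       n_module = 20, K_universe = 12, N_universe = 500),
    data.frame(motif = "NTANNCNNA", algorithm = "degen", algorithms = "degen",
               p = 1e-9, k_module = 10, n_module = 20, K_universe = 12,
               N_universe = 500),
    data.frame(motif = "TTACTAAG", algorithm = "words", algorithms = "words",
               p = 1e-6, k_module = 10, n_module = 20, K_universe = 12,
               N_universe = 500),
    data.frame(motif = "TTACTAAG", algorithm = "pwm", algorithms = "pwm",
               p = 2e-6, k_module = 10, n_module = 20, K_universe = 12,
               N_universe = 500),
    data.frame(motif = "CCGTTACC", algorithm = "words", algorithms = "words",
               p = 1e-8, k_module = 10, n_module = 20, K_universe = 12,
               N_universe = 500),
    data.frame(motif = "AAAAAAAA", algorithm = "words", algorithms = "words",
               p = 1e-3, k_module = 10, n_module = 20, K_universe = 12,
               N_universe = 500))
  out <- filter_cascade(cand)
  # 6-mer: out (length); 5-ambiguous 9-mer: out (degeneracy); p = 1e-3: out;
  # CCGTTACC: single algorithm: out; TTACTAAG from two algorithms: retained
  expect_setequal(unique(out$motif), "TTACTAAG")
  expect_setequal(strsplit(out$algorithms[1], ",")[[1]], c("pwm", "words"))
  again <- filter_cascade(out)
  expect_identical(again$motif, out$motif)
  expect_true(all(out$motif %in% cand$motif))  # output subset of input
})

test_that("consensus merging unions compatible motifs column-wise", {
  yres <- c("TTACTAA", "TTACTCA", "TTAGTCA", "TTACAAA", "TGACAAA", "TGACTCA")
  expect_identical(iupac_union(yres), "TKASWMA")
  cand <- data.frame(motif = c("TTACTAA", "TTASTAA"),
                     algorithm = "words", algorithms = "words,degen",
                     p = c(1e-8, 1e-7), k_module = 10, n_module = 20,
                     K_universe = 12, N_universe = 500)
  proms <- c(p1 = paste0(strrep("C", 20), "TTACTAA", strrep("C", 20)),
             p2 = strrep("G", 50))
  cons <- merge_to_consensus(cand, proms)
  expect_length(cons, 1L)
  expect_identical(cons[[1]]$consensus, "TTASTAA")
  expect_equal(cons[[1]]$coverage, 0.5)
  single <- merge_to_consensus(cand[1, ], proms)
  expect_identical(single[[1]]$consensus, "TTACTAA")
  # members match wherever the merged consensus matches their own sites
  expect_true(all(iupac_present(proms, "TTACTAA") <=
                  iupac_present(proms, cons[[1]]$consensus)))
})

test_that("coverage agrees with a position-by-position scan oracle", {
  set.seed(43)
  cfg <- sim_config(seed = 44, n_promoters = 50, de_fraction = 0.4,
                    promoter_length = 120, motif_prob_in_module = 0.8)
  pr <- gen_promoters(cfg, motif = "TTASTAA")
  motif <- "TTASTAA"
  sets <- lapply(strsplit(motif, "")[[1]], iupac_expand)
  rc_sets <- rev(lapply(sets, function(b) chartr("ACGT", "TGCA", b)))
  scan1 <- function(s, ss) {
    ch <- strsplit(s, "")[[1]]
    w <- length(ss)
    for (i in seq_len(length(ch) - w + 1)) {
      if (all(mapply(function(c1, set) c1 %in% set, ch[i:(i + w - 1)], ss)))
        return(TRUE)
    }
    FALSE
  }
  manual <- mean(vapply(pr$promoters, function(s)
    scan1(s, sets) || scan1(s, rc_sets), logical(1)))
  expect_equal(motif_coverage(pr$promoters, motif), manual)
})

test_that("promoter extraction respects neighbors, bounds and strand", {
  genome <- list(chr1 = paste(sample(c("A", "C", "G", "T"), 3000,
                                     replace = TRUE), collapse = ""))
  ann <- data.frame(gene = c("up", "g_plus", "g_minus", "g_far"),
                    chrom = "chr1",
                    start = c(500, 1001, 1200, 2500),
                    end = c(700, 1100, 1300, 2600),
                    strand = c("+", "+", "-", "+"))
  out <- extract_promoters(genome, ann, c("g_plus", "g_minus", "g_far", "ghost"),
                           upstream = 800)
  # plus strand: truncated by the neighbor ending at 700 -> spans 701..1000
  expect_equal(out$coords$start[out$coords$gene == "g_plus"], 701)
  expect_equal(out$coords$end[out$coords$gene == "g_plus"], 1000)
  expect_equal(nchar(out$seqs[["g_plus"]]), 300L)
  # minus strand: downstream slice, reverse complemented
  expect_equal(out$seqs[["g_minus"]],
               iupac_revcomp(substr(genome$chr1, 1301, 2100)))
  # no neighbor within range: full 800
  expect_equal(nchar(out$seqs[["g_far"]]), 800L)
  expect_false("ghost" %in% names(out$seqs))
})

test_that("retained motifs are invariant under reverse-complementing all input", {
  cfg <- sim_config(seed = 45, n_promoters = 400, de_fraction = 0.2,
                    promoter_length = 300, motif_prob_in_module = 0.8)
  pr <- gen_promoters(cfg, motif = "ATTACTAA")
  mod <- pr$promoters[pr$module_ids]
  bg <- pr$promoters[setdiff(names(pr$promoters), pr$module_ids)]
  fwd <- discover_words(mod, bg, k = 8)
  rev_mod <- vapply(mod, iupac_revcomp, character(1))
  rev_bg <- vapply(bg, iupac_revcomp, character(1))
  rev <- discover_words(rev_mod, rev_bg, k = 8)
  expect_identical(fwd$motif, rev$motif)  # canonical forms already collapsed
  expect_equal(fwd$p, rev$p)
})
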