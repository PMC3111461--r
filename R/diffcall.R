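# Consensus differential-expression calling.
#
# Three callers with deliberately different variance-modelling strategies --
# empirical-Bayes shrunken pooled variance (moderated t), permutation-based
# d-statistic with a variance-stabilizing offset, and a per-group
# unequal-variance (Welch-type) test -- are voted: a gene is retained when at
# least two callers agree in the requested direction. The voting scheme, not
# any single caller, is the unit of interest.

#' Expression dataset container
#'
#' @param mat numeric genes x samples matrix of log2 ratios, rownames = gene
#'   ids, colnames = sample ids. NA marks missing values.
#' @param groups factor of length `ncol(mat)` with exactly two levels; the
#'   first level is the condition of interest (treated / mutant).
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(mat, groups) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("mat must be a numeric matrix")
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (length(groups) != ncol(mat)) stop("one group label per sample required")
  if (min(table(groups)) < 2L) stop("need >= 2 samples per group")
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%04d", seq_len(nrow(mat)))
  structure(list(mat = mat, groups = groups), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$mat), "genes x", ncol(x$mat), "samples (",
      paste(levels(x$groups), table(x$groups), collapse = " vs "), ")\n")
  invisible(x)
}

# per-gene group summaries under pairwise-complete observations
.group_stats <- function(mat, idx) {
  fin <- is.finite(mat[, idx, drop = FALSE])
  n <- rowSums(fin)
  m <- rowSums(mat[, idx, drop = FALSE] * fin, na.rm = TRUE) / n
  dev <- (mat[, idx, drop = FALSE] - m)^2
  s2 <- rowSums(dev * fin, na.rm = TRUE) / pmax(n - 1L, 1L)
  s2[n < 2L] <- NA_real_
  list(n = n, mean = m, s2 = s2)
}

# solve trigamma(y) = x by Newton iteration (x > 0)
.trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-8) break
  }
  y
}

# method-of-moments fit of the scaled inverse-chi-square variance prior:
# var(log s^2) in excess of trigamma(df/2) identifies the prior df d0.
# Fallback d0 = 4 when the excess is non-positive.
.fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 3L) return(list(d0 = 4, s02 = median(s2[ok], na.rm = TRUE)))
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  evar <- var(z) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- 4
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

.calltable <- function(gene, statistic, p, fdr, call, direction, caller) {
  data.frame(gene = gene, statistic = statistic, p = p, fdr = fdr,
             call = call & !is.na(call), direction = direction,
             caller = caller, stringsAsFactors = FALSE, row.names = NULL)
}

#' Moderated t caller (empirical-Bayes shrunken pooled variance)
#'
#' Per-gene pooled variance is shrunk toward a prior:
#' `s~^2 = (d0 s0^2 + dg sg^2) / (d0 + dg)`, with the prior degrees of
#' freedom `d0` estimated by method of moments on `log s^2` (fallback 4).
#' Two-sided p-values from the t distribution on `d0 + dg` df; a gene is
#' called at p < `p_cut`.
#'
#' @param ds [expression_dataset()].
#' @param p_cut call threshold on the two-sided p-value.
#' @return call table (gene, statistic, p, fdr, call, direction, caller).
#' @export
moderated_t <- function(ds, p_cut = 0.05) {
  stopifnot(inherits(ds, "expression_dataset"))
  g1 <- .group_stats(ds$mat, ds$groups == levels(ds$groups)[1])
  g2 <- .group_stats(ds$mat, ds$groups == levels(ds$groups)[2])
  usable <- g1$n >= 2L & g2$n >= 2L
  dg <- g1$n + g2$n - 2
  s2 <- ((g1$n - 1) * g1$s2 + (g2$n - 1) * g2$s2) / dg
  prior <- .fit_variance_prior(s2[usable], dg[usable])
  s2_mod <- (prior$d0 * prior$s02 + dg * s2) / (prior$d0 + dg)
  delta <- g1$mean - g2$mean
  tstat <- delta / sqrt(s2_mod * (1 / g1$n + 1 / g2$n))
  p <- 2 * pt(-abs(tstat), df = prior$d0 + dg)
  tstat[!usable] <- NA_real_; p[!usable] <- NA_real_
  .calltable(rownames(ds$mat), tstat, p, p.adjust(p, "BH"),
             p < p_cut, sign(delta), "modt")
}

#' Permutation d-statistic caller (variance-stabilized, SAM-style contract)
#'
#' `d_g = (mean1 - mean2) / (s_g + s0)` with `s0` the median of the per-gene
#' standard errors. The null distribution of d is built by relabelling the
#' samples `n_perm` times; per-gene p-values are pooled across genes and the
#' FDR at each observed |d| is the expected number of null exceedances over
#' the observed count, made monotone in |d|. Genes are called at
#' FDR < `fdr_cut`.
#'
#' @param ds [expression_dataset()].
#' @param n_perm number of label permutations (>= 10).
#' @param seed RNG seed for the permutations.
#' @param fdr_cut call threshold on the estimated FDR.
#' @return call table.
#' @export
permutation_d <- function(ds, n_perm = 200L, seed = 1L, fdr_cut = 0.05) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (n_perm < 10L) stop("n_perm must be >= 10")
  mat <- ds$mat
  grp1 <- ds$groups == levels(ds$groups)[1]
  d_of <- function(lab1) {
    a <- .group_stats(mat, lab1); b <- .group_stats(mat, !lab1)
    dg <- a$n + b$n - 2
    s2 <- ((a$n - 1) * a$s2 + (b$n - 1) * b$s2) / dg
    se <- sqrt(s2 * (1 / a$n + 1 / b$n))
    list(delta = a$mean - b$mean, se = se)
  }
  obs <- d_of(grp1)
  s0 <- median(obs$se, na.rm = TRUE)
  d <- obs$delta / (obs$se + s0)
  perm_d <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- sample(grp1)
      pp <- d_of(lab)
      pp$delta / (pp$se + s0)
    }, numeric(nrow(mat)))
  })
  pool <- sort(abs(as.vector(perm_d)))
  n_pool <- length(pool)
  exceed <- n_pool - findInterval(abs(d) - 1e-12, pool)  # #{|d*| >= |d_g|}
  p <- (1 + exceed) / (1 + n_pool)
  n_called <- rank(-abs(d), ties.method = "max", na.last = "keep")
  fdr_raw <- pmin(1, (exceed / n_perm) / n_called)
  # enforce FDR monotone non-increasing in the |d| threshold
  ord <- order(abs(d), decreasing = TRUE, na.last = TRUE)
  fdr <- fdr_raw
  fdr[ord] <- cummax(ifelse(is.na(fdr_raw[ord]), 0, fdr_raw[ord]))
  fdr[is.na(fdr_raw)] <- NA_real_
  .calltable(rownames(mat), d, p, fdr, fdr < fdr_cut, sign(obs$delta), "permd")
}

#' Per-group variance caller (Welch-type with per-group shrinkage)
#'
#' Each group's per-gene variance is shrunk toward that group's prior
#' (method-of-moments fit, as in [moderated_t()]); the statistic is the
#' Welch t on the shrunken variances with Welch-Satterthwaite degrees of
#' freedom augmented by the prior df. Called at p < `p_cut`.
#'
#' @inheritParams moderated_t
#' @return call table.
#' @export
groupwise_variance_t <- function(ds, p_cut = 0.05) {
  stopifnot(inherits(ds, "expression_dataset"))
  g1 <- .group_stats(ds$mat, ds$groups == levels(ds$groups)[1])
  g2 <- .group_stats(ds$mat, ds$groups == levels(ds$groups)[2])
  usable <- g1$n >= 2L & g2$n >= 2L
  pr1 <- .fit_variance_prior(g1$s2[usable], (g1$n - 1)[usable])
  pr2 <- .fit_variance_prior(g2$s2[usable], (g2$n - 1)[usable])
  v1 <- (pr1$d0 * pr1$s02 + (g1$n - 1) * g1$s2) / (pr1$d0 + g1$n - 1)
  v2 <- (pr2$d0 * pr2$s02 + (g2$n - 1) * g2$s2) / (pr2$d0 + g2$n - 1)
  df1 <- pr1$d0 + g1$n - 1; df2 <- pr2$d0 + g2$n - 1
  a1 <- v1 / g1$n; a2 <- v2 / g2$n
  tstat <- (g1$mean - g2$mean) / sqrt(a1 + a2)
  df <- (a1 + a2)^2 / (a1^2 / df1 + a2^2 / df2)
  p <- 2 * pt(-abs(tstat), df = df)
  tstat[!usable] <- NA_real_; p[!usable] <- NA_real_
  .calltable(rownames(ds$mat), tstat, p, p.adjust(p, "BH"),
             p < p_cut, sign(g1$mean - g2$mean), "welch")
}

#' Vote differential-expression calls across callers
#'
#' A gene enters the consensus when it is called, in the requested direction,
#' by at least `min_agree` callers.
#'
#' @param tables list of call tables (as returned by the callers).
#' @param min_agree minimum number of agreeing callers.
#' @param direction `"up"`, `"down"` or `"both"`; `"up"` means the condition
#'   of interest (first group level) is higher.
#' @return list of class `consensus_set` with `genes`, per-gene `votes`,
#'   `min_agree` and `direction`.
#' @export
consensus_vote <- function(tables, min_agree = 2L, direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  if (length(tables) < min_agree) stop("need >= min_agree callers")
  genes <- unique(unlist(lapply(tables, `[[`, "gene")))
  votes <- setNames(integer(length(genes)), genes)
  for (tb in tables) {
    dir_ok <- switch(direction,
                     up = tb$direction > 0,
                     down = tb$direction < 0,
                     both = rep(TRUE, nrow(tb)))
    hit <- tb$gene[tb$call & dir_ok & !is.na(tb$call)]
    votes[hit] <- votes[hit] + 1L
  }
  structure(list(genes = names(votes)[votes >= min_agree],
                 votes = votes, min_agree = as.integer(min_agree),
                 direction = direction),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat("consensus_set:", length(x$genes), "genes with >=", x$min_agree,
      "votes (direction:", x$direction, ")\n")
  invisible(x)
}

#' Run all three callers and vote
#'
#' @param ds [expression_dataset()].
#' @param n_perm,seed passed to [permutation_d()].
#' @param min_agree,direction passed to [consensus_vote()].
#' @return list with `tables` (per-caller) and `consensus`.
#' @export
call_de_genes <- function(ds, n_perm = 200L, seed = 1L,
                          min_agree = 2L, direction = "up") {
  tables <- list(modt = moderated_t(ds),
                 permd = permutation_d(ds, n_perm = n_perm, seed = seed),
                 welch = groupwise_variance_t(ds))
  list(tables = tables,
       consensus = consensus_vote(tables, min_agree, direction))
}

# ---- one-sample variants (log-ratio vectors against zero) -------------------
# Used by the ChIP ratio-enrichment stage, where each probe carries replicate
# log(IP/INPUT) values tested against zero. Three distinct variance
# strategies again: EB-moderated one-sample t, sign-flip permutation d, and a
# plain per-gene one-sample t (unpooled variance).

.onesample_stats <- function(mat) {
  fin <- is.finite(mat)
  n <- rowSums(fin)
  m <- rowSums(mat * fin, na.rm = TRUE) / n
  s2 <- rowSums((mat - m)^2 * fin, na.rm = TRUE) / pmax(n - 1L, 1L)
  s2[n < 2L] <- NA_real_
  list(n = n, mean = m, s2 = s2)
}

#' One-sample consensus calls on replicate log-ratio rows
#'
#' @param mat numeric rows x replicates matrix of log ratios (tested vs 0).
#' @param n_perm sign-flip permutations for the d caller.
#' @param seed RNG seed.
#' @param min_agree,direction voting rule (see [consensus_vote()]).
#' @return list with `tables` and `consensus` as in [call_de_genes()].
#' @export
call_onesample <- function(mat, n_perm = 200L, seed = 1L,
                           min_agree = 2L, direction = "up") {
  if (ncol(mat) < 2L) stop("need >= 2 replicates to estimate variance")
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("r%05d", seq_len(nrow(mat)))
  st <- .onesample_stats(mat)
  usable <- st$n >= 2L
  dg <- st$n - 1
  # EB-moderated one-sample t
  prior <- .fit_variance_prior(st$s2[usable], dg[usable])
  s2_mod <- (prior$d0 * prior$s02 + dg * st$s2) / (prior$d0 + dg)
  t_mod <- st$mean / sqrt(s2_mod / st$n)
  p_mod <- 2 * pt(-abs(t_mod), df = prior$d0 + dg)
  tb1 <- .calltable(rownames(mat), t_mod, p_mod, p.adjust(p_mod, "BH"),
                    p_mod < 0.05, sign(st$mean), "modt")
  # sign-flip permutation d
  se <- sqrt(st$s2 / st$n)
  s0 <- median(se, na.rm = TRUE)
  d <- st$mean / (se + s0)
  perm_d <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      fl <- sample(c(-1, 1), ncol(mat), replace = TRUE)
      fm <- sweep(mat, 2L, fl, `*`)
      pp <- .onesample_stats(fm)
      pp$mean / (sqrt(pp$s2 / pp$n) + s0)
    }, numeric(nrow(mat)))
  })
  pool <- sort(abs(as.vector(perm_d)))
  exceed <- length(pool) - findInterval(abs(d) - 1e-12, pool)
  p_d <- (1 + exceed) / (1 + length(pool))
  n_called <- rank(-abs(d), ties.method = "max", na.last = "keep")
  fdr_raw <- pmin(1, (exceed / n_perm) / n_called)
  ord <- order(abs(d), decreasing = TRUE, na.last = TRUE)
  fdr <- fdr_raw
  fdr[ord] <- cummax(ifelse(is.na(fdr_raw[ord]), 0, fdr_raw[ord]))
  fdr[is.na(fdr_raw)] <- NA_real_
  tb2 <- .calltable(rownames(mat), d, p_d, fdr, fdr < 0.05, sign(st$mean), "permd")
  # plain per-gene one-sample t
  t_pl <- st$mean / se
  p_pl <- 2 * pt(-abs(t_pl), df = dg)
  tb3 <- .calltable(rownames(mat), t_pl, p_pl, p.adjust(p_pl, "BH"),
                    p_pl < 0.05, sign(st$mean), "plaint")
  tb1$call[!usable] <- FALSE
  tb2$call[!usable] <- FALSE
  tb3$call[!usable] <- FALSE
  tables <- list(modt = tb1, permd = tb2, plaint = tb3)
  list(tables = tables,
       consensus = consensus_vote(tables, min_agree, direction))
}
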