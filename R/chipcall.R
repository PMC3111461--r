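# TF-bound promoter identification from IP/INPUT probe intensities.
#
# Binding evidence requires two independent methodologies to agree:
# (i) a two-component mixture of linear
# regressions of IP on INPUT, fitted by EM, whose bound-component posterior
# classifies probes at risk alpha; (ii) consensus differential enrichment of
# replicate log(IP/INPUT) ratios against zero. A gene is declared bound only
# when both routes hit at least one of its promoter probes.

#' Fit a two-component mixture of linear regressions by EM
#'
#' Models the IP signal conditional on the INPUT signal as a mixture of two
#' homoscedastic regression lines: an unbound baseline (intercept `a0`, slope
#' `b0`) and a bound component (`a1`, `b1 >= b0` by label convention) with
#' shared residual sd `sigma` and bound weight `pi`. EM is restarted
#' `n_restarts` times from random assignment splits; the best final
#' log-likelihood wins. The fit is flagged degenerate when a component
#' weight vanishes (pi < 1e-3), the slopes collapse (|b1 - b0| < 1e-3), or
#' the mixture fails a likelihood-ratio comparison against a single
#' regression line (2 * delta-log-likelihood < 20): single-line data must
#' never look like binding evidence.
#'
#' @param probes data.frame with numeric columns `input` and `ip` (log2). If
#'   a `probe` column is present with repeated ids (replicates), rows are
#'   averaged per probe first.
#' @param max_iter,tol EM stopping rule (absolute log-likelihood change).
#' @param n_restarts random restarts.
#' @param seed RNG seed.
#' @return object of class `mixture_fit`: parameters, per-probe `posterior`
#'   (P(bound)), `loglik_trace` of the winning run, `converged`, `degenerate`,
#'   `probe` ids.
#' @export
fit_mixture <- function(probes, max_iter = 500L, tol = 1e-6,
                        n_restarts = 10L, seed = 1L) {
  stopifnot(is.data.frame(probes), all(c("input", "ip") %in% names(probes)))
  if ("probe" %in% names(probes) && anyDuplicated(probes$probe)) {
    agg <- stats::aggregate(probes[, c("input", "ip")],
                            by = list(probe = probes$probe), FUN = mean)
    ids <- agg$probe; x <- agg$input; y <- agg$ip
  } else {
    ids <- if ("probe" %in% names(probes)) probes$probe
           else sprintf("p%05d", seq_len(nrow(probes)))
    x <- probes$input; y <- probes$ip
  }
  if (length(x) < 50L) stop("need >= 50 probes to fit the mixture")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("intensities must be finite")
  n <- length(x)
  wls <- function(w) {
    sw <- sum(w); mx <- sum(w * x) / sw; my <- sum(w * y) / sw
    b <- sum(w * (x - mx) * (y - my)) / sum(w * (x - mx)^2)
    c(a = my - b * mx, b = b)
  }
  loglik <- function(th) {
    l0 <- dnorm(y, th$a0 + th$b0 * x, th$sigma, log = TRUE) + log(1 - th$pi)
    l1 <- dnorm(y, th$a1 + th$b1 * x, th$sigma, log = TRUE) + log(th$pi)
    m <- pmax(l0, l1)
    sum(m + log(exp(l0 - m) + exp(l1 - m)))
  }
  run_em <- function() {
    z <- sample(c(TRUE, FALSE), n, replace = TRUE)
    c0 <- wls(as.numeric(!z)); c1 <- wls(as.numeric(z))
    th <- list(a0 = c0[1], b0 = c0[2], a1 = c1[1], b1 = c1[2],
               sigma = sd(y - ifelse(z, c1[1] + c1[2] * x, c0[1] + c0[2] * x)),
               pi = mean(z))
    th$pi <- min(max(th$pi, 1e-6), 1 - 1e-6)
    trace <- numeric(0); post <- rep(0.5, n); conv <- FALSE
    for (it in seq_len(max_iter)) {
      l0 <- dnorm(y, th$a0 + th$b0 * x, th$sigma, log = TRUE) + log(1 - th$pi)
      l1 <- dnorm(y, th$a1 + th$b1 * x, th$sigma, log = TRUE) + log(th$pi)
      m <- pmax(l0, l1)
      ll <- sum(m + log(exp(l0 - m) + exp(l1 - m)))
      trace <- c(trace, ll)
      post <- 1 / (1 + exp(l0 - l1))
      if (it > 1L && abs(trace[it] - trace[it - 1L]) < tol) { conv <- TRUE; break }
      th$pi <- min(max(mean(post), 1e-6), 1 - 1e-6)
      c0 <- wls(1 - post); c1 <- wls(post)
      th$a0 <- c0[1]; th$b0 <- c0[2]; th$a1 <- c1[1]; th$b1 <- c1[2]
      res0 <- y - (th$a0 + th$b0 * x); res1 <- y - (th$a1 + th$b1 * x)
      th$sigma <- sqrt(sum((1 - post) * res0^2 + post * res1^2) / n)
      th$sigma <- max(th$sigma, 1e-8)
    }
    list(theta = th, trace = trace, post = post, converged = conv,
         final = trace[length(trace)])
  }
  best <- .with_seed(seed, {
    runs <- lapply(seq_len(n_restarts), function(i) run_em())
    runs[[which.max(vapply(runs, `[[`, numeric(1), "final"))]]
  })
  th <- best$theta; post <- best$post
  if (th$b1 < th$b0) {  # relabel so the bound component is the steeper line
    th <- list(a0 = th$a1, b0 = th$b1, a1 = th$a0, b1 = th$b0,
               sigma = th$sigma, pi = 1 - th$pi)
    post <- 1 - post
  }
  post <- pmin(pmax(post, 1e-12), 1 - 1e-12)  # keep posteriors strictly inside (0,1)
  # degenerate when a component vanishes, the slopes collapse, or the mixture
  # does not beat a single regression line by a clear likelihood margin
  ols <- stats::lm.fit(cbind(1, x), y)
  s_ols <- sqrt(mean(ols$residuals^2))
  ll_single <- sum(dnorm(ols$residuals, 0, s_ols, log = TRUE))
  lrt <- 2 * (best$final - ll_single)
  degenerate <- th$pi < 1e-3 || th$pi > 1 - 1e-3 ||
    abs(th$b1 - th$b0) < 1e-3 || lrt < 20
  structure(list(a0 = unname(th$a0), b0 = unname(th$b0),
                 a1 = unname(th$a1), b1 = unname(th$b1),
                 sigma = th$sigma, pi = th$pi,
                 posterior = setNames(post, ids), probe = ids,
                 loglik_trace = best$trace, converged = best$converged,
                 degenerate = degenerate, n_restarts_used = n_restarts),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: unbound ip = %.3f + %.3f input; bound ip = %.3f + %.3f input\n",
              x$a0, x$b0, x$a1, x$b1))
  cat(sprintf("  sigma = %.3f, pi(bound) = %.3f, converged = %s%s\n",
              x$sigma, x$pi, x$converged,
              if (x$degenerate) " [DEGENERATE]" else ""))
  invisible(x)
}

#' Classify probes as bound at risk alpha
#'
#' A probe is declared bound when its posterior probability of being unbound
#' is at most `alpha`.
#'
#' @param fit [fit_mixture()] result.
#' @param alpha risk level (default 0.05).
#' @return character vector of bound probe ids (empty, with a warning, for a
#'   degenerate fit).
#' @export
classify_probes <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (fit$degenerate) {
    warning("degenerate mixture fit: returning no bound probes")
    return(character(0))
  }
  fit$probe[(1 - fit$posterior) <= alpha]
}

#' Consensus enrichment of replicate log(IP/INPUT) ratios
#'
#' Builds the per-probe replicate matrix of `ip - input` log ratios and runs
#' the one-sample consensus callers against zero, direction up.
#'
#' @param probes data.frame with columns `probe`, `replicate`, `input`, `ip`.
#' @param n_perm,seed passed to the permutation caller.
#' @param min_agree voting rule.
#' @return character vector of enriched probe ids.
#' @export
ratio_enrichment <- function(probes, n_perm = 200L, seed = 1L, min_agree = 2L) {
  stopifnot(is.data.frame(probes),
            all(c("probe", "replicate", "input", "ip") %in% names(probes)))
  reps <- sort(unique(probes$replicate))
  if (length(reps) < 2L) stop("need >= 2 replicate arrays to estimate variance")
  ids <- sort(unique(probes$probe))
  mat <- matrix(NA_real_, length(ids), length(reps),
                dimnames = list(ids, paste0("rep", reps)))
  mat[cbind(match(probes$probe, ids), match(probes$replicate, reps))] <-
    probes$ip - probes$input
  res <- call_onesample(mat, n_perm = n_perm, seed = seed,
                        min_agree = min_agree, direction = "up")
  res$consensus$genes
}

#' Gene-level intersection of the two binding methodologies
#'
#' A gene is declared bound when at least one of its promoter probes is in
#' the mixture-classified set AND at least one is in the ratio-enriched set
#' (the conservative gene-level AND that minimizes false positives).
#'
#' @param mix_set probe ids from [classify_probes()].
#' @param ratio_set probe ids from [ratio_enrichment()].
#' @param probe_gene_map data.frame with columns `probe`, `gene`.
#' @return character vector of bound gene ids (sorted).
#' @export
binding_consensus <- function(mix_set, ratio_set, probe_gene_map) {
  stopifnot(is.data.frame(probe_gene_map),
            all(c("probe", "gene") %in% names(probe_gene_map)))
  map <- unique(probe_gene_map[, c("probe", "gene")])
  unmapped <- setdiff(union(mix_set, ratio_set), map$probe)
  if (length(unmapped))
    message(length(unmapped), " probes without gene assignment ignored")
  g_mix <- unique(map$gene[map$probe %in% mix_set])
  g_ratio <- unique(map$gene[map$probe %in% ratio_set])
  sort(intersect(g_mix, g_ratio))
}
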