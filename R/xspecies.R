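# Cross-species module comparison: thresholded homology links from all-vs-all
# local protein alignment, reciprocal-best-hit one-to-one orthologs, module
# overlap statistics against shuffled-module nulls, and the error rates of
# transferring a module across species by homology alone.

.check_protein <- function(seqs, label) {
  ok_alpha <- "ACDEFGHIKLMNPQRSTVWYX*"
  for (i in seq_along(seqs)) {
    bad <- regmatches(seqs[[i]],
                      gregexpr(sprintf("[^%s]", ok_alpha), seqs[[i]]))[[1]]
    if (length(bad))
      stop("non-amino-acid symbol '", bad[1], "' in ", label, " sequence ",
           names(seqs)[i] %||% i, " at position ",
           regexpr(sprintf("[^%s]", ok_alpha), seqs[[i]]))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

# Karlin-Altschul extreme-value statistics for gapped BLOSUM62 (standard
# gapped parameters, gap open 11 / extend 1): E = K m n exp(-lambda S)
.ka_lambda <- 0.267
.ka_K <- 0.041

#' All-vs-all homology links between two proteomes
#'
#' Local alignment (BLOSUM62, affine gaps 11/1) of every cross-proteome pair;
#' E-values from extreme-value statistics scaled by the search-space size
#' (query length x total subject length). A link is stored only when all
#' three rules hold: E-value < `e_max`, alignment length > `min_len` amino
#' acids, percent identity > `min_ident`.
#'
#' @param proteome_a,proteome_b named character vectors of protein sequences.
#' @param e_max,min_len,min_ident the three link thresholds.
#' @return data.frame with columns `a`, `b`, `score`, `evalue`, `length`
#'   (aligned columns), `pident`.
#' @export
homology_links <- function(proteome_a, proteome_b,
                           e_max = 1e-2, min_len = 100L, min_ident = 25) {
  if (length(proteome_a) == 0L || length(proteome_b) == 0L)
    stop("non-empty proteomes required")
  .check_protein(proteome_a, "proteome A")
  .check_protein(proteome_b, "proteome B")
  subj <- Biostrings::AAStringSet(proteome_b)
  tot_n <- sum(nchar(proteome_b))
  rows <- vector("list", length(proteome_a))
  for (i in seq_along(proteome_a)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = subj, subject = Biostrings::AAString(proteome_a[[i]]),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    score <- Biostrings::score(aln)
    # aligned width incl. gaps
    len <- nchar(as.character(Biostrings::pattern(aln)))
    pid <- Biostrings::pid(aln, type = "PID1")
    ev <- .ka_K * nchar(proteome_a[[i]]) * tot_n * exp(-.ka_lambda * score)
    keep <- ev < e_max & len > min_len & pid > min_ident
    if (any(keep)) {
      rows[[i]] <- data.frame(a = names(proteome_a)[i],
                              b = names(proteome_b)[keep],
                              score = score[keep], evalue = ev[keep],
                              length = len[keep], pident = pid[keep],
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(a = character(), b = character(), score = numeric(),
                      evalue = numeric(), length = integer(),
                      pident = numeric())
  rownames(out) <- NULL
  out
}

#' Read external tabular alignment output as homology links
#'
#' Adapter for the standard 12-column tabular alignment format
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore); the same three link thresholds are applied.
#'
#' @param path tab-separated file in the 12-column layout, no header.
#' @inheritParams homology_links
#' @return data.frame as in [homology_links()] (score = bitscore).
#' @export
read_alignment_links <- function(path, e_max = 1e-2, min_len = 100L,
                                 min_ident = 25) {
  cols <- c("a", "b", "pident", "length", "mismatch", "gapopen", "qstart",
            "qend", "sstart", "send", "evalue", "score")
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(tb) != 12L) stop("expected 12 tab-separated columns in ", path)
  names(tb) <- cols
  keep <- tb$evalue < e_max & tb$length > min_len & tb$pident > min_ident
  tb[keep, c("a", "b", "score", "evalue", "length", "pident"), drop = FALSE]
}

#' Reciprocal-best-hit one-to-one orthologs
#'
#' A pair (a, b) is kept iff b is a's best-scoring link and a is b's.
#' Score ties are broken lexicographically (and reported via a message).
#'
#' @param links data.frame from [homology_links()] (columns a, b, score).
#' @return data.frame of one-to-one pairs `a`, `b` (each id at most once).
#' @export
rbh_orthologs <- function(links) {
  if (nrow(links) == 0L)
    return(data.frame(a = character(), b = character()))
  best_of <- function(key, other) {
    sp <- split(links, links[[key]])
    ties <- 0L
    res <- vapply(sp, function(d) {
      top <- d[d$score == max(d$score), , drop = FALSE]
      if (nrow(top) > 1L) ties <<- ties + 1L
      sort(top[[other]])[1]
    }, character(1))
    if (ties > 0L) message(ties, " best-hit score ties broken lexicographically")
    res
  }
  best_b <- best_of("a", "b")   # a -> its best b
  best_a <- best_of("b", "a")   # b -> its best a
  keep <- names(best_b)[best_a[best_b] == names(best_b)]
  out <- data.frame(a = keep, b = unname(best_b[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$a), , drop = FALSE]
}

#' Module overlap through an ortholog map, with significance
#'
#' The overlap count is the number of ortholog pairs with one end in module A
#' and the other in module B. Two p-values are reported against the null in
#' which both modules are completely shuffled through evolution: an empirical
#' permutation p (random same-size gene sets drawn independently from each
#' universe) and an analytic hypergeometric on the ortholog-pair space.
#'
#' @param module_a,module_b gene id vectors.
#' @param orthologs data.frame of one-to-one pairs `a`, `b`.
#' @param universe_a,universe_b gene universes of the two species.
#' @param n_perm permutations (default 1e4).
#' @param seed RNG seed.
#' @param denominator how the overlap percentage is computed; `"min"`
#'   divides by the smaller module size.
#' @return list with `count`, `percent`, `p_perm`, `p_hyper`, `n_perm`,
#'   and the null descriptor.
#' @export
module_overlap <- function(module_a, module_b, orthologs,
                           universe_a, universe_b,
                           n_perm = 1e4L, seed = 1L,
                           denominator = c("min", "union")) {
  denominator <- match.arg(denominator)
  stopifnot(all(module_a %in% universe_a), all(module_b %in% universe_b))
  pairs <- orthologs[orthologs$a %in% universe_a &
                     orthologs$b %in% universe_b, , drop = FALSE]
  count_overlap <- function(ma, mb)
    sum(pairs$a %in% ma & pairs$b %in% mb)
  count <- count_overlap(module_a, module_b)
  denom <- switch(denominator,
                  min = min(length(module_a), length(module_b)),
                  union = length(module_a) + length(module_b) - count)
  percent <- if (denom > 0L) 100 * count / denom else NA_real_
  if (nrow(pairs) == 0L)
    return(list(count = 0L, percent = percent, p_perm = 1, p_hyper = 1,
                n_perm = 0L, null = "no ortholog pairs"))
  perm_counts <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      count_overlap(sample(universe_a, length(module_a)),
                    sample(universe_b, length(module_b)))
    }, numeric(1))
  })
  p_perm <- (1 + sum(perm_counts >= count)) / (1 + n_perm)
  # hypergeometric on the pair space: N pairs, K touched by module A, n by B
  N <- nrow(pairs)
  K <- sum(pairs$a %in% module_a)
  n <- sum(pairs$b %in% module_b)
  p_hyper <- hypergeom_enrichment(count, n, K, N)
  list(count = count, percent = percent, p_perm = p_perm, p_hyper = p_hyper,
       n_perm = as.integer(n_perm),
       null = "independent same-size shuffles of both modules")
}

#' Error rates of transferring a module across species by homology
#'
#' The predicted module in the target genome is every gene homologous to at
#' least one source-module gene. Against the experimentally defined reference
#' module: FP = |predicted \ reference| / |predicted| and
#' FN = |reference \ predicted| / |reference|. The alternative FP convention
#' with the reference size as denominator is reported as `fp_rate_refdenom`.
#'
#' @param source_module source-species gene ids.
#' @param links homology links data.frame (`a` = source ids, `b` = target ids).
#' @param reference target-species module defined from experiment.
#' @param target_universe all target-species genes.
#' @return list with `predicted`, `fp_rate`, `fn_rate`, `fp_rate_refdenom`
#'   (percentages; `fp_rate` NA when nothing is predicted).
#' @export
transfer_error_rates <- function(source_module, links, reference,
                                 target_universe) {
  stopifnot(all(reference %in% target_universe))
  predicted <- sort(unique(links$b[links$a %in% source_module]))
  predicted <- intersect(predicted, target_universe)
  fp <- if (length(predicted) > 0L)
    100 * length(setdiff(predicted, reference)) / length(predicted)
    else NA_real_
  fn <- if (length(reference) > 0L)
    100 * length(setdiff(reference, predicted)) / length(reference)
    else NA_real_
  fp_alt <- if (length(reference) > 0L)
    100 * length(setdiff(predicted, reference)) / length(reference)
    else NA_real_
  list(predicted = predicted, fp_rate = fp, fn_rate = fn,
       fp_rate_refdenom = fp_alt)
}
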