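# Evidence integration: a gene joins the condition-specific transcriptional
# module iff it is up-regulated under the condition (step 1) AND either
# TF-dependent (step 2) or TF-bound in promoter (step 3).

#' Build a condition-specific transcriptional module
#'
#' Members are `step1 intersect (step2 union step3)`. Evidence flags are kept
#' for every universe gene (members and non-members) for audit.
#'
#' @param step1 gene ids up-regulated under the condition.
#' @param step2 gene ids whose induction depends on the TF.
#' @param step3 gene ids bound by the TF in promoter.
#' @param universe all assayed gene ids (the expression-matrix universe);
#'   genes in the evidence sets but absent from the universe are dropped with
#'   a message.
#' @param species,tf metadata tags.
#' @return object of class `transcriptional_module` with `members`, `flags`
#'   (data.frame gene / step1_up / step2_dependent / step3_bound / member)
#'   and provenance metadata.
#' @export
build_btm <- function(step1, step2, step3, universe,
                      species = "synthetic", tf = "TF") {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  outside <- length(setdiff(unique(c(step1, step2, step3)), universe))
  if (outside > 0L)
    message(outside, " evidence genes outside the expression universe dropped")
  f1 <- universe %in% step1
  f2 <- universe %in% step2
  f3 <- universe %in% step3
  member <- f1 & (f2 | f3)
  flags <- data.frame(gene = universe, step1_up = f1, step2_dependent = f2,
                      step3_bound = f3, member = member,
                      stringsAsFactors = FALSE)
  structure(list(species = species, tf = tf,
                 members = sort(universe[member]), flags = flags,
                 n_dropped_outside_universe = outside),
            class = "transcriptional_module")
}

#' @export
print.transcriptional_module <- function(x, ...) {
  cat("transcriptional_module:", x$tf, "in", x$species, "-",
      length(x$members), "member genes of", nrow(x$flags), "universe genes\n")
  invisible(x)
}

#' Summarize a transcriptional module
#'
#' @param m [build_btm()] result.
#' @return list with `counts` (genes per evidence combination, all 8
#'   combinations, summing to the universe size), and `members` (member list
#'   with flags, lexicographic order).
#' @export
module_report <- function(m) {
  stopifnot(inherits(m, "transcriptional_module"))
  f <- m$flags
  combo <- interaction(f$step1_up, f$step2_dependent, f$step3_bound, sep = "/")
  lv <- apply(expand.grid(c(FALSE, TRUE), c(FALSE, TRUE), c(FALSE, TRUE)), 1L,
              paste, collapse = "/")
  counts <- table(factor(as.character(combo), levels = lv))
  names(dimnames(counts)) <- "step1_up/step2_dependent/step3_bound"
  members <- f[f$member, , drop = FALSE]
  members <- members[order(members$gene), , drop = FALSE]
  rownames(members) <- NULL
  list(counts = counts, members = members)
}
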