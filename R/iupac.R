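#' @importFrom stats median pt var rnorm runif rbinom sd quantile setNames
#' @importFrom stats p.adjust dist pnorm phyper dnorm
#' @importFrom utils head combn
#' @import methods
#' @import data.table
NULL

# single source of truth for the degenerate-nucleotide alphabet; the map is
# Biostrings' own so pattern matching and our set algebra cannot disagree
.iupac_map <- function() {
  m <- Biostrings::IUPAC_CODE_MAP
  strsplit(m, "", fixed = TRUE)
}

#' Expand an IUPAC code into the bases it allows
#'
#' @param code single IUPAC letter (e.g. `"M"`).
#' @return character vector of A/C/G/T bases.
#' @export
iupac_expand <- function(code) {
  map <- .iupac_map()
  code <- toupper(code)
  if (!code %in% names(map)) stop("not an IUPAC code: ", code)
  map[[code]]
}

#' Collapse a set of bases into the minimal IUPAC code
#'
#' @param bases character vector drawn from A/C/G/T.
#' @return single IUPAC letter covering exactly `bases`.
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (!all(bases %in% c("A", "C", "G", "T"))) stop("bases must be A/C/G/T")
  key <- paste(bases, collapse = "")
  hit <- names(Biostrings::IUPAC_CODE_MAP)[
    vapply(.iupac_map(), function(b) identical(sort(b), bases), logical(1))]
  if (length(hit) != 1L) stop("no IUPAC code for base set ", key)
  hit
}

#' Column-wise IUPAC union of equal-length motifs
#'
#' Each output column allows every base allowed by any input motif at that
#' column. `iupac_union(c("TTACTAA","TGACAAA", ...))` is the consensus-building
#' primitive used when degenerate motifs are merged.
#'
#' @param motifs character vector of equal-length IUPAC strings.
#' @return single IUPAC string.
#' @export
iupac_union <- function(motifs) {
  motifs <- toupper(motifs)
  w <- unique(nchar(motifs))
  if (length(w) != 1L) stop("motifs must have equal length")
  cols <- vapply(seq_len(w), function(j) {
    bases <- unlist(lapply(substr(motifs, j, j), iupac_expand))
    iupac_code(bases)
  }, character(1))
  paste(cols, collapse = "")
}

#' Do two IUPAC columns share at least one base?
#' @param a,b single IUPAC letters.
#' @return logical.
#' @export
iupac_intersects <- function(a, b) {
  length(intersect(iupac_expand(a), iupac_expand(b))) > 0L
}

#' Reverse complement of an IUPAC motif
#' @param motif IUPAC string.
#' @return IUPAC string.
#' @export
iupac_revcomp <- function(motif) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
}

#' Number of uncharacterized (non-A/C/G/T) columns in a motif
#' @param motif IUPAC string.
#' @return integer count of ambiguity-code columns.
#' @export
iupac_n_ambiguous <- function(motif) {
  sum(!strsplit(toupper(motif), "", fixed = TRUE)[[1]] %in% c("A", "C", "G", "T"))
}

#' Resolve an IUPAC motif into a concrete A/C/G/T word
#'
#' Each ambiguous column is resolved uniformly over its allowed bases.
#'
#' @param motif IUPAC string.
#' @return concrete DNA word of the same length.
#' @export
iupac_resolve <- function(motif) {
  cols <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  paste(vapply(cols, function(cc) {
    b <- iupac_expand(cc)
    if (length(b) == 1L) b else sample(b, 1L)
  }, character(1)), collapse = "")
}

.as_dnastringset <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) return(seqs)
  Biostrings::DNAStringSet(unlist(seqs))
}

#' Find matches of an IUPAC motif in a set of sequences (both strands)
#'
#' A palindromic motif (equal to its own reverse complement) yields one record
#' per site, never two.
#'
#' @param seqs named character vector or `DNAStringSet` of A/C/G/T sequences.
#' @param motif IUPAC string.
#' @return data.frame with columns `seq_id`, `offset` (1-based start on the
#'   forward strand) and `strand` (`"+"`/`"-"`).
#' @export
iupac_sites <- function(seqs, motif) {
  ss <- .as_dnastringset(seqs)
  ids <- names(ss)
  if (is.null(ids)) ids <- as.character(seq_along(ss))
  fwd <- Biostrings::vmatchPattern(motif, ss, fixed = "subject")
  rcm <- iupac_revcomp(motif)
  rev <- Biostrings::vmatchPattern(rcm, ss, fixed = "subject")
  pick <- function(mi, strand) {
    st <- Biostrings::startIndex(mi)
    n <- lengths(st); n[vapply(st, is.null, logical(1))] <- 0L
    data.frame(seq_id = rep(ids, n), offset = unlist(st),
               strand = rep(strand, sum(n)), stringsAsFactors = FALSE)
  }
  out <- rbind(pick(fwd, "+"), pick(rev, "-"))
  # collapse double hits of palindromes (same site found on both strands)
  out <- out[!duplicated(out[, c("seq_id", "offset")]), , drop = FALSE]
  out[order(out$seq_id, out$offset), , drop = FALSE]
}

#' Which sequences contain at least one match to an IUPAC motif?
#'
#' @inheritParams iupac_sites
#' @return named logical vector, one element per sequence.
#' @export
iupac_present <- function(seqs, motif) {
  ss <- .as_dnastringset(seqs)
  n <- Biostrings::vcountPattern(motif, ss, fixed = "subject")
  rcm <- iupac_revcomp(motif)
  if (rcm != toupper(motif)) {
    n <- n + Biostrings::vcountPattern(rcm, ss, fixed = "subject")
  }
  stats::setNames(n > 0L, names(ss))
}

#' Fraction of promoters carrying at least one motif match
#'
#' @param promoters promoter set (named character vector or `DNAStringSet`).
#' @param motif IUPAC string.
#' @return fraction in \[0, 1\].
#' @export
motif_coverage <- function(promoters, motif) {
  pres <- iupac_present(promoters, motif)
  if (length(pres) == 0L) return(0)
  mean(pres)
}
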