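# De-novo cis-regulatory motif discovery in promoter sets.
#
# Three complementary algorithms -- an exact word census, a greedy IUPAC
# generalizer seeded by the words, and a zero-or-one-site-per-sequence PWM EM
# -- each score candidates by hypergeometric enrichment of per-promoter
# presence (module vs promoter universe, both strands, reverse complements
# collapsed). Candidates then pass the filter cascade (length >= 7, at most 3
# uncharacterized positions, p < 1e-5, found by >= 2 algorithms) and are
# merged into IUPAC consensuses.

#' Upper-tail hypergeometric enrichment p-value
#'
#' P(X >= k) where X ~ Hypergeometric(N, K, n): k of the n module promoters
#' carry the motif while K of all N promoters do. Computed as a log-space sum
#' of `lchoose` terms. Vectorized over `k` and `K`.
#'
#' @param k module promoters with the motif.
#' @param n module promoters.
#' @param K universe promoters with the motif.
#' @param N universe promoters.
#' @return p-value(s) in \[0, 1\].
#' @export
hypergeom_enrichment <- function(k, n, K, N) {
  len <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(k, len); n <- rep_len(n, len)
  K <- rep_len(K, len); N <- rep_len(N, len)
  if (any(k < 0 | n < 0 | K < 0 | N < 0) || any(k > n) || any(k > K) ||
      any(n > N) || any(K > N))
    stop("inconsistent counts: need 0 <= k <= min(n, K) and n, K <= N")
  vapply(seq_len(len), function(i) {
    if (k[i] == 0) return(1)
    x <- k[i]:min(K[i], n[i])
    lo <- lchoose(K[i], x) + lchoose(N[i] - K[i], n[i] - x) - lchoose(N[i], n[i])
    m <- max(lo)
    min(1, exp(m + log(sum(exp(lo - m)))))
  }, numeric(1))
}

# one row per (promoter, canonical k-mer present in it); reverse complements
# collapsed so palindromes are counted once per site
.kmer_presence <- function(seqs, k) {
  per_seq <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    starts <- seq_len(L - k + 1L)
    unique(substring(s, starts, starts + k - 1L))
  })
  dt <- data.table::data.table(seq_id = rep(names(seqs), lengths(per_seq)),
                               kmer = unlist(per_seq, use.names = FALSE))
  uk <- unique(dt$kmer)
  ok <- !grepl("[^ACGT]", uk)
  rc <- rep(NA_character_, length(uk))
  rc[ok] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(uk[ok])))
  canon_map <- ifelse(ok & uk > rc, rc, uk)
  canon_map[!ok] <- NA_character_
  kmer <- NULL; canon <- NULL; seq_id <- NULL  # data.table NSE guards
  dt[, canon := canon_map[match(kmer, uk)]]
  unique(dt[!is.na(canon), list(seq_id, canon)])
}

.candidate_df <- function(motif, algorithm, p, k_module, n_module,
                          K_universe, N_universe, algorithms = algorithm) {
  data.frame(motif = motif, algorithm = algorithm, algorithms = algorithms,
             p = p, k_module = k_module, n_module = n_module,
             K_universe = K_universe, N_universe = N_universe,
             stringsAsFactors = FALSE, row.names = NULL)
}

# presence-based enrichment of an IUPAC motif: module vs module+background
.motif_enrichment <- function(motif, module_proms, background_proms) {
  pres_m <- iupac_present(module_proms, motif)
  pres_b <- iupac_present(background_proms, motif)
  k <- sum(pres_m); n <- length(pres_m)
  K <- k + sum(pres_b); N <- n + length(pres_b)
  list(p = hypergeom_enrichment(k, n, K, N), k = k, n = n, K = K, N = N)
}

#' Exact word census with hypergeometric scoring
#'
#' Every k-mer present in the promoter universe is scored by per-promoter
#' presence enrichment in the module; a motif and its reverse complement are
#' collapsed to one canonical word, so palindromes are never double-counted.
#'
#' @param module_proms named character vector of module promoters.
#' @param background_proms named character vector of background (non-module)
#'   promoters; the universe for enrichment is module + background.
#' @param k word length, between 4 and 12.
#' @param max_candidates cap on the number of returned candidates.
#' @param presence optional precomputed presence table (internal reuse).
#' @return candidate data.frame (motif, algorithm, p, counts), sorted by p.
#' @export
discover_words <- function(module_proms, background_proms, k = 8L,
                           max_candidates = 100L, presence = NULL) {
  if (k < 4L || k > 12L) stop("word length k must be in [4, 12]")
  ids_m <- names(module_proms); ids_b <- names(background_proms)
  if (is.null(ids_m) || is.null(ids_b) || anyDuplicated(c(ids_m, ids_b)))
    stop("promoters must carry unique names")
  dt <- if (is.null(presence))
    .kmer_presence(c(module_proms, background_proms), k)
    else presence
  n_mod <- length(module_proms); N <- n_mod + length(background_proms)
  k_module <- NULL; K_universe <- NULL; canon <- NULL; seq_id <- NULL
  counts <- dt[, list(k_module = sum(seq_id %chin% ids_m), K_universe = .N),
               by = canon]
  # only over-represented words can be enriched; others are scored p = 1
  cand <- counts[k_module >= 2L & k_module / n_mod > K_universe / N]
  if (nrow(cand) == 0L)
    return(.candidate_df(character(), character(), numeric(), integer(),
                         integer(), integer(), integer()))
  p <- hypergeom_enrichment(cand$k_module, n_mod, cand$K_universe, N)
  out <- .candidate_df(cand$canon, "words", p, cand$k_module, n_mod,
                       cand$K_universe, N)
  out <- out[order(out$p, out$motif), , drop = FALSE]
  head(out, max_candidates)
}

#' Greedy IUPAC generalization of seed words
#'
#' Each seed's concrete columns are generalized, one column at a time, to the
#' two-base IUPAC code that most improves the enrichment p-value; the greedy
#' search stops when no generalization improves p or when a further step
#' would exceed `max_ambig` ambiguous columns. The returned p is never worse
#' than the seed's.
#'
#' @inheritParams discover_words
#' @param seeds character vector of seed motifs (typically top words).
#' @param max_ambig maximum number of ambiguous columns introduced.
#' @param presence optional named list (by word length) of precomputed
#'   presence tables (internal reuse).
#' @return candidate data.frame, one row per distinct generalized motif.
#' @export
discover_degenerate <- function(module_proms, background_proms, seeds,
                                max_ambig = 3L, presence = NULL) {
  if (length(seeds) == 0L) stop("at least one seed motif required")
  bases <- c("A", "C", "G", "T")
  seeds <- unique(toupper(seeds))
  ids_m <- names(module_proms)
  n_mod <- length(module_proms)
  N <- n_mod + length(background_proms)
  # per seed length, an index canonical k-mer -> promoters containing it;
  # a degenerate motif's presence set is the union over its expansions,
  # which turns each candidate evaluation into hash lookups
  all_proms <- c(module_proms, background_proms)
  indexes <- new.env(parent = emptyenv())
  get_index <- function(len) {
    key <- as.character(len)
    if (is.null(indexes[[key]])) {
      dt <- if (!is.null(presence) && !is.null(presence[[key]]))
        presence[[key]]  # keyed in place; tables are internal to the stage
        else .kmer_presence(all_proms, len)
      data.table::setkey(dt, canon)
      indexes[[key]] <- dt
    }
    indexes[[key]]
  }
  rc1 <- function(w) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", w), "", fixed = TRUE)[[1]]),
          collapse = "")
  }
  expand_words <- function(motif) {
    sets <- lapply(strsplit(motif, "", fixed = TRUE)[[1]], iupac_expand)
    if (prod(lengths(sets)) > 512L) return(NULL)  # too degenerate to index
    words <- apply(do.call(expand.grid,
                           c(sets, stringsAsFactors = FALSE)), 1L,
                   paste, collapse = "")
    unique(vapply(words, function(w) min(w, rc1(w)), character(1)))
  }
  enrich <- function(motif) {
    words <- expand_words(motif)
    if (is.null(words))
      return(.motif_enrichment(motif, module_proms, background_proms))
    dtk <- get_index(nchar(motif))
    proms <- unique(dtk[list(words), on = "canon", nomatch = NULL]$seq_id)
    k <- sum(proms %in% ids_m); K <- length(proms)
    list(p = hypergeom_enrichment(k, n_mod, K, N), k = k, n = n_mod,
         K = K, N = N)
  }
  refine <- function(motif) {
    cur <- enrich(motif)
    repeat {
      if (iupac_n_ambiguous(motif) >= max_ambig) break
      cols <- strsplit(motif, "", fixed = TRUE)[[1]]
      best <- NULL
      for (j in which(cols %in% bases)) {
        for (b2 in setdiff(bases, cols[j])) {
          cand_cols <- cols
          cand_cols[j] <- iupac_code(c(cols[j], b2))
          cand <- paste(cand_cols, collapse = "")
          e <- enrich(cand)
          if (is.null(best) || e$p < best$e$p) best <- list(motif = cand, e = e)
        }
      }
      if (is.null(best) || best$e$p >= cur$p) break
      motif <- best$motif; cur <- best$e
    }
    list(motif = motif, e = cur)
  }
  res <- lapply(seeds, refine)
  out <- .candidate_df(vapply(res, `[[`, character(1), "motif"), "degen",
                       vapply(res, function(r) r$e$p, numeric(1)),
                       vapply(res, function(r) r$e$k, numeric(1)),
                       vapply(res, function(r) r$e$n, numeric(1)),
                       vapply(res, function(r) r$e$K, numeric(1)),
                       vapply(res, function(r) r$e$N, numeric(1)))
  out <- out[!duplicated(out$motif), , drop = FALSE]
  out[order(out$p, out$motif), , drop = FALSE]
}

.seq_to_int <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

#' PWM motif discovery by zero-or-one-site-per-sequence EM
#'
#' Fits a position weight matrix to the module promoters assuming each
#' promoter carries at most one site (on either strand) against an order-0
#' background estimated from the promoter universe. The EM objective is
#' non-decreasing; `n_starts` random initializations are tried and the best
#' final likelihood wins. The PWM is reported as an IUPAC motif (every base
#' with column frequency >= 0.25 enters the code) and scored by presence
#' enrichment like the other algorithms.
#'
#' @inheritParams discover_words
#' @param width motif width, in \[7, 12\].
#' @param n_starts random restarts.
#' @param seed RNG seed.
#' @param max_iter,tol EM stopping rule (relative log-likelihood change).
#' @return candidate data.frame (single row) with attribute `pwm` (4 x width
#'   frequency matrix) and `loglik_trace` of the winning run.
#' @export
discover_pwm <- function(module_proms, background_proms, width = 8L,
                         n_starts = 3L, seed = 1L, max_iter = 100L,
                         tol = 1e-4) {
  if (width < 7L || width > 12L) stop("width must be in [7, 12]")
  ints <- lapply(module_proms, function(s) {
    v <- .seq_to_int(s); v[is.na(v)] <- 5L; v  # N and friends -> pad code
  })
  lens <- lengths(ints)
  w <- width
  if (any(lens < w)) { ints <- ints[lens >= w]; lens <- lens[lens >= w] }
  nseq <- length(ints); L <- max(lens)
  V <- matrix(5L, nseq, L)
  for (i in seq_len(nseq)) V[i, seq_len(lens[i])] <- ints[[i]]
  all_bases <- unlist(lapply(background_proms, .seq_to_int))
  bg <- tabulate(all_bases, 4L); bg <- bg / sum(bg)
  npos_max <- L - w + 1L
  npos <- lens - w + 1L
  # precompute per-column window slices and base index sets once
  Vj <- lapply(seq_len(w), function(j)
    V[, j:(j + npos_max - 1L), drop = FALSE] + 5L * (j - 1L))
  Bidx <- lapply(seq_len(w), function(j) {
    Bj <- V[, j:(j + npos_max - 1L), drop = FALSE]
    lapply(1:4, function(b) which(Bj == b))
  })
  valid <- outer(npos, seq_len(npos_max), `>=`)
  win_scores <- function(lpwm5) {
    S <- matrix(0, nseq, npos_max)
    for (j in seq_len(w)) S <- S + matrix(lpwm5[Vj[[j]]], nseq, npos_max)
    S[!valid] <- -Inf
    S
  }
  em_steps <- function(pwm, gamma, n_iter, trace = numeric(0)) {
    converged <- FALSE
    for (it in seq_len(n_iter)) {
      lpwm <- rbind(log(pwm) - log(bg), -Inf)      # row 5 = pad, never matches
      lpwm_rc <- rbind((log(pwm) - log(bg))[4:1, w:1], -Inf)
      lw <- cbind(win_scores(lpwm), win_scores(lpwm_rc)) +
        log(gamma / (2 * npos))
      m <- pmax(lw[cbind(seq_len(nseq), max.col(lw, "first"))], log(1 - gamma))
      denom <- m + log(exp(log(1 - gamma) - m) + rowSums(exp(lw - m)))
      ll <- sum(denom)
      trace <- c(trace, ll)
      post <- exp(lw - denom)
      k <- length(trace)
      if (k > 1L && abs(trace[k] - trace[k - 1L]) < tol * (1 + abs(ll))) {
        converged <- TRUE; break
      }
      Pf <- post[, seq_len(npos_max), drop = FALSE]
      Pr <- post[, npos_max + seq_len(npos_max), drop = FALSE]
      counts <- matrix(0, 4L, w)
      for (j in seq_len(w)) for (b in 1:4) {
        idx <- Bidx[[j]][[b]]
        counts[b, j] <- counts[b, j] + sum(Pf[idx])
        counts[5L - b, w - j + 1L] <- counts[5L - b, w - j + 1L] + sum(Pr[idx])
      }
      pwm <- sweep(counts + 0.01, 2L, colSums(counts) + 0.04, `/`)
      gamma <- min(max(sum(post) / nseq, 1e-3), 1 - 1e-3)
    }
    list(pwm = pwm, gamma = gamma, trace = trace,
         final = trace[length(trace)], converged = converged)
  }
  # seed words: the most frequent width-w words of the module promoters
  # (reverse complements collapsed), a standard subsequence-seeding heuristic
  seed_words <- local({
    km <- unlist(lapply(module_proms, function(s) {
      L2 <- nchar(s)
      if (L2 < w) return(character(0))
      st <- seq_len(L2 - w + 1L)
      v <- substring(s, st, st + w - 1L)
      v[!grepl("[^ACGT]", v)]
    }), use.names = FALSE)
    uk <- unique(km)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(uk)))
    canon <- ifelse(uk <= rc, uk, rc)
    tab <- sort(tapply(tabulate(match(km, uk), length(uk)), canon, sum),
                decreasing = TRUE)
    names(tab)
  })
  pwm_from_word <- function(word) {
    v <- .seq_to_int(word)
    pwm <- matrix(0.1 / 3, 4L, w)
    pwm[cbind(v, seq_len(w))] <- 0.9
    pwm
  }
  best <- .with_seed(seed, {
    inits <- lapply(head(seed_words, n_starts), pwm_from_word)
    if (length(inits) == 0L) inits <- list(matrix(0.25, 4L, w))
    runs <- lapply(inits, function(p0) em_steps(p0, 0.5, max_iter))
    runs[[which.max(vapply(runs, `[[`, numeric(1), "final"))]]
  })
  iupac <- paste(apply(best$pwm, 2L, function(col) {
    picks <- c("A", "C", "G", "T")[col >= 0.25]
    if (length(picks) == 0L) picks <- c("A", "C", "G", "T")[which.max(col)]
    iupac_code(picks)
  }), collapse = "")
  e <- .motif_enrichment(iupac, module_proms, background_proms)
  out <- .candidate_df(iupac, "pwm", e$p, e$k, e$n, e$K, e$N)
  attr(out, "pwm") <- best$pwm
  attr(out, "loglik_trace") <- best$trace
  attr(out, "converged") <- best$converged
  out
}

#' Do two IUPAC motifs match at some ungapped offset?
#'
#' Two motifs match when some ungapped offset, on either strand, yields at
#' least `min_overlap` overlapping columns whose IUPAC base sets all
#' intersect.
#'
#' @param a,b IUPAC strings.
#' @param min_overlap minimum overlapping columns (default 7, the minimum
#'   retained motif length).
#' @return list with `match` (logical) and, when matched, `offset` (start of
#'   `b` relative to start of `a`), `strand` of `b`, and `overlap` width of
#'   the best-scoring placement.
#' @export
motifs_match <- function(a, b, min_overlap = 7L) {
  av <- .iupac_bits(a)
  best <- list(match = FALSE, overlap = 0L)
  for (strand in c("+", "-")) {
    bv <- if (strand == "+") .iupac_bits(b) else .iupac_bits_rc(b)
    na <- length(av); nb <- length(bv)
    for (off in (-(nb - min_overlap)):(na - min_overlap)) {
      ia <- max(1L, 1L + off):min(na, nb + off)
      if (length(ia) < min_overlap) next
      ib <- ia - off
      if (all(bitwAnd(av[ia], bv[ib]) > 0L) && length(ia) > best$overlap)
        best <- list(match = TRUE, offset = off, strand = strand,
                     overlap = length(ia))
    }
  }
  best
}

# IUPAC letters as 4-bit base sets (A=1, C=2, G=4, T=8)
.iupac_bit_map <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  v <- vapply(strsplit(m, "", fixed = TRUE), function(b)
    sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[b]), integer(1))
  setNames(v, names(m))
})

.iupac_bits <- function(motif) {
  b <- .iupac_bit_map[strsplit(toupper(motif), "", fixed = TRUE)[[1]]]
  if (anyNA(b)) stop("not an IUPAC motif: ", motif)
  unname(b)
}

# reverse complement in bit space: reverse order, swap A<->T and C<->G bits
.iupac_bits_rc <- function(motif) {
  v <- rev(.iupac_bits(motif))
  bitwOr(bitwOr(bitwShiftL(bitwAnd(v, 1L), 3L), bitwShiftR(bitwAnd(v, 8L), 3L)),
         bitwOr(bitwShiftL(bitwAnd(v, 2L), 1L), bitwShiftR(bitwAnd(v, 4L), 1L)))
}

#' The filter cascade for motif candidates
#'
#' Retains candidates that are at least `min_len` columns long, have at most
#' `max_ambig` uncharacterized (non-A/C/G/T) columns, are enriched at
#' p < `p_cut`, and are matched by candidates from at least `min_algos`
#' distinct algorithms (by [motifs_match()]); retained candidates carry the
#' merged algorithm tags. The output is a subset of the input and the cascade
#' is idempotent.
#'
#' @param candidates candidate data.frame (rows from the discover functions,
#'   rbind-ed).
#' @param p_cut,min_len,max_ambig,min_algos the four cascade thresholds.
#' @return filtered candidate data.frame.
#' @export
filter_cascade <- function(candidates, p_cut = 1e-5, min_len = 7L,
                           max_ambig = 3L, min_algos = 2L) {
  if (nrow(candidates) == 0L) return(candidates)
  len_ok <- nchar(candidates$motif) >= min_len
  amb_ok <- vapply(candidates$motif, iupac_n_ambiguous, integer(1)) <= max_ambig
  p_ok <- candidates$p < p_cut
  pass <- candidates[len_ok & amb_ok & p_ok, , drop = FALSE]
  if (nrow(pass) == 0L) return(pass)
  tags <- strsplit(pass$algorithms, ",", fixed = TRUE)
  merged <- character(nrow(pass)); keep <- logical(nrow(pass))
  for (i in seq_len(nrow(pass))) {
    if (length(unique(tags[[i]])) >= min_algos) {
      keep[i] <- TRUE; merged[i] <- paste(sort(unique(tags[[i]])), collapse = ",")
      next
    }
    partners <- unlist(lapply(seq_len(nrow(pass)), function(j) {
      if (motifs_match(pass$motif[i], pass$motif[j])$match) tags[[j]] else NULL
    }))
    u <- sort(unique(partners))
    keep[i] <- length(u) >= min_algos
    merged[i] <- paste(u, collapse = ",")
  }
  out <- pass[keep, , drop = FALSE]
  out$algorithms <- merged[keep]
  rownames(out) <- NULL
  out
}

#' Merge retained candidates into IUPAC consensus motifs
#'
#' Candidates are grouped by pairwise compatibility ([motifs_match()],
#' transitively closed); within a group, members are aligned at their best
#' ungapped offset to the most significant member and merged column-wise by
#' IUPAC union. A column is kept only when covered by at least
#' `min_col_coverage` of the members (interior low-coverage columns become
#' N); the per-column base-count matrix over members is kept as logo source.
#'
#' @param retained candidate data.frame from [filter_cascade()].
#' @param module_proms module promoters (for consensus coverage).
#' @param min_overlap passed to [motifs_match()].
#' @param min_col_coverage column-retention threshold.
#' @return list of `consensus_motif` objects: `consensus`, `members`,
#'   `counts` (4 x width), `coverage`, `p` (best member p).
#' @export
merge_to_consensus <- function(retained, module_proms, min_overlap = 7L,
                               min_col_coverage = 0.5) {
  if (nrow(retained) == 0L) return(list())
  n <- nrow(retained)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (motifs_match(retained$motif[i], retained$motif[j], min_overlap)$match)
      parent[find(j)] <- find(i)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  lapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    grp <- retained[idx, , drop = FALSE]
    grp <- grp[order(grp$p), , drop = FALSE]
    ref <- grp$motif[1]
    placed <- list(list(motif = toupper(ref), offset = 0L))
    for (i in seq_len(nrow(grp))[-1]) {
      mm <- motifs_match(ref, grp$motif[i], min_overlap)
      if (!mm$match) {  # transitive member: best-effort placement, any overlap
        mm <- motifs_match(ref, grp$motif[i], min_overlap = 1L)
        if (!mm$match) next
      }
      mot <- if (mm$strand == "+") toupper(grp$motif[i])
             else iupac_revcomp(grp$motif[i])
      placed[[length(placed) + 1L]] <- list(motif = mot, offset = mm$offset)
    }
    lo <- min(vapply(placed, function(p) 1L + p$offset, integer(1)))
    hi <- max(vapply(placed, function(p) nchar(p$motif) + p$offset, integer(1)))
    width <- hi - lo + 1L
    cover <- integer(width)
    sets <- vector("list", width)
    counts <- matrix(0L, 4L, width, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (p in placed) {
      cols <- strsplit(p$motif, "", fixed = TRUE)[[1]]
      for (j in seq_along(cols)) {
        pos <- j + p$offset - lo + 1L
        cover[pos] <- cover[pos] + 1L
        bs <- iupac_expand(cols[j])
        sets[[pos]] <- union(sets[[pos]], bs)
        counts[bs, pos] <- counts[bs, pos] + 1L
      }
    }
    ok <- cover / length(placed) >= min_col_coverage
    span <- range(which(ok))
    cons_cols <- vapply(span[1]:span[2], function(pos) {
      if (ok[pos]) iupac_code(sets[[pos]]) else "N"
    }, character(1))
    # flanking N columns carry no information; trim them
    core <- which(cons_cols != "N")
    if (length(core)) {
      span <- span[1] - 1L + c(min(core), max(core))
      cons_cols <- cons_cols[min(core):max(core)]
    }
    consensus <- paste(cons_cols, collapse = "")
    structure(list(consensus = consensus, members = grp,
                   counts = counts[, span[1]:span[2], drop = FALSE],
                   coverage = motif_coverage(module_proms, consensus),
                   p = min(grp$p)),
              class = "consensus_motif")
  })
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat(sprintf("consensus_motif %s: %d members, best p = %.3g, coverage %.0f%%\n",
              x$consensus, nrow(x$members), x$p, 100 * x$coverage))
  invisible(x)
}

#' Run the full motif stage: discovery, cascade, consensus merging
#'
#' @inheritParams discover_words
#' @param k_values word lengths for the census.
#' @param pwm_width,n_starts,seed PWM EM settings.
#' @param n_seeds number of top words seeding the IUPAC generalizer.
#' @param p_cut,min_len,max_ambig,min_algos cascade thresholds.
#' @return list with `candidates`, `retained`, `consensus` (list of
#'   consensus_motif).
#' @export
discover_motifs <- function(module_proms, background_proms,
                            k_values = c(7L, 8L, 9L), pwm_width = 8L,
                            n_starts = 3L, seed = 1L, n_seeds = 5L,
                            p_cut = 1e-5, min_len = 7L, max_ambig = 3L,
                            min_algos = 2L) {
  presence <- setNames(lapply(k_values, function(k)
    .kmer_presence(c(module_proms, background_proms), k)),
    as.character(k_values))
  words <- do.call(rbind, lapply(k_values, function(k)
    discover_words(module_proms, background_proms, k = k,
                   max_candidates = 50L,
                   presence = presence[[as.character(k)]])))
  seeds <- head(words$motif[order(words$p)], n_seeds)
  degen <- if (length(seeds))
    discover_degenerate(module_proms, background_proms, seeds, max_ambig,
                        presence = presence)
    else NULL
  pwm <- discover_pwm(module_proms, background_proms, width = pwm_width,
                      n_starts = n_starts, seed = seed)
  candidates <- rbind(words, degen, as.data.frame(pwm))
  retained <- filter_cascade(candidates, p_cut, min_len, max_ambig, min_algos)
  list(candidates = candidates, retained = retained,
       consensus = merge_to_consensus(retained, module_proms, min_len))
}

#' Extract upstream promoter regions from a genome and annotation
#'
#' Takes the region from `-upstream` to `-1` relative to the translation
#' start, strand-aware (reverse-complemented for minus-strand genes), and
#' truncated at the nearest annotated neighboring feature so promoters never
#' overlap ORFs. Coordinates are 1-based inclusive.
#'
#' @param genome named character vector (chromosome -> sequence).
#' @param annotation data.frame with columns `gene`, `chrom`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), 1-based inclusive.
#' @param gene_ids genes to extract; absent genes are skipped with a message.
#' @param upstream window size in nt (default 800).
#' @return list with `seqs` (named character vector) and `coords`
#'   (data.frame gene/chrom/start/end/strand of the extracted genomic span).
#' @export
extract_promoters <- function(genome, annotation, gene_ids, upstream = 800L) {
  stopifnot(all(c("gene", "chrom", "start", "end", "strand") %in%
                names(annotation)))
  seqs <- character(0); coords <- list()
  for (g in gene_ids) {
    row <- annotation[annotation$gene == g, , drop = FALSE]
    if (nrow(row) == 0L) { message("gene ", g, " absent from annotation; skipped"); next }
    row <- row[1, ]
    chrom_seq <- genome[[row$chrom]]
    if (is.null(chrom_seq)) stop("chromosome ", row$chrom, " missing from genome")
    others <- annotation[annotation$gene != g & annotation$chrom == row$chrom, ,
                         drop = FALSE]
    if (row$strand == "+") {
      lo <- max(1L, row$start - upstream); hi <- row$start - 1L
      nb <- others$end[others$end < row$start]
      if (length(nb)) lo <- max(lo, max(nb) + 1L)
      if (hi < lo) { message("gene ", g, ": no promoter space; skipped"); next }
      s <- substr(chrom_seq, lo, hi)
    } else {
      lo <- row$end + 1L; hi <- min(nchar(chrom_seq), row$end + upstream)
      nb <- others$start[others$start > row$end]
      if (length(nb)) hi <- min(hi, min(nb) - 1L)
      if (hi < lo) { message("gene ", g, ": no promoter space; skipped"); next }
      s <- iupac_revcomp(substr(chrom_seq, lo, hi))
    }
    seqs[[g]] <- s
    coords[[length(coords) + 1L]] <-
      data.frame(gene = g, chrom = row$chrom, start = lo, end = hi,
                 strand = row$strand, stringsAsFactors = FALSE)
  }
  list(seqs = seqs,
       coords = if (length(coords)) do.call(rbind, coords)
                else data.frame(gene = character(), chrom = character(),
                                start = integer(), end = integer(),
                                strand = character()))
}
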