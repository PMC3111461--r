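# shared fixture builders; everything is generated in code at test time

tiny_dataset <- function(mat_rows, groups = c("treated", "treated", "treated",
                                              "reference", "reference", "reference")) {
  mat <- do.call(rbind, mat_rows)
  rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  expression_dataset(mat, factor(groups, levels = unique(groups)))
}

toy_contact_plan <- function() {
  data.frame(
    resname = c("ARG", "LYS", "GLN", "ASN", "SER"),
    atom = c("NH1", "NZ", "NE2", "ND2", "OG"),
    dna_atom = c("OP1", "OP2", "N7", "O6", "OP1"),
    distance = c(3.0, 2.8, 3.0, 3.2, 6.0),
    class = c("salt_bridge", "salt_bridge", "hydrogen_bond", "hydrogen_bond",
              "water_mediated"),
    stringsAsFactors = FALSE)
}

# contact key for set comparisons
contact_key <- function(df) {
  sort(sprintf("%s%d:%s-%s%d:%s:%s", df$chain, df$resno, df$atom,
               df$dna_chain, df$dna_resno, df$dna_atom, df$class))
}

# brute-force all-pairs distance scan with the same atom vocabularies;
# independent of find_contacts' implementation
brute_force_contacts <- function(sc, dmin = 2, dmax = 5,
                                 hb = c(2.4, 3.5), wd = 3.5) {
  at <- sc$atoms
  salt <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
               HIS = c("ND1", "NE2"), ASP = c("OD1", "OD2"),
               GLU = c("OE1", "OE2"))
  phos <- c("OP1", "OP2", "O1P", "O2P")
  pk <- sc$chain_class[at$chain] == "protein" & at$elem %in% c("N", "O")
  dk <- sc$chain_class[at$chain] == "nucleic" & at$elem %in% c("N", "O")
  wk <- sc$chain_class[at$chain] == "water" & at$elem == "O"
  recs <- list()
  d3 <- function(i, j) sqrt(sum((unlist(at[i, c("x", "y", "z")]) -
                                 unlist(at[j, c("x", "y", "z")]))^2))
  for (i in which(pk)) for (j in which(dk)) {
    d <- d3(i, j)
    cls <- NULL
    if (d >= dmin && d <= dmax) {
      if (at$atom[i] %in% unlist(salt[at$resname[i]]) && at$atom[j] %in% phos)
        cls <- "salt_bridge"
      else if (d >= hb[1] && d <= hb[2]) cls <- "hydrogen_bond"
    }
    if (is.null(cls)) {
      for (wi in which(wk)) {
        if (d3(wi, i) <= wd && d3(wi, j) <= wd) { cls <- "water_mediated"; break }
      }
    }
    if (!is.null(cls))
      recs[[length(recs) + 1L]] <- data.frame(
        chain = at$chain[i], resno = at$resno[i], atom = at$atom[i],
        dna_chain = at$chain[j], dna_resno = at$resno[j],
        dna_atom = at$atom[j], class = cls, stringsAsFactors = FALSE)
  }
  if (length(recs)) do.call(rbind, recs)
  else data.frame(chain = character(), resno = integer(), atom = character(),
                  dna_chain = character(), dna_resno = integer(),
                  dna_atom = character(), class = character())
}

# plain-arithmetic hypergeometric upper tail (ratio of binomial coefficients,
# no logs) -- the enumeration oracle
hyper_tail_oracle <- function(k, n, K, N) {
  if (k == 0) return(1)
  x <- k:min(K, n)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}
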