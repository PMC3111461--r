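# Protein-DNA contact detection and classification in complex structures,
# and conservation of contacting residues across aligned basic regions.

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")
.nuc3 <- c("DA", "DT", "DG", "DC", "DU", "A", "T", "G", "C", "U")

#' Parse a PDB coordinate file into a structure complex
#'
#' Atoms are loaded via bio3d; chains are classified as protein, nucleic,
#' water or other from their residue-name vocabulary. Altloc duplicates keep
#' the highest-occupancy copy. An optional residue range restricts the
#' protein selection (e.g. the DNA-binding domain).
#'
#' @param path PDB file.
#' @return object of class `structure_complex`: `atoms` data.frame (chain,
#'   resno, resname, atom, elem, x, y, z), `chain_class` named vector.
#' @export
parse_complex <- function(path) {
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at$elem <- ifelse(is.na(at$elesy) | at$elesy == "",
                    substr(gsub("[^A-Za-z]", "", at$elety), 1L, 1L), at$elesy)
  # altloc: keep the highest-occupancy copy of each alternate location set
  has_alt <- !is.na(at$alt) & at$alt != ""
  if (any(has_alt)) {
    key <- paste(at$chain, at$resno, at$elety)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[has_alt])) {
      idx <- which(key == k)
      if (length(idx) > 1L) {
        best <- idx[which.max(ifelse(is.na(at$o[idx]), 0, at$o[idx]))]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
    at <- at[keep, , drop = FALSE]
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, resname = at$resid,
                      atom = at$elety, elem = toupper(at$elem),
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  cls <- vapply(split(atoms$resname, atoms$chain), function(rn) {
    rn <- unique(rn)
    if (all(rn %in% .aa3)) "protein"
    else if (all(rn %in% .nuc3)) "nucleic"
    else if (all(rn == "HOH")) "water"
    else if (any(rn %in% .aa3)) "protein"      # mixed chains by majority call
    else if (any(rn %in% .nuc3)) "nucleic"
    else "other"
  }, character(1))
  unknown <- setdiff(unique(atoms$resname), c(.aa3, .nuc3, "HOH"))
  if (length(unknown))
    message("unknown residue names classified as other: ",
            paste(unknown, collapse = ", "))
  structure(list(atoms = atoms, chain_class = cls),
            class = "structure_complex")
}

#' @export
print.structure_complex <- function(x, ...) {
  cat("structure_complex:", nrow(x$atoms), "atoms;",
      paste(names(x$chain_class), x$chain_class, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

.salt_protein <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                      HIS = c("ND1", "NE2"), ASP = c("OD1", "OD2"),
                      GLU = c("OE1", "OE2"))
.phosphate_ox <- c("OP1", "OP2", "O1P", "O2P")

.parse_domain <- function(domain) {
  # "A:61-100" -> list(chain = "A", from = 61, to = 100)
  m <- regmatches(domain, regexec("^([A-Za-z0-9]+):([0-9]+)-([0-9]+)$", domain))[[1]]
  if (length(m) != 4L) stop("domain must look like 'A:61-100'")
  list(chain = m[2], from = as.integer(m[3]), to = as.integer(m[4]))
}

#' Detect and classify protein-DNA contacts
#'
#' Candidate pairs are polar/charged protein atoms (N/O, side chain or
#' backbone) against polar DNA atoms (N/O), searched in the outer window
#' `[dmin, dmax]`. Classification precedence: a salt bridge (charged
#' side-chain nitrogen/oxygen against a phosphate oxygen, anywhere in the
#' outer window) beats a hydrogen bond (any N/O pair inside the geometric
#' H-bond window). Waters bridging a protein and a DNA polar atom, each
#' within `water_dist`, add water-mediated records for pairs not already in
#' direct contact. One record per atom pair.
#'
#' @param sc [parse_complex()] result (or the toy complexes written by
#'   [gen_complex()]).
#' @param dmin,dmax outer distance window in Angstrom (default 2-5).
#' @param domain optional protein residue range like `"A:61-100"` restricting
#'   the DNA-binding domain.
#' @param hbond_window geometric hydrogen-bond distance window.
#' @param water_dist maximum water-oxygen distance to each partner.
#' @return data.frame: chain, resno, resname, atom, dna_chain, dna_resno,
#'   dna_resname, dna_atom, distance, class, water_resno.
#' @export
find_contacts <- function(sc, dmin = 2, dmax = 5, domain = NULL,
                          hbond_window = c(2.4, 3.5), water_dist = 3.5) {
  stopifnot(inherits(sc, "structure_complex"))
  at <- sc$atoms
  prot_chains <- names(sc$chain_class)[sc$chain_class == "protein"]
  dna_chains <- names(sc$chain_class)[sc$chain_class == "nucleic"]
  if (length(prot_chains) == 0L || length(dna_chains) == 0L)
    stop("need at least one protein and one nucleic chain")
  prot <- at[at$chain %in% prot_chains & at$elem %in% c("N", "O"), , drop = FALSE]
  if (!is.null(domain)) {
    d <- .parse_domain(domain)
    prot <- prot[prot$chain == d$chain & prot$resno >= d$from &
                 prot$resno <= d$to, , drop = FALSE]
    if (nrow(prot) == 0L) stop("empty domain selection: ", domain)
  }
  dna <- at[at$chain %in% dna_chains & at$elem %in% c("N", "O"), , drop = FALSE]
  wat <- at[at$chain %in% names(sc$chain_class)[sc$chain_class == "water"] &
            at$elem == "O", , drop = FALSE]
  if (nrow(prot) == 0L || nrow(dna) == 0L) return(.empty_contacts())
  pd <- function(a, b) {
    outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
      sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2))
  }
  dm <- pd(prot, dna)
  is_salt_p <- mapply(function(rn, an) an %in% (.salt_protein[[rn]] %||% character(0)),
                      prot$resname, prot$atom)
  recs <- list()
  hit <- which(dm >= dmin & dm <= dmax, arr.ind = TRUE)
  for (r in seq_len(nrow(hit))) {
    i <- hit[r, 1]; j <- hit[r, 2]; d <- dm[i, j]
    cls <- if (is_salt_p[i] && dna$atom[j] %in% .phosphate_ox) "salt_bridge"
           else if (d >= hbond_window[1] && d <= hbond_window[2]) "hydrogen_bond"
           else NA_character_
    if (is.na(cls)) next
    recs[[length(recs) + 1L]] <- data.frame(
      chain = prot$chain[i], resno = prot$resno[i], resname = prot$resname[i],
      atom = prot$atom[i], dna_chain = dna$chain[j], dna_resno = dna$resno[j],
      dna_resname = dna$resname[j], dna_atom = dna$atom[j],
      distance = round(d, 3), class = cls, water_resno = NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (nrow(wat) > 0L) {
    dw_p <- pd(wat, prot); dw_d <- pd(wat, dna)
    for (wi in seq_len(nrow(wat))) {
      pi_ <- which(dw_p[wi, ] <= water_dist)
      di_ <- which(dw_d[wi, ] <= water_dist)
      for (i in pi_) for (j in di_) {
        direct <- any(vapply(recs, function(rr)
          rr$chain == prot$chain[i] && rr$resno == prot$resno[i] &&
          rr$atom == prot$atom[i] && rr$dna_chain == dna$chain[j] &&
          rr$dna_resno == dna$resno[j] && rr$dna_atom == dna$atom[j],
          logical(1)))
        if (isTRUE(direct)) next
        recs[[length(recs) + 1L]] <- data.frame(
          chain = prot$chain[i], resno = prot$resno[i],
          resname = prot$resname[i], atom = prot$atom[i],
          dna_chain = dna$chain[j], dna_resno = dna$resno[j],
          dna_resname = dna$resname[j], dna_atom = dna$atom[j],
          distance = round(dm[i, j], 3), class = "water_mediated",
          water_resno = wat$resno[wi], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else .empty_contacts()
  out <- out[!duplicated(out[, c("chain", "resno", "atom", "dna_chain",
                                 "dna_resno", "dna_atom")]), , drop = FALSE]
  out <- out[order(out$chain, out$resno, out$atom, out$dna_resno, out$dna_atom), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_contacts <- function() {
  data.frame(chain = character(), resno = integer(), resname = character(),
             atom = character(), dna_chain = character(), dna_resno = integer(),
             dna_resname = character(), dna_atom = character(),
             distance = numeric(), class = character(),
             water_resno = integer(), stringsAsFactors = FALSE)
}

#' Basic-region alignment container
#'
#' @param seqs named character vector of aligned sequences (equal lengths,
#'   `-` for gaps); the first sequence is the structural reference.
#' @param ref_start residue number of the reference's first non-gap column.
#' @return object of class `basic_region_alignment` with a column map from
#'   reference residue numbers to alignment columns.
#' @export
basic_region_alignment <- function(seqs, ref_start = 1L) {
  if (length(unique(nchar(seqs))) != 1L) stop("aligned sequences must have equal length")
  if (is.null(names(seqs))) stop("sequences must be named by their TF")
  ref <- strsplit(seqs[[1]], "", fixed = TRUE)[[1]]
  cols <- which(ref != "-")
  map <- setNames(cols, seq(ref_start, length.out = length(cols)))
  structure(list(seqs = seqs, ref = names(seqs)[1], ref_start = ref_start,
                 column_map = map),
            class = "basic_region_alignment")
}

#' Conservation of contacting residues across aligned basic regions
#'
#' A reference residue is conserved when every aligned sequence carries the
#' identical amino acid (no gap) at its alignment column.
#'
#' @param resnos reference residue numbers of the contacting residues.
#' @param aln [basic_region_alignment()].
#' @return data.frame: resno, column, ref_aa, conserved, plus one amino-acid
#'   column per aligned sequence. Unmapped residues are reported with
#'   `conserved = NA` and a warning, never silently dropped.
#' @export
contact_conservation <- function(resnos, aln) {
  stopifnot(inherits(aln, "basic_region_alignment"))
  mats <- lapply(aln$seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  rows <- lapply(resnos, function(rn) {
    col <- aln$column_map[as.character(rn)]
    if (is.na(col)) {
      warning("residue ", rn, " not mapped in the alignment")
      aa <- setNames(rep(NA_character_, length(mats)), names(mats))
      return(data.frame(resno = rn, column = NA_integer_,
                        ref_aa = NA_character_, conserved = NA,
                        t(aa), stringsAsFactors = FALSE))
    }
    aa <- vapply(mats, `[`, character(1), col)
    data.frame(resno = rn, column = unname(col), ref_aa = unname(aa[1]),
               conserved = all(aa == aa[1] & aa != "-"),
               t(aa), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
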