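# Synthetic-data generators with recorded ground truth.
#
# Every generator is a pure function of a sim_config (plus explicit extra
# arguments): the same config yields byte-identical artifacts. Randomness is
# confined to the config seed; no generator touches the global RNG state of
# the caller (they run inside withr-style local seeds implemented by hand).

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Holds every knob of the synthetic-data generators, with defaults emulating
#' the desk-scale study conditions: ~5000-gene expression matrices, 7 arrays
#' per group, 5000 ChIP probes from a two-component regression mixture, 2000
#' promoters of 800 nt at yeast-like GC content, and a planted motif carried
#' by 70\% of module promoters.
#'
#' @param seed integer RNG seed.
#' @param n_genes,n_samples_per_group,n_probes,n_promoters problem sizes.
#' @param de_fraction fraction of genes planted as differentially expressed.
#' @param bound_fraction fraction of promoters planted as TF-bound.
#' @param effect_size planted mean log2-ratio shift in the treated group.
#' @param noise_sd per-measurement log2 noise standard deviation.
#' @param a0,b0,a1,b1 intercept/slope of the unbound (0) and bound (1)
#'   regression components of the IP-on-INPUT mixture; `b1 > b0`.
#' @param sigma residual standard deviation of the mixture (log2 units).
#' @param pi_bound mixing weight of the bound component, in \[0, 1\].
#' @param n_replicates replicate IP/INPUT array pairs per probe.
#' @param promoter_length promoter length in nt (upstream -800..-1 window).
#' @param motif_prob_in_module probability that a module promoter receives a
#'   planted motif instance.
#' @param gc_content background GC fraction of generated promoters.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 5000L, n_samples_per_group = 7L,
                       n_probes = 5000L, n_promoters = 2000L,
                       de_fraction = 0.05, bound_fraction = 0.05,
                       effect_size = 1, noise_sd = 0.25,
                       a0 = 0, b0 = 1, a1 = 1, b1 = 1.5,
                       sigma = 0.2, pi_bound = 0.2,
                       n_replicates = 4L,
                       promoter_length = 800L,
                       motif_prob_in_module = 0.7,
                       gc_content = 0.38) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_samples_per_group = as.integer(n_samples_per_group),
              n_probes = as.integer(n_probes),
              n_promoters = as.integer(n_promoters),
              de_fraction = de_fraction, bound_fraction = bound_fraction,
              effect_size = effect_size, noise_sd = noise_sd,
              a0 = a0, b0 = b0, a1 = a1, b1 = b1,
              sigma = sigma, pi_bound = pi_bound,
              n_replicates = as.integer(n_replicates),
              promoter_length = as.integer(promoter_length),
              motif_prob_in_module = motif_prob_in_module,
              gc_content = gc_content)
  for (p in c("de_fraction", "bound_fraction", "pi_bound",
              "motif_prob_in_module", "gc_content")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop(p, " must be a proportion in [0, 1]")
  }
  for (p in c("n_genes", "n_samples_per_group", "n_probes", "n_promoters",
              "promoter_length", "n_replicates")) {
    if (cfg[[p]] < 1L) stop(p, " must be a positive count")
  }
  if (cfg$sigma <= 0) stop("sigma must be > 0")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$b1 <= cfg$b0) stop("bound component must be steeper: b1 > b0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_genes, "genes x",
      2L * x$n_samples_per_group, "samples;", x$n_probes, "probes;",
      x$n_promoters, "promoters of", x$promoter_length, "nt\n")
  invisible(x)
}

#' Generate a log2-ratio expression matrix with a planted up-regulated subset
#'
#' Background genes are centred at zero with i.i.d. Gaussian noise; a planted
#' fraction receives a mean shift of `effect_size` in the treated/mutant-
#' responsive group. `mode = "benomyl"` labels samples treated/reference,
#' `mode = "mutant"` labels them mutant/wildtype (the deletion-strain
#' comparison); the planted subset of the mutant design represents the genes
#' whose induction depends on the transcription factor.
#'
#' @param cfg [sim_config()].
#' @param mode experimental design to emulate.
#' @return list with `dataset` (an [expression_dataset()]) and `truth`
#'   (`de_genes`: planted gene ids).
#' @export
gen_expression <- function(cfg, mode = c("benomyl", "mutant")) {
  stopifnot(inherits(cfg, "sim_config"))
  mode <- match.arg(mode)
  labs <- if (mode == "benomyl") c("treated", "reference")
          else c("mutant", "wildtype")
  .with_seed(cfg$seed + if (mode == "benomyl") 101L else 151L, {
    n <- cfg$n_genes; m <- cfg$n_samples_per_group
    genes <- sprintf("g%04d", seq_len(n))
    n_de <- round(n * cfg$de_fraction)
    de <- genes[seq_len(n_de)]
    mat <- matrix(rnorm(n * 2L * m, sd = cfg$noise_sd), nrow = n,
                  dimnames = list(genes, c(sprintf("%s_%d", labs[1], 1:m),
                                           sprintf("%s_%d", labs[2], 1:m))))
    if (n_de > 0L) mat[seq_len(n_de), seq_len(m)] <-
      mat[seq_len(n_de), seq_len(m)] + cfg$effect_size
    groups <- factor(rep(labs, each = m), levels = labs)
    list(dataset = expression_dataset(mat, groups),
         truth = list(de_genes = de))
  })
}

#' Generate IP/INPUT probe intensities from a mixture of linear regressions
#'
#' INPUT intensities are drawn Normal(8, 1) on the log2 scale (log-normal
#' intensities, the typical array spread). Each probe belongs to the bound
#' component with probability `pi_bound`; its IP signal is
#' `a_k + b_k * input + N(0, sigma^2)`. With `n_replicates > 1`, each probe
#' gets that many independent replicate (input, ip) pairs sharing the probe's
#' component label.
#'
#' @param cfg [sim_config()].
#' @return list with `probes` (data.frame: probe, replicate, input, ip, gene)
#'   and `truth` (`bound_probes`, `bound_promoters`).
#' @export
gen_chip <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed + 202L, {
    n <- cfg$n_probes; r <- cfg$n_replicates
    probes <- sprintf("p%05d", seq_len(n))
    # probes tile promoters: two probes per promoter where counts allow
    genes <- sprintf("g%04d", ((seq_len(n) - 1L) %/% 2L) %% cfg$n_genes + 1L)
    z <- rbinom(n, 1L, cfg$pi_bound)
    input <- matrix(rnorm(n * r, mean = 8, sd = 1), nrow = n)
    a <- ifelse(z == 1L, cfg$a1, cfg$a0)
    b <- ifelse(z == 1L, cfg$b1, cfg$b0)
    ip <- a + b * input + matrix(rnorm(n * r, sd = cfg$sigma), nrow = n)
    out <- data.frame(probe = rep(probes, r),
                      replicate = rep(seq_len(r), each = n),
                      input = as.vector(input), ip = as.vector(ip),
                      gene = rep(genes, r), stringsAsFactors = FALSE)
    out <- out[order(out$probe, out$replicate), , drop = FALSE]
    rownames(out) <- NULL
    list(probes = out,
         truth = list(bound_probes = probes[z == 1L],
                      bound_promoters = unique(genes[z == 1L])))
  })
}

.random_dna <- function(n, len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = ""),
    character(1))
}

#' Generate promoter sequences with planted IUPAC motif instances
#'
#' Background promoters are i.i.d. nucleotides at the configured GC content
#' (an order-0 null, matching the expected-frequency background of the motif
#' stage). Each module promoter receives, with probability
#' `motif_prob_in_module`, one concrete resolution of the planted IUPAC motif
#' at a uniform offset and strand; planted sites are recorded in the truth.
#'
#' @param cfg [sim_config()].
#' @param motif IUPAC string to plant.
#' @param module_ids promoter ids (subset of the generated universe) forming
#'   the module. Defaults to the first `round(n_promoters * de_fraction)` ids.
#' @param ids optional vector of `n_promoters` unique promoter identifiers
#'   (defaults to `pr0001`, `pr0002`, ...).
#' @param background_motif_prob probability that a non-module promoter also
#'   receives a planted instance (default 0).
#' @return list with `promoters` (named character vector, ids `pr0001`...),
#'   `module_ids`, and `truth` (`planted_motif`, `motif_sites`: data.frame of
#'   seq_id/offset/strand/word).
#' @export
gen_promoters <- function(cfg, motif = "TTASTAA", module_ids = NULL,
                          ids = NULL, background_motif_prob = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nchar(motif) < 1L) stop("motif must have length >= 1")
  if (nchar(motif) > cfg$promoter_length)
    stop("motif longer than promoter length")
  .with_seed(cfg$seed + 303L, {
    if (is.null(ids)) ids <- sprintf("pr%04d", seq_len(cfg$n_promoters))
    if (length(ids) != cfg$n_promoters || anyDuplicated(ids))
      stop("ids must be ", cfg$n_promoters, " unique promoter identifiers")
    if (is.null(module_ids))
      module_ids <- ids[seq_len(max(1L, round(cfg$n_promoters * cfg$de_fraction)))]
    if (!all(module_ids %in% ids)) stop("module_ids outside promoter universe")
    seqs <- .random_dna(cfg$n_promoters, cfg$promoter_length, cfg$gc_content)
    names(seqs) <- ids
    w <- nchar(motif)
    sites <- list()
    plant_in <- c(module_ids,
                  setdiff(ids, module_ids)[
                    runif(cfg$n_promoters - length(module_ids)) <
                      background_motif_prob])
    for (id in plant_in) {
      in_module <- id %in% module_ids
      if (in_module && runif(1) > cfg$motif_prob_in_module) next
      word <- iupac_resolve(motif)
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") word else iupac_revcomp(word)
      off <- sample.int(cfg$promoter_length - w + 1L, 1L)
      substr(seqs[[id]], off, off + w - 1L) <- ins
      sites[[length(sites) + 1L]] <-
        data.frame(seq_id = id, offset = off, strand = strand, word = word,
                   stringsAsFactors = FALSE)
    }
    sites <- if (length(sites)) do.call(rbind, sites)
             else data.frame(seq_id = character(), offset = integer(),
                             strand = character(), word = character())
    list(promoters = seqs, module_ids = module_ids,
         truth = list(planted_motif = motif, motif_sites = sites))
  })
}

.random_protein <- function(len) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

.mutate_protein <- function(seq, rate) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(aa, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Generate a pair of proteomes with known ortholog structure
#'
#' Each family yields one ancestral sequence, copied into both proteomes and
#' mutated by substitutions only (so truth identity is analytic) at
#' `mutation_rate` per site. A `rewire_fraction` of families is dropped from
#' proteome B, leaving those A proteins without an ortholog.
#'
#' @param cfg [sim_config()].
#' @param n_families number of single-copy families.
#' @param rewire_fraction fraction of families missing from proteome B.
#' @param mutation_rate per-site substitution probability applied to each copy.
#' @param len_range family sequence lengths drawn uniformly from this range.
#' @return list with `proteome_a`, `proteome_b` (named character vectors) and
#'   `truth` (`ortholog_pairs`: data.frame a/b).
#' @export
gen_proteomes <- function(cfg, n_families = 100L, rewire_fraction = 0,
                          mutation_rate = 0.05, len_range = c(120L, 300L)) {
  stopifnot(inherits(cfg, "sim_config"))
  if (rewire_fraction < 0 || rewire_fraction > 1)
    stop("rewire_fraction must be in [0, 1]")
  .with_seed(cfg$seed + 404L, {
    lens <- sample(len_range[1]:len_range[2], n_families, replace = TRUE)
    anc <- vapply(lens, .random_protein, character(1))
    a_ids <- sprintf("A%03d", seq_len(n_families))
    b_ids <- sprintf("B%03d", seq_len(n_families))
    pa <- setNames(vapply(anc, .mutate_protein, character(1),
                          rate = mutation_rate), a_ids)
    pb <- setNames(vapply(anc, .mutate_protein, character(1),
                          rate = mutation_rate), b_ids)
    n_drop <- round(n_families * rewire_fraction)
    keep_b <- if (n_drop > 0L)
      setdiff(seq_len(n_families), sample.int(n_families, n_drop))
      else seq_len(n_families)
    pb <- pb[keep_b]
    pairs <- data.frame(a = a_ids[keep_b], b = b_ids[keep_b],
                        stringsAsFactors = FALSE)
    list(proteome_a = pa, proteome_b = pb,
         truth = list(ortholog_pairs = pairs))
  })
}

#' Generate a toy protein-DNA complex with planted contacts
#'
#' Builds a geometric toy structure in PDB format: DNA atoms strung along the
#' z axis with wide spacing, protein residues with backbone atoms far from the
#' DNA, and for each requested contact a single protein side-chain atom placed
#' radially at the stated distance from its DNA partner atom. The spacing
#' guarantees that only the planted pairs fall inside a 5 A search window, so
#' the recorded truth is exactly what a contact scan must return. A requested
#' water-mediated contact places a bridging water between a protein atom and a
#' DNA atom, each within hydrogen-bonding reach of the water oxygen.
#'
#' @param contacts data.frame with columns `resname` (e.g. `"ARG"`), `atom`
#'   (protein atom, e.g. `"NH1"`), `dna_atom` (e.g. `"OP1"`), `distance` (A)
#'   and `class` (`"salt_bridge"`, `"hydrogen_bond"` or `"water_mediated"`).
#' @param path output PDB file path.
#' @param n_dna number of DNA residues (one atom set each).
#' @return list with `path` and `truth` (`contacts` data.frame mirroring the
#'   request, with chain/residue numbers filled in).
#' @export
gen_complex <- function(contacts, path = tempfile(fileext = ".pdb"),
                        n_dna = max(6L, nrow(contacts) + 2L)) {
  stopifnot(is.data.frame(contacts),
            all(c("resname", "atom", "dna_atom", "distance", "class")
                %in% names(contacts)))
  if (any(contacts$distance < 1))
    stop("clashing atom placement: planted distance < 1 A")
  # planted classes must be realizable under the standard geometric rules,
  # otherwise the truth could not equal what a contact scan returns
  for (i in seq_len(nrow(contacts))) {
    cl <- contacts$class[i]; d <- contacts$distance[i]
    if (cl == "salt_bridge") {
      ok_atom <- contacts$atom[i] %in%
        (.salt_protein[[contacts$resname[i]]] %||% character(0))
      if (!ok_atom || !contacts$dna_atom[i] %in% .phosphate_ox)
        stop("salt bridge requires a charged side-chain atom vs phosphate oxygen")
      if (d < 2 || d > 5) stop("salt bridge distance must lie in [2, 5] A")
    } else if (cl == "hydrogen_bond") {
      if (d < 2.4 || d > 3.5)
        stop("hydrogen bond distance must lie in [2.4, 3.5] A")
      if (contacts$atom[i] %in%
          (.salt_protein[[contacts$resname[i]]] %||% character(0)) &&
          contacts$dna_atom[i] %in% .phosphate_ox)
        stop("this pair would classify as a salt bridge, not a hydrogen bond")
    } else if (cl != "water_mediated") {
      stop("unknown contact class: ", cl)
    }
  }
  spacing <- 6.5  # > sqrt(dmax^2 - min planted distance^2) for dmax = 5
  atoms <- list(); serial <- 0L
  add_atom <- function(record = "ATOM", name, resname, chain, resno, xyz,
                       elem) {
    serial <<- serial + 1L
    atoms[[length(atoms) + 1L]] <<- data.frame(
      record = record, serial = serial, name = name, resname = resname,
      chain = chain, resno = resno,
      x = round(xyz[1], 3), y = round(xyz[2], 3), z = round(xyz[3], 3),
      elem = elem, stringsAsFactors = FALSE)
  }
  # DNA chain B: one payload atom per residue on the z axis, plus a C1' rib
  dna_atoms <- character(n_dna)
  for (i in seq_len(n_dna)) {
    nm <- if (i <= nrow(contacts)) contacts$dna_atom[i] else "OP1"
    dna_atoms[i] <- nm
    z <- (i - 1L) * spacing
    elem <- substr(gsub("[^A-Z]", "", nm), 1L, 1L)
    add_atom("ATOM", nm, "DA", "B", i, c(0, 0, z), elem)
    add_atom("ATOM", "C1'", "DA", "B", i, c(0, 20, z), "C")
  }
  # protein chain A: backbone parked 25 A off axis, contact atom moved in
  truth <- contacts
  truth$chain <- "A"; truth$resno <- NA_integer_
  truth$dna_chain <- "B"; truth$dna_resno <- seq_len(nrow(contacts))
  truth$water_resno <- NA_integer_
  n_wat <- 0L
  for (i in seq_len(nrow(contacts))) {
    z <- (i - 1L) * spacing
    resno <- i
    truth$resno[i] <- resno
    backbone_contact <- contacts$atom[i] %in% c("N", "CA", "C", "O")
    for (bb in setdiff(c("N", "CA", "C", "O"),
                       if (backbone_contact) contacts$atom[i] else character(0))) {
      add_atom("ATOM", bb, contacts$resname[i], "A", resno,
               c(25 + match(bb, c("N", "CA", "C", "O")), 0, z),
               substr(bb, 1L, 1L))
    }
    d <- contacts$distance[i]
    elem <- substr(gsub("[^A-Z]", "", contacts$atom[i]), 1L, 1L)
    if (contacts$class[i] == "water_mediated") {
      # protein atom outside the direct window; water bridges both sides
      add_atom("ATOM", contacts$atom[i], contacts$resname[i], "A", resno,
               c(6, 0, z), elem)
      n_wat <- n_wat + 1L
      wat_no <- 500L + n_wat
      add_atom("HETATM", "O", "HOH", "W", wat_no, c(3, 0, z), "O")
      truth$water_resno[i] <- wat_no
      truth$distance[i] <- 6
    } else {
      add_atom("ATOM", contacts$atom[i], contacts$resname[i], "A", resno,
               c(d, 0, z), elem)
    }
  }
  df <- do.call(rbind, atoms)
  # clash guard over the full structure
  dmat <- as.matrix(stats::dist(df[, c("x", "y", "z")]))
  diag(dmat) <- Inf
  if (any(dmat < 1)) stop("clashing atom placement: atoms < 1 A apart")
  lines <- sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   df$record, df$serial,
                   ifelse(nchar(df$name) < 4L, paste0(" ", df$name), df$name),
                   df$resname, df$chain, df$resno, df$x, df$y, df$z,
                   1, 0, df$elem)
  writeLines(c(lines, "END"), path)
  list(path = path, truth = list(contacts = truth))
}
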