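# Orchestration and format adapters. All randomness flows through the seeds
# recorded in the run configuration; rerunning a configuration reproduces
# byte-identical outputs.

#' Run configuration for the end-to-end synthetic pipeline
#'
#' Bundles the simulation config with every analysis threshold at its
#' standard default: caller p < 0.05 / FDR < 0.05, binding risk alpha 0.05,
#' motif enrichment p < 1e-5 with minimum length 7, at most 3 uncharacterized
#' positions and 2-of-3 algorithm agreement, homology E < 1e-2 with aligned
#' length > 100 aa and identity > 25\%, contact window 2-5 Angstrom.
#'
#' @param sim [sim_config()].
#' @param p_cut,fdr_cut,alpha,min_agree expression/binding thresholds.
#' @param motif_p,motif_min_len,motif_max_ambig,motif_min_algos motif cascade.
#' @param homology_e,homology_len,homology_ident homology link thresholds.
#' @param contact_dmin,contact_dmax contact search window (Angstrom).
#' @param n_perm permutations for the d-statistic caller.
#' @param out_dir output directory for [run_all()].
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       p_cut = 0.05, fdr_cut = 0.05, alpha = 0.05,
                       min_agree = 2L,
                       motif_p = 1e-5, motif_min_len = 7L,
                       motif_max_ambig = 3L, motif_min_algos = 2L,
                       homology_e = 1e-2, homology_len = 100L,
                       homology_ident = 25,
                       contact_dmin = 2, contact_dmax = 5,
                       n_perm = 200L, out_dir = tempfile("yapmod_run_")) {
  cfg <- list(sim = sim, p_cut = p_cut, fdr_cut = fdr_cut, alpha = alpha,
              min_agree = as.integer(min_agree), motif_p = motif_p,
              motif_min_len = as.integer(motif_min_len),
              motif_max_ambig = as.integer(motif_max_ambig),
              motif_min_algos = as.integer(motif_min_algos),
              homology_e = homology_e, homology_len = as.integer(homology_len),
              homology_ident = homology_ident,
              contact_dmin = contact_dmin, contact_dmax = contact_dmax,
              n_perm = as.integer(n_perm), out_dir = out_dir)
  structure(cfg, class = "run_config")
}

#' Serialize / restore a run configuration (lossless round trip)
#' @param cfg [run_config()].
#' @param path JSON file path.
#' @return `write_run_config` the path; `read_run_config` the restored config.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  x <- unclass(cfg); x$sim <- unclass(cfg$sim)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- do.call(sim_config, x$sim)
  x$sim <- NULL
  do.call(run_config, c(list(sim = sim), x))
}

# ---- format adapters --------------------------------------------------------

#' Write / read an expression matrix as TSV with a group header row
#'
#' Layout: a `gene` header line with sample ids, a second `#group` line with
#' the group label of each sample, then one row per gene. Parsing is strict:
#' any malformed row aborts with its line number; CRLF line endings and a
#' trailing blank line are tolerated.
#'
#' @param ds [expression_dataset()].
#' @param path TSV file path.
#' @return `write_expression_tsv` the path; `read_expression_tsv` the dataset.
#' @export
write_expression_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  con <- file(path, "wb")  # binary mode: stable bytes across platforms
  on.exit(close(con))
  writeLines(c(paste(c("gene", colnames(ds$mat)), collapse = "\t"),
               paste(c("#group", as.character(ds$groups)), collapse = "\t"),
               vapply(seq_len(nrow(ds$mat)), function(i)
                 paste(c(rownames(ds$mat)[i],
                         format(ds$mat[i, ], digits = 15, trim = TRUE)),
                       collapse = "\t"), character(1))),
             con, sep = "\n")
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  if (length(lines) && lines[length(lines)] == "") lines <- lines[-length(lines)]
  if (length(lines) < 3L) stop("expression TSV too short: ", path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  grp <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "gene" || grp[1] != "#group")
    stop("line 1/2: expected 'gene' and '#group' headers in ", path)
  if (length(grp) != length(hdr))
    stop("line 2: group row has ", length(grp), " fields, expected ", length(hdr))
  n_samp <- length(hdr) - 1L
  rows <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != n_samp + 1L)
  if (length(bad))
    stop("line ", bad[1] + 2L, ": expected ", n_samp + 1L, " fields, got ",
         lengths(rows)[bad[1]])
  genes <- vapply(rows, `[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1L]), numeric(n_samp)))
  raw <- vapply(rows, function(r) r[-1L], character(n_samp))
  if (any(is.na(vals) & !(raw %in% c("NA", "NaN"))))
    stop("line ", which(apply(is.na(vals) & !(raw %in% c("NA", "NaN")), 2, any))[1] + 2L,
         ": non-numeric expression value")
  mat <- t(vals)
  dimnames(mat) <- list(genes, hdr[-1L])
  expression_dataset(mat, factor(grp[-1L], levels = unique(grp[-1L])))
}

#' Write / read ChIP probe tables as TSV
#'
#' Columns: probe, replicate, input, ip, gene.
#'
#' @param probes probe data.frame (as from [gen_chip()]).
#' @param path TSV file path.
#' @return the path, or the parsed data.frame.
#' @export
write_probe_tsv <- function(probes, path) {
  stopifnot(all(c("probe", "replicate", "input", "ip", "gene") %in% names(probes)))
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(c("probe\treplicate\tinput\tip\tgene",
               sprintf("%s\t%d\t%.10g\t%.10g\t%s", probes$probe,
                       as.integer(probes$replicate), probes$input, probes$ip,
                       probes$gene)), con, sep = "\n")
  invisible(path)
}

#' @rdname write_probe_tsv
#' @export
read_probe_tsv <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  if (length(lines) && lines[length(lines)] == "") lines <- lines[-length(lines)]
  if (lines[1] != "probe\treplicate\tinput\tip\tgene")
    stop("line 1: unexpected probe TSV header in ", path)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 5L)
  if (length(bad)) stop("line ", bad[1] + 1L, ": expected 5 fields")
  out <- data.frame(probe = vapply(rows, `[`, character(1), 1L),
                    replicate = as.integer(vapply(rows, `[`, character(1), 2L)),
                    input = as.numeric(vapply(rows, `[`, character(1), 3L)),
                    ip = as.numeric(vapply(rows, `[`, character(1), 4L)),
                    gene = vapply(rows, `[`, character(1), 5L),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$input) | is.na(out$ip) | is.na(out$replicate)))
    stop("line ", which(is.na(out$input) | is.na(out$ip) | is.na(out$replicate))[1] + 1L,
         ": non-numeric probe values")
  out
}

#' Write / read FASTA sequence sets
#' @param seqs named character vector.
#' @param path FASTA file.
#' @return the path, or the named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Write / read a transcriptional module as JSON
#' @param m [build_btm()] result.
#' @param path JSON file.
#' @return the path, or the restored module object.
#' @export
write_module_json <- function(m, path) {
  stopifnot(inherits(m, "transcriptional_module"))
  jsonlite::write_json(list(species = m$species, tf = m$tf,
                            members = m$members, flags = m$flags),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_module_json
#' @export
read_module_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  f <- x$flags
  build_btm(f$gene[f$step1_up], f$gene[f$step2_dependent],
            f$gene[f$step3_bound], f$gene, species = x$species, tf = x$tf)
}

#' Write a motif report (candidates or retained set) as TSV
#' @param candidates candidate data.frame.
#' @param path TSV file.
#' @return the path.
#' @export
write_motif_report <- function(candidates, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(c(paste(names(candidates), collapse = "\t"),
               do.call(sprintf, c(list(
                 fmt = paste(rep("%s", ncol(candidates)), collapse = "\t")),
                 lapply(candidates, function(col)
                   if (is.numeric(col)) format(col, digits = 10, trim = TRUE)
                   else as.character(col))))),
             con, sep = "\n")
  invisible(path)
}

# ---- the end-to-end synthetic run -------------------------------------------

.stage <- function(manifest, name, counts) {
  manifest$stages[[name]] <- c(list(status = "ok"), counts)
  manifest
}

#' Run the full synthetic pipeline
#'
#' Generates every synthetic input from the run configuration, executes the
#' four integration steps (condition up-regulation, TF dependence, promoter
#' binding, Boolean integration), then the cross-species comparison, motif
#' discovery and contact stages, and writes all outputs plus a manifest under
#' `cfg$out_dir`. Rerunning the same configuration reproduces byte-identical
#' outputs.
#'
#' @param cfg [run_config()].
#' @return the manifest (invisibly written as `manifest.json`): per-stage
#'   counts, thresholds, seeds and input hashes.
#' @export
run_all <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- cfg$sim
  manifest <- list(seed = sim$seed, thresholds = unclass(cfg)[
    setdiff(names(unclass(cfg)), c("sim", "out_dir"))],
    stages = list(), hashes = list())
  withCallingHandlers({
    # Step 1: condition-responsive up-regulated genes
    ben <- gen_expression(sim, "benomyl")
    write_expression_tsv(ben$dataset, file.path(cfg$out_dir, "expr_benomyl.tsv"))
    de1 <- call_de_genes(ben$dataset, n_perm = cfg$n_perm, seed = sim$seed,
                         min_agree = cfg$min_agree, direction = "up")
    step1 <- de1$consensus$genes
    manifest <- .stage(manifest, "step1_up",
                       list(n_genes = sim$n_genes, n_called = length(step1)))
    # Step 2: TF-dependent genes from the deletion-strain comparison
    mut <- gen_expression(sim, "mutant")
    write_expression_tsv(mut$dataset, file.path(cfg$out_dir, "expr_mutant.tsv"))
    de2 <- call_de_genes(mut$dataset, n_perm = cfg$n_perm, seed = sim$seed + 1L,
                         min_agree = cfg$min_agree, direction = "up")
    step2 <- de2$consensus$genes
    manifest <- .stage(manifest, "step2_dependent",
                       list(n_called = length(step2)))
    # Step 3: promoter binding (mixture classification AND ratio enrichment)
    chip <- gen_chip(sim)
    write_probe_tsv(chip$probes, file.path(cfg$out_dir, "chip_probes.tsv"))
    fit <- fit_mixture(chip$probes, seed = sim$seed + 2L)
    mix_set <- classify_probes(fit, alpha = cfg$alpha)
    ratio_set <- ratio_enrichment(chip$probes, n_perm = cfg$n_perm,
                                  seed = sim$seed + 3L,
                                  min_agree = cfg$min_agree)
    step3 <- binding_consensus(mix_set, ratio_set,
                               unique(chip$probes[, c("probe", "gene")]))
    manifest <- .stage(manifest, "step3_bound",
                       list(n_mix = length(mix_set), n_ratio = length(ratio_set),
                            n_genes_bound = length(step3),
                            pi_hat = fit$pi, degenerate = fit$degenerate))
    # Step 4: integration
    universe <- rownames(ben$dataset$mat)
    btm <- build_btm(step1, step2, step3, universe)
    write_module_json(btm, file.path(cfg$out_dir, "module.json"))
    manifest <- .stage(manifest, "step4_module",
                       list(n_members = length(btm$members)))
    # motif stage on the promoters of the truth module (planted sites)
    truth_module <- intersect(ben$truth$de_genes, mut$truth$de_genes)
    prom_ids <- universe[seq_len(min(sim$n_promoters, length(universe)))]
    module_ids <- intersect(truth_module, prom_ids)
    prom <- gen_promoters(sim, motif = "TTASTAA", module_ids = module_ids,
                          ids = prom_ids)
    write_fasta(prom$promoters, file.path(cfg$out_dir, "promoters.fasta"))
    mot <- discover_motifs(prom$promoters[module_ids],
                           prom$promoters[setdiff(prom_ids, module_ids)],
                           seed = sim$seed + 4L, p_cut = cfg$motif_p,
                           min_len = cfg$motif_min_len,
                           max_ambig = cfg$motif_max_ambig,
                           min_algos = cfg$motif_min_algos)
    write_motif_report(mot$retained, file.path(cfg$out_dir, "motifs_retained.tsv"))
    manifest <- .stage(manifest, "motifs",
                       list(n_candidates = nrow(mot$candidates),
                            n_retained = nrow(mot$retained),
                            n_consensus = length(mot$consensus),
                            consensus = vapply(mot$consensus, `[[`,
                                               character(1), "consensus")))
    # cross-species comparison on a synthetic proteome pair
    pro <- gen_proteomes(sim, n_families = 40L, rewire_fraction = 0.1)
    links <- homology_links(pro$proteome_a, pro$proteome_b,
                            e_max = cfg$homology_e, min_len = cfg$homology_len,
                            min_ident = cfg$homology_ident)
    orthos <- rbh_orthologs(links)
    mA <- pro$truth$ortholog_pairs$a[seq_len(min(12L, nrow(pro$truth$ortholog_pairs)))]
    mB <- pro$truth$ortholog_pairs$b[seq_len(min(12L, nrow(pro$truth$ortholog_pairs)))]
    ov <- module_overlap(mA, mB, orthos, names(pro$proteome_a),
                         names(pro$proteome_b), n_perm = 2000L,
                         seed = sim$seed + 5L)
    manifest <- .stage(manifest, "xspecies",
                       list(n_links = nrow(links), n_orthologs = nrow(orthos),
                            overlap = ov$count, overlap_percent = ov$percent,
                            p_perm = ov$p_perm, p_hyper = ov$p_hyper))
    # contact stage on a toy complex
    plan <- data.frame(
      resname = c("ARG", "LYS", "GLN", "ASN", "ARG"),
      atom = c("NH1", "NZ", "NE2", "ND2", "NH2"),
      dna_atom = c("OP1", "OP2", "N7", "O6", "OP1"),
      distance = c(3.0, 2.8, 3.0, 3.2, 2.9),
      class = c("salt_bridge", "salt_bridge", "hydrogen_bond",
                "hydrogen_bond", "salt_bridge"),
      stringsAsFactors = FALSE)
    cx <- gen_complex(plan, file.path(cfg$out_dir, "toy_complex.pdb"))
    sc <- parse_complex(cx$path)
    found <- find_contacts(sc, dmin = cfg$contact_dmin, dmax = cfg$contact_dmax)
    manifest <- .stage(manifest, "contacts",
                       list(n_contacts = nrow(found),
                            classes = as.list(table(found$class))))
  }, error = function(e) {
    stop("pipeline halted: ", conditionMessage(e), call. = FALSE)
  })
  outputs <- list.files(cfg$out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest$hashes <- as.list(setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
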