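# End-to-end orchestration: conservation census -> estimator consensus ->
# group-entropy scan -> evolutionary trace -> bootstrap NJ tree -> motif
# presence -> cross-method summary, with a provenance manifest. Every
# number in the report comes from one module call; the pipeline only
# formats.

#' Run the full group-conservation analysis
#'
#' @param aln A [prot_aln()] alignment, or a path to an aligned FASTA /
#'   MSF file.
#' @param partition A [group_partition()], or a path to a two-column group
#'   table.
#' @param out_dir Output directory (created if missing).
#' @param gent A [gent_params()] object.
#' @param estimators Estimator names to sweep (default all six).
#' @param top_fraction Identification fraction per estimator run.
#' @param patterns Optional motif patterns (list of [parse_motif()]
#'   results or a motif file path).
#' @param n_bootstrap Bootstrap replicates for the NJ tree (default 100;
#'   0 skips the tree stage).
#' @param trace_P Subgroup count for the evolutionary trace (default 4).
#' @param identity_threshold Census threshold used for the cross-method
#'   flag (default 60).
#' @param k_common Minimum number of flagging methods/groups for the
#'   common-positions table (default 4).
#' @param seed Integer seed for the bootstrap stage.
#' @return Invisibly, a list with the per-stage tables, the cross-method
#'   `summary`, the `common` positions table and the manifest. All tables
#'   are also written as TSVs under `out_dir` (floats at 3 decimals), the
#'   trees as Newick, the manifest as JSON.
#' @export
run_pipeline <- function(aln, partition, out_dir,
                         gent = gent_params(mode = "top_k"),
                         estimators = ESTIMATOR_NAMES,
                         top_fraction = 0.05,
                         patterns = NULL, n_bootstrap = 100L,
                         trace_P = 4L, identity_threshold = 60,
                         k_common = 4L, seed = 1L) {
  cfg <- list(top_fraction = top_fraction, n_bootstrap = n_bootstrap,
              trace_P = trace_P, identity_threshold = identity_threshold,
              k_common = k_common, seed = seed,
              gent = gent[setdiff(names(gent), "q")],
              estimators = estimators)
  inputs <- character()
  if (is.character(aln)) {
    inputs["alignment"] <- aln
    aln <- if (grepl("\\.msf$", aln, ignore.case = TRUE)) read_msf(aln)
           else read_fasta_alignment(aln)
  }
  if (is.character(partition)) {
    inputs["groups"] <- partition
    partition <- read_groups(partition)
  }
  validate_partition(partition, aln)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[groupcons] %-12s ...", name))
    out <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[groupcons] %-12s done (%.1fs)", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  census <- stage("conserve", conservation_census(aln))
  simil <- stage("similarity", similarity_census(aln))
  consensus <- stage("score", {
    lapply(stats::setNames(estimators, estimators), function(me)
      consensus_identified(aln, me, top_fraction = top_fraction))
  })
  gent_tab <- stage("gent", gent_scan(aln, partition, gent))
  dist_mat <- stage("distances", jtt_distance_matrix(aln))
  trace_tab <- stage("trace", {
    part <- partition_tree(upgma_dendrogram(dist_mat), trace_P)
    trace_residues(aln, part)
  })
  trees <- NULL
  if (n_bootstrap > 0L) {
    trees <- stage("tree", {
      nj_tree <- neighbor_joining(dist_mat)
      boots <- bootstrap_trees(aln, n = n_bootstrap, seed = seed)
      list(nj = nj_tree, consensus = majority_consensus(boots))
    })
  }
  motif_tab <- NULL
  if (!is.null(patterns)) {
    if (is.character(patterns)) {
      inputs["motifs"] <- patterns
      patterns <- read_motifs(patterns)
    }
    motif_tab <- stage("motif", motif_presence(aln, partition, patterns))
  }

  # cross-method flags per column
  flags <- data.frame(index = seq_len(aln$L))
  flags$identity <- census$table$percent >= identity_threshold
  for (me in names(consensus))
    flags[[me]] <- flags$index %in% consensus[[me]]
  for (g in partition$groups) {
    sel <- gent_tab$index[gent_tab$group == g & gent_tab$selected]
    flags[[paste0("gent_", g)]] <- flags$index %in% sel
  }
  flags$trace <- trace_tab$group_specific
  n_methods <- rowSums(flags[, -1, drop = FALSE])
  summary_tab <- cbind(flags, n_methods = n_methods)
  common <- summary_tab[summary_tab$n_methods >= k_common, , drop = FALSE]
  common <- common[order(-common$n_methods, common$index), ]

  write_tsv <- function(tab, name) {
    num <- vapply(tab, is.double, TRUE)
    tab[num] <- lapply(tab[num], function(x) formatC(x, digits = 3,
                                                     format = "f"))
    utils::write.table(tab, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(census$table, "conservation.tsv")
  write_tsv(simil, "similarity.tsv")
  write_tsv(gent_tab, "gent.tsv")
  write_tsv(trace_tab, "trace.tsv")
  write_tsv(summary_tab, "summary.tsv")
  write_tsv(common, "common_positions.tsv")
  cons_df <- data.frame(
    method = rep(names(consensus), lengths(consensus)),
    index = unlist(consensus), row.names = NULL)
  write_tsv(cons_df, "estimator_consensus.tsv")
  if (!is.null(trees)) {
    write_newick(trees$nj, file.path(out_dir, "nj.nwk"))
    write_newick(trees$consensus, file.path(out_dir, "consensus.nwk"))
  }
  if (!is.null(motif_tab)) write_tsv(motif_tab, "motif.tsv")

  manifest <- version_manifest(cfg, inputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(census = census, similarity = simil,
                 consensus = consensus, gent = gent_tab,
                 trace = trace_tab, trees = trees, motifs = motif_tab,
                 summary = summary_tab, common = common,
                 manifest = manifest))
}

#' Provenance manifest for a pipeline run
#'
#' Records the package version, R version, a hash of the configuration,
#' the seed, input file checksums and a timestamp.
#'
#' @param config Named list of pipeline parameters.
#' @param inputs Named character vector of input file paths (optional).
#' @return Named list.
#' @export
version_manifest <- function(config = list(), inputs = character()) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  cfg_hash <- unname(tools::md5sum(tf))
  checksums <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  list(tool = "groupcons",
       version = as.character(utils::packageVersion("groupcons")),
       r_version = R.version.string,
       config = config,
       config_hash = cfg_hash,
       input_checksums = checksums,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
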