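# End-to-end orchestration over multiple conditions and replicates, with a
# provenance record and deterministic, regenerable outputs.

#' Run configuration
#'
#' @param genome_fasta,annotation_gff Input paths.
#' @param conditions Named list; each element a character vector of
#'   replicate FASTQ paths (at least 1 condition with at least 1 replicate).
#' @param processing A [processing_config].
#' @param classifier A [classifier_config].
#' @param out_dir Output directory, or `NULL` for in-memory results only.
#' @param topology Replicon topology passed to [load_genome].
#' @param both_orientations Duplicate-site detection toggle (see
#'   [mark_duplicated_sites]).
#' @param log Emit progress messages to stderr.
#' @return list of class `tn_run_config`.
#' @export
run_config <- function(genome_fasta, annotation_gff, conditions,
                       processing = processing_config(),
                       classifier = classifier_config(),
                       out_dir = NULL, topology = "circular",
                       both_orientations = TRUE, log = TRUE) {
  stopifnot(length(conditions) >= 1L, !is.null(names(conditions)),
            all(lengths(conditions) >= 1L))
  structure(list(genome_fasta = genome_fasta,
                 annotation_gff = annotation_gff,
                 conditions = conditions, processing = processing,
                 classifier = classifier, out_dir = out_dir,
                 topology = topology,
                 both_orientations = both_orientations, log = log),
            class = "tn_run_config")
}

#' Load a run configuration from a YAML or JSON file
#'
#' Scalar fields mirror the [run_config] arguments; `processing` and
#' `classifier` are nested maps of the respective constructor arguments.
#'
#' @param path YAML/JSON file.
#' @return A `tn_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pc <- do.call(processing_config, as.list(y$processing))
  cc <- do.call(classifier_config, as.list(y$classifier))
  conditions <- lapply(y$conditions, unlist)
  run_config(genome_fasta = y$genome_fasta,
             annotation_gff = y$annotation_gff,
             conditions = conditions, processing = pc, classifier = cc,
             out_dir = y$out_dir,
             topology = if (is.null(y$topology)) "circular" else y$topology,
             both_orientations = !isFALSE(y$both_orientations),
             log = !isFALSE(y$log))
}

.log <- function(enabled, ...) if (enabled) message("[tnseqr] ", ...)

.stage <- function(what, condition, replicate, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed (condition '%s', replicate %s): %s",
                 what, condition, replicate, conditionMessage(e)),
         call. = FALSE))
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL   # analytic parameters only: identical analyses
  cfg$log <- NULL       # hash identically wherever outputs land
  cfg <- rapply(cfg, unclass, how = "replace")
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full Tn-seq essentiality pipeline
#'
#' Loads genome and annotation, enumerates and flags TA sites, processes and
#' maps every replicate FASTQ, tabulates and normalizes per-gene counts,
#' classifies essentiality per replicate with replicate consensus per
#' condition, and computes cross-condition summaries (per-condition category
#' counts, core essential genome, UpSet membership patterns). Deterministic
#' given inputs and configuration; when `out_dir` is set, all tables are
#' written as TSV with header comments carrying the configuration hash, plus
#' a provenance JSON.
#'
#' @param config A `tn_run_config` (or path to a YAML/JSON run file).
#' @return list of class `tn_run`: `genome_stats`, `ta_index`, `profiles`,
#'   `stats` (per condition/replicate processing and mapping stats), `calls`
#'   (named list of `tn_calls`), `summary`, `core_essential`, `membership`,
#'   `provenance`.
#' @export
run_tnseq <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "tn_run_config"))
  lg <- config$log

  .log(lg, "loading genome and annotation")
  genome <- load_genome(config$genome_fasta, topology = config$topology)
  genes <- load_annotation(config$annotation_gff, genome)
  ta <- enumerate_ta_sites(genome)
  ta <- mark_duplicated_sites(ta, config$both_orientations)
  profiles <- apply_gene_filters(gene_ta_profile(genes, ta))
  idx <- build_index(genome, ta,
                     lengths = seq(config$processing$min_insert_len,
                                   config$processing$max_insert_len))

  calls <- list()
  stats <- list()
  for (cond in names(config$conditions)) {
    paths <- config$conditions[[cond]]
    counts_list <- vector("list", length(paths))
    stats[[cond]] <- vector("list", length(paths))
    for (r in seq_along(paths)) {
      .log(lg, cond, " replicate ", r, ": processing ", basename(paths[r]))
      proc <- .stage("process", cond, r,
                     process_fastq(paths[r], config$processing))
      mapped <- .stage("map", cond, r, map_inserts(proc$inserts, idx))
      tab <- .stage("tally", cond, r, tally_insertions(mapped))
      counts_list[[r]] <- .stage("tabulate", cond, r,
                                 tabulate_genes(tab, genes, ta, profiles))
      stats[[cond]][[r]] <- list(processing = proc$stats,
                                 mapping = tab$totals)
    }
    .log(lg, cond, ": classifying")
    calls[[cond]] <- .stage("classify", cond, "all",
                            classify_replicates(counts_list,
                                                config$classifier,
                                                condition = cond))
  }

  summary <- summarize_conditions(calls)
  core <- if (length(calls) >= 2L) core_essential(calls) else
    essential_set(calls[[1L]])
  membership <- membership_matrix(calls)
  provenance <- list(
    package = "tnseqr",
    version = as.character(utils::packageVersion("tnseqr")),
    config_hash = .config_hash(config),
    both_orientations = config$both_orientations,
    thresholds = unclass(config$classifier),
    processing = unclass(config$processing),
    n_conditions = length(calls),
    timestamp = NULL)

  res <- structure(list(genome_stats = genome_stats(genome), ta_index = ta,
                        profiles = profiles, stats = stats, calls = calls,
                        summary = summary, core_essential = core,
                        membership = membership, provenance = provenance),
                   class = "tn_run")

  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    meta <- list(config_hash = provenance$config_hash,
                 tnseqr = provenance$version)
    write_ta_sites(ta, file.path(od, "ta_sites.tsv"), meta)
    write_gene_ta_profile(profiles, file.path(od, "gene_ta_profile.tsv"),
                          meta)
    for (cond in names(calls))
      write_calls(calls[[cond]],
                  file.path(od, paste0("calls_", cond, ".tsv")), meta)
    .write_tsv(summary, file.path(od, "summary.tsv"), meta)
    write_membership(membership, file.path(od, "upset.tsv"), meta)
    writeLines(core, file.path(od, "core_essential.txt"))
    jsonlite::write_json(provenance, file.path(od, "provenance.json"),
                         auto_unbox = TRUE, force = TRUE, digits = NA)
  }
  res
}

#' @export
print.tn_run <- function(x, ...) {
  cat("tn_run across", length(x$calls), "condition(s)\n")
  print(x$summary)
  cat("core essential genes:", length(x$core_essential), "\n")
  invisible(x)
}
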