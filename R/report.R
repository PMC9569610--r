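#' Annotate a cohort's calls for curation
#'
#' Adds patient metadata, read evidence levels, partner distance,
#' intrachromosomal status and (when a gene model is given) breakpoint
#' border classes to every call of a cohort.
#'
#' @param cohort a [fusion_cohort()] with mapping statistics.
#' @param model optional `gene_model` for border classification.
#' @return Annotated call tibble.
#' @export
annotate_cohort <- function(cohort, model = NULL) {
  calls <- ensure_call_id(cohort$calls)
  calls <- dplyr::left_join(
    calls, cohort$samples[c("sample_id", "patient_id", "disease")],
    by = "sample_id"
  )
  if (is.null(cohort$mapping_stats)) {
    abort("cohort has no mapping statistics; evidence levels undefined")
  }
  calls <- add_evidence_levels(calls, cohort$mapping_stats)
  calls$partner_distance <- partner_distance(calls)
  calls$intrachromosomal <- is_intrachromosomal(calls)
  if (!is.null(model)) {
    calls <- classify_calls(calls, model)
  }
  calls
}

#' Render an evidence report from a plain table
#'
#' Reads a tab-separated table carrying at least `five_gene`, `three_gene`,
#' `spanning_pairs`, `spanning_unique_reads` and
#' `total_uniquely_mapped_reads` (plus optional `patient_id`, point and
#' border columns), recomputes the read evidence level for every row and
#' writes the curated layout with evidence printed to two decimals.
#'
#' @param table_path input table path.
#' @param out_path output path.
#' @return The output tibble, invisibly.
#' @export
render_report <- function(table_path, out_path) {
  raw <- readr::read_tsv(table_path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("five_gene", "three_gene", "spanning_pairs",
            "spanning_unique_reads", "total_uniquely_mapped_reads")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(sprintf("report input '%s' lacks column(s): %s",
                  table_path, paste(missing, collapse = ", ")))
  }
  num <- function(x) as.numeric(gsub(",", "", x))
  out <- tibble::tibble(
    patient_id = raw$patient_id %||% NA_character_,
    five_gene = raw$five_gene,
    three_gene = raw$three_gene,
    spanning_pairs = as.integer(num(raw$spanning_pairs)),
    spanning_unique_reads = as.integer(num(raw$spanning_unique_reads)),
    read_evidence_level = sprintf("%.2f", read_evidence_level(
      num(raw$spanning_pairs), num(raw$spanning_unique_reads),
      num(raw$total_uniquely_mapped_reads)
    ))
  )
  for (col in c("five_point", "five_border", "three_point", "three_border")) {
    if (col %in% names(raw)) out[[col]] <- raw[[col]]
  }
  readr::write_tsv(out, out_path, progress = FALSE)
  invisible(out)
}

.cli_usage <- paste(
  "usage: fusiontriage <subcommand> [options]",
  "subcommands:",
  "  simulate       generate a synthetic cohort with planted truth",
  "  score          annotate a cohort directory and write the curated table",
  "  prioritize     run the filter/prioritization cascade with an audit log",
  "  recur          screen a cohort for recurrent secondary fusions",
  "  qpcr-validate  validate dilution series and confirm plate assays",
  "  report         recompute evidence levels for a plain candidate table",
  sep = "\n"
)

.cli_options <- function(subcommand) {
  o <- optparse::make_option
  common <- list(
    o("--config", type = "character", default = NULL,
      help = "YAML config file with per-subcommand sections"),
    o("--seed", type = "integer", default = NULL, help = "random seed")
  )
  extra <- switch(subcommand,
    simulate = list(
      o("--out", type = "character", default = NULL, help = "output directory"),
      o("--patients", type = "integer", default = NULL, help = "number of patients"),
      o("--genome", action = "store_true", default = FALSE,
        help = "also write a toy genome FASTA")
    ),
    score = list(
      o("--dir", type = "character", default = NULL, help = "cohort directory"),
      o("--gtf", type = "character", default = NULL, help = "gene model GTF"),
      o("--out", type = "character", default = NULL, help = "curated table path")
    ),
    prioritize = list(
      o("--dir", type = "character", default = NULL, help = "cohort directory"),
      o("--gtf", type = "character", default = NULL, help = "gene model GTF"),
      o("--catalog", type = "character", default = NULL,
        help = "pathognomonic catalog TSV (default: bundled sarcoma catalog)"),
      o("--literature", type = "character", default = NULL,
        help = "file with one literature gene symbol per line"),
      o("--out", type = "character", default = NULL, help = "decision table path"),
      o("--log", type = "character", default = NULL, help = "audit log path")
    ),
    recur = list(
      o("--dir", type = "character", default = NULL, help = "cohort directory"),
      o("--gtf", type = "character", default = NULL, help = "gene model GTF"),
      o("--catalog", type = "character", default = NULL, help = "catalog TSV"),
      o("--out", type = "character", default = NULL, help = "recurrence table path")
    ),
    `qpcr-validate` = list(
      o("--plate", type = "character", default = NULL, help = "plate table"),
      o("--dilutions", type = "character", default = NULL, help = "dilution table"),
      o("--out-prefix", type = "character", default = "qpcr", dest = "out_prefix",
        help = "output prefix for <prefix>_validation.tsv / <prefix>_confirmation.tsv")
    ),
    report = list(
      o("--table", type = "character", default = NULL, help = "input table"),
      o("--out", type = "character", default = NULL, help = "output table")
    ),
    abort(sprintf("unknown subcommand '%s'\n%s", subcommand, .cli_usage))
  )
  c(common, extra)
}

.cli_require <- function(opts, keys) {
  for (k in keys) {
    if (is.null(opts[[k]])) {
      abort(sprintf("missing required flag --%s", gsub("_", "-", k)))
    }
  }
}

.cli_merge_config <- function(opts, subcommand) {
  if (is.null(opts$config)) {
    return(opts)
  }
  if (!file.exists(opts$config)) {
    abort(sprintf("config file not found: %s", opts$config))
  }
  section <- yaml::read_yaml(opts$config)[[subcommand]]
  for (k in names(section)) {
    if (is.null(opts[[k]])) opts[[k]] <- section[[k]]
  }
  opts
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `score`, `prioritize`, `recur`,
#' `qpcr-validate` and `report` subcommands; see the `exec/fusiontriage`
#' script for shell use. Flags override values from the optional YAML config
#' file (one section per subcommand). Errors are reported on stderr and
#' turn into a non-zero exit status.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
fusiontriage_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
      message(.cli_usage)
      return(invisible(0L))
    }
    subcommand <- args[1]
    parser <- optparse::OptionParser(
      option_list = .cli_options(subcommand),
      prog = paste("fusiontriage", subcommand)
    )
    opts <- optparse::parse_args(parser, args = args[-1])
    opts <- .cli_merge_config(opts, subcommand)
    switch(subcommand,
      simulate = .cli_simulate(opts),
      score = .cli_score(opts),
      prioritize = .cli_prioritize(opts),
      recur = .cli_recur(opts),
      `qpcr-validate` = .cli_qpcr(opts),
      report = .cli_report(opts)
    )
    0L
  }, error = function(e) {
    message("fusiontriage: error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.cli_simulate <- function(opts) {
  .cli_require(opts, "out")
  cfg <- simulation_config(
    n_patients = opts$patients %||% 17,
    seed = opts$seed %||% 1L
  )
  sim <- simulate_cohort(cfg, dir = opts$out, write_genome = isTRUE(opts$genome))
  message(sprintf("simulate: wrote %d samples, %d calls to %s",
                  nrow(sim$cohort$samples), nrow(sim$cohort$calls), opts$out))
}

.cli_load_cohort <- function(opts) {
  .cli_require(opts, "dir")
  if (!dir.exists(opts$dir)) {
    abort(sprintf("cohort directory not found: %s", opts$dir))
  }
  read_cohort_dir(opts$dir)
}

.cli_model <- function(opts) {
  if (is.null(opts$gtf)) {
    return(NULL)
  }
  if (!file.exists(opts$gtf)) abort(sprintf("GTF not found: %s", opts$gtf))
  read_gene_model(opts$gtf)
}

.cli_catalog <- function(opts) {
  if (is.null(opts$catalog)) {
    default_pathognomonic_catalog()
  } else {
    read_pathognomonic_catalog(opts$catalog)
  }
}

.cli_score <- function(opts) {
  .cli_require(opts, "out")
  cohort <- .cli_load_cohort(opts)
  model <- .cli_model(opts)
  ann <- annotate_cohort(cohort, model)
  if (is.null(model)) {
    ann$five_border <- "unclassified"
    ann$three_border <- "unclassified"
  }
  write_curated_table(ann, opts$out)
  message(sprintf("score: wrote %d annotated calls to %s", nrow(ann), opts$out))
}

.cli_prioritize <- function(opts) {
  .cli_require(opts, "out")
  cohort <- .cli_load_cohort(opts)
  catalog <- .cli_catalog(opts)
  lit <- if (is.null(opts$literature)) character() else readLines(opts$literature)
  config <- filter_config(literature_genes = trimws(lit),
                          pathognomonic_catalog = catalog)
  positives <- unique(unlist(lapply(cohort$samples$sample_id, function(sid) {
    dis <- cohort$samples$disease[cohort$samples$sample_id == sid]
    hits <- detect_pathognomonic(cohort$calls[cohort$calls$sample_id == sid, ],
                                 dis, catalog)
    if (nrow(hits)) cohort$samples$patient_id[cohort$samples$sample_id == sid]
  })))
  decisions <- filter_novel_candidates(cohort, positives, config)
  out <- decisions
  out$reasons <- vapply(out$reasons, paste, "", collapse = ";")
  out$flags <- vapply(out$flags, paste, "", collapse = ",")
  readr::write_tsv(out, opts$out, progress = FALSE)
  log_lines <- c(
    sprintf("pathognomonic-positive patients: %s",
            paste(positives %||% "none", collapse = ",")),
    sprintf("%s\t%s\t%s->%s\t%s", out$status, out$call_id,
            out$five_gene, out$three_gene,
            ifelse(nzchar(out$reasons), out$reasons, "-"))
  )
  if (!is.null(opts$log)) writeLines(log_lines, opts$log) else message(
    sprintf("prioritize: %d retained / %d excluded",
            sum(decisions$status == "retained"),
            sum(decisions$status == "excluded")))
}

.cli_recur <- function(opts) {
  .cli_require(opts, "out")
  cohort <- .cli_load_cohort(opts)
  config <- filter_config(pathognomonic_catalog = .cli_catalog(opts))
  model <- .cli_model(opts)
  rec <- recurrence_screen(cohort, config, model)
  flat <- recurrence_table(rec, cohort$mapping_stats)
  if (nrow(flat)) flat$flags <- vapply(flat$flags, paste, "", collapse = ",")
  readr::write_tsv(flat, opts$out, progress = FALSE)
  message(sprintf("recur: %d recurrent pair(s)", nrow(rec)))
}

.cli_qpcr <- function(opts) {
  .cli_require(opts, c("plate", "dilutions"))
  for (f in c(opts$plate, opts$dilutions)) {
    if (!file.exists(f)) abort(sprintf("input not found: %s", f))
  }
  dil <- read_dilution_table(opts$dilutions)
  plate <- read_plate_table(opts$plate)
  config <- qpcr_config()
  val <- validate_assays(dil, config)
  conf <- confirm_plate(plate, config)
  readr::write_tsv(val, paste0(opts$out_prefix, "_validation.tsv"), progress = FALSE)
  readr::write_tsv(conf, paste0(opts$out_prefix, "_confirmation.tsv"), progress = FALSE)
  message(sprintf("qpcr-validate: %d assay(s) validated, %d confirmed",
                  sum(val$valid), sum(conf$status == "confirmed")))
}

.cli_report <- function(opts) {
  .cli_require(opts, c("table", "out"))
  if (!file.exists(opts$table)) {
    abort(sprintf("input table not found: %s", opts$table))
  }
  out <- render_report(opts$table, opts$out)
  message(sprintf("report: wrote %d rows to %s", nrow(out), opts$out))
}
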