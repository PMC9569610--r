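#' Canonical fusion-table column mapping
#'
#' Maps the internal call fields onto the header names of the caller's
#' final-list table (the FusionCatcher dialect). Pass a modified copy to
#' [read_fusion_table()] to ingest other dialects.
#'
#' @return Named character vector: internal field -> file column header.
#' @export
fusion_table_columns <- function() {
  c(
    five_gene = "Gene_1_symbol(5end_fusion_partner)",
    three_gene = "Gene_2_symbol(3end_fusion_partner)",
    five_point = "Fusion_point_for_gene_1(5end_fusion_partner)",
    three_point = "Fusion_point_for_gene_2(3end_fusion_partner)",
    spanning_pairs = "Spanning_pairs",
    spanning_unique_reads = "Spanning_unique_reads",
    common_mapping_reads = "Counts_of_common_mapping_reads",
    flags = "Fusion_description",
    predicted_effect = "Predicted_effect",
    fusion_sequence = "Fusion_sequence"
  )
}

# Fields that must be present in any dialect; the rest default with a warning.
.mandatory_fields <- c(
  "five_gene", "three_gene", "five_point", "three_point",
  "spanning_pairs", "spanning_unique_reads"
)

# Junction marker used inside predicted fusion sequences ("ACGT*ACGT").
junction_marker <- function() "*"

validate_fusion_calls <- function(calls) {
  counts <- c("spanning_pairs", "spanning_unique_reads", "common_mapping_reads")
  for (col in counts) {
    if (any(is.na(calls[[col]])) || any(calls[[col]] < 0)) {
      abort(sprintf("column '%s' must contain non-negative counts", col))
    }
  }
  if (any(calls$five_pos < 1) || any(calls$three_pos < 1)) {
    abort("fusion point positions must be >= 1")
  }
  n_marker <- lengths(regmatches(
    calls$fusion_sequence,
    gregexpr(junction_marker(), calls$fusion_sequence, fixed = TRUE)
  ))
  bad <- nzchar(calls$fusion_sequence) & n_marker != 1L
  if (any(bad)) {
    abort("fusion_sequence must be empty or contain exactly one junction marker")
  }
  invisible(calls)
}

#' Read a fusion-caller candidate table
#'
#' Reads one sample's candidate fusion transcripts from a tab-separated
#' final-list table. Fusion points are parsed from `chrom:pos:strand`
#' (thousands separators tolerated), the description column is split on
#' commas into a set of caller flags, and missing optional columns are
#' defaulted (0 counts, empty strings) with a warning.
#'
#' @param path path to the tab-separated table (UTF-8, header row).
#' @param sample_id sample identifier attached to every call.
#' @param columns header mapping, see [fusion_table_columns()].
#' @return A tibble with one row per candidate call and columns `sample_id`,
#'   `call_id`, `five_gene`, `three_gene`, `five_chrom`/`five_pos`/`five_strand`,
#'   `three_chrom`/`three_pos`/`three_strand`, `spanning_pairs`,
#'   `spanning_unique_reads`, `common_mapping_reads`, `flags` (list column of
#'   character vectors), `predicted_effect`, `fusion_sequence`.
#' @export
read_fusion_table <- function(path, sample_id, columns = fusion_table_columns()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  missing_mand <- .mandatory_fields[!columns[.mandatory_fields] %in% names(raw)]
  if (length(missing_mand)) {
    abort(sprintf(
      "fusion table '%s' is missing mandatory column(s): %s",
      path, paste(columns[missing_mand], collapse = ", ")
    ))
  }
  optional <- setdiff(names(columns), .mandatory_fields)
  absent <- optional[!columns[optional] %in% names(raw)]
  if (length(absent) && nrow(raw) > 0) {
    warn(sprintf(
      "fusion table '%s': optional column(s) absent, using defaults: %s",
      path, paste(columns[absent], collapse = ", ")
    ))
  }
  get_col <- function(field, default) {
    header <- columns[[field]]
    if (header %in% names(raw)) raw[[header]] else rep(default, nrow(raw))
  }
  n <- nrow(raw)
  if (n == 0) {
    return(empty_fusion_calls())
  }
  five <- tryCatch(parse_genomic_point(get_col("five_point", NA)),
    error = function(e) abort(sprintf("%s: 5' fusion point: %s", path, conditionMessage(e)))
  )
  three <- tryCatch(parse_genomic_point(get_col("three_point", NA)),
    error = function(e) abort(sprintf("%s: 3' fusion point: %s", path, conditionMessage(e)))
  )
  parse_count <- function(field) {
    x <- gsub(",", "", get_col(field, "0"))
    x[!nzchar(x)] <- "0"
    v <- suppressWarnings(as.integer(x))
    if (any(is.na(v))) {
      abort(sprintf("%s: non-integer value in column '%s' (line %d)",
                    path, columns[[field]], which(is.na(v))[1] + 1L))
    }
    v
  }
  flags_raw <- get_col("flags", "")
  flags <- lapply(strsplit(flags_raw, ",", fixed = TRUE), function(f) {
    f <- trimws(f)
    f[nzchar(f)]
  })
  calls <- tibble::tibble(
    sample_id = rep(sample_id, n),
    five_gene = get_col("five_gene", NA),
    three_gene = get_col("three_gene", NA),
    five_chrom = five$chrom, five_pos = five$pos, five_strand = five$strand,
    three_chrom = three$chrom, three_pos = three$pos, three_strand = three$strand,
    spanning_pairs = parse_count("spanning_pairs"),
    spanning_unique_reads = parse_count("spanning_unique_reads"),
    common_mapping_reads = parse_count("common_mapping_reads"),
    flags = flags,
    predicted_effect = get_col("predicted_effect", ""),
    fusion_sequence = get_col("fusion_sequence", "")
  )
  calls <- ensure_call_id(calls)
  validate_fusion_calls(calls)
  calls
}

empty_fusion_calls <- function() {
  tibble::tibble(
    sample_id = character(), five_gene = character(), three_gene = character(),
    five_chrom = character(), five_pos = numeric(), five_strand = character(),
    three_chrom = character(), three_pos = numeric(), three_strand = character(),
    spanning_pairs = integer(), spanning_unique_reads = integer(),
    common_mapping_reads = integer(), flags = list(),
    predicted_effect = character(), fusion_sequence = character(),
    call_id = character()
  )
}

#' Write a fusion call table in the caller dialect
#'
#' Inverse of [read_fusion_table()]; positions are written without thousands
#' separators, flags re-joined on commas.
#'
#' @param calls fusion call tibble.
#' @param path output path.
#' @export
write_fusion_table <- function(calls, path) {
  cols <- fusion_table_columns()
  out <- tibble::tibble(
    a = calls$five_gene, b = calls$three_gene,
    fl = vapply(calls$flags, paste, "", collapse = ","),
    cmr = calls$common_mapping_reads,
    sp = calls$spanning_pairs, su = calls$spanning_unique_reads,
    fp5 = format_genomic_point(calls$five_chrom, calls$five_pos, calls$five_strand),
    fp3 = format_genomic_point(calls$three_chrom, calls$three_pos, calls$three_strand),
    eff = calls$predicted_effect, seq = calls$fusion_sequence
  )
  names(out) <- unname(cols[c(
    "five_gene", "three_gene", "flags", "common_mapping_reads",
    "spanning_pairs", "spanning_unique_reads", "five_point", "three_point",
    "predicted_effect", "fusion_sequence"
  )])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read per-sample mapping statistics
#'
#' Two-column tab-separated table `sample_id`, `total_uniquely_mapped_reads`
#' (thousands separators tolerated). Duplicate sample ids and non-integer
#' totals are rejected.
#'
#' @param path path to the table.
#' @return Tibble with columns `sample_id`, `total_uniquely_mapped_reads`.
#' @export
read_mapping_stats <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("sample_id", "total_uniquely_mapped_reads")
  if (!all(need %in% names(raw))) {
    abort(sprintf("mapping statistics '%s' must have columns %s",
                  path, paste(need, collapse = ", ")))
  }
  if (anyDuplicated(raw$sample_id)) {
    abort(sprintf("duplicate sample id(s) in '%s': %s", path,
                  paste(unique(raw$sample_id[duplicated(raw$sample_id)]), collapse = ", ")))
  }
  tot_chr <- gsub(",", "", raw$total_uniquely_mapped_reads)
  tot <- suppressWarnings(as.numeric(tot_chr))
  if (any(is.na(tot)) || any(tot != floor(tot))) {
    abort(sprintf("non-integer total in '%s'", path))
  }
  tibble::tibble(sample_id = raw$sample_id, total_uniquely_mapped_reads = tot)
}

#' @rdname read_mapping_stats
#' @param stats tibble as returned by [read_mapping_stats()].
#' @export
write_mapping_stats <- function(stats, path) {
  out <- stats[c("sample_id", "total_uniquely_mapped_reads")]
  out$total_uniquely_mapped_reads <-
    sprintf("%d", as.integer(out$total_uniquely_mapped_reads))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write cohort sample metadata
#'
#' Tab-separated table with columns `sample_id`, `patient_id`, `tissue`
#' (`tumor` or `normal`), `disease`, `cohort` and optional `dv200` (percent
#' of RNA fragments > 200 nt, an FFPE RNA-quality metric).
#'
#' @param path path to the table.
#' @return Tibble of sample records.
#' @export
read_sample_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("sample_id", "patient_id", "tissue", "disease", "cohort")
  if (!all(need %in% names(raw))) {
    abort(sprintf("sample table '%s' must have columns %s",
                  path, paste(need, collapse = ", ")))
  }
  raw$dv200 <- if ("dv200" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$dv200))
  } else {
    NA_real_
  }
  if (any(!is.na(raw$dv200) & (raw$dv200 < 0 | raw$dv200 > 100))) {
    abort("dv200 must lie in [0, 100]")
  }
  tibble::as_tibble(raw[c(need, "dv200")])
}

#' @rdname read_sample_table
#' @param samples sample tibble.
#' @export
write_sample_table <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' Assemble a cohort
#'
#' Bundles sample metadata, mapping statistics and per-sample calls, checking
#' that every call belongs to a known sample and that (patient, tissue) pairs
#' are unique.
#'
#' @param samples sample tibble, see [read_sample_table()].
#' @param calls fusion call tibble covering all samples.
#' @param mapping_stats per-sample totals, see [read_mapping_stats()].
#' @return An object of class `fusion_cohort` (a list with elements
#'   `samples`, `calls`, `mapping_stats`).
#' @export
fusion_cohort <- function(samples, calls, mapping_stats = NULL) {
  orphan <- setdiff(unique(calls$sample_id), samples$sample_id)
  if (length(orphan)) {
    abort(sprintf("calls reference unknown sample(s): %s",
                  paste(orphan, collapse = ", ")))
  }
  key <- paste(samples$patient_id, samples$tissue)
  if (anyDuplicated(key)) {
    abort("duplicate (patient_id, tissue) pair in sample table")
  }
  structure(
    list(samples = samples, calls = ensure_call_id(calls),
         mapping_stats = mapping_stats),
    class = "fusion_cohort"
  )
}

#' @export
print.fusion_cohort <- function(x, ...) {
  cat(sprintf(
    "<fusion_cohort> %d samples / %d patients, %d candidate calls\n",
    nrow(x$samples), length(unique(x$samples$patient_id)), nrow(x$calls)
  ))
  invisible(x)
}

#' Read a cohort from a directory
#'
#' Expects `samples.tsv`, `mapping_stats.tsv` and one `<sample_id>.fusions.tsv`
#' per sample, the layout written by [simulate_cohort()] and the `simulate`
#' subcommand.
#'
#' @param dir directory path.
#' @return A `fusion_cohort`.
#' @export
read_cohort_dir <- function(dir) {
  samples <- read_sample_table(file.path(dir, "samples.tsv"))
  stats <- read_mapping_stats(file.path(dir, "mapping_stats.tsv"))
  calls <- dplyr::bind_rows(lapply(samples$sample_id, function(sid) {
    path <- file.path(dir, paste0(sid, ".fusions.tsv"))
    if (!file.exists(path)) {
      return(empty_fusion_calls())
    }
    read_fusion_table(path, sid)
  }))
  fusion_cohort(samples, calls, stats)
}

#' Write a curated fusion table
#'
#' Writes annotated calls in the curated report layout: partner genes,
#' spanning pairs, spanning unique reads, read evidence level (printed with
#' exactly two decimals) and fusion points with their exon-border classes.
#' Rows are sorted by (patient, descending evidence level, 5' gene, 3' gene)
#' so repeated runs produce identical diffs.
#'
#' @param calls call tibble annotated with `patient_id`,
#'   `read_evidence_level`, `five_border` and `three_border` columns.
#' @param path output path.
#' @export
write_curated_table <- function(calls, path) {
  need <- c("patient_id", "read_evidence_level", "five_border", "three_border")
  missing <- setdiff(need, names(calls))
  if (length(missing)) {
    abort(sprintf("calls lack annotation column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  ord <- order(calls$patient_id, -calls$read_evidence_level,
               calls$five_gene, calls$three_gene)
  calls <- calls[ord, ]
  out <- tibble::tibble(
    patient_id = calls$patient_id,
    sample_id = calls$sample_id,
    five_gene = calls$five_gene,
    three_gene = calls$three_gene,
    spanning_pairs = calls$spanning_pairs,
    spanning_unique_reads = calls$spanning_unique_reads,
    read_evidence_level = sprintf("%.2f", calls$read_evidence_level),
    five_point = sprintf("%s(%s)",
      format_genomic_point(calls$five_chrom, calls$five_pos, calls$five_strand),
      gsub("_", " ", calls$five_border)),
    three_point = sprintf("%s(%s)",
      format_genomic_point(calls$three_chrom, calls$three_pos, calls$three_strand),
      gsub("_", " ", calls$three_border))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a curated fusion table
#'
#' @param path path written by [write_curated_table()].
#' @return Tibble with parsed points and numeric evidence levels.
#' @export
read_curated_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  five <- parse_genomic_point(raw$five_point)
  three <- parse_genomic_point(raw$three_point)
  border_of <- function(x) {
    m <- regmatches(x, regexpr("\\(([^)]*)\\)$", x))
    gsub(" ", "_", substr(m, 2, nchar(m) - 1))
  }
  tibble::tibble(
    patient_id = raw$patient_id, sample_id = raw$sample_id,
    five_gene = raw$five_gene, three_gene = raw$three_gene,
    spanning_pairs = as.integer(raw$spanning_pairs),
    spanning_unique_reads = as.integer(raw$spanning_unique_reads),
    read_evidence_level = as.numeric(raw$read_evidence_level),
    five_chrom = five$chrom, five_pos = five$pos, five_strand = five$strand,
    five_border = border_of(raw$five_point),
    three_chrom = three$chrom, three_pos = three$pos, three_strand = three$strand,
    three_border = border_of(raw$three_point)
  )
}
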