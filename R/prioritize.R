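#' Filter configuration for the curation cascade
#'
#' Thresholds and reference sets used when filtering and prioritizing fusion
#' candidates:
#' * `min_partner_distance` — intrachromosomal calls whose fusion points are
#'   closer than this (bp) are treated as likely readthrough artifacts;
#'   the comparison is strict (`distance < threshold` excludes).
#' * `max_common_mapping_reads` — calls with more reads mapping to both
#'   partners simultaneously than this are likely paralog-driven artifacts;
#'   default 0, i.e. any common-mapping read excludes.
#' * `exclude_banned` — drop calls the upstream caller itself flagged
#'   as `banned`.
#' * `literature_genes` — gene symbols described as fusion partners or in
#'   the disease literature; candidate prioritization requires at least one
#'   partner in this set. A curated list, deliberately user-supplied.
#' * `pathognomonic_catalog` — tibble of disease-defining fusions, see
#'   [read_pathognomonic_catalog()].
#' * `require_exon_exon_for_qpcr` — restrict validation candidates to
#'   exon-exon border transcripts.
#'
#' @param min_partner_distance bp, default 100000.
#' @param max_common_mapping_reads count, default 0.
#' @param exclude_banned logical, default TRUE.
#' @param literature_genes character vector of gene symbols.
#' @param pathognomonic_catalog tibble with columns `disease`, `five_gene`,
#'   `three_gene`; default the bundled sarcoma catalog.
#' @param require_exon_exon_for_qpcr logical, default TRUE.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(min_partner_distance = 100000,
                          max_common_mapping_reads = 0,
                          exclude_banned = TRUE,
                          literature_genes = character(),
                          pathognomonic_catalog = default_pathognomonic_catalog(),
                          require_exon_exon_for_qpcr = TRUE) {
  if (min_partner_distance <= 0) abort("min_partner_distance must be positive")
  if (max_common_mapping_reads < 0) abort("max_common_mapping_reads must be >= 0")
  structure(
    list(
      min_partner_distance = min_partner_distance,
      max_common_mapping_reads = max_common_mapping_reads,
      exclude_banned = exclude_banned,
      literature_genes = literature_genes,
      pathognomonic_catalog = pathognomonic_catalog,
      require_exon_exon_for_qpcr = require_exon_exon_for_qpcr
    ),
    class = "filter_config"
  )
}

#' Read a pathognomonic fusion catalog
#'
#' Tab-separated table with columns `disease`, `five_gene`, `three_gene`.
#' Pairs are ORDERED: a catalog entry EWSR1 -> FLI1 does not match a call
#' FLI1 -> EWSR1, because fusion orientation is biologically meaningful.
#'
#' @param path path to the catalog table.
#' @return Tibble with the three columns.
#' @export
read_pathognomonic_catalog <- function(path) {
  raw <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  need <- c("disease", "five_gene", "three_gene")
  if (!all(need %in% names(raw))) {
    abort(sprintf("catalog '%s' must have columns %s",
                  path, paste(need, collapse = ", ")))
  }
  raw
}

#' Bundled sarcoma pathognomonic catalog
#'
#' Disease-defining fusions of the sarcoma entities this workflow targets
#' (alveolar rhabdomyosarcoma, Ewing sarcoma and other EWSR1-rearranged
#' round cell sarcomas, myxoid liposarcoma, synovial sarcoma). Shipped as a
#' plain-text table under `extdata`; replaceable by any user catalog.
#'
#' @return Tibble with columns `disease`, `five_gene`, `three_gene`.
#' @export
default_pathognomonic_catalog <- function() {
  read_pathognomonic_catalog(
    system.file("extdata", "pathognomonic_catalog.tsv",
                package = "fusiontriage", mustWork = TRUE)
  )
}

.pair_key <- function(five, three) paste(five, three, sep = "->")

#' Detect pathognomonic fusion transcripts in a sample
#'
#' Returns the calls whose ordered (5', 3') gene pair is in the catalog
#' entry for the sample's disease. A disease absent from the catalog yields
#' an empty result with a message, not an error.
#'
#' @param sample_calls fusion call tibble of one sample.
#' @param disease disease label of the sample.
#' @param catalog catalog tibble (see [read_pathognomonic_catalog()]).
#' @return Subset of `sample_calls`.
#' @export
detect_pathognomonic <- function(sample_calls, disease,
                                 catalog = default_pathognomonic_catalog()) {
  entry <- catalog[catalog$disease == disease, ]
  if (nrow(entry) == 0) {
    rlang::inform(sprintf("disease '%s' not in pathognomonic catalog", disease))
    return(sample_calls[0, ])
  }
  keys <- .pair_key(sample_calls$five_gene, sample_calls$three_gene)
  sample_calls[keys %in% .pair_key(entry$five_gene, entry$three_gene), ]
}

#' Artifact rules fired by a call
#'
#' Evaluates the three false-positive signatures: `HIGH_COMMON_MAPPING`
#' (common-mapping reads above threshold — paralog cross-mapping),
#' `BANNED` (flagged by the upstream caller), and `CLOSE_PARTNERS`
#' (intrachromosomal partners closer than the readthrough distance
#' threshold).
#'
#' @param calls fusion call tibble.
#' @param config a [filter_config()].
#' @return List of character vectors, one per call, each a subset of the
#'   three rule identifiers (empty = clean).
#' @export
artifact_flags <- function(calls, config = filter_config()) {
  dist <- partner_distance(calls)
  high_cmr <- calls$common_mapping_reads > config$max_common_mapping_reads
  banned <- config$exclude_banned &
    vapply(calls$flags, function(f) "banned" %in% f, logical(1))
  close <- !is.na(dist) & dist < config$min_partner_distance
  lapply(seq_len(nrow(calls)), function(i) {
    c(
      if (high_cmr[i]) "HIGH_COMMON_MAPPING",
      if (banned[i]) "BANNED",
      if (close[i]) "CLOSE_PARTNERS"
    ) %||% character()
  })
}

#' Filter and prioritize novel fusion candidates
#'
#' Applies the three-criterion cascade to every call of every
#' pathognomonic-NEGATIVE patient:
#' 1. `SEEN_IN_POSITIVE` — the ordered gene pair also occurs in a patient
#'    carrying a pathognomonic fusion, so it is unlikely to be the missing
#'    driver;
#' 2. `NO_LITERATURE_PARTNER` — neither partner is a known fusion-gene or
#'    disease-literature gene;
#' 3. artifact rules, see [artifact_flags()].
#'
#' Each decision is per-call and auditable: an excluded call carries the
#' ordered list of every rule it fired; a retained call carries none.
#'
#' @param cohort a [fusion_cohort()].
#' @param positive_patients character vector of patient ids in whom a
#'   pathognomonic fusion was detected.
#' @param config a [filter_config()].
#' @return Tibble of decisions: the call columns plus `patient_id`, `status`
#'   (`retained`/`excluded`) and `reasons` (list column).
#' @export
filter_novel_candidates <- function(cohort, positive_patients,
                                    config = filter_config()) {
  calls <- ensure_call_id(cohort$calls)
  calls <- dplyr::left_join(
    calls, cohort$samples[c("sample_id", "patient_id")], by = "sample_id"
  )
  pos <- calls$patient_id %in% positive_patients
  positive_pairs <- unique(.pair_key(calls$five_gene[pos], calls$three_gene[pos]))
  cand <- calls[!pos, ]
  if (nrow(cand) == 0) {
    cand$status <- character()
    cand$reasons <- list()
    return(cand)
  }
  seen <- .pair_key(cand$five_gene, cand$three_gene) %in% positive_pairs
  no_lit <- !(cand$five_gene %in% config$literature_genes |
                cand$three_gene %in% config$literature_genes)
  art <- artifact_flags(cand, config)
  cand$reasons <- lapply(seq_len(nrow(cand)), function(i) {
    c(
      if (seen[i]) "SEEN_IN_POSITIVE",
      if (no_lit[i]) "NO_LITERATURE_PARTNER",
      art[[i]]
    )
  })
  cand$status <- ifelse(lengths(cand$reasons) > 0, "excluded", "retained")
  cand
}

#' Select the representative transcript of a fusion gene pair
#'
#' When the caller reports several transcripts for the same gene pair (e.g.
#' alternative 5' breakpoints from splice variants), the transcript with the
#' highest number of uniquely mapping junction-encompassing reads (spanning
#' unique reads) is put forward for validation. Ties break on higher
#' spanning pairs, then on the lexicographically smallest (5' point,
#' 3' point) for determinism.
#'
#' @param calls non-empty fusion call tibble, all rows sharing one
#'   (5' gene, 3' gene) pair.
#' @return The selected one-row tibble.
#' @export
select_representative <- function(calls) {
  if (nrow(calls) == 0) abort("no calls to select from")
  key <- unique(.pair_key(calls$five_gene, calls$three_gene))
  if (length(key) != 1) {
    abort("select_representative expects calls of a single gene pair")
  }
  p5 <- sprintf("%s:%012.0f:%s", calls$five_chrom, calls$five_pos, calls$five_strand)
  p3 <- sprintf("%s:%012.0f:%s", calls$three_chrom, calls$three_pos, calls$three_strand)
  ord <- order(-calls$spanning_unique_reads, -calls$spanning_pairs, p5, p3)
  calls[ord[1], ]
}

#' Flag same-sample calls with identical predicted sequences
#'
#' Two calls of one sample that share the 5' partner and predict an
#' identical fusion sequence (after removing the junction marker and case)
#' likely arise from one alignment artifact between near-identical 3'
#' partner paralogs, not from two distinct fusions.
#'
#' @param sample_calls fusion call tibble of one sample.
#' @return Tibble of flagged pairs: `sample_id`, `five_gene`,
#'   `three_gene_a`, `three_gene_b`, `call_id_a`, `call_id_b`.
#' @export
flag_identical_sequence_calls <- function(sample_calls) {
  sample_calls <- ensure_call_id(sample_calls)
  norm <- toupper(gsub(junction_marker(), "", sample_calls$fusion_sequence,
                       fixed = TRUE))
  out <- list()
  n <- nrow(sample_calls)
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq((i + 1), n)) {
      if (nzchar(norm[i]) && norm[i] == norm[j] &&
          sample_calls$five_gene[i] == sample_calls$five_gene[j] &&
          sample_calls$sample_id[i] == sample_calls$sample_id[j]) {
        out[[length(out) + 1]] <- tibble::tibble(
          sample_id = sample_calls$sample_id[i],
          five_gene = sample_calls$five_gene[i],
          three_gene_a = sample_calls$three_gene[i],
          three_gene_b = sample_calls$three_gene[j],
          call_id_a = sample_calls$call_id[i],
          call_id_b = sample_calls$call_id[j]
        )
      }
    }
  }
  if (length(out)) {
    dplyr::bind_rows(out)
  } else {
    tibble::tibble(sample_id = character(), five_gene = character(),
                   three_gene_a = character(), three_gene_b = character(),
                   call_id_a = character(), call_id_b = character())
  }
}
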