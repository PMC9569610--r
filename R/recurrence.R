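#' Screen a cohort for recurrent secondary fusions
#'
#' Groups calls by ordered (5', 3') gene pair across patients, within each
#' disease group by default, and reports pairs detected in at least
#' `min_patients` patients after dropping pathognomonic pairs and pairs
#' whose calls all carry artifact flags. Within each patient the
#' representative transcript is chosen by [select_representative()],
#' restricted to exon-exon border transcripts when
#' `config$require_exon_exon_for_qpcr` is set (junctions at annotated exon
#' borders are the ones a junction-spanning qPCR assay can target). Patients
#' with no eligible transcript drop out; pairs retaining fewer than
#' `min_patients` patients are not reported.
#'
#' @param cohort a [fusion_cohort()].
#' @param config a [filter_config()].
#' @param model a `gene_model` (may be NULL if calls carry border columns).
#' @param within_disease group recurrence within disease labels (default
#'   TRUE); set FALSE to screen the whole cohort as one group.
#' @param min_patients minimum number of distinct patients (default 2).
#' @return Tibble with one row per recurrent pair: `disease`, `five_gene`,
#'   `three_gene`, `n_patients`, `patients` (list column),
#'   `shared_breakpoints` (TRUE when every selected transcript has both
#'   fusion points identical), and `selected` (list column of the selected
#'   one-row call tibbles).
#' @export
recurrence_screen <- function(cohort, config = filter_config(), model = NULL,
                              within_disease = TRUE, min_patients = 2) {
  calls <- ensure_call_id(cohort$calls)
  calls <- dplyr::left_join(
    calls, cohort$samples[c("sample_id", "patient_id", "disease")],
    by = "sample_id"
  )
  if (nrow(calls) == 0) {
    return(.empty_recurrence())
  }
  if (!within_disease) calls$disease <- "all"
  cat_keys <- .pair_key(config$pathognomonic_catalog$five_gene,
                        config$pathognomonic_catalog$three_gene)
  calls$pair <- .pair_key(calls$five_gene, calls$three_gene)
  calls <- calls[!calls$pair %in% cat_keys, ]
  if (nrow(calls) == 0) {
    return(.empty_recurrence())
  }
  calls$artifact <- lengths(artifact_flags(calls, config)) > 0
  if (!all(c("five_border", "three_border") %in% names(calls))) {
    if (!is.null(model)) {
      calls <- classify_calls(calls, model)
    } else if (config$require_exon_exon_for_qpcr) {
      abort("exon-exon selection requires a gene model or border annotations")
    }
  }

  groups <- split(calls, list(calls$disease, calls$pair), drop = TRUE)
  rows <- lapply(groups, function(g) {
    # gene-level recurrence among patients with at least one non-artifact call
    clean <- g[!g$artifact, ]
    if (length(unique(clean$patient_id)) < min_patients) {
      return(NULL)
    }
    if (config$require_exon_exon_for_qpcr) {
      eligible <- clean[clean$five_border == "end_of_exon" &
                          clean$three_border == "start_of_exon", ]
    } else {
      eligible <- clean
    }
    pats <- sort(unique(eligible$patient_id))
    if (length(pats) < min_patients) {
      return(NULL)
    }
    selected <- lapply(pats, function(p) {
      select_representative(eligible[eligible$patient_id == p, ])
    })
    sel <- dplyr::bind_rows(selected)
    shared <- nrow(unique(sel[c("five_chrom", "five_pos", "five_strand",
                                "three_chrom", "three_pos", "three_strand")])) == 1
    tibble::tibble(
      disease = g$disease[1],
      five_gene = g$five_gene[1],
      three_gene = g$three_gene[1],
      n_patients = length(pats),
      patients = list(pats),
      shared_breakpoints = shared,
      selected = list(sel)
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(.empty_recurrence())
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$disease, out$five_gene, out$three_gene), ]
}

.empty_recurrence <- function() {
  tibble::tibble(
    disease = character(), five_gene = character(), three_gene = character(),
    n_patients = integer(), patients = list(),
    shared_breakpoints = logical(), selected = list()
  )
}

#' Flatten a recurrence report for export
#'
#' One row per (pair, patient) with the selected transcript's evidence
#' columns, mirroring the curated report layout.
#'
#' @param recurrent output of [recurrence_screen()].
#' @param mapping_stats optional per-sample totals to add evidence levels.
#' @return Tibble.
#' @export
recurrence_table <- function(recurrent, mapping_stats = NULL) {
  if (nrow(recurrent) == 0) {
    return(tibble::tibble())
  }
  rows <- lapply(seq_len(nrow(recurrent)), function(i) {
    sel <- recurrent$selected[[i]]
    sel$disease <- recurrent$disease[i]
    sel$shared_breakpoints <- recurrent$shared_breakpoints[i]
    sel
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(mapping_stats)) {
    out <- add_evidence_levels(out, mapping_stats)
  }
  out
}
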