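#' Read evidence level of a fusion call
#'
#' The read evidence level of a fusion transcript is the number of
#' fusion-supporting reads — spanning pairs (read pairs bridging the junction
#' without covering it) plus spanning unique reads (uniquely mapping split
#' reads covering the junction) — per million uniquely mapped reads in the
#' sample:
#'
#' \deqn{E = 10^6 (P + U) / T}
#'
#' where `P` is the spanning-pair count, `U` the spanning-unique-read count
#' and `T` the sample's total number of uniquely mapped reads. Values are
#' reported rounded half-up to two decimals; this normalization makes
#' detection sensitivity comparable across libraries of very different depth
#' (targeted panels at a few million reads versus whole-exome capture at
#' tens of millions).
#'
#' @param spanning_pairs integer vector, read pairs spanning the junction.
#' @param spanning_unique_reads integer vector, uniquely mapping split reads.
#' @param total_uniquely_mapped integer vector (recycled), total uniquely
#'   mapped reads of the sample; must be positive.
#' @param digits decimals reported (default 2, the published convention).
#' @return Numeric vector of evidence levels, rounded.
#' @examples
#' read_evidence_level(4, 6, 2521243) # 3.97
#' read_evidence_level(66, 26, 2998047) # 30.69
#' @export
read_evidence_level <- function(spanning_pairs, spanning_unique_reads,
                                total_uniquely_mapped, digits = 2) {
  if (any(is.na(total_uniquely_mapped)) || any(total_uniquely_mapped <= 0)) {
    abort("total_uniquely_mapped must be a positive count")
  }
  if (any(spanning_pairs < 0) || any(spanning_unique_reads < 0)) {
    abort("read counts must be non-negative")
  }
  supporting <- spanning_pairs + spanning_unique_reads
  round_half_up(supporting * 1e6 / total_uniquely_mapped, digits)
}

#' Add read evidence levels to a call table
#'
#' Joins per-sample totals onto a fusion call table and computes the
#' `read_evidence_level` column.
#'
#' @param calls fusion call tibble (see [read_fusion_table()]).
#' @param mapping_stats tibble with columns `sample_id` and
#'   `total_uniquely_mapped_reads` (see [read_mapping_stats()]).
#' @return `calls` with columns `total_uniquely_mapped_reads` and
#'   `read_evidence_level` added.
#' @export
add_evidence_levels <- function(calls, mapping_stats) {
  out <- dplyr::left_join(
    calls,
    mapping_stats[c("sample_id", "total_uniquely_mapped_reads")],
    by = "sample_id"
  )
  missing <- unique(out$sample_id[is.na(out$total_uniquely_mapped_reads)])
  if (length(missing)) {
    abort(sprintf(
      "no mapping statistics for sample(s): %s", paste(missing, collapse = ", ")
    ))
  }
  out$read_evidence_level <- read_evidence_level(
    out$spanning_pairs, out$spanning_unique_reads,
    out$total_uniquely_mapped_reads
  )
  out
}

#' Summarise evidence levels across a cohort
#'
#' Minimum, maximum and median of per-call evidence levels, the form in which
#' cohort detection sensitivity is reported. The median over an even number
#' of calls is the mean of the two middle values, rounded half-up to two
#' decimals; inputs are taken as already rounded per-call values so the
#' summary matches what a reader recomputes from a published table.
#'
#' @param levels numeric vector of evidence levels; must be non-empty.
#' @return Named list with `min`, `max`, `median`.
#' @examples
#' cohort_summary(c(3.97, 4.23, 3.52, 11.66, 6.28, 30.69, 12.50, 12.50))
#' @export
cohort_summary <- function(levels) {
  if (length(levels) == 0 || all(is.na(levels))) {
    abort("cannot summarise an empty set of evidence levels")
  }
  s <- sort(levels)
  n <- length(s)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else round_half_up(mean(s[n / 2 + 0:1]))
  list(min = min(s), max = max(s), median = med)
}
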