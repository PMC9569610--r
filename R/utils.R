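#' @importFrom rlang %||% abort warn .data
#' @importFrom stats lm coef median rnbinom rnorm runif setNames
#' @importFrom utils head tail
NULL

# Round half-up at `digits` decimals. Printed evidence levels and summary
# medians use commercial rounding (1.5356 -> 1.54), not banker's rounding.
# The epsilon absorbs binary-representation error in values such as 12.495
# that are stored fractionally below the true half.
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  floor(x * scale + 0.5 + 1e-9 * pmax(1, abs(x))) / scale
}

# Chromosome names are compared without a "chr" prefix ("chr17" == "17").
norm_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

#' Parse fusion points written as "chrom:pos:strand"
#'
#' Accepts thousands separators in the position ("16:31,184,396:+"), a
#' Unicode minus sign for the strand, and an optional trailing parenthetical
#' annotation such as "(end of exon)", which is discarded (border classes are
#' computed from the gene model, not trusted from input).
#'
#' @param x character vector of fusion-point strings.
#' @return A tibble with columns `chrom` (character), `pos` (integer-valued
#'   numeric, 1-based) and `strand` (`"+"` or `"-"`).
#' @examples
#' parse_genomic_point(c("16:31,184,396:+", "12:57517753:-"))
#' @export
parse_genomic_point <- function(x) {
  x <- as.character(x)
  clean <- sub("\\s*\\(.*\\)\\s*$", "", trimws(x))
  clean <- gsub("−", "-", clean)
  parts <- strsplit(clean, ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) {
    abort(sprintf(
      "unparseable fusion point(s): %s",
      paste(sprintf("'%s' (entry %d)", x[bad], which(bad)), collapse = ", ")
    ))
  }
  chrom <- norm_chrom(vapply(parts, `[[`, "", 1L))
  pos <- suppressWarnings(as.numeric(gsub(",", "", vapply(parts, `[[`, "", 2L))))
  strand <- vapply(parts, `[[`, "", 3L)
  ok <- !is.na(pos) & pos >= 1 & strand %in% c("+", "-") & nzchar(chrom)
  if (!all(ok)) {
    abort(sprintf(
      "invalid fusion point(s): %s",
      paste(sprintf("'%s' (entry %d)", x[!ok], which(!ok)), collapse = ", ")
    ))
  }
  tibble::tibble(chrom = chrom, pos = pos, strand = strand)
}

# "17:17276035:-" without thousands separators; machine output never prints them.
format_genomic_point <- function(chrom, pos, strand) {
  sprintf("%s:%d:%s", chrom, as.integer(pos), strand)
}

# Stable call identifiers so filter decisions can be joined back to calls.
ensure_call_id <- function(calls) {
  if (!"call_id" %in% names(calls)) {
    calls$call_id <- sprintf("%s#%03d", calls$sample_id, seq_len(nrow(calls)))
  }
  calls
}
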