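#' Construct a gene model from exon (and CDS) tables
#'
#' A gene model holds the exon structure used to classify fusion breakpoints
#' and to splice flanking sequence. Coordinates are 1-based inclusive (GTF
#' convention); the fusion point of a call is the last transcribed base of
#' the 5' partner and the first transcribed base of the 3' partner.
#'
#' @param exons tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `gene`, `transcript_id`, `exon_rank` (1-based, transcription order).
#' @param cds optional tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `transcript_id` giving coding intervals.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(exons, cds = NULL) {
  need <- c("chrom", "start", "end", "strand", "gene", "transcript_id", "exon_rank")
  missing <- setdiff(need, names(exons))
  if (length(missing)) {
    abort(sprintf("exon table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (any(exons$start > exons$end)) abort("exon start must be <= end")
  if (any(exons$exon_rank < 1)) abort("exon_rank must be >= 1")
  exons$chrom <- norm_chrom(exons$chrom)
  exons <- exons[order(exons$transcript_id, exons$exon_rank), ]
  if (!is.null(cds)) cds$chrom <- norm_chrom(cds$chrom)
  structure(list(exons = tibble::as_tibble(exons),
                 cds = if (is.null(cds)) NULL else tibble::as_tibble(cds)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %d genes, %d transcripts, %d exons%s\n",
              length(unique(x$exons$gene)),
              length(unique(x$exons$transcript_id)),
              nrow(x$exons),
              if (is.null(x$cds)) "" else sprintf(", %d CDS segments", nrow(x$cds))))
  invisible(x)
}

#' Read a gene model from GTF
#'
#' Imports exon and CDS features via `rtracklayer` and indexes them by gene
#' symbol (`gene_name`, falling back to `gene_id`). Chromosome names are
#' normalized by stripping a leading `chr`.
#'
#' @param path GTF file path.
#' @return A `gene_model`.
#' @export
read_gene_model <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  gene <- if ("gene_name" %in% names(df) && !all(is.na(df$gene_name))) {
    ifelse(is.na(df$gene_name), df$gene_id, df$gene_name)
  } else {
    df$gene_id
  }
  df$gene <- gene
  ex <- df[df$type == "exon", ]
  rank <- if ("exon_number" %in% names(ex)) {
    as.integer(as.character(ex$exon_number))
  } else {
    NA_integer_
  }
  exons <- tibble::tibble(
    chrom = as.character(ex$seqnames), start = ex$start, end = ex$end,
    strand = as.character(ex$strand), gene = ex$gene,
    transcript_id = ex$transcript_id, exon_rank = rank
  )
  # Derive ranks from coordinates when the GTF lacks exon_number.
  if (any(is.na(exons$exon_rank))) {
    exons <- dplyr::group_by(exons, .data$transcript_id)
    exons <- dplyr::mutate(exons, exon_rank = ifelse(
      .data$strand == "+", rank(.data$start), rank(-.data$start)
    ))
    exons <- dplyr::ungroup(exons)
  }
  cd <- df[df$type == "CDS", ]
  cds <- if (nrow(cd)) {
    tibble::tibble(chrom = as.character(cd$seqnames), start = cd$start,
                   end = cd$end, strand = as.character(cd$strand),
                   transcript_id = cd$transcript_id)
  } else {
    NULL
  }
  gene_model(exons, cds)
}

#' Write a gene model as GTF
#'
#' Emits exon (and CDS) lines with `gene_id`, `gene_name`, `transcript_id`
#' and `exon_number` attributes; the output is re-readable by
#' [read_gene_model()].
#'
#' @param model a `gene_model`.
#' @param path output path.
#' @export
write_gene_model_gtf <- function(model, path) {
  ex <- model$exons
  attr_str <- sprintf(
    'gene_id "%s"; gene_name "%s"; transcript_id "%s"; exon_number "%d";',
    ex$gene, ex$gene, ex$transcript_id, as.integer(ex$exon_rank)
  )
  lines <- sprintf("%s\tfusiontriage\texon\t%d\t%d\t.\t%s\t.\t%s",
                   ex$chrom, as.integer(ex$start), as.integer(ex$end),
                   ex$strand, attr_str)
  if (!is.null(model$cds)) {
    cd <- model$cds
    tx_gene <- ex$gene[match(cd$transcript_id, ex$transcript_id)]
    cds_attr <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s";',
                        tx_gene, tx_gene, cd$transcript_id)
    lines <- c(lines, sprintf("%s\tfusiontriage\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                              cd$chrom, as.integer(cd$start), as.integer(cd$end),
                              cd$strand, cds_attr))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Classify a fusion breakpoint against exon structure
#'
#' For the 5' partner the breakpoint is an exon border (`end_of_exon`) when
#' it equals the transcriptional 3' edge of any exon of any transcript of the
#' gene — for minus-strand transcripts that is the LOWER genomic coordinate.
#' For the 3' partner the corresponding border class is `start_of_exon`
#' (transcriptional 5' edge). Otherwise the point is `in_exon` if it falls
#' inside an exon of the gene, `in_intron` if it falls between exons of a
#' containing transcript, and `intergenic` otherwise (including genes absent
#' from the model). A border in ANY transcript counts (union over
#' transcripts).
#'
#' @param model a `gene_model`.
#' @param chrom,pos breakpoint location (1-based).
#' @param gene gene symbol of the partner.
#' @param role `"five_prime"` or `"three_prime"`.
#' @return One of `"end_of_exon"`, `"start_of_exon"`, `"in_exon"`,
#'   `"in_intron"`, `"intergenic"`.
#' @export
classify_breakpoint <- function(model, chrom, pos, gene, role) {
  role <- match.arg(role, c("five_prime", "three_prime"))
  ex <- model$exons[model$exons$gene == gene &
                      model$exons$chrom == norm_chrom(chrom), ]
  if (nrow(ex) == 0) {
    return("intergenic")
  }
  edge3 <- ifelse(ex$strand == "+", ex$end, ex$start)
  edge5 <- ifelse(ex$strand == "+", ex$start, ex$end)
  if (role == "five_prime" && any(edge3 == pos)) {
    return("end_of_exon")
  }
  if (role == "three_prime" && any(edge5 == pos)) {
    return("start_of_exon")
  }
  if (any(ex$start <= pos & pos <= ex$end)) {
    return("in_exon")
  }
  spans <- dplyr::summarise(dplyr::group_by(ex, .data$transcript_id),
                            lo = min(.data$start), hi = max(.data$end))
  if (any(spans$lo <= pos & pos <= spans$hi)) {
    return("in_intron")
  }
  "intergenic"
}

#' Annotate calls with breakpoint border classes
#'
#' Adds `five_border` and `three_border` columns via [classify_breakpoint()].
#'
#' @param calls fusion call tibble.
#' @param model a `gene_model`.
#' @return `calls` with border columns added.
#' @export
classify_calls <- function(calls, model) {
  calls$five_border <- vapply(seq_len(nrow(calls)), function(i) {
    classify_breakpoint(model, calls$five_chrom[i], calls$five_pos[i],
                        calls$five_gene[i], "five_prime")
  }, character(1))
  calls$three_border <- vapply(seq_len(nrow(calls)), function(i) {
    classify_breakpoint(model, calls$three_chrom[i], calls$three_pos[i],
                        calls$three_gene[i], "three_prime")
  }, character(1))
  calls
}

#' Is a call an exon-exon border fusion?
#'
#' TRUE when the 5' breakpoint is the end of a known exon and the 3'
#' breakpoint the start of one — the class of junction consistent with a
#' spliced fusion transcript, and the selection rule for RT-qPCR validation.
#'
#' @param calls fusion call tibble (annotated or not).
#' @param model a `gene_model`; not needed if `calls` already carry
#'   `five_border`/`three_border` columns.
#' @return Logical vector.
#' @export
is_exon_exon <- function(calls, model = NULL) {
  if (!all(c("five_border", "three_border") %in% names(calls))) {
    if (is.null(model)) abort("calls are unannotated; supply a gene model")
    calls <- classify_calls(calls, model)
  }
  calls$five_border == "end_of_exon" & calls$three_border == "start_of_exon"
}

#' Distance between fusion partners
#'
#' Absolute difference of the two fusion-point coordinates when both lie on
#' the same chromosome; `NA` for interchromosomal calls. Small distances
#' (< 100 kbp by default elsewhere) are the signature of transcriptional
#' readthrough between neighboring genes rather than rearrangement.
#'
#' @param calls fusion call tibble.
#' @return Numeric vector (bp), `NA` = interchromosomal.
#' @export
partner_distance <- function(calls) {
  ifelse(norm_chrom(calls$five_chrom) == norm_chrom(calls$three_chrom),
         abs(calls$five_pos - calls$three_pos), NA_real_)
}

#' Are both partners on the same chromosome?
#'
#' @param calls fusion call tibble.
#' @return Logical vector.
#' @export
is_intrachromosomal <- function(calls) {
  norm_chrom(calls$five_chrom) == norm_chrom(calls$three_chrom)
}

# CDS bases of transcript `tx` lying at transcript positions up to (and
# including) genomic position `pos` when inclusive, strictly before otherwise.
.cds_upstream <- function(cds, strand, pos, inclusive = TRUE) {
  if (strand == "+") {
    lim <- if (inclusive) pos else pos - 1
    sum(pmax(0, pmin(cds$end, lim) - cds$start + 1))
  } else {
    lim <- if (inclusive) pos else pos + 1
    sum(pmax(0, cds$end - pmax(cds$start, lim) + 1))
  }
}

#' Reading-frame status of an exon-exon fusion
#'
#' A fused transcript is `in_frame` when the cumulative CDS length 5' of the
#' junction is congruent modulo 3 with the CDS phase of the 3' partner's
#' junction exon (the number of coding bases its native transcript has
#' already used before that exon). A call that is not an exon-exon border
#' fusion, or whose junction exon lacks CDS on either side (long non-coding
#' RNA or pseudogene partners), is `non_coding`.
#'
#' @param calls fusion call tibble.
#' @param model a `gene_model` with CDS annotation.
#' @return Character vector: `"in_frame"`, `"out_of_frame"`, `"non_coding"`.
#' @export
frame_status <- function(calls, model) {
  if (is.null(model$cds)) {
    return(rep("non_coding", nrow(calls)))
  }
  ee <- is_exon_exon(calls, model)
  vapply(seq_len(nrow(calls)), function(i) {
    if (!ee[i]) return("non_coding")
    ph5 <- .junction_cds(model, calls$five_chrom[i], calls$five_pos[i],
                         calls$five_gene[i], side = "five")
    ph3 <- .junction_cds(model, calls$three_chrom[i], calls$three_pos[i],
                         calls$three_gene[i], side = "three")
    if (is.null(ph5) || is.null(ph3)) return("non_coding")
    if (ph5 %% 3 == ph3 %% 3) "in_frame" else "out_of_frame"
  }, character(1))
}

# Returns the relevant cumulative CDS length for the junction, or NULL when
# no transcript of the gene is coding at the junction exon.
.junction_cds <- function(model, chrom, pos, gene, side) {
  ex <- model$exons[model$exons$gene == gene &
                      model$exons$chrom == norm_chrom(chrom), ]
  if (nrow(ex) == 0) return(NULL)
  edge <- if (side == "five") {
    ifelse(ex$strand == "+", ex$end, ex$start)
  } else {
    ifelse(ex$strand == "+", ex$start, ex$end)
  }
  hits <- ex[edge == pos, ]
  for (k in order(hits$transcript_id)) {
    tx <- hits$transcript_id[k]
    cds <- model$cds[model$cds$transcript_id == tx, ]
    if (nrow(cds) == 0) next
    jex <- hits[k, ]
    coding_exon <- any(cds$start <= jex$end & jex$start <= cds$end)
    if (!coding_exon) next
    return(.cds_upstream(cds, jex$strand, pos, inclusive = (side == "five")))
  }
  NULL
}

# Spliced sequence of one transcript (exons in rank order, minus-strand
# exons reverse-complemented), as a character string.
.transcript_seq <- function(model, genome, tx) {
  ex <- model$exons[model$exons$transcript_id == tx, ]
  ex <- ex[order(ex$exon_rank), ]
  pieces <- vapply(seq_len(nrow(ex)), function(i) {
    chrom <- ex$chrom[i]
    if (!chrom %in% names(genome)) {
      abort(sprintf("genome lacks sequence for chromosome '%s'", chrom))
    }
    if (ex$end[i] > length(genome[[chrom]])) {
      abort(sprintf("genome sequence too short for interval %s:%d-%d",
                    chrom, ex$start[i], ex$end[i]))
    }
    s <- Biostrings::subseq(genome[[chrom]], ex$start[i], ex$end[i])
    if (ex$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
  paste(pieces, collapse = "")
}

# Spliced coordinate of genomic position `pos` within transcript `tx`.
.spliced_pos <- function(model, tx, pos) {
  ex <- model$exons[model$exons$transcript_id == tx, ]
  ex <- ex[order(ex$exon_rank), ]
  offset <- 0
  for (i in seq_len(nrow(ex))) {
    w <- ex$end[i] - ex$start[i] + 1
    if (ex$start[i] <= pos && pos <= ex$end[i]) {
      within <- if (ex$strand[i] == "+") pos - ex$start[i] + 1 else ex$end[i] - pos + 1
      return(offset + within)
    }
    offset <- offset + w
  }
  NA_integer_
}

#' Extend a fusion junction sequence with flanking exon sequence
#'
#' Extends the caller-reported predicted fusion sequence upstream and
#' downstream along the partner transcripts' exon order (splicing over
#' introns, reverse-complementing minus-strand exons), e.g. to enlarge the
#' design space for junction-spanning qPCR primers. The reported 5' and 3'
#' segments are assumed to be the spliced transcript suffix ending at /
#' prefix starting at the junction; a mismatch against the genome triggers a
#' warning but extension proceeds by coordinate arithmetic.
#'
#' @param call one-row fusion call tibble; must be an exon-exon call.
#' @param model a `gene_model`.
#' @param genome a `Biostrings::DNAStringSet` (names = chromosome) or path
#'   to a FASTA file.
#' @param flank maximum bases added on each side (default 200).
#' @return List with `sequence` (extended sequence, no marker),
#'   `junction_offset` (number of bases 5' of the junction), and
#'   `added` (bases added on each side).
#' @export
extend_junction_sequence <- function(call, model, genome, flank = 200) {
  if (nrow(call) != 1) abort("extend_junction_sequence takes a single call")
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- norm_chrom(sub("\\s.*$", "", names(genome)))
  if (!all(is_exon_exon(call, model))) {
    abort("junction extension requires an exon-exon border call")
  }
  seqp <- strsplit(call$fusion_sequence, junction_marker(), fixed = TRUE)[[1]]
  r5 <- toupper(seqp[1] %||% "")
  r3 <- toupper(if (length(seqp) > 1) seqp[2] else "")

  pick_tx <- function(gene, chrom, pos, side) {
    ex <- model$exons[model$exons$gene == gene &
                        model$exons$chrom == norm_chrom(chrom), ]
    edge <- if (side == "five") {
      ifelse(ex$strand == "+", ex$end, ex$start)
    } else {
      ifelse(ex$strand == "+", ex$start, ex$end)
    }
    txs <- sort(unique(ex$transcript_id[edge == pos]))
    if (!length(txs)) abort("no transcript with the junction exon border")
    txs[1]
  }

  tx5 <- pick_tx(call$five_gene, call$five_chrom, call$five_pos, "five")
  tx3 <- pick_tx(call$three_gene, call$three_chrom, call$three_pos, "three")
  s5 <- .transcript_seq(model, genome, tx5)
  s3 <- .transcript_seq(model, genome, tx3)
  j5 <- .spliced_pos(model, tx5, call$five_pos) # junction = last 5' base
  j3 <- .spliced_pos(model, tx3, call$three_pos) # junction = first 3' base

  if (nchar(r5) > 0 && nchar(r5) <= j5 &&
      substr(s5, j5 - nchar(r5) + 1, j5) != r5) {
    warn("reported 5' junction segment does not match the spliced genome sequence")
  }
  if (nchar(r3) > 0 && j3 + nchar(r3) - 1 <= nchar(s3) &&
      substr(s3, j3, j3 + nchar(r3) - 1) != r3) {
    warn("reported 3' junction segment does not match the spliced genome sequence")
  }

  ext5_end <- j5 - nchar(r5)
  ext5_start <- max(1, ext5_end - flank + 1)
  ext5 <- if (ext5_end >= ext5_start) substr(s5, ext5_start, ext5_end) else ""
  ext3_start <- j3 + nchar(r3)
  ext3_end <- min(nchar(s3), ext3_start + flank - 1)
  ext3 <- if (ext3_start <= ext3_end) substr(s3, ext3_start, ext3_end) else ""

  list(
    sequence = paste0(ext5, r5, r3, ext3),
    junction_offset = nchar(ext5) + nchar(r5),
    added = c(five = nchar(ext5), three = nchar(ext3))
  )
}
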