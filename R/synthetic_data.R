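#' Simulation configuration for a synthetic FFPE fusion cohort
#'
#' The generator plants calls of known classes into per-sample caller tables
#' so that every downstream stage (scoring, filtering, recurrence screening,
#' qPCR confirmation) can be checked against ground truth. Defaults emulate
#' a whole-exome FFPE sarcoma cohort: 17 patients split between alveolar
#' rhabdomyosarcoma (ARMS) and undifferentiated round cell sarcoma (URCS),
#' six of them carrying a pathognomonic fusion detected around 1.4
#' supporting reads per million uniquely mapped reads, library totals
#' uniform between 17.5 and 25.9 million uniquely mapped reads, and
#' secondary/novel candidates around 0.45 supporting reads per million.
#' Supporting-read counts are negative-binomial (over-dispersed, as read
#' counts are).
#'
#' @param n_patients number of tumor samples (one per patient).
#' @param diseases character vector of length `n_patients` (default: first
#'   ~half ARMS, rest URCS).
#' @param planted_pathognomonic tibble with columns `patient_id`,
#'   `five_gene`, `three_gene`; pairs must be catalog entries for the
#'   patient's disease. Default plants six (two ARMS PAX3-FOXO1, four URCS
#'   EWSR1 fusions).
#' @param n_artifacts named integer vector with elements `banned`,
#'   `close_partners`, `high_common_mapping`.
#' @param n_recurrent_pairs number of recurrent secondary gene pairs.
#' @param recurrent_multiplicity patients per recurrent pair (default 2).
#' @param n_novel_singletons clean literature-supported candidates planted
#'   in single patients.
#' @param n_background_shared pairs planted in both a pathognomonic-positive
#'   and a -negative patient (excluded from prioritization as already seen).
#' @param n_background_unknown clean pairs with no literature partner.
#' @param totals_range range of total uniquely mapped reads per sample.
#' @param support_means supporting reads per million for the
#'   `pathognomonic` and `other` regimes.
#' @param dispersion negative-binomial size parameter.
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 17,
                              diseases = NULL,
                              planted_pathognomonic = NULL,
                              n_artifacts = c(banned = 2, close_partners = 2,
                                              high_common_mapping = 2),
                              n_recurrent_pairs = 2,
                              recurrent_multiplicity = 2,
                              n_novel_singletons = 4,
                              n_background_shared = 1,
                              n_background_unknown = 1,
                              totals_range = c(17.5e6, 25.9e6),
                              support_means = c(pathognomonic = 1.4, other = 0.45),
                              dispersion = 5,
                              seed = 1) {
  if (n_patients < 1) abort("n_patients must be >= 1")
  patient_id <- sprintf("P%02d", seq_len(n_patients))
  if (is.null(diseases)) {
    n_arms <- ceiling(n_patients * 9 / 17)
    diseases <- c(rep("ARMS", n_arms), rep("URCS", n_patients - n_arms))
  }
  if (length(diseases) != n_patients) {
    abort("diseases must have one entry per patient")
  }
  if (is.null(planted_pathognomonic)) {
    planted_pathognomonic <- .default_planted(patient_id, diseases)
  }
  for (nm in c("banned", "close_partners", "high_common_mapping")) {
    if (is.na(n_artifacts[nm])) abort(sprintf("n_artifacts lacks '%s'", nm))
  }
  if (any(n_artifacts < 0) || n_novel_singletons < 0 || n_recurrent_pairs < 0 ||
      n_background_shared < 0 || n_background_unknown < 0) {
    abort("planted class counts must be >= 0")
  }
  if (totals_range[1] <= 0 || totals_range[1] > totals_range[2]) {
    abort("totals_range must be a positive interval")
  }
  structure(
    list(
      n_patients = n_patients, patient_id = patient_id, diseases = diseases,
      planted_pathognomonic = planted_pathognomonic,
      n_artifacts = n_artifacts, n_recurrent_pairs = n_recurrent_pairs,
      recurrent_multiplicity = recurrent_multiplicity,
      n_novel_singletons = n_novel_singletons,
      n_background_shared = n_background_shared,
      n_background_unknown = n_background_unknown,
      totals_range = totals_range, support_means = support_means,
      dispersion = dispersion, seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

.default_planted <- function(patient_id, diseases) {
  arms <- patient_id[diseases == "ARMS"]
  urcs <- patient_id[diseases == "URCS"]
  rows <- list()
  for (p in head(arms, 2)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      patient_id = p, five_gene = "PAX3", three_gene = "FOXO1"
    )
  }
  urcs_three <- c("ERG", "NFATC2", "NFATC2", "FLI1")
  for (i in seq_len(min(4, length(urcs)))) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      patient_id = urcs[i], five_gene = "EWSR1", three_gene = urcs_three[i]
    )
  }
  if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(patient_id = character(), five_gene = character(),
                   three_gene = character())
  }
}

# Ten-gene toy universe on three chromosomes. SYNCLOSE1/SYNCLOSE2 are the
# single deliberately adjacent pair (starts 50 kbp apart) used to plant
# readthrough-distance artifacts; every other same-chromosome gene pair is
# >= 250 kbp apart. Exon widths are multiples of 3 so planted junctions can
# be frame-consistent.
.toy_gene_layout <- function() {
  tibble::tibble(
    gene = c("PAX3", "EWSR1", "SYNG01",
             "FOXO1", "FLI1", "SYNG02",
             "ERG", "NFATC2", "SYNCLOSE1", "SYNCLOSE2"),
    chrom = c("1", "1", "1", "2", "2", "2", "3", "3", "3", "3"),
    offset = c(100001, 400001, 700001,
               100001, 400001, 700001,
               100001, 400001, 700001, 750001)
  )
}

.sim_literature_genes <- function() {
  c("PAX3", "FOXO1", "EWSR1", "FLI1", "ERG", "NFATC2", "SYNG01", "SYNCLOSE1")
}

# Build the toy gene model: 2-4 exons per gene, one transcript each, CDS
# covering all exons.
.build_toy_model <- function() {
  layout <- .toy_gene_layout()
  exons <- list()
  for (i in seq_len(nrow(layout))) {
    n_ex <- sample(2:4, 1)
    widths <- 3 * sample(40:200, n_ex, replace = TRUE)
    gaps <- sample(500:5000, n_ex, replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    start <- layout$offset[i]
    rows <- vector("list", n_ex)
    for (k in seq_len(n_ex)) {
      rows[[k]] <- tibble::tibble(
        chrom = layout$chrom[i], start = start, end = start + widths[k] - 1,
        strand = strand, gene = layout$gene[i],
        transcript_id = paste0(layout$gene[i], ".t1"),
        exon_rank = NA_integer_
      )
      start <- start + widths[k] + gaps[k]
    }
    ex <- dplyr::bind_rows(rows)
    # transcription order: genomic for +, reverse genomic for -
    ex$exon_rank <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    exons[[i]] <- ex
  }
  exons <- dplyr::bind_rows(exons)
  cds <- exons[c("chrom", "start", "end", "strand", "transcript_id")]
  gene_model(exons, cds)
}

# Exon-border fusion point inside gene `g`: transcriptional 3' edge of a
# random exon for the 5' role, 5' edge for the 3' role.
.border_point <- function(model, g, role) {
  ex <- model$exons[model$exons$gene == g, ]
  k <- sample(nrow(ex), 1)
  strand <- ex$strand[k]
  pos <- if (role == "five") {
    if (strand == "+") ex$end[k] else ex$start[k]
  } else {
    if (strand == "+") ex$start[k] else ex$end[k]
  }
  list(chrom = ex$chrom[k], pos = pos, strand = strand)
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a synthetic fusion cohort with planted truth
#'
#' Generates per-sample caller tables, mapping statistics, sample metadata,
#' a toy gene model (and optionally a toy genome), together with a truth
#' table labelling every planted call and its expected fate in the
#' filter/prioritization cascade. Planted pathognomonic calls always sit at
#' exon-exon borders and never violate an artifact rule; each planted
#' artifact call violates exactly its designated rule and no other; planted
#' recurrent pairs share both breakpoints across their patients. Everything
#' is deterministic given `config$seed`, including written files.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory; when given, `samples.tsv`,
#'   `mapping_stats.tsv`, `<sample>.fusions.tsv`, `model.gtf`,
#'   `literature_genes.txt`, `truth.tsv` (and `genome.fa` with
#'   `write_genome`) are written there.
#' @param write_genome also generate and write a random toy genome FASTA
#'   consistent with the gene model.
#' @return Object of class `fusion_simulation`: list with `cohort`
#'   ([fusion_cohort()]), `model` (`gene_model`), `truth` (tibble),
#'   `expected_recurrence` (the gene pairs a recurrence screen must report),
#'   `filter_config` ([filter_config()] with the simulation's literature
#'   genes and catalog), `positives` (patient ids carrying a planted
#'   pathognomonic fusion), `genome` (`DNAStringSet` or NULL), `config`,
#'   `dir`.
#' @export
simulate_cohort <- function(config = simulation_config(), dir = NULL,
                            write_genome = FALSE) {
  set.seed(config$seed)
  model <- .build_toy_model()
  layout <- .toy_gene_layout()
  lit <- .sim_literature_genes()
  catalog <- default_pathognomonic_catalog()

  patients <- tibble::tibble(
    patient_id = config$patient_id,
    disease = config$diseases,
    sample_id = paste0(config$patient_id, "_T")
  )
  planted <- config$planted_pathognomonic
  unknown <- setdiff(planted$patient_id, patients$patient_id)
  if (length(unknown)) {
    abort(sprintf("planted pathognomonic patients not in cohort: %s",
                  paste(unknown, collapse = ", ")))
  }
  for (i in seq_len(nrow(planted))) {
    dis <- patients$disease[patients$patient_id == planted$patient_id[i]]
    ok <- any(catalog$disease == dis &
                catalog$five_gene == planted$five_gene[i] &
                catalog$three_gene == planted$three_gene[i])
    if (!ok) {
      abort(sprintf("planted pair %s->%s is not pathognomonic for %s",
                    planted$five_gene[i], planted$three_gene[i], dis))
    }
  }
  positives <- unique(planted$patient_id)
  negatives <- setdiff(patients$patient_id, positives)

  # ---- ordered-pair pool for non-pathognomonic classes --------------------
  genes <- layout$gene
  pool <- expand.grid(five = genes, three = genes, stringsAsFactors = FALSE)
  pool <- pool[pool$five != pool$three, ]
  cat_keys <- c(.pair_key(catalog$five_gene, catalog$three_gene),
                .pair_key(catalog$three_gene, catalog$five_gene))
  pool <- pool[!.pair_key(pool$five, pool$three) %in% cat_keys, ]
  close_set <- c("SYNCLOSE1", "SYNCLOSE2")
  is_close_pair <- pool$five %in% close_set & pool$three %in% close_set
  close_pool <- pool[is_close_pair, ]
  nonlit_pool <- pool[!is_close_pair &
                        !(pool$five %in% lit) & !(pool$three %in% lit), ]
  lit_pool <- pool[!is_close_pair &
                     (pool$five %in% lit | pool$three %in% lit), ]
  lit_pool <- lit_pool[sample(nrow(lit_pool)), ]
  nonlit_pool <- nonlit_pool[sample(nrow(nonlit_pool)), ]

  n_close <- config$n_artifacts[["close_partners"]]
  if (n_close > nrow(close_pool)) {
    abort(sprintf(
      "impossible config: %d close-partner artifacts requested but the toy genome has only %d gene pair(s) under the distance threshold",
      n_close, nrow(close_pool)
    ))
  }
  if (config$n_background_unknown > nrow(nonlit_pool)) {
    abort(sprintf(
      "impossible config: %d no-literature background calls requested but only %d pairs lack literature partners",
      config$n_background_unknown, nrow(nonlit_pool)
    ))
  }
  n_lit_needed <- config$n_artifacts[["banned"]] +
    config$n_artifacts[["high_common_mapping"]] +
    config$n_novel_singletons + config$n_recurrent_pairs +
    config$n_background_shared
  if (n_lit_needed > nrow(lit_pool)) {
    abort("impossible config: not enough distinct literature-supported gene pairs")
  }
  take_lit <- function(n) {
    if (n == 0) {
      return(lit_pool[0, , drop = FALSE])
    }
    out <- lit_pool[seq_len(n), , drop = FALSE]
    lit_pool <<- lit_pool[-seq_len(n), , drop = FALSE]
    out
  }

  banned_pairs <- take_lit(config$n_artifacts[["banned"]])
  cmr_pairs <- take_lit(config$n_artifacts[["high_common_mapping"]])
  novel_pairs <- take_lit(config$n_novel_singletons)
  recurrent_pairs <- take_lit(config$n_recurrent_pairs)
  shared_pairs <- take_lit(config$n_background_shared)
  close_pairs <- close_pool[seq_len(n_close), , drop = FALSE]
  unknown_pairs <- nonlit_pool[seq_len(config$n_background_unknown), , drop = FALSE]

  if (config$n_background_shared > 0 &&
      (length(positives) == 0 || length(negatives) == 0)) {
    abort("impossible config: shared background calls need both a pathognomonic-positive and a -negative patient")
  }
  if (config$n_recurrent_pairs > 0) {
    neg_by_dis <- table(patients$disease[patients$patient_id %in% negatives])
    if (!length(neg_by_dis) || max(neg_by_dis) < config$recurrent_multiplicity) {
      abort("impossible config: no disease group has enough pathognomonic-negative patients for a recurrent pair")
    }
  }

  totals <- tibble::tibble(
    sample_id = patients$sample_id,
    total_uniquely_mapped_reads =
      round(runif(nrow(patients), config$totals_range[1], config$totals_range[2]))
  )
  total_of <- setNames(totals$total_uniquely_mapped_reads, totals$sample_id)

  draw_counts <- function(sample_id, regime) {
    mu <- config$support_means[[regime]] * total_of[[sample_id]] / 1e6
    pairs <- rnbinom(1, mu = mu * 0.6, size = config$dispersion)
    uniq <- rnbinom(1, mu = mu * 0.4, size = config$dispersion) + 1L
    list(pairs = as.integer(pairs), uniq = as.integer(uniq))
  }

  calls <- list()
  truth <- list()
  emit <- function(patient, five, three, label, regime = "other",
                   flags = character(), cmr = 0L, points = NULL,
                   expected_status, expected_reasons = "") {
    sid <- patients$sample_id[patients$patient_id == patient]
    cnt <- draw_counts(sid, regime)
    p5 <- points$five %||% .border_point(model, five, "five")
    p3 <- points$three %||% .border_point(model, three, "three")
    calls[[length(calls) + 1]] <<- tibble::tibble(
      sample_id = sid, five_gene = five, three_gene = three,
      five_chrom = p5$chrom, five_pos = p5$pos, five_strand = p5$strand,
      three_chrom = p3$chrom, three_pos = p3$pos, three_strand = p3$strand,
      spanning_pairs = cnt$pairs, spanning_unique_reads = cnt$uniq,
      common_mapping_reads = as.integer(cmr), flags = list(flags),
      predicted_effect = sample(c("in-frame", "out-of-frame", "unknown"), 1),
      fusion_sequence = paste0(.random_seq(30), junction_marker(), .random_seq(30))
    )
    truth[[length(truth) + 1]] <<- tibble::tibble(
      patient_id = patient, sample_id = sid,
      five_gene = five, three_gene = three, label = label,
      expected_status = expected_status, expected_reasons = expected_reasons
    )
  }

  for (i in seq_len(nrow(planted))) {
    emit(planted$patient_id[i], planted$five_gene[i], planted$three_gene[i],
         label = "pathognomonic", regime = "pathognomonic",
         expected_status = "not_screened")
  }

  neg_cycle <- function(i) negatives[(i - 1) %% length(negatives) + 1]
  need_negatives <- function(what) {
    if (length(negatives) == 0) {
      abort(sprintf("impossible config: %s calls need a pathognomonic-negative patient", what))
    }
  }
  idx <- 0
  for (i in seq_len(nrow(banned_pairs))) {
    need_negatives("banned-artifact")
    idx <- idx + 1
    emit(neg_cycle(idx), banned_pairs$five[i], banned_pairs$three[i],
         label = "artifact:BANNED", flags = "banned",
         expected_status = "excluded", expected_reasons = "BANNED")
  }
  for (i in seq_len(nrow(close_pairs))) {
    need_negatives("close-partner-artifact")
    idx <- idx + 1
    emit(neg_cycle(idx), close_pairs$five[i], close_pairs$three[i],
         label = "artifact:CLOSE_PARTNERS",
         expected_status = "excluded", expected_reasons = "CLOSE_PARTNERS")
  }
  for (i in seq_len(nrow(cmr_pairs))) {
    need_negatives("high-common-mapping-artifact")
    idx <- idx + 1
    emit(neg_cycle(idx), cmr_pairs$five[i], cmr_pairs$three[i],
         label = "artifact:HIGH_COMMON_MAPPING", cmr = sample(5:60, 1),
         expected_status = "excluded", expected_reasons = "HIGH_COMMON_MAPPING")
  }
  for (i in seq_len(nrow(novel_pairs))) {
    need_negatives("novel-candidate")
    idx <- idx + 1
    emit(neg_cycle(idx), novel_pairs$five[i], novel_pairs$three[i],
         label = "novel", expected_status = "retained")
  }
  for (i in seq_len(nrow(unknown_pairs))) {
    need_negatives("no-literature background")
    idx <- idx + 1
    emit(neg_cycle(idx), unknown_pairs$five[i], unknown_pairs$three[i],
         label = "background_unknown",
         expected_status = "excluded", expected_reasons = "NO_LITERATURE_PARTNER")
  }
  expected_recurrence <- list()
  disease_of <- setNames(patients$disease, patients$patient_id)
  for (i in seq_len(nrow(shared_pairs))) {
    emit(positives[1], shared_pairs$five[i], shared_pairs$three[i],
         label = "background_shared", expected_status = "not_screened")
    emit(negatives[1], shared_pairs$five[i], shared_pairs$three[i],
         label = "background_shared",
         expected_status = "excluded", expected_reasons = "SEEN_IN_POSITIVE")
    # a shared pair whose two carriers have the same disease is, by
    # definition, a recurrent (gene-level) fusion in that group
    if (disease_of[[positives[1]]] == disease_of[[negatives[1]]]) {
      expected_recurrence[[length(expected_recurrence) + 1]] <- tibble::tibble(
        disease = disease_of[[positives[1]]],
        five_gene = shared_pairs$five[i], three_gene = shared_pairs$three[i]
      )
    }
  }
  if (config$n_recurrent_pairs > 0) {
    neg_tbl <- patients[patients$patient_id %in% negatives, ]
    neg_by_dis <- split(neg_tbl$patient_id, neg_tbl$disease)
    neg_by_dis <- neg_by_dis[lengths(neg_by_dis) >= config$recurrent_multiplicity]
    for (i in seq_len(nrow(recurrent_pairs))) {
      grp <- neg_by_dis[[(i - 1) %% length(neg_by_dis) + 1]]
      pts <- head(grp, config$recurrent_multiplicity)
      shared_points <- list(
        five = .border_point(model, recurrent_pairs$five[i], "five"),
        three = .border_point(model, recurrent_pairs$three[i], "three")
      )
      for (p in pts) {
        emit(p, recurrent_pairs$five[i], recurrent_pairs$three[i],
             label = "recurrent_secondary", points = shared_points,
             expected_status = "retained")
      }
      expected_recurrence[[length(expected_recurrence) + 1]] <- tibble::tibble(
        disease = disease_of[[pts[1]]],
        five_gene = recurrent_pairs$five[i],
        three_gene = recurrent_pairs$three[i]
      )
    }
  }
  expected_recurrence <- if (length(expected_recurrence)) {
    dplyr::bind_rows(expected_recurrence)
  } else {
    tibble::tibble(disease = character(), five_gene = character(),
                   three_gene = character())
  }

  calls <- if (length(calls)) dplyr::bind_rows(calls) else empty_fusion_calls()
  truth <- if (length(truth)) dplyr::bind_rows(truth) else tibble::tibble()
  ord <- order(match(calls$sample_id, patients$sample_id))
  calls <- calls[ord, ]
  truth <- truth[ord, ]
  calls <- ensure_call_id(calls)
  truth$call_id <- calls$call_id

  samples <- tibble::tibble(
    sample_id = patients$sample_id, patient_id = patients$patient_id,
    tissue = "tumor", disease = patients$disease, cohort = "synthetic",
    dv200 = round(runif(nrow(patients), 10, 76), 1)
  )
  cohort <- fusion_cohort(samples, calls, totals)

  genome <- if (write_genome) .toy_genome(model) else NULL

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_sample_table(samples, file.path(dir, "samples.tsv"))
    write_mapping_stats(totals, file.path(dir, "mapping_stats.tsv"))
    for (sid in samples$sample_id) {
      write_fusion_table(calls[calls$sample_id == sid, ],
                         file.path(dir, paste0(sid, ".fusions.tsv")))
    }
    write_gene_model_gtf(model, file.path(dir, "model.gtf"))
    writeLines(lit, file.path(dir, "literature_genes.txt"))
    readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
    if (write_genome) {
      Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
    }
  }

  structure(
    list(cohort = cohort, model = model, truth = truth,
         expected_recurrence = expected_recurrence,
         filter_config = filter_config(literature_genes = lit,
                                       pathognomonic_catalog = catalog),
         positives = positives, genome = genome, config = config, dir = dir),
    class = "fusion_simulation"
  )
}

#' @export
print.fusion_simulation <- function(x, ...) {
  cat(sprintf("<fusion_simulation> seed %d: %d samples, %d planted calls\n",
              x$config$seed, nrow(x$cohort$samples), nrow(x$cohort$calls)))
  invisible(x)
}

# Random toy genome covering every annotated interval.
.toy_genome <- function(model) {
  chroms <- sort(unique(model$exons$chrom))
  seqs <- vapply(chroms, function(ch) {
    len <- max(model$exons$end[model$exons$chrom == ch]) + 1000
    .random_seq(len)
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, chroms))
}

#' Simulate qPCR plates and dilution series for a cohort's assays
#'
#' Designs one confirmation assay per planted true fusion (pathognomonic,
#' novel, recurrent secondary) and simulates: a plate with two tumor
#' replicates plus normal-tissue, no-template and carrier-RNA controls, and
#' a six-point 10-fold dilution series (1e6 down to 10 molecules/uL) from a
#' planted per-assay amplification efficiency. Confirmable assays amplify
#' the tumor (Cq drawn around a mean in `cq_range`, sd `cq_sd`) in at least
#' one replicate with silent controls; non-confirmable assays either show
#' control amplification or no tumor amplification.
#'
#' @param sim a `fusion_simulation` (or its truth tibble plus `seed`).
#' @param confirm_prob probability an assay is planted confirmable.
#' @param cq_range range of tumor mean Cq (cycles).
#' @param cq_sd replicate standard deviation (cycles).
#' @param efficiency_range planted efficiency range (percent).
#' @param dilution_noise_sd Cq noise added to dilution points (cycles).
#' @param seed seed for the qPCR layer (default derived from the cohort's).
#' @return List with `plate`, `dilutions`, `assays` (planted truth per
#'   assay) and `config` (a [qpcr_config()] carrying the expected Tm map).
#' @export
simulate_qpcr <- function(sim, confirm_prob = 0.75, cq_range = c(27, 36),
                          cq_sd = 0.3, efficiency_range = c(95, 105),
                          dilution_noise_sd = 0,
                          seed = sim$config$seed + 1L) {
  truth <- sim$truth
  set.seed(seed)
  targets <- truth[truth$label %in%
                     c("pathognomonic", "novel", "recurrent_secondary"), ]
  if (nrow(targets) == 0) {
    abort("no true fusions to design assays for")
  }
  n <- nrow(targets)
  assays <- tibble::tibble(
    assay_id = sprintf("FT%03d", seq_len(n)),
    sample_id = targets$sample_id,
    five_gene = targets$five_gene,
    three_gene = targets$three_gene,
    label = targets$label,
    expected_tm = round(runif(n, 78, 88), 1),
    planted_efficiency = round(runif(n, efficiency_range[1], efficiency_range[2]), 1),
    expected_confirmed = runif(n) < confirm_prob
  )
  n_fail <- sum(!assays$expected_confirmed)
  assays$failure_mode <- NA_character_
  assays$failure_mode[!assays$expected_confirmed] <-
    rep_len(c("control_amplified", "no_tumor"), n_fail)

  plate <- list()
  controls <- tibble::tibble(
    sample_id = c("NORM_CTRL", "NTC", "CARRIER"),
    role = c("normal_control", "ntc", "carrier_control")
  )
  for (i in seq_len(n)) {
    a <- assays[i, ]
    mean_cq <- runif(1, cq_range[1], cq_range[2])
    rep_cq <- c(NA_real_, NA_real_)
    rep_tm <- c(NA_real_, NA_real_)
    if (a$expected_confirmed || identical(a$failure_mode, "control_amplified")) {
      rep_cq[1] <- round(rnorm(1, mean_cq, cq_sd), 2)
      rep_tm[1] <- round(a$expected_tm + runif(1, -0.3, 0.3), 2)
      if (runif(1) < 0.6) {
        rep_cq[2] <- round(rnorm(1, mean_cq, cq_sd), 2)
        rep_tm[2] <- round(a$expected_tm + runif(1, -0.3, 0.3), 2)
      }
    }
    tumor <- tibble::tibble(
      sample_id = a$sample_id, assay_id = a$assay_id, role = "tumor",
      replicate = 1:2, cq = rep_cq, tm = rep_tm
    )
    ctrl <- tidyr::crossing(controls, replicate = 1:2)
    ctrl$assay_id <- a$assay_id
    ctrl$cq <- NA_real_
    ctrl$tm <- NA_real_
    if (identical(a$failure_mode, "control_amplified")) {
      k <- which(ctrl$role == "ntc")[1]
      ctrl$cq[k] <- round(runif(1, 33, 38), 2)
      ctrl$tm[k] <- round(a$expected_tm + runif(1, -0.3, 0.3), 2)
    }
    plate[[i]] <- dplyr::bind_rows(
      tumor, ctrl[c("sample_id", "assay_id", "role", "replicate", "cq", "tm")]
    )
  }
  plate <- dplyr::bind_rows(plate)

  inputs <- 10^(6:1)
  dilutions <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    slope <- -1 / log10(1 + assays$planted_efficiency[i] / 100)
    intercept <- runif(1, 36, 40)
    tibble::tibble(
      assay_id = assays$assay_id[i],
      input_molecules_per_ul = inputs,
      cq = intercept + slope * log10(inputs) +
        rnorm(length(inputs), 0, dilution_noise_sd)
    )
  }))

  list(
    plate = plate,
    dilutions = dilutions,
    assays = assays,
    config = qpcr_config(expected_tm = setNames(assays$expected_tm, assays$assay_id))
  )
}
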