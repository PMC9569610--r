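# Fixture builders and independent brute-force oracles used across tests.

# Two-gene toy model: G on + strand (exons 101-200, 301-400),
# H on - strand (exons 501-600, 701-800). One transcript each, no CDS.
toy_two_gene_model <- function() {
  exons <- tibble::tibble(
    chrom = "1",
    start = c(101, 301, 501, 701),
    end = c(200, 400, 600, 800),
    strand = c("+", "+", "-", "-"),
    gene = c("G", "G", "H", "H"),
    transcript_id = c("G.t1", "G.t1", "H.t1", "H.t1"),
    exon_rank = c(1, 2, 2, 1) # H transcribed right-to-left
  )
  gene_model(exons)
}

# Random multi-transcript toy model on two chromosomes for oracle tests.
random_toy_model <- function(seed) {
  set.seed(seed)
  n_genes <- sample(2:6, 1)
  rows <- list()
  for (g in seq_len(n_genes)) {
    chrom <- sample(c("1", "2"), 1)
    base <- 1000 * g + sample(0:200, 1)
    strand <- sample(c("+", "-"), 1)
    for (t in seq_len(sample(1:2, 1))) {
      n_ex <- sample(1:4, 1)
      pos <- base + sample(0:50, 1)
      ex <- list()
      for (k in seq_len(n_ex)) {
        w <- sample(5:60, 1)
        ex[[k]] <- c(start = pos, end = pos + w - 1)
        pos <- pos + w + sample(3:40, 1)
      }
      ex <- do.call(rbind, ex)
      rank <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = chrom, start = ex[, "start"], end = ex[, "end"],
        strand = strand, gene = paste0("G", g),
        transcript_id = sprintf("G%d.t%d", g, t), exon_rank = rank
      )
    }
  }
  gene_model(dplyr::bind_rows(rows))
}

# Naive edge-scan oracle for breakpoint classification: plain loops over
# exon rows, no shared code with classify_breakpoint().
brute_force_classify <- function(model, chrom, pos, gene, role) {
  ex <- as.data.frame(model$exons)
  ex <- ex[ex$gene == gene & ex$chrom == chrom, ]
  if (nrow(ex) == 0) return("intergenic")
  for (i in seq_len(nrow(ex))) {
    tail3 <- if (ex$strand[i] == "+") ex$end[i] else ex$start[i]
    head5 <- if (ex$strand[i] == "+") ex$start[i] else ex$end[i]
    if (role == "five_prime" && pos == tail3) return("end_of_exon")
    if (role == "three_prime" && pos == head5) return("start_of_exon")
  }
  for (i in seq_len(nrow(ex))) {
    if (ex$start[i] <= pos && pos <= ex$end[i]) return("in_exon")
  }
  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx, ]
    if (min(e$start) <= pos && pos <= max(e$end)) return("in_intron")
  }
  "intergenic"
}

# Independent reverse-complement (no Biostrings).
revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
}

# Minimal one-row call builder for tests.
make_call <- function(five_gene = "G", three_gene = "H",
                      five_chrom = "1", five_pos = 200, five_strand = "+",
                      three_chrom = "1", three_pos = 701, three_strand = "-",
                      spanning_pairs = 5L, spanning_unique_reads = 3L,
                      common_mapping_reads = 0L, flags = character(),
                      predicted_effect = "in-frame", fusion_sequence = "",
                      sample_id = "S1") {
  tibble::tibble(
    sample_id = sample_id, five_gene = five_gene, three_gene = three_gene,
    five_chrom = five_chrom, five_pos = five_pos, five_strand = five_strand,
    three_chrom = three_chrom, three_pos = three_pos,
    three_strand = three_strand,
    spanning_pairs = spanning_pairs,
    spanning_unique_reads = spanning_unique_reads,
    common_mapping_reads = common_mapping_reads, flags = list(flags),
    predicted_effect = predicted_effect, fusion_sequence = fusion_sequence
  )
}

# Random call tibble for round-trip properties.
random_calls <- function(n, seed, sample_id = "S1") {
  set.seed(seed)
  tibble::tibble(
    sample_id = sample_id,
    five_gene = paste0("FG", sample(99, n)),
    three_gene = paste0("TG", sample(99, n)),
    five_chrom = as.character(sample(1:5, n, replace = TRUE)),
    five_pos = sample(1e6, n),
    five_strand = sample(c("+", "-"), n, replace = TRUE),
    three_chrom = as.character(sample(1:5, n, replace = TRUE)),
    three_pos = sample(1e6, n),
    three_strand = sample(c("+", "-"), n, replace = TRUE),
    spanning_pairs = sample(0:100, n, replace = TRUE),
    spanning_unique_reads = sample(0:50, n, replace = TRUE),
    common_mapping_reads = sample(0:5, n, replace = TRUE),
    flags = replicate(n, sample(c("banned", "readthrough", "known"),
                                sample(0:2, 1)), simplify = FALSE),
    predicted_effect = sample(c("in-frame", "out-of-frame", ""), n, replace = TRUE),
    fusion_sequence = replicate(n, paste0(
      paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE), collapse = ""),
      "*",
      paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE), collapse = "")
    ))
  )
}

# Bundled worked-example tables.
extdata <- function(name) {
  system.file("extdata", name, package = "fusiontriage", mustWork = TRUE)
}

read_example_table <- function(name) {
  readr::read_tsv(extdata(name), show_col_types = FALSE, progress = FALSE)
}

# Random generator configuration for cascade-recovery properties: sized so
# every planted class is feasible (>= 2 ARMS negatives for recurrence).
random_sim_config <- function(seed) {
  set.seed(seed)
  n_arms <- sample(3:5, 1)
  n_urcs <- sample(2:5, 1)
  diseases <- c(rep("ARMS", n_arms), rep("URCS", n_urcs))
  patient_id <- sprintf("P%02d", seq_along(diseases))
  planted <- tibble::tibble(
    patient_id = patient_id[1], five_gene = "PAX3", three_gene = "FOXO1"
  )
  if (sample(c(TRUE, FALSE), 1)) {
    planted <- dplyr::bind_rows(planted, tibble::tibble(
      patient_id = patient_id[n_arms + 1],
      five_gene = "EWSR1", three_gene = "NFATC2"
    ))
  }
  simulation_config(
    n_patients = length(diseases),
    diseases = diseases,
    planted_pathognomonic = planted,
    n_artifacts = c(banned = sample(0:3, 1), close_partners = sample(0:2, 1),
                    high_common_mapping = sample(0:3, 1)),
    n_recurrent_pairs = sample(0:2, 1),
    n_novel_singletons = sample(0:3, 1),
    n_background_shared = sample(0:1, 1),
    n_background_unknown = sample(0:2, 1),
    seed = seed
  )
}

# Run detection + the filter cascade + the recurrence screen on a simulated
# cohort and check every outcome against the planted truth. Used by both
# module tests and the acceptance suite.
check_truth_recovery <- function(sim) {
  cohort <- sim$cohort
  catalog <- sim$filter_config$pathognomonic_catalog

  detected <- dplyr::bind_rows(lapply(cohort$samples$sample_id, function(sid) {
    dis <- cohort$samples$disease[cohort$samples$sample_id == sid]
    detect_pathognomonic(cohort$calls[cohort$calls$sample_id == sid, ],
                         dis, catalog)
  }))
  truth_patho <- sim$truth$call_id[sim$truth$label == "pathognomonic"]
  expect_setequal(detected$call_id, truth_patho)

  dec <- filter_novel_candidates(cohort, sim$positives, sim$filter_config)
  screened <- sim$truth[sim$truth$expected_status != "not_screened", ]
  expect_setequal(dec$call_id, screened$call_id)
  dec$reason_str <- vapply(dec$reasons, paste, "", collapse = ";")
  m <- dplyr::left_join(screened, dec[c("call_id", "status", "reason_str")],
                        by = "call_id")
  expect_equal(m$status, m$expected_status)
  expect_equal(m$reason_str, m$expected_reasons)

  rec <- recurrence_screen(cohort, sim$filter_config, sim$model)
  got <- sort(paste(rec$disease, rec$five_gene, rec$three_gene, sep = "|"))
  want <- sort(paste(sim$expected_recurrence$disease,
                     sim$expected_recurrence$five_gene,
                     sim$expected_recurrence$three_gene, sep = "|"))
  expect_identical(got, want)
  cat_keys <- paste(catalog$five_gene, catalog$three_gene, sep = "|")
  expect_length(intersect(paste(rec$five_gene, rec$three_gene, sep = "|"),
                          cat_keys), 0)
  invisible(TRUE)
}
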