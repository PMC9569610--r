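# Cohort fixture around the bundled recurrent-fusion example: two URCS
# patients sharing secondary fusions alongside their pathognomonic call.
make_recurrence_fixture <- function() {
  samples <- tibble::tibble(
    sample_id = c("S27", "S28", "S30"),
    patient_id = c("P27", "P28", "P30"),
    tissue = "tumor", disease = c("URCS", "URCS", "URCS"),
    cohort = "II", dv200 = NA_real_
  )
  cops4 <- function(sid, sp, su) {
    make_call(sample_id = sid, five_gene = "COPS4", three_gene = "TBC1D9",
              five_chrom = "4", five_pos = 83035298, five_strand = "+",
              three_chrom = "4", three_pos = 140679843, three_strand = "-",
              spanning_pairs = sp, spanning_unique_reads = su)
  }
  calls <- dplyr::bind_rows(
    make_call(sample_id = "S27", five_gene = "EWSR1", three_gene = "NFATC2",
              five_chrom = "22", three_chrom = "20"),
    make_call(sample_id = "S28", five_gene = "EWSR1", three_gene = "NFATC2",
              five_chrom = "22", three_chrom = "20"),
    cops4("S27", 4L, 3L),
    cops4("S28", 4L, 4L),
    # singleton pair: seen in one patient only
    make_call(sample_id = "S30", five_gene = "SMG6", three_gene = "VPS53",
              five_chrom = "17", three_chrom = "17", three_pos = 7e6)
  )
  fusion_cohort(samples, calls)
}

# Border columns assigned directly: these points are exon borders by fiat.
annotate_borders <- function(cohort, five = "end_of_exon",
                             three = "start_of_exon") {
  cohort$calls$five_border <- five
  cohort$calls$three_border <- three
  cohort
}

test_that("recurrent pairs are reported with shared breakpoints, pathognomonic and singleton pairs never", {
  cohort <- annotate_borders(make_recurrence_fixture())
  rec <- recurrence_screen(cohort, filter_config())
  expect_equal(nrow(rec), 1)
  expect_equal(rec$five_gene, "COPS4")
  expect_equal(rec$three_gene, "TBC1D9")
  expect_true(rec$shared_breakpoints)
  expect_setequal(rec$patients[[1]], c("P27", "P28"))
  # the representative per patient carries that patient's counts
  sel <- rec$selected[[1]]
  expect_equal(sel$spanning_unique_reads[match(c("P27", "P28"), sel$patient_id)],
               c(3L, 4L))
})

test_that("breakpoint sharing is FALSE when selected transcripts differ", {
  cohort <- make_recurrence_fixture()
  cohort$calls$three_pos[cohort$calls$sample_id == "S28" &
                           cohort$calls$five_gene == "COPS4"] <- 140680000
  cohort <- annotate_borders(cohort)
  rec <- recurrence_screen(cohort, filter_config())
  expect_false(rec$shared_breakpoints)
})

test_that("exon-exon restriction drops ineligible patients from a pair", {
  cohort <- make_recurrence_fixture()
  cohort$calls$five_border <- "end_of_exon"
  cohort$calls$three_border <- "start_of_exon"
  idx <- cohort$calls$sample_id == "S28" & cohort$calls$five_gene == "COPS4"
  cohort$calls$three_border[idx] <- "in_exon"
  expect_equal(nrow(recurrence_screen(cohort, filter_config())), 0)
  # without the exon-exon requirement the pair is reported again
  cfg <- filter_config(require_exon_exon_for_qpcr = FALSE)
  expect_equal(nrow(recurrence_screen(cohort, cfg)), 1)
})

test_that("pairs whose calls all carry artifact flags are dropped", {
  cohort <- make_recurrence_fixture()
  idx <- cohort$calls$five_gene == "COPS4"
  cohort$calls$flags[idx] <- list("banned")
  cohort <- annotate_borders(cohort)
  expect_equal(nrow(recurrence_screen(cohort, filter_config())), 0)
})

test_that("recurrence is grouped within disease by default", {
  cohort <- make_recurrence_fixture()
  cohort$samples$disease <- c("URCS", "ARMS", "URCS")
  cohort <- annotate_borders(cohort)
  expect_equal(nrow(recurrence_screen(cohort, filter_config())), 0)
  rec <- recurrence_screen(cohort, filter_config(), within_disease = FALSE)
  expect_equal(nrow(rec), 1)
})

test_that("patients without calls never change the screen; counts match brute force", {
  cohort <- annotate_borders(make_recurrence_fixture())
  base <- recurrence_screen(cohort, filter_config())
  extra <- cohort
  extra$samples <- dplyr::bind_rows(extra$samples, tibble::tibble(
    sample_id = "S99", patient_id = "P99", tissue = "tumor",
    disease = "URCS", cohort = "II", dv200 = NA_real_
  ))
  with_extra <- recurrence_screen(extra, filter_config())
  expect_equal(with_extra[setdiff(names(with_extra), "selected")],
               base[setdiff(names(base), "selected")])

  # brute-force per-pair patient counts over simulated cohorts
  for (seed in c(2, 8)) {
    sim <- simulate_cohort(simulation_config(seed = seed))
    rec <- recurrence_screen(sim$cohort, sim$filter_config, sim$model)
    calls <- dplyr::left_join(sim$cohort$calls,
                              sim$cohort$samples[c("sample_id", "patient_id")],
                              by = "sample_id")
    for (i in seq_len(nrow(rec))) {
      n <- length(unique(calls$patient_id[
        calls$five_gene == rec$five_gene[i] &
          calls$three_gene == rec$three_gene[i]
      ]))
      expect_equal(rec$n_patients[i], n)
    }
  }
})

test_that("the recurrence table flattens selections with evidence levels", {
  cohort <- annotate_borders(make_recurrence_fixture())
  stats <- tibble::tibble(
    sample_id = c("S27", "S28", "S30"),
    total_uniquely_mapped_reads = c(28739150, 24863986, 23211375)
  )
  rec <- recurrence_screen(cohort, filter_config())
  flat <- recurrence_table(rec, stats)
  expect_equal(nrow(flat), 2)
  expect_equal(sort(flat$read_evidence_level), c(0.24, 0.32))
})
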