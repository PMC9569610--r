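test_that("pathognomonic detection matches ordered catalog pairs", {
  calls <- dplyr::bind_rows(
    make_call(five_gene = "PAX3", three_gene = "FOXO1"),
    make_call(five_gene = "FLI1", three_gene = "EWSR1"), # reversed pair
    make_call(five_gene = "COPS3", three_gene = "TOM1L2")
  )
  hits <- detect_pathognomonic(calls, "ARMS")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$five_gene, "PAX3")
  # reversed orientation never matches
  expect_equal(nrow(detect_pathognomonic(calls, "Ewing sarcoma")), 0)
  expect_message(
    none <- detect_pathognomonic(calls, "unknown disease"),
    "not in"
  )
  expect_equal(nrow(none), 0)
})

test_that("artifact rules fire independently and only when violated", {
  config <- filter_config(literature_genes = "COPS3")
  clean <- make_call(five_gene = "COPS3", three_gene = "TOM1L2",
                     five_chrom = "17", five_pos = 17276035,
                     three_chrom = "17", three_pos = 17898674)
  expect_equal(artifact_flags(clean, config)[[1]], character())
  close <- make_call(five_chrom = "4", five_pos = 100000,
                     three_chrom = "4", three_pos = 150000)
  expect_equal(artifact_flags(close, config)[[1]], "CLOSE_PARTNERS")
  banned <- make_call(five_chrom = "1", three_chrom = "2",
                      flags = c("banned", "known"))
  expect_equal(artifact_flags(banned, config)[[1]], "BANNED")
  cmr <- make_call(five_chrom = "1", three_chrom = "2",
                   common_mapping_reads = 3L)
  expect_equal(artifact_flags(cmr, config)[[1]], "HIGH_COMMON_MAPPING")
  # threshold semantics: distance comparison is strict, cmr is "greater than"
  at_threshold <- make_call(five_chrom = "4", five_pos = 1e6,
                            three_chrom = "4", three_pos = 1.1e6)
  expect_equal(artifact_flags(at_threshold, config)[[1]], character())
  relaxed <- filter_config(max_common_mapping_reads = 5, exclude_banned = FALSE)
  expect_equal(artifact_flags(cmr, relaxed)[[1]], character())
  expect_equal(artifact_flags(banned, relaxed)[[1]], character())
})

make_filter_fixture <- function() {
  samples <- tibble::tibble(
    sample_id = c("SP", "SN"), patient_id = c("PPOS", "PNEG"),
    tissue = "tumor", disease = "ARMS", cohort = "x", dv200 = NA_real_
  )
  calls <- dplyr::bind_rows(
    make_call(sample_id = "SP", five_gene = "PAX3", three_gene = "FOXO1",
              five_chrom = "2", three_chrom = "13"),
    make_call(sample_id = "SP", five_gene = "SHAREDA", three_gene = "SHAREDB",
              five_chrom = "1", three_chrom = "2"),
    make_call(sample_id = "SN", five_gene = "LITG", three_gene = "X1",
              five_chrom = "1", three_chrom = "2", flags = "banned"),
    make_call(sample_id = "SN", five_gene = "LITG", three_gene = "X2",
              five_chrom = "3", five_pos = 5e5, three_chrom = "3",
              three_pos = 5.8e5),
    make_call(sample_id = "SN", five_gene = "SHAREDA", three_gene = "SHAREDB",
              five_chrom = "1", three_chrom = "2"),
    make_call(sample_id = "SN", five_gene = "NOB1", three_gene = "NOB2",
              five_chrom = "1", three_chrom = "2"),
    make_call(sample_id = "SN", five_gene = "LITG", three_gene = "X3",
              five_chrom = "1", three_chrom = "2")
  )
  fusion_cohort(samples, calls)
}

test_that("the filter cascade retains exactly the clean literature-backed call", {
  cohort <- make_filter_fixture()
  config <- filter_config(literature_genes = c("LITG", "SHAREDA", "SHAREDB"))
  dec <- filter_novel_candidates(cohort, "PPOS", config)
  # only the negative patient's calls are screened
  expect_setequal(unique(dec$patient_id), "PNEG")
  expect_equal(sum(dec$status == "retained"), 1)
  retained <- dec[dec$status == "retained", ]
  expect_equal(retained$three_gene, "X3")
  by_pair <- setNames(dec$reasons, paste(dec$five_gene, dec$three_gene))
  expect_equal(by_pair[["LITG X1"]], "BANNED")
  expect_equal(by_pair[["LITG X2"]], "CLOSE_PARTNERS")
  expect_equal(by_pair[["SHAREDA SHAREDB"]], "SEEN_IN_POSITIVE")
  expect_equal(by_pair[["NOB1 NOB2"]], "NO_LITERATURE_PARTNER")
  expect_true(all(lengths(dec$reasons[dec$status == "excluded"]) > 0))
  expect_true(all(lengths(dec$reasons[dec$status == "retained"]) == 0))
})

test_that("the filter is idempotent and monotone in the positive set", {
  cohort <- make_filter_fixture()
  config <- filter_config(literature_genes = c("LITG", "SHAREDA", "SHAREDB"))
  dec <- filter_novel_candidates(cohort, "PPOS", config)
  kept <- dec[dec$status == "retained", names(cohort$calls)]
  cohort2 <- fusion_cohort(cohort$samples, kept)
  dec2 <- filter_novel_candidates(cohort2, "PPOS", config)
  expect_setequal(dec2$call_id[dec2$status == "retained"], kept$call_id)

  # removing the positive patient can only grow the retained set
  dec_none <- filter_novel_candidates(cohort, character(), config)
  expect_true(all(
    dec$call_id[dec$status == "retained"] %in%
      dec_none$call_id[dec_none$status == "retained"]
  ))
  # and with no positives, criterion (1) excludes nothing
  expect_false(any(vapply(dec_none$reasons, function(r) {
    "SEEN_IN_POSITIVE" %in% r
  }, logical(1))))
})

test_that("an empty cohort yields an empty decision table", {
  samples <- tibble::tibble(sample_id = "S1", patient_id = "P1",
                            tissue = "tumor", disease = "ARMS", cohort = "x",
                            dv200 = NA_real_)
  cohort <- fusion_cohort(samples, make_call(sample_id = "S1")[0, ])
  expect_equal(nrow(filter_novel_candidates(cohort, character(),
                                            filter_config())), 0)
})

test_that("representative selection prefers spanning unique reads", {
  p12 <- dplyr::bind_rows(
    make_call(five_gene = "EWSR1", three_gene = "FLI1",
              five_chrom = "22", five_pos = 29288786, five_strand = "+",
              three_chrom = "11", three_pos = 128807180, three_strand = "+",
              spanning_pairs = 8L, spanning_unique_reads = 4L),
    make_call(five_gene = "EWSR1", three_gene = "FLI1",
              five_chrom = "22", five_pos = 29291599, five_strand = "+",
              three_chrom = "11", three_pos = 128807180, three_strand = "+",
              spanning_pairs = 8L, spanning_unique_reads = 2L)
  )
  expect_equal(select_representative(p12)$five_pos, 29288786)
  expect_equal(select_representative(p12[2, ])$five_pos, 29291599)

  # tie on unique reads -> higher spanning pairs; full tie -> smaller point
  tie <- p12
  tie$spanning_unique_reads <- 4L
  tie$spanning_pairs <- c(3L, 9L)
  expect_equal(select_representative(tie)$five_pos, 29291599)
  tie$spanning_pairs <- 8L
  expect_equal(select_representative(tie)$five_pos, 29288786)
  expect_error(select_representative(p12[0, ]), "no calls")
  mixed <- dplyr::bind_rows(p12, make_call())
  expect_error(select_representative(mixed), "single gene pair")
})

test_that("identical predicted sequences with a shared 5' partner are flagged", {
  seq <- "ACGTACGTAC*GGTTGGTTGG"
  calls <- dplyr::bind_rows(
    make_call(five_gene = "SS18", three_gene = "SSX2", fusion_sequence = seq),
    make_call(five_gene = "SS18", three_gene = "SSX2B", fusion_sequence = seq),
    make_call(five_gene = "SS18", three_gene = "SSX1",
              fusion_sequence = "AAAATTTTCC*GGGGCCCCAA")
  )
  flags <- flag_identical_sequence_calls(calls)
  expect_equal(nrow(flags), 1)
  expect_equal(flags$three_gene_a, "SSX2")
  expect_equal(flags$three_gene_b, "SSX2B")
  expect_equal(nrow(flag_identical_sequence_calls(calls[c(1, 3), ])), 0)
})

test_that("sequence flagging agrees with a brute-force all-pairs scan", {
  set.seed(77)
  for (rep in 1:5) {
    calls <- random_calls(10, seed = rep * 13)
    # force some collisions
    calls$fusion_sequence[4] <- calls$fusion_sequence[2]
    calls$five_gene[4] <- calls$five_gene[2]
    calls$fusion_sequence[9] <- tolower(calls$fusion_sequence[7])
    calls$five_gene[9] <- calls$five_gene[7]
    calls <- calls[sample(nrow(calls)), ]
    calls$call_id <- NULL
    got <- flag_identical_sequence_calls(calls)
    norm <- toupper(gsub("*", "", calls$fusion_sequence, fixed = TRUE))
    want <- 0
    for (i in 1:(nrow(calls) - 1)) {
      for (j in (i + 1):nrow(calls)) {
        if (calls$five_gene[i] == calls$five_gene[j] &&
            norm[i] == norm[j] && nzchar(norm[i])) {
          want <- want + 1
        }
      }
    }
    expect_equal(nrow(got), want)
  }
})
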