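test_that("breakpoint classes follow transcriptional exon edges", {
  m <- toy_two_gene_model()
  expect_equal(classify_breakpoint(m, "1", 200, "G", "five_prime"), "end_of_exon")
  expect_equal(classify_breakpoint(m, "1", 301, "G", "three_prime"), "start_of_exon")
  # minus strand: the transcriptional 3' edge is the LOWER genomic coordinate
  expect_equal(classify_breakpoint(m, "1", 701, "H", "five_prime"), "end_of_exon")
  expect_equal(classify_breakpoint(m, "1", 800, "H", "three_prime"), "start_of_exon")
  expect_equal(classify_breakpoint(m, "1", 650, "H", "five_prime"), "in_intron")
  expect_equal(classify_breakpoint(m, "1", 650, "H", "three_prime"), "in_intron")
  expect_equal(classify_breakpoint(m, "1", 150, "G", "five_prime"), "in_exon")
  expect_equal(classify_breakpoint(m, "1", 900, "H", "five_prime"), "intergenic")
  expect_equal(classify_breakpoint(m, "1", 200, "MISSING", "five_prime"), "intergenic")
  # chromosome mismatch is intergenic, and "chr" prefixes are normalized away
  expect_equal(classify_breakpoint(m, "2", 200, "G", "five_prime"), "intergenic")
  expect_equal(classify_breakpoint(m, "chr1", 200, "G", "five_prime"), "end_of_exon")
})

test_that("classification agrees with a brute-force edge scan on random models", {
  for (seed in 1:12) {
    m <- random_toy_model(seed)
    genes <- unique(m$exons$gene)
    set.seed(seed + 500)
    edge_pos <- unique(c(m$exons$start, m$exons$end))
    probe <- unique(c(edge_pos, edge_pos + 1, edge_pos - 1,
                      sample(min(m$exons$start):max(m$exons$end), 40)))
    for (g in genes) {
      chrom <- m$exons$chrom[m$exons$gene == g][1]
      for (role in c("five_prime", "three_prime")) {
        got <- vapply(probe, function(p) {
          classify_breakpoint(m, chrom, p, g, role)
        }, character(1))
        want <- vapply(probe, function(p) {
          brute_force_classify(m, chrom, p, g, role)
        }, character(1))
        expect_identical(got, want, info = sprintf("seed %d gene %s %s", seed, g, role))
      }
    }
  }
})

test_that("exon-exon detection matches the border definition", {
  m <- toy_two_gene_model()
  both <- make_call(five_pos = 200, three_gene = "H", three_pos = 800,
                    three_strand = "-")
  inexon <- make_call(five_pos = 150, three_gene = "H", three_pos = 800)
  expect_true(is_exon_exon(both, m))
  expect_false(is_exon_exon(inexon, m))
  # oracle equivalence over random calls against random models
  for (seed in 1:6) {
    m2 <- random_toy_model(seed)
    genes <- unique(m2$exons$gene)
    set.seed(seed + 900)
    for (i in 1:20) {
      g5 <- sample(genes, 1)
      g3 <- sample(genes, 1)
      p5 <- sample(min(m2$exons$start):max(m2$exons$end), 1)
      p3 <- sample(min(m2$exons$start):max(m2$exons$end), 1)
      c5 <- m2$exons$chrom[m2$exons$gene == g5][1]
      c3 <- m2$exons$chrom[m2$exons$gene == g3][1]
      call <- make_call(five_gene = g5, five_chrom = c5, five_pos = p5,
                        three_gene = g3, three_chrom = c3, three_pos = p3)
      want <- brute_force_classify(m2, c5, p5, g5, "five_prime") == "end_of_exon" &&
        brute_force_classify(m2, c3, p3, g3, "three_prime") == "start_of_exon"
      expect_equal(is_exon_exon(call, m2), want)
    }
  }
})

test_that("partner distance and intrachromosomal status follow coordinates", {
  cops3 <- make_call(five_chrom = "17", five_pos = 17276035,
                     three_chrom = "17", three_pos = 17898674)
  expect_equal(partner_distance(cops3), 622639)
  expect_true(is_intrachromosomal(cops3))
  igk <- make_call(five_chrom = "2", five_pos = 89631593,
                   three_chrom = "21", three_pos = 10499475)
  expect_true(is.na(partner_distance(igk)))
  expect_false(is_intrachromosomal(igk))
  same <- make_call(five_chrom = "4", five_pos = 100, three_chrom = "chr4",
                    three_pos = 100)
  expect_equal(partner_distance(same), 0)
  expect_true(is_intrachromosomal(same))
})

test_that("frame status follows CDS phase arithmetic", {
  # A: + strand, exons 60 and 30 bp, fully coding; junction after exon 1
  # carries 60 coding bases (0 mod 3).
  build <- function(len_a1) {
    exons <- tibble::tibble(
      chrom = "1",
      start = c(101, 301, 1001, 1201, 2001),
      end = c(100 + len_a1, 330, 1030, 1230, 2050),
      strand = "+",
      gene = c("A", "A", "B", "B", "C"),
      transcript_id = c("A.t1", "A.t1", "B.t1", "B.t1", "C.t1"),
      exon_rank = c(1, 2, 1, 2, 1)
    )
    cds <- exons[exons$gene != "C", c("chrom", "start", "end", "strand", "transcript_id")]
    gene_model(exons, cds)
  }
  call_ab <- function(m, five_pos) {
    make_call(five_gene = "A", five_pos = five_pos,
              three_gene = "B", three_pos = 1201, three_strand = "+")
  }
  m0 <- build(60)
  # 3' junction exon of B is exon 2: phase = 30 %% 3 = 0; 60 %% 3 = 0
  expect_equal(frame_status(call_ab(m0, 160), m0), "in_frame")
  m1 <- build(59) # 59 %% 3 = 2 != 0
  expect_equal(frame_status(call_ab(m1, 159), m1), "out_of_frame")
  # junction into a transcript without CDS
  nc <- make_call(five_gene = "A", five_pos = 160,
                  three_gene = "C", three_pos = 2001, three_strand = "+")
  expect_equal(frame_status(nc, m0), "non_coding")
  # non-exon-exon calls are non_coding by definition
  expect_equal(frame_status(call_ab(m0, 150), m0), "non_coding")
})

test_that("frame status is invariant under splitting an exon", {
  make <- function(split) {
    a_exons <- if (split) {
      tibble::tibble(start = c(101, 131), end = c(130, 160), exon_rank = c(1, 2))
    } else {
      tibble::tibble(start = 101, end = 160, exon_rank = 1)
    }
    n <- nrow(a_exons)
    exons <- tibble::tibble(
      chrom = "1",
      start = c(a_exons$start, 1001, 1201),
      end = c(a_exons$end, 1030, 1230),
      strand = "+",
      gene = c(rep("A", n), "B", "B"),
      transcript_id = c(rep("A.t1", n), "B.t1", "B.t1"),
      exon_rank = c(a_exons$exon_rank, 1, 2)
    )
    cds <- exons[c("chrom", "start", "end", "strand", "transcript_id")]
    gene_model(exons, cds)
  }
  call <- make_call(five_gene = "A", five_pos = 160,
                    three_gene = "B", three_pos = 1201, three_strand = "+")
  expect_equal(frame_status(call, make(FALSE)), frame_status(call, make(TRUE)))
})

test_that("junction sequences extend along spliced transcripts", {
  set.seed(42)
  chrom_seq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                     collapse = "")
  genome <- Biostrings::DNAStringSet(c(`1` = chrom_seq))
  exons <- tibble::tibble(
    chrom = "1",
    start = c(11, 31, 61, 81),
    end = c(20, 40, 70, 90),
    strand = "+",
    gene = c("G5", "G5", "G3", "G3"),
    transcript_id = c("G5.t1", "G5.t1", "G3.t1", "G3.t1"),
    exon_rank = c(1, 2, 1, 2)
  )
  m <- gene_model(exons)
  sub <- function(a, b) substr(chrom_seq, a, b)
  s5 <- paste0(sub(11, 20), sub(31, 40)) # spliced G5
  s3 <- paste0(sub(61, 70), sub(81, 90)) # spliced G3
  r5 <- substr(s5, 17, 20) # last 4 bases before junction at pos 40
  r3 <- substr(s3, 11, 14) # first 4 bases from junction at pos 81 (exon 2)
  call <- make_call(five_gene = "G5", five_pos = 40,
                    three_gene = "G3", three_pos = 81, three_strand = "+",
                    fusion_sequence = paste0(r5, "*", r3))
  ext <- extend_junction_sequence(call, m, genome, flank = 10)
  # manual construction: 10 bases upstream of r5 in s5, 6 remaining bases of s3
  expect_equal(ext$sequence,
               paste0(substr(s5, 7, 16), r5, r3, substr(s3, 15, 20)))
  expect_equal(ext$junction_offset, 14)
  expect_equal(unname(ext$added), c(10, 6))

  ext0 <- extend_junction_sequence(call, m, genome, flank = 0)
  expect_equal(ext0$sequence, paste0(r5, r3))
  expect_equal(ext0$junction_offset, nchar(r5))
})

test_that("minus-strand extension reverse-complements genomic flank", {
  set.seed(43)
  chrom_seq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                     collapse = "")
  genome <- Biostrings::DNAStringSet(c(`1` = chrom_seq))
  # minus-strand 5' gene: transcription right-to-left, exon ranks reversed
  exons <- tibble::tibble(
    chrom = "1",
    start = c(11, 31, 61, 81),
    end = c(20, 40, 70, 90),
    strand = c("-", "-", "+", "+"),
    gene = c("G5", "G5", "G3", "G3"),
    transcript_id = c("G5.t1", "G5.t1", "G3.t1", "G3.t1"),
    exon_rank = c(2, 1, 1, 2)
  )
  m <- gene_model(exons)
  sub <- function(a, b) substr(chrom_seq, a, b)
  s5 <- paste0(revcomp_chr(sub(31, 40)), revcomp_chr(sub(11, 20)))
  # transcriptional 3' edge of minus-strand exon [11,20] is genomic pos 11
  r5 <- substr(s5, 17, 20)
  r3 <- sub(61, 64)
  call <- make_call(five_gene = "G5", five_pos = 11, five_strand = "-",
                    three_gene = "G3", three_pos = 61, three_strand = "+",
                    fusion_sequence = paste0(r5, "*", r3))
  ext <- extend_junction_sequence(call, m, genome, flank = 8)
  expect_equal(ext$sequence, paste0(substr(s5, 9, 16), r5, r3,
                                    paste0(sub(65, 70), sub(81, 82))))
  expect_equal(ext$junction_offset, 12)
})

test_that("extension reports missing genome sequence by interval", {
  m <- toy_two_gene_model()
  genome <- Biostrings::DNAStringSet(c(`1` = "ACGT"))
  call <- make_call(five_pos = 200, three_gene = "H", three_pos = 800,
                    three_strand = "-", fusion_sequence = "AC*GT")
  expect_error(extend_junction_sequence(call, m, genome, flank = 5),
               "1:101-200")
})

test_that("GTF round-trips through rtracklayer import", {
  sim <- simulate_cohort(simulation_config(seed = 5))
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gene_model_gtf(sim$model, path)
  back <- read_gene_model(path)
  norm <- function(d) {
    d <- dplyr::arrange(d, transcript_id, exon_rank)
    d <- d[c("chrom", "start", "end", "strand", "gene",
             "transcript_id", "exon_rank")]
    d$start <- as.numeric(d$start)
    d$end <- as.numeric(d$end)
    d$exon_rank <- as.numeric(d$exon_rank)
    d
  }
  expect_equal(norm(back$exons), norm(sim$model$exons))
  expect_equal(nrow(back$cds), nrow(sim$model$cds))
})
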