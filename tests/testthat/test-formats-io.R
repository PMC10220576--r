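test_that("read_fastq returns records in file order with U->T normalisation", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGUacgu", "+", "IIIIIIII",
               "@r2 extra", "TTTT", "+", "IIII"), fq)
  out <- read_fastq(fq)
  expect_equal(nrow(out), 2)
  expect_equal(out$read_id, c("r1", "r2"))
  expect_equal(out$sequence, c("ACGTACGT", "TTTT"))
  expect_equal(out$quality, c("IIIIIIII", "IIII"))
})

test_that("read_fastq handles empty files and rejects malformed records", {
  empty <- withr::local_tempfile(fileext = ".fastq")
  file.create(empty)
  expect_equal(nrow(read_fastq(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), bad)  # quality too short
  expect_error(read_fastq(bad), "line 4")

  trunc <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "AC"), trunc)
  expect_error(read_fastq(trunc), "line 5")
})

test_that("fastq writer round-trips through the reader", {
  reads <- tibble::tibble(read_id = c("a", "b"),
                          sequence = c("ACGTACGT", "GGGTTT"),
                          quality = c("IIIIIIII", "IIIIII"))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  expect_equal(read_fastq(fq), reads)
})

test_that("miRBase identifiers parse into species, family and arm", {
  p <- parse_mirbase_id(c("gma-miR156a", "ath-miR172b-3p", "osa-let7c-5p",
                          "not_a_mirna"))
  expect_equal(p$family, c("miR156", "miR172", "let7", NA))
  expect_equal(p$species_code, c("gma", "ath", "osa", NA))
  expect_equal(p$arm, c(NA, "3p", "5p", NA))
  expect_equal(p$parseable, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("read_mirbase_fasta normalises sequences, skips junk, rejects dups", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">gma-miR156a MIMAT0001", "UUGACAGAAGAUAGAGAGCAC",
               ">weird_header", "ACGUACGUACGUACGUACG",
               ">ath-miR172b-3p", "AGAAUCUUGAUGAUGCUGCAU"), fa)
  expect_warning(refs <- read_mirbase_fasta(fa), "parseable")
  expect_equal(nrow(refs), 2)
  expect_equal(refs$sequence[1], "TTGACAGAAGATAGAGAGCAC")
  expect_equal(refs$family, c("miR156", "miR172"))

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">gma-miR156a", "ACGUACGUACGUACGUACG",
               ">gma-miR156a", "ACGUACGUACGUACGUACG"), dup)
  expect_error(read_mirbase_fasta(dup), "duplicate")
})

test_that("GFF3 export uses 1-based inclusive coordinates and round-trips", {
  cand <- tibble::tibble(
    mirna_id = c("m1", "m2"), contig = c("C1", "C1"),
    strand = c("+", "-"),
    pre_start0 = c(99L, 500L), pre_end0 = c(199L, 580L),
    mature_start = c(10L, 5L), mature_end = c(30L, 25L),
    star_start = c(60L, 45L), star_end = c(80L, 65L),
    family = c("miR156", "miR166"), group_id = c("miR156_g1", "miR166_g1"),
    mfei = c(1.1, 0.9), passes = c(TRUE, TRUE)
  )
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(cand, gff)
  lines <- readLines(gff)
  pre1 <- grep("pre_miRNA", lines, value = TRUE)[1]
  fields <- strsplit(pre1, "\t")[[1]]
  # 0-based half-open [99,199) becomes 1-based inclusive 100..199
  expect_equal(as.integer(fields[4:5]), c(100L, 199L))

  back <- read_gff3(gff)
  expect_equal(back$pre_start0, cand$pre_start0)
  expect_equal(back$pre_end0, cand$pre_end0)
  expect_equal(back$strand, cand$strand)
  expect_equal(back$family, cand$family)
  expect_equal(back$mfei, cand$mfei)
  # minus-strand mature span maps to the forward axis
  expect_equal(back$mature_contig_start0[2], cand$pre_end0[2] - 25L)
  expect_equal(back$mature_contig_end0[2], cand$pre_end0[2] - 5L + 1L)
})

test_that("write_gff3 rejects coordinates outside the contig", {
  cand <- tibble::tibble(
    mirna_id = "m1", contig = "C1", strand = "+",
    pre_start0 = 99L, pre_end0 = 199L,
    mature_start = 10L, mature_end = 30L,
    star_start = 60L, star_end = 80L,
    family = "miR156", group_id = "g", mfei = 1, passes = TRUE
  )
  gff <- withr::local_tempfile(fileext = ".gff3")
  expect_error(write_gff3(cand, gff, contig_lengths = c(C1 = 150L)),
               "outside contig")
})

test_that("run configuration validates invariants and reads from YAML", {
  expect_error(run_config(min_len = 26, max_len = 25), "min_len")
  expect_error(run_config(seed_start = 13, seed_end = 13), "seed_start")
  expect_error(run_config(mfei_threshold = -1), "positive")

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("min_len: 19", "fc_threshold: 2.0", "seed: 42"), yml)
  cfg <- read_config(yml)
  expect_equal(cfg$min_len, 19L)
  expect_equal(cfg$fc_threshold, 2)
  expect_equal(cfg$max_len, 25L)  # untouched default

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("min_length: 19", bad)
  expect_error(read_config(bad), "unknown config keys")
})
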