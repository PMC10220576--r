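test_that("generators are pure functions of their seed", {
  r1 <- make_reference_mirnas(6, seed = 5)
  r2 <- make_reference_mirnas(6, seed = 5)
  expect_identical(r1, r2)
  expect_false(identical(r1, make_reference_mirnas(6, seed = 6)))

  g1 <- make_genome(r1, n_contigs = 2, contig_len = 5000, n_decoys = 4,
                    seed = 5)
  g2 <- make_genome(r1, n_contigs = 2, contig_len = 5000, n_decoys = 4,
                    seed = 5)
  expect_identical(g1, g2)
})

test_that("written studies are byte-identical across reruns of one seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(simulate_study(seed = 9, preset = "tiny"), d1)
  write_study(simulate_study(seed = 9, preset = "tiny"), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("the genome manifest books valid and decoy loci with flags", {
  refs <- make_reference_mirnas(5, seed = 3)
  gen <- make_genome(refs, n_contigs = 3, contig_len = 6000, n_decoys = 5,
                     seed = 3)
  loci <- gen$loci
  # 5 families, the first planted as a 3-copy tandem cluster, plus 5 decoys
  expect_equal(sum(loci$is_valid_hairpin), 7)
  expect_equal(sum(!loci$is_valid_hairpin), 5)
  expect_equal(sum(loci$in_cluster), 3)
  # planted sequences really sit at the recorded coordinates
  for (i in which(loci$is_valid_hairpin & loci$strand == "+")) {
    l <- loci[i, ]
    cassette <- substr(gen$genome[[l$contig]], l$start0 + 1, l$end0)
    mat <- refs$sequence[refs$accession == l$mirna_id]
    expect_true(grepl(mat, cassette, fixed = TRUE))
  }
  expect_error(make_genome(refs, n_contigs = 1, contig_len = 900,
                           n_decoys = 0, seed = 1), ">= 1000")
})

test_that("planted cassettes refold into qualifying hairpins", {
  refs <- make_reference_mirnas(4, seed = 13)
  cfg <- run_config()
  for (i in 1:4) {
    cas <- withr::with_seed(13 + i, phasemir:::hairpin_cassette(refs$sequence[i]))
    f <- fold_rna(cas$sequence)
    pt <- phasemir:::pair_table(f$dotbracket)
    expect_gte(phasemir:::longest_helix_run(pt), cfg$min_ds_segment)
    # single terminal loop
    expect_equal(stringr::str_count(f$dotbracket, "\\(\\.*\\)"), 1)
  }
})

test_that("reads trace to planted families when background is off", {
  design <- default_design()[c(1, 5), ]
  truth <- make_expression_truth(make_reference_mirnas(4, seed = 2),
                                 n_de = 0, seed = 2)
  reads <- make_reads(truth, design, seed = 2, depth = 500,
                      background_fraction = 0, adapter = "TGGAATTCTCGG")
  trimmed <- sub("TGGAATTCTCGG.*$", "", reads$sequence)
  catalogue <- unlist(lapply(truth$mature_sequence, function(m) {
    phasemir:::isomir_catalogue(m)$sequence
  }))
  expect_true(all(trimmed %in% catalogue))
})

test_that("planted fold changes are recovered in empirical CPM ratios", {
  design <- default_design()
  refs <- make_reference_mirnas(10, seed = 31)
  ratios <- vapply(1:20, function(r) {
    truth <- make_expression_truth(refs, n_de = 4, fold_change = 4,
                                   seed = 31 + r)
    fam <- truth$family[truth$is_de][1]
    up <- truth$up_group[truth$family == fam]
    other <- setdiff(c("REV", "IVM", "JUV", "MAT"), up)[1]
    reads <- make_reads(truth, design, seed = 31 + r, depth = 4000)
    cfg <- run_config(adapter = "TGGAATTCTCGGGTGCCAAGG")
    tags <- collapse_reads(reads, cfg)
    asn <- assign_tags(tags, refs, cfg)
    grp <- isomir_groups(asn, design$library_id)
    cpm <- normalize_cpm(grp[, c("group_id", design$library_id)],
                         library_sizes(reads, cfg))
    row <- cpm[grp$family == fam, ]
    libs_up <- design$library_id[design$sample_group == up]
    libs_ot <- design$library_id[design$sample_group == other]
    mean(unlist(row[, libs_up])) / mean(unlist(row[, libs_ot]))
  }, numeric(1))
  expect_gt(mean(ratios >= 2.5 & ratios <= 6.5), 0.8)
  expect_equal(median(ratios), 4, tolerance = 0.35)
})

test_that("designed target sites hit their designed expectations", {
  truth <- make_expression_truth(make_reference_mirnas(8, seed = 17),
                                 n_de = 8, seed = 17)
  tx <- make_transcripts(truth, seed = 17)
  sites <- tx$sites
  for (i in seq_len(nrow(sites))) {
    site_seq <- substr(tx$transcripts[[sites$transcript_id[i]]],
                       sites$site_start[i], sites$site_end[i])
    d <- score_duplex(sites$mirna_sequence[i], site_seq)
    expect_equal(d$expectation, sites$expectation_designed[i])
  }
  # scanning recovers <=cutoff designs and suppresses the >5 negatives
  mirnas <- tibble::tibble(mirna_id = truth$family,
                           sequence = truth$mature_sequence)
  hits <- scan_transcripts(mirnas, tx$transcripts)
  for (i in seq_len(nrow(sites))) {
    found <- any(hits$mirna_id == sites$family[i] &
                   hits$transcript_id == sites$transcript_id[i] &
                   hits$target_start <= sites$site_end[i] &
                   hits$target_end >= sites$site_start[i] &
                   hits$expectation <= sites$expectation_designed[i])
    if (sites$expectation_designed[i] <= 5) {
      expect_true(found, label = sites$transcript_id[i])
    } else {
      exact <- hits[hits$mirna_id == sites$family[i] &
                      hits$transcript_id == sites$transcript_id[i] &
                      hits$target_start == sites$site_start[i], ]
      expect_equal(nrow(exact), 0)
    }
  }
})

test_that("zero-noise Ct tables recover planted effects exactly", {
  design <- default_design()
  flat <- make_ct_table(list(g = c(MAT = 0, JUV = 0, REV = 0, IVM = 0)),
                        design, seed = 4, sample_sd = 0, replicate_sd = 0)
  rq <- tidy(delta_delta_ct(flat, "g", "MAT"))
  expect_equal(rq$rq, rep(1, 4))

  eff <- make_ct_table(list(g = c(MAT = 0, JUV = -2, REV = 0, IVM = 0)),
                       design, seed = 4, sample_sd = 0, replicate_sd = 0)
  rq2 <- tidy(delta_delta_ct(eff, "g", "MAT"))
  expect_equal(rq2$rq[rq2$sample_group == "JUV"], 4)
  # identical seeds give identical tables
  expect_identical(eff, make_ct_table(list(g = c(MAT = 0, JUV = -2, REV = 0,
                                                 IVM = 0)),
                                      design, seed = 4, sample_sd = 0,
                                      replicate_sd = 0))
})
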