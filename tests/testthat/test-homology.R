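ref_tbl <- function(...) {
  seqs <- c(...)
  tibble::tibble(
    accession = names(seqs),
    species_code = substr(names(seqs), 1, 3),
    family = parse_mirbase_id(names(seqs))$family,
    arm = NA_character_, kind = "mature", sequence = unname(seqs)
  )
}

tag_tbl <- function(seqs, counts = NULL, libs = "L1") {
  out <- tibble::tibble(sequence = seqs, length = nchar(seqs))
  if (is.null(counts)) counts <- matrix(10L, length(seqs), length(libs))
  for (j in seq_along(libs)) out[[libs[j]]] <- as.integer(counts[, j])
  out$total_count <- as.integer(rowSums(counts))
  out
}

test_that("match_tag handles identity, threshold and mixed-offset cases", {
  ref <- "TTGACAGAAGATAGAGAGCAC"
  expect_equal(match_tag(ref, ref),
               list(mismatches = 0L, offset_5p = 0L, offset_3p = 0L))

  three_subs <- ref
  substr(three_subs, 5, 5) <- "G"   # C -> G
  substr(three_subs, 9, 9) <- "C"   # A -> C
  substr(three_subs, 15, 15) <- "C" # A -> C
  stopifnot(is.null(oracle_match_tag(three_subs, ref)))
  expect_null(match_tag(three_subs, ref))

  # drop the reference's first base, add one 3' base, one internal sub
  tag <- paste0(substr(ref, 2, nchar(ref)), "G")
  substr(tag, 8, 8) <- "C"   # ref position 9 was 'A'
  expect_equal(match_tag(tag, ref),
               list(mismatches = 1L, offset_5p = -1L, offset_3p = 1L))
})

test_that("match_tag agrees with exhaustive placement enumeration", {
  set.seed(301)
  n_cases <- 1000
  for (i in seq_len(n_cases)) {
    ref <- rand_dna(sample(19:24, 1))
    tag <- if (runif(1) < 0.5) {
      # perturbed copy: random end offsets and substitutions
      x <- substr(ref, sample(1:3, 1), nchar(ref) - sample(0:2, 1))
      nsub <- sample(0:3, 1)
      for (k in seq_len(nsub)) {
        p <- sample(nchar(x), 1)
        substr(x, p, p) <- sample(DNA, 1)
      }
      x
    } else {
      rand_dna(sample(18:25, 1))
    }
    got <- match_tag(tag, ref)
    want <- oracle_match_tag(tag, ref)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$mismatches, want$mismatches)
      expect_equal(abs(got$offset_5p) + abs(got$offset_3p),
                   abs(want$offset_5p) + abs(want$offset_3p))
    }
  }
})

test_that("ties across same-family references are flagged ambiguous", {
  a <- "TTGACAGAAGATAGAGAGCAC"
  b <- a
  substr(b, 11, 11) <- "C"  # 1 substitution apart
  refs <- ref_tbl("gma-miR156a" = a, "gma-miR156b" = b)
  # tag exactly between the two: 1 mismatch to each
  tag <- a
  substr(tag, 11, 11) <- "G"
  stopifnot(substr(a, 11, 11) != "G", substr(b, 11, 11) != "G")
  asn <- assign_tags(tag_tbl(tag), refs)
  expect_true(asn$annotated)
  expect_equal(asn$family, "miR156")
  expect_true(asn$ambiguous)
  expect_equal(asn$accessions, "gma-miR156a,gma-miR156b")
})

test_that("unmatched tags are unannotated; distinct families separate", {
  set.seed(302)
  refs <- ref_tbl("gma-miR156a" = rand_dna(21), "gma-miR166a" = rand_dna(21),
                  "gma-miR172a" = rand_dna(21))
  tags <- tag_tbl(c(refs$sequence, rand_dna(21)))
  asn <- assign_tags(tags, refs)
  expect_equal(asn$annotated, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(asn$family[1:3], c("miR156", "miR166", "miR172"))
  expect_false(any(asn$ambiguous[1:3]))
  expect_equal(dplyr::n_distinct(asn$group_id[1:3]), 3)
  expect_error(assign_tags(tags, refs[0, ]), "empty")
})

test_that("assignments are invariant to reference ordering", {
  set.seed(303)
  refs <- ref_tbl("gma-miR156a" = rand_dna(21), "ath-miR156b" = rand_dna(21),
                  "gma-miR166a" = rand_dna(21))
  tags <- tag_tbl(vapply(1:6, function(i) {
    x <- refs$sequence[sample(3, 1)]
    p <- sample(nchar(x), 1)
    substr(x, p, p) <- sample(DNA, 1)
    x
  }, character(1)))
  a1 <- assign_tags(tags, refs)
  a2 <- assign_tags(tags, refs[rev(seq_len(nrow(refs))), ])
  expect_equal(a1, a2)
})

test_that("group counts conserve tag counts and consensus matches majority", {
  mat <- "TTGACAGAAGATAGAGAGCAC"
  refs <- ref_tbl("gma-miR156a" = mat)
  variants <- c(mat, substr(mat, 2, 21), paste0(mat, "A"))
  counts <- matrix(c(10L, 4L, 3L, 5L, 2L, 1L), ncol = 2)
  tags <- tag_tbl(variants, counts, libs = c("L1", "L2"))
  asn <- assign_tags(tags, refs)
  grp <- isomir_groups(asn, c("L1", "L2"))
  expect_equal(nrow(grp), 1)
  expect_equal(grp$L1, 17L)
  expect_equal(grp$L2, 8L)
  expect_equal(grp$consensus, mat)  # canonical majority, rare ends trimmed
  # conservation: group counts + unannotated = total
  expect_equal(grp$total_count + sum(tags$total_count[!asn$annotated]),
               sum(tags$total_count))
})

test_that("family summaries report presence per sample group", {
  refs <- ref_tbl("gma-miR156a" = strrep("ACTG", 5),
                  "gma-miR166a" = strrep("GATC", 5))
  tags <- tag_tbl(refs$sequence,
                  counts = matrix(c(5L, 0L, 0L, 0L, 0L, 7L), ncol = 3),
                  libs = c("R1", "R2", "M1"))
  design <- tibble::tibble(library_id = c("R1", "R2", "M1"),
                           sample_group = c("REV", "REV", "MAT"))
  asn <- assign_tags(tags, refs)
  fs <- summarize_families(asn, design)
  expect_equal(fs$present[fs$family == "miR156" & fs$sample_group == "REV"],
               TRUE)
  expect_equal(fs$present[fs$family == "miR156" & fs$sample_group == "MAT"],
               FALSE)
  expect_equal(fs$read_count[fs$family == "miR166" & fs$sample_group == "MAT"],
               7L)
  bad_design <- tibble::tibble(library_id = "ZZ", sample_group = "REV")
  expect_error(summarize_families(asn, bad_design), "absent")
})

test_that("planted presence patterns are recovered from a simulated study", {
  st <- simulate_study(seed = 11, preset = "tiny")
  run <- run_study(st, stages = c("collapse", "annotate"))
  fs <- run$family_summary
  # every planted family must be seen in every group at default depths
  # (means are a few hundred reads per library, far above detection)
  expect_true(all(fs$present))
  expect_setequal(unique(fs$family), st$truth$family)
})
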