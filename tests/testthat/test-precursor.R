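test_that("verbatim, reverse-complement and mutated plantings are all found", {
  set.seed(601)
  bg <- rand_dna(10000, gc = 0.4)
  q <- rand_dna(21, gc = 0.5)
  plant <- function(genome, seq, at) {
    substr(genome, at + 1, at + nchar(seq)) <- seq
    genome
  }
  g1 <- plant(bg, q, 3000)
  hits <- map_to_genome(c(m = q), c(C1 = g1))
  exact <- hits[hits$mismatches == 0 & hits$gaps == 0, ]
  expect_equal(nrow(exact), 1)
  expect_equal(exact$start0, 3000L)
  expect_equal(exact$end0, 3021L)
  expect_equal(exact$strand, "+")

  g2 <- plant(bg, paste(rc_chars(q), collapse = ""), 5000)
  hits2 <- map_to_genome(c(m = q), c(C1 = g2))
  exact2 <- hits2[hits2$mismatches == 0 & hits2$gaps == 0, ]
  expect_equal(exact2$strand, "-")
  expect_equal(exact2$start0, 5000L)

  mutate2 <- function(x) {
    for (p in sample(nchar(x), 2)) {
      substr(x, p, p) <- setdiff(DNA, substr(x, p, p))[1]
    }
    x
  }
  g3 <- bg
  for (at in c(1000, 4000, 7000)) g3 <- plant(g3, mutate2(q), at)
  hits3 <- map_to_genome(c(m = q), c(C1 = g3))
  expect_true(all(c(1000, 4000, 7000) %in% hits3$start0[hits3$gaps == 0]))
})

test_that("genome mapping equals the sliding-window oracle", {
  set.seed(602)
  for (rep in 1:3) {
    genome <- c(A = rand_dna(3000, gc = 0.45), B = rand_dna(2000, gc = 0.45))
    q <- rand_dna(20, gc = 0.5)
    # plant exact, substituted, deleted and inserted copies
    v_sub <- q; substr(v_sub, 7, 7) <- setdiff(DNA, substr(q, 7, 7))[1]
    v_del <- paste0(substr(q, 1, 9), substr(q, 11, 20))
    v_ins <- paste0(substr(q, 1, 12), "A", substr(q, 13, 20))
    substr(genome[["A"]], 201, 200 + nchar(q)) <- q
    substr(genome[["A"]], 901, 900 + nchar(v_sub)) <- v_sub
    substr(genome[["B"]], 301, 300 + nchar(v_del)) <- v_del
    substr(genome[["B"]], 1301, 1300 + nchar(v_ins)) <- v_ins
    got <- map_to_genome(c(m = q), genome)
    want <- oracle_map(q, genome)
    key <- function(df) sort(paste(df$contig, df$start0, df$end0, df$strand))
    expect_equal(key(got), key(want))
    # agreeing coordinates must agree on the best interpretation
    got_o <- got[order(got$contig, got$start0, got$end0, got$strand), ]
    want_o <- want[order(want$contig, want$start0, want$end0, want$strand), ]
    expect_equal(got_o$gaps, want_o$gaps)
    expect_equal(got_o$mismatches, want_o$mismatches)
  }
})

test_that("candidate windows are flanked, clipped and strand-oriented", {
  set.seed(603)
  contig <- rand_dna(1000, gc = 0.4)
  genome <- c(C1 = contig)
  hit <- tibble::tibble(mirna_id = "m", contig = "C1", start0 = 400L,
                        end0 = 421L, strand = "+")
  win <- extract_candidate(hit, genome, flank = 100L)
  expect_equal(nchar(win$window), 221)
  expect_equal(win$mature_start, 101L)
  expect_equal(win$mature_end, 121L)
  expect_equal(substr(win$window, 101, 121), substr(contig, 401, 421))

  edge <- tibble::tibble(mirna_id = "m", contig = "C1", start0 = 10L,
                         end0 = 31L, strand = "+")
  winE <- extract_candidate(edge, genome, flank = 100L)
  expect_equal(winE$win_start0, 0L)
  expect_equal(winE$mature_start, 11L)

  minus <- tibble::tibble(mirna_id = "m", contig = "C1", start0 = 400L,
                          end0 = 421L, strand = "-")
  winM <- extract_candidate(minus, genome, flank = 50L)
  fwd <- substr(contig, 351, 471)
  expect_equal(winM$window,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(fwd))))
})

test_that("the star arm mirrors the mature arm with the 2-nt 3' overhang", {
  set.seed(604)
  arm <- rand_dna(25, gc = 0.55)
  hp <- paste0(arm, "TTTTT", paste(rc_chars(arm), collapse = ""))
  db <- paste0(strrep("(", 25), ".....", strrep(")", 25))
  star <- locate_star(db, 3, 23)  # mature inside the 5' arm
  # partners of 3..23 are 53..33; shifted by +2
  expect_equal(star$star_start, 35L)
  expect_equal(star$star_end, 55L)
  expect_equal(star$star_end - star$star_start, 20L)  # same width as mature

  # mature sitting in the terminal loop has no pairing partners
  db2 <- paste0(strrep("(", 10), strrep(".", 20), strrep(")", 10))
  expect_null(locate_star(db2, 12, 28))
})

test_that("star location tolerates an interior bulge in the duplex", {
  # 10 pairs, 2-nt bulge on the 5' arm, 10 more pairs
  db <- paste0(strrep("(", 10), "..", strrep("(", 10), "....",
               strrep(")", 20))
  pt <- phasemir:::pair_table(db)
  star <- locate_star(db, 1, 22)
  expect_equal(star$star_start, min(pt[1:22][pt[1:22] > 0]) + 2L)
  # the +2 shift of the far end is clipped at the sequence boundary
  expect_equal(star$star_end,
               min(nchar(db), max(pt[1:22][pt[1:22] > 0]) + 2L))
})

test_that("trimming cuts after the first bulge beyond the duplex", {
  # outer stem 7 bp, 3-nt bulge on the left, duplex 12 bp, loop 4
  db <- paste0(strrep("(", 7), "...", strrep("(", 12), "....",
               strrep(")", 12), strrep(")", 7))
  n <- nchar(db)
  mature <- c(11, 22)          # the inner 12-bp helix, 5' side
  star <- c(27, 38)
  tr <- trim_to_pre(db, mature, star)
  # left: walk meets the 3-nt bulge at 10..8, include it, cut before pos 7
  expect_equal(tr$t_start, 8L)
  # right: position 39 is paired but continues the outer stem cleanly
  # (pt[10]? no -- pt of left break is unpaired), so the walk stops there
  expect_equal(tr$t_end, 38L)

  # clean stem all the way: trim at the window edges
  db2 <- paste0(strrep("(", 20), "....", strrep(")", 20))
  tr2 <- trim_to_pre(db2, c(3, 12), c(33, 42))
  expect_equal(tr2$t_start, 1L)
  expect_equal(tr2$t_end, 44L)
})

test_that("MFEI arithmetic follows AMFE magnitude over GC percent", {
  cand <- tibble::tibble(
    mirna_id = "m", contig = "C", strand = "+", pre_start0 = 0L,
    pre_end0 = 100L,
    pre_sequence = paste0(strrep("G", 25), strrep("C", 25), strrep("A", 50)),
    dotbracket = paste0(strrep("(", 25), strrep(".", 50), strrep(")", 25)),
    mfe = -50, engine = "test",
    mature_start = 1L, mature_end = 21L, star_start = 60L, star_end = 80L
  )
  sc <- score_candidate(cand, run_config())
  expect_equal(sc$amfe, 50)
  expect_equal(sc$gc_percent, 50)
  expect_equal(sc$mfei, 1.0)

  # mfei scales as 1/GC for fixed AMFE
  cand2 <- cand
  cand2$pre_sequence <- paste0(strrep("G", 13), strrep("C", 12),
                               strrep("A", 75))
  sc2 <- score_candidate(cand2, run_config())
  expect_equal(sc2$mfei, sc$mfei * 50 / 25)

  # zero GC fails with the documented reason
  cand3 <- cand
  cand3$pre_sequence <- strrep("A", 100)
  sc3 <- score_candidate(cand3, run_config())
  expect_false(sc3$passes)
  expect_match(sc3$fail_reason, "zero GC")
})

test_that("an MFEI of 0.84 fails the 0.85 filter when all else passes", {
  arm <- strrep("GC", 11)  # 22 nt, GC-rich mature
  hp <- paste0(arm, "AAAA", paste(rc_chars(arm), collapse = ""))
  db <- paste0(strrep("(", 22), "....", strrep(")", 22))
  len <- nchar(hp)
  gc <- phasemir:::gc_percent(hp) # on 0-100
  cand <- tibble::tibble(
    mirna_id = "m", contig = "C", strand = "+", pre_start0 = 0L,
    pre_end0 = len, pre_sequence = hp, dotbracket = db,
    mfe = -(0.84 * gc * len / 100), engine = "test",
    mature_start = 1L, mature_end = 22L,
    star_start = 27L, star_end = 48L
  )
  sc <- score_candidate(cand, run_config())
  expect_equal(sc$mfei, 0.84, tolerance = 1e-9)
  expect_false(sc$passes)
  expect_match(sc$fail_reason, "MFEI")
  # nudging the energy to the threshold makes it pass
  cand$mfe <- -(0.85 * gc * len / 100)
  expect_true(score_candidate(cand, run_config())$passes)
})

test_that("tandem precursors cluster; distant or cross-contig ones do not", {
  cand <- tibble::tibble(
    mirna_id = "m", contig = c("C1", "C1", "C1", "C2", "C3"),
    strand = "+",
    pre_start0 = c(1000L, 1600L, 2200L, 1000L, 99000L),
    pre_end0 = c(1100L, 1700L, 2300L, 1100L, 99100L),
    passes = TRUE
  )
  cl <- find_clusters(cand, max_gap = 10000L)
  expect_equal(sum(cl$contig == "C1"), 3)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 1)
  expect_false(any(c("C2", "C3") %in% cl$contig))

  far <- cand[1:2, ]
  far$pre_start0 <- c(1000L, 60000L)
  far$pre_end0 <- c(1100L, 60100L)
  expect_equal(nrow(find_clusters(far, max_gap = 10000L)), 0)
})

test_that("planted hairpins pass and shuffled decoy contexts fail", {
  st <- simulate_study(seed = 21, preset = "tiny")
  mirnas <- st$truth |>
    dplyr::transmute(mirna_id = family, sequence = mature_sequence,
                     family = family, group_id = family)
  prec <- predict_precursors(mirnas, st$genome, run_config())
  loci <- st$loci
  hit_locus <- function(l) {
    any(prec$passes & prec$contig == l$contig &
          prec$pre_start0 < l$end0 & prec$pre_end0 > l$start0)
  }
  valid <- loci[loci$is_valid_hairpin, ]
  decoy <- loci[!loci$is_valid_hairpin, ]
  sens <- mean(vapply(seq_len(nrow(valid)), function(i) hit_locus(valid[i, ]),
                      logical(1)))
  fp <- mean(vapply(seq_len(nrow(decoy)), function(i) hit_locus(decoy[i, ]),
                    logical(1)))
  expect_gte(sens, 0.9)
  expect_lte(fp, 0.1)
  # the planted tandem family is recovered as a cluster
  cl <- find_clusters(prec[prec$passes, ], 10000L)
  expect_gte(dplyr::n_distinct(cl$cluster_id), 1)
})
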