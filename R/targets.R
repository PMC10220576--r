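# Complementarity-based target prediction. A miRNA is aligned 5'->3' against
# the 3'->5' read of a candidate transcript site; each aligned column is
# penalised (Watson-Crick pair 0, G:U wobble 0.5, mismatch 1, gap 2 per
# gapped position) with penalties doubled inside the seed region (miRNA
# positions 2-13 by default), and the summed penalty is the expectation
# score. Sites with expectation <= 5 and at most 2 seed mismatches+gaps are
# reported. At most one gap of up to 2 nt is considered per duplex.

# Column penalty in "Q-space": q is the complement-expected base
# (Q = revcomp(miRNA)), t the observed target base.
# match 0; wobble (miRNA G : target T, or miRNA T/U : target G) 0.5; else 1.
q_penalty <- function(q, t) {
  ifelse(t == q, 0,
         ifelse((q == "C" & t == "T") | (q == "A" & t == "G"), 0.5, 1))
}

# Alignment configurations for a miRNA of length L: gapless plus single
# bulges of 1-2 nt on either side at interior positions. Each config is a
# list of columns with: off (0-based offset into the target window, NA for a
# miRNA bulge), q_idx (index into Q, NA for a target bulge), mirna_pos.
duplex_configs <- function(L, max_gap_len = 2L) {
  cfgs <- list()
  add <- function(cols, wlen, gaps) {
    cfgs[[length(cfgs) + 1]] <<- list(cols = cols, wlen = wlen, gaps = gaps)
  }
  base_cols <- tibble(off = 0:(L - 1), q_idx = 1:L, mirna_pos = L:1)
  add(base_cols, L, 0L)
  for (g in seq_len(max_gap_len)) {
    for (j in 2:L) {                       # target bulge before Q column j
      cols <- bind_rows(
        tibble(off = 0:(j - 2), q_idx = 1:(j - 1), mirna_pos = (L:1)[1:(j - 1)]),
        tibble(off = (j - 1):(j + g - 2), q_idx = NA_integer_,
               mirna_pos = L + 1L - j),
        tibble(off = (j + g - 1):(L + g - 1), q_idx = j:L,
               mirna_pos = (L + 1L - j):1)
      )
      add(cols, L + g, g)
    }
    for (j in 2:(L - g)) {                 # miRNA bulge: Q columns j..j+g-1 unpaired
      cols <- bind_rows(
        tibble(off = 0:(j - 2), q_idx = 1:(j - 1), mirna_pos = (L:1)[1:(j - 1)]),
        tibble(off = NA_integer_, q_idx = j:(j + g - 1),
               mirna_pos = (L + 1L - (j:(j + g - 1)))),
        tibble(off = (j - 1):(L - g - 1), q_idx = (j + g):L,
               mirna_pos = (L + 1L - ((j + g):L)))
      )
      add(cols, L - g, g)
    }
  }
  cfgs
}

#' Score one miRNA-target duplex
#'
#' Evaluates every admissible alignment (gapless plus one bulge of up to 2 nt
#' on either strand) of the miRNA against the given target site and returns
#' the best-scoring one with a three-row text rendering of the alignment.
#'
#' @param mirna miRNA sequence, 5'->3' (DNA or RNA alphabet).
#' @param target_site Target site subsequence, 5'->3'.
#' @param config A [run_config()]; uses `seed_start`, `seed_end`.
#' @return List with `expectation`, `seed_mismatches`, `annotation` (a
#'   character vector of three aligned rows: miRNA 3'->5' on top row order
#'   reversed to match the target, marks, target 5'->3').
#' @export
score_duplex <- function(mirna, target_site, config = run_config()) {
  mirna <- normalize_dna(mirna)
  target_site <- normalize_dna(target_site)
  if (!nzchar(mirna) || !nzchar(target_site)) abort("empty input")
  L <- nchar(mirna)
  Q <- strsplit(revcomp(mirna), "")[[1]]
  Tc <- strsplit(target_site, "")[[1]]
  cfgs <- duplex_configs(L)
  cfgs <- cfgs[vapply(cfgs, function(cf) cf$wlen == length(Tc), logical(1))]
  if (length(cfgs) == 0) {
    abort("target_site length incompatible with miRNA length (gap limit 2)")
  }
  best <- NULL
  for (cf in cfgs) {
    sc <- score_config_at(cf, Q, Tc, 1L, config)
    if (is.null(best) || sc$expectation < best$sc$expectation) {
      best <- list(cf = cf, sc = sc)
    }
  }
  ann <- render_alignment(best$cf, Q, Tc, mirna)
  list(expectation = best$sc$expectation,
       seed_mismatches = best$sc$seed_mismatches,
       annotation = ann)
}

# Score one config against one window starting at position s (1-based).
score_config_at <- function(cf, Q, Tc, s, config) {
  seed <- function(p) p >= config$seed_start & p <= config$seed_end
  exp_total <- 0
  seed_mm <- 0L
  for (i in seq_len(nrow(cf$cols))) {
    col <- cf$cols[i, ]
    mult <- if (seed(col$mirna_pos)) 2 else 1
    if (is.na(col$q_idx) || is.na(col$off)) {
      exp_total <- exp_total + 2 * mult
      if (seed(col$mirna_pos)) seed_mm <- seed_mm + 1L
    } else {
      pen <- q_penalty(Q[col$q_idx], Tc[s + col$off])
      exp_total <- exp_total + pen * mult
      if (pen == 1 && seed(col$mirna_pos)) seed_mm <- seed_mm + 1L
    }
  }
  list(expectation = exp_total, seed_mismatches = seed_mm)
}

# Three-row rendering: target 5'->3', marks, miRNA 3'->5' (so complementary
# columns line up).
render_alignment <- function(cf, Q, Tc, mirna) {
  mir_rev <- strsplit(revcomp(mirna), "")[[1]]  # = Q; display complement back
  mir_chars <- chartr("ACGT", "TGCA", mir_rev)  # miRNA 3'->5'
  top <- character(nrow(cf$cols))
  mid <- character(nrow(cf$cols))
  bot <- character(nrow(cf$cols))
  for (i in seq_len(nrow(cf$cols))) {
    col <- cf$cols[i, ]
    if (is.na(col$q_idx)) {
      top[i] <- Tc[col$off + 1]; mid[i] <- " "; bot[i] <- "-"
    } else if (is.na(col$off)) {
      top[i] <- "-"; mid[i] <- " "; bot[i] <- mir_chars[col$q_idx]
    } else {
      t <- Tc[col$off + 1]
      pen <- q_penalty(Q[col$q_idx], t)
      top[i] <- t
      mid[i] <- if (pen == 0) "|" else if (pen == 0.5) "o" else " "
      bot[i] <- mir_chars[col$q_idx]
    }
  }
  c(paste0("5' ", paste(top, collapse = ""), " 3' target"),
    paste0("   ", paste(mid, collapse = ""), ""),
    paste0("3' ", paste(bot, collapse = ""), " 5' miRNA"))
}

#' Scan transcripts for miRNA target sites
#'
#' Slides every alignment configuration along each transcript, reports sites
#' with expectation at most `config$expectation_cutoff` and at most
#' `config$max_seed_mismatches` mismatches+gaps in the seed region, and
#' deduplicates overlapping sites of the same miRNA-transcript pair to the
#' best-scoring one.
#'
#' @param mirnas Tibble with `mirna_id`, `sequence` (or named character
#'   vector).
#' @param transcripts Named character vector of transcript sequences.
#' @param config A [run_config()].
#' @return Tibble: `mirna_id`, `transcript_id`, `target_start`, `target_end`
#'   (1-based inclusive), `expectation`, `seed_mismatches`, `gaps`, ordered
#'   by transcript, position, miRNA.
#' @export
scan_transcripts <- function(mirnas, transcripts, config = run_config()) {
  if (!is.data.frame(mirnas)) {
    mirnas <- tibble(mirna_id = names(mirnas), sequence = unname(mirnas))
  }
  hits <- list()
  for (qi in seq_len(nrow(mirnas))) {
    mirna <- normalize_dna(mirnas$sequence[qi])
    L <- nchar(mirna)
    Q <- strsplit(revcomp(mirna), "")[[1]]
    cfgs <- duplex_configs(L)
    for (ti in seq_along(transcripts)) {
      Tc <- strsplit(normalize_dna(transcripts[[ti]]), "")[[1]]
      n <- length(Tc)
      for (cf in cfgs) {
        if (cf$wlen > n) next
        ns <- n - cf$wlen + 1L
        exp_total <- numeric(ns)
        seed_mm <- integer(ns)
        for (i in seq_len(nrow(cf$cols))) {
          col <- cf$cols[i, ]
          in_seed <- col$mirna_pos >= config$seed_start &&
            col$mirna_pos <= config$seed_end
          mult <- if (in_seed) 2 else 1
          if (is.na(col$q_idx) || is.na(col$off)) {
            exp_total <- exp_total + 2 * mult
            if (in_seed) seed_mm <- seed_mm + 1L
          } else {
            pen <- q_penalty(Q[col$q_idx], Tc[col$off + seq_len(ns)])
            exp_total <- exp_total + pen * mult
            if (in_seed) seed_mm <- seed_mm + as.integer(pen == 1)
          }
        }
        ok <- which(exp_total <= config$expectation_cutoff &
                      seed_mm <= config$max_seed_mismatches)
        if (length(ok) > 0) {
          hits[[length(hits) + 1]] <- tibble(
            mirna_id = mirnas$mirna_id[qi],
            transcript_id = names(transcripts)[ti],
            target_start = ok, target_end = ok + cf$wlen - 1L,
            expectation = exp_total[ok], seed_mismatches = seed_mm[ok],
            gaps = cf$gaps
          )
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble(mirna_id = character(), transcript_id = character(),
                  target_start = integer(), target_end = integer(),
                  expectation = numeric(), seed_mismatches = integer(),
                  gaps = integer()))
  }
  bind_rows(hits) %>%
    group_by(.data$mirna_id, .data$transcript_id) %>%
    dplyr::group_modify(~dedup_overlaps(.x)) %>%
    ungroup() %>%
    arrange(.data$transcript_id, .data$target_start, .data$mirna_id)
}

# Greedy best-first removal of overlapping sites of one miRNA-transcript pair.
dedup_overlaps <- function(df) {
  df <- arrange(df, .data$expectation, .data$gaps, .data$target_start)
  kept <- df[0, ]
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (nrow(kept) == 0 ||
        !any(row$target_start <= kept$target_end &
             row$target_end >= kept$target_start)) {
      kept <- bind_rows(kept, row)
    }
  }
  arrange(kept, .data$target_start)
}
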