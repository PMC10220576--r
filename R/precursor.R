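# Hairpin precursor prediction: mature miRNAs are mapped to genome contigs
# (both strands, bounded substitutions and at most one single-nucleotide
# gap), +/-100 nt flanks are folded, candidates are trimmed to the next bulge
# or loop beyond the miRNA/miRNA* duplex, and the trimmed hairpins are
# filtered on MFEI, double-stranded segment length and arm lengths.

#' Map mature miRNA sequences to genome contigs
#'
#' Finds every placement on either strand with at most
#' `config$max_mismatches_genome` substitutions and at most one
#' single-nucleotide gap. The search enumerates the gap-free pattern plus all
#' one-base-deleted and one-base-inserted variants through
#' [Biostrings::matchPattern()], so it is exhaustive within tolerance. Minus
#' strand hits carry forward-axis coordinates. Contigs shorter than the query
#' are skipped.
#'
#' @param mirnas Tibble with `mirna_id` and `sequence` columns (a named
#'   character vector is also accepted).
#' @param genome Named character vector of contig sequences.
#' @param config A [run_config()].
#' @return Tibble: `mirna_id`, `contig`, `start0`, `end0` (0-based half-open,
#'   forward axis), `strand`, `mismatches`, `gaps`.
#' @export
map_to_genome <- function(mirnas, genome, config = run_config()) {
  if (!is.data.frame(mirnas)) {
    mirnas <- tibble(mirna_id = names(mirnas), sequence = unname(mirnas))
  }
  max_mm <- config$max_mismatches_genome
  max_gap <- min(config$max_gaps_genome, 1L)
  hits <- list()
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    subject <- Biostrings::DNAString(genome[[ci]])
    for (qi in seq_len(nrow(mirnas))) {
      q <- normalize_dna(mirnas$sequence[qi])
      if (nchar(q) > length(subject)) next
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") q else revcomp(q)
        h <- scan_one_pattern(pat, subject, max_mm, max_gap)
        if (nrow(h) > 0) {
          h$mirna_id <- mirnas$mirna_id[qi]
          h$contig <- contig
          h$strand <- strand
          hits[[length(hits) + 1]] <- h
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble(mirna_id = character(), contig = character(),
                  start0 = integer(), end0 = integer(), strand = character(),
                  mismatches = integer(), gaps = integer()))
  }
  bind_rows(hits) %>%
    group_by(.data$mirna_id, .data$contig, .data$strand,
             .data$start0, .data$end0) %>%
    slice_min(order_by = .data$gaps * 10L + .data$mismatches,
              n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    select("mirna_id", "contig", "start0", "end0", "strand",
           "mismatches", "gaps") %>%
    arrange(.data$mirna_id, .data$contig, .data$start0, .data$strand)
}

# All matches of one oriented pattern against one contig: exact/substitution
# hits plus single-deletion and single-insertion variants.
scan_one_pattern <- function(pat, subject, max_mm, max_gap) {
  out <- list()
  grab <- function(pattern, gaps, fixed = TRUE) {
    v <- Biostrings::matchPattern(pattern, subject, max.mismatch = max_mm,
                                  fixed = fixed)
    if (length(v) == 0) return(NULL)
    winseq <- as.character(v)
    mm <- vapply(winseq, function(w) count_subs(pattern, w), integer(1),
                 USE.NAMES = FALSE)
    keep <- mm <= max_mm
    if (!any(keep)) return(NULL)
    tibble(start0 = BiocGenerics::start(v)[keep] - 1L,
           end0 = BiocGenerics::end(v)[keep],
           mismatches = mm[keep], gaps = gaps)
  }
  out[[1]] <- grab(pat, 0L)
  if (max_gap >= 1L) {
    L <- nchar(pat)
    dels <- unique(vapply(seq_len(L), function(j) {
      paste0(substr(pat, 1, j - 1), substr(pat, j + 1, L))
    }, character(1)))
    for (d in dels) out[[length(out) + 1]] <- grab(d, 1L)
    ins <- unique(vapply(2:L, function(j) {
      paste0(substr(pat, 1, j - 1), "N", substr(pat, j, L))
    }, character(1)))
    for (p in ins) out[[length(out) + 1]] <- grab(p, 1L, fixed = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(tibble())
  bind_rows(out)
}

# Substitution count between equal-length strings; N in the pattern matches
# anything (used for insertion variants).
count_subs <- function(pattern, window) {
  pc <- strsplit(pattern, "")[[1]]
  wc <- strsplit(window, "")[[1]]
  as.integer(sum(pc != wc & pc != "N"))
}

#' Extract the flanked candidate window around a genome hit
#'
#' The window is `[start0 - flank, end0 + flank)` clipped to the contig; when
#' the hit is on the minus strand the window is reverse-complemented so the
#' mature arm reads 5'->3'. At contig edges the available sequence is used.
#'
#' @param hit One-row tibble from [map_to_genome()].
#' @param genome Named character vector of contigs.
#' @param flank Flank length in nt (default 100).
#' @return One-row tibble: window coordinates (`win_start0`, `win_end0`,
#'   forward axis), `window` (oriented sequence) and the mature span within
#'   the oriented window (`mature_start`, `mature_end`, 1-based inclusive).
#' @export
extract_candidate <- function(hit, genome, flank = 100L) {
  contig_seq <- genome[[hit$contig]]
  clen <- nchar(contig_seq)
  ws <- max(0L, hit$start0 - flank)
  we <- min(clen, hit$end0 + flank)
  win <- substr(contig_seq, ws + 1L, we)
  if (hit$strand == "-") {
    win <- revcomp(win)
    offset <- we - hit$end0
  } else {
    offset <- hit$start0 - ws
  }
  tibble(
    mirna_id = hit$mirna_id, contig = hit$contig, strand = hit$strand,
    win_start0 = ws, win_end0 = we, window = win,
    mature_start = offset + 1L,
    mature_end = offset + (hit$end0 - hit$start0)
  )
}

#' Locate the miRNA* arm from a folded structure
#'
#' The star arm spans the pairing partners of the mature arm shifted by the
#' 2-nt 3' overhang of the Dicer duplex. Returns no star when fewer than 60%
#' of mature positions are paired or when the derived star overlaps the
#' mature arm.
#'
#' @param dotbracket Dot-bracket structure of the (window or precursor)
#'   sequence.
#' @param mature_start,mature_end Mature span, 1-based inclusive.
#' @return List with `star_start`, `star_end`, or `NULL` when no star can be
#'   placed.
#' @export
locate_star <- function(dotbracket, mature_start, mature_end) {
  pt <- pair_table(dotbracket)
  n <- length(pt)
  span <- mature_start:mature_end
  partners <- pt[span]
  paired <- partners > 0
  if (mean(paired) < 0.6) return(NULL)
  ss <- max(1L, min(partners[paired]) + 2L)
  se <- min(n, max(partners[paired]) + 2L)
  if (ss <= mature_end && se >= mature_start) return(NULL)  # overlap
  list(star_start = as.integer(ss), star_end = as.integer(se))
}

#' Trim a folded window to pre-miRNA bounds
#'
#' Starting from the outer edge of the mature/star duplex, the stem is walked
#' outward while base pairs continue cleanly; the cut is placed immediately
#' after the first bulge or interior loop beyond the duplex (the unpaired run
#' is included), or at the window end when the stem runs out cleanly.
#'
#' @param dotbracket Dot-bracket of the window.
#' @param mature_span,star_span Lists/vectors with start and end (1-based).
#' @return List with `t_start`, `t_end`: trimmed bounds within the window.
#' @export
trim_to_pre <- function(dotbracket, mature_span, star_span) {
  pt <- pair_table(dotbracket)
  n <- length(pt)
  left <- min(mature_span[[1]], star_span[[1]])
  right <- max(mature_span[[2]], star_span[[2]])
  i <- left - 1L
  j <- right + 1L
  while (i >= 1L && j <= n && pt[i] == j) {
    i <- i - 1L
    j <- j + 1L
  }
  if (i < 1L || j > n) {
    return(list(t_start = max(1L, i + 1L), t_end = min(n, j - 1L)))
  }
  # include the interrupting bulge/interior loop, cut before the next helix
  i2 <- i
  while (i2 >= 1L && pt[i2] == 0L) i2 <- i2 - 1L
  j2 <- j
  while (j2 <= n && pt[j2] == 0L) j2 <- j2 + 1L
  t_start <- if (pt[max(i, 1L)] == 0L && i >= 1L) i2 + 1L else i + 1L
  t_end <- if (j <= n && pt[min(j, n)] == 0L) j2 - 1L else j - 1L
  list(t_start = as.integer(t_start), t_end = as.integer(t_end))
}

#' Score a trimmed precursor candidate
#'
#' Computes base composition, MFE-derived quantities and the pass/fail
#' decision: AMFE is `|MFE| / length x 100` (kcal/mol per 100 nt), MFEI is
#' AMFE divided by GC percentage (0-100 scale), and a candidate passes when
#' MFEI >= `mfei_threshold`, the longest clean helix run on one arm is at
#' least `min_ds_segment`, both arms are within `[arm_min, arm_max]` and the
#' hairpin has a single terminal loop.
#'
#' @param candidate One-row tibble with `pre_sequence`, `dotbracket`, `mfe`,
#'   `mature_start`, `mature_end`, `star_start`, `star_end` (precursor
#'   coordinates).
#' @param config A [run_config()].
#' @return The candidate row with `gc_percent`, `au_percent`, `amfe`, `mfei`,
#'   `n_base_pairs`, `ds_segment_len`, `passes`, `fail_reason` added.
#' @export
score_candidate <- function(candidate, config = run_config()) {
  out <- candidate
  len <- nchar(out$pre_sequence)
  out$gc_percent <- gc_percent(out$pre_sequence)
  out$au_percent <- 100 - out$gc_percent
  out$amfe <- abs(out$mfe) / len * 100
  out$mfei <- if (out$gc_percent > 0) out$amfe / out$gc_percent else NA_real_
  pt <- pair_table(out$dotbracket)
  out$n_base_pairs <- sum(pt > 0) / 2L
  out$ds_segment_len <- longest_helix_run(pt)
  n_loops <- stringr::str_count(out$dotbracket, "\\(\\.*\\)")
  mature_len <- out$mature_end - out$mature_start + 1L
  star_len <- if (is.na(out$star_start)) NA_integer_ else {
    out$star_end - out$star_start + 1L
  }
  reasons <- character()
  if (is.na(out$star_start)) reasons <- c(reasons, "no star arm")
  if (is.na(out$mfei)) {
    reasons <- c(reasons, "zero GC")
  } else if (out$mfei < config$mfei_threshold) {
    reasons <- c(reasons, "MFEI below threshold")
  }
  if (out$ds_segment_len < config$min_ds_segment) {
    reasons <- c(reasons, "double-stranded segment too short")
  }
  arm_bad <- mature_len < config$arm_min || mature_len > config$arm_max ||
    (!is.na(star_len) && (star_len < config$arm_min || star_len > config$arm_max))
  if (arm_bad) reasons <- c(reasons, "arm length out of range")
  if (n_loops != 1) reasons <- c(reasons, "not a single-loop hairpin")
  out$passes <- length(reasons) == 0
  out$fail_reason <- if (out$passes) NA_character_ else {
    paste(reasons, collapse = "; ")
  }
  out
}

# Longest run of consecutive paired positions forming a clean helix
# (partners strictly consecutive).
longest_helix_run <- function(pt) {
  best <- 0L
  run <- 0L
  for (i in seq_along(pt)) {
    if (pt[i] > 0 && (run == 0L || pt[i] == pt[i - 1L] - 1L)) {
      run <- run + 1L
    } else {
      run <- if (pt[i] > 0) 1L else 0L
    }
    if (run > best) best <- run
  }
  best
}

#' Predict hairpin precursors for a set of mature miRNAs
#'
#' Full precursor stage: genome mapping, flank extraction, folding, star
#' location, trimming, refolding of the trimmed precursor and scoring.
#' Candidates from nearby hits whose trimmed coordinates coincide are
#' deduplicated.
#'
#' @param mirnas Tibble with `mirna_id`, `sequence` and optionally `family`,
#'   `group_id` columns.
#' @param genome Named character vector of contigs.
#' @param config A [run_config()].
#' @return Tibble of precursor candidates, one row per retained candidate,
#'   with genomic coordinates, folded structure, scores and `passes` flag.
#'   The folding engine used is recorded in the `engine` column.
#' @export
predict_precursors <- function(mirnas, genome, config = run_config()) {
  if (!is.data.frame(mirnas)) {
    mirnas <- tibble(mirna_id = names(mirnas), sequence = unname(mirnas))
  }
  if (!"family" %in% names(mirnas)) mirnas$family <- NA_character_
  if (!"group_id" %in% names(mirnas)) mirnas$group_id <- NA_character_
  hits <- map_to_genome(mirnas, genome, config)
  if (nrow(hits) == 0) return(empty_precursor_table())
  windows <- purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    extract_candidate(hits[i, ], genome, config$flank)
  })
  folded <- fold_rna(windows$window, engine = config$fold_engine)
  rows <- purrr::map(seq_len(nrow(windows)), function(i) {
    build_candidate(windows[i, ], folded[i, ], config)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty_precursor_table())
  cand <- bind_rows(rows) %>%
    left_join(select(mirnas, "mirna_id", "family", "group_id"),
              by = "mirna_id") %>%
    distinct(.data$contig, .data$strand, .data$pre_start0, .data$pre_end0,
             .data$mirna_id, .keep_all = TRUE) %>%
    arrange(.data$contig, .data$pre_start0, .data$mirna_id)
  cand
}

# Fold-derived construction of one candidate from its window row.
build_candidate <- function(win, fold_row, config) {
  star <- locate_star(fold_row$dotbracket, win$mature_start, win$mature_end)
  if (is.null(star)) {
    # keep as a failed candidate anchored on the untrimmed window
    pre <- win$window
    cand <- tibble(
      mirna_id = win$mirna_id, contig = win$contig, strand = win$strand,
      pre_start0 = win$win_start0, pre_end0 = win$win_end0,
      pre_sequence = pre, dotbracket = fold_row$dotbracket,
      mfe = fold_row$mfe, engine = fold_row$engine,
      mature_start = win$mature_start, mature_end = win$mature_end,
      star_start = NA_integer_, star_end = NA_integer_
    )
    return(score_candidate(cand, config))
  }
  tr <- trim_to_pre(fold_row$dotbracket,
                    c(win$mature_start, win$mature_end),
                    c(star$star_start, star$star_end))
  pre <- substr(win$window, tr$t_start, tr$t_end)
  if (nchar(pre) < 15) return(NULL)
  refold <- fold_rna(pre, engine = fold_row$engine)
  ms <- win$mature_start - tr$t_start + 1L
  me <- win$mature_end - tr$t_start + 1L
  star2 <- locate_star(refold$dotbracket, ms, me)
  if (win$strand == "+") {
    ps0 <- win$win_start0 + tr$t_start - 1L
    pe0 <- win$win_start0 + tr$t_end
  } else {
    ps0 <- win$win_end0 - tr$t_end
    pe0 <- win$win_end0 - tr$t_start + 1L
  }
  cand <- tibble(
    mirna_id = win$mirna_id, contig = win$contig, strand = win$strand,
    pre_start0 = ps0, pre_end0 = pe0,
    pre_sequence = pre, dotbracket = refold$dotbracket,
    mfe = refold$mfe, engine = refold$engine,
    mature_start = ms, mature_end = me,
    star_start = if (is.null(star2)) NA_integer_ else star2$star_start,
    star_end = if (is.null(star2)) NA_integer_ else star2$star_end
  )
  score_candidate(cand, config)
}

empty_precursor_table <- function() {
  tibble(
    mirna_id = character(), contig = character(), strand = character(),
    pre_start0 = integer(), pre_end0 = integer(), pre_sequence = character(),
    dotbracket = character(), mfe = numeric(), engine = character(),
    mature_start = integer(), mature_end = integer(),
    star_start = integer(), star_end = integer(), gc_percent = numeric(),
    au_percent = numeric(), amfe = numeric(), mfei = numeric(),
    n_base_pairs = numeric(), ds_segment_len = integer(), passes = logical(),
    fail_reason = character(), family = character(), group_id = character()
  )
}

#' Find genomic clusters of precursor candidates
#'
#' Same-contig candidates whose consecutive gaps are at most `max_gap` are
#' chained; chains of at least two members are reported as clusters
#' (tandemly repeated precursors).
#'
#' @param candidates Precursor candidate tibble.
#' @param max_gap Maximum gap (nt) between consecutive members.
#' @return The candidate rows that fall in clusters, with `cluster_id` and
#'   `cluster_size` columns.
#' @export
find_clusters <- function(candidates, max_gap = 10000L) {
  if (nrow(candidates) == 0) {
    return(mutate(candidates, cluster_id = character(),
                  cluster_size = integer()))
  }
  candidates %>%
    arrange(.data$contig, .data$pre_start0) %>%
    group_by(.data$contig) %>%
    mutate(gap = .data$pre_start0 - dplyr::lag(.data$pre_end0),
           chain = cumsum(is.na(.data$gap) | .data$gap > max_gap)) %>%
    group_by(.data$contig, .data$chain) %>%
    mutate(cluster_size = n()) %>%
    ungroup() %>%
    filter(.data$cluster_size >= 2) %>%
    mutate(cluster_id = paste0(.data$contig, "_c", .data$chain)) %>%
    select(-"gap", -"chain")
}

#' @rdname predict_precursors
#' @param object Precursor candidate tibble (for the plot helper).
#' @param ... Unused.
#' @export
plot_mfei <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$mfei, fill = .data$passes)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.8, position = "identity") +
    ggplot2::geom_vline(xintercept = 0.85, linetype = "dashed") +
    ggplot2::labs(x = "MFEI", y = "candidates") +
    ggplot2::theme_minimal()
}
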