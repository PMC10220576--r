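# Assignment of unique tags to conserved miRNA families and isomiR groups by
# ungapped comparison with reference mature miRNAs, tolerating a bounded
# number of substitutions and short end overhangs. Internal gaps are not
# allowed here (they are, in genome mapping).

#' Match one tag against one reference mature miRNA
#'
#' Slides the tag over the reference through every ungapped placement in which
#' each end of the tag overhangs or falls short of the reference by at most
#' `max_overhang` nucleotides, and returns the placement with the fewest
#' mismatches in the overlapping region (ties broken by smaller total end
#' offset). Overhanging tag bases are not counted as mismatches.
#'
#' Offsets follow the "additional/missing nucleotide" convention: a tag
#' missing the reference's first base has `offset_5p = -1`; a tag with one
#' extra base beyond the reference 3' end has `offset_3p = +1`.
#'
#' @param tag_sequence,reference_mature DNA sequences (character scalars).
#' @param max_mismatches Maximum substitutions tolerated.
#' @param max_overhang Maximum end offset (nt).
#' @return A list with `mismatches`, `offset_5p`, `offset_3p`, or `NULL` when
#'   no placement is within tolerance.
#' @export
match_tag <- function(tag_sequence, reference_mature,
                      max_mismatches = 2L, max_overhang = 2L) {
  tc <- strsplit(normalize_dna(tag_sequence), "")[[1]]
  rc <- strsplit(normalize_dna(reference_mature), "")[[1]]
  match_tag_chars(tc, rc, max_mismatches, max_overhang)
}

# Character-vector core used by both the public wrapper and assign_tags().
match_tag_chars <- function(tc, rc, max_mismatches, max_overhang) {
  lt <- length(tc)
  lr <- length(rc)
  best <- NULL
  for (a in seq.int(1L - max_overhang, 1L + max_overhang)) {
    off5 <- 1L - a
    off3 <- (a + lt - 1L) - lr
    if (abs(off3) > max_overhang) next
    lo <- max(1L, a)
    hi <- min(lr, a + lt - 1L)
    if (hi < lo) next
    mm <- sum(tc[(lo - a + 1L):(hi - a + 1L)] != rc[lo:hi])
    cand <- c(mm, abs(off5) + abs(off3))
    if (is.null(best) || cand[1] < best$key[1] ||
        (cand[1] == best$key[1] && cand[2] < best$key[2])) {
      best <- list(key = cand, mismatches = as.integer(mm),
                   offset_5p = off5, offset_3p = off3)
    }
  }
  if (is.null(best) || best$mismatches > max_mismatches) return(NULL)
  best[c("mismatches", "offset_5p", "offset_3p")]
}

#' Assign unique tags to reference miRNAs, families and isomiR groups
#'
#' Every tag is compared against every reference mature sequence with
#' [match_tag()]; the best assignment minimises mismatches, then total end
#' offset. Ties across two or more distinct reference mature sequences flag
#' the tag as ambiguously annotated; ties across families are resolved to the
#' lexicographically smallest family (also flagged ambiguous). Tags with no
#' reference within tolerance are labelled unannotated.
#'
#' IsomiR groups are the connected components of the bipartite graph linking
#' tags to their tied best reference sequences: tags sharing a best reference
#' mature sequence fall in one group, a partition finer than the family.
#'
#' @param tags Unique-tag tibble from [collapse_reads()].
#' @param references Reference tibble from [read_mirbase_fasta()].
#' @param config A [run_config()]; uses `max_mismatches_annotation`,
#'   `max_overhang`.
#' @return The tag tibble with added columns `annotated`, `family`,
#'   `group_id`, `accessions` (comma-separated tied best references),
#'   `mismatches`, `offset_5p`, `offset_3p`, `ambiguous`.
#' @export
assign_tags <- function(tags, references, config = run_config()) {
  if (nrow(references) == 0) abort("reference set is empty")
  mm_max <- config$max_mismatches_annotation
  ov_max <- config$max_overhang
  ref_chars <- strsplit(references$sequence, "")
  tag_chars <- strsplit(tags$sequence, "")

  res <- purrr::map(tag_chars, function(tc) {
    hits <- vector("list", nrow(references))
    for (r in seq_len(nrow(references))) {
      m <- match_tag_chars(tc, ref_chars[[r]], mm_max, ov_max)
      if (!is.null(m)) hits[[r]] <- c(r, m$mismatches, m$offset_5p, m$offset_3p)
    }
    hits <- hits[!vapply(hits, is.null, logical(1))]
    if (length(hits) == 0) return(NULL)
    h <- do.call(rbind, hits)
    key <- h[, 2] * 1000 + abs(h[, 3]) + abs(h[, 4])
    h[key == min(key), , drop = FALSE]
  })

  annotated <- !vapply(res, is.null, logical(1))
  out <- tags
  out$annotated <- annotated
  out$family <- NA_character_
  out$accessions <- NA_character_
  out$mismatches <- NA_integer_
  out$offset_5p <- NA_integer_
  out$offset_3p <- NA_integer_
  out$ambiguous <- NA
  ref_index <- vector("list", nrow(tags))  # tied best reference rows per tag
  for (i in which(annotated)) {
    h <- res[[i]]
    refs <- h[, 1]
    # order tied references deterministically by accession
    ord <- order(references$accession[refs])
    refs <- refs[ord]
    h <- h[ord, , drop = FALSE]
    ref_index[[i]] <- refs
    fams <- sort(unique(references$family[refs]))
    out$family[i] <- fams[1]
    out$accessions[i] <- paste(references$accession[refs], collapse = ",")
    out$mismatches[i] <- as.integer(h[1, 2])
    out$offset_5p[i] <- as.integer(h[1, 3])
    out$offset_3p[i] <- as.integer(h[1, 4])
    out$ambiguous[i] <- length(unique(references$sequence[refs])) >= 2
  }
  out$group_id <- group_components(ref_index, references)
  out
}

# Connected components of the tag <-> best-reference-sequence graph, labelled
# "<family>_g<k>" with k ordered by the smallest accession in the component.
group_components <- function(ref_index, references) {
  # union-find over distinct reference mature sequences
  seq_ids <- references$sequence
  parent <- seq_len(nrow(references))
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  # identical sequences are one node
  seq_map <- split(seq_len(nrow(references)), seq_ids)
  for (grp in seq_map) {
    for (j in grp[-1]) parent[find(j)] <- find(grp[1])
  }
  for (refs in ref_index) {
    if (is.null(refs) || length(refs) < 2) next
    for (j in refs[-1]) parent[find(j)] <- find(refs[1])
  }
  roots <- vapply(seq_len(nrow(references)), find, integer(1))
  # label components that actually received tags
  labels <- rep(NA_character_, length(ref_index))
  used_roots <- unique(vapply(
    which(!vapply(ref_index, is.null, logical(1))),
    function(i) find(ref_index[[i]][1]), integer(1)
  ))
  if (length(used_roots) > 0) {
    comp_fam <- vapply(used_roots, function(r) {
      sort(references$family[roots == r])[1]
    }, character(1))
    comp_acc <- vapply(used_roots, function(r) {
      sort(references$accession[roots == r])[1]
    }, character(1))
    ord <- order(comp_fam, comp_acc)
    comp_id <- setNames(
      paste0(comp_fam[ord], "_g", stats::ave(seq_along(ord), comp_fam[ord],
                                             FUN = seq_along)),
      used_roots[ord]
    )
    for (i in seq_along(ref_index)) {
      if (!is.null(ref_index[[i]])) {
        labels[i] <- comp_id[[as.character(find(ref_index[[i]][1]))]]
      }
    }
  }
  labels
}

#' Aggregate tag assignments into isomiR groups
#'
#' Sums member-tag counts per library within each isomiR group and builds a
#' per-group consensus sequence: members are stacked at the alignment offsets
#' of their best reference placement and the majority base is taken at each
#' column (ties to the alphabetically first base).
#'
#' @param assignments Output of [assign_tags()].
#' @param library_ids Character vector naming the count columns.
#' @return Tibble with one row per group: `group_id`, `family`, `n_members`,
#'   `consensus`, one count column per library, `total_count`.
#' @export
isomir_groups <- function(assignments, library_ids) {
  ann <- filter(assignments, .data$annotated)
  if (nrow(ann) == 0) {
    out <- tibble(group_id = character(), family = character(),
                  n_members = integer(), consensus = character())
    for (lib in library_ids) out[[lib]] <- integer()
    out$total_count <- integer()
    return(out)
  }
  ann %>%
    group_by(.data$group_id, .data$family) %>%
    summarise(
      n_members = n(),
      consensus = consensus_sequence(.data$sequence, .data$offset_5p),
      across(dplyr::all_of(library_ids), sum),
      total_count = sum(.data$total_count),
      .groups = "drop"
    ) %>%
    arrange(.data$group_id)
}

# Majority-base consensus of sequences stacked at reference-relative offsets.
# offset_5p > 0 means the tag starts before reference position 1.
consensus_sequence <- function(sequences, offset_5p) {
  starts <- 1L - offset_5p            # position of tag base 1 on the ref axis
  ends <- starts + nchar(sequences) - 1L
  lo <- min(starts)
  width <- max(ends) - lo + 1L
  mat <- matrix(NA_character_, nrow = length(sequences), ncol = width)
  for (i in seq_along(sequences)) {
    cols <- (starts[i] - lo + 1L):(ends[i] - lo + 1L)
    mat[i, cols] <- strsplit(sequences[i], "")[[1]]
  }
  # columns carried by fewer than half the members (rare end extensions)
  # are trimmed so the consensus reflects the canonical span
  covered <- colSums(!is.na(mat)) >= length(sequences) / 2
  mat <- mat[, covered, drop = FALSE]
  cons <- apply(mat, 2, function(col) {
    col <- col[!is.na(col)]
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[tab == max(tab)][1]
  })
  paste(cons, collapse = "")
}

#' Per-family presence and isomiR summaries across sample groups
#'
#' A family is present in a sample group when any member tag has a nonzero
#' count in any library of that group; the per-group isomiR count counts
#' member tags with nonzero counts in the group.
#'
#' @param assignments Output of [assign_tags()].
#' @param design Design tibble (`library_id`, `sample_group`).
#' @return Tibble with one row per family and sample group: `family`,
#'   `sample_group`, `n_isomirs`, `read_count`, `present`; plus attribute-free
#'   totals obtainable by summarising.
#' @export
summarize_families <- function(assignments, design) {
  validate_design(design, groups = NULL)
  libs_missing <- setdiff(design$library_id, names(assignments))
  if (length(libs_missing) > 0) {
    abort(paste0("design libraries absent from assignment counts: ",
                 paste(libs_missing, collapse = ", ")))
  }
  ann <- filter(assignments, .data$annotated)
  long <- ann %>%
    select("sequence", "family", dplyr::all_of(design$library_id)) %>%
    tidyr::pivot_longer(dplyr::all_of(design$library_id),
                        names_to = "library_id", values_to = "count") %>%
    left_join(select(design, "library_id", "sample_group"), by = "library_id")
  long %>%
    group_by(.data$family, .data$sample_group, .data$sequence) %>%
    summarise(tag_count = sum(.data$count), .groups = "drop") %>%
    group_by(.data$family, .data$sample_group) %>%
    summarise(
      n_isomirs = sum(.data$tag_count > 0),
      read_count = sum(.data$tag_count),
      present = any(.data$tag_count > 0),
      .groups = "drop"
    ) %>%
    arrange(.data$family, .data$sample_group)
}
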