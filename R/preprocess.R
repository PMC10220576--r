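# Read preprocessing: adapter trimming, length filtering and collapsing of
# reads into unique tags with per-library counts.

#' Trim a 3' adapter from read sequences
#'
#' Finds the leftmost exact match of the adapter's first `match_len` bases and
#' removes everything from that position onwards. Sequences without a match
#' pass through unchanged; with `adapter = NULL` the call is a no-op.
#'
#' @param sequences Character vector of read sequences (DNA alphabet).
#' @param adapter Adapter sequence, or `NULL` for no trimming.
#' @param match_len Number of leading adapter bases that must match exactly
#'   (default 8).
#' @return Character vector of trimmed sequences.
#' @export
trim_adapter <- function(sequences, adapter = NULL, match_len = 8L) {
  if (is.null(adapter)) return(sequences)
  if (!nzchar(adapter)) abort("adapter must be non-empty when provided")
  probe <- substr(normalize_dna(adapter), 1L, match_len)
  hit <- unname(stringr::str_locate(sequences, stringr::fixed(probe))[, "start"])
  ifelse(is.na(hit), sequences, substr(sequences, 1L, hit - 1L))
}

#' Collapse reads into unique tags with per-library counts
#'
#' Applies adapter trimming and the length window, then counts each distinct
#' surviving sequence per library and drops tags whose total count across all
#' libraries falls below `min_total_count`. This is the unique-tag table on
#' which all downstream annotation and expression analysis operates.
#'
#' @param reads Tibble with columns `library_id` and `sequence` (one row per
#'   read; all libraries stacked).
#' @param config A [run_config()]; uses `adapter`, `adapter_match_len`,
#'   `min_len`, `max_len` and `min_total_count`.
#' @return Tibble with columns `sequence`, `length`, one count column per
#'   library (named by `library_id`), and `total_count`; rows ordered by
#'   descending `total_count` then sequence. Zero surviving tags yield an
#'   empty tibble with a warning.
#' @export
collapse_reads <- function(reads, config = run_config()) {
  stopifnot(all(c("library_id", "sequence") %in% names(reads)))
  libs <- sort(unique(reads$library_id))  # column order independent of input
  trimmed <- trim_adapter(normalize_dna(reads$sequence), config$adapter,
                          config$adapter_match_len)
  keep <- nchar(trimmed) >= config$min_len & nchar(trimmed) <= config$max_len
  dat <- tibble(library_id = reads$library_id[keep], sequence = trimmed[keep])
  if (nrow(dat) == 0) {
    warn("no reads survive trimming and length filtering")
    return(empty_tag_table(libs))
  }
  tags <- dat %>%
    count(.data$sequence, .data$library_id) %>%
    tidyr::pivot_wider(names_from = "library_id", values_from = "n",
                       values_fill = 0L)
  for (lib in setdiff(libs, names(tags))) tags[[lib]] <- 0L
  tags <- tags[, c("sequence", libs)]
  tags$total_count <- as.integer(rowSums(tags[, libs, drop = FALSE]))
  tags <- tags %>%
    filter(.data$total_count >= config$min_total_count) %>%
    mutate(length = nchar(.data$sequence), .after = "sequence") %>%
    arrange(desc(.data$total_count), .data$sequence)
  if (nrow(tags) == 0) warn("no tags reach the minimum total count")
  tags
}

empty_tag_table <- function(libs) {
  out <- tibble(sequence = character(), length = integer())
  for (lib in libs) out[[lib]] <- integer()
  out$total_count <- integer()
  out
}

#' Collapse FASTQ libraries listed in a design table
#'
#' Convenience wrapper that reads every FASTQ in the design and calls
#' [collapse_reads()].
#'
#' @param design Design tibble with `library_id` and `fastq_path`.
#' @param config A [run_config()].
#' @return Unique-tag tibble (see [collapse_reads()]).
#' @export
collapse_libraries <- function(design, config = run_config()) {
  validate_design(design, groups = NULL)
  reads <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
    fq <- read_fastq(design$fastq_path[i])
    tibble(library_id = design$library_id[i], sequence = fq$sequence)
  })
  # make sure empty libraries still get a count column
  if (nrow(reads) == 0) {
    warn("no reads in any library")
    return(empty_tag_table(design$library_id))
  }
  reads$library_id <- factor(reads$library_id, levels = design$library_id)
  out <- collapse_reads(mutate(reads, library_id = as.character(.data$library_id)),
                        config)
  for (lib in setdiff(design$library_id, names(out))) out[[lib]] <- 0L
  out[, c("sequence", "length", design$library_id, "total_count")]
}

#' Library sizes from a stacked read table
#'
#' Number of reads per library inside the length window after trimming;
#' used as the denominator for counts-per-million normalisation.
#'
#' @param reads Tibble with `library_id`, `sequence`.
#' @param config A [run_config()].
#' @return Named integer vector of per-library read counts.
#' @export
library_sizes <- function(reads, config = run_config()) {
  trimmed <- trim_adapter(normalize_dna(reads$sequence), config$adapter,
                          config$adapter_match_len)
  keep <- nchar(trimmed) >= config$min_len & nchar(trimmed) <= config$max_len
  tab <- table(reads$library_id[keep])
  setNames(as.integer(tab), names(tab))
}
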