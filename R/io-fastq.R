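# FASTQ input for small-RNA libraries. Records are the plain 4-line form
# (Sanger qualities). A strict record-level parser is used rather than a bulk
# reader so malformed records can be reported with their line number, which is
# the failure mode that actually occurs with truncated small-RNA uploads.

#' Read a FASTQ file
#'
#' Sequences are uppercased and U is normalised to T on the way in.
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return A tibble with columns `read_id`, `sequence`, `quality`, in file
#'   order. Empty files yield an empty tibble.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    return(tibble(read_id = character(), sequence = character(),
                  quality = character()))
  }
  if (length(lines) %% 4 != 0) {
    abort(paste0("malformed FASTQ: ", path, " has ", length(lines),
                 " lines (truncated record starting at line ",
                 4 * (length(lines) %/% 4) + 1, ")"))
  }
  idx <- seq(1, length(lines), by = 4)
  hdr <- lines[idx]
  seqs <- lines[idx + 1]
  plus <- lines[idx + 2]
  qual <- lines[idx + 3]

  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr) > 0) {
    abort(paste0("malformed FASTQ record: line ", idx[bad_hdr[1]],
                 " does not start with '@'"))
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus) > 0) {
    abort(paste0("malformed FASTQ record: line ", idx[bad_plus[1]] + 2,
                 " does not start with '+'"))
  }
  bad_len <- which(nchar(seqs) != nchar(qual))
  if (length(bad_len) > 0) {
    abort(paste0("malformed FASTQ record: quality length differs from ",
                 "sequence length at line ", idx[bad_len[1]] + 3))
  }
  tibble(
    read_id = sub("^@", "", sub("\\s.*$", "", hdr)),
    sequence = normalize_dna(seqs),
    quality = qual
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  out <- character(4 * nrow(reads))
  if (nrow(reads) > 0) {
    out[seq(1, length(out), 4)] <- paste0("@", reads$read_id)
    out[seq(2, length(out), 4)] <- reads$sequence
    out[seq(3, length(out), 4)] <- "+"
    out[seq(4, length(out), 4)] <- reads$quality
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a library design table
#'
#' The design table links sequencing libraries to sample groups (by default
#' the four maturity states REV, IVM, JUV and MAT) and to their FASTQ files.
#'
#' @param path Path to a TSV with columns `library_id`, `sample_group`,
#'   `fastq_path`.
#' @param groups Allowed sample-group labels.
#' @return A tibble with the three design columns.
#' @export
read_design <- function(path, groups = c("REV", "IVM", "JUV", "MAT")) {
  design <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if ("fastq_path" %in% names(design)) {
    # relative FASTQ paths are resolved against the design file's directory
    rel <- !grepl("^(/|[A-Za-z]:)", design$fastq_path)
    design$fastq_path[rel] <- file.path(dirname(path), design$fastq_path[rel])
  }
  validate_design(design, groups)
}

#' Validate a design table
#'
#' @param design Data frame with `library_id` and `sample_group` columns
#'   (`fastq_path` optional for in-memory runs).
#' @param groups Allowed sample-group labels, or `NULL` to accept any.
#' @return The design as a tibble, invisibly checked.
#' @export
validate_design <- function(design, groups = NULL) {
  need <- c("library_id", "sample_group")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0) {
    abort(paste0("design table lacks columns: ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(design$library_id)) {
    abort("design table has duplicated library_ids")
  }
  if (!is.null(groups)) {
    bad <- setdiff(unique(design$sample_group), groups)
    if (length(bad) > 0) {
      abort(paste0("unknown sample groups in design: ",
                   paste(bad, collapse = ", ")))
    }
  }
  as_tibble(design)
}
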