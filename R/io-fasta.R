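# FASTA input/output. Plain sequence files (genome contigs, transcripts) go
# through Biostrings; the miRBase reader adds header parsing into species,
# family and arm.

#' Read a FASTA file into a named character vector
#'
#' @param path Path to a (multi-)FASTA file.
#' @param normalize Convert to the internal DNA alphabet (uppercase, U->T)?
#' @return Named character vector of sequences; names are the first
#'   whitespace-separated header token.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  ss <- Biostrings::readBStringSet(path)
  out <- normalize_dna(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Parse a miRBase-style identifier into species, family and arm
#'
#' The family is obtained by stripping the species prefix (e.g. `gma-`), the
#' arm suffix (`-3p`/`-5p`) and any trailing variant letters or numbers after
#' the core `miR<number>`/`let<number>` identifier, so `gma-miR156a` and
#' `ath-miR156f-5p` both collapse to family `miR156`. This matches the family
#' granularity at which conserved plant miRNAs are conventionally reported.
#'
#' @param id Character vector of miRBase identifiers.
#' @return Tibble with columns `accession`, `species_code`, `family`, `arm`
#'   (`NA` when no arm suffix), `parseable` (logical).
#' @export
parse_mirbase_id <- function(id) {
  m <- stringr::str_match(
    id,
    "^([A-Za-z]{3,4})-((?:miR|let)-?[0-9]+)([A-Za-z][A-Za-z0-9._-]*)?$"
  )
  arm <- stringr::str_match(id, "-(3p|5p)$")[, 2]
  family <- sub("^let-?", "let", sub("^miR-?", "miR", m[, 3]))
  tibble(
    accession = id,
    species_code = tolower(m[, 2]),
    family = family,
    arm = arm,
    parseable = !is.na(m[, 1])
  )
}

#' Read reference mature miRNAs from a miRBase-style FASTA
#'
#' Headers are expected to begin with a miRBase-style identifier such as
#' `gma-miR156a` or `ath-miR172b-3p`. Sequences are normalised to the DNA
#' alphabet (U->T). Records whose header does not contain a parseable
#' miR/let identifier are skipped with a warning.
#'
#' @param path Path to the FASTA file.
#' @param kind Label recorded for all records (`"mature"` or `"hairpin"`).
#' @return Tibble with columns `accession`, `species_code`, `family`, `arm`,
#'   `kind`, `sequence`.
#' @export
read_mirbase_fasta <- function(path, kind = c("mature", "hairpin")) {
  kind <- match.arg(kind)
  seqs <- read_fasta(path)
  if (anyDuplicated(names(seqs))) {
    dup <- unique(names(seqs)[duplicated(names(seqs))])
    abort(paste0("duplicate accessions in ", path, ": ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  parsed <- parse_mirbase_id(names(seqs))
  if (any(!parsed$parseable)) {
    skipped <- parsed$accession[!parsed$parseable]
    warn(paste0("skipping ", length(skipped),
                " record(s) without a parseable miR/let identifier: ",
                paste(head(skipped, 5), collapse = ", ")))
  }
  parsed %>%
    mutate(kind = kind, sequence = unname(seqs)) %>%
    filter(.data$parseable) %>%
    select("accession", "species_code", "family", "arm", "kind", "sequence")
}
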