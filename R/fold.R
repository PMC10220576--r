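# RNA secondary-structure prediction behind a pluggable engine contract:
# (sequence) -> (dot-bracket, MFE). The default engine shells out to RNAfold
# (ViennaRNA); the built-in "stackmax" engine is a stacking-weighted
# base-pair maximisation implemented in C++ for hermetic use. The engine used
# is recorded in the output so downstream tables carry their provenance.

#' Fold RNA sequences into minimum-free-energy secondary structures
#'
#' @param sequences Character vector of sequences (DNA or RNA alphabet;
#'   converted to RNA internally). Each must be at least 15 nt.
#' @param engine `"auto"` (RNAfold when available, otherwise the built-in
#'   engine), `"vienna"`, or `"stackmax"`.
#' @return Tibble with columns `sequence` (RNA), `dotbracket`, `mfe`
#'   (kcal/mol, <= 0), `n_base_pairs`, `engine`.
#' @export
fold_rna <- function(sequences, engine = c("auto", "vienna", "stackmax")) {
  engine <- match.arg(engine)
  if (length(sequences) == 0) {
    return(tibble(sequence = character(), dotbracket = character(),
                  mfe = numeric(), n_base_pairs = integer(),
                  engine = character()))
  }
  if (any(nchar(sequences) < 15)) {
    abort("sequences must be at least 15 nt to fold")
  }
  rna <- dna_to_rna(sequences)
  if (engine == "auto") {
    engine <- if (rnafold_available()) "vienna" else "stackmax"
  }
  out <- switch(engine,
    vienna = fold_vienna(rna),
    stackmax = fold_stackmax(rna)
  )
  out$n_base_pairs <- stringr::str_count(out$dotbracket, "\\(")
  out$engine <- engine
  out
}

rnafold_available <- function() nzchar(Sys.which("RNAfold"))

fold_vienna <- function(rna) {
  if (!rnafold_available()) {
    abort("RNAfold binary not found; use engine = \"stackmax\"")
  }
  ids <- sprintf("s%06d", seq_along(rna))
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa), add = TRUE)
  writeLines(paste0(">", ids, "\n", rna), fa)
  raw <- suppressWarnings(
    system2("RNAfold", c("--noPS", "--infile", fa), stdout = TRUE)
  )
  # records: >id / sequence / structure ( energy )
  hdr <- grep("^>", raw)
  if (length(hdr) != length(rna)) abort("RNAfold returned unexpected output")
  struct_line <- raw[hdr + 2]
  m <- stringr::str_match(struct_line, "^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)")
  if (anyNA(m[, 1])) abort("could not parse RNAfold structure line")
  tibble(sequence = rna, dotbracket = m[, 2], mfe = as.numeric(m[, 3]))
}

fold_stackmax <- function(rna) {
  res <- purrr::map(rna, function(s) .nussinov_fold(s, 3L))
  db <- vapply(res, function(r) drop_lone_pairs(r$dotbracket), character(1))
  # surrogate energy: stability-weighted pairs plus a stacking bonus,
  # scaled so designed GC-rich hairpins land near thermodynamic magnitudes
  mfe <- vapply(seq_along(rna), function(i) {
    pt <- pair_table(db[i])
    if (!any(pt > 0)) return(0)
    ch <- strsplit(rna[i], "")[[1]]
    idx <- which(pt > seq_along(pt))
    w <- vapply(idx, function(p) {
      pairing <- paste0(ch[p], ch[pt[p]])
      switch(pairing, GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1, 0)
    }, numeric(1))
    stacks <- sum(vapply(idx, function(p) {
      p < length(pt) && pt[p + 1] == pt[p] - 1
    }, logical(1)))
    -0.6 * (sum(w) + stacks)
  }, numeric(1))
  tibble(sequence = rna, dotbracket = db, mfe = mfe)
}

# Remove isolated base pairs (no stacked neighbour), which the base-pair
# maximisation otherwise scatters through loops.
drop_lone_pairs <- function(db) {
  pt <- pair_table(db)
  n <- length(pt)
  keep <- rep(FALSE, n)
  for (i in which(pt > 0)) {
    j <- pt[i]
    up <- i > 1 && j < n && pt[i - 1] == j + 1
    down <- i < n && j > 1 && pt[i + 1] == j - 1
    keep[i] <- up || down
  }
  ch <- strsplit(db, "")[[1]]
  ch[!keep & ch != "."] <- "."
  paste(ch, collapse = "")
}

#' Write folded structures in Vienna format
#'
#' One record per structure: header, sequence, and the dot-bracket line with
#' the energy in parentheses.
#'
#' @param folded Tibble from [fold_rna()] (or a candidate table with
#'   `pre_sequence`, `dotbracket`, `mfe`).
#' @param path Output path.
#' @param ids Optional record identifiers.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(folded, path, ids = NULL) {
  seqs <- if ("pre_sequence" %in% names(folded)) {
    dna_to_rna(folded$pre_sequence)
  } else {
    folded$sequence
  }
  if (is.null(ids)) ids <- sprintf("structure_%d", seq_along(seqs))
  rec <- paste0(">", ids, "\n", seqs, "\n", folded$dotbracket,
                sprintf(" (%.2f)", folded$mfe))
  writeLines(rec, path)
  invisible(path)
}
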