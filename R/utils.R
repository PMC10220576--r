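# Sequence helpers shared across modules. All sequences are held internally in
# the DNA alphabet (U -> T) because the genome and transcript references are
# DNA; conversion back to RNA happens only at the folding boundary.

#' Reverse complement of DNA sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (ACGT).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Normalise a sequence to the internal DNA alphabet
#'
#' Uppercases and converts U to T.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector in ACGT.
#' @export
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Convert DNA to RNA alphabet (T -> U)
#' @param x Character vector of DNA sequences.
#' @return Character vector in ACGU.
#' @export
dna_to_rna <- function(x) chartr("T", "U", toupper(x))

#' GC percentage of a sequence
#' @param x Character vector of sequences.
#' @return Numeric vector, percent on the 0-100 scale.
#' @export
gc_percent <- function(x) {
  n <- nchar(x)
  gc <- stringr::str_count(toupper(x), "[GCgc]")
  ifelse(n == 0, NA_real_, 100 * gc / n)
}

# Random DNA of given lengths with a target GC fraction.
random_dna <- function(n_seqs, len, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n_seqs), function(i) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# Base-pair table of a dot-bracket string: integer vector with pt[i] = j when
# i pairs j, 0 when unpaired. Errors on unbalanced brackets.
pair_table <- function(dotbracket) {
  ch <- strsplit(dotbracket, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) abort("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    } else if (ch[i] != ".") {
      abort(paste0("invalid dot-bracket character '", ch[i], "'"))
    }
  }
  if (length(stack) > 0) abort("unbalanced dot-bracket string")
  pt
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles a sequence while preserving its exact dinucleotide composition
#' (random Eulerian walk on the dinucleotide transition multigraph). Used to
#' build structure-free null sequences with realistic local composition, the
#' standard control when arguing that hairpin MFEI reflects structure rather
#' than base content.
#'
#' @param x A single sequence (character scalar).
#' @param max_tries Retry budget for drawing a complete Eulerian walk.
#' @return A shuffled sequence with identical dinucleotide counts.
#' @export
shuffle_dinucleotide <- function(x, max_tries = 200L) {
  ch <- strsplit(toupper(x), "")[[1]]
  n <- length(ch)
  if (n < 3) return(x)
  for (try in seq_len(max_tries)) {
    succ <- split(ch[-1], ch[-n])            # outgoing edges per vertex
    succ <- lapply(succ, sample)             # permute edge order
    used <- lapply(succ, function(v) 0L)
    walk <- character(n)
    walk[1] <- ch[1]
    cur <- ch[1]
    ok <- TRUE
    for (i in 2:n) {
      k <- used[[cur]] + 1L
      if (k > length(succ[[cur]])) { ok <- FALSE; break }
      used[[cur]] <- k
      cur <- succ[[cur]][k]
      walk[i] <- cur
    }
    if (ok) return(paste(walk, collapse = ""))
  }
  warn("dinucleotide shuffle failed; returning a mononucleotide shuffle")
  paste(sample(ch), collapse = "")
}

# Internal: run code with a derived RNG seed without touching caller state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% .Machine$integer.max), code)
}
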