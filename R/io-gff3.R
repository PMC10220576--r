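# GFF3 output of predicted precursors. Internally all genomic intervals are
# 0-based half-open on the forward strand; GFF3 is 1-based inclusive, so the
# conversion is start+1 / end. Features are written as pre_miRNA parents with
# miRNA (mature) and miRNA_star children, through rtracklayer.

#' Write precursor candidates to GFF3
#'
#' @param precursors Precursor candidate tibble as returned by
#'   [predict_precursors()] (needs `contig`, `strand`, `pre_start0`,
#'   `pre_end0`, mature/star spans, `family`, `group_id`, `mfei`, `passes`).
#' @param path Output path.
#' @param contig_lengths Optional named integer vector of contig lengths; when
#'   given, coordinates outside a contig raise an error.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(precursors, path, contig_lengths = NULL) {
  p <- precursors
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[p$contig]
    if (anyNA(len)) abort("precursor contig absent from contig_lengths")
    if (any(p$pre_start0 < 0 | p$pre_end0 > len)) {
      abort("precursor coordinates outside contig length")
    }
  }
  rows <- list()
  for (i in seq_len(nrow(p))) {
    id <- sprintf("premir%03d", i)
    pre <- p[i, ]
    mat <- mature_contig_span(pre)
    star <- star_contig_span(pre)
    rows[[length(rows) + 1]] <- tibble(
      seqnames = pre$contig, start = pre$pre_start0 + 1L, end = pre$pre_end0,
      strand = pre$strand, type = "pre_miRNA", ID = id, Parent = NA_character_,
      family = pre$family, group_id = pre$group_id,
      mfei = pre$mfei, passes = pre$passes
    )
    rows[[length(rows) + 1]] <- tibble(
      seqnames = pre$contig, start = mat[1] + 1L, end = mat[2],
      strand = pre$strand, type = "miRNA", ID = paste0(id, ".mature"),
      Parent = id, family = pre$family, group_id = pre$group_id,
      mfei = NA_real_, passes = NA
    )
    if (!is.na(pre$star_start)) {
      rows[[length(rows) + 1]] <- tibble(
        seqnames = pre$contig, start = star[1] + 1L, end = star[2],
        strand = pre$strand, type = "miRNA_star", ID = paste0(id, ".star"),
        Parent = id, family = pre$family, group_id = pre$group_id,
        mfei = NA_real_, passes = NA
      )
    }
  }
  tab <- bind_rows(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$seqnames,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = tab$type, ID = tab$ID,
    Parent = ifelse(is.na(tab$Parent), "", tab$Parent),
    family = tab$family, group_id = tab$group_id,
    mfei = tab$mfei, passes = tab$passes
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# Contig-forward 0-based half-open span of the mature arm of one candidate row.
mature_contig_span <- function(pre) {
  span_to_contig(pre$mature_start, pre$mature_end, pre)
}

star_contig_span <- function(pre) {
  if (is.na(pre$star_start)) return(c(NA_integer_, NA_integer_))
  span_to_contig(pre$star_start, pre$star_end, pre)
}

# Convert a 1-based inclusive span within the oriented pre_sequence to a
# 0-based half-open contig-forward interval.
span_to_contig <- function(s, e, pre) {
  if (pre$strand == "+") {
    c(pre$pre_start0 + s - 1L, pre$pre_start0 + e)
  } else {
    c(pre$pre_end0 - e, pre$pre_end0 - s + 1L)
  }
}

#' Read a precursor GFF3 back into a coordinate table
#'
#' Inverse of [write_gff3()] at the coordinate level: sequences and folding
#' detail are not stored in GFF3 and come back as `NA`.
#'
#' @param path Path to a GFF3 written by [write_gff3()].
#' @return Tibble with one row per pre_miRNA: `contig`, `strand`,
#'   `pre_start0`, `pre_end0`, contig-level mature/star spans, `family`,
#'   `group_id`, `mfei`, `passes`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(x) {
    if (length(x) == 0 || x == "") NA_character_ else as.character(x[[1]])
  }, character(1))
  pre <- df[df$type == "pre_miRNA", ]
  kids <- df[df$type != "pre_miRNA", ]
  purrr::map_dfr(seq_len(nrow(pre)), function(i) {
    id <- pre$ID[i]
    mat <- kids[kids$Parent == id & kids$type == "miRNA", ]
    star <- kids[kids$Parent == id & kids$type == "miRNA_star", ]
    tibble(
      contig = as.character(pre$seqnames[i]),
      strand = as.character(pre$strand[i]),
      pre_start0 = pre$start[i] - 1L, pre_end0 = pre$end[i],
      mature_contig_start0 = if (nrow(mat)) mat$start[1] - 1L else NA_integer_,
      mature_contig_end0 = if (nrow(mat)) mat$end[1] else NA_integer_,
      star_contig_start0 = if (nrow(star)) star$start[1] - 1L else NA_integer_,
      star_contig_end0 = if (nrow(star)) star$end[1] else NA_integer_,
      family = pre$family[i], group_id = pre$group_id[i],
      mfei = as.numeric(pre$mfei[i]), passes = as.logical(pre$passes[i])
    )
  })
}
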