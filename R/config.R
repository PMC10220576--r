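#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the pipeline with the defaults used
#' throughout: read length window 18-25 nt, minimum total tag count 5,
#' annotation tolerance of 2 mismatches and 2-nt end overhangs, differential
#' expression cut-offs |FC| >= 1.5 at FDR < 0.05, 100-nt precursor flanks,
#' MFEI >= 0.85 hairpin filter with a 19-nt double-stranded segment and
#' 19-25 nt arms, and psRNATarget-style target scoring with seed region 2-13
#' and expectation cut-off 5.
#'
#' @param min_len,max_len Read length window (nt) retained after trimming.
#' @param min_total_count Minimum summed count across all libraries for a
#'   unique tag to be kept.
#' @param max_mismatches_annotation Maximum mismatches when assigning tags to
#'   reference mature miRNAs.
#' @param max_overhang Maximum additional/missing nucleotides at either tag
#'   end relative to the reference (nt).
#' @param fc_threshold Absolute fold-change threshold for differential
#'   expression.
#' @param fdr_threshold Benjamini-Hochberg FDR threshold.
#' @param flank Flank length (nt) extracted either side of a genomic mature
#'   miRNA hit when building precursor candidates.
#' @param mfei_threshold Minimal folding free energy index required of a
#'   passing precursor.
#' @param min_ds_segment Minimum double-stranded segment length (nt) in the
#'   folded precursor.
#' @param arm_min,arm_max Allowed mature/star arm lengths (nt).
#' @param max_mismatches_genome Maximum substitutions when mapping mature
#'   sequences to the genome.
#' @param max_gaps_genome Maximum single-nucleotide gaps in a genome hit.
#' @param expectation_cutoff Maximum expectation score of a reported target
#'   site.
#' @param seed_start,seed_end Seed region bounds (miRNA positions, 1-based).
#' @param max_seed_mismatches Maximum mismatches+gaps tolerated in the seed.
#' @param cluster_max_gap Maximum gap (nt) between consecutive precursors in a
#'   genomic cluster.
#' @param adapter Adapter sequence to trim from the 3' end of reads, or `NULL`
#'   for no trimming.
#' @param adapter_match_len Number of leading adapter bases that must match
#'   exactly.
#' @param fold_engine Folding engine: `"vienna"` (RNAfold binary) or
#'   `"stackmax"` (built-in stacking-weighted base-pair maximisation).
#' @param seed Integer seed for every stochastic step.
#' @return A list of class `phasemir_config`.
#' @export
run_config <- function(min_len = 18L,
                       max_len = 25L,
                       min_total_count = 5L,
                       max_mismatches_annotation = 2L,
                       max_overhang = 2L,
                       fc_threshold = 1.5,
                       fdr_threshold = 0.05,
                       flank = 100L,
                       mfei_threshold = 0.85,
                       min_ds_segment = 19L,
                       arm_min = 19L,
                       arm_max = 25L,
                       max_mismatches_genome = 2L,
                       max_gaps_genome = 1L,
                       expectation_cutoff = 5.0,
                       seed_start = 2L,
                       seed_end = 13L,
                       max_seed_mismatches = 2L,
                       cluster_max_gap = 10000L,
                       adapter = NULL,
                       adapter_match_len = 8L,
                       fold_engine = c("vienna", "stackmax"),
                       seed = 1L) {
  fold_engine <- match.arg(fold_engine)
  cfg <- list(
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    min_total_count = as.integer(min_total_count),
    max_mismatches_annotation = as.integer(max_mismatches_annotation),
    max_overhang = as.integer(max_overhang),
    fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
    flank = as.integer(flank), mfei_threshold = mfei_threshold,
    min_ds_segment = as.integer(min_ds_segment),
    arm_min = as.integer(arm_min), arm_max = as.integer(arm_max),
    max_mismatches_genome = as.integer(max_mismatches_genome),
    max_gaps_genome = as.integer(max_gaps_genome),
    expectation_cutoff = expectation_cutoff,
    seed_start = as.integer(seed_start), seed_end = as.integer(seed_end),
    max_seed_mismatches = as.integer(max_seed_mismatches),
    cluster_max_gap = as.integer(cluster_max_gap),
    adapter = adapter, adapter_match_len = as.integer(adapter_match_len),
    fold_engine = fold_engine, seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "phasemir_config")
}

validate_config <- function(cfg) {
  if (cfg$min_len > cfg$max_len) abort("min_len must be <= max_len")
  if (cfg$seed_start >= cfg$seed_end) abort("seed_start must be < seed_end")
  pos <- c("min_total_count", "fc_threshold", "fdr_threshold", "flank",
           "mfei_threshold", "min_ds_segment", "arm_min", "arm_max",
           "expectation_cutoff", "cluster_max_gap")
  for (p in pos) {
    if (cfg[[p]] <= 0) abort(paste0(p, " must be positive"))
  }
  if (cfg$arm_min > cfg$arm_max) abort("arm_min must be <= arm_max")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys raise an error so
#' typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file of flat key-value pairs.
#' @return A `phasemir_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' @export
print.phasemir_config <- function(x, ...) {
  cat("<phasemir_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-26s %s\n", nm,
                if (is.null(val)) "NULL" else paste(val, collapse = ", ")))
  }
  invisible(x)
}
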