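# End-to-end orchestration: collapse -> annotate -> differential expression
# -> precursor prediction and target scanning (on DE-significant groups only,
# mirroring the analysis flow of a phase-change small-RNA study) -> optional
# qPCR stage. Stage outputs are plain tibbles/files so any stage can be
# re-run independently.

#' Run the full analysis pipeline on a study
#'
#' @param study A `phasemir_study` from [simulate_study()], or any list with
#'   the same elements (`design`, `reads`, `reference`, optionally `genome`,
#'   `transcripts`, `ct_table`).
#' @param config A [run_config()]. When `config$adapter` is `NULL` the
#'   study's adapter (if recorded) is used.
#' @param stages Stages to execute, in order.
#' @param out_dir Optional directory for stage output files.
#' @return Object of class `phasemir_run`: all stage outputs plus a
#'   `manifest` of per-stage counts. `glance()` returns the manifest as a
#'   one-row tibble.
#' @export
run_study <- function(study, config = run_config(),
                      stages = c("collapse", "annotate", "de", "precursors",
                                 "targets", "qpcr"),
                      out_dir = NULL) {
  t0 <- Sys.time()
  if (is.null(config$adapter) && !is.null(study$params$adapter)) {
    config$adapter <- study$params$adapter
  }
  design <- validate_design(study$design)
  out <- list(config = config, design = design)
  manifest <- list(seed = config$seed, fold_engine = config$fold_engine)

  if ("collapse" %in% stages) {
    tags <- collapse_reads(study$reads, config)
    libsz <- library_sizes(study$reads, config)
    out$tags <- tags
    out$library_sizes <- libsz
    manifest$n_reads <- nrow(study$reads)
    manifest$n_tags <- nrow(tags)
  }
  if ("annotate" %in% stages) {
    stage_require(out, "tags", "annotate")
    assignments <- assign_tags(out$tags, study$reference, config)
    groups <- isomir_groups(assignments, design$library_id)
    out$assignments <- assignments
    out$groups <- groups
    out$family_summary <- summarize_families(assignments, design)
    manifest$n_annotated <- sum(assignments$annotated)
    manifest$n_ambiguous <- sum(assignments$ambiguous, na.rm = TRUE)
    manifest$n_groups <- nrow(groups)
    manifest$n_families <- n_distinct(groups$family)
  }
  if ("de" %in% stages) {
    stage_require(out, "groups", "de")
    de <- run_all_comparisons(out$groups, design, config, out$library_sizes)
    out$de <- de
    cmp <- glance(de)
    manifest$n_comparisons <- nrow(cmp)
    manifest$de_per_comparison <- setNames(cmp$n_significant, cmp$comparison)
    manifest$n_de_union <- length(significant_union(de))
  }
  de_groups <- if (!is.null(out[["de"]])) significant_union(out[["de"]]) else character()
  de_mirnas <- if (length(de_groups) > 0) {
    out$groups %>%
      filter(.data$group_id %in% de_groups) %>%
      mutate(mirna_id = .data$group_id, sequence = .data$consensus) %>%
      select("mirna_id", "sequence", "family", "group_id")
  } else {
    tibble(mirna_id = character(), sequence = character(),
           family = character(), group_id = character())
  }
  if ("precursors" %in% stages) {
    if (is.null(study$genome)) abort("precursor stage requested but the study has no genome")
    stage_require(out, "de", "precursors")
    prec <- predict_precursors(de_mirnas, study$genome, config)
    out$precursors <- prec
    out$clusters <- find_clusters(filter(prec, .data$passes),
                                  config$cluster_max_gap)
    manifest$n_precursors_found <- nrow(prec)
    manifest$n_precursors_passing <- sum(prec$passes)
    manifest$n_clusters <- n_distinct(out$clusters$cluster_id)
  }
  if ("targets" %in% stages) {
    if (is.null(study$transcripts)) abort("target stage requested but the study has no transcripts")
    stage_require(out, "de", "targets")
    hits <- scan_transcripts(de_mirnas, study$transcripts, config)
    out$target_hits <- hits
    manifest$n_target_hits <- nrow(hits)
    manifest$n_target_genes <- n_distinct(hits$transcript_id)
  }
  if ("qpcr" %in% stages && !is.null(study$ct_table)) {
    targets <- setdiff(unique(study$ct_table$gene_id),
                       c("actin", "cyclophilin"))
    out$rq <- purrr::map(setNames(targets, targets), function(g) {
      delta_delta_ct(study$ct_table, g)
    })
    manifest$n_qpcr_targets <- length(targets)
  }
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out$manifest <- manifest
  res <- structure(out, class = "phasemir_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

stage_require <- function(out, field, stage) {
  if (is.null(out[[field]])) {
    abort(paste0("stage '", stage, "' requires a previous stage output: ",
                 field))
  }
}

#' @export
print.phasemir_run <- function(x, ...) {
  m <- x$manifest
  cat("<phasemir_run>\n")
  for (nm in setdiff(names(m), "de_per_comparison")) {
    val <- unlist(m[[nm]])
    if (is.numeric(val)) val <- signif(val, 6)
    cat(sprintf("  %-24s %s\n", nm, paste(val, collapse = ", ")))
  }
  if (!is.null(m$de_per_comparison)) {
    cat("  DE groups per comparison:\n")
    for (cmp in names(m$de_per_comparison)) {
      cat(sprintf("    %-12s %d\n", cmp, m$de_per_comparison[[cmp]]))
    }
  }
  invisible(x)
}

#' @rdname run_study
#' @param x A `phasemir_run` object.
#' @param ... Unused.
#' @export
glance.phasemir_run <- function(x, ...) {
  m <- x$manifest
  as_tibble(m[!vapply(m, function(v) length(v) != 1, logical(1))])
}

#' Write pipeline outputs as plain files
#'
#' @param run A `phasemir_run`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) readr::write_tsv(df, file.path(out_dir, name))
  if (!is.null(run$tags)) w(run$tags, "tags.tsv")
  if (!is.null(run$assignments)) w(run$assignments, "assignments.tsv")
  if (!is.null(run$groups)) w(run$groups, "isomir_groups.tsv")
  if (!is.null(run$family_summary)) w(run$family_summary, "family_summary.tsv")
  if (!is.null(run[["de"]])) {
    w(run[["de"]]$results, "de_results.tsv")
    w(run[["de"]]$cpm, "normalized_cpm.tsv")
  }
  if (!is.null(run$precursors)) {
    w(select(run$precursors, -"dotbracket", -"pre_sequence"),
      "precursors.tsv")
    passing <- filter(run$precursors, .data$passes)
    if (nrow(passing) > 0) {
      write_gff3(passing, file.path(out_dir, "precursors.gff3"))
      write_vienna(passing, file.path(out_dir, "precursors.vienna"),
                   ids = paste0(passing$group_id, "_", passing$contig, "_",
                                passing$pre_start0))
    }
    w(run$clusters, "precursor_clusters.tsv")
  }
  if (!is.null(run$target_hits)) w(run$target_hits, "target_hits.tsv")
  if (!is.null(run$rq)) {
    w(bind_rows(purrr::map(run$rq, "rq")), "qpcr_rq.tsv")
  }
  man <- run$manifest
  yaml::write_yaml(man, file.path(out_dir, "run_manifest.yaml"))
  invisible(out_dir)
}
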