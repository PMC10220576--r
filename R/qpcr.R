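# Relative quantification of qPCR data by the 2^-ddCt method with two
# reference genes. Technical replicates are averaged per (sample, gene);
# the two reference genes are combined by averaging their mean Cts
# (equivalent to the geometric mean of their linear quantities); the
# standard error of dCt over biological samples within a group gives the
# RQmin/RQmax error bounds.

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, dCt = mean Ct(target) - mean of the two reference genes'
#' mean Cts; per group, ddCt = mean dCt(group) - mean dCt(calibrator);
#' RQ = 2^-ddCt with RQmin = 2^-(ddCt + SE) and RQmax = 2^-(ddCt - SE),
#' where SE is the standard error of dCt across the group's samples.
#' Samples missing a reference gene are excluded with a warning.
#'
#' @param ct_table Tibble with `sample_id`, `sample_group`, `gene_id`,
#'   `replicate`, `ct`.
#' @param target_gene Gene to quantify.
#' @param calibrator_group Group fixed at RQ = 1.
#' @param reference_genes The two endogenous control gene ids.
#' @return An object of class `phasemir_rq`: list with `rq` (tibble:
#'   `gene_id`, `sample_group`, `ddct`, `se_dct`, `rq`, `rq_min`, `rq_max`,
#'   `calibrator_group`), `dct` (per-sample dCt values) and the inputs'
#'   identifiers. `tidy()` returns the RQ tibble.
#' @export
delta_delta_ct <- function(ct_table, target_gene,
                           calibrator_group = "MAT",
                           reference_genes = c("actin", "cyclophilin")) {
  if (any(ct_table$ct <= 0)) abort("Ct values must be positive")
  if (!calibrator_group %in% ct_table$sample_group) {
    abort(paste0("calibrator group not in table: ", calibrator_group))
  }
  if (!target_gene %in% ct_table$gene_id) {
    abort(paste0("target gene not in table: ", target_gene))
  }
  means <- ct_table %>%
    filter(.data$gene_id %in% c(target_gene, reference_genes)) %>%
    group_by(.data$sample_id, .data$sample_group, .data$gene_id) %>%
    summarise(mean_ct = mean(.data$ct), .groups = "drop")
  wide <- means %>%
    tidyr::pivot_wider(names_from = "gene_id", values_from = "mean_ct")
  missing_ref <- !stats::complete.cases(wide[, reference_genes, drop = FALSE])
  if (any(missing_ref)) {
    warn(paste0("excluding ", sum(missing_ref),
                " sample(s) missing a reference gene"))
    wide <- wide[!missing_ref, ]
  }
  wide <- wide[!is.na(wide[[target_gene]]), ]
  dct <- wide %>%
    mutate(dct = .data[[target_gene]] -
             rowMeans(dplyr::pick(dplyr::all_of(reference_genes)))) %>%
    select("sample_id", "sample_group", "dct")
  if (!calibrator_group %in% dct$sample_group) {
    abort("calibrator group empty after exclusions")
  }
  cal_mean <- mean(dct$dct[dct$sample_group == calibrator_group])
  rq <- dct %>%
    group_by(.data$sample_group) %>%
    summarise(
      ddct = mean(.data$dct) - cal_mean,
      se_dct = ifelse(n() > 1, sd(.data$dct) / sqrt(n()), 0),
      .groups = "drop"
    ) %>%
    mutate(
      gene_id = target_gene,
      rq = 2^-.data$ddct,
      rq_min = 2^-(.data$ddct + .data$se_dct),
      rq_max = 2^-(.data$ddct - .data$se_dct),
      calibrator_group = calibrator_group
    ) %>%
    select("gene_id", "sample_group", "ddct", "se_dct", "rq", "rq_min",
           "rq_max", "calibrator_group")
  structure(list(rq = rq, dct = dct, target_gene = target_gene,
                 calibrator_group = calibrator_group),
            class = "phasemir_rq")
}

#' @export
print.phasemir_rq <- function(x, ...) {
  cat("<phasemir_rq> ", x$target_gene, " relative to ", x$calibrator_group,
      "\n", sep = "")
  print(x$rq)
  invisible(x)
}

#' @rdname delta_delta_ct
#' @param x,object A `phasemir_rq` object.
#' @param ... Unused.
#' @export
tidy.phasemir_rq <- function(x, ...) x$rq

#' @rdname delta_delta_ct
#' @export
autoplot.phasemir_rq <- function(object, ...) {
  ggplot2::ggplot(object$rq,
                  ggplot2::aes(.data$sample_group, .data$rq)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rq_min,
                                        ymax = .data$rq_max), width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "relative quantity (2^-ddCt)",
                  title = object$target_gene) +
    ggplot2::theme_minimal()
}

#' Group significance tests on dCt values
#'
#' One-way ANOVA across all groups plus Benjamini-Hochberg-corrected pairwise
#' Welch t-tests. Degenerate inputs (identical dCt everywhere) return p = 1
#' with a flag.
#'
#' @param rq A `phasemir_rq` object (or a tibble with `sample_group`, `dct`).
#' @return List with `anova_p`, `pairwise` (tibble: `group_a`, `group_b`,
#'   `p_value`, `fdr`), `degenerate`.
#' @export
group_tests <- function(rq) {
  dct <- if (inherits(rq, "phasemir_rq")) rq$dct else as_tibble(rq)
  groups <- unique(dct$sample_group)
  if (length(groups) < 2) abort("need >= 2 groups")
  sizes <- table(dct$sample_group)
  if (any(sizes < 2)) abort("each group needs >= 2 samples")
  degenerate <- var(dct$dct) == 0
  if (degenerate) {
    pairs <- utils::combn(sort(groups), 2, simplify = FALSE)
    pw <- purrr::map_dfr(pairs, function(p) {
      tibble(group_a = p[1], group_b = p[2], p_value = 1)
    })
    pw$fdr <- 1
    return(list(anova_p = 1, pairwise = pw, degenerate = TRUE))
  }
  fit <- aov(dct ~ sample_group, data = dct)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  pairs <- utils::combn(sort(groups), 2, simplify = FALSE)
  pw <- purrr::map_dfr(pairs, function(p) {
    x <- dct$dct[dct$sample_group == p[1]]
    y <- dct$dct[dct$sample_group == p[2]]
    tibble(group_a = p[1], group_b = p[2], p_value = welch_p(x, y))
  })
  pw$fdr <- p.adjust(pw$p_value, method = "BH")
  list(anova_p = anova_p, pairwise = pw, degenerate = FALSE)
}
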