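# Group-level differential expression between maturity states. Counts are
# normalised to counts per million (CPM); fold changes use a 1-CPM
# pseudocount and the signed negative-reciprocal convention (a halving is
# reported as -2). P-values come, by default, from a limma moderated t-test
# on log2(CPM + 1) (variance pooling matters at 3-4 libraries per group);
# Welch's t-test is available as a dependency-light alternative. FDR is
# Benjamini-Hochberg within each pairwise comparison.

#' Counts-per-million normalisation
#'
#' @param counts Tibble or data frame with a `group_id` id column and one
#'   integer count column per library.
#' @param library_sizes Named numeric vector of library sizes; defaults to
#'   the column sums of `counts`.
#' @return Tibble of the same shape with counts replaced by CPM.
#' @export
normalize_cpm <- function(counts, library_sizes = NULL) {
  libs <- setdiff(names(counts), c("group_id", "family", "n_members",
                                   "consensus", "total_count"))
  if (is.null(library_sizes)) {
    library_sizes <- colSums(counts[, libs, drop = FALSE])
  }
  if (any(library_sizes[libs] <= 0)) abort("library sizes must be positive")
  out <- counts[, c("group_id", libs)]
  for (lib in libs) {
    out[[lib]] <- counts[[lib]] / library_sizes[[lib]] * 1e6
  }
  as_tibble(out)
}

#' Test one pairwise comparison for differential expression
#'
#' Fold change is computed from pseudocount-stabilised group mean CPMs,
#' `(mean_a + 1) / (mean_b + 1)`, reported as a negative reciprocal when the
#' first group is lower. The p-value comes from a moderated t-test
#' ([limma::eBayes()] with a mean-variance trend) on log2(CPM + 1) per
#' library, or from Welch's t-test when `test = "welch"`; identical values in
#' both groups give p = 1 by convention. FDR is Benjamini-Hochberg within the
#' comparison.
#'
#' @param counts Group-by-library count tibble (`group_id` + count columns).
#' @param design Design tibble (`library_id`, `sample_group`).
#' @param group_a,group_b Sample-group labels; `group_a` is the numerator.
#' @param config A [run_config()]; uses `fc_threshold`, `fdr_threshold`.
#' @param library_sizes Optional named vector passed to [normalize_cpm()].
#' @param test `"moderated"` (default) or `"welch"`.
#' @return Tibble with one row per group_id: `comparison`, `mean_a`,
#'   `mean_b` (CPM), `fold_change`, `p_value`, `fdr`, `significant`.
#' @export
test_pairwise <- function(counts, design, group_a, group_b,
                          config = run_config(), library_sizes = NULL,
                          test = c("moderated", "welch")) {
  test <- match.arg(test)
  validate_design(design, groups = NULL)
  for (g in c(group_a, group_b)) {
    if (!g %in% design$sample_group) {
      abort(paste0("unknown sample group: ", g))
    }
  }
  libs_a <- design$library_id[design$sample_group == group_a]
  libs_b <- design$library_id[design$sample_group == group_b]
  if (length(libs_a) < 2 || length(libs_b) < 2) {
    abort("each compared group needs >= 2 libraries")
  }
  cpm <- normalize_cpm(counts, library_sizes)
  ma <- rowMeans(cpm[, libs_a, drop = FALSE])
  mb <- rowMeans(cpm[, libs_b, drop = FALSE])
  ratio <- (ma + 1) / (mb + 1)
  fc <- ifelse(ratio >= 1, ratio, -1 / ratio)
  la <- log2(as.matrix(cpm[, libs_a, drop = FALSE]) + 1)
  lb <- log2(as.matrix(cpm[, libs_b, drop = FALSE]) + 1)
  pv <- if (test == "moderated") {
    moderated_p(la, lb)
  } else {
    vapply(seq_len(nrow(cpm)), function(i) welch_p(la[i, ], lb[i, ]),
           numeric(1))
  }
  fdr <- p.adjust(pv, method = "BH")
  tibble(
    group_id = cpm$group_id,
    comparison = paste0(group_a, "-", group_b),
    mean_a = ma, mean_b = mb,
    fold_change = fc, p_value = pv, fdr = fdr,
    significant = abs(fc) >= config$fc_threshold & fdr < config$fdr_threshold
  )
}

# Moderated two-group t-test on log2 CPM via limma, with the same p = 1
# convention for rows that are constant across all libraries. Falls back to
# Welch when the moderated fit cannot be computed (e.g. a single row).
moderated_p <- function(la, lb) {
  m <- cbind(la, lb)
  design <- cbind(Intercept = 1,
                  groupA = c(rep(1, ncol(la)), rep(0, ncol(lb))))
  pv <- tryCatch({
    fit <- limma::eBayes(limma::lmFit(m, design), trend = nrow(m) >= 10)
    fit$p.value[, "groupA"]
  }, error = function(e) NULL)
  if (is.null(pv)) {
    return(vapply(seq_len(nrow(la)), function(i) welch_p(la[i, ], lb[i, ]),
                  numeric(1)))
  }
  degenerate <- which(row_vars(m) == 0)
  pv[degenerate] <- 1
  pv[is.na(pv)] <- 1
  unname(pv)
}

row_vars <- function(m) apply(m, 1, var)

# Welch t-test p-value with a p = 1 convention for degenerate (zero-variance,
# equal-mean) inputs.
welch_p <- function(x, y) {
  if (var(x) == 0 && var(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  tryCatch(t.test(x, y)$p.value, error = function(e) 1)
}

#' Run every pairwise comparison between sample groups
#'
#' @inheritParams test_pairwise
#' @return An object of class `phasemir_de`: a list with `results` (stacked
#'   per-comparison tibbles), `cpm` (normalised matrix), `config` and
#'   `design`. `tidy()` returns the stacked results, `glance()`
#'   per-comparison and union counts, `autoplot()` a fold-change/FDR panel.
#' @export
run_all_comparisons <- function(counts, design, config = run_config(),
                                library_sizes = NULL,
                                test = c("moderated", "welch")) {
  test <- match.arg(test)
  groups <- sort(unique(design$sample_group))
  if (length(groups) < 2) abort("need >= 2 sample groups")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  results <- purrr::map_dfr(pairs, function(p) {
    test_pairwise(counts, design, p[1], p[2], config, library_sizes, test)
  })
  structure(
    list(results = results,
         cpm = normalize_cpm(counts, library_sizes),
         config = config, design = as_tibble(design)),
    class = "phasemir_de"
  )
}

#' Union of significantly differentially expressed groups
#'
#' @param de A `phasemir_de` object.
#' @return Character vector of group_ids significant in at least one
#'   comparison.
#' @export
significant_union <- function(de) {
  sort(unique(de$results$group_id[de$results$significant]))
}

#' @export
print.phasemir_de <- function(x, ...) {
  n_cmp <- n_distinct(x$results$comparison)
  cat("<phasemir_de> ", n_distinct(x$results$group_id), " groups, ",
      n_cmp, " pairwise comparisons, ",
      length(significant_union(x)), " groups significant in >= 1\n", sep = "")
  invisible(x)
}

#' @rdname run_all_comparisons
#' @param x A `phasemir_de` object.
#' @param ... Unused.
#' @export
tidy.phasemir_de <- function(x, ...) x$results

#' @rdname run_all_comparisons
#' @export
glance.phasemir_de <- function(x, ...) {
  x$results %>%
    group_by(.data$comparison) %>%
    summarise(n_groups = n(), n_significant = sum(.data$significant),
              .groups = "drop") %>%
    mutate(n_union_significant = length(significant_union(x)))
}

#' @rdname run_all_comparisons
#' @param object A `phasemir_de` object.
#' @export
autoplot.phasemir_de <- function(object, ...) {
  dat <- object$results %>%
    mutate(log2fc = sign(.data$fold_change) * log2(abs(.data$fold_change)),
           neglog_fdr = -log10(pmax(.data$fdr, 1e-300)))
  ggplot2::ggplot(dat, ggplot2::aes(.data$log2fc, .data$neglog_fdr,
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$config$fdr_threshold),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(object$config$fc_threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "signed log2 fold change", y = "-log10 FDR",
                  colour = "significant") +
    ggplot2::theme_minimal()
}
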