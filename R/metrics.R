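#' Internalization index
#'
#' Global uptake summary: the fraction of neurons internalizing at least one
#' spot multiplied by the mean number of internalized spots per neuron. The
#' percentage enters as a fraction (91% -> 0.91), which is the reading under
#' which published index magnitudes (e.g. 91% and 5.3 spots/neuron giving an
#' index near 4.9) are reproduced.
#'
#' @param pct_internalizing Percentage of neurons internalizing, in `[0, 100]`.
#' @param mean_spots Mean internalized spots per neuron (>= 0).
#' @return `(pct_internalizing / 100) * mean_spots`.
#' @examples
#' internalization_index(91, 5.3)  # 4.823
#' @export
internalization_index <- function(pct_internalizing, mean_spots) {
  if (any(!is.finite(pct_internalizing)) ||
      any(pct_internalizing < 0 | pct_internalizing > 100)) {
    abort("pct_internalizing must lie in [0, 100]",
          class = "oligouptake_validation_error")
  }
  if (any(!is.finite(mean_spots)) || any(mean_spots < 0)) {
    abort("mean_spots must be >= 0", class = "oligouptake_validation_error")
  }
  (pct_internalizing / 100) * mean_spots
}

#' Percent reduction of a test value relative to a reference
#'
#' @param index_ref Reference value (> 0), e.g. the wild-type index.
#' @param index_test Test value, e.g. the knock-out index.
#' @return `100 * (1 - index_test / index_ref)`.
#' @examples
#' percent_reduction(4.9, 1.9)  # 61.2
#' @export
percent_reduction <- function(index_ref, index_test) {
  if (any(!is.finite(index_ref)) || any(index_ref <= 0)) {
    abort("index_ref must be a positive finite number",
          class = "oligouptake_validation_error")
  }
  100 * (1 - index_test / index_ref)
}

resolve_n_neurons <- function(labels) {
  if (inherits(labels, "neuron_label_map")) labels$n_neurons
  else as.integer(labels)
}

#' Summarize classified spots of one field into uptake statistics
#'
#' @param spots Classified, neuron-assigned spot tibble.
#' @param labels A `neuron_label_map` (or a plain neuron count).
#' @param field_id Identifier copied into the output row.
#' @param mean_over Average internalized spots over `"internalizing"`
#'   neurons only (default; matches how published percentage/mean pairs
#'   combine into the index) or over `"all"` neurons.
#' @return One-row tibble: `field_id`, `n_neurons`, `n_neurons_internalizing`,
#'   `pct_internalizing`, `mean_internalized_spots_per_neuron`,
#'   `mean_attached_spots_per_neuron`, `internalization_index`,
#'   `n_internalized`, `n_attached`. With zero neurons the percentages are
#'   `NA` (flagged via warning), never silently zero.
#' @export
summarize_field <- function(spots, labels, field_id = 1L,
                            mean_over = c("internalizing", "all")) {
  mean_over <- match.arg(mean_over)
  n_neurons <- resolve_n_neurons(labels)
  internal <- dplyr::filter(spots, .data$class == "internalized",
                            !is.na(.data$neuron_id))
  attached <- dplyr::filter(spots, .data$class == "attached")
  if (n_neurons == 0L) {
    warn("field has zero neurons; uptake percentages are undefined")
    return(tibble::tibble(
      field_id = field_id, n_neurons = 0L, n_neurons_internalizing = 0L,
      pct_internalizing = NA_real_,
      mean_internalized_spots_per_neuron = NA_real_,
      mean_attached_spots_per_neuron = NA_real_,
      internalization_index = NA_real_,
      n_internalized = nrow(internal), n_attached = nrow(attached)
    ))
  }
  per_neuron <- dplyr::count(internal, .data$neuron_id)
  n_int_neurons <- nrow(per_neuron)
  pct <- 100 * n_int_neurons / n_neurons
  mean_spots <- if (mean_over == "all") {
    nrow(internal) / n_neurons
  } else if (n_int_neurons == 0L) {
    0  # no internalizing neurons: mean undefined, index must be 0
  } else {
    mean(per_neuron$n)
  }
  tibble::tibble(
    field_id = field_id,
    n_neurons = n_neurons,
    n_neurons_internalizing = n_int_neurons,
    pct_internalizing = pct,
    mean_internalized_spots_per_neuron = mean_spots,
    mean_attached_spots_per_neuron = nrow(attached) / n_neurons,
    internalization_index = internalization_index(pct, mean_spots),
    n_internalized = nrow(internal),
    n_attached = nrow(attached)
  )
}

#' Two-group comparison by t test
#'
#' Pooled-variance Student (default) or Welch t test, two-sided, with group
#' means, SEMs, and the percent reduction of group B relative to group A.
#'
#' @param values_a,values_b Numeric vectors of per-unit measurements (>= 2
#'   finite values each); group A is the reference for the reduction.
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @param labels Length-2 character vector naming the groups.
#' @return A `group_comparison` object; see [tidy()] / [glance()].
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_groups <- function(values_a, values_b,
                           variant = c("student", "welch"),
                           labels = c("A", "B")) {
  variant <- match.arg(variant)
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L) {
    abort("each group needs at least 2 finite values",
          class = "oligouptake_validation_error")
  }
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (va == 0 && vb == 0) {
    if (mean(values_a) == mean(values_b)) {
      t_stat <- 0; df <- length(values_a) + length(values_b) - 2; p <- 1
    } else {
      abort("both groups are constant with different means: t is degenerate",
            class = "oligouptake_validation_error")
    }
  } else {
    tt <- t.test(values_a, values_b, var.equal = variant == "student")
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  m <- c(mean(values_a), mean(values_b))
  structure(list(
    labels = labels,
    n = c(length(values_a), length(values_b)),
    means = m,
    sems = c(sqrt(va / length(values_a)), sqrt(vb / length(values_b))),
    variant = variant,
    t_statistic = t_stat, df = df, p_value = p,
    percent_reduction = if (m[1] > 0) percent_reduction(m[1], m[2]) else NA_real_
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s (%s t test)\n",
              x$labels[1], x$labels[2], x$variant))
  cat(sprintf("  %s: %.3g +/- %.2g (n=%d)   %s: %.3g +/- %.2g (n=%d)\n",
              x$labels[1], x$means[1], x$sems[1], x$n[1],
              x$labels[2], x$means[2], x$sems[2], x$n[2]))
  cat(sprintf("  t(%.4g) = %.4g, p = %.4g", x$df, x$t_statistic, x$p_value))
  if (is.finite(x$percent_reduction)) {
    cat(sprintf(", reduction vs %s = %.1f%%", x$labels[1], x$percent_reduction))
  }
  cat("\n")
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(
    group_a = x$labels[1], group_b = x$labels[2],
    n_a = x$n[1], n_b = x$n[2],
    mean_a = x$means[1], mean_b = x$means[2],
    sem_a = x$sems[1], sem_b = x$sems[2],
    t_statistic = x$t_statistic, df = x$df, p_value = x$p_value,
    percent_reduction = x$percent_reduction, variant = x$variant
  )
}

#' @rdname compare_groups
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(t_statistic = x$t_statistic, df = x$df,
                 p_value = x$p_value,
                 percent_reduction = x$percent_reduction)
}

#' Compare uptake metrics between groups of field summaries
#'
#' Runs [compare_groups()] for each uptake metric between a reference group
#' and every other group in a field-summary table.
#'
#' @param summaries Field-summary tibble (rows from [summarize_field()])
#'   with a grouping column.
#' @param group_col Name of the grouping column. Default `"group"`.
#' @param reference Reference group label (defaults to the first level).
#' @param metrics Metric columns to compare.
#' @param variant `"student"` or `"welch"`.
#' @return A tibble with one row per (metric, comparison).
#' @export
compare_summaries <- function(summaries, group_col = "group", reference = NULL,
                              metrics = c("pct_internalizing",
                                          "mean_internalized_spots_per_neuron",
                                          "internalization_index",
                                          "mean_attached_spots_per_neuron"),
                              variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (!group_col %in% names(summaries)) {
    abort(sprintf("no column '%s' in summaries", group_col),
          class = "oligouptake_validation_error")
  }
  groups <- unique(summaries[[group_col]])
  if (length(groups) < 2L) {
    abort("need at least 2 groups to compare", class = "oligouptake_validation_error")
  }
  if (is.null(reference)) reference <- groups[1]
  if (!reference %in% groups) {
    abort(sprintf("reference group '%s' not present", reference),
          class = "oligouptake_validation_error")
  }
  others <- setdiff(groups, reference)
  ref_rows <- summaries[summaries[[group_col]] == reference, ]
  rows <- list()
  for (g in others) {
    test_rows <- summaries[summaries[[group_col]] == g, ]
    for (m in metrics) {
      cmp <- compare_groups(ref_rows[[m]], test_rows[[m]], variant = variant,
                            labels = c(reference, g))
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(metric = m), tidy(cmp))
    }
  }
  dplyr::bind_rows(rows)
}
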