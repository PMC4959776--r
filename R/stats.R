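#' Unpaired two-sample t test between genotype groups
#'
#' Compares proliferation indices of two groups. The default
#' `"student_pooled"` variant is the classic unpaired two-sided Student's
#' t test with pooled variance and `n_a + n_b - 2` degrees of freedom;
#' `"welch"` (Satterthwaite df) is available and preferable when variances
#' differ. No multiple-testing correction is applied anywhere in this
#' package — comparisons against each reference are reported as-is.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param variant `"student_pooled"` or `"welch"`.
#' @param group_a,group_b Labels carried into the result.
#' @return A one-row data frame of class `wq_group_comparison` with columns
#'   `group_a`, `group_b`, `n_a`, `n_b`, `mean_a`, `mean_b`, `t_stat`, `df`,
#'   `p_value`, `stars`, `variant`.
#' @export
t_test_groups <- function(values_a, values_b,
                          variant = c("student_pooled", "welch"),
                          group_a = "A", group_b = "B") {
  variant <- match.arg(variant)
  values_a <- as.numeric(values_a); values_b <- as.numeric(values_b)
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values (got ", length(values_a),
         " and ", length(values_b), ")")
  if (anyNA(values_a) || anyNA(values_b)) stop("NA values in input groups")
  pooled_var <- ((length(values_a) - 1) * stats::var(values_a) +
                   (length(values_b) - 1) * stats::var(values_b)) /
    (length(values_a) + length(values_b) - 2)
  if (pooled_var == 0) {
    if (mean(values_a) == mean(values_b)) {
      t_stat <- 0; p <- 1
      df <- length(values_a) + length(values_b) - 2
    } else stop("degenerate input: zero within-group variance with unequal means")
  } else {
    ht <- t.test(values_a, values_b, var.equal = (variant == "student_pooled"),
                 alternative = "two.sided")
    t_stat <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
  }
  structure(data.frame(group_a = group_a, group_b = group_b,
                       n_a = length(values_a), n_b = length(values_b),
                       mean_a = mean(values_a), mean_b = mean(values_b),
                       t_stat = t_stat, df = df, p_value = p,
                       stars = star_annotation(p), variant = variant,
                       stringsAsFactors = FALSE),
            class = c("wq_group_comparison", "data.frame"))
}

#' Significance star annotation
#'
#' The conventional mapping with strict inequalities: `"***"` for p < .001,
#' `"**"` for p < .01, `"*"` for p < .05, `""` otherwise (rendered "ns" in
#' plots). p = .05 exactly gets no star.
#'
#' @param p_value Numeric vector of p values in \[0, 1\].
#' @return Character vector of star strings.
#' @export
star_annotation <- function(p_value) {
  if (!is.numeric(p_value) || anyNA(p_value) ||
      any(p_value < 0) || any(p_value > 1))
    stop("p_value must lie in [0, 1]")
  ifelse(p_value < 0.001, "***",
         ifelse(p_value < 0.01, "**",
                ifelse(p_value < 0.05, "*", "")))
}

#' Compare every genotype against named reference conditions
#'
#' For each reference genotype (e.g. the driver-only control and the
#' apoptosis-inhibited baseline), every other genotype — including the other
#' references — is compared to it by [t_test_groups()]; references are never
#' compared to themselves. Failed quantification rows are excluded first.
#'
#' @param records A [quantify_batch()] result (or any data frame with
#'   `genotype` and `proliferation_index` columns; a `status` column, if
#'   present, is filtered to `"ok"`).
#' @param reference_groups Ordered character vector of reference genotype
#'   labels; each must occur in `records`.
#' @param variant Passed to [t_test_groups()].
#' @return A data frame of class `wq_comparisons`: one `wq_group_comparison`
#'   row per (genotype, reference) pair, with a `reference` column.
#' @export
compare_all <- function(records, reference_groups,
                        variant = c("student_pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(records),
            all(c("genotype", "proliferation_index") %in% names(records)))
  if ("status" %in% names(records)) records <- records[records$status == "ok", ]
  groups <- split(records$proliferation_index, records$genotype)
  missing_ref <- setdiff(reference_groups, names(groups))
  if (length(missing_ref))
    stop("reference genotype(s) absent from records: ",
         paste(missing_ref, collapse = ", "))
  out <- list()
  for (ref in reference_groups) {
    for (g in setdiff(names(groups), ref)) {
      cmp <- t_test_groups(groups[[g]], groups[[ref]], variant = variant,
                           group_a = g, group_b = ref)
      cmp$reference <- ref
      out[[length(out) + 1L]] <- cmp
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("wq_comparisons", "data.frame")
  res
}

#' Bar plot of group proliferation indices
#'
#' Mean +/- s.e.m. per genotype with star marks over each non-reference bar
#' for its comparison to the first reference; non-significant comparisons
#' are marked "ns".
#'
#' @param records A [quantify_batch()] result.
#' @param comparisons A [compare_all()] result (stars for its first
#'   reference are drawn).
#' @param ylab Axis label.
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_group_indices <- function(records, comparisons = NULL,
                               ylab = "GFP area / total disc area (AU)", ...) {
  if ("status" %in% names(records)) records <- records[records$status == "ok", ]
  groups <- split(records$proliferation_index, records$genotype)
  means <- vapply(groups, mean, numeric(1))
  sems <- vapply(groups, function(v) sd(v) / sqrt(length(v)), numeric(1))
  ylim <- c(0, max(means + sems) * 1.25)
  mid <- graphics::barplot(means, ylab = ylab, ylim = ylim, las = 2, ...)
  graphics::arrows(mid, means - sems, mid, means + sems,
                   angle = 90, code = 3, length = 0.04)
  if (!is.null(comparisons)) {
    ref1 <- comparisons$reference[1]
    for (i in seq_along(groups)) {
      g <- names(groups)[i]
      row <- comparisons[comparisons$reference == ref1 & comparisons$group_a == g, ]
      if (nrow(row) == 1L) {
        lab <- if (row$stars == "") "ns" else row$stars
        graphics::text(mid[i], means[i] + sems[i], lab, pos = 3, xpd = NA)
      }
    }
  }
  invisible(mid)
}
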