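#' Tally activity classes for a cohort
#'
#' Exact per-class counts for one group of neurons. Percentages are derived
#' on demand (never stored) by [tally_percentages()].
#'
#' @param classes factor or character vector of activity classes (induced
#'   or non-induced coding; the two are never mixed), optionally named by
#'   neuron id.
#' @param group_label free-text group tag.
#' @return a list of class `cohort_tally`: `group_label`, `counts` (named
#'   integer vector over the coding's levels), `n`.
#' @export
tally <- function(classes, group_label = NA_character_) {
  if (length(classes) == 0L) stop("validation error: empty class list")
  lv <- if (is.factor(classes)) levels(classes) else {
    u <- unique(as.character(classes))
    if (all(u %in% induced_levels)) induced_levels
    else if (all(u %in% noninduced_levels)) noninduced_levels
    else stop("classes mix induced and non-induced codings")
  }
  counts <- table(factor(as.character(classes), levels = lv))
  structure(list(group_label = group_label,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 n = length(classes)),
            class = "cohort_tally")
}

#' Integer percentages of a tally
#'
#' Percentages rounded half-up to whole percent, mirroring how cohort
#' compositions are conventionally printed; the exact proportions are
#' available as `t$counts / t$n`.
#'
#' @param t a `cohort_tally`.
#' @return named integer vector of percentages.
#' @export
tally_percentages <- function(t) {
  stopifnot(inherits(t, "cohort_tally"))
  floor(100 * t$counts / t$n + 0.5)
}

#' @export
print.cohort_tally <- function(x, ...) {
  cat(sprintf("<cohort_tally> %s (n = %d)\n",
              if (is.na(x$group_label)) "ungrouped" else x$group_label, x$n))
  pct <- tally_percentages(x)
  for (k in names(x$counts))
    cat(sprintf("  %-17s %3d  (%d%%)\n", k, x$counts[[k]], pct[[k]]))
  invisible(x)
}

#' Share of neurons with genuine action potentials
#'
#' Percentage of the cohort in the Single, AttemptingTrain or Train classes
#' (at least one overshooting excursion).
#'
#' @param t an induced-coding `cohort_tally`.
#' @return percentage in \[0, 100\].
#' @export
genuine_ap_share <- function(t) {
  stopifnot(inherits(t, "cohort_tally"))
  if (t$n == 0L) stop("validation error: empty tally")
  if (!all(c("Single", "AttemptingTrain", "Train") %in% names(t$counts)))
    stop("genuine_ap_share needs an induced-coding tally")
  100 * sum(t$counts[c("Single", "AttemptingTrain", "Train")]) / t$n
}

#' Two-group and multi-group comparisons of means
#'
#' Two-group designs use an unpaired two-sided t-test (Welch variance
#' handling by default, pooled optional); multi-group designs use one-way
#' ANOVA followed by Tukey's post-hoc pairwise comparisons. Group means are
#' reported with their SEM.
#'
#' @param a numeric sample (two-group design), or a named list of numeric
#'   samples (multi-group design).
#' @param b second numeric sample for the two-group design.
#' @param design `"two_group"` or `"multi_group"`.
#' @param var_equal use the pooled-variance (classic Student) t-test.
#' @return a list: `design`, `statistic`, `p`, and a `groups` data.frame
#'   with `n`, `mean`, `sem` per group; multi-group results add `tukey`
#'   (pairwise table).
#' @export
compare_groups <- function(a, b = NULL,
                           design = c("two_group", "multi_group"),
                           var_equal = FALSE) {
  design <- match.arg(design)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  if (design == "two_group") {
    if (length(a) < 2L || length(b) < 2L)
      stop("validation error: each group needs n >= 2")
    groups <- data.frame(group = c("a", "b"),
                         n = c(length(a), length(b)),
                         mean = c(mean(a), mean(b)),
                         sem = c(sem(a), sem(b)))
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) {
        warning("zero variance in both groups with equal means; p = 1 by convention")
        return(list(design = design, statistic = 0, p = 1, groups = groups))
      }
      stop("zero variance in both groups with unequal means")
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
    list(design = design, statistic = unname(tt$statistic),
         p = tt$p.value, groups = groups)
  } else {
    if (!is.list(a) || length(a) < 2L)
      stop("multi_group design needs a list of >= 2 samples")
    if (any(vapply(a, length, integer(1L)) < 2L))
      stop("validation error: each group needs n >= 2")
    if (is.null(names(a))) names(a) <- paste0("g", seq_along(a))
    d <- data.frame(y = unlist(a, use.names = FALSE),
                    g = factor(rep(names(a), vapply(a, length, integer(1L)))))
    fit <- stats::aov(y ~ g, data = d)
    an <- summary(fit)[[1L]]
    tk <- stats::TukeyHSD(fit)$g
    groups <- data.frame(group = names(a),
                         n = vapply(a, length, integer(1L)),
                         mean = vapply(a, mean, numeric(1L)),
                         sem = vapply(a, sem, numeric(1L)))
    list(design = design, statistic = an[["F value"]][1L],
         p = an[["Pr(>F)"]][1L], groups = groups,
         tukey = data.frame(pair = rownames(tk), tk, row.names = NULL))
  }
}

#' Relative gene expression by the 2^-ddCt method
#'
#' `dCt = Ct_target - Ct_reference` within each condition;
#' `fold = 2^-(dCt_sample - dCt_control)` relative to the control condition
#' and the reference gene.
#'
#' @param ct_target_sample,ct_ref_sample threshold cycles of target and
#'   reference gene in the treated sample.
#' @param ct_target_control,ct_ref_control threshold cycles in the control
#'   sample.
#' @param target_gene,reference_gene gene labels carried into the result.
#' @return a list of class `ddct_result`: `target_gene`, `reference_gene`,
#'   `delta_ct_sample`, `delta_ct_control`, `fold_change`.
#' @export
ddct <- function(ct_target_sample, ct_ref_sample,
                 ct_target_control, ct_ref_control,
                 target_gene = "target", reference_gene = "GAPDH") {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_control, ct_ref_control)
  if (!all(is.finite(cts)) || any(cts <= 0))
    stop("all Ct values must be finite and positive")
  d_s <- ct_target_sample - ct_ref_sample
  d_c <- ct_target_control - ct_ref_control
  structure(list(target_gene = target_gene, reference_gene = reference_gene,
                 delta_ct_sample = d_s, delta_ct_control = d_c,
                 fold_change = 2^-(d_s - d_c)),
            class = "ddct_result")
}

#' Structured cohort report
#'
#' Assembles per-group tallies (with derived percentages and genuine-AP
#' shares), optional feature-table and calcium summaries, and pairwise
#' group comparisons into a JSON-ready list or a Markdown document.
#'
#' @param cohorts list of `cohort_tally` objects.
#' @param feature_tables optional named list of [cohort_feature_table()]
#'   data.frames, one per group.
#' @param calcium_tables optional named list of per-cell calcium summary
#'   data.frames (e.g. columns `band_peak_psd`, `events_per_min`).
#' @param format `"list"`, `"json"` or `"markdown"`.
#' @return the report in the requested format.
#' @export
report <- function(cohorts, feature_tables = NULL, calcium_tables = NULL,
                   format = c("list", "json", "markdown")) {
  format <- match.arg(format)
  if (length(cohorts) == 0L) stop("validation error: no cohorts given")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  sections <- lapply(cohorts, function(t) {
    induced <- all(c("Single", "Train") %in% names(t$counts))
    c(list(group = t$group_label, n = t$n,
           counts = as.list(t$counts),
           percentages = as.list(tally_percentages(t)),
           proportions = as.list(t$counts / t$n)),
      if (induced) list(genuine_ap_pct = genuine_ap_share(t)))
  })
  summarize_tab <- function(tab) {
    num <- names(tab)[vapply(tab, is.numeric, logical(1L))]
    stats_list <- lapply(num, function(cn) {
      x <- tab[[cn]][is.finite(tab[[cn]])]
      if (length(x) == 0L) return(NULL)
      list(n = length(x), mean = mean(x),
           sem = if (length(x) > 1L) sem(x) else NA_real_)
    })
    names(stats_list) <- num
    stats_list[!vapply(stats_list, is.null, logical(1L))]
  }
  rep_list <- list(tallies = sections)
  if (!is.null(feature_tables))
    rep_list$features <- lapply(feature_tables, summarize_tab)
  if (!is.null(calcium_tables))
    rep_list$calcium <- lapply(calcium_tables, summarize_tab)
  if (length(cohorts) >= 2L) {
    cmp <- lapply(utils::combn(length(cohorts), 2L, simplify = FALSE),
                  function(ij) {
                    t1 <- cohorts[[ij[1L]]]; t2 <- cohorts[[ij[2L]]]
                    induced <- all(c("Single", "Train") %in% names(t1$counts)) &&
                      all(c("Single", "Train") %in% names(t2$counts))
                    c(list(groups = c(t1$group_label, t2$group_label)),
                      if (induced) list(
                        genuine_ap_pct = c(genuine_ap_share(t1),
                                           genuine_ap_share(t2))))
                  })
    rep_list$comparisons <- cmp
  }
  switch(format,
         list = rep_list,
         json = jsonlite::toJSON(rep_list, auto_unbox = TRUE, digits = NA,
                                 pretty = TRUE),
         markdown = .report_markdown(rep_list))
}

.report_markdown <- function(r) {
  out <- c("# Cohort report", "")
  for (s in r$tallies) {
    out <- c(out, sprintf("## %s (n = %d)",
                          if (is.na(s$group)) "ungrouped" else s$group, s$n),
             "", "| class | count | percent |", "|---|---|---|")
    for (k in names(s$counts))
      out <- c(out, sprintf("| %s | %d | %d%% |", k, s$counts[[k]],
                            s$percentages[[k]]))
    if (!is.null(s$genuine_ap_pct))
      out <- c(out, "",
               sprintf("Genuine-AP share: %.1f%%", s$genuine_ap_pct))
    out <- c(out, "")
  }
  for (nm in names(r$features)) {
    out <- c(out, sprintf("## Features: %s", nm), "",
             "| metric | n | mean | sem |", "|---|---|---|---|")
    fl <- r$features[[nm]]
    for (k in names(fl))
      out <- c(out, sprintf("| %s | %d | %.3g | %.3g |", k, fl[[k]]$n,
                            fl[[k]]$mean, fl[[k]]$sem))
    out <- c(out, "")
  }
  paste(out, collapse = "\n")
}
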