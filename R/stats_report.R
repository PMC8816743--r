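# Thin statistical layer: maps the figure-legend test names onto standard
# procedures and fixes the unit of analysis (cell-level values vs replicate
# means).

#' Specification of a group comparison
#'
#' @param metric metric_name to analyse from a measurement table.
#' @param group_by grouping column (default `"condition"`).
#' @param design one of `"welch_t"` (unpaired t-test with Welch's
#'   correction), `"one_way_anova_dunnett"` (ordinary one-way ANOVA with
#'   Dunnett's correction against the control), `"one_way_anova_tukey"`
#'   (ordinary one-way ANOVA with Tukey's correction, all pairs) or
#'   `"bf_welch_anova_dunnett"` (Welch's heteroscedastic ANOVA omnibus with
#'   Welch-t contrasts against control, Sidak-adjusted).
#' @param control control group label for against-control designs.
#' @param alpha significance level (default 0.05).
#' @param replicate_level analyse replicate means (TRUE) or cell-level
#'   values (FALSE, default — the common convention of reporting per-cell n).
#' @export
group_comparison_spec <- function(metric, group_by = "condition",
                                  design = c("welch_t",
                                             "one_way_anova_dunnett",
                                             "one_way_anova_tukey",
                                             "bf_welch_anova_dunnett"),
                                  control = NULL, alpha = 0.05,
                                  replicate_level = FALSE) {
  design <- match.arg(design)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(metric = metric, group_by = group_by, design = design,
                 control = control, alpha = alpha,
                 replicate_level = replicate_level),
            class = "group_comparison_spec")
}

#' Compare groups of a measurement table
#'
#' Runs the per-group Shapiro-Wilk normality check, the omnibus test of the
#' chosen design, and the design's multiple-comparison-adjusted contrasts,
#' and flags significance at `alpha`. Adjusted p-values are never smaller
#' than the raw per-contrast p-values.
#'
#' @param table a measurement table (see [measurement_table()]).
#' @param spec a [group_comparison_spec()].
#' @return list of class `group_comparison`: `design`, `groups` (data.frame
#'   with mean, sd, n, shapiro_p per group), `omnibus_p`, `contrasts`
#'   (data.frame: contrast, estimate, p_raw, p_adj, significant), `alpha`.
#' @export
compare_groups <- function(table, spec) {
  validate_measurements(table)
  df <- table[table$metric_name == spec$metric, , drop = FALSE]
  if (!nrow(df)) stop("no rows with metric '", spec$metric, "'")
  if (spec$replicate_level) {
    agg <- stats::aggregate(df$value,
                            by = list(group = df[[spec$group_by]],
                                      replicate = df$replicate_id), FUN = mean)
    df <- data.frame(group = agg$group, value = agg$x,
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(group = df[[spec$group_by]], value = df$value,
                     stringsAsFactors = FALSE)
  }
  groups <- split(df$value, df$group)
  if (length(groups) < 2) stop("need at least 2 groups")
  small <- names(groups)[vapply(groups, length, 0L) < 2]
  if (length(small)) {
    stop("group(s) with n < 2: ", paste(small, collapse = ", "))
  }
  control <- spec$control
  if (is.null(control)) control <- names(groups)[1]
  if (!control %in% names(groups)) stop("unknown control group: ", control)

  gstats <- data.frame(
    group = names(groups),
    mean = vapply(groups, mean, 0),
    sd = vapply(groups, stats::sd, 0),
    n = vapply(groups, length, 0L),
    shapiro_p = vapply(groups, function(v) {
      if (length(v) >= 3 && length(v) <= 5000 && stats::sd(v) > 0) {
        stats::shapiro.test(v)$p.value
      } else NA_real_
    }, 0),
    stringsAsFactors = FALSE)
  rownames(gstats) <- NULL

  # Welch t-test robust to zero within-group variance
  welch_p <- function(a, b) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (mean(a) == mean(b)) 1 else .Machine$double.xmin)
    }
    tryCatch(stats::t.test(a, b, var.equal = FALSE)$p.value,
             error = function(e) NA_real_)
  }

  df$group <- factor(df$group)
  df$group <- stats::relevel(df$group, ref = control)
  others <- setdiff(levels(df$group), control)

  if (spec$design == "welch_t") {
    if (length(groups) != 2) stop("welch_t requires exactly 2 groups")
    p <- welch_p(groups[[control]], groups[[setdiff(names(groups), control)]])
    contrasts <- data.frame(
      contrast = paste(setdiff(names(groups), control), "vs", control),
      estimate = mean(groups[[setdiff(names(groups), control)]]) -
        mean(groups[[control]]),
      p_raw = p, p_adj = p, stringsAsFactors = FALSE)
    omnibus_p <- p
  } else if (spec$design == "one_way_anova_dunnett") {
    fit <- stats::aov(value ~ group, data = df)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    glht <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    sm <- summary(glht)
    raw <- summary(glht, test = multcomp::univariate())
    contrasts <- data.frame(
      contrast = names(sm$test$coefficients),
      estimate = unname(sm$test$coefficients),
      p_raw = unname(raw$test$pvalues),
      p_adj = pmax(unname(sm$test$pvalues), unname(raw$test$pvalues)),
      stringsAsFactors = FALSE)
  } else if (spec$design == "one_way_anova_tukey") {
    fit <- stats::aov(value ~ group, data = df)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$group
    pairs <- rownames(tk)
    raw <- vapply(pairs, function(pr) {
      gs <- strsplit(pr, "-", fixed = TRUE)[[1]]
      welch_p(df$value[df$group == gs[1]], df$value[df$group == gs[2]])
    }, 0)
    contrasts <- data.frame(
      contrast = pairs, estimate = tk[, "diff"],
      p_raw = raw, p_adj = pmax(tk[, "p adj"], raw),
      stringsAsFactors = FALSE)
  } else { # bf_welch_anova_dunnett
    omnibus_p <- if (all(vapply(groups, stats::sd, 0) > 0)) {
      stats::oneway.test(value ~ group, data = df, var.equal = FALSE)$p.value
    } else NA_real_
    raw <- vapply(others, function(g) {
      welch_p(groups[[g]], groups[[control]])
    }, 0)
    m <- length(others)
    contrasts <- data.frame(
      contrast = paste(others, "vs", control),
      estimate = vapply(others, function(g) mean(groups[[g]]), 0) -
        mean(groups[[control]]),
      p_raw = raw, p_adj = pmin(1, 1 - (1 - raw)^m),
      stringsAsFactors = FALSE)
    contrasts$p_adj <- pmax(contrasts$p_adj, contrasts$p_raw)
  }
  rownames(contrasts) <- NULL
  contrasts$significant <- contrasts$p_adj < spec$alpha
  structure(list(design = spec$design, groups = gstats,
                 omnibus_p = omnibus_p, contrasts = contrasts,
                 alpha = spec$alpha, control = control,
                 unit = if (spec$replicate_level) "replicate" else "cell"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (", x$design, ", ", x$unit, "-level), omnibus p = ",
      format.pval(x$omnibus_p, digits = 3), "\n", sep = "")
  print(x$groups, row.names = FALSE)
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Replicate-mean summary of a measurement table
#'
#' One row per (condition, replicate) with the replicate mean and n, plus a
#' condition-level summary: the unweighted mean of replicate means (the same
#' replicate-weighted convention used for aligned profiles) and the SD
#' across replicate means (NA for a single replicate).
#'
#' @param table a measurement table.
#' @param metric metric_name to summarise.
#' @param group_by grouping column (default `"condition"`).
#' @return list with `replicates` and `conditions` data.frames.
#' @export
summarize_replicates <- function(table, metric, group_by = "condition") {
  validate_measurements(table)
  df <- table[table$metric_name == metric, , drop = FALSE]
  if (!nrow(df)) stop("no rows with metric '", metric, "'")
  if (any(is.na(df$replicate_id)) || any(df$replicate_id == "")) {
    stop("missing replicate labels")
  }
  reps <- stats::aggregate(df$value,
                           by = list(condition = df[[group_by]],
                                     replicate_id = df$replicate_id),
                           FUN = mean)
  names(reps)[3] <- "mean"
  reps$n <- stats::aggregate(df$value,
                             by = list(df[[group_by]], df$replicate_id),
                             FUN = length)$x
  conds <- do.call(rbind, lapply(split(reps, reps$condition), function(g) {
    data.frame(condition = g$condition[1], mean = mean(g$mean),
               sd = if (nrow(g) > 1) stats::sd(g$mean) else NA_real_,
               n_replicates = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(conds) <- NULL
  list(replicates = reps, conditions = conds)
}
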