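# State/region-stratified occurrence rates, per-group summaries, and
# behavior-electrophysiology regressions.

#' State-stratified occurrence rates
#'
#' Counts events whose `peak_time_s` falls in intervals of each requested
#' sleep state (half-open membership) and divides by the analyzed time in
#' that state. Grouping keys are any subset of columns present in the event
#' table (e.g. `animal`, `group`, `region`, `kind`, `epoch`); the `state`
#' stratum is always added. When the `states` table has an `animal` column,
#' each animal's schedule supplies its own denominator.
#'
#' @param events event table (needs `peak_time_s`; other key columns as
#'   used in `by`).
#' @param states state intervals (`label`, `start_s`, `end_s`, optionally
#'   `animal`).
#' @param by character vector of grouping columns in `events`.
#' @param state_labels states to report (default NREM and REM).
#' @param unit `"per_min"` (default) or `"per_sec"`.
#' @return data.frame with the grouping columns, `state`,
#'   `analyzed_minutes`, `n_events`, `rate`. Strata with zero analyzed time
#'   are omitted with a warning.
#' @export
occurrence_rates <- function(events, states, by = c("region", "kind"),
                             state_labels = c("NREM", "REM"),
                             unit = c("per_min", "per_sec")) {
  unit <- match.arg(unit)
  by <- intersect(by, names(events))
  per_animal <- "animal" %in% names(states) && "animal" %in% names(events)
  out <- list()
  for (st in state_labels) {
    stab <- states[states$label == st, , drop = FALSE]
    groups <- if (length(by) > 0) {
      unique(events[, by, drop = FALSE])
    } else {
      data.frame(row.names = 1)
    }
    if (nrow(groups) == 0 && length(by) > 0) next
    for (g in seq_len(max(1L, nrow(groups)))) {
      sel <- rep(TRUE, nrow(events))
      for (col in by) sel <- sel & events[[col]] == groups[[col]][g]
      sub <- events[sel, , drop = FALSE]
      stg <- stab
      if (per_animal && nrow(sub) > 0) {
        stg <- stab[stab$animal == sub$animal[1], , drop = FALSE]
      }
      secs <- sum(stg$end_s - stg$start_s)
      if (secs <= 0) {
        warning("stratum omitted: zero analyzed time in state ", st)
        next
      }
      n_ev <- sum(times_in_states(sub$peak_time_s, stg, st))
      denom <- if (unit == "per_min") secs / 60 else secs
      row <- if (length(by) > 0) groups[g, , drop = FALSE]
             else data.frame(row.names = 1)
      row$state <- st
      row$analyzed_minutes <- secs / 60
      row$n_events <- n_ev
      row$rate <- n_ev / denom
      out[[length(out) + 1L]] <- row
    }
  }
  if (length(out) == 0) {
    return(data.frame(state = character(), analyzed_minutes = numeric(),
                      n_events = integer(), rate = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Regress behavioral completion time on an electrophysiological measure
#'
#' Ordinary least squares of `y` on `x` with Pearson r, R-squared and the
#' two-sided p-value from the t distribution with n - 2 degrees of freedom.
#'
#' @param x per-animal predictor (e.g. coupling strength h).
#' @param y per-animal task completion time, seconds.
#' @param predictor name recorded in the result.
#' @return list of class `regression_result`: `predictor`, `n`, `slope`,
#'   `intercept`, `r`, `r_squared`, `p_value`.
#' @export
regress_behavior <- function(x, y, predictor = "x") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("insufficient data: at least 3 paired observations needed")
  if (stats::sd(x) == 0) stop("degenerate predictor: x is constant")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(predictor = predictor, n = n,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_se = suppressWarnings(   # perfect fits are legal
                   summary(fit)$coefficients[2, 2]),
                 r = r, r_squared = r^2, p_value = p),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> %s: slope = %.4g, r = %.3f, R^2 = %.3f, p = %.4g (n = %d)\n",
    x$predictor, x$slope, x$r, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Per-stratum group summaries with Welch t statistics
#'
#' For each stratum (combination of the given stratum columns), computes the
#' group means, SEMs, their difference (first minus second contrast level)
#' and the Welch (unequal-variance) t statistic with its degrees of freedom.
#' Strata missing a group, or with fewer than 2 animals in either group, are
#' omitted with a warning. No multiple-testing correction is applied; the
#' table carries enough metadata for external correction.
#'
#' @param rates rate table (one row per animal per stratum) with a grouping
#'   column and a value column.
#' @param contrast character vector of the two group labels, difference =
#'   first - second.
#' @param group_col name of the group column (default `"group"`).
#' @param value_col name of the value column (default `"rate"`).
#' @param strata stratum columns present in `rates`.
#' @return data.frame with per-stratum means, SEMs, `mean_diff`, `t`, `df`,
#'   `p_value`, `n1`, `n2`.
#' @export
summarize_groups <- function(rates, contrast, group_col = "group",
                             value_col = "rate",
                             strata = c("region", "state", "epoch", "kind")) {
  strata <- intersect(strata, names(rates))
  stopifnot(group_col %in% names(rates), value_col %in% names(rates),
            length(contrast) == 2)
  combos <- if (length(strata) > 0) unique(rates[, strata, drop = FALSE])
            else data.frame(row.names = 1)
  out <- list()
  for (i in seq_len(max(1L, nrow(combos)))) {
    sel <- rep(TRUE, nrow(rates))
    for (col in strata) sel <- sel & rates[[col]] == combos[[col]][i]
    sub <- rates[sel, , drop = FALSE]
    v1 <- sub[[value_col]][sub[[group_col]] == contrast[1]]
    v2 <- sub[[value_col]][sub[[group_col]] == contrast[2]]
    if (length(v1) < 2 || length(v2) < 2) {
      warning("stratum omitted: need at least 2 observations per group")
      next
    }
    if (stats::sd(v1) == 0 && stats::sd(v2) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
                 p.value = if (mean(v1) == mean(v2)) 1 else 0)
    } else {
      tt <- stats::t.test(v1, v2)
    }
    row <- if (length(strata) > 0) combos[i, , drop = FALSE]
           else data.frame(row.names = 1)
    row$mean_1 <- mean(v1); row$sem_1 <- stats::sd(v1) / sqrt(length(v1))
    row$mean_2 <- mean(v2); row$sem_2 <- stats::sd(v2) / sqrt(length(v2))
    row$mean_diff <- mean(v1) - mean(v2)
    row$t <- unname(tt$statistic)
    row$df <- unname(tt$parameter)
    row$p_value <- tt$p.value
    row$n1 <- length(v1); row$n2 <- length(v2)
    out[[length(out) + 1L]] <- row
  }
  if (length(out) == 0) {
    warning("no strata with both groups represented")
    return(data.frame())
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
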