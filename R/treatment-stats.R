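#' Summarize per-track mobility for one condition
#'
#' The experimental unit is the biological replicate (one movie/field):
#' the per-track values (typically MSD at a chosen lag) are reduced to a
#' median within each replicate, and the condition is summarized by the
#' mean of the replicate medians with its standard error (sample SD over
#' the square root of the number of replicates). With a single replicate
#' the SE is undefined and reported as `NA`, never 0.
#'
#' @param values Numeric vector of per-track values (e.g. MSD(10 s), um^2).
#' @param replicates Replicate label per value (same length).
#' @param marker,condition,treatment_time Optional provenance labels.
#' @return A `condition_summary` list: `replicate_medians`,
#'   `mean_of_medians`, `standard_error`, `n_replicates`, `n_tracks`, plus
#'   the labels.
#' @export
summarize_condition <- function(values, replicates,
                                marker = NA_character_,
                                condition = NA_character_,
                                treatment_time = NA_real_) {
  stopifnot(length(values) == length(replicates), length(values) >= 1)
  if (any(!is.finite(values))) {
    keep <- is.finite(values)
    values <- values[keep]
    replicates <- replicates[keep]
  }
  if (length(values) == 0) stop("no finite values to summarize", call. = FALSE)
  med <- tapply(values, replicates, stats::median)
  n_rep <- length(med)
  se <- if (n_rep >= 2) stats::sd(med) / sqrt(n_rep) else NA_real_
  structure(list(
    marker = marker, condition = condition, treatment_time = treatment_time,
    replicate_medians = as.numeric(med),
    replicate_labels = names(med),
    mean_of_medians = mean(med),
    standard_error = se,
    n_replicates = n_rep,
    n_tracks = length(values)
  ), class = "condition_summary")
}

#' Log fold change of treated versus control mobility
#'
#' `log_base(treated mean / control mean)`; zero iff the means are equal,
#' antisymmetric under swapping treated and control. Base 10 is the default
#' for mobility comparisons; base 2 is conventional when plotting against
#' crowding changes.
#'
#' @param treated,control `condition_summary` objects (their
#'   `mean_of_medians` is used) or positive scalars.
#' @param log_base Logarithm base (default 10).
#' @param lag_s Optional lag-time label carried through, seconds.
#' @return A `fold_change` list: `value`, `log_base`, `lag_s`, labels, and
#'   the two means.
#' @export
fold_change <- function(treated, control, log_base = 10, lag_s = NA_real_) {
  tm <- if (inherits(treated, "condition_summary")) treated$mean_of_medians else treated
  cm <- if (inherits(control, "condition_summary")) control$mean_of_medians else control
  assert_scalar_num(tm, "treated mean", 0, strict_lower = TRUE)
  assert_scalar_num(cm, "control mean", 0, strict_lower = TRUE)
  structure(list(
    value = log(tm / cm, base = log_base),
    log_base = log_base,
    lag_s = lag_s,
    marker = if (inherits(treated, "condition_summary")) treated$marker else NA_character_,
    condition = if (inherits(treated, "condition_summary")) treated$condition else NA_character_,
    treatment_time = if (inherits(treated, "condition_summary")) treated$treatment_time else NA_real_,
    treated_mean = tm, control_mean = cm
  ), class = "fold_change")
}

#' Two-sided test of treated versus control distributions
#'
#' `mann_whitney` (Wilcoxon rank-sum; default for MSD distributions, which
#' are right-skewed) or `welch_t` (default choice for assay ratios).
#' Degenerate comparisons (both samples constant and identical) return
#' p = 1 with a warning.
#'
#' @param treated,control Numeric vectors (>= 3 values each).
#' @param method `"mann_whitney"` or `"welch_t"`.
#' @return Two-sided p-value.
#' @export
compare_to_control <- function(treated, control,
                               method = c("mann_whitney", "welch_t")) {
  method <- match.arg(method)
  stopifnot(length(treated) >= 3, length(control) >= 3)
  if (stats::var(treated) == 0 && stats::var(control) == 0 &&
      treated[1] == control[1]) {
    warning("degenerate samples (identical constants); p = 1", call. = FALSE)
    return(1)
  }
  if (method == "mann_whitney") {
    suppressWarnings(stats::wilcox.test(treated, control, exact = FALSE))$p.value
  } else {
    stats::t.test(treated, control, var.equal = FALSE)$p.value
  }
}

# Total-least-squares (major-axis) slope; symmetric under exchanging x/y
# up to inversion. Standard closed form from the 2x2 scatter matrix.
tls_slope <- function(x, y) {
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxy == 0) {
    if (syy > sxx) return(Inf)
    return(0)
  }
  (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
}

#' Consistency of fold changes between two markers
#'
#' Given paired fold changes for two markers (e.g. an origin-proximal and a
#' terminus-proximal chromosomal locus, or a chromosomal locus versus a
#' cytosolic aggregate) across conditions and treatment times, quantifies
#' whether the responses fall on the identity line: total-least-squares
#' slope (symmetric in the two markers), Pearson correlation, and the RMS
#' perpendicular distance of the pairs to the line `y = x`.
#'
#' @param fc_a,fc_b Numeric vectors of paired fold changes (>= 3 pairs), or
#'   lists of `fold_change` objects.
#' @return List: `slope`, `pearson_r`, `rms_deviation_from_identity`, `n`.
#' @export
cross_marker_consistency <- function(fc_a, fc_b) {
  num <- function(z) {
    if (is.list(z) && all(vapply(z, inherits, logical(1), "fold_change"))) {
      vapply(z, function(f) f$value, numeric(1))
    } else as.numeric(z)
  }
  a <- num(fc_a); b <- num(fc_b)
  stopifnot(length(a) == length(b))
  if (length(a) < 3) stop("need at least 3 paired fold changes", call. = FALSE)
  list(
    slope = tls_slope(a, b),
    pearson_r = stats::cor(a, b),
    rms_deviation_from_identity = sqrt(mean((b - a)^2 / 2)),
    n = length(a)
  )
}

#' Tabulate condition summaries and fold changes across an experiment
#'
#' Convenience aggregation over a per-track value table: groups by
#' marker/condition/treatment time, summarizes each group with
#' [summarize_condition()], and computes fold changes of every treated
#' group against the control group at the same treatment time and marker.
#'
#' @param per_track Data frame with columns `marker`, `condition`,
#'   `treatment_time`, `replicate`, `value`.
#' @param control Name of the control condition (default `"control"`).
#' @param log_base Fold-change log base.
#' @param lag_s Lag label carried into the fold changes.
#' @return List of data frames: `summary` (one row per group) and
#'   `fold_changes` (one row per treated group), plus `p_value` columns
#'   from [compare_to_control()] on the replicate medians.
#' @export
summarize_experiment <- function(per_track, control = "control",
                                 log_base = 10, lag_s = NA_real_) {
  need <- c("marker", "condition", "treatment_time", "replicate", "value")
  stopifnot(all(need %in% names(per_track)))
  key <- interaction(per_track$marker, per_track$condition,
                     per_track$treatment_time, drop = TRUE)
  groups <- split(per_track, key)
  sums <- lapply(groups, function(g) {
    summarize_condition(g$value, g$replicate, marker = g$marker[1],
                        condition = g$condition[1],
                        treatment_time = g$treatment_time[1])
  })
  summary_df <- do.call(rbind, lapply(sums, function(s) data.frame(
    marker = s$marker, condition = s$condition,
    treatment_time = s$treatment_time,
    mean_of_medians = s$mean_of_medians, standard_error = s$standard_error,
    n_replicates = s$n_replicates, n_tracks = s$n_tracks)))
  rownames(summary_df) <- NULL

  fc_rows <- list()
  for (s in sums) {
    if (s$condition == control) next
    ctrl <- Filter(function(z) z$condition == control && z$marker == s$marker &&
                     identical(z$treatment_time, s$treatment_time), sums)
    if (length(ctrl) == 0) next
    ctrl <- ctrl[[1]]
    fc <- fold_change(s, ctrl, log_base = log_base, lag_s = lag_s)
    pv <- if (s$n_replicates >= 3 && ctrl$n_replicates >= 3) {
      compare_to_control(s$replicate_medians, ctrl$replicate_medians)
    } else NA_real_
    fc_rows[[length(fc_rows) + 1L]] <- data.frame(
      marker = s$marker, condition = s$condition,
      treatment_time = s$treatment_time, lag_s = lag_s,
      log_fold_change = fc$value, log_base = log_base,
      treated_mean = fc$treated_mean, control_mean = fc$control_mean,
      p_value = pv)
  }
  fold_df <- if (length(fc_rows)) do.call(rbind, fc_rows) else
    data.frame(marker = character(0), condition = character(0),
               treatment_time = numeric(0), lag_s = numeric(0),
               log_fold_change = numeric(0), log_base = numeric(0),
               treated_mean = numeric(0), control_mean = numeric(0),
               p_value = numeric(0))
  rownames(fold_df) <- NULL
  list(summary = summary_df, fold_changes = fold_df)
}
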