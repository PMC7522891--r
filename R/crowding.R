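#' Ratio of two means with propagated standard error
#'
#' The standard error of a ratio of two independently estimated means
#' A/B is propagated to first order as
#' `SE_{a/b} = (A/B) * sqrt((SE_a/A)^2 + (SE_b/B)^2)`.
#'
#' @param a_mean,b_mean Means of numerator and denominator.
#' @param a_se,b_se Their standard errors.
#' @param n Number of (biological) replicates behind the estimate.
#' @return A `ratio_estimate` list: `value`, `standard_error`, `n`.
#' @export
ratio_estimate <- function(a_mean, b_mean, a_se, b_se, n = NA_integer_) {
  assert_scalar_num(b_mean, "b_mean", 0, strict_lower = TRUE)
  value <- a_mean / b_mean
  se <- if (is.na(a_se) || is.na(b_se)) NA_real_ else
    abs(value) * sqrt((a_se / a_mean)^2 + (b_se / b_mean)^2)
  structure(list(value = value, standard_error = se, n = n),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("ratio estimate: %.4g +/- %.3g (n = %s)\n",
              x$value, x$standard_error, x$n))
  invisible(x)
}

# Collapse technical replicates within biological replicate, then return
# per-replicate means of one column.
replicate_means <- function(assay_table, condition, column) {
  rows <- assay_table[assay_table$condition == condition &
                        is.finite(assay_table[[column]]), , drop = FALSE]
  if (nrow(rows) == 0) {
    stop(sprintf("no `%s` rows for condition '%s'", column, condition),
         call. = FALSE)
  }
  as.numeric(tapply(rows[[column]], rows$replicate, mean))
}

mean_se <- function(x) {
  list(mean = mean(x),
       se = if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_)
}

#' Biomass-to-OD600 ratio of a condition
#'
#' Dry mass per unit optical density is a proxy for intracellular density
#' and hence macromolecular crowding: it stays constant in steady-state
#' growth but shifts when treatments change cell density. Technical
#' replicates are averaged within each biological replicate; the ratio of
#' the across-replicate means is reported with the propagated SE of
#' [ratio_estimate()]. SE is undefined (`NA`) with a single replicate.
#'
#' @param assay_table Data frame with columns `condition`, `replicate`,
#'   `technical_rep`, `od600`, `dry_mass_mg_ml` (see
#'   [generate_assay_table()]).
#' @param condition Condition label.
#' @return A `ratio_estimate` (mg/mL per OD600 unit).
#' @export
biomass_od_ratio <- function(assay_table, condition) {
  dm <- mean_se(replicate_means(assay_table, condition, "dry_mass_mg_ml"))
  od <- mean_se(replicate_means(assay_table, condition, "od600"))
  if (od$mean <= 0) stop("mean OD600 must be positive", call. = FALSE)
  ratio_estimate(dm$mean, od$mean, dm$se, od$se,
                 n = length(replicate_means(assay_table, condition, "od600")))
}

#' Protein contribution to total biomass of a condition
#'
#' `mean(protein) / mean(dry mass)` across biological replicates, SE
#' propagated as in [biomass_od_ratio()]. A stable protein fraction under
#' treatment indicates that biomass composition, not just amount, is
#' preserved.
#'
#' @inheritParams biomass_od_ratio
#' @return A `ratio_estimate` (dimensionless fraction).
#' @export
protein_fraction <- function(assay_table, condition) {
  pr <- mean_se(replicate_means(assay_table, condition, "protein_mg_ml"))
  dm <- mean_se(replicate_means(assay_table, condition, "dry_mass_mg_ml"))
  if (dm$mean <= 0) stop("mean dry mass must be positive", call. = FALSE)
  ratio_estimate(pr$mean, dm$mean, pr$se, dm$se,
                 n = length(replicate_means(assay_table, condition, "dry_mass_mg_ml")))
}

#' Fold change in a crowding proxy, treated versus control
#'
#' Ratio of two [ratio_estimate()]s (e.g. biomass/OD of a treated condition
#' over control) with the same first-order relative-error propagation; the
#' `log2` element gives the symmetric log-scale version used when plotting
#' against mobility fold changes.
#'
#' @param treated,control `ratio_estimate` objects.
#' @return A `ratio_estimate` with an extra `log2` element.
#' @export
crowding_fold_change <- function(treated, control) {
  stopifnot(inherits(treated, "ratio_estimate"), inherits(control, "ratio_estimate"))
  out <- ratio_estimate(treated$value, control$value,
                        treated$standard_error, control$standard_error,
                        n = min(treated$n, control$n))
  out$log2 <- log2(out$value)
  out
}

#' Estimate cell refractive index by BSA titration index matching
#'
#' Optical density scales with the refractive-index (RI) mismatch between
#' cells and medium and vanishes when the two match. Adding BSA raises the
#' medium RI linearly (`medium_ri + bsa_ri_increment * concentration`), so
#' the OD-versus-concentration titration is fit with a least-squares line
#' and extrapolated to its zero crossing `c0 = -intercept/slope`; the cell
#' RI is the medium RI at that concentration. A non-decreasing series
#' cannot cross zero and is refused.
#'
#' @param titration Data frame with columns `bsa_g_per_ml` and
#'   `od_titration` (>= 3 points spanning positive OD).
#' @param medium_ri RI of the plain medium (default 1.335, aqueous buffer).
#' @param bsa_ri_increment dn/dc of BSA, RI per (g/mL); default 0.185, the
#'   standard protein refractive increment.
#' @return List: `cell_ri`, `c0_g_per_ml`, `slope`, `intercept`, `n`.
#' @export
ri_match <- function(titration, medium_ri = 1.335, bsa_ri_increment = 0.185) {
  stopifnot(all(c("bsa_g_per_ml", "od_titration") %in% names(titration)))
  ok <- is.finite(titration$bsa_g_per_ml) & is.finite(titration$od_titration)
  tt <- titration[ok, , drop = FALSE]
  if (nrow(tt) < 3) stop("need at least 3 titration points", call. = FALSE)
  if (max(tt$od_titration) <= 0) {
    stop("titration series has no positive OD values", call. = FALSE)
  }
  fit <- stats::lm(od_titration ~ bsa_g_per_ml, data = tt)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0) {
    stop("titration OD must decrease with BSA concentration; fitted slope >= 0",
         call. = FALSE)
  }
  c0 <- -intercept / slope
  list(cell_ri = medium_ri + bsa_ri_increment * c0,
       c0_g_per_ml = c0, slope = slope, intercept = intercept, n = nrow(tt))
}

#' Correlate mobility fold changes with crowding fold changes
#'
#' Tests the crowding hypothesis that intracellular mobility is inversely
#' proportional to crowding: plotted as log2 mobility fold change against
#' log2 crowding fold change, inverse proportionality is a line of slope
#' -1. Reports the total-least-squares slope, Pearson correlation and the
#' deviation of the slope from -1.
#'
#' @param msd_log2_fc Numeric vector of log2 MSD fold changes, one per
#'   condition.
#' @param crowding_fc Paired crowding fold changes: either linear ratios
#'   (converted with log2 when `crowding_scale = "ratio"`) or already-log2
#'   values (`crowding_scale = "log2"`).
#' @param crowding_scale `"ratio"` (default) or `"log2"`.
#' @return List: `slope`, `pearson_r`, `deviation_from_minus_one`, `n`.
#' @export
crowding_mobility_correlation <- function(msd_log2_fc, crowding_fc,
                                          crowding_scale = c("ratio", "log2")) {
  crowding_scale <- match.arg(crowding_scale)
  x <- if (crowding_scale == "ratio") log2(as.numeric(crowding_fc)) else
    as.numeric(crowding_fc)
  y <- as.numeric(msd_log2_fc)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired conditions", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("all crowding fold changes identical; slope undefined", call. = FALSE)
  }
  slope <- tls_slope(x, y)
  list(slope = slope, pearson_r = stats::cor(x, y),
       deviation_from_minus_one = slope - (-1), n = length(x))
}
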