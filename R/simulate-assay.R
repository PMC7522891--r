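#' Configuration for synthetic crowding-assay tables
#'
#' Describes the ground truth behind plate-reader style assays: per
#' condition a true biomass-to-OD600 ratio (mg dry mass per mL per OD
#' unit), a true protein fraction of biomass, and a true cell refractive
#' index (RI); globally the medium RI, the refractive increment of BSA,
#' the multiplicative replicate noise (coefficient of variation) and the
#' replicate structure.
#'
#' Defaults emulate exponentially growing enteric bacteria: biomass/OD
#' about 0.45 mg/mL per OD unit, protein about 55% of dry mass, cell RI
#' about 1.388 against an aqueous medium at 1.335, measured in three
#' biological replicates each performed in technical triplicate.
#'
#' @param conditions Named list; each element a list with `biomass_per_od`
#'   (mg/mL/OD), `protein_fraction` (0-1) and `cell_ri` (> medium RI).
#' @param medium_ri Medium refractive index (default 1.335).
#' @param bsa_ri_increment dn/dc of BSA, RI per g/mL (default 0.185).
#' @param cv Coefficient of variation of the multiplicative Gaussian
#'   replicate noise (default 0.05).
#' @param n_replicates,n_technical Biological and technical replicates.
#' @param od_nominal Nominal culture OD600 at harvest (default 0.4).
#' @param n_titration Number of BSA concentrations per titration series.
#' @param seed Master seed.
#' @return An `assay_config` list.
#' @export
assay_config <- function(conditions = list(
                           control = list(biomass_per_od = 0.45,
                                          protein_fraction = 0.55,
                                          cell_ri = 1.388)),
                         medium_ri = 1.335,
                         bsa_ri_increment = 0.185,
                         cv = 0.05,
                         n_replicates = 3L,
                         n_technical = 3L,
                         od_nominal = 0.4,
                         n_titration = 7L,
                         seed = 1L) {
  stopifnot(is.list(conditions), length(conditions) >= 1,
            !is.null(names(conditions)), all(nzchar(names(conditions))))
  for (nm in names(conditions)) {
    cc <- conditions[[nm]]
    assert_scalar_num(cc$biomass_per_od, paste0(nm, "$biomass_per_od"), 0, strict_lower = TRUE)
    assert_scalar_num(cc$protein_fraction, paste0(nm, "$protein_fraction"), 0, 1,
                      strict_lower = TRUE, strict_upper = TRUE)
    assert_scalar_num(cc$cell_ri, paste0(nm, "$cell_ri"), 1, strict_lower = TRUE)
  }
  assert_scalar_num(medium_ri, "medium_ri", 1, strict_lower = TRUE)
  assert_scalar_num(bsa_ri_increment, "bsa_ri_increment", 0, strict_lower = TRUE)
  assert_scalar_num(cv, "cv", 0)
  structure(list(
    conditions = conditions, medium_ri = medium_ri,
    bsa_ri_increment = bsa_ri_increment, cv = cv,
    n_replicates = assert_count(n_replicates, "n_replicates"),
    n_technical = assert_count(n_technical, "n_technical"),
    od_nominal = assert_scalar_num(od_nominal, "od_nominal", 0, strict_lower = TRUE),
    n_titration = assert_count(n_titration, "n_titration", min = 3L),
    seed = assert_count(seed, "seed", min = 0L)
  ), class = "assay_config")
}

#' Generate a synthetic crowding-assay table
#'
#' For every condition and biological/technical replicate, draws an OD600
#' reading and a dry-mass measurement consistent with the condition's true
#' biomass-per-OD ratio under multiplicative Gaussian noise (`1 + cv * N(0,1)`
#' applied independently to each measured quantity); protein mass is
#' `dry mass * protein_fraction * noise`. Each biological replicate also
#' carries a BSA index-matching titration: OD decreasing linearly in the
#' BSA-induced medium RI and crossing zero exactly where the medium RI
#' reaches the condition's true cell RI.
#'
#' With `cv = 0` the table is exact: downstream estimators recover the
#' configured truths to machine precision.
#'
#' @param config An [assay_config()].
#' @return Data frame with columns `condition`, `replicate`,
#'   `technical_rep`, `od600`, `dry_mass_mg_ml`, `protein_mg_ml`,
#'   `bsa_g_per_ml`, `od_titration`. Assay rows carry `NA` in the titration
#'   columns and vice versa.
#' @export
generate_assay_table <- function(config) {
  stopifnot(inherits(config, "assay_config"))
  noise <- function(n) 1 + config$cv * stats::rnorm(n)
  rows <- list()
  for (cond in names(config$conditions)) {
    truth <- config$conditions[[cond]]
    c0 <- (truth$cell_ri - config$medium_ri) / config$bsa_ri_increment
    for (rep_i in seq_len(config$n_replicates)) {
      rows[[length(rows) + 1L]] <- with_seed(
        derive_seed(config$seed, "assay", cond, rep_i), {
          nt <- config$n_technical
          od <- config$od_nominal * noise(nt)
          dm <- config$od_nominal * truth$biomass_per_od * noise(nt)
          pr <- dm * truth$protein_fraction * noise(nt)
          assay <- data.frame(
            condition = cond, replicate = rep_i, technical_rep = seq_len(nt),
            od600 = od, dry_mass_mg_ml = dm, protein_mg_ml = pr,
            bsa_g_per_ml = NA_real_, od_titration = NA_real_)
          conc <- seq(0, max(c0, 0), length.out = config$n_titration)
          frac <- if (c0 > 0) 1 - conc / c0 else rep(0, config$n_titration)
          od_tit <- config$od_nominal * frac * noise(config$n_titration)
          titr <- data.frame(
            condition = cond, replicate = rep_i, technical_rep = NA_integer_,
            od600 = NA_real_, dry_mass_mg_ml = NA_real_,
            protein_mg_ml = NA_real_,
            bsa_g_per_ml = conc, od_titration = od_tit)
          rbind(assay, titr)
        })
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- config$conditions
  out
}
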