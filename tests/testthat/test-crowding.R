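test_that("ratio SE propagation matches the relative-error formula exactly", {
  r <- ratio_estimate(2, 1, 0.2, 0.1)
  expect_equal(r$value, 2)
  expect_equal(r$standard_error, 2 * sqrt(0.01 + 0.01), tolerance = 1e-15)
  # zero scatter in both -> zero SE; symmetric in the relative errors
  expect_equal(ratio_estimate(3, 2, 0, 0)$standard_error, 0)
  r1 <- ratio_estimate(10, 5, 10 * 0.03, 5 * 0.07)
  r2 <- ratio_estimate(10, 5, 10 * 0.07, 5 * 0.03)
  expect_equal(r1$standard_error, r2$standard_error, tolerance = 1e-15)
  # homogeneity: scaling the numerator scales value and SE
  r3 <- ratio_estimate(2 * 5, 1, 0.2 * 5, 0.1)
  expect_equal(r3$value, 5 * r$value)
  expect_equal(r3$standard_error, 5 * r$standard_error, tolerance = 1e-12)
})

test_that("ratio SE matches the delta-method variance on simulated Gaussians", {
  set.seed(31)
  A <- 2; B <- 1; cv <- 0.05; n <- 5
  ratios <- replicate(4000, {
    a <- rnorm(n, A, A * cv); b <- rnorm(n, B, B * cv)
    mean(a) / mean(b)
  })
  # analytic SE using the true SEs of the two means
  se_theory <- (A / B) * sqrt((cv / sqrt(n))^2 + (cv / sqrt(n))^2)
  expect_equal(sd(ratios), se_theory, tolerance = 0.05)
})

test_that("biomass/OD and protein-fraction estimators recover exact tables", {
  acfg <- assay_config(conditions = list(
    control = list(biomass_per_od = 0.45, protein_fraction = 0.55, cell_ri = 1.388),
    sorbitol = list(biomass_per_od = 0.585, protein_fraction = 0.55, cell_ri = 1.388)),
    cv = 0, seed = 1)
  tab <- generate_assay_table(acfg)
  br <- biomass_od_ratio(tab, "control")
  expect_equal(br$value, 0.45, tolerance = 1e-12)
  expect_equal(br$standard_error, 0)
  pf <- protein_fraction(tab, "sorbitol")
  expect_equal(pf$value, 0.55, tolerance = 1e-12)
  # doubling protein and dry mass together leaves the fraction unchanged
  tab2 <- tab
  tab2$protein_mg_ml <- tab2$protein_mg_ml * 2
  tab2$dry_mass_mg_ml <- tab2$dry_mass_mg_ml * 2
  expect_equal(protein_fraction(tab2, "sorbitol")$value, 0.55, tolerance = 1e-12)
  fc <- crowding_fold_change(biomass_od_ratio(tab, "sorbitol"), br)
  expect_equal(fc$value, 1.3, tolerance = 1e-12)
  expect_equal(fc$log2, log2(1.3), tolerance = 1e-12)
  # treated = control -> ratio exactly 1
  expect_equal(crowding_fold_change(br, br)$value, 1)
})

test_that("a 10% lower and a 30% higher density come out as printed ratios", {
  ctrl <- ratio_estimate(1.0, 1, 0.02, 0)
  cip <- ratio_estimate(0.9, 1, 0.02, 0)
  sor <- ratio_estimate(1.3, 1, 0.02, 0)
  expect_equal(crowding_fold_change(cip, ctrl)$value, 0.9, tolerance = 1e-12)
  expect_equal(crowding_fold_change(sor, ctrl)$value, 1.3, tolerance = 1e-12)
})

test_that("protein-fraction coverage: truth within 3 propagated SEs almost always", {
  hits <- vapply(1:300, function(s) {
    acfg <- assay_config(cv = 0.05, seed = s)
    tab <- generate_assay_table(acfg)
    pf <- protein_fraction(tab, "control")
    abs(pf$value - 0.55) <= 3 * pf$standard_error
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("refractive-index matching is exact on noiseless titrations", {
  titr <- data.frame(bsa_g_per_ml = c(0, 0.1, 0.2),
                     od_titration = c(0.2, 0.1, 0.0))
  ri <- ri_match(titr, medium_ri = 1.335, bsa_ri_increment = 0.185)
  expect_equal(ri$c0_g_per_ml, 0.2, tolerance = 1e-12)
  expect_equal(ri$cell_ri, 1.335 + 0.185 * 0.2, tolerance = 1e-12)
  # adding a constant OD offset shifts the crossing by offset/|slope|
  titr2 <- titr; titr2$od_titration <- titr2$od_titration + 0.05
  ri2 <- ri_match(titr2)
  expect_equal(ri2$c0_g_per_ml, 0.2 + 0.05 / 1.0, tolerance = 1e-12)
  # non-decreasing series refused
  bad <- data.frame(bsa_g_per_ml = c(0, 0.1, 0.2), od_titration = c(0.1, 0.1, 0.2))
  expect_error(ri_match(bad), "decrease")
})

test_that("configured cell RI is recovered from noisy synthetic titrations", {
  acfg <- assay_config(conditions = list(
    control = list(biomass_per_od = 0.45, protein_fraction = 0.55, cell_ri = 1.388)),
    cv = 0.02, seed = 12)
  tab <- generate_assay_table(acfg)
  titr <- tab[is.finite(tab$bsa_g_per_ml), ]
  ri <- ri_match(titr, medium_ri = 1.335, bsa_ri_increment = 0.185)
  expect_lt(abs(ri$cell_ri - 1.388), 0.001)
})

test_that("matched cell and medium RI gives zero titration OD at zero BSA", {
  acfg <- assay_config(conditions = list(
    control = list(biomass_per_od = 0.45, protein_fraction = 0.55, cell_ri = 1.335)),
    medium_ri = 1.335, cv = 0, seed = 1)
  tab <- generate_assay_table(acfg)
  titr <- tab[is.finite(tab$bsa_g_per_ml), ]
  expect_true(all(titr$bsa_g_per_ml == 0))
  expect_true(all(titr$od_titration == 0))
})

test_that("mobility-crowding correlation flags inverse proportionality", {
  x <- c(-0.2, -0.1, 0.05, 0.15, 0.3, 0.38)
  res <- crowding_mobility_correlation(msd_log2_fc = -x, crowding_fc = x,
                                       crowding_scale = "log2")
  expect_equal(res$slope, -1, tolerance = 1e-12)
  expect_equal(res$pearson_r, -1, tolerance = 1e-12)
  expect_equal(res$deviation_from_minus_one, 0, tolerance = 1e-12)
  expect_error(crowding_mobility_correlation(c(1, 2, 3), c(1, 1, 1),
                                             crowding_scale = "log2"),
               "identical")
  expect_error(crowding_mobility_correlation(c(1, 2), c(1, 2)), "3")
})
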