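test_that("cohort spec validation rejects degenerate settings", {
  expect_error(cohort_spec(n_patients = 1), "n_patients")
  expect_error(cohort_spec(bimodal_fraction = 1.2), "proportion")
  expect_error(cohort_spec(n_somatic_range = c(10, 5)), "range")
  expect_error(cohort_spec(n_somatic_range = c(0, 5)), "positive")
  expect_error(cohort_spec(paf_range = c(0, 1)), "positive")
  expect_error(cohort_spec(censor_rate = 1), "proportion|censor")
  expect_error(cohort_spec(volume_dim = c(63, 64, 48)), "even")
})

test_that("variant tables are byte-identical under the same spec and seed", {
  spec <- cohort_spec(n_patients = 3, seed = 42)
  t1 <- generate_variant_table(spec, 2)
  t2 <- generate_variant_table(spec, 2)
  expect_identical(t1, t2)
  t3 <- generate_variant_table(cohort_spec(n_patients = 3, seed = 43), 2)
  expect_false(identical(t1$pos, t3$pos))
})

test_that("bimodal patients show two VAF density modes at the configured centers", {
  spec <- cohort_spec(n_patients = 2, seed = 7, bimodal_fraction = 1,
                      purity_range = c(0.8, 0.8), n_somatic_range = c(6000L, 6000L),
                      n_germline_range = c(0L, 0L), ccf_dispersion = 0.1,
                      vaf_overdispersion = 0)
  tab <- generate_variant_table(spec, 1)
  truth <- attr(tab, "truth")
  expect_true(truth$bimodal)
  qf <- apply_quality_filters(tab)
  modes <- density_mode_locations(qf$variants$vaf_percent)
  expect_length(modes, 2)
  # configured centers: 100*purity/2 * (1, 0.35) = (40, 14)
  expect_lt(abs(max(modes) - truth$clone_vaf_modes[1]), 5)
  expect_lt(abs(min(modes) - truth$clone_vaf_modes[2]), 5)
})

test_that("default calibration yields a cohort mean TMB at the 1% cutoff within 10-28 /Mb", {
  spec <- cohort_spec(n_patients = 15, seed = 19)
  tmbs <- vapply(1:15, function(i) {
    qf <- apply_quality_filters(generate_variant_table(spec, i))
    genomic_feature_sets(qf$variants)$tmb[1]
  }, numeric(1))
  expect_gte(mean(tmbs), 10)
  expect_lte(mean(tmbs), 28)
})

test_that("every default-spec patient keeps a somatic variant through all filters", {
  coh <- suppressWarnings(suppressMessages(
    simulate_cohort(cohort_spec(n_patients = 8, seed = 31), pet = FALSE)))
  expect_true(all(coh$features$n_somatic_m >= 1))
  expect_true(all(coh$features$n_somatic_c >= coh$features$n_somatic_m))
})

test_that("PET phantoms are deterministic and spacing matches the standard grid", {
  spec <- cohort_spec(n_patients = 2, seed = 5)
  p1 <- generate_pet_volume(spec, 1)
  p2 <- generate_pet_volume(spec, 1)
  expect_identical(p1$volume$values, p2$volume$values)
  expect_equal(p1$volume$spacing, c(2.7, 2.7, 2.79))
  expect_identical(p1$volume$grid_label, "standard")
  # VOI encloses the tumor with margin inside the grid
  expect_true(all(p1$voi$lo >= 1) && all(p1$voi$hi <= dim(p1$volume$values)))
})

test_that("zero texture amplitude gives a uniform tumor at the base SUV", {
  spec <- cohort_spec(n_patients = 2, seed = 5, texture_amplitude = 0)
  ph <- generate_pet_volume(spec, 1)
  vals <- ph$volume$values
  tumor_vals <- vals[vals != spec$background_suv]
  expect_gt(length(tumor_vals), 0)
  expect_equal(length(unique(tumor_vals)), 1L)
  expect_equal(unique(tumor_vals), ph$truth$base_suv)
})

test_that("oversized tumors are rejected", {
  spec <- cohort_spec(n_patients = 2, seed = 5,
                      tumor_radius_mm_range = c(90, 95), ellipticity = 0)
  expect_error(generate_pet_volume(spec, 1), "fit")
})

test_that("a 13-mm sphere segments to within 15% of its analytic volume", {
  vol <- make_phantom(semi_axes = c(13, 13, 13), tumor_suv = 8)
  seg <- segment_tumor(vol, full_voi(vol))
  mtv <- first_order_features(vol, seg)$mtv
  analytic <- 4 / 3 * pi * 1.3^3
  expect_lt(abs(mtv - analytic) / analytic, 0.15)
})

test_that("clinical generation honours censoring, null links and stage links", {
  feats <- data.frame(patient_id = sprintf("P%03d", 1:200),
                      entropy_std = rnorm(200, 4, 0.8))
  spec0 <- cohort_spec(n_patients = 200, seed = 9, censor_rate = 0)
  cl0 <- generate_clinical(feats, spec0)
  expect_true(all(cl0$os_event == 1L))

  spec_cens <- cohort_spec(n_patients = 200, seed = 9, censor_rate = 0.76)
  cl <- generate_clinical(feats, spec_cens)
  expect_gt(mean(cl$os_event == 0), 0.6)
  expect_lt(mean(cl$os_event == 0), 0.9)

  # a positive stage logit link on entropy raises entropy in stage IV
  spec_link <- cohort_spec(n_patients = 200, seed = 9,
                           stage_betas = c(entropy_std = 0.8))
  cl2 <- generate_clinical(feats, spec_link)
  tt <- t.test(feats$entropy_std[cl2$stage_group == "IV"],
               feats$entropy_std[cl2$stage_group == "I-III"],
               alternative = "greater")
  expect_lt(tt$p.value, 0.05)

  expect_error(generate_clinical(feats, cohort_spec(
    n_patients = 200, survival_betas = c(nonexistent = 1))), "unknown feature")
})

test_that("null survival links give hazard-ratio confidence intervals covering 1", {
  feats <- data.frame(patient_id = sprintf("P%03d", 1:80), f = rnorm(80))
  covered <- 0L
  n_rep <- 60
  for (r in 1:n_rep) {
    spec <- cohort_spec(n_patients = 80, seed = 1000 + r, censor_rate = 0.2)
    cl <- generate_clinical(feats, spec)
    res <- cox_univariate(cl$os_months, cl$os_event, feats$f)
    if (res$ci_low <= 1 && res$ci_high >= 1) covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.9)
})

test_that("one master seed reproduces the full cohort exactly", {
  c1 <- suppressWarnings(suppressMessages(
    simulate_cohort(cohort_spec(n_patients = 3, seed = 77), pet = TRUE)))
  c2 <- suppressWarnings(suppressMessages(
    simulate_cohort(cohort_spec(n_patients = 3, seed = 77), pet = TRUE)))
  expect_identical(c1$features, c2$features)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$patients[[2]]$pet$volume$values,
                   c2$patients[[2]]$pet$volume$values)
})
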