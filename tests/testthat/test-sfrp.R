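test_that("hidden seeds are stratified for even cohorts, weighted otherwise", {
  set.seed(1)
  s100 <- generate_hidden_seeds(100)
  expect_equal(as.integer(table(factor(s100, levels = 0:4))), rep(20L, 5))
  s5 <- generate_hidden_seeds(5)
  expect_setequal(s5, 0:4)
  expect_true(all(generate_hidden_seeds(1000, c(1, 0, 0, 0, 0)) == 0L))
  expect_error(generate_hidden_seeds(0), ">= 1")
  expect_error(generate_hidden_seeds(10, c(-1, 1, 1, 1, 1)), "non-negative")
  expect_error(generate_hidden_seeds(10, rep(0, 5)), "not all zero")
})

test_that("potassium follows the acid-base relation", {
  expect_equal(compute_potassium(7.35, 4.00), 4.00)
  expect_equal(compute_potassium(7.25, 4.00), 4.60)
  expect_equal(compute_potassium(7.45, 4.00), 3.40)  # alkalosis lowers K
  expect_error(compute_potassium(7.30, 5.60), "eukalemic")
  expect_error(compute_potassium(8.5, 4.0), "plausibility gate")
})

test_that("zero-noise panels realize their severity profile", {
  # seed 0: sampled analytes all normal; potassium equals baseline shifted
  # by the (unconditional) acid-base term, so it can dip mildly below the
  # eukalemic floor under alkalosis but never exceed it
  tab <- regime_table()
  set.seed(42)
  for (i in 1:50) {
    p <- sample_panel(0, noise = noise_off())
    expect_equal(classify_regime("glucose", p[["glucose"]]), "normal")
    expect_equal(classify_regime("lactate", p[["lactate"]]), "normal")
    expect_equal(classify_regime("ph", p[["ph"]]), "normal")
    expect_equal(classify_regime("po2", p[["po2"]]), "normal")
    expect_lte(p[["potassium"]], 5.50)
    expect_gte(p[["potassium"]], 2.90)
  }
  # seed 4: fully deranged panel, potassium raised above its baseline
  for (i in 1:50) {
    p <- sample_panel(4, noise = noise_off())
    expect_lt(p[["ph"]], 7.35)
    expect_gt(p[["lactate"]], 2.00)
    expect_true(classify_regime("glucose", p[["glucose"]]) != "normal")
    expect_lt(p[["po2"]], 100)
    expect_gt(p[["potassium"]], attr(p, "potassium_baseline"))
  }
})

test_that("panel sampling is deterministic given the RNG state", {
  set.seed(7); a <- sample_panel(3)
  set.seed(7); b <- sample_panel(3)
  expect_identical(a, b)
})

test_that("cohort generation is reproducible and exports byte-identical", {
  co1 <- generate_cohort(100, seed = 5)
  co2 <- generate_cohort(100, seed = 5)
  expect_identical(co1, co2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_sfrp_csv(co1, f1)
  write_sfrp_csv(co2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(co1$patient_id, 1:100)
  # every record passes validation
  feats <- as.matrix(co1[, -1])
  for (i in 1:100) {
    p <- structure(feats[i, ], names = c("glucose", "lactate", "ph",
                                         "potassium", "po2"))
    expect_identical(validate_panel(p), character(0))
  }
})

test_that("zero-noise cohorts match their hidden seed's regime pattern", {
  co <- generate_cohort(200, noise = noise_off(), seed = 9)
  seeds <- hidden_seeds(co)
  sets <- hisskit:::profile_regime_sets(default_severity_profile())
  cols <- c(glucose = "glucose_mg_dl", lactate = "lactate_mmol_l",
            ph = "ph", po2 = "po2_mmhg")
  for (a in names(cols)) {
    reg <- classify_regime(a, co[[cols[[a]]]])
    ok <- vapply(seq_len(nrow(co)), function(i) {
      reg[i] %in% sets[[seeds[i] + 1L]][[a]]
    }, logical(1))
    expect_true(all(ok), info = a)
  }
})

test_that("severity is monotone in hidden seed with noise off", {
  co <- generate_cohort(5000, noise = noise_off(), seed = 21)
  seeds <- hidden_seeds(co)
  lac <- tapply(co$lactate_mmol_l, seeds, mean)
  ph_dev <- tapply(abs(7.40 - co$ph), seeds, mean)
  expect_true(all(diff(lac) >= 0))
  expect_true(all(diff(ph_dev) >= 0))
})

test_that("potassium relation holds exactly on every generated record", {
  co <- generate_cohort(500, seed = 13)
  baseline <- co$potassium_mmol_l - 6 * (7.35 - co$ph)
  expect_true(all(baseline >= 3.50 - 1e-9 & baseline <= 5.50 + 1e-9))
  expect_equal(baseline, potassium_baselines(co), tolerance = 1e-12)
})

test_that("glucose drift rate converges to p_drift", {
  p <- 0.2
  n <- 10000
  co <- generate_cohort(n, noise = noise_config(p_drift = p, p_adrenergic = 0,
                                                p_ph_normal = 0,
                                                p_resp_comp = 0,
                                                po2_jitter = 0),
                        class_weights = c(1, 0, 0, 0, 0), seed = 31)
  # for level-0 seeds, a drifted glucose draw always leaves the normal band
  outside <- mean(classify_regime("glucose", co$glucose_mg_dl) != "normal")
  ci <- p + c(-1, 1) * 4 * sqrt(p * (1 - p) / n)
  expect_gt(outside, ci[1])
  expect_lt(outside, ci[2])
})

test_that("severity profile validation enforces its invariants", {
  expect_true(validate_severity_profile(default_severity_profile()))
  bad <- default_severity_profile()
  bad[["0"]]$glucose <- matrix(c(60, 99), 1)  # outside normal band
  expect_error(validate_severity_profile(bad), "normal band")
  bad2 <- default_severity_profile()
  bad2[["4"]]$lactate <- matrix(c(0.5, 1.0), 1)  # breaks monotonicity
  expect_error(validate_severity_profile(bad2), "non-decreasing")
})

test_that("severity profile JSON round-trips and shipped default matches", {
  path <- withr::local_tempfile(fileext = ".json")
  write_severity_profile(default_severity_profile(), path)
  rt <- read_severity_profile(path)
  expect_equal(unclass(rt), unclass(default_severity_profile()),
               tolerance = 1e-12)
  shipped <- system.file("extdata", "severity_profile.json",
                         package = "hisskit")
  expect_equal(unclass(read_severity_profile(shipped)),
               unclass(default_severity_profile()), tolerance = 1e-12)
})
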