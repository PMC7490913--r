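test_that("confusion matrix, accuracy and per-class TPR", {
  r <- confusion_and_accuracy(c(0, 1, 1, 0, 1), c(0, 1, 1, 0, 1), c = 2)
  expect_equal(r$accuracy, 1)
  expect_equal(unname(diag(r$confusion)), c(2L, 3L))
  r2 <- confusion_and_accuracy(c(0, 0, 1, 1, 1), c(0, 0, 0, 1, 1), c = 2)
  expect_equal(r2$accuracy, 0.8)
  expect_equal(unname(r2$confusion), matrix(c(2L, 1L, 0L, 2L), 2))
  # class absent from truth: TPR reported absent, not zero
  r3 <- confusion_and_accuracy(c(0, 1, 1), c(0, 1, 4), c = 5)
  expect_true(is.na(r3$tpr[["4"]]))
  expect_error(confusion_and_accuracy(0:1, 0L, 2), "length mismatch")
  # independent-oracle cross-check: accuracy == direct match fraction
  set.seed(12)
  for (i in 1:50) {
    yt <- sample(0:4, 30, replace = TRUE)
    yp <- sample(0:4, 30, replace = TRUE)
    expect_equal(confusion_and_accuracy(yt, yp)$accuracy, mean(yt == yp))
  }
})

test_that("baselines train, predict and respect their contracts", {
  # linearly separable two-class toy
  set.seed(20)
  x <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 6), 30))
  y <- rep(0:1, each = 30)
  for (k in c("svm_linear", "ebdt", "ann")) {
    m <- train_baseline(k, x, y, nclass = 2, seed = 1)
    expect_equal(mean(predict(m, x) == y), 1, info = k)
  }
  # softmax probabilities sum to one
  m_ann <- train_baseline("ann", x, y, nclass = 2, seed = 1)
  pr <- predict(m_ann, x, type = "prob")
  expect_equal(rowSums(pr), rep(1, nrow(x)), tolerance = 1e-9)
  # degenerate labels
  expect_error(train_baseline("ebdt", x, rep(1L, 60)), "single class")
  # seed determinism (fold assignment + hyper selection + fit)
  ds <- zero_noise_dataset(60, seed = 23)
  m1 <- train_baseline("ebdt", ds$x, ds$y, seed = 5)
  m2 <- train_baseline("ebdt", ds$x, ds$y, seed = 5)
  expect_identical(predict(m1, ds$x), predict(m2, ds$x))
  expect_identical(m1$hyper, m2$hyper)
})

test_that("k-fold cross-validation is stratified and reproducible", {
  ds <- zero_noise_dataset(100, seed = 24)
  perfect <- function(x, y) {
    structure(list(), class = "oracle_model")
  }
  # a "classifier" that replays the core rubric exactly
  registerS3method("predict", "oracle_model",
                   function(object, newdata, ...) {
                     apply(newdata, 1, function(r) {
                       core_policy_score(structure(r, names = c(
                         "glucose", "lactate", "ph", "potassium", "po2")))
                     })
                   }, envir = asNamespace("stats"))
  cv <- kfold_cv(perfect, ds$x, ds$y, k = 5, seed = 2)
  expect_equal(cv$fold_accuracies, rep(1, 5))
  expect_equal(cv$mean, 1)
  expect_equal(cv$sd, 0)
  cv1 <- kfold_cv(list(kind = "ebdt", hyper_grid = 10L), ds$x, ds$y,
                  k = 5, seed = 3)
  cv2 <- kfold_cv(list(kind = "ebdt", hyper_grid = 10L), ds$x, ds$y,
                  k = 5, seed = 3)
  expect_identical(cv1$fold_accuracies, cv2$fold_accuracies)
  expect_error(kfold_cv(perfect, ds$x, ds$y, k = 200), "exceeds")
})

test_that("learning curve spans the requested sizes", {
  ds <- zero_noise_dataset(100, seed = 25)
  lc <- learning_curve(list(kind = "ebdt", hyper_grid = 8L), ds$x, ds$y,
                       train_sizes = seq(30, 80, 5), repeats = 1,
                       test_size = 20, seed = 4)
  expect_equal(nrow(lc), 11)
  expect_equal(lc$size, seq(30, 80, 5))
  lc2 <- learning_curve(list(kind = "ebdt", hyper_grid = 8L), ds$x, ds$y,
                        train_sizes = seq(30, 80, 5), repeats = 1,
                        test_size = 20, seed = 4)
  expect_identical(lc$mean_test, lc2$mean_test)
  expect_error(learning_curve(list(kind = "ebdt"), ds$x, ds$y,
                              train_sizes = 95, test_size = 20), "exceeds")
  # stratified sampling represents every feasible class
  set.seed(6)
  y <- rep(0:4, each = 20)
  idx <- hisskit:::strat_sample(y, 30, stratified = TRUE)
  expect_setequal(unique(y[idx]), 0:4)
})

test_that("one-way ANOVA across classifiers behaves canonically", {
  same <- list(a = c(0.9, 0.9, 0.9), b = c(0.9, 0.9, 0.9))
  r <- compare_classifiers_anova(same)
  expect_equal(r$F, 0)
  expect_equal(r$p_value, 1)
  far <- list(a = c(0.10, 0.11, 0.10, 0.11), b = c(0.90, 0.91, 0.90, 0.91))
  expect_lt(compare_classifiers_anova(far)$p_value, 1e-6)
  g <- list(a = c(0.8, 0.85, 0.9), b = c(0.7, 0.75, 0.72),
            c = c(0.9, 0.95, 0.92))
  expect_equal(compare_classifiers_anova(g)$F,
               compare_classifiers_anova(rev(g))$F)
  # agreement with the standard implementation
  expect_equal(compare_classifiers_anova(g)$p_value,
               stats::oneway.test(v ~ grp, data.frame(
                 v = unlist(g), grp = rep(names(g), lengths(g))),
                 var.equal = TRUE)$p.value)
  expect_error(compare_classifiers_anova(list(a = 1:3)), "two groups")
  expect_error(compare_classifiers_anova(list(a = 1:3, b = 1)), "at least two values")
})

test_that("sizing surface fits quadratics exactly and predicts requirements", {
  grid <- expand.grid(n_patients = seq(40, 160, 20), n_experts = 3:9)
  # exact quadratic (kept inside (0,1) so clamping is inactive)
  grid$accuracy <- 0.5 + 0.002 * grid$n_patients + 0.01 * grid$n_experts -
    4e-6 * grid$n_patients^2 - 3e-4 * grid$n_experts^2 +
    1e-5 * grid$n_patients * grid$n_experts
  sm <- fit_sizing_model(grid)
  expect_equal(sm$r_squared, 1, tolerance = 1e-9)
  # permuting rows leaves the fit unchanged
  sm_p <- fit_sizing_model(grid[sample(nrow(grid)), ])
  expect_equal(sm_p$coefficients, sm$coefficients, tolerance = 1e-9)
  # constant surface: zero slope coefficients
  flat <- grid
  flat$accuracy <- 0.9
  sm_f <- fit_sizing_model(flat)
  expect_equal(unname(sm_f$coefficients[-1]), rep(0, 5), tolerance = 1e-9)
  expect_equal(sm_f$ss_total, 0)
  # degenerate designs
  expect_error(fit_sizing_model(grid[1:4, ]), "at least 6")
  one_axis <- grid[grid$n_experts == 5, ]
  expect_error(fit_sizing_model(one_axis), "span both axes")
})

test_that("predict_requirements walks experts then patients and is monotone", {
  grid <- expand.grid(n_patients = seq(40, 200, 20), n_experts = 2:12)
  grid$accuracy <- 0.80 + 0.0009 * grid$n_patients + 0.008 * grid$n_experts
  sm <- fit_sizing_model(grid)
  lo <- predict_requirements(sm, 0.85, patients_range = c(10, 400),
                             experts_range = c(2, 25))
  hi <- predict_requirements(sm, 0.95, patients_range = c(10, 400),
                             experts_range = c(2, 25))
  expect_true(all(hi >= lo))
  # a target below the minimum of the surface: the scan's first pair
  tiny <- predict_requirements(sm, 0.82, patients_range = c(10, 400),
                               experts_range = c(2, 25))
  expect_equal(unname(tiny), c(10, 2))
  expect_error(predict_requirements(sm, 0.9999, patients_range = c(10, 50),
                                    experts_range = c(2, 3)), "unreachable")
  expect_error(predict_requirements(sm, 1.2), "target_accuracy")
})

test_that("the sizing grid simulator produces usable accuracy cells", {
  # small cohorts can leave rare classes with fewer members than folds;
  # the fold builder warns and falls back to plain random folds
  grid <- suppressWarnings(
    simulate_sizing_grid(n_patients_grid = c(40, 60),
                         n_experts_grid = c(3, 5),
                         estimator = list(kind = "ebdt", hyper_grid = 8L),
                         k = 4, seed = 77))
  expect_equal(nrow(grid), 4)
  expect_true(all(grid$accuracy > 0 & grid$accuracy <= 1))
  com7 <- make_committee(7, seed = 1)
  expect_length(com7, 7)
  expect_equal(com7[[7]]$id, "D7")
})
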