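test_that("config validation rejects out-of-range hyperparameters", {
  expect_error(prbf_config(population_size = 0), "population_size")
  expect_error(prbf_config(learning_rate = 0), "learning_rate")
  expect_error(prbf_config(learning_rate = 1.5), "learning_rate")
  expect_error(prbf_config(stretch = -1), "stretch")
  expect_error(prbf_config(iterations = 0), "iterations")
})

test_that("covering creates a rule that matches and predicts its instance", {
  set.seed(4)
  x <- c(0.3, -1.2)
  u <- c(0.2, 1, 0, 0, 0)
  r <- cover(x, u, prbf_config(stretch = 25), ranges = c(4, 4))
  expect_true(all(abs(x - r$center) <= r$halfwidth))
  expect_true(all(r$halfwidth <= 25 / 100 * 4 + 1e-12))
  # consequent at the center immediately predicts u
  expect_equal(as.numeric(r$coef[1, ]), u)
  expect_equal(r$experience, 0L)
  set.seed(4); r2 <- cover(x, u, prbf_config(stretch = 25), ranges = c(4, 4))
  expect_identical(r$halfwidth, r2$halfwidth)
})

test_that("match_set uses closed-interval containment", {
  pop <- list(center = rbind(c(0, 0), c(3, 3)),
              halfwidth = rbind(c(1, 1), c(0.5, 0.5)),
              coef = array(0, c(2, 3, 5)), err = c(0.1, 0.1),
              experience = c(5L, 5L), birth = c(1L, 2L))
  # exactly on the first rule's closed boundary: included
  expect_equal(hisskit:::prbf_match_idx(pop, c(1, 1)), 1L)
  expect_equal(hisskit:::prbf_match_idx(pop, c(0, 0)), 1L)
  # inside the second only
  expect_equal(hisskit:::prbf_match_idx(pop, c(3.2, 2.8)), 2L)
  # disjoint from all conditions
  expect_length(hisskit:::prbf_match_idx(pop, c(10, 10)), 0)
  # and through the public interface of a trained model
  x <- matrix(c(0, 0, 1, 1, 5, 5), 3, 2, byrow = TRUE)
  m <- train_prbf(x, diag(3), prbf_config(population_size = 20,
                                          iterations = 50, stretch = 20,
                                          rng_seed = 1))
  expect_gte(length(match_set(m, x[1, ])), 1)
})

test_that("a single-point fit converges to its one-hot label", {
  x <- matrix(c(90, 1.0, 7.40, 4.2, 110), 1)
  u <- matrix(c(0, 0, 1, 0, 0), 1)
  m <- train_prbf(x, u, prbf_config(population_size = 10, iterations = 1000,
                                    rng_seed = 2))
  pi <- predict_possibility(m, x[1, ])
  expect_equal(crispify(pi), 2L)
  expect_gt(pi[3], 0.9)
})

test_that("training is deterministic given a seed, and models round-trip", {
  ds <- zero_noise_dataset(30, seed = 15)
  u <- diag(5)[ds$y + 1, ]
  cfg <- prbf_config(population_size = 80, iterations = 1500, rng_seed = 7)
  m1 <- train_prbf(ds$x, u, cfg)
  m2 <- train_prbf(ds$x, u, cfg)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_prbf(m1, f1); write_prbf(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # deserialized model predicts identically
  mr <- read_prbf(f1)
  expect_equal(predict(mr, ds$x), predict(m1, ds$x))
  expect_equal(predict(m1, ds$x, type = "possibility"),
               predict(mr, ds$x, type = "possibility"), tolerance = 1e-12)
})

test_that("inference fuses matching rules and defaults to ignorance", {
  ds <- zero_noise_dataset(30, seed = 16)
  u <- diag(5)[ds$y + 1, ]
  m <- train_prbf(ds$x, u, prbf_config(population_size = 100,
                                       iterations = 2000, rng_seed = 3))
  # possibility bounded in [0,1] on arbitrary inputs
  for (i in seq_len(nrow(ds$x))) {
    pi <- predict_possibility(m, ds$x[i, ])
    expect_true(all(pi >= 0 & pi <= 1))
    expect_length(pi, 5)
  }
  # empty match set: total ignorance, crispified to the severe end
  far <- c(1e5, 1e5, 1e5, 1e5, 1e5)
  expect_equal(predict_possibility(m, far), rep(1, 5))
  expect_equal(crispify(predict_possibility(m, far)), 4L)
  # single-source fusion is the identity on the rule's prediction
  single <- m
  single$pop <- hisskit:::prbf_delete_idx(m$pop, 1L)
  xs <- single$pop$center[1, ] * single$scale + single$center
  pred <- hisskit:::prbf_rule_predict(single$pop, 1L, single$pop$center[1, ])
  expect_equal(predict_possibility(single, xs), as.numeric(pred),
               tolerance = 1e-9)
})

test_that("crispification takes the highest possibility, severe on ties", {
  expect_equal(crispify(c(0.979, 0.321, 0, 0, 0)), 0L)
  expect_equal(crispify(rep(1, 5)), 4L)
  expect_equal(crispify(c(0, 0, 1, 0, 0)), 2L)
  expect_equal(crispify(c(0.5, 0.9, 0.9, 0.2, 0.1)), 2L)
})

test_that("training MAE does not increase across 10-window medians", {
  ds <- zero_noise_dataset(60, seed = 17)
  u <- diag(5)[ds$y + 1, ]
  m <- train_prbf(ds$x, u, prbf_config(population_size = 150,
                                       iterations = 8000, rng_seed = 5))
  tr <- m$mae_trace
  expect_gte(length(tr), 20)
  expect_lte(stats::median(utils::tail(tr, 10)),
             stats::median(utils::head(tr, 10)))
})

test_that("PRBF approaches the exhaustive interval-grid oracle", {
  # tiny 1-feature, 2-class possibility regression: overlapping ramps
  x1 <- seq(0, 1, length.out = 40)
  u <- cbind(pmin(pmax(1.2 - 2 * x1, 0), 1), pmin(pmax(2 * x1 - 0.2, 0), 1))
  oracle <- grid_interval_oracle_mae(x1, u, grid_n = 25)
  m <- train_prbf(matrix(x1), u, prbf_config(population_size = 200,
                                             iterations = 15000,
                                             stretch = 25, rng_seed = 9))
  pred <- predict(m, matrix(x1), type = "possibility")
  prbf_mae <- mean(abs(pred - u))
  expect_lte(prbf_mae, oracle + 0.05)
})

test_that("PRBF learns the noiseless severity mapping at n = 100", {
  ds <- zero_noise_dataset(100, seed = 18)
  sm <- score_cohort(ds$cohort, noiseless_committee(), seed = 19)
  y <- apply(sm$scores, 1, majority_vote)
  u <- t(apply(sm$scores, 1, possibility_labels))
  m <- train_prbf(ds$x, u, prbf_config(population_size = 400,
                                       iterations = 20000, rng_seed = 10))
  acc <- mean(predict(m, ds$x) == y)
  expect_gte(acc, 0.95)
})
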