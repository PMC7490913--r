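# Possibility rule-based classifier using function approximation: an
# XCSF-style learning classifier system. A population of overlapping
# interval-condition rules is evolved online; each rule carries a local
# linear model per class predicting the class possibility, updated by a
# normalized delta rule; inference fuses matching rules' clamped outputs by
# fitness-weighted averaging (possibilistic information fusion), and an
# empty match set returns total ignorance (all-ones).

#' PRBF training configuration
#'
#' @param population_size maximum rule count (default 4000).
#' @param stretch maximum condition half-width, as a percentage of each
#'   standardized feature's observed range; covering draws half-widths
#'   uniformly on `(0, stretch/100 * range]` (default 25).
#' @param learning_rate delta-rule step for consequent updates, in (0, 1\]
#'   (default 0.1).
#' @param iterations number of online training steps (default 100000; tests
#'   and examples use far fewer).
#' @param ga_period run the evolutionary step every this many iterations.
#' @param deletion_experience updates a rule must have received before it can
#'   be deleted on fitness grounds.
#' @param fusion `"weighted_mean"` (default; combines all matching sources)
#'   or `"max"` (component-wise maximum of rule outputs).
#' @param rng_seed optional integer seed making training deterministic.
#' @return a list of class `prbf_config`.
#' @export
prbf_config <- function(population_size = 4000, stretch = 25,
                        learning_rate = 0.1, iterations = 100000,
                        ga_period = 50, deletion_experience = 20,
                        fusion = c("weighted_mean", "max"),
                        rng_seed = NULL) {
  fusion <- match.arg(fusion)
  if (population_size < 1) stopf("population_size must be >= 1")
  if (stretch <= 0) stopf("stretch must be > 0")
  if (learning_rate <= 0 || learning_rate > 1) {
    stopf("learning_rate must lie in (0, 1]")
  }
  if (iterations < 1) stopf("iterations must be >= 1")
  structure(list(population_size = as.integer(population_size),
                 stretch = stretch, learning_rate = learning_rate,
                 iterations = as.integer(iterations),
                 ga_period = as.integer(ga_period),
                 deletion_experience = as.integer(deletion_experience),
                 fusion = fusion, rng_seed = rng_seed),
            class = "prbf_config")
}

# Fitness is a decreasing function of a rule's running mean absolute error.
PRBF_EPS0 <- 0.05
prbf_fitness_of <- function(err) 1 / (1 + err / PRBF_EPS0)

#' Create a covering rule
#'
#' When no rule in the population matches a training instance, a new rule is
#' created centered on it: half-widths are drawn uniformly up to the stretch
#' bound, consequent intercepts start at the instance's possibility label and
#' slopes at zero, so the rule immediately predicts `u` at `x`.
#'
#' @param x standardized feature vector.
#' @param u possibility label (length-c vector in \[0, 1\]).
#' @param config a [prbf_config()].
#' @param ranges per-feature observed ranges on the standardized scale
#'   (defaults to 4, about the range of a standardized feature).
#' @return a list describing one rule: `center`, `halfwidth`, `coef`
#'   (`(d+1) x c` matrix, first row intercepts), `err`, `fitness`,
#'   `experience`. Uses the current RNG stream.
#' @export
cover <- function(x, u, config = prbf_config(), ranges = rep(4, length(x))) {
  d <- length(x)
  hmax <- config$stretch / 100 * ranges
  hw <- stats::runif(d, 0, 1) * hmax
  hw <- pmax(hw, 0.02 * ranges)  # floor: a rule must have nonzero volume
  coef <- rbind(u, matrix(0, d, length(u)))
  rownames(coef) <- NULL
  list(center = as.numeric(x), halfwidth = hw, coef = coef,
       err = PRBF_EPS0, fitness = prbf_fitness_of(PRBF_EPS0), experience = 0L)
}

# Internal population representation: parallel matrices for speed.
prbf_empty_pop <- function(d, c, cap) {
  list(center = matrix(NA_real_, 0, d), halfwidth = matrix(NA_real_, 0, d),
       coef = array(NA_real_, c(0, d + 1, c)),
       err = numeric(0), experience = integer(0), birth = integer(0))
}

prbf_insert <- function(pop, rule, t) {
  pop$center <- rbind(pop$center, rule$center)
  pop$halfwidth <- rbind(pop$halfwidth, rule$halfwidth)
  nc <- dim(pop$coef)
  coef <- array(NA_real_, c(nc[1] + 1, nc[2], nc[3]))
  if (nc[1] > 0) coef[seq_len(nc[1]), , ] <- pop$coef
  coef[nc[1] + 1, , ] <- rule$coef
  pop$coef <- coef
  pop$err <- c(pop$err, rule$err)
  pop$experience <- c(pop$experience, rule$experience)
  pop$birth <- c(pop$birth, t)
  pop
}

prbf_delete_idx <- function(pop, keep) {
  pop$center <- pop$center[keep, , drop = FALSE]
  pop$halfwidth <- pop$halfwidth[keep, , drop = FALSE]
  pop$coef <- pop$coef[keep, , , drop = FALSE]
  pop$err <- pop$err[keep]
  pop$experience <- pop$experience[keep]
  pop$birth <- pop$birth[keep]
  pop
}

prbf_match_idx <- function(pop, x) {
  P <- nrow(pop$center)
  if (P == 0) return(integer(0))
  diff <- abs(pop$center - matrix(x, P, length(x), byrow = TRUE))
  which(rowSums(diff > pop$halfwidth) == 0L)
}

# Per-rule linear predictions at x for rules `m` (|m| x c), optionally clamped.
prbf_rule_predict <- function(pop, m, x, clamp01 = TRUE) {
  d <- ncol(pop$center)
  cc <- dim(pop$coef)[3]
  diff <- pop$center[m, , drop = FALSE]
  diff <- matrix(x, nrow(diff), d, byrow = TRUE) - diff
  X <- cbind(1, diff)
  out <- matrix(0, length(m), cc)
  for (k in seq_len(cc)) {
    out[, k] <- rowSums(X * pop$coef[m, , k, drop = FALSE][, , 1])
  }
  if (clamp01) out <- clamp(out, 0, 1)
  out
}

#' Train a possibility rule-based classifier
#'
#' Online training: at each step a training instance is drawn at random; the
#' set of rules whose interval conditions cover it is formed (a covering
#' rule is created if the set is empty); each matching rule's per-class
#' linear consequent is moved toward the instance's possibility label by a
#' normalized delta rule, its running approximation error and fitness
#' updated; periodically two high-fitness matching rules are crossed over
#' and mutated into a new rule; and when the population exceeds its cap the
#' lowest-fitness experienced rules are deleted.
#'
#' @param x numeric matrix (n x d) of biomarker panels (raw units;
#'   features are standardized internally and the scaling stored in the
#'   model).
#' @param u numeric matrix (n x c) of possibility labels in \[0, 1\].
#' @param config a [prbf_config()].
#' @return an object of class `prbf_model`: the rule population, feature
#'   scaling, fusion mode, and a windowed trace of training MAE.
#' @export
train_prbf <- function(x, u, config = prbf_config()) {
  x <- as.matrix(x)
  u <- as.matrix(u)
  if (nrow(x) != nrow(u)) stopf("x and u must have the same number of rows")
  if (nrow(x) < 1) stopf("need at least one training instance")
  if (any(u < 0 | u > 1)) stopf("possibility labels must lie in [0, 1]")
  n <- nrow(x)
  d <- ncol(x)
  cc <- ncol(u)

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  ranges <- apply(xs, 2, function(v) max(diff(range(v)), 1e-6))

  with_seed(config$rng_seed, {
    pop <- prbf_empty_pop(d, cc, config$population_size)
    beta <- 0.2
    lr <- config$learning_rate
    trace_every <- max(100L, config$iterations %/% 200L)
    mae_acc <- 0
    mae_n <- 0L
    mae_trace <- numeric(0)

    for (t in seq_len(config$iterations)) {
      i <- sample.int(n, 1L)
      xi <- xs[i, ]
      ui <- u[i, ]
      m <- prbf_match_idx(pop, xi)
      if (length(m) == 0L) {
        pop <- prbf_insert(pop, cover(xi, ui, config, ranges), t)
        m <- nrow(pop$center)
      }

      # fused prediction error before update (training MAE trace)
      predc <- prbf_rule_predict(pop, m, xi, clamp01 = TRUE)
      w <- prbf_fitness_of(pop$err[m])
      fused <- colSums(predc * w) / sum(w)
      mae_acc <- mae_acc + mean(abs(fused - ui))
      mae_n <- mae_n + 1L
      if (t %% trace_every == 0L) {
        mae_trace <- c(mae_trace, mae_acc / mae_n)
        mae_acc <- 0
        mae_n <- 0L
      }

      # normalized delta-rule update of matching consequents
      diff <- sweep(pop$center[m, , drop = FALSE], 2, xi, function(a, b) b - a)
      X <- cbind(1, diff)
      denom <- rowSums(X * X)
      inst_err <- numeric(length(m))
      for (k in seq_len(cc)) {
        raw <- rowSums(X * pop$coef[m, , k, drop = FALSE][, , 1])
        ek <- ui[k] - raw
        inst_err <- inst_err + abs(ui[k] - clamp(raw, 0, 1))
        upd <- (lr * ek / denom) * X
        pop$coef[m, , k] <- pop$coef[m, , k, drop = FALSE][, , 1] + upd
      }
      inst_err <- inst_err / cc
      exp_m <- pop$experience[m] + 1L
      pop$experience[m] <- exp_m
      # MAM-style error tracking: average until 1/beta updates, then EWMA
      mam <- pmax(1 / exp_m, beta)
      pop$err[m] <- pop$err[m] + mam * (inst_err - pop$err[m])

      # evolutionary step on the match set
      if (config$ga_period > 0 && t %% config$ga_period == 0L &&
          length(m) >= 2L) {
        fit_m <- prbf_fitness_of(pop$err[m])
        parents <- sample(m, 2L, prob = fit_m / sum(fit_m))
        child <- prbf_crossover_mutate(pop, parents, ranges, config)
        pop <- prbf_insert(pop, child, t)
      }

      if (nrow(pop$center) > config$population_size) {
        pop <- prbf_enforce_cap(pop, config)
      }
    }
    if (mae_n > 0L) mae_trace <- c(mae_trace, mae_acc / mae_n)

    structure(list(pop = pop, center = ctr, scale = scl, ranges = ranges,
                   classes = seq_len(cc) - 1L, fusion = config$fusion,
                   config = config, mae_trace = mae_trace),
              class = "prbf_model")
  })
}

prbf_crossover_mutate <- function(pop, parents, ranges, config) {
  d <- ncol(pop$center)
  cc <- dim(pop$coef)[3]
  pick <- stats::runif(d) < 0.5
  center <- ifelse(pick, pop$center[parents[1], ], pop$center[parents[2], ])
  hw <- ifelse(pick, pop$halfwidth[parents[1], ], pop$halfwidth[parents[2], ])
  coef <- (pop$coef[parents[1], , , drop = FALSE][, , , drop = TRUE] +
           pop$coef[parents[2], , , drop = FALSE][, , , drop = TRUE]) / 2
  dim(coef) <- c(d + 1, cc)
  mut <- stats::runif(d) < 0.1
  center[mut] <- center[mut] + stats::rnorm(sum(mut), 0, 0.1 * ranges[mut])
  hw <- hw * exp(stats::rnorm(d, 0, 0.1))
  hw <- clamp(hw, 0.02 * ranges, config$stretch / 100 * ranges)
  err <- mean(pop$err[parents])
  list(center = center, halfwidth = hw, coef = coef, err = err,
       fitness = prbf_fitness_of(err),
       experience = 0L)
}

prbf_enforce_cap <- function(pop, config) {
  excess <- nrow(pop$center) - config$population_size
  if (excess <= 0) return(pop)
  fit <- prbf_fitness_of(pop$err)
  mature <- which(pop$experience >= config$deletion_experience)
  drop <- integer(0)
  if (length(mature) >= excess) {
    drop <- mature[order(fit[mature])][seq_len(excess)]
  } else {
    drop <- order(fit)[seq_len(excess)]
  }
  keep <- setdiff(seq_len(nrow(pop$center)), drop)
  prbf_delete_idx(pop, keep)
}

#' Rules matching an input
#'
#' Exact closed-interval containment: rule j matches x when
#' `|x - center_j| <= halfwidth_j` in every dimension.
#'
#' @param model a `prbf_model`.
#' @param x a raw feature vector (standardized internally).
#' @return integer indices of matching rules (possibly empty).
#' @export
match_set <- function(model, x) {
  xs <- (as.numeric(x) - model$center) / model$scale
  prbf_match_idx(model$pop, xs)
}

#' Predict a possibility distribution
#'
#' Per class, the fitness-weighted average (or component-wise maximum, per
#' the model's fusion mode) of the matching rules' clamped consequent
#' outputs. An empty match set means the model knows nothing about this
#' region and returns total possibilistic ignorance: all ones.
#'
#' @param model a `prbf_model`.
#' @param x raw feature vector, or matrix of rows.
#' @return possibility vector (or matrix) with components in \[0, 1\].
#' @export
predict_possibility <- function(model, x) {
  if (is.matrix(x) || is.data.frame(x)) {
    return(t(apply(as.matrix(x), 1L, function(r) predict_possibility(model, r))))
  }
  cc <- dim(model$pop$coef)[3]
  xs <- (as.numeric(x) - model$center) / model$scale
  m <- prbf_match_idx(model$pop, xs)
  if (length(m) == 0L) return(rep(1, cc))
  pred <- prbf_rule_predict(model$pop, m, xs, clamp01 = TRUE)
  if (model$fusion == "max") {
    apply(pred, 2L, max)
  } else {
    w <- prbf_fitness_of(model$pop$err[m])
    as.numeric(colSums(pred * w) / sum(w))
  }
}

#' Collapse a possibility distribution to a crisp severity class
#'
#' Argmax of the possibility vector; ties break toward the higher (more
#' severe) class, so total ignorance crispifies to SEVERE.
#'
#' @param pi possibility vector over classes 0..c-1.
#' @return integer class.
#' @export
#' @examples
#' crispify(c(0.979, 0.321, 0, 0, 0))  # 0
crispify <- function(pi) {
  if (any(!is.finite(pi))) stopf("possibility vector must be finite")
  max(which(pi == max(pi))) - 1L
}

#' @export
predict.prbf_model <- function(object, newdata, type = c("class", "possibility"),
                               ...) {
  type <- match.arg(type)
  pi <- predict_possibility(object, newdata)
  if (type == "possibility") return(pi)
  if (is.matrix(pi)) apply(pi, 1L, crispify) else crispify(pi)
}

#' Serialize / deserialize a PRBF model as JSON
#'
#' The document stores the feature scaling, fusion mode, configuration and
#' the full rule list (condition intervals, consequent coefficients, running
#' error, experience), so a written model round-trips exactly.
#'
#' @param model a `prbf_model`.
#' @param path file path.
#' @return for `read_prbf`, the restored `prbf_model`.
#' @export
write_prbf <- function(model, path) {
  pop <- model$pop
  doc <- list(
    center = model$center, scale = model$scale, ranges = model$ranges,
    classes = model$classes, fusion = model$fusion,
    config = unclass(model$config), mae_trace = model$mae_trace,
    rules = list(center = pop$center, halfwidth = pop$halfwidth,
                 coef = as.numeric(pop$coef), coef_dim = dim(pop$coef),
                 err = pop$err, experience = pop$experience,
                 birth = pop$birth)
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_prbf
#' @export
read_prbf <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  r <- doc$rules
  coef <- array(r$coef, dim = r$coef_dim)
  pop <- list(center = matrix(r$center, nrow = r$coef_dim[1]),
              halfwidth = matrix(r$halfwidth, nrow = r$coef_dim[1]),
              coef = coef, err = r$err,
              experience = as.integer(r$experience),
              birth = as.integer(r$birth))
  cfg <- doc$config
  config <- prbf_config(cfg$population_size, cfg$stretch, cfg$learning_rate,
                        cfg$iterations, cfg$ga_period,
                        cfg$deletion_experience, cfg$fusion,
                        cfg$rng_seed)
  structure(list(pop = pop, center = doc$center, scale = doc$scale,
                 ranges = doc$ranges, classes = as.integer(doc$classes),
                 fusion = doc$fusion, config = config,
                 mae_trace = doc$mae_trace),
            class = "prbf_model")
}
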