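# Baseline classifiers and the evaluation harness: confusion/accuracy,
# stratified k-fold CV, learning curves, one-way ANOVA comparison, and the
# (n_patients x n_experts) -> accuracy sizing surface.
#
# The classifiers are self-contained implementations (no tree/SVM/net
# package is available in the target environment): a CART with
# cross-entropy splits plus bagging, a one-vs-one batch-subgradient linear
# SVM, and a single-hidden-layer softmax network fitted by BFGS with L2
# regularization.

## ---- decision tree + bagging -------------------------------------------

tree_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# Recursive CART on continuous features; split criterion = weighted
# cross-entropy of the children.
grow_tree <- function(x, y, nclass, depth = 0L, max_depth = 10L,
                      min_split = 4L) {
  counts <- tabulate(y + 1L, nbins = nclass)
  node <- list(counts = counts)
  if (depth >= max_depth || length(y) < min_split || tree_entropy(counts) == 0) {
    return(node)
  }
  n <- length(y)
  best <- list(gain = 1e-12)
  parent_h <- tree_entropy(counts)
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    ord <- order(xj)
    xs <- xj[ord]
    ys <- y[ord]
    cut_at <- which(diff(xs) > 0)
    if (!length(cut_at)) next
    left <- matrix(0L, length(cut_at), nclass)
    run <- integer(nclass)
    ci <- 1L
    for (i in seq_len(n - 1L)) {
      run[ys[i] + 1L] <- run[ys[i] + 1L] + 1L
      if (ci <= length(cut_at) && i == cut_at[ci]) {
        left[ci, ] <- run
        ci <- ci + 1L
      }
    }
    for (ci in seq_along(cut_at)) {
      nl <- sum(left[ci, ])
      nr <- n - nl
      h <- (nl * tree_entropy(left[ci, ]) +
            nr * tree_entropy(counts - left[ci, ])) / n
      gain <- parent_h - h
      if (gain > best$gain) {
        i <- cut_at[ci]
        best <- list(gain = gain, var = j,
                     threshold = (xs[i] + xs[i + 1L]) / 2)
      }
    }
  }
  if (is.null(best$var)) return(node)
  go_left <- x[, best$var] <= best$threshold
  node$var <- best$var
  node$threshold <- best$threshold
  node$left <- grow_tree(x[go_left, , drop = FALSE], y[go_left], nclass,
                         depth + 1L, max_depth, min_split)
  node$right <- grow_tree(x[!go_left, , drop = FALSE], y[!go_left], nclass,
                          depth + 1L, max_depth, min_split)
  node
}

tree_predict_row <- function(node, r) {
  while (!is.null(node$var)) {
    node <- if (r[node$var] <= node$threshold) node$left else node$right
  }
  node$counts / sum(node$counts)
}

fit_ebdt <- function(x, y, nclass, n_estimators = 12L) {
  n <- nrow(x)
  trees <- lapply(seq_len(n_estimators), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    grow_tree(x[idx, , drop = FALSE], y[idx], nclass)
  })
  list(trees = trees, nclass = nclass)
}

predict_ebdt <- function(fit, x) {
  apply(x, 1L, function(r) {
    probs <- Reduce(`+`, lapply(fit$trees, tree_predict_row, r = r))
    max(which(probs == max(probs))) - 1L
  })
}

## ---- linear SVM (one-vs-one, batch subgradient) ------------------------

# Deterministic full-batch subgradient descent on the regularized hinge
# objective lambda/2 ||w||^2 + mean(hinge).
svm_binary <- function(x, y01, lambda = 0.01, epochs = 300L) {
  d <- ncol(x)
  w <- numeric(d)
  b <- 0
  yy <- ifelse(y01 == 1L, 1, -1)
  n <- nrow(x)
  for (t in seq_len(epochs)) {
    eta <- 1 / (lambda * (t + 10))
    margins <- yy * (x %*% w + b)
    viol <- margins < 1
    gw <- lambda * w - colSums(x[viol, , drop = FALSE] * yy[viol]) / n
    gb <- -sum(yy[viol]) / n
    w <- w - eta * gw
    b <- b - eta * gb
  }
  list(w = w, b = b)
}

fit_svm_linear <- function(x, y, nclass, lambda = 0.01) {
  classes <- sort(unique(y))
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  machines <- lapply(pairs, function(p) {
    sel <- y %in% p
    svm_binary(x[sel, , drop = FALSE], as.integer(y[sel] == p[2]), lambda)
  })
  list(pairs = pairs, machines = machines, nclass = nclass)
}

predict_svm_linear <- function(fit, x) {
  votes <- matrix(0L, nrow(x), fit$nclass)
  for (i in seq_along(fit$pairs)) {
    p <- fit$pairs[[i]]
    m <- fit$machines[[i]]
    s <- as.numeric(x %*% m$w + m$b)
    winner <- ifelse(s >= 0, p[2], p[1])
    for (r in seq_len(nrow(x))) {
      votes[r, winner[r] + 1L] <- votes[r, winner[r] + 1L] + 1L
    }
  }
  apply(votes, 1L, function(v) max(which(v == max(v))) - 1L)
}

## ---- single-hidden-layer softmax network -------------------------------

ann_unpack <- function(par, d, h, c) {
  i <- 0
  W1 <- matrix(par[i + seq_len(d * h)], d, h); i <- i + d * h
  b1 <- par[i + seq_len(h)]; i <- i + h
  W2 <- matrix(par[i + seq_len(h * c)], h, c); i <- i + h * c
  b2 <- par[i + seq_len(c)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

ann_forward <- function(p, x) {
  hid <- tanh(sweep(x %*% p$W1, 2, p$b1, `+`))
  z <- sweep(hid %*% p$W2, 2, p$b2, `+`)
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  list(hidden = hid, probs = ez / rowSums(ez))
}

fit_ann <- function(x, y, nclass, size = 8L, decay = 1e-2, maxit = 300L) {
  d <- ncol(x)
  n <- nrow(x)
  Y <- matrix(0, n, nclass)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  npar <- d * size + size + size * nclass + nclass
  init <- stats::runif(npar, -0.5, 0.5)
  obj <- function(par) {
    p <- ann_unpack(par, d, size, nclass)
    probs <- ann_forward(p, x)$probs
    -sum(Y * log(probs + 1e-12)) / n + decay * sum(par^2)
  }
  grad <- function(par) {
    p <- ann_unpack(par, d, size, nclass)
    fw <- ann_forward(p, x)
    delta2 <- (fw$probs - Y) / n
    gW2 <- t(fw$hidden) %*% delta2
    gb2 <- colSums(delta2)
    back <- delta2 %*% t(p$W2) * (1 - fw$hidden^2)
    gW1 <- t(x) %*% back
    gb1 <- colSums(back)
    c(as.numeric(gW1), gb1, as.numeric(gW2), gb2) + 2 * decay * par
  }
  opt <- stats::optim(init, obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  list(par = opt$par, d = d, size = size, nclass = nclass)
}

predict_ann <- function(fit, x, type = "class") {
  p <- ann_unpack(fit$par, fit$d, fit$size, fit$nclass)
  probs <- ann_forward(p, x)$probs
  if (type == "prob") return(probs)
  apply(probs, 1L, function(v) max(which(v == max(v))) - 1L)
}

## ---- unified baseline interface ----------------------------------------

#' Train a baseline HISS classifier
#'
#' Three standard classifiers used as benchmarks: `"svm_linear"` (one-vs-one
#' linear maximum-margin classifier), `"ebdt"` (bagged decision trees with
#' cross-entropy split criterion; ensemble size chosen from 6--20 in steps
#' of 2), and `"ann"` (one-hidden-layer feed-forward network with softmax
#' output and an L2-regularized cross-entropy objective). The best
#' hyper-grid member is selected by internal cross-validated accuracy.
#'
#' @param kind one of `"svm_linear"`, `"ebdt"`, `"ann"`.
#' @param x numeric feature matrix (n x d), raw units (standardized
#'   internally for SVM and ANN).
#' @param y integer class labels in 0..c-1; at least two classes must be
#'   present.
#' @param hyper_grid optional list of hyperparameter candidates; defaults
#'   per kind (`lambda` for the SVM, `n_estimators` for bagging,
#'   `size`/`decay` for the network).
#' @param nclass number of classes (default 5).
#' @param seed RNG seed controlling fold assignment, bootstrap resampling
#'   and network initialization.
#' @param select_folds folds for internal hyperparameter selection.
#' @return an object of class `hiss_baseline` with a [predict][predict.hiss_baseline] method.
#' @export
train_baseline <- function(kind = c("svm_linear", "ebdt", "ann"), x, y,
                           hyper_grid = NULL, nclass = 5L, seed = NULL,
                           select_folds = 3L) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stopf("labels contain a single class")
  if (nrow(x) != length(y)) stopf("x and y sizes differ")

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  grids <- switch(kind,
    svm_linear = lapply(hyper_grid %||% c(0.001, 0.01, 0.1),
                        function(l) list(lambda = l)),
    ebdt = lapply(hyper_grid %||% seq(6L, 20L, 2L),
                  function(m) list(n_estimators = m)),
    ann = hyper_grid %||% list(list(size = 6L, decay = 1e-2),
                               list(size = 12L, decay = 1e-2),
                               list(size = 12L, decay = 1e-3))
  )

  fit_one <- function(hp, xtr, ytr) {
    switch(kind,
      svm_linear = fit_svm_linear(xtr, ytr, nclass, lambda = hp$lambda),
      ebdt = fit_ebdt(xtr, ytr, nclass, n_estimators = hp$n_estimators),
      ann = fit_ann(xtr, ytr, nclass, size = hp$size, decay = hp$decay)
    )
  }
  pred_one <- function(fit, xte) {
    switch(kind,
      svm_linear = predict_svm_linear(fit, xte),
      ebdt = predict_ebdt(fit, xte),
      ann = predict_ann(fit, xte)
    )
  }

  with_seed(seed, {
    best_hp <- grids[[1]]
    if (length(grids) > 1L) {
      folds <- make_folds(y, select_folds)
      cv_acc <- vapply(grids, function(hp) {
        accs <- vapply(seq_len(select_folds), function(f) {
          te <- folds == f
          if (length(unique(y[!te])) < 2L) return(NA_real_)
          fit <- fit_one(hp, xs[!te, , drop = FALSE], y[!te])
          mean(pred_one(fit, xs[te, , drop = FALSE]) == y[te])
        }, numeric(1))
        mean(accs, na.rm = TRUE)
      }, numeric(1))
      best_hp <- grids[[which.max(cv_acc)]]
    }
    fit <- fit_one(best_hp, xs, y)
    structure(list(kind = kind, fit = fit, hyper = best_hp,
                   center = ctr, scale = scl, nclass = nclass),
              class = "hiss_baseline")
  })
}

#' Predict with a baseline classifier
#'
#' @param object a `hiss_baseline` from [train_baseline()].
#' @param newdata feature matrix in raw units.
#' @param type `"class"` for crisp labels; `"prob"` (ANN only) for softmax
#'   class probabilities, which sum to one per row.
#' @param ... unused.
#' @return integer classes, or a probability matrix.
#' @export
predict.hiss_baseline <- function(object, newdata, type = "class", ...) {
  x <- as.matrix(newdata)
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  if (type == "prob") {
    if (object$kind != "ann") stopf("probabilities only available for ann")
    return(predict_ann(object$fit, xs, type = "prob"))
  }
  switch(object$kind,
    svm_linear = predict_svm_linear(object$fit, xs),
    ebdt = predict_ebdt(object$fit, xs),
    ann = predict_ann(object$fit, xs)
  )
}

## ---- metrics -------------------------------------------------------------

#' Confusion matrix, accuracy and per-class sensitivity
#'
#' Accuracy is the sum of the major diagonal over the total count. Per-class
#' TPR (sensitivity) is diagonal over row sum; classes absent from `y_true`
#' are reported as `NA` (absent), not zero.
#'
#' @param y_true,y_pred integer vectors in 0..c-1.
#' @param c number of classes.
#' @return list with `confusion` (c x c matrix, rows = true), `accuracy`,
#'   and `tpr` (named numeric, `NA` for absent classes).
#' @export
confusion_and_accuracy <- function(y_true, y_pred, c = 5L) {
  if (length(y_true) != length(y_pred)) stopf("length mismatch")
  if (any(c(y_true, y_pred) < 0) || any(c(y_true, y_pred) >= c)) {
    stopf("labels must lie in 0..c-1")
  }
  cm <- matrix(0L, c, c, dimnames = list(true = 0:(c - 1), pred = 0:(c - 1)))
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  rs <- rowSums(cm)
  tpr <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  names(tpr) <- 0:(c - 1)
  list(confusion = cm, accuracy = sum(diag(cm)) / length(y_true), tpr = tpr)
}

# Stratified-where-possible fold assignment (plain random with a warning
# when some class has fewer members than folds).
make_folds <- function(y, k) {
  n <- length(y)
  folds <- integer(n)
  counts <- table(y)
  if (any(counts < k)) {
    warning("some classes have fewer members than folds; using plain random folds",
            call. = FALSE)
    return(sample(rep_len(seq_len(k), n)))
  }
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Resolve an estimator spec into a (train, predict) pair. Accepts a function
# (x, y) -> object with a predict method, or list(kind =, hyper_grid =)
# forwarded to train_baseline.
resolve_estimator <- function(estimator, nclass) {
  if (is.function(estimator)) {
    list(train = estimator, predict = function(m, x) predict(m, x))
  } else {
    list(train = function(x, y) {
           train_baseline(estimator$kind, x, y,
                          hyper_grid = estimator$hyper_grid, nclass = nclass)
         },
         predict = function(m, x) predict(m, x))
  }
}

#' Stratified k-fold cross-validation
#'
#' @param estimator a function `(x, y)` returning a model with a `predict`
#'   method, or `list(kind = , hyper_grid = )` forwarded to
#'   [train_baseline()].
#' @param x feature matrix.
#' @param y integer labels in 0..nclass-1.
#' @param k number of folds (default 5).
#' @param nclass number of classes.
#' @param seed RNG seed (governs fold assignment and any estimator
#'   randomness).
#' @return list of class `cv_result`: `fold_accuracies`, `mean`, `sd`, and
#'   `tpr` (per-class sensitivity pooled over folds).
#' @export
kfold_cv <- function(estimator, x, y, k = 5L, nclass = 5L, seed = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- length(y)
  if (k < 2L) stopf("k must be >= 2")
  if (k > n) stopf("k exceeds the number of instances")
  est <- resolve_estimator(estimator, nclass)
  with_seed(seed, {
    folds <- make_folds(y, k)
    preds <- integer(n)
    accs <- vapply(seq_len(k), function(f) {
      te <- folds == f
      model <- est$train(x[!te, , drop = FALSE], y[!te])
      preds[te] <<- est$predict(model, x[te, , drop = FALSE])
      mean(preds[te] == y[te])
    }, numeric(1))
    pooled <- confusion_and_accuracy(y, preds, nclass)
    structure(list(fold_accuracies = accs, mean = mean(accs),
                   sd = stats::sd(accs), tpr = pooled$tpr,
                   confusion = pooled$confusion),
              class = "cv_result")
  })
}

#' Learning curve over training-set size
#'
#' A fixed held-out test set of `test_size` instances is carved out once;
#' for each training size, `repeats` random training subsets are drawn from
#' the remaining pool (class-stratified in `"sorted"` mode, mirroring an
#' 80:20-style balanced split; plain random in `"unsorted"` mode), a model
#' is fitted and train/test accuracies recorded.
#'
#' @param estimator as in [kfold_cv()].
#' @param x,y dataset.
#' @param train_sizes integer vector of training sizes (default 30..80 by 5).
#' @param repeats repetitions per size (default 20).
#' @param test_size held-out test-set size (default 20).
#' @param mode `"sorted"` (stratified) or `"unsorted"`.
#' @param nclass number of classes.
#' @param seed RNG seed.
#' @return data.frame with one row per size: `size`, `mean_train`,
#'   `sd_train`, `mean_test`, `sd_test`, plus attribute `"test_accuracy"`
#'   holding the repeats x sizes test-accuracy matrix.
#' @export
learning_curve <- function(estimator, x, y, train_sizes = seq(30L, 80L, 5L),
                           repeats = 20L, test_size = 20L,
                           mode = c("sorted", "unsorted"), nclass = 5L,
                           seed = NULL) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- length(y)
  if (max(train_sizes) + test_size > n) {
    stopf("max(train_sizes) + test_size exceeds the dataset size")
  }
  est <- resolve_estimator(estimator, nclass)
  with_seed(seed, {
    te_idx <- strat_sample(y, test_size, stratified = mode == "sorted")
    pool <- setdiff(seq_len(n), te_idx)
    acc_te <- matrix(NA_real_, repeats, length(train_sizes))
    acc_tr <- matrix(NA_real_, repeats, length(train_sizes))
    for (si in seq_along(train_sizes)) {
      for (r in seq_len(repeats)) {
        tr <- pool[strat_sample(y[pool], train_sizes[si],
                                stratified = mode == "sorted")]
        if (length(unique(y[tr])) < 2L) {
          tr <- pool[sample.int(length(pool), train_sizes[si])]
        }
        model <- est$train(x[tr, , drop = FALSE], y[tr])
        acc_tr[r, si] <- mean(est$predict(model, x[tr, , drop = FALSE]) == y[tr])
        acc_te[r, si] <- mean(est$predict(model, x[te_idx, , drop = FALSE]) ==
                                y[te_idx])
      }
    }
    out <- data.frame(size = train_sizes,
                      mean_train = colMeans(acc_tr),
                      sd_train = apply(acc_tr, 2, stats::sd),
                      mean_test = colMeans(acc_te),
                      sd_test = apply(acc_te, 2, stats::sd))
    attr(out, "test_accuracy") <- acc_te
    out
  })
}

# Sample `size` indices from labels `y`, proportionally per class when
# stratified (every class represented when counts permit).
strat_sample <- function(y, size, stratified = TRUE) {
  n <- length(y)
  if (!stratified) return(sample.int(n, size))
  classes <- sort(unique(y))
  want <- floor(size * as.numeric(table(y)[as.character(classes)]) / n)
  want <- pmax(want, 1L)
  while (sum(want) > size) want[which.max(want)] <- want[which.max(want)] - 1L
  idx <- unlist(lapply(seq_along(classes), function(i) {
    members <- which(y == classes[i])
    sample(members, min(want[i], length(members)))
  }))
  short <- size - length(idx)
  if (short > 0) {
    idx <- c(idx, sample(setdiff(seq_len(n), idx), short))
  }
  idx
}

#' One-way ANOVA across classifiers' fold accuracies
#'
#' @param cv_accuracies named list of numeric vectors (one per classifier,
#'   each of length >= 2), e.g. fold accuracies from [kfold_cv()].
#' @return list with `F`, `p_value`, `df_between`, `df_within`.
#' @export
compare_classifiers_anova <- function(cv_accuracies) {
  if (length(cv_accuracies) < 2L) stopf("need at least two groups")
  sizes <- lengths(cv_accuracies)
  if (any(sizes < 2L)) stopf("each group needs at least two values")
  all_v <- unlist(cv_accuracies)
  grand <- mean(all_v)
  ssb <- sum(sizes * (vapply(cv_accuracies, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(cv_accuracies, function(v) sum((v - mean(v))^2), numeric(1)))
  dfb <- length(cv_accuracies) - 1L
  dfw <- sum(sizes) - length(cv_accuracies)
  if (ssw == 0 && ssb == 0) {
    return(list(F = 0, p_value = 1, df_between = dfb, df_within = dfw))
  }
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p_value = stats::pf(f, dfb, dfw, lower.tail = FALSE),
       df_between = dfb, df_within = dfw)
}

## ---- sizing surface ------------------------------------------------------

#' Simulate an accuracy grid over cohort size and committee size
#'
#' For each (n_patients, n_experts) cell, generates a fresh synthetic cohort,
#' scores it with a committee of that size (the default five profiles,
#' extended with jittered variants beyond five), fuses labels by majority
#' vote, and measures cross-validated accuracy of the given estimator.
#'
#' @param n_patients_grid,n_experts_grid grid axes.
#' @param estimator as in [kfold_cv()] (default bagged trees).
#' @param reps cohorts averaged per cell.
#' @param k CV folds.
#' @param seed RNG seed.
#' @return data.frame `n_patients`, `n_experts`, `accuracy`.
#' @export
simulate_sizing_grid <- function(n_patients_grid = c(50, 75, 100, 125, 150),
                                 n_experts_grid = c(3, 5, 7, 9),
                                 estimator = list(kind = "ebdt",
                                                  hyper_grid = 12L),
                                 reps = 1L, k = 5L, seed = NULL) {
  grid <- expand.grid(n_patients = n_patients_grid,
                      n_experts = n_experts_grid)
  seeds <- derive_seeds(seed, nrow(grid) * reps)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cell <- vapply(seq_len(reps), function(r) {
      s <- seeds[[(g - 1L) * reps + r]]
      co <- generate_cohort(grid$n_patients[g], seed = s)
      committee <- make_committee(grid$n_experts[g], seed = s)
      sm <- score_cohort(co, committee, seed = s)
      yy <- apply(sm$scores, 1L, majority_vote)
      if (length(unique(yy)) < 2L) return(NA_real_)
      kfold_cv(estimator, cohort_features(co), yy, k = k, seed = s)$mean
    }, numeric(1))
    acc[g] <- mean(cell, na.rm = TRUE)
  }
  grid$accuracy <- acc
  grid
}

#' Build a committee of a given size
#'
#' The first five experts are the default committee; further experts are
#' jittered copies of it (fresh threshold-shift perturbations), so larger
#' committees keep the default's disagreement character.
#'
#' @param n_experts committee size.
#' @param intra_noise lapse rate for all profiles.
#' @param seed RNG seed for the jittered extras.
#' @return list of [expert_profile()]s.
#' @export
make_committee <- function(n_experts, intra_noise = 0.08, seed = NULL) {
  base <- default_committee(intra_noise)
  if (n_experts <= 5L) return(base[seq_len(n_experts)])
  jitter_scale <- c(glucose = 3, lactate = 0.12, ph = 0.012,
                    potassium = 0.12, po2 = 3)
  with_seed(seed, {
    extra <- lapply(seq_len(n_experts - 5L), function(i) {
      proto <- base[[(i - 1L) %% 5L + 1L]]
      proto$id <- sprintf("D%d", 5L + i)
      proto$threshold_shift <- proto$threshold_shift +
        stats::rnorm(5) * jitter_scale
      proto
    })
    c(base, extra)
  })
}

#' Fit a quadratic sizing response surface
#'
#' Least-squares quadratic surface `accuracy ~ n_patients + n_experts +
#' n_patients^2 + n_experts^2 + n_patients:n_experts`, with R-squared and
#' the total sum of squares reported as fit diagnostics.
#'
#' @param grid data.frame with columns `n_patients`, `n_experts`,
#'   `accuracy` (e.g. from [simulate_sizing_grid()]).
#' @return object of class `sizing_model` wrapping the `lm` fit.
#' @export
fit_sizing_model <- function(grid) {
  grid <- grid[is.finite(grid$accuracy), , drop = FALSE]
  if (nrow(grid) < 6L) stopf("need at least 6 grid points")
  if (length(unique(grid$n_patients)) < 2L ||
      length(unique(grid$n_experts)) < 2L) {
    stopf("grid must span both axes")
  }
  fit <- stats::lm(accuracy ~ n_patients + n_experts + I(n_patients^2) +
                     I(n_experts^2) + n_patients:n_experts, data = grid)
  if (any(is.na(stats::coef(fit)))) stopf("rank-deficient sizing design")
  ss_total <- sum((grid$accuracy - mean(grid$accuracy))^2)
  r2 <- if (ss_total > 0) 1 - sum(stats::residuals(fit)^2) / ss_total else 1
  structure(list(fit = fit, coefficients = stats::coef(fit),
                 r_squared = r2, ss_total = ss_total,
                 grid = grid),
            class = "sizing_model")
}

#' @export
predict.sizing_model <- function(object, newdata, ...) {
  p <- stats::predict(object$fit, newdata)
  clamp(p, 1e-9, 1 - 1e-9)
}

#' Smallest (experts, patients) pair reaching a target accuracy
#'
#' Scans committee sizes in ascending order (experts are the scarcer
#' resource) and, within each, patient counts in ascending order, returning
#' the first pair whose predicted accuracy reaches the target.
#'
#' @param model a `sizing_model`.
#' @param target_accuracy target in (0, 1).
#' @param patients_range,experts_range integer search bounds.
#' @return named integer vector `c(n_patients, n_experts)`; errors with
#'   "unreachable" if no pair in range attains the target.
#' @export
predict_requirements <- function(model, target_accuracy,
                                 patients_range = c(10L, 500L),
                                 experts_range = c(2L, 25L)) {
  if (!is.finite(target_accuracy) || target_accuracy <= 0 ||
      target_accuracy >= 1) {
    stopf("target_accuracy must lie in (0, 1)")
  }
  for (ne in seq(experts_range[1], experts_range[2])) {
    np_grid <- seq(patients_range[1], patients_range[2])
    acc <- predict(model, data.frame(n_patients = np_grid, n_experts = ne))
    hit <- which(acc >= target_accuracy)
    if (length(hit)) {
      return(c(n_patients = np_grid[hit[1]], n_experts = ne))
    }
  }
  stopf("target accuracy %.4f unreachable within the configured bounds",
        target_accuracy)
}
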