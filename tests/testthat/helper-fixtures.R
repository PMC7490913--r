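# Shared fixtures: the three fully printed worked-example patients and the
# expert votes recorded for them, plus small builders used across tests.

# patient 1, patient 2 and the last training-row patient of the published
# partial dataset, with their five expert votes
worked_examples <- function() {
  list(
    p1 = list(panel = analyte_panel(70, 2.7, 7.42, 5.10, 78),
              votes = c(1, 1, 1, 1, 0), consensus = 1L),
    p2 = list(panel = analyte_panel(160, 6.0, 7.11, 6.14, 44),
              votes = c(4, 2, 3, 3, 3), consensus = 3L),
    pn = list(panel = analyte_panel(41, 9.7, 7.26, 4.84, 97),
              votes = c(3, 3, 4, 3, 3), consensus = 3L)
  )
}

# a committee of identical unbiased noiseless raters
noiseless_committee <- function(k = 5L) {
  lapply(seq_len(k), function(i) {
    expert_profile(sprintf("D%d", i), intra_noise = 0)
  })
}

# hand-built score_matrix object (for fusion/variability arithmetic tests)
fake_score_matrix <- function(scores, probe = NULL) {
  structure(list(scores = scores,
                 expert_ids = colnames(scores),
                 probe_pairs = probe %||% data.frame(
                   patient_id = integer(0), expert = character(0),
                   original = integer(0), rescore = integer(0))),
            class = "score_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# features + deterministic core-policy labels of a zero-noise cohort
zero_noise_dataset <- function(n = 100, seed = 11) {
  co <- generate_cohort(n, noise = noise_off(), seed = seed)
  x <- as.matrix(co[, c("glucose_mg_dl", "lactate_mmol_l", "ph",
                        "potassium_mmol_l", "po2_mmhg")])
  colnames(x) <- c("glucose", "lactate", "ph", "potassium", "po2")
  y <- apply(x, 1, function(r) {
    core_policy_score(structure(r, names = colnames(x)))
  })
  list(cohort = co, x = x, y = as.integer(y))
}

# brute-force interval-grid oracle for 1-feature possibility approximation:
# pointwise best |u - fit| over all grid intervals covering the point, each
# interval fitted per class by least squares on its covered points
grid_interval_oracle_mae <- function(x, u, grid_n = 25) {
  gs <- seq(min(x), max(x), length.out = grid_n)
  n <- length(x)
  best <- rep(Inf, n)
  for (i in seq_len(grid_n - 1)) {
    for (j in seq(i + 1, grid_n)) {
      pts <- which(x >= gs[i] & x <= gs[j])
      if (length(pts) < 2) next
      X <- cbind(1, x[pts])
      coef <- qr.solve(crossprod(X), crossprod(X, u[pts, , drop = FALSE]))
      err <- rowMeans(abs(pmin(pmax(X %*% coef, 0), 1) - u[pts, , drop = FALSE]))
      best[pts] <- pmin(best[pts], err)
    }
  }
  mean(best)
}
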