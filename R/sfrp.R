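# Synthetic patient generator: hidden severity seeding, per-analyte interval
# sampling, noise filters (regime drift, adrenergic glucose, late-onset pH,
# respiratory compensation of pO2), and the acid-base potassium relation.

# Finite caps used when a draw must come from an open-ended regime
# (e.g. "hypoglycemia < 70 mg/dL" needs a lower edge to sample from).
REGIME_DRAW_CAPS <- list(
  glucose = c(25, 350),
  lactate = c(0, 12),
  ph      = c(7.00, 7.60),
  po2     = c(40, 140)
)

#' Default severity sampling profile
#'
#' Per hidden severity level 0--4 and per sampled analyte (glucose, lactate,
#' pH, pO2; potassium is derived from pH, see [compute_potassium()]), the
#' target sampling interval(s) in canonical units. Where a level admits
#' derangement in either direction (hypo- or hyperglycemia) the analyte
#' carries two intervals and the sampler picks one uniformly.
#'
#' Level 0 draws entirely inside the normal bands. Severity is expressed as
#' progressively rising lactate, falling pH (a late, severe biomarker),
#' drifting glucose, and falling oxygen tension, with level 4 reaching
#' profound acidosis (pH 7.00--7.25) and hypoxia (pO2 40--70 mmHg).
#'
#' @return an object of class `severity_profile`: a list with elements
#'   `"0"` .. `"4"`, each a named list of interval matrices (rows = candidate
#'   intervals, columns = lo, hi).
#' @export
default_severity_profile <- function() {
  iv <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  p <- list(
    `0` = list(glucose = iv(70, 99), lactate = iv(0.50, 2.00),
               ph = iv(7.35, 7.45), po2 = iv(100, 120)),
    `1` = list(glucose = iv(70, 99), lactate = iv(2.00, 3.00),
               ph = iv(7.35, 7.45), po2 = iv(100, 120)),
    `2` = list(glucose = iv(55, 70, 99, 180), lactate = iv(2.50, 4.00),
               ph = iv(7.30, 7.40), po2 = iv(100, 120)),
    `3` = list(glucose = iv(30, 60, 180, 300), lactate = iv(3.50, 8.00),
               ph = iv(7.20, 7.35), po2 = iv(70, 100)),
    `4` = list(glucose = iv(25, 60, 200, 350), lactate = iv(4.00, 12.00),
               ph = iv(7.00, 7.25), po2 = iv(40, 70))
  )
  structure(p, class = "severity_profile")
}

#' Validate a severity profile
#'
#' Checks that every level defines intervals for glucose, lactate, ph and
#' po2 with lo < hi; that level-0 intervals lie inside the normal bands; and
#' that mean lactate is non-decreasing and mean pH non-increasing in level.
#'
#' @param profile a severity profile (see [default_severity_profile()]).
#' @param table a [regime_table()].
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_severity_profile <- function(profile, table = regime_table()) {
  needed <- c("glucose", "lactate", "ph", "po2")
  lvls <- as.character(0:4)
  if (!all(lvls %in% names(profile))) stopf("profile must define levels 0..4")
  for (l in lvls) {
    for (a in needed) {
      m <- profile[[l]][[a]]
      if (is.null(m) || !is.matrix(m) || ncol(m) != 2 ||
          any(!is.finite(m)) || any(m[, 1] >= m[, 2])) {
        stopf("profile level %s analyte %s: need interval matrix with lo < hi",
              l, a)
      }
    }
  }
  for (a in needed) {
    m <- profile[["0"]][[a]]
    row <- table[table$analyte == a, ]
    if (any(m[, 1] < row$normal_lo) || any(m[, 2] > row$normal_hi)) {
      stopf("level-0 %s interval must lie inside the normal band", a)
    }
  }
  mean_of <- function(l, a) mean(rowMeans(profile[[as.character(l)]][[a]]))
  lac <- vapply(0:4, mean_of, numeric(1), a = "lactate")
  ph <- vapply(0:4, mean_of, numeric(1), a = "ph")
  if (any(diff(lac) < 0)) stopf("mean lactate must be non-decreasing in level")
  if (any(diff(ph) > 0)) stopf("mean pH must be non-increasing in level")
  invisible(TRUE)
}

#' Noise configuration for the synthetic generator
#'
#' @param p_drift probability that a glucose or lactate draw is replaced by a
#'   draw from an adjacent regime (confounding "bleed" between severity
#'   regimes).
#' @param p_adrenergic probability that glucose is forced hyperglycemic
#'   regardless of seed (stress adrenergic response).
#' @param p_ph_normal probability that a non-zero seed receives a normal-band
#'   pH (pH is a late and severe biomarker; many sick patients still look
#'   normal on it).
#' @param p_resp_comp probability, given acidosis (pH < 7.35), that pO2 is
#'   normalized by respiratory compensation (hyperventilation).
#' @param po2_jitter additive uniform jitter half-width on pO2, mmHg.
#' @return a list of class `noise_config`.
#' @export
noise_config <- function(p_drift = 0.10, p_adrenergic = 0.10,
                         p_ph_normal = 0.25, p_resp_comp = 0.30,
                         po2_jitter = 5) {
  p <- c(p_drift = p_drift, p_adrenergic = p_adrenergic,
         p_ph_normal = p_ph_normal, p_resp_comp = p_resp_comp)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stopf("noise probabilities must lie in [0, 1]")
  }
  if (!is.finite(po2_jitter) || po2_jitter < 0) stopf("po2_jitter must be >= 0")
  structure(as.list(c(p, po2_jitter = po2_jitter)), class = "noise_config")
}

#' @rdname noise_config
#' @export
noise_off <- function() {
  noise_config(p_drift = 0, p_adrenergic = 0, p_ph_normal = 0,
               p_resp_comp = 0, po2_jitter = 0)
}

#' Generate hidden severity seeds
#'
#' With equal weights and `n` divisible by 5, allocation is stratified:
#' exactly `n/5` patients per class, shuffled. Otherwise classes are drawn
#' multinomially with the given weights.
#'
#' @param n cohort size (>= 1).
#' @param weights non-negative per-class weights for classes 0..4.
#' @return integer vector of severity classes in 0..4. Uses the current RNG
#'   stream; seed through [generate_cohort()] or `set.seed()`.
#' @export
generate_hidden_seeds <- function(n, weights = rep(1, 5)) {
  if (length(n) != 1L || !is.finite(n) || n < 1) stopf("n must be >= 1")
  n <- as.integer(n)
  if (length(weights) != 5 || any(!is.finite(weights)) || any(weights < 0) ||
      sum(weights) == 0) {
    stopf("weights must be 5 non-negative values, not all zero")
  }
  equal <- length(unique(weights)) == 1L
  if (equal && n %% 5L == 0L) {
    sample(rep(0:4, n / 5L))
  } else {
    sample(0:4, n, replace = TRUE, prob = weights / sum(weights))
  }
}

#' Acid-base potassium relation
#'
#' Serum potassium rises as pH falls: a 0.1 unit drop in pH raises potassium
#' by 0.6 mmol/L. Given a eukalemic baseline draw, the generated potassium is
#' `baseline + (7.35 - ph) * 6`, applied unconditionally, so mild alkalosis
#' lowers potassium below its baseline.
#'
#' @param ph pH value(s) within the plausibility gate \[6.5, 8.0\].
#' @param baseline eukalemic baseline draw(s), mmol/L, within \[3.50, 5.50\].
#' @return potassium, mmol/L.
#' @export
#' @examples
#' compute_potassium(7.25, 4.0)  # 4.6
compute_potassium <- function(ph, baseline) {
  if (any(!is.finite(baseline)) || any(baseline < 3.50) || any(baseline > 5.50)) {
    stopf("baseline potassium must be a eukalemic draw in [3.50, 5.50] mmol/L")
  }
  if (any(!is.finite(ph)) || any(ph < PH_GATE[1]) || any(ph > PH_GATE[2])) {
    stopf("ph outside plausibility gate [%.1f, %.1f]", PH_GATE[1], PH_GATE[2])
  }
  baseline + (7.35 - ph) * 6
}

# Uniform draw from one of the level's candidate intervals (rows).
draw_from_intervals <- function(m) {
  i <- if (nrow(m) > 1L) sample.int(nrow(m), 1L) else 1L
  stats::runif(1, m[i, 1], m[i, 2])
}

# Draw from a regime adjacent to the regime of `value` (direction uniform
# where both neighbours exist), bounded by the plausibility caps.
draw_adjacent_regime <- function(analyte, value, table) {
  row <- table[table$analyte == analyte, ]
  caps <- REGIME_DRAW_CAPS[[analyte]]
  regime <- classify_regime(analyte, value, table)
  target <- switch(regime,
    low = "normal",
    high = "normal",
    normal = sample(c("low", "high"), 1L)
  )
  band <- switch(target,
    low = c(caps[1], row$normal_lo),
    normal = c(row$normal_lo, row$normal_hi),
    high = c(row$normal_hi, caps[2])
  )
  stats::runif(1, band[1], band[2])
}

#' Sample one biomarker panel for a hidden severity seed
#'
#' Draws glucose, lactate, pH and pO2 uniformly from the seed level's
#' intervals, then applies the noise filters: independent adjacent-regime
#' drift for glucose and lactate, a forced hyperglycemic adrenergic scenario
#' for glucose, normal-band replacement for pH at non-zero seeds, and
#' pH-conditional respiratory compensation plus additive jitter for pO2.
#' Potassium is not sampled: it is a eukalemic uniform baseline transformed
#' through [compute_potassium()].
#'
#' @param seed_level hidden severity class, 0..4.
#' @param profile a severity profile.
#' @param noise a [noise_config()].
#' @param table a [regime_table()].
#' @return an [analyte_panel()] with attribute `"potassium_baseline"` (the
#'   pre-adjustment eukalemic draw). Uses the current RNG stream.
#' @export
sample_panel <- function(seed_level, profile = default_severity_profile(),
                         noise = noise_config(), table = regime_table()) {
  if (!seed_level %in% 0:4) stopf("seed_level must be in 0..4")
  lv <- profile[[as.character(seed_level)]]

  glucose <- draw_from_intervals(lv$glucose)
  if (stats::runif(1) < noise$p_drift) {
    glucose <- draw_adjacent_regime("glucose", glucose, table)
  }
  if (stats::runif(1) < noise$p_adrenergic) {
    glucose <- stats::runif(1, 100, 180)  # stress hyperglycemia
  }

  lactate <- draw_from_intervals(lv$lactate)
  if (stats::runif(1) < noise$p_drift) {
    lactate <- draw_adjacent_regime("lactate", lactate, table)
  }

  ph <- draw_from_intervals(lv$ph)
  if (seed_level > 0 && stats::runif(1) < noise$p_ph_normal) {
    phrow <- table[table$analyte == "ph", ]
    ph <- stats::runif(1, phrow$normal_lo, phrow$normal_hi)
  }

  baseline <- stats::runif(1, 3.50, 5.50)
  potassium <- compute_potassium(ph, baseline)

  po2 <- draw_from_intervals(lv$po2)
  if (ph < 7.35 && stats::runif(1) < noise$p_resp_comp) {
    porow <- table[table$analyte == "po2", ]
    po2 <- stats::runif(1, porow$normal_lo, porow$normal_hi)
  }
  if (noise$po2_jitter > 0) {
    po2 <- po2 + stats::runif(1, -noise$po2_jitter, noise$po2_jitter)
  }
  po2 <- max(po2, 25)

  panel <- analyte_panel(glucose, lactate, ph, potassium, po2)
  attr(panel, "potassium_baseline") <- baseline
  panel
}

#' Generate a synthetic patient cohort
#'
#' Produces `n` synthetic patient records: a hidden severity seed per
#' patient (evenly distributed by default), a biomarker panel sampled from
#' the seed's severity profile under the configured noise filters, and the
#' internal potassium baseline. The hidden seed drives generation but is
#' withheld from standard exports (see [write_sfrp_csv()]).
#'
#' @param n cohort size.
#' @param profile a severity profile.
#' @param noise a [noise_config()].
#' @param class_weights per-class seed weights (default equal).
#' @param table a [regime_table()].
#' @param seed RNG seed; the whole cohort is a pure function of
#'   `(n, profile, noise, class_weights, seed)`.
#' @return a data.frame of class `sfrp_cohort` with columns `patient_id`,
#'   `glucose_mg_dl`, `lactate_mmol_l`, `ph`, `potassium_mmol_l`,
#'   `po2_mmhg`, plus attributes `hidden_seed` (integer vector) and
#'   `potassium_baseline` (numeric vector).
#' @export
#' @examples
#' co <- generate_cohort(10, seed = 1)
#' hidden_seeds(co)
generate_cohort <- function(n, profile = default_severity_profile(),
                            noise = noise_config(),
                            class_weights = rep(1, 5),
                            table = regime_table(), seed = NULL) {
  validate_severity_profile(profile, table)
  with_seed(seed, {
    seeds <- generate_hidden_seeds(n, class_weights)
    panels <- matrix(NA_real_, n, 5,
                     dimnames = list(NULL, HISS_ANALYTES))
    baseline <- numeric(n)
    for (i in seq_len(n)) {
      p <- sample_panel(seeds[i], profile, noise, table)
      bad <- validate_panel(p)
      if (length(bad)) {
        stopf("generated panel %d invalid: %s", i, paste(bad, collapse = "; "))
      }
      panels[i, ] <- as.numeric(p)
      baseline[i] <- attr(p, "potassium_baseline")
    }
    out <- data.frame(
      patient_id = seq_len(n),
      glucose_mg_dl = panels[, "glucose"],
      lactate_mmol_l = panels[, "lactate"],
      ph = panels[, "ph"],
      potassium_mmol_l = panels[, "potassium"],
      po2_mmhg = panels[, "po2"]
    )
    attr(out, "hidden_seed") <- as.integer(seeds)
    attr(out, "potassium_baseline") <- baseline
    class(out) <- c("sfrp_cohort", "data.frame")
    out
  })
}

#' Accessors for withheld cohort internals
#'
#' The hidden severity seed and the eukalemic potassium baseline are part of
#' the generative state, not of the exported record; these accessors exist
#' for testing and calibration.
#'
#' @param cohort an `sfrp_cohort`.
#' @return integer severity seeds / numeric baselines.
#' @export
hidden_seeds <- function(cohort) attr(cohort, "hidden_seed")

#' @rdname hidden_seeds
#' @export
potassium_baselines <- function(cohort) attr(cohort, "potassium_baseline")

# Matrix of the five biomarker columns of a cohort (canonical order).
cohort_features <- function(cohort) {
  m <- as.matrix(cohort[, c("glucose_mg_dl", "lactate_mmol_l", "ph",
                            "potassium_mmol_l", "po2_mmhg")])
  colnames(m) <- HISS_ANALYTES
  m
}

# Regimes compatible with a level's sampling intervals (zero-noise oracle).
profile_regime_sets <- function(profile, table = regime_table()) {
  lapply(profile[as.character(0:4)], function(lv) {
    sets <- lapply(c("glucose", "lactate", "ph", "po2"), function(a) {
      m <- lv[[a]]
      row <- table[table$analyte == a, ]
      regs <- character(0)
      for (i in seq_len(nrow(m))) {
        if (m[i, 1] < row$normal_lo) regs <- c(regs, "low")
        if (m[i, 2] > row$normal_hi) regs <- c(regs, "high")
        if (m[i, 2] >= row$normal_lo && m[i, 1] <= row$normal_hi) {
          regs <- c(regs, "normal")
        }
      }
      unique(regs)
    })
    names(sets) <- c("glucose", "lactate", "ph", "po2")
    sets
  })
}

#' Read or write a severity profile as JSON
#'
#' @param path file path. The file shipped at
#'   `system.file("extdata", "severity_profile.json", package = "hisskit")`
#'   reproduces [default_severity_profile()].
#' @return for `read_severity_profile`, a `severity_profile`.
#' @export
read_severity_profile <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- lapply(doc, function(lv) {
    lapply(lv, function(m) {
      if (is.matrix(m)) m else matrix(unlist(m), ncol = 2, byrow = TRUE)
    })
  })
  structure(p, class = "severity_profile")
}

#' @rdname read_severity_profile
#' @param profile a severity profile to serialize.
#' @export
write_severity_profile <- function(profile, path) {
  doc <- lapply(unclass(profile), function(lv) {
    lapply(lv, function(m) lapply(seq_len(nrow(m)), function(i) m[i, ]))
  })
  jsonlite::write_json(doc, path, digits = NA, pretty = TRUE)
  invisible(path)
}
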