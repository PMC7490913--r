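# Domain types: biomarker panels, the three-regime pathophysiological
# partition (low / normal / high) per analyte, and unit conversion.

#' Construct a regime table
#'
#' A regime table holds, per analyte, the closed normal band and the names of
#' the pathological regimes below and above it. The default bands are the
#' standard adult reference ranges used throughout the package: glucose
#' 70--99 mg/dL (euglycemia), lactate 0.50--2.00 mmol/L, potassium
#' 3.50--5.50 mmol/L (eukalemia), pH 7.35--7.45, pO2 100--120 mmHg.
#'
#' Values above the lactate band remain "high" no matter how extreme: severe
#' hemorrhage routinely exceeds 4 mmol/L, so the hyperlactatemia regime is
#' open-ended.
#'
#' @param bands named list mapping each analyte to `c(lo, hi)` of its normal
#'   band, in canonical units (glucose mg/dL; lactate, potassium mmol/L;
#'   pH unitless; pO2 mmHg).
#' @return an object of class `regime_table`: a data.frame with one row per
#'   analyte and columns `analyte`, `normal_lo`, `normal_hi`, `low_label`,
#'   `high_label`, `unit`.
#' @export
#' @examples
#' tab <- regime_table()
#' classify_regime("potassium", 6.14, tab)  # "high"
regime_table <- function(bands = NULL) {
  defaults <- list(
    glucose   = c(70, 99),
    lactate   = c(0.50, 2.00),
    ph        = c(7.35, 7.45),
    potassium = c(3.50, 5.50),
    po2       = c(100, 120)
  )
  if (!is.null(bands)) {
    bad <- setdiff(names(bands), HISS_ANALYTES)
    if (length(bad)) stopf("unknown analyte(s): %s", paste(bad, collapse = ", "))
    defaults[names(bands)] <- bands
  }
  lo <- vapply(defaults[HISS_ANALYTES], `[`, numeric(1), 1L)
  hi <- vapply(defaults[HISS_ANALYTES], `[`, numeric(1), 2L)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi)) {
    stopf("each normal band must be finite with lo < hi")
  }
  tab <- data.frame(
    analyte = HISS_ANALYTES,
    normal_lo = lo,
    normal_hi = hi,
    low_label = c("hypoglycemia", "hypolactatemia", "acidosis",
                  "hypokalemia", "hypoxia"),
    high_label = c("hyperglycemia", "hyperlactatemia", "alkalosis",
                   "hyperkalemia", "hyperoxia"),
    unit = c("mg/dL", "mmol/L", "pH", "mmol/L", "mmHg"),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("regime_table", "data.frame")
  tab
}

#' @export
print.regime_table <- function(x, ...) {
  cat("Pathophysiological regime table (closed normal bands)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Classify a measurement into its pathophysiological regime
#'
#' The normal band is closed: a value exactly on either bound is `"normal"`.
#'
#' @param analyte one of `"glucose"`, `"lactate"`, `"ph"`, `"potassium"`,
#'   `"po2"`.
#' @param value numeric vector of measurements in canonical units.
#' @param table a [regime_table()].
#' @return character vector in `c("low", "normal", "high")`.
#' @export
classify_regime <- function(analyte, value, table = regime_table()) {
  if (length(analyte) != 1L || !analyte %in% HISS_ANALYTES) {
    stopf("unknown analyte '%s'; valid analytes: %s",
          paste(analyte, collapse = ","), paste(HISS_ANALYTES, collapse = ", "))
  }
  if (any(!is.finite(value))) stopf("non-finite value for analyte '%s'", analyte)
  row <- table[table$analyte == analyte, ]
  out <- rep("normal", length(value))
  out[value < row$normal_lo] <- "low"
  out[value > row$normal_hi] <- "high"
  out
}

# Molar mass factor: 18.016 mg/dL of glucose per mmol/L (180.16 g/mol / 10).
GLUCOSE_MGDL_PER_MMOLL <- 18.016

#' Convert glucose concentrations between mg/dL and mmol/L
#'
#' @param value positive numeric vector.
#' @param to target unit, `"mmol_l"` or `"mg_dl"`.
#' @return converted concentrations. Round trips are exact to within 1e-9
#'   relative error.
#' @export
#' @examples
#' convert_glucose_units(70, "mmol_l")   # 3.885...
#' convert_glucose_units(5.5, "mg_dl")   # 99.09
convert_glucose_units <- function(value, to = c("mmol_l", "mg_dl")) {
  to <- match.arg(to)
  if (any(!is.finite(value)) || any(value <= 0)) {
    stopf("glucose concentration must be positive and finite")
  }
  switch(to,
    mmol_l = value / GLUCOSE_MGDL_PER_MMOLL,
    mg_dl  = value * GLUCOSE_MGDL_PER_MMOLL
  )
}

#' Construct a biomarker panel
#'
#' One patient's five biomarker values, in canonical units (glucose mg/dL,
#' lactate mmol/L, pH, potassium mmol/L, pO2 mmHg).
#'
#' @param glucose,lactate,ph,potassium,po2 scalar measurements.
#' @return a named numeric vector of class `analyte_panel`.
#' @export
analyte_panel <- function(glucose, lactate, ph, potassium, po2) {
  x <- c(glucose = glucose, lactate = lactate, ph = ph,
         potassium = potassium, po2 = po2)
  structure(as.numeric(x), names = HISS_ANALYTES, class = "analyte_panel")
}

#' Validate a biomarker panel
#'
#' Checks the hard plausibility invariants: all five values present and
#' finite; glucose, potassium and pO2 strictly positive; lactate
#' non-negative; pH within the wide plausibility gate \[6.5, 8.0\] (much wider
#' than the normal band -- this gate rejects physically impossible values,
#' not abnormal ones). Validation never throws.
#'
#' @param panel an [analyte_panel()] or named numeric vector with the five
#'   analyte names.
#' @return character vector of violation descriptors; `character(0)` if the
#'   panel is valid.
#' @export
validate_panel <- function(panel) {
  v <- character(0)
  x <- unclass(panel)
  missing <- setdiff(HISS_ANALYTES, names(x))
  if (length(missing)) {
    return(sprintf("missing analyte: %s", missing))
  }
  x <- x[HISS_ANALYTES]
  bad <- !is.finite(x)
  if (any(bad)) v <- c(v, sprintf("%s is not finite", names(x)[bad]))
  ok <- is.finite(x)
  if (ok[["glucose"]] && x[["glucose"]] <= 0)
    v <- c(v, "glucose must be > 0")
  if (ok[["lactate"]] && x[["lactate"]] < 0)
    v <- c(v, "lactate must be >= 0")
  if (ok[["potassium"]] && x[["potassium"]] <= 0)
    v <- c(v, "potassium must be > 0")
  if (ok[["po2"]] && x[["po2"]] <= 0)
    v <- c(v, "po2 must be > 0")
  if (ok[["ph"]] && (x[["ph"]] < PH_GATE[1] || x[["ph"]] > PH_GATE[2]))
    v <- c(v, sprintf("ph outside plausibility gate [%.1f, %.1f]",
                      PH_GATE[1], PH_GATE[2]))
  v
}

#' Read or write a regime table as JSON
#'
#' The JSON document is keyed by analyte name, each entry carrying `low_max`
#' (upper edge of the low regime), `normal` (the closed band), and `high_min`
#' (lower edge of the high regime). The file shipped at
#' `system.file("extdata", "regime_table.json", package = "hisskit")`
#' reproduces the default bands.
#'
#' @param path file path.
#' @return for `read_regime_table`, a [regime_table()].
#' @export
read_regime_table <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  bands <- lapply(doc, function(e) as.numeric(e$normal))
  regime_table(bands)
}

#' @rdname read_regime_table
#' @param table a [regime_table()] to serialize.
#' @export
write_regime_table <- function(table, path) {
  doc <- lapply(seq_len(nrow(table)), function(i) {
    list(low_max = table$normal_lo[i],
         normal = c(table$normal_lo[i], table$normal_hi[i]),
         high_min = table$normal_hi[i],
         unit = table$unit[i])
  })
  names(doc) <- table$analyte
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
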