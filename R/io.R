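# CSV exchange format: patient id, the five biomarkers in canonical units,
# optional expert score columns D1..Dk, optional fused columns (mode,
# u0..u4). Undeclared scores are written and parsed as the literal "UD".

SFRP_COLUMNS <- c("patient_id", "glucose_mg_dl", "lactate_mmol_l", "ph",
                  "potassium_mmol_l", "po2_mmhg")

TABLE2_HEADERS <- c("Fictitious Patient", "Glucose (mg/dl)",
                    "Lactate (mmol/l)", "pH", "Potassium (mmol/l)",
                    "pO_2 (mmHg)")

#' Write a cohort (and optional scores / fused labels) to CSV
#'
#' @param cohort an `sfrp_cohort` or data.frame with the canonical columns.
#' @param path output path.
#' @param scores optional `score_matrix` (or plain integer matrix) appended
#'   as columns `D1..Dk`; `NA` scores are written as `"UD"` (undeclared).
#' @param fuse if `TRUE` and scores are present, append the majority-vote
#'   `mode` and possibility-label columns `u0..u4`.
#' @param reveal_seeds if `TRUE`, append the withheld `hidden_seed` column
#'   (testing only; the hidden seed never appears in standard exports).
#' @param table2_headers if `TRUE`, emit display-style biomarker headers
#'   instead of the canonical unit-bearing ones.
#' @return `path`, invisibly.
#' @export
write_sfrp_csv <- function(cohort, path, scores = NULL, fuse = FALSE,
                           reveal_seeds = FALSE, table2_headers = FALSE) {
  df <- as.data.frame(cohort)[, SFRP_COLUMNS]
  if (!is.null(scores)) {
    sm <- if (inherits(scores, "score_matrix")) scores$scores else scores
    sm_chr <- matrix(as.character(sm), nrow(sm), ncol(sm))
    sm_chr[is.na(sm_chr)] <- "UD"
    colnames(sm_chr) <- colnames(sm) %||% paste0("D", seq_len(ncol(sm)))
    df <- cbind(df, as.data.frame(sm_chr, stringsAsFactors = FALSE))
    if (fuse) {
      fused <- t(apply(sm, 1L, function(r) {
        c(majority_vote(r), possibility_labels(r))
      }))
      colnames(fused) <- c("mode", paste0("u", 0:4))
      df <- cbind(df, as.data.frame(fused))
    }
  }
  if (reveal_seeds && !is.null(attr(cohort, "hidden_seed"))) {
    df$hidden_seed <- attr(cohort, "hidden_seed")
  }
  if (table2_headers) {
    names(df)[seq_along(TABLE2_HEADERS)] <- TABLE2_HEADERS
  }
  utils::write.csv(df, path, row.names = FALSE, quote = table2_headers)
  invisible(path)
}

#' Read an SFRP-format CSV
#'
#' Parses the canonical header names (or their display-style equivalents),
#' preserves unknown columns, and treats `"UD"` score cells as missing.
#'
#' @param path input path.
#' @return a list of class `sfrp_dataset`: `records` (data.frame with the
#'   canonical columns), `scores` (integer matrix or `NULL`), `fused`
#'   (data.frame of `mode`/`u*` columns or `NULL`), `extra` (data.frame of
#'   preserved unknown columns or `NULL`).
#' @export
read_sfrp_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  nm <- names(raw)
  canon <- match(TABLE2_HEADERS, nm)
  if (any(!is.na(canon))) {
    nm[canon[!is.na(canon)]] <- SFRP_COLUMNS[!is.na(canon)]
    names(raw) <- nm
  }
  missing <- setdiff(SFRP_COLUMNS, nm)
  if (length(missing)) {
    stopf("missing mandatory column(s): %s", paste(missing, collapse = ", "))
  }
  parse_num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad)) {
      stopf("unparseable value '%s' in column %s, row %d",
            raw[[col]][bad[1]], col, bad[1])
    }
    v
  }
  records <- data.frame(patient_id = as.integer(parse_num("patient_id")))
  for (col in SFRP_COLUMNS[-1]) records[[col]] <- parse_num(col)

  score_cols <- grep("^D[0-9]+$", nm, value = TRUE)
  scores <- NULL
  if (length(score_cols)) {
    scores <- sapply(score_cols, function(col) {
      v <- raw[[col]]
      v[v %in% c("UD", "")] <- NA
      out <- suppressWarnings(as.integer(v))
      bad <- which(is.na(out) & !is.na(v))
      if (length(bad)) {
        stopf("unparseable score '%s' in column %s, row %d",
              v[bad[1]], col, bad[1])
      }
      out
    })
    scores <- matrix(scores, nrow = nrow(raw),
                     dimnames = list(NULL, score_cols))
  }
  fused_cols <- intersect(c("mode", paste0("u", 0:4)), nm)
  fused <- if (length(fused_cols)) {
    as.data.frame(lapply(raw[fused_cols], as.numeric))
  }
  known <- c(SFRP_COLUMNS, score_cols, fused_cols, "hidden_seed")
  extra_cols <- setdiff(nm, known)
  extra <- if (length(extra_cols)) raw[extra_cols]
  hidden <- if ("hidden_seed" %in% nm) as.integer(raw$hidden_seed)

  structure(list(records = records, scores = scores, fused = fused,
                 extra = extra, hidden_seed = hidden),
            class = "sfrp_dataset")
}

#' Read a run configuration
#'
#' JSON (or YAML, when the `yaml` package is installed) document with any of
#' the fields `n`, `rng_seed`, `class_weights`, `noise`, `profile` (path or
#' inline), `committee` (path), `probe_fraction`, `prbf`, `out_dir`. Missing
#' fields fall back to package defaults.
#'
#' @param path config file path (`.json`, `.yml` or `.yaml`).
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  doc <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("YAML configs need the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- list(
    n = doc$n %||% 100L,
    rng_seed = doc$rng_seed,
    class_weights = doc$class_weights %||% rep(1, 5),
    noise = if (!is.null(doc$noise)) do.call(noise_config, as.list(doc$noise))
            else noise_config(),
    profile = if (is.character(doc$profile)) read_severity_profile(doc$profile)
              else default_severity_profile(),
    committee = if (is.character(doc$committee)) read_committee(doc$committee)
                else default_committee(),
    probe_fraction = doc$probe_fraction %||% 0,
    prbf = if (!is.null(doc$prbf)) do.call(prbf_config, as.list(doc$prbf))
           else prbf_config()
  )
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(rapply(cfg, unclass, how = "replace"),
                        auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}
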