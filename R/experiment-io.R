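#' @name experiment-io
#' @title Transmission-chain experiment records
#'
#' @description
#' The experiment data are tables of transmission events.  Each record holds
#' one copying event: a participant in condition `condition` ("larger" or
#' "smaller" initial size of the image they resized), in chain `chain_id`,
#' at generation `generation` (1..10 in the canonical design), saw a target
#' image of height `target_size_cm` and produced a copy of height
#' `produced_size_cm`.  Heights are bounded by the 14.4 cm device screen;
#' widths are always 7/15 of the height and are never stored.  Within a
#' chain, the target at generation g equals the size produced at g - 1, and
#' the generation-1 target is the seed size (10 cm).
NULL

EXPERIMENT_COLUMNS <- c("condition", "chain_id", "generation",
                        "target_size_cm", "produced_size_cm")

#' Validate transmission-chain records
#'
#' Checks the structural invariants of a record table: required columns,
#' positive sizes within the screen bound, generation-1 targets equal to
#' the seed size, and chain linkage (each generation's target equals the
#' previous generation's produced size, to a relative tolerance that
#' absorbs rounding in externally produced files).
#'
#' @param records Data frame of transmission records (see
#'   [read_experiment_csv()] for the schema).
#' @param x0 Expected seed size in cm (generation-1 target).
#' @param screen_max Maximum possible produced size in cm.
#' @param tol Relative tolerance for the linkage and seed checks.
#' @param strict If `TRUE` (the default for data generated in-session),
#'   violations are errors; if `FALSE` (recommended when ingesting external
#'   files, where rounding may break exact linkage), they are warnings.
#' @return `records`, invisibly, if validation passes.
#' @export
validate_records <- function(records, x0 = 10, screen_max = 14.4,
                             tol = 1e-6, strict = TRUE) {
  missing_cols <- setdiff(EXPERIMENT_COLUMNS, names(records))
  if (length(missing_cols) > 0)
    stop("records are missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  complain <- if (strict) {
    function(...) stop(..., call. = FALSE)
  } else {
    function(...) warning(..., call. = FALSE)
  }
  for (col in c("target_size_cm", "produced_size_cm")) {
    if (!is.numeric(records[[col]]) || anyNA(records[[col]]))
      stop("column `", col, "` must be numeric with no missing values",
           call. = FALSE)
  }
  if (any(records$produced_size_cm <= 0) || any(records$target_size_cm <= 0))
    complain("non-positive sizes found")
  if (any(records$produced_size_cm > screen_max * (1 + tol)))
    complain("produced sizes exceed the screen bound of ", screen_max, " cm")
  if (!is.numeric(records$generation) ||
      any(records$generation != round(records$generation)) ||
      any(records$generation < 1))
    stop("`generation` must contain positive integers", call. = FALSE)

  split_idx <- split(seq_len(nrow(records)),
                     list(records$condition, records$chain_id), drop = TRUE)
  for (idx in split_idx) {
    chain <- records[idx[order(records$generation[idx])], ]
    g1 <- chain[chain$generation == 1, ]
    if (nrow(g1) == 1 && abs(g1$target_size_cm - x0) > tol * x0)
      complain(sprintf(
        "chain %s (%s): generation-1 target is %g cm, expected the seed %g cm",
        chain$chain_id[1], chain$condition[1], g1$target_size_cm, x0))
    if (nrow(chain) > 1) {
      prev <- chain$produced_size_cm[-nrow(chain)]
      curr <- chain$target_size_cm[-1]
      bad <- abs(curr - prev) > tol * pmax(prev, .Machine$double.eps)
      if (any(bad))
        complain(sprintf(
          "chain %s (%s): target at generation %s does not match the size produced at the previous generation",
          chain$chain_id[1], chain$condition[1],
          paste(chain$generation[-1][bad], collapse = ", ")))
    }
  }
  invisible(records)
}

#' Read transmission-chain experiment data from CSV
#'
#' Reads a CSV of transmission events into the canonical record schema
#' (columns `condition`, `chain_id`, `generation`, `target_size_cm`,
#' `produced_size_cm`), sorted by condition, chain and generation.  Files
#' with a different column layout — such as a supplementary data file from
#' another source — can be adapted with `col_map`, a named character vector
#' mapping canonical names to the names used in the file, or the path to a
#' YAML file holding such a mapping.  Unknown extra columns are dropped
#' with a warning.
#'
#' @param path Path to the CSV file.
#' @param col_map Optional column mapping, e.g.
#'   `c(produced_size_cm = "RightFinal")`, or a path to a YAML file of
#'   `canonical: original` pairs.
#' @param validate If `TRUE`, run [validate_records()] in non-strict mode
#'   (violations become warnings, since external files may be rounded).
#' @param ... Passed on to [validate_records()] (e.g. `x0`, `tol`).
#' @return A data frame of transmission records.
#' @export
read_experiment_csv <- function(path, col_map = NULL, validate = TRUE, ...) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.character(col_map) && length(col_map) == 1L && is.null(names(col_map))) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a column-mapping file requires the `yaml` package",
           call. = FALSE)
    col_map <- unlist(yaml::read_yaml(col_map))
  }
  if (!is.null(col_map)) {
    for (canonical in names(col_map)) {
      orig <- col_map[[canonical]]
      if (!orig %in% names(df))
        stop("column mapping refers to `", orig,
             "`, which is not in the file", call. = FALSE)
      names(df)[names(df) == orig] <- canonical
    }
  }
  missing_cols <- setdiff(EXPERIMENT_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), EXPERIMENT_COLUMNS)
  if (length(extra) > 0) {
    warning("ignoring unrecognised column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
    df <- df[EXPERIMENT_COLUMNS]
  }
  for (col in c("target_size_cm", "produced_size_cm")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
      stop("non-numeric value in `", col, "` at data row ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  df <- df[order(df$condition, df$chain_id, df$generation), ,
           drop = FALSE]
  rownames(df) <- NULL
  if (validate) validate_records(df, strict = FALSE, ...)
  df
}

#' Write transmission-chain experiment data to CSV
#'
#' Records are validated (strictly) before anything is written, then saved
#' with the canonical column order so that
#' `read_experiment_csv(write_experiment_csv(x))` restores `x` exactly.
#'
#' @param records Data frame of transmission records.
#' @param path Output path.
#' @param ... Passed on to [validate_records()].
#' @return `path`, invisibly.
#' @export
write_experiment_csv <- function(records, path, ...) {
  if (nrow(records) > 0) validate_records(records, strict = TRUE, ...)
  missing_cols <- setdiff(EXPERIMENT_COLUMNS, names(records))
  if (length(missing_cols) > 0)
    stop("records are missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(records[EXPERIMENT_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Per-event copying-error ratios
#'
#' The copying error of a single transmission event is the produced size
#' divided by the target size — the realized error ratio `eps` of the ACE
#' model.  Under the model these ratios are i.i.d. `N(1, sigma^2)`.
#'
#' @param records Data frame of transmission records (validated first).
#' @param ... Passed on to [validate_records()].
#' @return A data frame with columns `condition`, `chain_id`, `generation`,
#'   `ratio`, one row per transmission event.
#' @export
compute_copying_errors <- function(records, ...) {
  validate_records(records, strict = TRUE, ...)
  data.frame(condition = records$condition,
             chain_id = records$chain_id,
             generation = records$generation,
             ratio = records$produced_size_cm / records$target_size_cm)
}
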