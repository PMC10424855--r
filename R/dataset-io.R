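# On-disk dataset format: comma-separated, UTF-8, '.' decimal, mandatory
# header, '#' comment lines ignored.  Tristimulus values (not u'v'Y) are
# the on-disk unit since every transform starts from XYZ; chromaticity is
# always derived.

CC_REQUIRED_COLS <- c("pair_id", "condition_id", "kind", "phase",
                      "X", "Y", "Z", "illum_X", "illum_Y", "illum_Z")
CC_OPTIONAL_COLS <- c("prev_illum_X", "prev_illum_Y", "prev_illum_Z")

#' Validate a data frame as a corresponding-color dataset
#'
#' Checks the column schema, record kinds (`"pair"` records need exactly
#' one phase-1 and one phase-2 row per `pair_id`; `"neutral"` records
#' exactly one row), and that all tristimulus fields are finite and
#' non-negative.
#'
#' @param df A data frame with the dataset columns (see [read_dataset()]).
#' @return The validated data frame with class `cc_dataset` prepended.
#' @export
as_cc_dataset <- function(df) {
  if (inherits(df, "cc_dataset")) return(df)
  if (!is.data.frame(df)) stop_schema("dataset must be a data frame")
  missing_cols <- setdiff(CC_REQUIRED_COLS, names(df))
  if (length(missing_cols) > 0L)
    stop_schema("missing dataset columns: %s",
                paste(missing_cols, collapse = ", "))
  bad_kind <- !df$kind %in% c("pair", "neutral")
  if (any(bad_kind))
    stop_schema("unknown kind '%s' (row %d)", df$kind[which(bad_kind)[1L]],
                which(bad_kind)[1L])
  num_cols <- intersect(c("X", "Y", "Z", "illum_X", "illum_Y", "illum_Z",
                          CC_OPTIONAL_COLS), names(df))
  for (cc in num_cols) {
    v <- df[[cc]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v < 0))
      stop_schema("column %s must be finite and non-negative (row %d)",
                  cc, which(!is.finite(df[[cc]]) | df[[cc]] < 0)[1L])
  }
  pr <- df[df$kind == "pair", , drop = FALSE]
  if (nrow(pr) > 0L) {
    if (any(!pr$phase %in% c(1L, 2L)))
      stop_schema("pair records must have phase 1 or 2")
    tab <- table(pr$pair_id, pr$phase)
    bad <- rownames(tab)[rowSums(tab != 1L) > 0L | ncol(tab) < 2L]
    if (ncol(tab) < 2L) bad <- rownames(tab)
    if (length(bad) > 0L)
      stop_schema("pair_id '%s' lacks exactly one phase-1 and one phase-2 row",
                  bad[1L])
  }
  nt <- df[df$kind == "neutral", , drop = FALSE]
  if (nrow(nt) > 0L && anyDuplicated(nt$pair_id))
    stop_schema("neutral pair_id '%s' appears more than once",
                nt$pair_id[anyDuplicated(nt$pair_id)])
  class(df) <- c("cc_dataset", class(df))
  df
}

#' Read a corresponding-color dataset
#'
#' Reads the delimited schema written by [write_dataset()] and the
#' synthetic generators: columns `pair_id, condition_id, kind, phase, X, Y,
#' Z, illum_X, illum_Y, illum_Z` (plus optional `prev_illum_*`), comma
#' separated with a mandatory header; `#` lines are comments.  Schema
#' errors name the offending 1-based file line.  A ground-truth sidecar
#' `<path>.json`, if present, is attached as the `ground_truth` attribute.
#'
#' @param path File path.
#' @return A `cc_dataset`, row order preserved.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop_schema("no such file: %s", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  line_no <- which(keep)
  if (length(lines) < 2L)
    stop_schema("%s: need a header line and at least one data row", path)
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        stringsAsFactors = FALSE)
  data_lines <- line_no[-1L]
  out <- tryCatch(as_cc_dataset(df), error = function(e) {
    row <- regmatches(conditionMessage(e),
                      regexpr("(?<=\\(row )[0-9]+", conditionMessage(e),
                              perl = TRUE))
    extra <- if (length(row) == 1L)
      sprintf(" [file line %d]", data_lines[as.integer(row)]) else ""
    stop_schema("%s: %s%s", path, conditionMessage(e), extra)
  })
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(out, "ground_truth") <- jsonlite::fromJSON(sidecar)
  out
}

#' Write a corresponding-color dataset
#'
#' Values are written with 15 significant digits so a write/read round trip
#' is lossless at 12 significant digits.  When the dataset carries a
#' `ground_truth` attribute (synthetic data), it is written to a sidecar
#' `<path>.json` for test harnesses.
#'
#' @param dataset A `cc_dataset`.
#' @param path Output file path.
#' @param sidecar Write the ground-truth sidecar if available (default
#'   `TRUE`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, sidecar = TRUE) {
  dataset <- as_cc_dataset(dataset)
  df <- as.data.frame(dataset)
  num <- vapply(df, is.numeric, logical(1L)) & names(df) != "phase"
  df[num] <- lapply(df[num], function(x) format(x, digits = 15,
                                                scientific = FALSE,
                                                trim = TRUE))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# wgmcat corresponding-color dataset", con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  gt <- attr(dataset, "ground_truth")
  if (sidecar && !is.null(gt))
    writeLines(jsonlite::toJSON(gt, auto_unbox = TRUE, digits = NA),
               paste0(path, ".json"))
  invisible(path)
}
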