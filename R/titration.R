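#' Titration dataset
#'
#' Tidy table of plate-reader measurements over an inducer dilution grid:
#' one row per (concentration A, concentration B, replicate) with raw
#' fluorescence and culture density (OD600). Blank (medium-only) readings are
#' carried as metadata and subtracted by [normalize_od()].
#'
#' @param conc_a,conc_b Inducer concentrations, mol/L, `>= 0`.
#' @param replicate Replicate index, integers starting at 1.
#' @param fluorescence Raw fluorescence (au).
#' @param od600 Optical density at 600 nm, > 0.
#' @param device Name of the device or gate measured.
#' @param blank_fluorescence,blank_od Blank readings (medium + antibiotic).
#' @param normalized Logical: has [normalize_od()] been applied?
#' @return A `data.frame` of class `titration_dataset` with attributes
#'   `device`, `blank_fluorescence`, `blank_od`, `normalized`.
#' @export
titration_dataset <- function(conc_a, conc_b, replicate, fluorescence, od600,
                              device = "unnamed",
                              blank_fluorescence = 0, blank_od = 0,
                              normalized = FALSE) {
  n <- max(length(conc_a), length(conc_b), length(replicate),
           length(fluorescence), length(od600))
  df <- data.frame(conc_a = rep_len(conc_a, n), conc_b = rep_len(conc_b, n),
                   replicate = as.integer(rep_len(replicate, n)),
                   fluorescence = rep_len(fluorescence, n),
                   od600 = rep_len(od600, n))
  if (any(df$conc_a < 0) || any(df$conc_b < 0))
    stop("inducer concentrations must be >= 0.", call. = FALSE)
  if (any(df$replicate < 1L))
    stop("replicate ids must be integers >= 1.", call. = FALSE)
  reps <- sort(unique(df$replicate))
  if (!identical(reps, seq_len(length(reps))))
    stop("replicate ids must be contiguous from 1.", call. = FALSE)
  if (!normalized && any(df$od600 <= 0))
    stop("od600 must be > 0.", call. = FALSE)
  structure(df, device = device, blank_fluorescence = blank_fluorescence,
            blank_od = blank_od, normalized = normalized,
            class = c("titration_dataset", "data.frame"))
}

#' OD-normalise a titration dataset
#'
#' Converts raw plate-reader readings to per-cell-density output:
#' `fluorescence' = (fluorescence - blank_fluorescence) / (od600 - blank_od)`.
#' Rows whose OD600 does not exceed the blank OD cannot be normalised; they
#' are removed with a warning naming the offending rows (never silently).
#'
#' @param raw A [titration_dataset()] with blank metadata set.
#' @return A normalised `titration_dataset` (attribute `normalized = TRUE`);
#'   the `od600` column is retained for reference.
#' @export
normalize_od <- function(raw) {
  stopifnot(inherits(raw, "titration_dataset"))
  if (isTRUE(attr(raw, "normalized")))
    stop("dataset is already OD-normalised.", call. = FALSE)
  bf <- attr(raw, "blank_fluorescence")
  bo <- attr(raw, "blank_od")
  if (is.null(bf) || is.null(bo))
    stop("blank_fluorescence and blank_od metadata are required.", call. = FALSE)
  bad <- which(raw$od600 <= bo)
  if (length(bad)) {
    warning(sprintf(
      "%d row(s) have od600 <= blank_od and were rejected (rows: %s).",
      length(bad), paste(utils::head(bad, 10L), collapse = ", ")),
      call. = FALSE)
    raw <- raw[-bad, , drop = FALSE]
  }
  out <- raw
  out$fluorescence <- (raw$fluorescence - bf) / (raw$od600 - bo)
  attr(out, "normalized") <- TRUE
  attr(out, "device") <- attr(raw, "device")
  attr(out, "blank_fluorescence") <- bf
  attr(out, "blank_od") <- bo
  class(out) <- c("titration_dataset", "data.frame")
  out
}

#' Read / write titration CSV files
#'
#' CSV dialect: header `conc_a_M,conc_b_M,replicate,fluorescence_au,od600`,
#' UTF-8, '.' decimal separator. Blank readings and the device name travel in
#' a JSON sidecar (`<path>.json`) so the CSV stays purely tabular.
#'
#' @param data A [titration_dataset()].
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_titration_csv` returns `path` invisibly;
#'   `read_titration_csv` returns a [titration_dataset()].
#' @export
write_titration_csv <- function(data, path) {
  stopifnot(inherits(data, "titration_dataset"))
  df <- data.frame(conc_a_M = data$conc_a, conc_b_M = data$conc_b,
                   replicate = data$replicate,
                   fluorescence_au = data$fluorescence, od600 = data$od600)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(device = attr(data, "device"),
               blank_fluorescence = attr(data, "blank_fluorescence"),
               blank_od = attr(data, "blank_od"),
               normalized = isTRUE(attr(data, "normalized")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("conc_a_M", "conc_b_M", "replicate", "fluorescence_au", "od600")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("malformed titration CSV '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cl in needed) {
    if (!is.numeric(df[[cl]]))
      stop("malformed titration CSV '", path, "': column ", cl,
           " is not numeric (first bad row: ",
           which(is.na(suppressWarnings(as.numeric(df[[cl]]))))[1L], ").",
           call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  else list(device = "unnamed", blank_fluorescence = 0, blank_od = 0,
            normalized = FALSE)
  titration_dataset(df$conc_a_M, df$conc_b_M, df$replicate,
                    df$fluorescence_au, df$od600,
                    device = meta$device,
                    blank_fluorescence = meta$blank_fluorescence,
                    blank_od = meta$blank_od,
                    normalized = isTRUE(meta$normalized))
}
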