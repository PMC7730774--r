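#' Balanced agreement data
#'
#' Construct a validated balanced agreement dataset: `a` subjects each measured
#' by `b` observers, every (subject, observer) pair contributing exactly `c`
#' replicate measurements. All estimation in this package assumes this balance,
#' so violations are hard errors rather than warnings.
#'
#' Replicates are treated as exchangeable repeated measurements: when a
#' replicate label is supplied it is kept for provenance, but no formula in the
#' package depends on it. Duplicate (subject, observer, replicate) triples are
#' rejected, because silently aggregating them would change `c`.
#'
#' @param subject vector of subject identifiers (coerced to character).
#' @param observer vector of observer identifiers (coerced to character).
#' @param value numeric vector of measurements; must be finite.
#' @param replicate optional replicate labels. If `NULL`, replicate indices are
#'   synthesized in order of appearance within each subject-by-observer cell.
#' @param unit optional free-text measurement unit (e.g. `"mm"`), used for axis
#'   and report labels only.
#'
#' @return An object of class `agreement_data`: a data frame with columns
#'   `subject`, `observer`, `replicate`, `value`, and attributes `dims`
#'   (named vector `a`, `b`, `c`) and `unit`.
#'
#' @examples
#' d <- agreement_data(subject  = c(1, 1, 2, 2),
#'                     observer = c("X", "Y", "X", "Y"),
#'                     value    = c(1, 2, 3, 5))
#' dims(d)
#' @seealso [read_agreement_table()], [loam()], [observer_summary()]
#' @export
agreement_data <- function(subject, observer, value, replicate = NULL,
                           unit = NULL) {
  n <- length(value)
  if (length(subject) != n || length(observer) != n)
    stop("'subject', 'observer' and 'value' must have equal length")
  if (!is.numeric(value))
    stop("'value' must be numeric")
  if (anyNA(value) || any(!is.finite(value)))
    stop("all measurement values must be finite (no NA/NaN/Inf)")
  subject <- as.character(subject)
  observer <- as.character(observer)
  if (anyNA(subject) || anyNA(observer))
    stop("subject and observer identifiers must not be missing")

  if (is.null(replicate)) {
    cell <- paste(subject, observer, sep = "\r")
    replicate <- as.character(stats::ave(seq_len(n), cell, FUN = seq_along))
  } else {
    if (length(replicate) != n)
      stop("'replicate' must have the same length as 'value'")
    replicate <- as.character(replicate)
  }
  if (anyDuplicated(paste(subject, observer, replicate, sep = "\r")))
    stop("duplicate (subject, observer, replicate) triples are not allowed")

  counts <- table(subject, observer)
  cc <- unique(as.vector(counts))
  if (length(cc) != 1L) {
    bad <- which(counts != stats::median(as.vector(counts)), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "unbalanced design: subject '%s', observer '%s' has %d measurement(s) but other cells differ",
      rownames(counts)[bad[1]], colnames(counts)[bad[2]],
      counts[bad[1], bad[2]]))
  }
  a <- nrow(counts)
  b <- ncol(counts)
  if (a < 2L) stop("need at least 2 subjects")
  if (b < 2L) stop("need at least 2 observers")
  if (cc < 1L) stop("need at least 1 replicate per cell")

  out <- data.frame(subject = subject, observer = observer,
                    replicate = replicate, value = as.numeric(value),
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject, out$observer), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            dims = c(a = a, b = b, c = as.integer(cc)),
            unit = unit,
            class = c("agreement_data", "data.frame"))
}

#' Design dimensions of an agreement dataset
#'
#' @param x an [agreement_data] object.
#' @return Named integer vector with elements `a` (subjects), `b` (observers)
#'   and `c` (replicates per subject-by-observer cell).
#' @export
dims <- function(x) {
  stopifnot(inherits(x, "agreement_data"))
  attr(x, "dims")
}

#' @export
print.agreement_data <- function(x, ...) {
  d <- attr(x, "dims")
  unit <- attr(x, "unit")
  cat(sprintf("Balanced agreement data: %d subjects x %d observers x %d replicate(s)%s\n",
              d["a"], d["b"], d["c"],
              if (!is.null(unit)) paste0(" [", unit, "]") else ""))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... (%d rows total)\n", nrow(x)))
  invisible(x)
}

#' Read a balanced agreement table from delimited text
#'
#' Reads a long-format CSV/TSV (one measurement per row) and validates it as a
#' balanced agreement dataset. The delimiter is auto-detected among comma, tab
#' and semicolon from the header line; decimal points are `"."` only.
#'
#' @param file path to a delimited text file with a header row, or a
#'   connection.
#' @param columns named list or character vector mapping roles to column names;
#'   must contain `subject`, `observer` and `value`, and may contain
#'   `replicate`. When no replicate column is mapped, replicate indices are
#'   synthesized in order of appearance within each cell.
#' @param unit optional measurement unit label.
#' @param sep field delimiter; `NULL` (default) auto-detects.
#'
#' @return An [agreement_data] object.
#' @examples
#' f <- system.file("extdata", "synthetic_aorta_oto.csv", package = "loamci")
#' d <- read_agreement_table(f,
#'        columns = c(subject = "image", observer = "radiologist",
#'                    value = "diameter", replicate = "take"),
#'        unit = "mm")
#' dims(d)
#' @export
read_agreement_table <- function(file, columns, unit = NULL, sep = NULL) {
  columns <- as.list(columns)
  needed <- c("subject", "observer", "value")
  if (!all(needed %in% names(columns)))
    stop("'columns' must map at least: ", paste(needed, collapse = ", "))

  if (is.null(sep)) {
    header <- readLines(file, n = 1L)
    if (length(header) == 0L) stop("input file is empty")
    seps <- c("," = ",", "\t" = "\t", ";" = ";")
    hits <- vapply(seps, function(s)
      length(strsplit(header, s, fixed = TRUE)[[1]]), integer(1))
    sep <- seps[[which.max(hits)]]
  }

  tab <- utils::read.table(file, header = TRUE, sep = sep, dec = ".",
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)
  if (nrow(tab) == 0L) stop("input file contains no data rows")
  for (role in names(columns)) {
    if (!columns[[role]] %in% names(tab))
      stop(sprintf("column '%s' (mapped to role '%s') not found in input",
                   columns[[role]], role))
  }
  raw <- tab[[columns$value]]
  val <- suppressWarnings(as.numeric(raw))
  if (anyNA(val)) {
    bad <- which(is.na(val))[1]
    stop(sprintf("non-numeric measurement value '%s' at data row %d",
                 raw[bad], bad))
  }
  agreement_data(subject = tab[[columns$subject]],
                 observer = tab[[columns$observer]],
                 value = val,
                 replicate = if (!is.null(columns$replicate))
                   tab[[columns$replicate]] else NULL,
                 unit = unit)
}

#' Write an agreement dataset to CSV
#'
#' Round-trips through [read_agreement_table()] bit-identically on values and
#' labels (values are written with full `.Machine$double` precision).
#'
#' @param x an [agreement_data] object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_agreement_table <- function(x, file) {
  stopifnot(inherits(x, "agreement_data"))
  df <- as.data.frame(x)
  df$value <- format(df$value, digits = 17, scientific = FALSE, trim = TRUE)
  utils::write.table(df, file, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Per-observer (or per-subject) empirical summaries
#'
#' Empirical mean and sample standard deviation of the measurements conditional
#' on observer (or on subject). Inspecting per-observer means flags observers
#' who systematically measure high or low; per-observer SDs and per-subject SDs
#' are a first check of the homoscedasticity assumed by the two-way random
#' effects model.
#'
#' @param data an [agreement_data] object.
#' @param by `"observer"` (default) or `"subject"`.
#' @return A data frame with one row per level: columns `observer` (or
#'   `subject`), `n`, `mean`, `sd`.
#' @examples
#' d <- agreement_data(c(1, 1, 2, 2), c("X", "Y", "X", "Y"), c(1, 2, 3, 5))
#' observer_summary(d)
#' observer_summary(d, by = "subject")
#' @export
observer_summary <- function(data, by = c("observer", "subject")) {
  stopifnot(inherits(data, "agreement_data"))
  by <- match.arg(by)
  g <- data[[by]]
  lev <- unique(g)
  out <- data.frame(
    level = lev,
    n = as.integer(tapply(data$value, g, length)[lev]),
    mean = as.numeric(tapply(data$value, g, mean)[lev]),
    sd = as.numeric(tapply(data$value, g, stats::sd)[lev]),
    stringsAsFactors = FALSE)
  names(out)[1] <- by
  rownames(out) <- NULL
  out
}

#' @export
summary.agreement_data <- function(object, ...) {
  structure(list(dims = attr(object, "dims"),
                 unit = attr(object, "unit"),
                 grand_mean = mean(object$value),
                 by_observer = observer_summary(object, "observer"),
                 by_subject = observer_summary(object, "subject")),
            class = "summary.agreement_data")
}

#' @export
print.summary.agreement_data <- function(x, digits = 3, ...) {
  u <- if (!is.null(x$unit)) paste0(" ", x$unit) else ""
  cat(sprintf("Balanced agreement data: a = %d subjects, b = %d observers, c = %d replicate(s)\n",
              x$dims["a"], x$dims["b"], x$dims["c"]))
  cat(sprintf("Grand mean: %s%s\n\n", format(x$grand_mean, digits = digits), u))
  cat("Conditional on observer:\n")
  print(x$by_observer, digits = digits, row.names = FALSE)
  invisible(x)
}
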