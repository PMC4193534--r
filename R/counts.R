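#' Observed counts of a two-stage screening study
#'
#' Container for the seven-number count summary of a two-test screening
#' design in which every subject positive on at least one test is verified
#' by a gold standard and double negatives are never verified.
#'
#' Stage one cross-classifies all \code{n} subjects by the two test results;
#' stage two splits the verified joint positives into diseased
#' (\code{a11}) and non-diseased (\code{a10}), while the unverified total
#' \code{a0} equals the double-negative count \code{x00}.
#'
#' @param x11,x10,x01,x00 Nonnegative integer counts of the stage-one test
#'   patterns (T1,T2) = (+,+), (+,-), (-,+), (-,-).
#' @param a11 Verified diseased among joint positives.
#' @param a10 Verified non-diseased among joint positives.
#' @param a0 Unverified joint negatives; must equal \code{x00}. Defaults to
#'   \code{x00}.
#' @return An object of class \code{screening_counts}: a named list with the
#'   seven cells plus the total \code{n}.
#' @examples
#' counts <- screening_counts(x11 = 39, x10 = 91, x01 = 237, x00 = 5360,
#'                            a11 = 29, a10 = 338)
#' counts
#' @export
screening_counts <- function(x11, x10, x01, x00, a11, a10, a0 = x00) {
  cells <- c(x11 = x11, x10 = x10, x01 = x01, x00 = x00,
             a11 = a11, a10 = a10, a0 = a0)
  if (anyNA(cells) || !is.numeric(cells))
    stop("all counts must be non-missing numbers")
  if (any(cells < 0))
    stop("invariant violated: all counts must be >= 0")
  if (any(cells != round(cells)))
    stop("all counts must be whole numbers")
  n <- x11 + x10 + x01 + x00
  if (a11 + a10 != x11 + x10 + x01)
    stop("invariant violated: a11 + a10 must equal x11 + x10 + x01 ",
         "(all joint positives are verified)")
  if (a0 != x00)
    stop("invariant violated: a0 must equal x00 ",
         "(unverified subjects are exactly the double negatives)")
  structure(list(x11 = x11, x10 = x10, x01 = x01, x00 = x00,
                 a11 = a11, a10 = a10, a0 = a0, n = n),
            class = "screening_counts")
}

#' @export
print.screening_counts <- function(x, ...) {
  cat("Two-stage screening counts (n =", x$n, ")\n")
  cat("  stage one:  x11 =", x$x11, " x10 =", x$x10,
      " x01 =", x$x01, " x00 =", x$x00, "\n")
  cat("  stage two:  a11 =", x$a11, " a10 =", x$a10, " a0 =", x$a0, "\n")
  invisible(x)
}

#' @export
as.data.frame.screening_counts <- function(x, ...) {
  data.frame(x11 = x$x11, x10 = x$x10, x01 = x$x01, x00 = x$x00,
             a11 = x$a11, a10 = x$a10, a0 = x$a0, n = x$n)
}

#' Colorectal cancer screening counts
#'
#' The worked-example data: 5727 subjects aged 40-59 screened for colorectal
#' cancer or large adenomas with rehydrated Hemoccult (test 1) and
#' RPHA-Hemeselect (test 2); subjects positive on either test underwent
#' pancolonoscopy (the gold standard), double negatives were not verified.
#'
#' @return A \code{\link{screening_counts}} object.
#' @examples
#' colorectal_counts()
#' @export
colorectal_counts <- function() {
  screening_counts(x11 = 39, x10 = 91, x01 = 237, x00 = 5360,
                   a11 = 29, a10 = 338)
}

#' Read and write screening counts
#'
#' JSON files carry the keys \code{x11, x10, x01, x00, a11, a10, a0};
#' CSV files are a header line plus one row of values with the same column
#' names. \code{n} is recomputed and cross-checked on read. Validation
#' errors name the violated invariant.
#'
#' @param path File path; format is chosen by extension (\code{.json} or
#'   \code{.csv}) unless \code{format} is given.
#' @param format \code{"json"} or \code{"csv"}.
#' @return \code{read_counts} returns a \code{\link{screening_counts}};
#'   \code{write_counts} returns \code{path} invisibly.
#' @export
read_counts <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  rec <- if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    as.list(utils::read.csv(path)[1L, , drop = FALSE])
  }
  need <- c("x11", "x10", "x01", "x00", "a11", "a10")
  missing <- setdiff(need, names(rec))
  if (length(missing))
    stop("counts file is missing fields: ", paste(missing, collapse = ", "))
  counts <- screening_counts(x11 = rec$x11, x10 = rec$x10, x01 = rec$x01,
                             x00 = rec$x00, a11 = rec$a11, a10 = rec$a10,
                             a0 = if (is.null(rec$a0)) rec$x00 else rec$a0)
  if (!is.null(rec$n) && rec$n != counts$n)
    stop("invariant violated: x11 + x10 + x01 + x00 must equal n")
  counts
}

#' @rdname read_counts
#' @param counts A \code{\link{screening_counts}} object.
#' @export
write_counts <- function(counts, path, format = c("auto", "json", "csv")) {
  stopifnot(inherits(counts, "screening_counts"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "json") {
    jsonlite::write_json(unclass(counts), path, auto_unbox = TRUE)
  } else {
    utils::write.csv(as.data.frame(counts), path, row.names = FALSE)
  }
  invisible(path)
}
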