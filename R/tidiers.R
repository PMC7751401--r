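#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration table
#'
#' Returns the table entries as a tibble with one row per calibration key
#' (caller combination, SV type, size class).
#'
#' @param x An `sv_calibration` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.sv_calibration <- function(x, ...) x$entries

#' @rdname tidy.sv_calibration
#' @exportS3Method generics::glance
glance.sv_calibration <- function(x, ...) {
  tibble::tibble(
    n_entries = nrow(x$entries),
    n_combinations = dplyr::n_distinct(x$entries$combination),
    n_calls = sum(x$entries$n_calls),
    mean_precision = if (nrow(x$entries) > 0) {
      stats::weighted.mean(x$entries$precision, x$entries$n_calls)
    } else NA_real_,
    default_qv = x$default_qv,
    provenance = x$provenance
  )
}

#' Tidy a benchmark report
#'
#' One row per size class plus an `OVERALL` row, with TP/FP/FN counts and
#' precision, recall and F1.
#'
#' @param x An `sv_benchmark` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.sv_benchmark <- function(x, ...) {
  overall <- tibble::tibble(size_bin = "OVERALL", tp = x$tp, fp = x$fp,
                            fn = x$fn, precision = x$precision,
                            recall = x$recall, f1 = x$f1)
  if (is.null(x$per_stratum)) overall
  else dplyr::bind_rows(x$per_stratum, overall)
}

#' @rdname tidy.sv_benchmark
#' @exportS3Method generics::glance
glance.sv_benchmark <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn,
                 precision = x$precision, recall = x$recall, f1 = x$f1)
}
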