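#' Phred-encode an empirical precision
#'
#' The consensus quality value is the Phred encoding of the category's
#' empirical false-discovery rate: `QV = -10 * log10(1 - precision)`,
#' capped at `cap` (so a category with precision 1 receives the cap, 40 by
#' default, even if the observed precision is higher than the cap implies).
#' Rounded to 2 decimal places.
#'
#' @param precision Empirical precision in \[0, 1\] (vectorized).
#' @param cap Maximum QV. Default 40.
#' @return Numeric QV in \[0, cap\].
#' @export
#' @examples
#' phred_quality(c(0, 0.9, 0.999, 1))
phred_quality <- function(precision, cap = 40) {
  if (any(is.na(precision)) || any(precision < 0 | precision > 1)) {
    stop("precision must lie in [0, 1]", call. = FALSE)
  }
  qv <- ifelse(precision >= 1, cap, pmin(cap, -10 * log10(1 - precision)))
  round(qv, 2)
}

#' Build a quality-calibration table from consensus calls and a truth set
#'
#' Labels each consensus call true or false positive by matching against the
#' truth set (see [match_calls()]), then groups calls by calibration key —
#' the combination of supporting callers, the SV type, and the size class
#' (deletion-like events are stratified into 50–300, 300–1000 and >1000 bp;
#' insertions form a single bin). Each key observed on at least
#' `min_category_count` calls yields an entry with its empirical precision
#' and the Phred quality [phred_quality()] of that precision; smaller
#' categories are omitted. Breakends cannot be matched against the truth
#' protocol and are excluded from table building.
#'
#' @param consensus Consensus tibble from [merge_callsets()].
#' @param truth Truth calls tibble.
#' @param match_params A [match_params()] object.
#' @param min_category_count Minimum calls per key for the key to be
#'   retained; default 3 (categories with two or fewer calls are dropped).
#' @param default_qv Quality for keys absent from the table. Default 0, so
#'   unknown combinations sort last.
#' @param provenance Free-text description of the truth set.
#' @return An object of class `sv_calibration`: entries tibble plus
#'   `default_qv` and `provenance`.
#' @export
build_calibration_table <- function(consensus, truth,
                                    match_params = NULL,
                                    min_category_count = 3L,
                                    default_qv = 0,
                                    provenance = "unspecified truth set") {
  if (is.null(match_params)) match_params <- svensemble::match_params()
  if (nrow(consensus) == 0) {
    warning("no consensus calls; returning an empty calibration table",
            call. = FALSE)
    return(new_calibration(empty_calibration_entries(), default_qv, provenance))
  }
  cand <- consensus[consensus$svtype != "BND", , drop = FALSE]
  rep <- match_calls(cand, truth, match_params)
  lab <- dplyr::mutate(
    cand,
    tp = seq_len(nrow(cand)) %in% rep$matches$cand_idx,
    size_bin = size_bin(.data$svlen, .data$svtype)
  )
  entries <- lab |>
    dplyr::group_by(combination = .data$support, svtype = .data$svtype,
                    size_bin = .data$size_bin) |>
    dplyr::summarise(n_calls = dplyr::n(),
                     precision = mean(.data$tp), .groups = "drop") |>
    dplyr::filter(.data$n_calls >= min_category_count) |>
    dplyr::mutate(qv = phred_quality(.data$precision)) |>
    dplyr::arrange(.data$combination, .data$svtype, .data$size_bin)
  new_calibration(entries, default_qv, provenance)
}

new_calibration <- function(entries, default_qv, provenance) {
  structure(list(entries = entries,
                 default_qv = as.numeric(default_qv),
                 provenance = provenance),
            class = "sv_calibration")
}

empty_calibration_entries <- function() {
  tibble::tibble(combination = character(), svtype = character(),
                 size_bin = character(), n_calls = integer(),
                 precision = numeric(), qv = numeric())
}

#' @export
print.sv_calibration <- function(x, ...) {
  cat("SV quality calibration table:", nrow(x$entries), "entries",
      sprintf("(default QV %.2f)\n", x$default_qv))
  cat("Truth set:", x$provenance, "\n")
  print(x$entries, ...)
  invisible(x)
}

#' Assign calibrated quality values to consensus calls
#'
#' Each call's QV comes from the table entry whose key matches its
#' supporting-caller combination, SV type and size class. Types absent from
#' the truth protocol (inversions, duplications, breakends) fall back to
#' the deletion-trained entry at the same combination and size class — the
#' ruleset learned on deletions is applied to types for which no benchmark
#' exists. Keys absent from both routes receive the table's `default_qv`;
#' lookup never fails.
#'
#' @param consensus Consensus tibble.
#' @param table An `sv_calibration` object.
#' @return The consensus tibble with `qv` filled in.
#' @export
assign_qualities <- function(consensus, table) {
  stopifnot(inherits(table, "sv_calibration"))
  if (nrow(consensus) == 0) return(consensus)
  e <- dplyr::select(table$entries, "combination", "svtype", "size_bin",
                     .table_qv = "qv")
  key <- consensus |>
    dplyr::select("support", "svtype", "svlen") |>
    dplyr::mutate(.bin = size_bin(.data$svlen, .data$svtype))
  exact <- dplyr::left_join(
    key, e,
    by = c(support = "combination", svtype = "svtype", .bin = "size_bin")
  )$.table_qv
  fallback <- dplyr::left_join(
    dplyr::mutate(key, .ft = "DEL"), e,
    by = c(support = "combination", .ft = "svtype", .bin = "size_bin")
  )$.table_qv
  consensus$qv <- dplyr::coalesce(exact, fallback, table$default_qv)
  consensus
}

#' Filter consensus calls by quality value
#'
#' Keeps calls whose QV is strictly greater than the threshold (the
#' filtering rule used for platform-concordance analyses is `QV > 3`).
#' Order is preserved.
#'
#' @param consensus Quality-annotated consensus tibble.
#' @param threshold Strict lower bound on QV.
#' @return The filtered tibble.
#' @export
filter_by_quality <- function(consensus, threshold) {
  consensus[!is.na(consensus$qv) & consensus$qv > threshold, , drop = FALSE]
}

#' Write a calibration table to a tab-separated file
#'
#' Columns: `combination` (comma-joined sorted caller names), `svtype`,
#' `size_bin`, `n_calls`, `precision`, `qv`. `#`-prefixed header lines
#' carry the provenance and default QV, so the file round-trips through
#' [read_calibration_table()] bit-exactly.
#'
#' @param table An `sv_calibration` object.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_calibration_table <- function(table, path) {
  stopifnot(inherits(table, "sv_calibration"))
  hdr <- c(paste0("# provenance: ", table$provenance),
           paste0("# default_qv: ", sprintf("%.17g", table$default_qv)),
           paste("combination", "svtype", "size_bin", "n_calls",
                 "precision", "qv", sep = "\t"))
  e <- table$entries
  rec <- paste(e$combination, e$svtype, e$size_bin, e$n_calls,
               sprintf("%.17g", e$precision), sprintf("%.17g", e$qv),
               sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a calibration table written by [write_calibration_table()]
#'
#' @param path Path to the TSV file.
#' @return An `sv_calibration` object.
#' @export
read_calibration_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  prov <- sub("^# provenance: ", "", grep("^# provenance:", meta, value = TRUE))
  dqv <- as.numeric(sub("^# default_qv: ", "",
                        grep("^# default_qv:", meta, value = TRUE)))
  body <- lines[!startsWith(lines, "#")]
  if (length(body) <= 1) {
    return(new_calibration(empty_calibration_entries(),
                           dqv %||% 0, prov %||% ""))
  }
  e <- utils::read.delim(text = body, sep = "\t",
                         colClasses = c("character", "character",
                                        "character", "integer", "numeric",
                                        "numeric"))
  new_calibration(tibble::as_tibble(e), dqv %||% 0, prov %||% "")
}
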