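#' Construct a tibble of structural-variant calls
#'
#' The central data structure of the package is a plain tibble with one row
#' per SV call. `sv_calls()` builds and validates one from vectors; every
#' user-facing function accepts and returns this shape so calls chain with
#' the pipe.
#'
#' Coordinates follow the VCF convention: 1-based, `pos` is the start
#' breakpoint and `end` the end breakpoint, stored exactly as in the file so
#' breakpoint distances are plain integer differences. `svlen` is the
#' non-negative event size in bp. For insertions `end == pos` and
#' `svlen > 0`; for breakends (`BND`) the partner breakpoint lives in
#' `mate_contig`/`mate_pos`.
#'
#' @param contig Chromosome names (character).
#' @param pos 1-based start breakpoints (integer).
#' @param end 1-based end breakpoints (integer).
#' @param svtype One of `"DEL"`, `"DUP"`, `"INS"`, `"INV"`, `"BND"`.
#' @param svlen Event sizes in bp (non-negative; any sign is stripped).
#' @param caller Identifier of the originating method.
#' @param sample Sample identifier (recycled).
#' @param qual Optional per-caller quality scores.
#' @param genotype Optional diploid genotype strings such as `"0/1"`;
#'   missing genotypes are kept as `"./."`.
#' @param filter FILTER field tokens (`"PASS"` or `"."` mean unfiltered).
#' @param mate_contig,mate_pos Second breakend for BND records.
#' @param origin Optional truth-event identifier used by the simulator
#'   (`NA` marks a false call).
#'
#' @return A tibble with one row per call, sorted by `(contig, pos)`.
#' @export
#' @examples
#' sv_calls(contig = "chr1", pos = 1000L, end = 2000L,
#'          svtype = "DEL", svlen = 1000L, caller = "manta")
sv_calls <- function(contig = character(), pos = integer(), end = integer(),
                     svtype = character(), svlen = integer(),
                     caller = character(), sample = "sample",
                     qual = NA_real_, genotype = "./.", filter = "PASS",
                     mate_contig = NA_character_, mate_pos = NA_integer_,
                     origin = NA_character_) {
  n <- length(pos)
  x <- tibble::tibble(
    contig = as.character(contig),
    pos = as.integer(pos),
    end = as.integer(end),
    svtype = as.character(svtype),
    svlen = abs(as.integer(svlen)),
    caller = rep_len(as.character(caller), n),
    sample = rep_len(as.character(sample), n),
    qual = rep_len(as.numeric(qual), n),
    genotype = rep_len(as.character(genotype), n),
    filter = rep_len(as.character(filter), n),
    mate_contig = rep_len(as.character(mate_contig), n),
    mate_pos = rep_len(as.integer(mate_pos), n),
    origin = rep_len(as.character(origin), n)
  )
  validate_sv_calls(x)
  sort_calls(x)
}

sv_types <- c("DEL", "DUP", "INS", "INV", "BND")

validate_sv_calls <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  bad_type <- setdiff(unique(x$svtype), sv_types)
  if (length(bad_type) > 0) {
    stop("unknown svtype(s): ", paste(bad_type, collapse = ", "), call. = FALSE)
  }
  if (any(x$pos < 1L)) stop("pos must be >= 1", call. = FALSE)
  if (any(x$svlen < 0L)) stop("svlen must be non-negative", call. = FALSE)
  spanned <- x$svtype %in% c("DEL", "DUP", "INV")
  if (any(spanned & x$end < x$pos)) {
    stop("end < pos for a DEL/DUP/INV record", call. = FALSE)
  }
  ins <- x$svtype == "INS"
  if (any(ins & (x$end != x$pos | x$svlen <= 0L))) {
    stop("INS records require end == pos and svlen > 0", call. = FALSE)
  }
  bnd <- x$svtype == "BND"
  if (any(bnd & (is.na(x$mate_contig) | is.na(x$mate_pos)))) {
    stop("BND records require mate_contig and mate_pos", call. = FALSE)
  }
  invisible(x)
}

sort_calls <- function(x) dplyr::arrange(x, .data$contig, .data$pos, .data$end)

#' Normalize a table of SV calls
#'
#' Applies the ingest conventions used throughout the package: `svlen` is
#' made non-negative, `end` is filled from `pos + svlen` where missing for
#' spanned types, insertions are forced to `end == pos`, and events shorter
#' than `min_size` bp are dropped (the conventional 50 bp floor below which
#' an event is an indel, not an SV). Normalization is idempotent.
#'
#' @param calls A calls tibble (see [sv_calls()]).
#' @param min_size Minimum event size in bp to retain (BND records, which
#'   have no size, are exempt). Default 50.
#' @return The normalized, sorted tibble.
#' @export
normalize_calls <- function(calls, min_size = 50L) {
  if (nrow(calls) == 0) return(calls)
  calls <- dplyr::mutate(
    calls,
    svlen = abs(.data$svlen),
    end = dplyr::case_when(
      .data$svtype == "INS" ~ .data$pos,
      .data$svtype == "BND" ~ .data$pos,
      is.na(.data$end) ~ .data$pos + .data$svlen,
      TRUE ~ .data$end
    ),
    svlen = dplyr::if_else(
      .data$svtype %in% c("DEL", "DUP", "INV") & .data$svlen == 0L,
      .data$end - .data$pos, .data$svlen
    )
  )
  keep <- calls$svtype == "BND" | calls$svlen >= min_size
  if (any(!keep)) {
    calls <- calls[keep, , drop = FALSE]
  }
  validate_sv_calls(calls)
  sort_calls(calls)
}

#' Size class of a structural variant
#'
#' Maps event sizes onto the half-open strata used for both quality
#' calibration and benchmarking: `SMALL` = \[50, 300) bp, `MEDIUM` =
#' \[300, 1000) bp, `LARGE` = \[1000, Inf) bp. Breakends have no size and
#' map to `UNSIZED`; insertions are calibrated in a single collapsed bin
#' (`ALL`) because the size stratification of the quality ruleset applies
#' to deletion-like events only.
#'
#' @param svlen Event sizes in bp (vector).
#' @param svtype SV types (vector, recycled against `svlen`).
#' @return A character vector of bin labels.
#' @export
#' @examples
#' size_bin(c(150, 300, 1500), "DEL")
size_bin <- function(svlen, svtype) {
  n <- max(length(svlen), length(svtype))
  svlen <- rep_len(svlen, n)
  svtype <- rep_len(svtype, n)
  sized <- svtype %in% c("DEL", "DUP", "INV")
  if (any(sized & svlen < 50)) {
    stop("svlen < 50 bp: below the SV size floor", call. = FALSE)
  }
  out <- rep(NA_character_, n)
  out[svtype == "BND"] <- "UNSIZED"
  out[svtype == "INS"] <- "ALL"
  out[sized] <- cut(svlen[sized], breaks = c(50, 300, 1000, Inf),
                    labels = c("SMALL", "MEDIUM", "LARGE"), right = FALSE) |>
    as.character()
  out
}
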