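#' Read a single-caller SV VCF into a calls tibble
#'
#' Parses a VCF 4.x file produced by one SV caller and normalizes its
#' records into the package's tabular call representation. `SVTYPE` is taken
#' from INFO when present, else inferred from a symbolic ALT (`<DEL>`,
#' `<DUP>`, `<INS>`, `<INV>`) or from breakend ALT syntax. The event size is
#' `|SVLEN|` when present, else `END - POS` for spanned types; `END` falls
#' back to `POS + |SVLEN|`. Non-BND records lacking both `SVLEN` and `END`
#' are dropped with a warning, as are records below the `min_size` floor.
#' Multi-allelic records are split into one call per ALT allele.
#'
#' Breakend pairs are normalized so that the lexicographically smaller
#' breakend is the record anchor, and duplicate anchors are collapsed, so a
#' reciprocal BND pair counts once.
#'
#' @param path Path to the VCF file (plain or bgzipped).
#' @param caller Identifier recorded in the `caller` column; combination
#'   keys downstream are built from these, so use stable names.
#' @param min_size Ingest floor in bp; events smaller than this are dropped.
#' @return A calls tibble (see [sv_calls()]).
#' @export
read_sv_vcf <- function(path, caller, min_size = 50L) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  n_body <- count_vcf_records(path)
  if (n_body == 0) {
    return(sv_calls(caller = character()))
  }
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  fix <- vcf_fix_frame(v)
  sample_id <- if (ncol(v@gt) >= 2) colnames(v@gt)[2] else "sample"
  gt <- if (ncol(v@gt) >= 2) {
    g <- vcfR::extract.gt(v, element = "GT")
    as.character(g[, 1])
  } else rep(NA_character_, nrow(fix))

  info_svtype <- unname(vcfR::extract.info(v, element = "SVTYPE"))
  info_end <- suppressWarnings(as.integer(vcfR::extract.info(v, element = "END")))
  info_svlen <- unname(vcfR::extract.info(v, element = "SVLEN"))

  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    parse_vcf_record(
      contig = fix$CHROM[i], pos = suppressWarnings(as.integer(fix$POS[i])),
      alt = fix$ALT[i], qual = suppressWarnings(as.numeric(fix$QUAL[i])),
      filter = fix$FILTER[i], svtype = info_svtype[i], info_end = info_end[i],
      svlen_raw = info_svlen[i], gt = gt[i]
    )
  })
  n_bad <- sum(purrr::map_lgl(rows, is.null))
  if (n_bad > 0) {
    warning(n_bad, " record(s) skipped in ", basename(path),
            " (no resolvable type/size)", call. = FALSE)
  }
  calls <- dplyr::bind_rows(rows)
  if (nrow(calls) == 0) {
    return(sv_calls(caller = character()))
  }
  calls$caller <- caller
  calls$sample <- sample_id
  calls$origin <- NA_character_
  calls <- anchor_bnd(calls)
  validate_sv_calls(calls)
  normalize_calls(sort_calls(calls), min_size = min_size)
}

count_vcf_records <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  sum(!startsWith(lines, "#") & nzchar(lines))
}

# getFIX() drops to a bare vector for single-record files.
vcf_fix_frame <- function(v) {
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  as.data.frame(fix, stringsAsFactors = FALSE)
}

# "N[chr2:321[" / "]chr2:321]N" -> c(mate_contig, mate_pos) or NULL.
parse_bnd_alt <- function(a) {
  m <- regmatches(a, regexec("[][]([^]:[]+):([0-9]+)[][]", a))[[1]]
  if (length(m) == 3) m[2:3] else NULL
}

# One VCF row -> zero or more normalized call rows (NULL if unresolvable).
parse_vcf_record <- function(contig, pos, alt, qual, filter, svtype,
                             info_end, svlen_raw, gt) {
  if (is.na(contig) || is.na(pos)) return(NULL)
  alts <- strsplit(alt %||% "", ",", fixed = TRUE)[[1]]
  if (length(alts) == 0) alts <- NA_character_
  svlens <- suppressWarnings(as.integer(strsplit(svlen_raw %||% "", ",",
                                                 fixed = TRUE)[[1]]))
  out <- purrr::map(seq_along(alts), function(k) {
    a <- alts[k]
    type <- svtype
    mate <- c(NA_character_, NA_integer_)
    if (!is.na(a) && grepl("[][]", a)) {
      type <- "BND"
      mate <- parse_bnd_alt(a) %||% mate
    } else if (is.na(type) && !is.na(a) && grepl("^<(DEL|DUP|INS|INV)", a)) {
      type <- stringr::str_match(a, "^<(DEL|DUP|INS|INV)")[1, 2]
    }
    if (is.na(type) || !type %in% sv_types) return(NULL)
    if (type == "BND") {
      if (is.na(mate[1])) return(NULL)
      return(tibble::tibble(contig = contig, pos = pos, end = pos,
                            svtype = "BND", svlen = 0L, qual = qual,
                            genotype = gt %||% "./.", filter = filter,
                            mate_contig = mate[1],
                            mate_pos = as.integer(mate[2])))
    }
    sl <- if (length(svlens) >= k && !is.na(svlens[k])) abs(svlens[k])
          else if (length(svlens) == 1 && !is.na(svlens[1])) abs(svlens[1])
          else NA_integer_
    en <- info_end
    if (is.na(sl) && is.na(en)) return(NULL)
    if (is.na(sl)) sl <- if (type == "INS") NA_integer_ else en - pos
    if (is.na(sl)) return(NULL)   # INS with END only carries no size
    if (is.na(en)) en <- if (type == "INS") pos else pos + sl
    if (type == "INS") en <- pos
    tibble::tibble(contig = contig, pos = pos, end = as.integer(en),
                   svtype = type, svlen = as.integer(sl), qual = qual,
                   genotype = gt %||% "./.", filter = filter,
                   mate_contig = NA_character_, mate_pos = NA_integer_)
  })
  out <- purrr::compact(out)
  if (length(out) == 0) NULL else dplyr::bind_rows(out)
}

# Keep the lexicographically smaller breakend of each BND pair as anchor.
anchor_bnd <- function(calls) {
  bnd <- calls$svtype == "BND"
  if (!any(bnd)) return(calls)
  b <- calls[bnd, ]
  swap <- (b$mate_contig < b$contig) |
    (b$mate_contig == b$contig & b$mate_pos < b$pos)
  tmp_c <- b$contig[swap]; tmp_p <- b$pos[swap]
  b$contig[swap] <- b$mate_contig[swap]
  b$pos[swap] <- b$mate_pos[swap]
  b$end[swap] <- b$pos[swap]
  b$mate_contig[swap] <- tmp_c
  b$mate_pos[swap] <- tmp_p
  b <- dplyr::distinct(b, .data$contig, .data$pos, .data$mate_contig,
                       .data$mate_pos, .keep_all = TRUE)
  dplyr::bind_rows(calls[!bnd, ], b)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Write consensus calls to a VCF 4.2 file
#'
#' Serializes a consensus tibble (output of [merge_callsets()], optionally
#' quality-annotated by [assign_qualities()]) as VCF. `QUAL` carries the
#' assigned Phred quality; INFO carries `SVTYPE`, `SVLEN`, `END`, `SUPP`
#' (number of supporting callers) and `SUPP_CALLERS` (comma-joined sorted
#' caller names). Records are sorted by contig then position.
#'
#' @param consensus Consensus tibble.
#' @param path Output path.
#' @param contig_lengths Named integer vector of contig lengths; must cover
#'   every contig referenced.
#' @param sample Sample name for the genotype column.
#' @return Invisibly, the path.
#' @export
write_consensus_vcf <- function(consensus, path, contig_lengths,
                                sample = NULL) {
  sample <- sample %||%
    (if (nrow(consensus) > 0 && "sample" %in% names(consensus))
       consensus$sample[1] else "sample")
  missing_ctg <- setdiff(unique(consensus$contig), names(contig_lengths))
  if (length(missing_ctg) > 0) {
    stop("contig(s) not in contig_lengths: ",
         paste(missing_ctg, collapse = ", "), call. = FALSE)
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svensemble",
    paste0("##contig=<ID=", names(contig_lengths),
           ",length=", as.integer(contig_lengths), ">"),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length in bp\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End breakpoint\">",
    "##INFO=<ID=SUPP,Number=1,Type=Integer,Description=\"Number of supporting callers\">",
    "##INFO=<ID=SUPP_CALLERS,Number=1,Type=String,Description=\"Comma-joined sorted supporting callers\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  if (nrow(consensus) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  x <- sort_consensus(consensus)
  alt <- ifelse(x$svtype == "BND",
                paste0("N[", x$mate_contig, ":", x$mate_pos, "["),
                paste0("<", x$svtype, ">"))
  qual <- ifelse(is.na(x$qv), ".", format(x$qv, trim = TRUE, digits = 15,
                                          scientific = FALSE))
  gt <- if ("genotype" %in% names(x)) {
    ifelse(is.na(x$genotype), "./.", x$genotype)
  } else "./."
  info <- paste0("SVTYPE=", x$svtype, ";SVLEN=", x$svlen, ";END=", x$end,
                 ";SUPP=", x$n_support, ";SUPP_CALLERS=", x$support)
  rec <- paste(x$contig, x$pos, paste0("sv", seq_len(nrow(x))), "N", alt,
               qual, "PASS", info, "GT", gt, sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

sort_consensus <- function(x) dplyr::arrange(x, .data$contig, .data$pos, .data$end)

#' Read a consensus VCF written by [write_consensus_vcf()]
#'
#' Recovers the consensus tibble: breakpoints, type, size, supporting-caller
#' set (`SUPP_CALLERS`) and the Phred quality from `QUAL`.
#'
#' @param path Path to the consensus VCF.
#' @param sample Sample identifier to record (defaults to the VCF's sample
#'   column name).
#' @return A consensus tibble.
#' @export
read_consensus_vcf <- function(path, sample = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  if (count_vcf_records(path) == 0) return(empty_consensus())
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf_fix_frame(v)
  sample_id <- sample %||% (if (ncol(v@gt) >= 2) colnames(v@gt)[2] else "sample")
  gt <- if (ncol(v@gt) >= 2) as.character(vcfR::extract.gt(v, "GT")[, 1])
        else rep(NA_character_, nrow(fix))
  svtype <- unname(vcfR::extract.info(v, "SVTYPE"))
  out <- tibble::tibble(
    contig = fix$CHROM,
    pos = as.integer(fix$POS),
    end = as.integer(vcfR::extract.info(v, "END")),
    svtype = svtype,
    svlen = abs(as.integer(vcfR::extract.info(v, "SVLEN"))),
    support = unname(vcfR::extract.info(v, "SUPP_CALLERS")),
    n_support = as.integer(vcfR::extract.info(v, "SUPP")),
    qv = suppressWarnings(as.numeric(fix$QUAL)),
    genotype = ifelse(is.na(gt), "./.", gt),
    sample = sample_id,
    mate_contig = NA_character_,
    mate_pos = NA_integer_
  )
  bnd <- !is.na(svtype) & svtype == "BND"
  if (any(bnd)) {
    mates <- lapply(fix$ALT[bnd], parse_bnd_alt)
    out$mate_contig[bnd] <- vapply(mates, function(m) m[1] %||% NA_character_,
                                   character(1))
    out$mate_pos[bnd] <- vapply(mates,
                                function(m) as.integer(m[2] %||% NA),
                                integer(1))
  }
  sort_consensus(out)
}

empty_consensus <- function() {
  tibble::tibble(contig = character(), pos = integer(), end = integer(),
                 svtype = character(), svlen = integer(),
                 support = character(), n_support = integer(),
                 qv = numeric(), genotype = character(), sample = character(),
                 mate_contig = character(), mate_pos = integer())
}

#' Write a raw calls tibble as a single-sample SV VCF
#'
#' Serializes one caller's (or the truth set's) calls with symbolic ALT
#' alleles and `SVTYPE`/`SVLEN`/`END` INFO fields, the dialect
#' [read_sv_vcf()] ingests. Per-caller qualities go to `QUAL`.
#'
#' @param calls A calls tibble.
#' @param path Output path.
#' @param contig_lengths Named integer vector covering every contig; when
#'   `NULL`, lengths are padded out from the observed maxima.
#' @return Invisibly, the path.
#' @export
write_sv_vcf <- function(calls, path, contig_lengths = NULL) {
  if (is.null(contig_lengths)) contig_lengths <- contig_lengths_from_calls(calls)
  missing_ctg <- setdiff(unique(calls$contig), names(contig_lengths))
  if (length(missing_ctg) > 0) {
    stop("contig(s) not in contig_lengths: ",
         paste(missing_ctg, collapse = ", "), call. = FALSE)
  }
  sample_id <- if (nrow(calls) > 0) calls$sample[1] else "sample"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svensemble",
    paste0("##contig=<ID=", names(contig_lengths),
           ",length=", as.integer(contig_lengths), ">"),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length in bp\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End breakpoint\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  if (nrow(calls) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  x <- sort_calls(calls)
  alt <- ifelse(x$svtype == "BND",
                paste0("N[", x$mate_contig, ":", x$mate_pos, "["),
                paste0("<", x$svtype, ">"))
  qual <- ifelse(is.na(x$qual), ".",
                 format(x$qual, trim = TRUE, digits = 15,
                        scientific = FALSE))
  info <- paste0("SVTYPE=", x$svtype, ";SVLEN=",
                 ifelse(x$svtype == "DEL", -x$svlen, x$svlen),
                 ";END=", x$end)
  gt <- ifelse(is.na(x$genotype), "./.", x$genotype)
  filt <- ifelse(is.na(x$filter), ".", x$filter)
  rec <- paste(x$contig, x$pos, paste0("call", seq_len(nrow(x))), "N", alt,
               qual, filt, info, "GT", gt, sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Contig lengths inferred from observed calls
#'
#' @param calls A calls or consensus tibble.
#' @param pad Padding in bp added beyond the largest observed breakpoint.
#' @return A named integer vector.
#' @export
contig_lengths_from_calls <- function(calls, pad = 10000L) {
  if (nrow(calls) == 0) return(stats::setNames(integer(0), character(0)))
  agg <- calls |>
    dplyr::group_by(.data$contig) |>
    dplyr::summarise(len = max(.data$end, .data$pos) + pad,
                     .groups = "drop")
  stats::setNames(as.integer(agg$len), agg$contig)
}

#' Read a 3-column BED file of high-confidence regions
#'
#' BED is 0-based half-open; the returned tibble keeps those conventions in
#' `start0`/`end0`. Used to restrict benchmarking to high-confidence regions.
#'
#' @param path Path to the BED file.
#' @return A tibble with columns `contig`, `start0`, `end0`.
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("contig", "start0", "end0"),
                         col_types = "cii", comment = "#", progress = FALSE)
  bed
}
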