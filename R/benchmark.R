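#' Truth-matching parameters
#'
#' Mirrors the published SV benchmarking protocol: a candidate and a truth
#' record may match when both breakpoints are displaced by at most
#' `refdist` bp (2000 by default) and their sizes agree to at least
#' `pctsize` (`min(a,b)/max(a,b)`, 0.7 by default). Sequence similarity is
#' disabled throughout (the protocol fixes it to 0), so no FASTA is ever
#' touched.
#'
#' @param refdist Maximum breakpoint displacement in bp. Default 2000.
#' @param pctsize Minimum size-similarity ratio in \[0, 1\]. Default 0.7.
#' @param passonly Consider only records whose FILTER is `PASS` or `.`.
#'   Default `TRUE`.
#' @param include_bed Optional high-confidence regions ([read_bed()]
#'   tibble); both call sets are restricted to records fully inside a
#'   region.
#' @param size_min,size_max Optional half-open size-stratum bounds in bp
#'   applied to both sets before matching.
#' @return A list with class `match_params`.
#' @export
match_params <- function(refdist = 2000L, pctsize = 0.7, passonly = TRUE,
                         include_bed = NULL, size_min = NULL,
                         size_max = NULL) {
  stopifnot(refdist >= 0, pctsize >= 0, pctsize <= 1)
  structure(list(refdist = as.integer(refdist), pctsize = pctsize,
                 passonly = isTRUE(passonly), include_bed = include_bed,
                 size_min = size_min, size_max = size_max),
            class = "match_params")
}

apply_set_filters <- function(x, params) {
  keep <- x$svtype != "BND"
  if (params$passonly && "filter" %in% names(x)) {
    keep <- keep & (is.na(x$filter) | x$filter %in% c("PASS", "."))
  }
  if (!is.null(params$size_min)) keep <- keep & x$svlen >= params$size_min
  if (!is.null(params$size_max)) keep <- keep & x$svlen < params$size_max
  if (!is.null(params$include_bed)) {
    bed <- params$include_bed
    inside <- vapply(seq_len(nrow(x)), function(i) {
      any(bed$contig == x$contig[i] & x$pos[i] >= bed$start0 + 1L &
            x$end[i] <= bed$end0)
    }, logical(1))
    keep <- keep & inside
  }
  which(keep)
}

#' Match candidate calls against a truth set
#'
#' Implements the package's benchmarking contract. A candidate is
#' compatible with a truth record iff they share contig and SV type, both
#' breakpoint displacements are at most `refdist`, and the size ratio is at
#' least `pctsize`. Assignment is greedy and one-to-one: candidates are
#' processed in coordinate order and each takes its nearest compatible
#' unmatched truth record, with distance `|dpos| + |dend|` and ties broken
#' towards the lower truth position — fully deterministic. Breakends are
#' excluded from the metrics (the truth protocol covers sized events only).
#'
#' @param candidates Consensus or per-caller calls tibble.
#' @param truth Truth calls tibble.
#' @param params A [match_params()] object.
#' @param stratify Also compute metrics per size class (50–300, 300–1000,
#'   >=1000 bp); default `TRUE` when no explicit size bounds are set.
#' @return An object of class `sv_benchmark` with elements `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1`, `matches` (tibble of
#'   `cand_idx`/`truth_idx` row indices into the *input* tibbles plus the
#'   breakpoint distance) and `per_stratum`.
#' @export
match_calls <- function(candidates, truth, params = match_params(),
                        stratify = is.null(params$size_min) &&
                          is.null(params$size_max)) {
  ci <- apply_set_filters(candidates, params)
  ti <- apply_set_filters(truth, params)
  cand <- candidates[ci, , drop = FALSE]
  tru <- truth[ti, , drop = FALSE]

  matches <- greedy_match(cand, tru, params)
  if (nrow(matches) > 0) {
    matches$cand_idx <- ci[matches$cand_idx]
    matches$truth_idx <- ti[matches$truth_idx]
  }
  tp <- nrow(matches)
  fp <- nrow(cand) - tp
  fn <- nrow(tru) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_

  per_stratum <- NULL
  if (stratify) {
    bounds <- list(SMALL = c(50, 300), MEDIUM = c(300, 1000),
                   LARGE = c(1000, Inf))
    per_stratum <- purrr::imap(bounds, function(b, lab) {
      p2 <- params
      p2$size_min <- b[1]
      p2$size_max <- if (is.finite(b[2])) b[2] else NULL
      r <- match_calls(candidates, truth, p2, stratify = FALSE)
      tibble::tibble(size_bin = lab, tp = r$tp, fp = r$fp, fn = r$fn,
                     precision = r$precision, recall = r$recall, f1 = r$f1)
    }) |> dplyr::bind_rows()
  }
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall,
                 f1 = f1(precision %||% 0, recall %||% 0),
                 matches = matches, per_stratum = per_stratum,
                 params = params),
            class = "sv_benchmark")
}

greedy_match <- function(cand, tru, params) {
  empty <- tibble::tibble(cand_idx = integer(), truth_idx = integer(),
                          distance = integer())
  if (nrow(cand) == 0 || nrow(tru) == 0) return(empty)
  t_ord <- order(tru$contig, tru$pos, tru$end)
  taken <- rep(FALSE, nrow(tru))
  t_grp <- split(t_ord, paste(tru$contig[t_ord], tru$svtype[t_ord], sep = "\r"))
  c_ord <- order(cand$contig, cand$pos, cand$end)
  out_c <- integer(0); out_t <- integer(0); out_d <- integer(0)
  for (i in c_ord) {
    g <- t_grp[[paste(cand$contig[i], cand$svtype[i], sep = "\r")]]
    if (is.null(g)) next
    tp_pos <- tru$pos[g]
    lo <- findInterval(cand$pos[i] - params$refdist - 1L, tp_pos) + 1L
    hi <- findInterval(cand$pos[i] + params$refdist, tp_pos)
    if (hi < lo) next
    j <- g[lo:hi]
    j <- j[!taken[j]]
    if (length(j) == 0) next
    ok <- abs(tru$end[j] - cand$end[i]) <= params$refdist &
      pmin(tru$svlen[j], cand$svlen[i]) /
        pmax(tru$svlen[j], cand$svlen[i], 1L) >= params$pctsize
    j <- j[ok]
    if (length(j) == 0) next
    d <- abs(tru$pos[j] - cand$pos[i]) + abs(tru$end[j] - cand$end[i])
    pick <- j[order(d, tru$pos[j])][1]
    taken[pick] <- TRUE
    out_c <- c(out_c, i); out_t <- c(out_t, pick)
    out_d <- c(out_d, d[match(pick, j)])
  }
  tibble::tibble(cand_idx = out_c, truth_idx = out_t,
                 distance = as.integer(out_d))
}

#' @export
print.sv_benchmark <- function(x, ...) {
  cat(sprintf("SV benchmark: TP %d, FP %d, FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("precision %.4f, recall %.4f, F1 %.4f\n",
              x$precision, x$recall, x$f1))
  if (!is.null(x$per_stratum)) print(x$per_stratum, ...)
  invisible(x)
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Values in \[0, 1\]. Defined as 0 when both are 0.
#' @return The F1 score.
#' @export
#' @examples
#' f1(0.8517, 0.5654)
f1 <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Precision and recall contribution per supporting-caller combination
#'
#' Groups consensus calls by their exact support set and reports, for every
#' observed combination, its call count, share of total calls, empirical
#' precision against the truth set, and recall contribution (the fraction
#' of all truth records recovered by calls with exactly that support).
#'
#' @param consensus Consensus tibble with support sets.
#' @param truth Truth calls tibble.
#' @param params A [match_params()] object.
#' @return A tibble with one row per combination, sorted by call count.
#' @export
combination_breakdown <- function(consensus, truth, params = match_params()) {
  rep <- match_calls(consensus, truth, params, stratify = FALSE)
  n_truth <- rep$tp + rep$fn
  included <- apply_set_filters(consensus, params)
  lab <- consensus[included, , drop = FALSE]
  lab$tp <- included %in% rep$matches$cand_idx
  out <- lab |>
    dplyr::group_by(combination = .data$support) |>
    dplyr::summarise(n_calls = dplyr::n(), tp = sum(.data$tp),
                     .groups = "drop") |>
    dplyr::mutate(
      pct_of_calls = 100 * .data$n_calls / sum(.data$n_calls),
      precision = .data$tp / .data$n_calls,
      recall_contribution = if (n_truth > 0) .data$tp / n_truth else NA_real_
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_calls))
  out
}

#' Concordance between two consensus call sets
#'
#' Jaccard similarity over matched events between two call sets — e.g. the
#' same sample sequenced on two platforms or in replicate runs. When a
#' quality threshold is given, both sets are first filtered with
#' [filter_by_quality()]; filtering at QV > 3 is the rule under which
#' replicate concordance is expected to increase. Matching follows
#' [match_calls()] with `b` as the reference; the reverse-direction match
#' count is also reported since the greedy assignment is not symmetric.
#'
#' @param a,b Consensus tibbles (quality-annotated when `qv_threshold` is
#'   given).
#' @param params A [match_params()] object.
#' @param qv_threshold Optional strict QV cutoff applied to both sets.
#' @return A one-row tibble: set sizes, match counts in both directions and
#'   the Jaccard index `matches / (|a| + |b| - matches)`.
#' @export
concordance <- function(a, b, params = match_params(), qv_threshold = NULL) {
  if (!is.null(qv_threshold)) {
    a <- filter_by_quality(a, qv_threshold)
    b <- filter_by_quality(b, qv_threshold)
  }
  ai <- apply_set_filters(a, params)
  bi <- apply_set_filters(b, params)
  m_ab <- match_calls(a, b, params, stratify = FALSE)$tp
  m_ba <- match_calls(b, a, params, stratify = FALSE)$tp
  denom <- length(ai) + length(bi) - m_ab
  tibble::tibble(
    n_a = length(ai), n_b = length(bi),
    matches_ab = m_ab, matches_ba = m_ba,
    jaccard = if (denom > 0) m_ab / denom else NA_real_,
    qv_threshold = qv_threshold %||% NA_real_
  )
}

#' Cross-sample merge and population allele frequencies
#'
#' Merges per-sample consensus calls across a cohort (the same
#' breakpoint-distance clustering as [merge_callsets()], with samples in
#' the role of callers) and reports, per merged SV, the carrier count and
#' the allele frequency: the alternate-allele count over `2 * n_samples`
#' when genotypes are available, else carriers over `n_samples`.
#'
#' @param per_sample A stacked consensus tibble with a `sample` column, or
#'   a list of per-sample consensus tibbles.
#' @param params A [merge_params()] object.
#' @param n_samples Cohort size; defaults to the number of distinct samples
#'   present.
#' @return A tibble with one row per merged SV: coordinates, type, size,
#'   `carriers`, `n_samples` and `af`, sorted by position.
#' @export
population_af <- function(per_sample, params = merge_params(),
                          n_samples = NULL) {
  if (is.list(per_sample) && !is.data.frame(per_sample)) {
    per_sample <- dplyr::bind_rows(per_sample)
  }
  n_samples <- n_samples %||% dplyr::n_distinct(per_sample$sample)
  calls <- dplyr::mutate(per_sample, caller = .data$sample,
                         sample = "population")
  merged <- merge_callsets(calls, params)
  if (nrow(merged) == 0) {
    return(tibble::tibble(contig = character(), pos = integer(),
                          end = integer(), svtype = character(),
                          svlen = integer(), carriers = integer(),
                          n_samples = integer(), af = numeric()))
  }
  stats <- purrr::map(merged$members, function(m) {
    m1 <- m[!duplicated(m$caller), , drop = FALSE]   # one record per sample
    carriers <- nrow(m1)
    informative <- !is.na(m1$genotype) & grepl("[01]", m1$genotype)
    if (any(informative)) {
      alt <- sum(stringr::str_count(m1$genotype[informative], "1"))
      tibble::tibble(carriers = carriers, af = alt / (2 * n_samples))
    } else {
      tibble::tibble(carriers = carriers, af = carriers / n_samples)
    }
  }) |> dplyr::bind_rows()
  dplyr::bind_cols(
    dplyr::select(merged, "contig", "pos", "end", "svtype", "svlen"),
    stats
  ) |>
    dplyr::mutate(n_samples = n_samples, .before = "af")
}
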