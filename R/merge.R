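#' Merge parameters
#'
#' Controls the breakpoint-distance clustering that turns per-caller calls
#' into consensus candidates.
#'
#' @param max_dist Maximum allowed distance in bp between both start
#'   breakpoints and both end breakpoints of two mergeable calls. Default
#'   1000 bp, the common default of SV merging tools.
#' @param require_type_match Merge only calls of the same SV type. Default
#'   `TRUE`.
#' @param min_support Minimum number of distinct supporting callers for a
#'   consensus record to be emitted. Default 1.
#' @return A list with class `merge_params`.
#' @export
merge_params <- function(max_dist = 1000L, require_type_match = TRUE,
                         min_support = 1L) {
  stopifnot(max_dist >= 0, min_support >= 1)
  structure(list(max_dist = as.integer(max_dist),
                 require_type_match = isTRUE(require_type_match),
                 min_support = as.integer(min_support)),
            class = "merge_params")
}

#' Can two SV calls be merged?
#'
#' Pure predicate behind the clustering: two calls are mergeable iff they
#' lie on the same contig, have the same SV type (when
#' `require_type_match`), and both their start and end breakpoints are
#' within `max_dist` of each other. Breakends additionally require matching
#' mate contigs with mate positions within `max_dist`; a breakend never
#' merges with a non-breakend.
#'
#' @param a,b Single-row calls tibbles.
#' @param params A [merge_params()] object.
#' @return `TRUE` or `FALSE`.
#' @export
mergeable <- function(a, b, params = merge_params()) {
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  if (a$contig != b$contig) return(FALSE)
  if ((a$svtype == "BND") != (b$svtype == "BND")) return(FALSE)
  if (params$require_type_match && a$svtype != b$svtype) return(FALSE)
  if (abs(a$pos - b$pos) > params$max_dist) return(FALSE)
  if (a$svtype == "BND") {
    return(!is.na(a$mate_contig) && !is.na(b$mate_contig) &&
             a$mate_contig == b$mate_contig &&
             abs(a$mate_pos - b$mate_pos) <= params$max_dist)
  }
  abs(a$end - b$end) <= params$max_dist
}

#' Cluster calls from multiple callers into consensus candidates
#'
#' Consensus calls are the connected components (single-linkage, transitive
#' closure) of the graph whose vertices are the input calls and whose edges
#' join [mergeable()] pairs. Each component yields one consensus record:
#' representative `pos` and `end` are the lower medians of the member
#' breakpoints (so representatives are always observed coordinates),
#' `svlen` is recomputed from the representatives (lower median of member
#' sizes for insertions), and `support` is the set of distinct member
#' callers — a caller contributing several calls to one component counts
#' once. Components supported by fewer than `min_support` distinct callers
#' are discarded.
#'
#' @param calls A calls tibble with a `caller` column (stack several
#'   callers' tables with `dplyr::bind_rows()`), or a list of such tibbles.
#'   All calls must come from the same sample.
#' @param params A [merge_params()] object.
#' @return A consensus tibble, sorted by `(contig, pos)`, with a `members`
#'   list-column holding each component's constituent calls.
#' @export
#' @examples
#' a <- sv_calls(contig = "chr1", pos = 1000L, end = 2000L, svtype = "DEL",
#'               svlen = 1000L, caller = "manta")
#' b <- sv_calls(contig = "chr1", pos = 1010L, end = 1995L, svtype = "DEL",
#'               svlen = 985L, caller = "delly")
#' merge_callsets(dplyr::bind_rows(a, b))
merge_callsets <- function(calls, params = merge_params()) {
  if (is.list(calls) && !is.data.frame(calls)) calls <- dplyr::bind_rows(calls)
  if (nrow(calls) == 0) {
    out <- empty_consensus()
    out$members <- list()
    return(out)
  }
  if ("sample" %in% names(calls) && dplyr::n_distinct(calls$sample) > 1) {
    stop("calls mix samples: ",
         paste(unique(calls$sample), collapse = ", "), call. = FALSE)
  }
  comp <- merge_components(calls, params)
  calls$.comp <- comp
  summarize_components(calls, params)
}

# Component id per call: candidate pairs by a sorted sweep on pos within
# each (contig, type-key) group, then connected components via igraph.
merge_components <- function(calls, params) {
  type_key <- if (params$require_type_match) calls$svtype else
    ifelse(calls$svtype == "BND", "BND", "ANY")
  grp <- paste(calls$contig, type_key, sep = "\r")
  idx <- seq_len(nrow(calls))
  edges <- integer(0)
  for (g in split(idx, grp)) {
    if (length(g) < 2) next
    o <- g[order(calls$pos[g])]
    p <- calls$pos[o]
    hi <- findInterval(p + params$max_dist, p)
    for (i in seq_along(o)) {
      if (hi[i] <= i) next
      j <- (i + 1):hi[i]
      ok <- abs(calls$end[o[j]] - calls$end[o[i]]) <= params$max_dist
      if (calls$svtype[o[i]] == "BND") {
        ok <- ok & !is.na(calls$mate_contig[o[j]]) &
          calls$mate_contig[o[j]] == calls$mate_contig[o[i]] &
          abs(calls$mate_pos[o[j]] - calls$mate_pos[o[i]]) <= params$max_dist
        ok[is.na(ok)] <- FALSE
      }
      if (any(ok)) edges <- c(edges, rbind(o[i], o[j][ok]))
    }
  }
  gph <- igraph::make_empty_graph(n = nrow(calls), directed = FALSE)
  if (length(edges) > 0) gph <- igraph::add_edges(gph, edges)
  igraph::components(gph)$membership
}

lower_median <- function(x) sort(x)[(length(x) + 1L) %/% 2L]

# Vectorized per-component summaries: the lower median of a sorted group
# is the element at offset ceiling(size/2) from the group start.
group_lower_median <- function(x, comp, starts, sizes) {
  sorted <- x[order(comp, x, method = "radix")]
  sorted[starts + (sizes + 1L) %/% 2L - 1L]
}

summarize_components <- function(calls, params) {
  comp <- as.integer(calls$.comp)
  k <- max(comp)
  sizes <- tabulate(comp, nbins = k)
  starts <- cumsum(c(1L, sizes[-k]))
  first_ix <- match(seq_len(k), comp)

  svtype <- if (params$require_type_match) {
    calls$svtype[first_ix]          # components are type-pure
  } else {
    vapply(split(calls$svtype, comp),
           function(x) names(which.max(table(x))),  # modal; ties alphabetical
           character(1), USE.NAMES = FALSE)
  }
  pos <- group_lower_median(calls$pos, comp, starts, sizes)
  end_med <- group_lower_median(calls$end, comp, starts, sizes)
  svlen_med <- group_lower_median(calls$svlen, comp, starts, sizes)
  by_caller <- split(calls$caller, comp)
  support_sets <- unname(lapply(by_caller, function(x) sort.int(unique(x))))
  is_ins <- svtype == "INS"
  is_bnd <- svtype == "BND"
  end <- ifelse(is_ins, pos, end_med)
  svlen <- as.integer(ifelse(is_ins, svlen_med,
                             ifelse(is_bnd, 0L, end - pos)))
  members <- unname(split(dplyr::select(calls, -".comp"), comp))
  out <- tibble::tibble(
    contig = calls$contig[first_ix],
    pos = pos, end = as.integer(end), svtype = svtype, svlen = svlen,
    support = vapply(support_sets, paste, character(1), collapse = ","),
    n_support = lengths(support_sets, use.names = FALSE),
    qv = NA_real_,
    genotype = vapply(split(calls$genotype, comp), first_informative_gt,
                      character(1), USE.NAMES = FALSE),
    sample = if ("sample" %in% names(calls)) calls$sample[first_ix]
             else "sample",
    mate_contig = ifelse(is_bnd, calls$mate_contig[first_ix], NA_character_),
    mate_pos = as.integer(ifelse(
      is_bnd, group_lower_median(calls$mate_pos, comp, starts, sizes),
      NA_integer_)),
    members = members
  )
  out <- out[out$n_support >= params$min_support, , drop = FALSE]
  sort_consensus(out)
}

first_informative_gt <- function(g) {
  inf <- g[!is.na(g) & g != "./."]
  if (length(inf) > 0) inf[1] else "./."
}
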