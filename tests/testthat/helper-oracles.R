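# Independent oracles and fixture generators used across the suite.
# The oracles deliberately share no code with the package internals:
# all-pairs adjacency + union-find for clustering, and igraph's maximum
# bipartite matching for the matcher bound.

random_calls <- function(n, n_contigs = 2, n_callers = 3,
                         pos_max = 100000L, size_max = 5000L,
                         types = c("DEL", "DUP", "INS", "INV")) {
  contig <- paste0("ctg", sample.int(n_contigs, n, replace = TRUE))
  svtype <- sample(types, n, replace = TRUE)
  pos <- sample.int(pos_max, n, replace = TRUE)
  svlen <- sample(50:size_max, n, replace = TRUE)
  end <- ifelse(svtype == "INS", pos, pos + svlen)
  calls <- sv_calls(contig = contig, pos = pos, end = as.integer(end),
                    svtype = svtype, svlen = svlen,
                    caller = paste0("c", sample.int(n_callers, n,
                                                    replace = TRUE)))
  calls$uid <- paste0("u", seq_len(nrow(calls)))
  calls
}

# All-pairs mergeability + union-find connected components.
oracle_components <- function(calls, params) {
  n <- nrow(calls)
  if (n == 0) return(integer(0))
  same_ctg <- outer(calls$contig, calls$contig, "==")
  type_ok <- if (params$require_type_match) {
    outer(calls$svtype, calls$svtype, "==")
  } else {
    matrix(TRUE, n, n)
  }
  adj <- same_ctg & type_ok &
    abs(outer(calls$pos, calls$pos, "-")) <= params$max_dist &
    abs(outer(calls$end, calls$end, "-")) <= params$max_dist
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Oracle consensus records built straight from the component definition.
oracle_consensus <- function(calls, params) {
  comp <- oracle_components(calls, params)
  lower_med <- function(x) sort(x)[ceiling(length(x) / 2)]
  groups <- split(seq_len(nrow(calls)), comp)
  g <- length(groups)
  contig <- character(g); pos <- integer(g); end <- integer(g)
  svtype <- character(g); svlen <- integer(g); support <- character(g)
  n_support <- integer(g); members <- vector("list", g)
  for (gi in seq_len(g)) {
    ix <- groups[[gi]]
    svtype[gi] <- names(which.max(table(calls$svtype[ix])))
    pos[gi] <- lower_med(calls$pos[ix])
    end[gi] <- if (svtype[gi] == "INS") pos[gi] else lower_med(calls$end[ix])
    svlen[gi] <- if (svtype[gi] == "INS") lower_med(calls$svlen[ix])
                 else end[gi] - pos[gi]
    contig[gi] <- calls$contig[ix[1]]
    callers <- sort(unique(calls$caller[ix]))
    support[gi] <- paste(callers, collapse = ",")
    n_support[gi] <- length(callers)
    members[[gi]] <- sort(calls$uid[ix])
  }
  out <- data.frame(contig = contig, pos = pos, end = end, svtype = svtype,
                    svlen = svlen, support = support,
                    n_support = n_support, stringsAsFactors = FALSE)
  out$members <- members
  out <- out[out$n_support >= params$min_support, , drop = FALSE]
  out[order(out$contig, out$pos, out$end), , drop = FALSE]
}

# Canonical partition signature: sorted member-uid sets.
partition_signature <- function(member_uid_sets) {
  sets <- vapply(member_uid_sets, function(u) paste(sort(u), collapse = "|"),
                 character(1))
  sort(sets)
}

# Maximum one-to-one matching size under the compatibility predicate,
# via igraph's maximum bipartite matching.
oracle_max_matching <- function(cand, tru, params) {
  nc <- nrow(cand); nt <- nrow(tru)
  if (nc == 0 || nt == 0) return(0L)
  compat <- outer(seq_len(nc), seq_len(nt), function(i, j) {
    cand$contig[i] == tru$contig[j] & cand$svtype[i] == tru$svtype[j] &
      abs(cand$pos[i] - tru$pos[j]) <= params$refdist &
      abs(cand$end[i] - tru$end[j]) <= params$refdist &
      pmin(cand$svlen[i], tru$svlen[j]) /
        pmax(cand$svlen[i], tru$svlen[j], 1) >= params$pctsize
  })
  edges <- which(compat, arr.ind = TRUE)
  if (nrow(edges) == 0) return(0L)
  g <- igraph::make_empty_graph(nc + nt, directed = FALSE)
  g <- igraph::add_edges(g, t(cbind(edges[, 1], nc + edges[, 2])))
  igraph::V(g)$type <- c(rep(FALSE, nc), rep(TRUE, nt))
  igraph::max_bipartite_match(g)$matching_size
}

# A small literal single-caller VCF, written at test time.
write_fixture_vcf <- function(path, records) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    "##contig=<ID=chr2,length=1000000>",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=.,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "NA00001", sep = "\t")
  )
  writeLines(c(hdr, records), path)
}

empty_consensus_fixture <- function() {
  tibble::tibble(contig = character(), pos = integer(), end = integer(),
                 svtype = character(), svlen = integer(),
                 support = character(), n_support = integer(),
                 qv = numeric(), genotype = character(),
                 sample = character(), mate_contig = character(),
                 mate_pos = integer())
}

# Consensus tibbles with randomized fields for serialization tests.
random_consensus <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  svtype <- sample(c("DEL", "DUP", "INS", "INV"), n, replace = TRUE)
  pos <- sort(sample.int(900000L, n))
  svlen <- sample(50:20000, n, replace = TRUE)
  end <- as.integer(ifelse(svtype == "INS", pos, pos + svlen))
  callers <- c("breakdancer", "cnvnator", "delly", "lumpy", "manta")
  support <- vapply(seq_len(n), function(i) {
    paste(sort(sample(callers, sample.int(5, 1))), collapse = ",")
  }, character(1))
  tibble::tibble(
    contig = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = pos, end = end, svtype = svtype, svlen = as.integer(svlen),
    support = support,
    n_support = lengths(strsplit(support, ",")),
    qv = round(stats::runif(n, 0, 40), 2),
    genotype = sample(c("0/1", "1/1", "./."), n, replace = TRUE),
    sample = "s1",
    mate_contig = NA_character_, mate_pos = NA_integer_
  ) |> dplyr::arrange(contig, pos, end)
}
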