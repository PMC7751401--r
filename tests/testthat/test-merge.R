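one_call <- function(contig, pos, end, svtype = "DEL", caller = "a",
                     svlen = NULL) {
  sv_calls(contig = contig, pos = as.integer(pos), end = as.integer(end),
           svtype = svtype,
           svlen = as.integer(svlen %||% max(end - pos, 60L)),
           caller = caller)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the mergeability predicate applies both breakpoint distances", {
  p <- merge_params(max_dist = 1000)
  expect_true(mergeable(one_call("chr1", 1000, 2000),
                        one_call("chr1", 1010, 1995, caller = "b"), p))
  expect_false(mergeable(one_call("chr1", 1000, 2000),
                         one_call("chr1", 1000, 2000, svtype = "DUP",
                                  svlen = 1000L), p))
  expect_false(mergeable(one_call("chr1", 1000, 2000),
                         one_call("chr1", 1000, 3500), p))   # end apart
  expect_false(mergeable(one_call("chr1", 1000, 2000),
                         one_call("chr2", 1000, 2000), p))
})

test_that("a single call passes through as its own consensus record", {
  a <- one_call("chr1", 5000, 6000)
  cons <- merge_callsets(a)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$pos, 5000L)
  expect_equal(cons$end, 6000L)
  expect_equal(cons$support, "a")
  expect_equal(cons$n_support, 1L)
})

test_that("two concordant callers produce lower-median representatives", {
  calls <- dplyr::bind_rows(one_call("chr1", 1000, 2000, caller = "A"),
                            one_call("chr1", 1010, 1995, caller = "B"))
  cons <- merge_callsets(calls)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$pos, 1000L)      # lower median of {1000, 1010}
  expect_equal(cons$end, 1995L)      # lower median of {1995, 2000}
  expect_equal(cons$svlen, 995L)     # recomputed from representatives
  expect_equal(cons$support, "A,B")
})

test_that("clustering is transitive: chains collapse into one component", {
  # A-B mergeable and B-C mergeable but A-C not (pos 0, 900, 1800)
  calls <- dplyr::bind_rows(
    one_call("chr1", 1000, 2000, caller = "A"),
    one_call("chr1", 1900, 2900, caller = "B"),
    one_call("chr1", 2800, 3800, caller = "C"))
  p <- merge_params(max_dist = 1000)
  expect_true(mergeable(calls[1, ], calls[2, ], p))
  expect_true(mergeable(calls[2, ], calls[3, ], p))
  expect_false(mergeable(calls[1, ], calls[3, ], p))
  cons <- merge_callsets(calls, p)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$support, "A,B,C")
})

test_that("one caller contributing twice counts once in support", {
  calls <- dplyr::bind_rows(one_call("chr1", 1000, 2000, caller = "A"),
                            one_call("chr1", 1005, 2003, caller = "A"),
                            one_call("chr1", 1010, 1995, caller = "B"))
  cons <- merge_callsets(calls)
  expect_equal(cons$n_support, 2L)
  expect_equal(cons$pos, 1005L)   # representatives use all three members
})

test_that("min_support discards weakly supported components", {
  calls <- dplyr::bind_rows(one_call("chr1", 1000, 2000, caller = "A"),
                            one_call("chr1", 1010, 1995, caller = "B"),
                            one_call("chr1", 50000, 51000, caller = "A"))
  cons <- merge_callsets(calls, merge_params(min_support = 2))
  expect_equal(nrow(cons), 1)
  expect_equal(cons$support, "A,B")
})

test_that("mixed samples are rejected and empty input yields empty output", {
  a <- one_call("chr1", 1000, 2000)
  b <- one_call("chr1", 1010, 1995, caller = "b")
  b$sample <- "other"
  expect_error(merge_callsets(dplyr::bind_rows(a, b)), "sample")
  expect_equal(nrow(merge_callsets(sv_calls(caller = character()))), 0)
})

test_that("breakends merge only when anchor and mate both agree", {
  bnd <- function(pos, mate_ctg, mate_pos, caller) {
    x <- sv_calls(contig = "chr1", pos = as.integer(pos),
                  end = as.integer(pos), svtype = "BND", svlen = 0L,
                  caller = caller, mate_contig = mate_ctg,
                  mate_pos = as.integer(mate_pos))
    x
  }
  p <- merge_params()
  expect_true(mergeable(bnd(1000, "chr5", 200, "a"),
                        bnd(1400, "chr5", 600, "b"), p))
  expect_false(mergeable(bnd(1000, "chr5", 200, "a"),
                         bnd(1400, "chr6", 200, "b"), p))
  expect_false(mergeable(bnd(1000, "chr5", 200, "a"),
                         bnd(1400, "chr5", 5000, "b"), p))
  cons <- merge_callsets(dplyr::bind_rows(bnd(1000, "chr5", 200, "a"),
                                          bnd(1400, "chr5", 600, "b")))
  expect_equal(nrow(cons), 1)
  expect_equal(cons$svtype, "BND")
  expect_equal(cons$n_support, 2L)
})

test_that("merging agrees with the brute-force oracle on random inputs", {
  withr::local_seed(101)
  for (k in 1:60) {
    n <- sample(2:80, 1)
    params <- merge_params(max_dist = sample(c(100, 500, 1000, 2000), 1),
                           require_type_match = k %% 5 != 0)
    calls <- random_calls(n)
    cons <- merge_callsets(calls, params)
    oracle <- oracle_consensus(calls, params)
    expect_equal(nrow(cons), nrow(oracle))
    expect_identical(
      partition_signature(lapply(cons$members, function(m) m$uid)),
      partition_signature(oracle$members))
    expect_equal(cons$pos, oracle$pos)
    expect_equal(cons$end, oracle$end)
    expect_equal(cons$support, oracle$support)
  }
})

test_that("consensus output is invariant under input permutation", {
  withr::local_seed(202)
  calls <- random_calls(120)
  base <- merge_callsets(calls)
  for (k in 1:5) {
    shuffled <- calls[sample.int(nrow(calls)), ]
    again <- merge_callsets(shuffled)
    expect_equal(dplyr::select(again, -"members"),
                 dplyr::select(base, -"members"))
  }
})

test_that("every surviving input call appears in exactly one component", {
  withr::local_seed(303)
  calls <- random_calls(150)
  cons <- merge_callsets(calls)
  uids <- unlist(lapply(cons$members, function(m) m$uid))
  expect_setequal(uids, calls$uid)
  expect_equal(anyDuplicated(uids), 0)
})

test_that("growing the merge window never increases the component count", {
  withr::local_seed(404)
  calls <- random_calls(150)
  counts <- vapply(c(50, 200, 500, 1000, 3000), function(d) {
    nrow(merge_callsets(calls, merge_params(max_dist = d)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
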