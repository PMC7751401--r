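simple_calls <- function(pos, end, svtype = "DEL", caller = "x",
                         contig = "chr1", filter = "PASS") {
  sv_calls(contig = contig, pos = as.integer(pos), end = as.integer(end),
           svtype = svtype, svlen = as.integer(abs(end - pos) + (svtype == "INS") * 100L),
           caller = caller, filter = filter)
}

test_that("breakpoint displacement within refdist matches; beyond does not", {
  truth <- simple_calls(6500, 7000, caller = "truth")
  hit <- match_calls(simple_calls(5000, 5500), truth, stratify = FALSE)
  expect_equal(hit$tp, 1)                       # both deltas 1500 <= 2000
  miss <- match_calls(simple_calls(4000, 4500), truth, stratify = FALSE)
  expect_equal(miss$tp, 0)                      # deltas 2500 > 2000
})

test_that("type and size-similarity gates are enforced", {
  truth <- simple_calls(5000, 5500, caller = "truth")
  ins <- sv_calls(contig = "chr1", pos = 5000L, end = 5000L, svtype = "INS",
                  svlen = 500L, caller = "x")
  expect_equal(match_calls(ins, truth, stratify = FALSE)$tp, 0)
  small <- simple_calls(5000, 5100)             # size 100 vs 500: ratio 0.2
  expect_equal(match_calls(small, truth, stratify = FALSE)$tp, 0)
  close_size <- simple_calls(5000, 5400)        # ratio 0.8
  expect_equal(match_calls(close_size, truth, stratify = FALSE)$tp, 1)
})

test_that("matching is one-to-one with deterministic tie-breaking", {
  truth <- simple_calls(c(1000, 1200), c(2000, 2200), caller = "truth")
  cand <- simple_calls(c(1100, 1100), c(2100, 2120))
  rep <- match_calls(cand, truth, stratify = FALSE)
  expect_equal(rep$tp, 2)
  # first candidate is equidistant (200) from both: takes the lower pos
  first <- rep$matches[rep$matches$cand_idx == 1, ]
  expect_equal(first$truth_idx, 1L)
})

test_that("passonly, BED restriction and empty truth behave as specified", {
  truth <- simple_calls(c(5000, 50000), c(6000, 51000), caller = "truth")
  cand <- simple_calls(c(5010, 50010), c(6010, 51010),
                       filter = c("PASS", "LowQual"))
  rep <- match_calls(cand, truth, match_params())
  expect_equal(rep$tp, 1)                       # LowQual candidate dropped
  expect_equal(rep$fn, 1)
  keep_all <- match_calls(cand, truth, match_params(passonly = FALSE))
  expect_equal(keep_all$tp, 2)
  bed <- tibble::tibble(contig = "chr1", start0 = 4000L, end0 = 10000L)
  in_bed <- match_calls(cand, truth, match_params(include_bed = bed))
  expect_equal(in_bed$tp + in_bed$fp, 1)        # only the first region call
  expect_equal(in_bed$fn, 0)
  empty <- match_calls(cand, sv_calls(caller = character()),
                       match_params(passonly = FALSE))
  expect_equal(empty$tp, 0)
  expect_equal(empty$fp, 2)                     # all candidates false
})

test_that("harmonic mean F1 handles the degenerate and equal cases", {
  expect_equal(f1(0.75, 0.75), 0.75)
  expect_equal(f1(0, 0), 0)
  p <- runif(50); r <- runif(50)
  f <- f1(p, r)
  expect_true(all(f >= pmin(p, r) - 1e-12 | pmin(p, r) == 0))
  expect_true(all(f <= pmax(p, r) + 1e-12))
})

test_that("stratified truth counts tile the unstratified totals", {
  withr::local_seed(55)
  truth <- random_calls(120, types = c("DEL", "DUP", "INV"))
  truth$caller <- "truth"
  cand <- random_calls(100, types = c("DEL", "DUP", "INV"))
  rep <- match_calls(cand, truth)
  expect_equal(sum(rep$per_stratum$tp + rep$per_stratum$fn),
               rep$tp + rep$fn)
  expect_equal(sum(rep$per_stratum$tp + rep$per_stratum$fp),
               rep$tp + rep$fp)
})

test_that("greedy matching is within one pair of the optimum", {
  withr::local_seed(66)
  params <- match_params(refdist = 500, pctsize = 0.7)
  for (k in 1:40) {
    nt <- sample(3:30, 1); nc <- sample(3:30, 1)
    truth <- random_calls(nt, pos_max = 20000L, size_max = 2000L,
                          types = "DEL")
    truth$caller <- "truth"
    cand <- random_calls(nc, pos_max = 20000L, size_max = 2000L,
                         types = "DEL")
    rep <- match_calls(cand, truth, params, stratify = FALSE)
    best <- oracle_max_matching(cand, truth, params)
    expect_lte(rep$tp, best)
    expect_gte(rep$tp, best - 1L)
  }
})

test_that("combination percentages conserve the total call count", {
  withr::local_seed(88)
  cfg <- sim_config(n_true = 150, seed = 88)
  ens <- simulate_ensemble(cfg)
  cons <- merge_callsets(ens$calls)
  combos <- combination_breakdown(cons, ens$truth)
  expect_equal(sum(combos$n_calls), sum(cons$svtype != "BND"))
  expect_equal(sum(combos$pct_of_calls), 100)
  expect_true(all(combos$precision >= 0 & combos$precision <= 1))
  expect_lte(sum(combos$recall_contribution), 1 + 1e-12)
})

test_that("single-combination precision equals its TP fraction", {
  cons <- tibble::tibble(
    contig = "chr1", pos = c(10000L, 50000L), end = c(11000L, 51000L),
    svtype = "DEL", svlen = 1000L, support = "manta", n_support = 1L,
    qv = NA_real_, genotype = "./.", sample = "s1",
    mate_contig = NA_character_, mate_pos = NA_integer_)
  truth <- simple_calls(10005, 11005, caller = "truth")
  combos <- combination_breakdown(cons, truth)
  expect_equal(combos$precision, 0.5)
  expect_equal(combos$recall_contribution, 1)
})

test_that("concordance is 1 for identical and 0 for disjoint call sets", {
  a <- random_consensus(30, seed = 9)
  expect_equal(concordance(a, a)$jaccard, 1)
  b <- dplyr::mutate(a, pos = pos + 500000L, end = end + 500000L)
  expect_equal(concordance(a, b)$jaccard, 0)
})

test_that("population AF falls back to carrier frequency without genotypes", {
  one <- random_consensus(1, seed = 3)
  one$sample <- "s1"
  one$genotype <- "./."
  af <- population_af(one, n_samples = 100)
  expect_equal(af$af, 0.01)
  expect_equal(af$carriers, 1L)
})

test_that("population AF counts alternate alleles when genotyped", {
  per_sample <- purrr::map(1:4, function(i) {
    x <- random_consensus(1, seed = 12)     # same SV in every sample
    x$sample <- paste0("s", i)
    x$genotype <- "1/1"
    x
  })
  af <- population_af(per_sample)
  expect_equal(af$af, 1)
  expect_equal(af$carriers, 4L)
  het <- purrr::map(per_sample, function(x) {
    x$genotype <- "0/1"
    x
  })
  expect_equal(population_af(het)$af, 0.5)
})

test_that("a rare-variant cohort yields a decreasing AF spectrum", {
  withr::local_seed(44)
  n_samples <- 60
  n_sv <- 250
  carriers <- pmin(1 + stats::rgeom(n_sv, 0.55), n_samples)
  pos <- 20000L * seq_len(n_sv)
  per_sample <- purrr::map(seq_len(n_sv), function(i) {
    smp <- sample.int(n_samples, carriers[i])
    p0 <- pos[i]
    tibble::tibble(
      contig = "chr1", pos = p0, end = p0 + 500L, svtype = "DEL",
      svlen = 500L, support = "manta", n_support = 1L, qv = NA_real_,
      genotype = "./.", sample = paste0("s", smp),
      mate_contig = NA_character_, mate_pos = NA_integer_)
  }) |> dplyr::bind_rows()
  af <- population_af(per_sample, n_samples = n_samples)
  expect_equal(nrow(af), n_sv)
  counts <- table(cut(af$af, breaks = c(0, 0.05, 0.1, 0.2, 1)))
  expect_true(all(diff(as.numeric(counts)) <= 0))
})
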