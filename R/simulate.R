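#' Caller error profile for the ensemble simulator
#'
#' Describes how one simulated caller distorts the truth: per-type (and
#' optionally per size class) detection sensitivity, a genome-wide false
#' call rate, Gaussian breakpoint jitter, and a multiplicative size error.
#'
#' @param sensitivity Either a single detection probability, a named vector
#'   by SV type (`DEL`, `DUP`, `INS`, `INV`), or a named vector by
#'   `type:bin` keys such as `"DEL:SMALL"` (most specific key wins).
#' @param fp_per_mb Expected false calls per megabase of genome (Poisson).
#' @param jitter_sd Standard deviation in bp of the zero-mean Gaussian
#'   perturbation applied independently to each breakpoint.
#' @param size_error Fractional standard deviation of the multiplicative
#'   size perturbation.
#' @return A list with class `caller_profile`.
#' @export
caller_profile <- function(sensitivity = 0.7, fp_per_mb = 1,
                           jitter_sd = 50, size_error = 0.05) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            fp_per_mb >= 0, jitter_sd >= 0, size_error >= 0)
  structure(list(sensitivity = sensitivity, fp_per_mb = fp_per_mb,
                 jitter_sd = jitter_sd, size_error = size_error),
            class = "caller_profile")
}

#' Simulation configuration
#'
#' Defines a fictitious genome, a truth-SV distribution and a set of caller
#' error profiles. The defaults emulate a five-caller short-read ensemble
#' with the heterogeneity seen across real SV callers: sensitivities from
#' 0.35 to 0.9, false-call rates from 0.2 to 4 per Mb, and breakpoint
#' jitter from 10 to 150 bp.
#'
#' @param contigs Named vector of contig lengths in bp.
#' @param n_true Number of truth SVs to place.
#' @param type_mix Named probability vector over `DEL`, `DUP`, `INS`,
#'   `INV`; must sum to 1.
#' @param size_range Log-uniform size bounds in bp.
#' @param callers Named list of [caller_profile()] objects.
#' @param exclusion Minimum gap in bp between truth events (twice the
#'   default merge distance, so distinct truth events never cluster).
#' @param seed Master seed; all per-caller streams derive from it.
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(contigs = c(ctgA = 6e7, ctgB = 5e7, ctgC = 4e7,
                                   ctgD = 3e7, ctgE = 2e7),
                       n_true = 1000L,
                       type_mix = c(DEL = 0.55, DUP = 0.15, INS = 0.15,
                                    INV = 0.15),
                       size_range = c(50, 1e5),
                       callers = default_caller_profiles(),
                       exclusion = 2000L,
                       seed = 1L) {
  stopifnot(all(contigs > 0), n_true >= 0,
            abs(sum(type_mix) - 1) < 1e-8, all(type_mix >= 0),
            length(size_range) == 2, size_range[1] >= 50,
            size_range[2] >= size_range[1])
  structure(list(contigs = contigs, n_true = as.integer(n_true),
                 type_mix = type_mix, size_range = size_range,
                 callers = callers, exclusion = as.integer(exclusion),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_caller_profiles <- function() {
  list(
    breakdancer = caller_profile(sensitivity = c(DEL = 0.55, DUP = 0.30,
                                                 INS = 0.10, INV = 0.40),
                                 fp_per_mb = 2.0, jitter_sd = 100,
                                 size_error = 0.10),
    cnvnator = caller_profile(sensitivity = c(DEL = 0.35, DUP = 0.60,
                                              INS = 0.00, INV = 0.00),
                              fp_per_mb = 4.0, jitter_sd = 150,
                              size_error = 0.15),
    delly = caller_profile(sensitivity = c(DEL = 0.65, DUP = 0.45,
                                           INS = 0.15, INV = 0.55),
                           fp_per_mb = 1.0, jitter_sd = 30,
                           size_error = 0.05),
    lumpy = caller_profile(sensitivity = c(DEL = 0.60, DUP = 0.40,
                                           INS = 0.05, INV = 0.50),
                           fp_per_mb = 1.5, jitter_sd = 40,
                           size_error = 0.05),
    manta = caller_profile(sensitivity = c(DEL = 0.90, DUP = 0.55,
                                           INS = 0.45, INV = 0.65),
                           fp_per_mb = 0.2, jitter_sd = 10,
                           size_error = 0.02)
  )
}

# Deterministic 31-bit polynomial hash of a string; keeps per-caller seeds
# stable when callers are added or reordered.
stable_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

caller_seed <- function(master, name) {
  as.integer((as.numeric(master) + stable_hash(name)) %% 2147483647)
}

sample_sizes <- function(n, size_range) {
  as.integer(round(exp(stats::runif(n, log(size_range[1]),
                                    log(size_range[2])))))
}

#' Simulate a truth SV set
#'
#' Places `n_true` events with types drawn from `type_mix`, log-uniform
#' sizes, and positions uniform over the genome (per contig, proportional
#' to length), rejecting placements closer than `exclusion` bp to an
#' accepted event so truth events never fall within one merge window of
#' each other. Deterministic given the config seed.
#'
#' @param config A [sim_config()] object.
#' @return A truth calls tibble with `caller = "truth"` and an `origin` id
#'   per event.
#' @export
simulate_truth <- function(config) {
  withr::with_seed(config$seed, simulate_truth_impl(config))
}

simulate_truth_impl <- function(config) {
  if (config$n_true == 0) return(sv_calls(caller = character()))
  mean_size <- diff(config$size_range) /
    log(config$size_range[2] / config$size_range[1])
  needed <- config$n_true * (mean_size + 2 * config$exclusion)
  if (sum(config$contigs) < needed) {
    stop("genome too small for ", config$n_true, " disjoint events; ",
         "need roughly ", format(round(needed), big.mark = ","),
         " bp, have ", format(sum(config$contigs), big.mark = ","),
         call. = FALSE)
  }
  placed <- list()
  occupied <- stats::setNames(
    lapply(names(config$contigs), function(x) matrix(numeric(0), ncol = 2)),
    names(config$contigs))
  n_done <- 0
  attempts <- 0
  max_attempts <- 200 * config$n_true
  while (n_done < config$n_true && attempts < max_attempts) {
    attempts <- attempts + 1
    ctg <- sample(names(config$contigs), 1, prob = config$contigs)
    size <- sample_sizes(1, config$size_range)
    span <- if (size >= config$contigs[[ctg]] - 2) next else size
    pos <- sample.int(config$contigs[[ctg]] - span - 1L, 1)
    lo <- pos - config$exclusion
    hi <- pos + span + config$exclusion
    occ <- occupied[[ctg]]
    if (nrow(occ) > 0 && any(occ[, 1] <= hi & occ[, 2] >= lo)) next
    occupied[[ctg]] <- rbind(occ, c(pos, pos + span))
    type <- sample(names(config$type_mix), 1, prob = config$type_mix)
    n_done <- n_done + 1
    placed[[n_done]] <- tibble::tibble(
      contig = ctg, pos = as.integer(pos),
      end = if (type == "INS") as.integer(pos) else as.integer(pos + size),
      svtype = type, svlen = size
    )
  }
  if (n_done < config$n_true) {
    stop("genome too small to place ", config$n_true,
         " events with the exclusion buffer", call. = FALSE)
  }
  truth <- dplyr::bind_rows(placed)
  truth <- sv_calls(contig = truth$contig, pos = truth$pos, end = truth$end,
                    svtype = truth$svtype, svlen = truth$svlen,
                    caller = "truth", genotype = "0/1")
  truth$origin <- paste0("truth", seq_len(nrow(truth)))
  truth
}

profile_sensitivity <- function(profile, svtype, bin) {
  s <- profile$sensitivity
  if (is.null(names(s))) return(rep_len(s, length(svtype)))
  key_tb <- paste0(svtype, ":", bin)
  out <- unname(s[key_tb])
  out[is.na(out)] <- unname(s[svtype[is.na(out)]])
  out[is.na(out)] <- 0
  out
}

#' Simulate one caller's output from a truth set
#'
#' Each truth event is detected independently with the profile's
#' sensitivity for its type and size class. Detected calls have both
#' breakpoints perturbed by independent rounded Gaussian jitter and their
#' size by a multiplicative Gaussian error, with the end clamped so the
#' size never drops below the 50 bp SV floor. False calls arrive as a
#' Poisson process at `fp_per_mb`, with positions uniform over the genome
#' and types/sizes from the truth distribution; their `origin` is `NA`.
#'
#' @param truth Truth calls tibble from [simulate_truth()].
#' @param profile A [caller_profile()].
#' @param config The [sim_config()] (for genome layout and size law).
#' @param caller Caller name recorded in the output.
#' @param seed Stream seed for this caller.
#' @return A labeled calls tibble.
#' @export
simulate_caller_output <- function(truth, profile, config, caller,
                                   seed = config$seed) {
  withr::with_seed(seed,
                   simulate_caller_impl(truth, profile, config, caller))
}

simulate_caller_impl <- function(truth, profile, config, caller) {
  detected <- if (nrow(truth) > 0) {
    sens <- profile_sensitivity(profile, truth$svtype,
                                size_bin(truth$svlen, truth$svtype))
    truth[stats::runif(nrow(truth)) < sens, , drop = FALSE]
  } else truth
  if (nrow(detected) > 0) {
    n <- nrow(detected)
    pos <- detected$pos + as.integer(round(stats::rnorm(n, 0,
                                                        profile$jitter_sd)))
    end <- detected$end + as.integer(round(stats::rnorm(n, 0,
                                                        profile$jitter_sd)))
    size_scale <- pmax(0.1, 1 + stats::rnorm(n, 0, profile$size_error))
    pos <- pmax(1L, pos)
    ins <- detected$svtype == "INS"
    svlen <- integer(n)
    svlen[ins] <- pmax(50L, as.integer(round(detected$svlen[ins] *
                                               size_scale[ins])))
    end[ins] <- pos[ins]
    if (any(!ins)) {
      raw <- pmax(50L, as.integer(round((end[!ins] - pos[!ins]) *
                                          size_scale[!ins])))
      end[!ins] <- pos[!ins] + raw
      svlen[!ins] <- raw
    }
    detected <- dplyr::mutate(detected, pos = pos, end = end, svlen = svlen,
                              caller = .env$caller)
  }
  genome_mb <- sum(config$contigs) / 1e6
  n_fp <- stats::rpois(1, profile$fp_per_mb * genome_mb)
  fps <- if (n_fp > 0) {
    ctg <- sample(names(config$contigs), n_fp, replace = TRUE,
                  prob = config$contigs)
    size <- sample_sizes(n_fp, config$size_range)
    type <- sample(names(config$type_mix), n_fp, replace = TRUE,
                   prob = config$type_mix)
    pos <- vapply(seq_len(n_fp), function(i) {
      limit <- max(2, config$contigs[[ctg[i]]] - size[i] - 1)
      sample.int(limit, 1)
    }, numeric(1)) |> as.integer()
    tibble::tibble(
      contig = ctg, pos = pos,
      end = as.integer(ifelse(type == "INS", pos, pos + size)),
      svtype = type, svlen = size, caller = caller,
      sample = truth$sample[1] %||% "sample",
      qual = NA_real_, genotype = "0/1", filter = "PASS",
      mate_contig = NA_character_, mate_pos = NA_integer_,
      origin = NA_character_
    )
  } else NULL
  out <- dplyr::bind_rows(detected, fps)
  if (nrow(out) == 0) return(sv_calls(caller = character()))
  validate_sv_calls(out)
  sort_calls(out)
}

#' Simulate a full multi-caller ensemble
#'
#' One truth set plus one labeled call set per configured caller, each
#' caller on an independent stream derived from the master seed plus a
#' stable hash of the caller name — adding a caller never perturbs the
#' other callers' outputs. Fully deterministic given the config.
#'
#' @param config A [sim_config()] object.
#' @return A list with class `sv_ensemble`: `truth` (calls tibble),
#'   `calls` (stacked per-caller tibble, `origin` labeling each call's
#'   truth event or `NA` for false calls) and the `config`.
#' @export
simulate_ensemble <- function(config = sim_config()) {
  truth <- simulate_truth(config)
  calls <- purrr::imap(config$callers, function(profile, name) {
    simulate_caller_output(truth, profile, config, caller = name,
                           seed = caller_seed(config$seed, name))
  }) |> dplyr::bind_rows()
  structure(list(truth = truth, calls = calls, config = config),
            class = "sv_ensemble")
}

#' @export
print.sv_ensemble <- function(x, ...) {
  cat("Simulated SV ensemble:", nrow(x$truth), "truth events,",
      dplyr::n_distinct(x$calls$caller), "callers,",
      nrow(x$calls), "calls\n")
  invisible(x)
}

#' Read/write a simulation configuration as YAML
#'
#' @param path Path to the YAML file.
#' @return For `read_sim_config()`, a [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  callers <- purrr::map(y$callers, function(p) {
    caller_profile(sensitivity = unlist(p$sensitivity),
                   fp_per_mb = p$fp_per_mb %||% 1,
                   jitter_sd = p$jitter_sd %||% 50,
                   size_error = p$size_error %||% 0.05)
  })
  sim_config(contigs = unlist(y$contigs),
             n_true = y$n_true %||% 1000L,
             type_mix = unlist(y$type_mix) %||%
               c(DEL = 0.55, DUP = 0.15, INS = 0.15, INV = 0.15),
             size_range = unlist(y$size_range) %||% c(50, 1e5),
             callers = callers,
             exclusion = y$exclusion %||% 2000L,
             seed = y$seed %||% 1L)
}

#' @rdname read_sim_config
#' @param config A [sim_config()] object to serialize.
#' @export
write_sim_config <- function(config, path) {
  y <- list(
    contigs = as.list(config$contigs),
    n_true = config$n_true,
    type_mix = as.list(config$type_mix),
    size_range = as.numeric(config$size_range),
    exclusion = config$exclusion,
    seed = config$seed,
    callers = purrr::map(config$callers, function(p) {
      list(sensitivity = as.list(p$sensitivity), fp_per_mb = p$fp_per_mb,
           jitter_sd = p$jitter_sd, size_error = p$size_error)
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
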