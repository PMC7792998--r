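#' Four-arm initialization benchmark
#'
#' Reproduces the comparison of iterative phase retrieval under four
#' initializations on held-out patterns: (i) random phase with the central
#' rectangular support; (ii) random phase with the support binarized from the
#' CNN amplitude; (iii) CNN phase and support; (iv) the NNS match's amplitude
#' and phase (support binarized from its amplitude). Random-phase arms are
#' repeated `replicates` times with independent seeds; per-iteration
#' chi-squared traces are averaged with their standard deviation.
#'
#' @param model A trained `inverter_model`.
#' @param dataset A `cdi_dataset` (queries come from its validation split).
#' @param index An [nns_index()] built from the same corpus (default: built
#'   from the training split).
#' @param n_queries Number of validation patterns to benchmark.
#' @param replicates Independent random restarts for arms (i) and (ii).
#' @param schedule List of [schedule_step()]s; by default the standard
#'   ER/HIO switch schedule with shrink-wrap refinement active, applied
#'   uniformly to all arms so imperfect binarized supports can both grow and
#'   shrink during the run.
#' @param support_threshold Binarization threshold for CNN/NNS supports. The
#'   default is deliberately low: particle edges are Gaussian-smoothed, and a
#'   high cut visibly truncates the amplitude skirt at coarse resolution.
#' @param seed Integer seed.
#' @return A `benchmark_report`: `results` (tibble: query, arm, replicate,
#'   start/final chi2, CNN-alone chi2), `traces` (tibble: query, arm,
#'   iteration, mean and sd of chi2), `meta`.
#' @export
run_benchmark <- function(model, dataset, index = NULL, n_queries = 3L,
                          replicates = 5L,
                          schedule = default_schedule(shrinkwrap = TRUE),
                          support_threshold = 0.02, seed = 1L) {
  if (is.null(index)) index <- nns_index(dataset)
  va <- dataset$split$validation
  if (!length(va)) stop("dataset has no validation split to query")
  n_queries <- min(n_queries, length(va))
  queries <- va[seq_len(n_queries)]
  n_det <- model$config$input_size
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                             n_queries * replicates * 2L),
                                  nrow = n_queries))
  res <- list(); tr <- list()
  for (qi in seq_along(queries)) {
    i <- queries[qi]
    s <- dataset$samples[[i]]
    pat <- s$pattern
    cnn <- infer(model, pat, support_threshold = support_threshold)
    meas <- normalize_pattern(pat$intensity)
    calc <- Mod(fft2c(central_embed(cnn$amplitude * exp(1i * cnn$phase), n_det)))
    cnn_chi2 <- chi2_modulus(calc / max(calc), meas)
    sup_cnn <- support_from_amplitude(cnn$amplitude, support_threshold, n_det)
    cnn_init <- central_embed(cnn$amplitude * exp(1i * cnn$phase), n_det)
    nq <- nns_query(index, pat)
    nns_init <- central_embed(nq$amplitude *
                                exp(1i * (2 * pi * nq$phase_scaled - pi)), n_det)
    sup_nns <- support_from_amplitude(nq$amplitude, support_threshold, n_det)
    arms <- list(
      random_rect = list(init = "random", support = support_rect(n_det),
                         reps = replicates, seeds = seeds[qi, 1:replicates]),
      random_cnn_support = list(init = "random", support = sup_cnn,
                                reps = replicates,
                                seeds = seeds[qi, replicates + 1:replicates]),
      cnn_phase_support = list(init = cnn_init, support = sup_cnn,
                               reps = 1L, seeds = 1L),
      nns = list(init = nns_init, support = sup_nns, reps = 1L, seeds = 1L)
    )
    for (arm in names(arms)) {
      a <- arms[[arm]]
      traces <- matrix(NA_real_, nrow = 0, ncol = 0)
      for (r in seq_len(a$reps)) {
        out <- run_schedule(pat, init_phase = a$init, init_support = a$support,
                            schedule = schedule, seed = a$seeds[r])
        if (!nrow(traces)) traces <- matrix(NA_real_, length(out$trace$chi2), a$reps)
        traces[, r] <- out$trace$chi2
        res[[length(res) + 1L]] <- tibble::tibble(
          query = i, arm = arm, replicate = r,
          start_chi2 = out$trace$chi2[1], final_chi2 = out$final_chi2,
          cnn_chi2 = cnn_chi2, nns_chi2 = nq$chi2)
      }
      tr[[length(tr) + 1L]] <- tibble::tibble(
        query = i, arm = arm, iteration = seq_len(nrow(traces)),
        chi2_mean = rowMeans(traces),
        chi2_sd = apply(traces, 1, sd))
    }
  }
  structure(list(results = do.call(rbind, res), traces = do.call(rbind, tr),
                 meta = list(n_queries = n_queries, replicates = replicates,
                             support_threshold = support_threshold, seed = seed)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>\n")
  print(summarize_benchmark(x))
  invisible(x)
}

#' Per-arm summary of a benchmark report
#'
#' @param report A `benchmark_report`.
#' @return Tibble with per-arm mean and sd of starting and final chi2.
#' @export
summarize_benchmark <- function(report) {
  r <- report$results
  arms <- unique(r$arm)
  do.call(rbind, lapply(arms, function(a) {
    d <- r[r$arm == a, ]
    tibble::tibble(arm = a, runs = nrow(d),
                   start_chi2_mean = mean(d$start_chi2),
                   start_chi2_sd = sd(d$start_chi2),
                   final_chi2_mean = mean(d$final_chi2),
                   final_chi2_sd = sd(d$final_chi2))
  }))
}

#' @rdname summarize_benchmark
#' @param x A `benchmark_report`.
#' @param ... Unused.
#' @export
tidy.benchmark_report <- function(x, ...) x$results

#' @rdname summarize_benchmark
#' @export
glance.benchmark_report <- function(x, ...) {
  s <- summarize_benchmark(x)
  tibble::tibble(
    n_queries = x$meta$n_queries,
    replicates = x$meta$replicates,
    cnn_chi2_mean = mean(x$results$cnn_chi2[!duplicated(x$results$query)]),
    nns_chi2_mean = mean(x$results$nns_chi2[!duplicated(x$results$query)]),
    hybrid_final_chi2_mean = s$final_chi2_mean[s$arm == "cnn_phase_support"],
    random_final_chi2_mean = s$final_chi2_mean[s$arm == "random_rect"]
  )
}

#' Render a human-readable benchmark summary
#'
#' @param report A `benchmark_report`.
#' @return Character vector of summary lines (also printed).
#' @export
report_text <- function(report) {
  s <- summarize_benchmark(report)
  if (!nrow(s)) {
    lines <- "benchmark report: no data"
  } else {
    lines <- c("Four-arm initialization benchmark",
               sprintf("  queries: %d, replicates (random arms): %d",
                       report$meta$n_queries, report$meta$replicates),
               sprintf("  %-22s start chi2 %.4g +/- %.4g   final chi2 %.4g +/- %.4g",
                       s$arm, s$start_chi2_mean,
                       ifelse(is.na(s$start_chi2_sd), 0, s$start_chi2_sd),
                       s$final_chi2_mean,
                       ifelse(is.na(s$final_chi2_sd), 0, s$final_chi2_sd)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Run the full desk-scale study
#'
#' One call reproducing the package's end-to-end comparison at desk scale:
#' generate a simulated corpus, train the two-branch inverter, evaluate it
#' and the NNS baseline on the held-out split, and run the four-arm
#' initialization benchmark. All randomness derives from `seed`.
#'
#' The default problem size (grid 32, 800 samples, 26 + 10 epochs) is the
#' package's standard desk configuration: large enough for the orderings of
#' interest (CNN vs NNS, phase vs amplitude error, hybrid vs CNN-alone) to be
#' reproducible, small enough to run on one CPU in minutes.
#'
#' @param seed Master seed.
#' @param n_samples Corpus size.
#' @param grid_n Object/detector grid size.
#' @param base_channels,depth Model size (see [model_config()]).
#' @param epochs Length-2 integer vector: epochs at `lr` and at `lr / 3`.
#' @param batch_size,lr Training batch size and initial learning rate.
#' @param n_queries,replicates Benchmark arms (see [run_benchmark()]).
#' @param verbose Print progress.
#' @return List: `dataset`, `model`, `cnn_eval` (tibble from
#'   [evaluate_on_split()]), `nns_eval` (tibble from [nns_evaluate()]),
#'   `benchmark` (a `benchmark_report`), `summary` (one-row tibble of the
#'   headline numbers).
#' @export
run_desk_study <- function(seed = 1L, n_samples = 800L, grid_n = 32L,
                           base_channels = 10L, depth = 3L,
                           epochs = c(26L, 10L), batch_size = 32L, lr = 1e-3,
                           n_queries = 3L, replicates = 5L, verbose = FALSE) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 8L))
  cfg <- simulator_config(grid_spec(grid_n))
  ds <- make_dataset(n_samples, cfg, seed = seeds[1])
  mc <- model_config(input_size = grid_n, base_channels = base_channels,
                     depth = depth, batch_norm = TRUE)
  m <- build_model(mc, seed = seeds[2])
  m <- train_inverter(m, ds, epochs = epochs[1], batch_size = batch_size,
                      lr = lr, seed = seeds[3], verbose = verbose)
  if (length(epochs) > 1 && epochs[2] > 0) {
    m <- train_inverter(m, ds, epochs = epochs[2], batch_size = batch_size,
                        lr = lr / 3, seed = seeds[4], verbose = verbose)
  }
  cnn_eval <- evaluate_on_split(m, ds, "validation")
  index <- nns_index(ds)
  nns_eval <- nns_evaluate(index, ds)
  bm <- run_benchmark(m, ds, index = index, n_queries = n_queries,
                      replicates = replicates, seed = seeds[5])
  s <- summarize_benchmark(bm)
  learned <- s$arm %in% c("cnn_phase_support", "random_cnn_support")
  summary <- tibble::tibble(
    chi2_modulus_cnn = mean(cnn_eval$chi2_modulus),
    chi2_amplitude_cnn = mean(cnn_eval$chi2_amplitude),
    chi2_phase_cnn = mean(cnn_eval$chi2_phase),
    chi2_modulus_nns = mean(nns_eval$chi2_modulus),
    start_chi2_learned = mean(s$start_chi2_mean[s$arm == "cnn_phase_support"]),
    start_chi2_random = mean(s$start_chi2_mean[s$arm == "random_rect"]),
    final_chi2_hybrid = s$final_chi2_mean[s$arm == "cnn_phase_support"],
    final_chi2_random = s$final_chi2_mean[s$arm == "random_rect"],
    n_train = length(ds$split$train),
    n_validation = length(ds$split$validation))
  list(dataset = ds, model = m, cnn_eval = cnn_eval, nns_eval = nns_eval,
       benchmark = bm, summary = summary)
}
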