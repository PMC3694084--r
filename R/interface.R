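#' Benchmark the Jacobian workload across complexity, data length and strategy
#'
#' For each combination of model complexity (free-parameter count), data
#' length (samples) and arrangement strategy, scales the base model, tiles
#' the dataset, runs one response-Jacobian computation and records the
#' deterministic makespan of the task arrangement under the fabric's cost
#' model together with informational wall-clock timings (which depend on the
#' host and are never asserted).
#'
#' @param base_spec base `erpdcm_spec` to scale
#' @param leadfield gain matrix for the base model
#' @param complexities free-parameter counts to benchmark
#' @param data_lengths epoch lengths (samples) to benchmark
#' @param strategies arrangement strategies
#' @param fabric a [fabric_descriptor()]
#' @param workers pool workers for the wall-clock measurement
#' @param snr,seed generation settings for the benchmark dataset
#' @param grid base time grid (ms) before tiling
#' @param path optional TSV output
#' @return data frame of benchmark records: `n_tasks`, `data_length`,
#'   `strategy`, `blocks`, `makespan`, and informational `wall_s` split into
#'   `compute_s` and `marshal_s`
#' @export
run_benchmark <- function(base_spec, leadfield,
                          complexities = n_parameters(base_spec),
                          data_lengths = 500L,
                          strategies = c("thread", "block", "blockX"),
                          fabric = fabric_descriptor(), workers = 1L,
                          snr = 10, seed = 1L,
                          grid = seq(0, 498, by = 2), path = NULL) {
  cells <- expand.grid(n_tasks = complexities, data_length = data_lengths,
                       strategy = strategies, stringsAsFactors = FALSE)
  if (nrow(cells) == 0) {
    out <- data.frame(n_tasks = integer(), data_length = integer(),
                      strategy = character(), blocks = integer(),
                      makespan = numeric(), compute_s = numeric(),
                      marshal_s = numeric(), wall_s = numeric())
    return(out)
  }
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    cell <- cells[k, ]
    rec <- tryCatch({
      t0 <- proc.time()[["elapsed"]]
      spec <- scale_model_complexity(base_spec, cell$n_tasks)
      ds <- simulate_erp(spec, prior_mean_theta(spec), leadfield,
                         snr = snr, seed = seed, grid = grid)
      ds <- extend_data_length(ds, cell$data_length)
      t1 <- proc.time()[["elapsed"]]
      jac <- response_jacobian_parallel(spec, prior_mean_theta(spec),
                                        leadfield, ds$input, ds$times,
                                        strategy = cell$strategy,
                                        fabric = fabric, workers = workers)
      t2 <- proc.time()[["elapsed"]]
      a <- assign_tasks(cell$n_tasks, cell$strategy, fabric)
      data.frame(cell, blocks = length(a$blocks),
                 makespan = makespan(a, fabric)$makespan,
                 compute_s = t2 - t1, marshal_s = t1 - t0,
                 wall_s = t2 - t0)
    }, error = function(e) {
      warning("benchmark cell (N=", cell$n_tasks, ", L=", cell$data_length,
              ", ", cell$strategy, ") failed: ", conditionMessage(e),
              call. = FALSE)
      data.frame(cell, blocks = NA_integer_, makespan = NA_real_,
                 compute_s = NA_real_, marshal_s = NA_real_,
                 wall_s = NA_real_)
    })
    rec
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' Simulate, invert and compare models end to end
#'
#' Runs a full synthetic group study: generate one dataset per subject from
#' the generating model (subject-specific noise seeds), invert every
#' candidate model on every subject, and select the winning architecture by
#' fixed-effects Bayesian model selection. All artifacts — datasets,
#' posteriors, the evidence table, the BMS report and a reproducibility
#' manifest — are written under `out_dir` when given.
#'
#' @param generating_spec the true `erpdcm_spec`
#' @param theta_true true parameter vector for the generating model
#' @param candidate_specs named list of candidate `erpdcm_spec`s to compare
#' @param leadfield gain matrix shared by all subjects
#' @param n_subjects number of subjects
#' @param snr trial-averaged SNR of each subject's data
#' @param seed master seed; subject seeds are derived deterministically
#' @param grid time grid (ms)
#' @param input stimulus
#' @param subject_sd standard deviation of subject-specific jitter added to
#'   the true parameters (0 = identical subjects)
#' @param options EM options passed to [dcm_invert()]
#' @param backend,strategy,workers Jacobian execution settings
#' @param out_dir optional output directory for artifacts
#' @return list: `evidence` (subjects x models), `bms`, `posteriors` (list of
#'   lists), `seed`
#' @export
end_to_end <- function(generating_spec, theta_true, candidate_specs,
                       leadfield, n_subjects = 10L, snr = 10, seed = 1L,
                       grid = seq(0, 248, by = 4), input = stimulus_input(),
                       subject_sd = 0, options = list(),
                       backend = "serial", strategy = "blockX",
                       workers = 1L, out_dir = NULL) {
  if (is.null(names(candidate_specs)))
    names(candidate_specs) <- paste0("model", seq_along(candidate_specs))
  evidence <- matrix(NA_real_, n_subjects, length(candidate_specs),
                     dimnames = list(NULL, names(candidate_specs)))
  posteriors <- vector("list", n_subjects)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_len(n_subjects)) {
    th_s <- theta_true
    if (subject_sd > 0)
      th_s <- theta_true + with_local_seed(
        sub_seed(seed, 1000L + s),
        stats::rnorm(length(theta_true), sd = subject_sd))
    ds <- tryCatch(
      simulate_erp(generating_spec, th_s, leadfield, input, snr = snr,
                   seed = sub_seed(seed, s), grid = grid),
      error = function(e) stop("simulation stage failed for subject ", s,
                               ": ", conditionMessage(e), call. = FALSE))
    if (!is.null(out_dir))
      write_dataset(ds, file.path(out_dir, sprintf("subject%02d", s)))
    posteriors[[s]] <- lapply(names(candidate_specs), function(mname) {
      cand <- candidate_specs[[mname]]
      post <- tryCatch(
        dcm_invert(ds, cand, leadfield, input = input, options = options,
                   backend = backend, strategy = strategy,
                   workers = workers),
        error = function(e) stop("inversion stage failed (subject ", s,
                                 ", ", mname, "): ", conditionMessage(e),
                                 call. = FALSE))
      if (!is.null(out_dir))
        write_posterior(post, file.path(
          out_dir, sprintf("posterior_s%02d_%s.json", s, mname)))
      post
    })
    names(posteriors[[s]]) <- names(candidate_specs)
    evidence[s, ] <- vapply(posteriors[[s]], function(p)
      suppressWarnings(as.numeric(log_evidence(p))), numeric(1))
  }
  bms <- fixed_effects_bms(evidence)
  if (!is.null(out_dir)) {
    write_evidence_table(evidence, file.path(out_dir, "evidence.tsv"))
    jsonlite::write_json(
      list(sum_log_evidence = as.list(bms$sum_log_evidence),
           probability = as.list(bms$probability), best = bms$best),
      file.path(out_dir, "bms.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    manifest <- list(package_version = as.character(utils::packageVersion("erpdcm")),
                     r_version = R.version.string,
                     seed = seed, n_subjects = n_subjects, snr = snr,
                     subject_sd = subject_sd, grid = range(grid),
                     n_samples = length(grid),
                     models = names(candidate_specs),
                     backend = backend, strategy = strategy,
                     workers = workers,
                     theta_true = as.list(theta_true))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(evidence = evidence, bms = bms, posteriors = posteriors, seed = seed)
}
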