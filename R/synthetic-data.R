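#' Generate a synthetic ERP dataset with known ground truth
#'
#' Integrates the generating model, maps it through the lead field and adds
#' Gaussian sensor noise calibrated so that the trial-averaged
#' signal-to-noise ratio — peak signal power over noise power after averaging
#' `n_trials` trials — equals `snr`. The default sampling rate (250 Hz) and
#' peristimulus window (0–900 ms) match a typical averaged evoked-response
#' recording.
#'
#' @param spec generating `erpdcm_spec`
#' @param theta true parameter vector
#' @param leadfield gain matrix (channels x sources)
#' @param input an `erpdcm_input`
#' @param snr trial-averaged peak-power signal-to-noise ratio (> 0; `Inf`
#'   for noise-free data)
#' @param n_trials number of trials averaged (>= 1)
#' @param seed RNG seed; the same seed regenerates the identical dataset
#' @param srate sampling rate (Hz), used when `grid` is not given
#' @param window peristimulus window `c(start, end)` in ms
#' @param grid explicit time grid (ms); overrides `srate`/`window`
#' @return object of class `erpdcm_dataset`: `y` (list of channels x time
#'   matrices per condition), `times`, `srate`, `conditions`, `input`, and a
#'   `ground_truth` record (`spec`, `theta`, `leadfield`, `noise_var`,
#'   `snr`, `n_trials`, `seed`)
#' @export
simulate_erp <- function(spec, theta = prior_mean_theta(spec), leadfield,
                         input = stimulus_input(), snr = 10, n_trials = 1L,
                         seed = 1L, srate = 250, window = c(0, 900),
                         grid = NULL) {
  stopifnot(snr > 0, n_trials >= 1)
  if (is.null(grid)) grid <- seq(window[1], window[2], by = 1000 / srate)
  h <- predict_response(spec, theta, leadfield, input, grid)
  peak_power <- max(vapply(h, function(m) max(m^2), numeric(1)))
  noise_var_avg <- if (is.infinite(snr)) 0 else peak_power / snr
  y <- with_local_seed(seed, lapply(h, function(m) {
    if (noise_var_avg == 0) return(m)
    m + matrix(stats::rnorm(length(m), sd = sqrt(noise_var_avg)),
               nrow(m), ncol(m))
  }))
  structure(list(y = y, times = grid, srate = 1000 / mean(diff(grid)),
                 conditions = spec$conditions, input = input,
                 ground_truth = list(spec = spec, theta = theta,
                                     leadfield = leadfield,
                                     noise_var = noise_var_avg * n_trials,
                                     snr = snr, n_trials = n_trials,
                                     seed = seed)),
            class = "erpdcm_dataset")
}

#' @export
print.erpdcm_dataset <- function(x, ...) {
  cat("ERP dataset:", nrow(x$y[[1]]), "channels x", length(x$times),
      "samples,", length(x$conditions), "condition(s),",
      round(x$srate, 1), "Hz\n")
  invisible(x)
}

#' Extend a dataset by epoch concatenation
#'
#' Tiles the epoch along time and truncates to the requested length — the
#' standard trick for benchmarking how computation scales with data length
#' without changing the data's statistics. Sample `k` (0-based) of the
#' extended data equals sample `k mod L` of the original length-`L` epoch.
#'
#' @param dataset an `erpdcm_dataset`
#' @param target_length desired number of samples (>= 1)
#' @return the extended `erpdcm_dataset`
#' @export
extend_data_length <- function(dataset, target_length) {
  target_length <- as.integer(target_length)
  stopifnot(target_length >= 1)
  L <- length(dataset$times)
  idx <- ((seq_len(target_length) - 1L) %% L) + 1L
  dataset$y <- lapply(dataset$y, function(m) m[, idx, drop = FALSE])
  dt <- 1000 / dataset$srate
  dataset$times <- dataset$times[1] + (seq_len(target_length) - 1L) * dt
  dataset
}

#' Scale a model's complexity to a target parameter count
#'
#' Enables additional free parameters in a deterministic order — forward,
#' backward and lateral connections (column-major), condition modulations,
#' then per-source intrinsic deviations with duplicated-prior copies — until
#' the free-parameter count equals `target_N`. Used to benchmark how the
#' per-iteration Jacobian workload grows with model complexity.
#'
#' @param spec base `erpdcm_spec`
#' @param target_N desired number of free parameters (>= the base count)
#' @return an `erpdcm_spec` with `n_parameters(spec) == target_N`
#' @export
scale_model_complexity <- function(spec, target_N) {
  target_N <- as.integer(target_N)
  base_N <- n_parameters(spec)
  if (target_N < base_N)
    stop("target complexity ", target_N, " is below the base model's ", base_N)
  if (target_N == base_N) return(spec)
  need <- function() target_N - n_parameters(spec)
  offdiag <- function() {
    m <- matrix(TRUE, spec$n_sources, spec$n_sources); diag(m) <- FALSE; m
  }
  enable <- function(mask) {
    # column-major fill of disabled off-diagonal entries
    cand <- which(offdiag() & !mask)
    if (length(cand) > 0) {
      take <- cand[seq_len(min(need(), length(cand)))]
      mask[take] <- TRUE
    }
    mask
  }
  for (blk in c("F_mask", "B_mask", "L_mask")) {
    if (need() <= 0) break
    spec[[blk]] <- enable(spec[[blk]])
  }
  if (need() > 0 && length(spec$conditions) > 1) {
    per_cond <- length(spec$conditions) - 1L
    cand <- which(offdiag() & (spec$F_mask | spec$B_mask | spec$L_mask) &
                    !spec$M_mask)
    take <- cand[seq_len(min(need() %/% per_cond, length(cand)))]
    spec$M_mask[take] <- TRUE
  }
  if (need() > 0) {
    # remaining shortfall is absorbed by intrinsic log-deviations, with
    # duplicated-prior copies (and a partial copy) to hit the count exactly
    spec$intrinsic <- c("H_e", "H_i", "tau_e", "tau_i")
    spec$intrinsic_copies <- 0L
    spec$intrinsic_partial <- 0L
    per_copy <- 4L * spec$n_sources
    r <- need()
    spec$intrinsic_copies <- r %/% per_copy
    spec$intrinsic_partial <- r %% per_copy
  }
  stopifnot(n_parameters(spec) == target_N)
  spec
}
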