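#' Free-parameter index map of a model
#'
#' Enumerates the free parameters of a model specification in a fixed order:
#' forward, backward and lateral coupling log-scalings (column-major over each
#' mask), input log-gains, condition-modulation log-scalings (one per enabled
#' modulated connection per non-baseline condition), then intrinsic
#' log-deviations (with duplicated-prior copies when requested). All
#' parameters are log-scalings of positive baseline values, so positivity of
#' the physical quantities is structural.
#'
#' @param spec an `erpdcm_spec`
#' @return data frame with columns `name`, `block` (`F`, `B`, `L`, `U`, `M`,
#'   `I`), `row`, `col`, `condition`, `field`, `prior_mean`, `prior_sd`
#' @export
parameter_map <- function(spec) {
  n <- spec$n_sources
  rows <- list()
  conn <- function(mask, block, sd) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
    data.frame(name = sprintf("%s_%d_%d", block, idx[, 1], idx[, 2]),
               block = block, row = idx[, 1], col = idx[, 2],
               condition = NA_character_, field = NA_character_,
               prior_mean = 0, prior_sd = sd, stringsAsFactors = FALSE)
  }
  rows$F <- conn(spec$F_mask, "F", sqrt(1 / 16))
  rows$B <- conn(spec$B_mask, "B", sqrt(1 / 16))
  rows$L <- conn(spec$L_mask, "L", sqrt(1 / 16))
  if (spec$estimate_input && any(spec$U_mask)) {
    w <- which(spec$U_mask)
    rows$U <- data.frame(name = sprintf("U_%d", w), block = "U",
                         row = w, col = NA_integer_,
                         condition = NA_character_, field = NA_character_,
                         prior_mean = 0, prior_sd = sqrt(1 / 16),
                         stringsAsFactors = FALSE)
  }
  if (any(spec$M_mask) && length(spec$conditions) > 1) {
    idx <- which(spec$M_mask, arr.ind = TRUE)
    idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
    for (cond in spec$conditions[-1]) {
      rows[[paste0("M_", cond)]] <-
        data.frame(name = sprintf("M_%d_%d_%s", idx[, 1], idx[, 2], cond),
                   block = "M", row = idx[, 1], col = idx[, 2],
                   condition = cond, field = NA_character_,
                   prior_mean = 0, prior_sd = sqrt(1 / 32),
                   stringsAsFactors = FALSE)
    }
  }
  if (length(spec$intrinsic) > 0) {
    partial <- spec$intrinsic_partial %||% 0L
    n_copies <- spec$intrinsic_copies + (partial > 0L)
    for (copy in seq_len(n_copies)) {
      enum <- expand.grid(src = seq_len(n), field = spec$intrinsic,
                          stringsAsFactors = FALSE)
      enum <- enum[order(match(enum$field, spec$intrinsic), enum$src), ]
      if (copy > spec$intrinsic_copies)
        enum <- enum[seq_len(partial), , drop = FALSE]
      nm <- sprintf("I_%s_%d", enum$field, enum$src)
      if (copy > 1) nm <- sprintf("%s_copy%d", nm, copy)
      rows[[paste0("Icopy", copy)]] <-
        data.frame(name = nm, block = "I", row = enum$src,
                   col = NA_integer_, condition = NA_character_,
                   field = enum$field, prior_mean = 0,
                   prior_sd = sqrt(1 / 128), stringsAsFactors = FALSE)
    }
  }
  map <- do.call(rbind, rows)
  if (is.null(map))
    map <- data.frame(name = character(), block = character(),
                      row = integer(), col = integer(),
                      condition = character(), field = character(),
                      prior_mean = numeric(), prior_sd = numeric(),
                      stringsAsFactors = FALSE)
  rownames(map) <- NULL
  map
}

#' Number of free parameters (model complexity N)
#'
#' @param spec an `erpdcm_spec`
#' @export
n_parameters <- function(spec) nrow(parameter_map(spec))

#' A zero (prior-mean) parameter vector for a model
#'
#' @param spec an `erpdcm_spec`
#' @return named numeric vector of log-scalings, all zero
#' @export
prior_mean_theta <- function(spec) {
  map <- parameter_map(spec)
  stats::setNames(rep(0, nrow(map)), map$name)
}

# validate / name-align a parameter vector against the map
check_theta <- function(theta, map) {
  if (length(theta) != nrow(map))
    stop("parameter vector has length ", length(theta),
         " but the model has ", nrow(map), " free parameters")
  if (!is.null(names(theta)) && !identical(names(theta), map$name)) {
    if (!setequal(names(theta), map$name))
      stop("parameter names do not match the model's parameter map")
    theta <- theta[map$name]
  }
  stats::setNames(as.numeric(theta), map$name)
}

#' Structured view of a flat parameter vector
#'
#' Reshapes the flat log-scaling vector into the matrices and per-source
#' constants it parameterizes. The round trip with the flat form is lossless.
#'
#' @param spec an `erpdcm_spec`
#' @param theta flat parameter vector (see [parameter_map()])
#' @return list with log-scaling matrices `F`, `B`, `L`, input vector `U`,
#'   per-condition modulation matrices `M`, and intrinsic deviation matrix `I`
#'   (sources x fields)
#' @export
theta_to_structured <- function(spec, theta) {
  map <- parameter_map(spec)
  theta <- check_theta(theta, map)
  n <- spec$n_sources
  out <- list(F = matrix(0, n, n), B = matrix(0, n, n), L = matrix(0, n, n),
              U = rep(0, n), M = list(),
              I = matrix(0, n, 4, dimnames = list(NULL, c("H_e", "H_i", "tau_e", "tau_i"))))
  for (k in seq_len(nrow(map))) {
    b <- map$block[k]
    if (b %in% c("F", "B", "L")) out[[b]][map$row[k], map$col[k]] <- theta[k]
    else if (b == "U") out$U[map$row[k]] <- theta[k]
    else if (b == "M") {
      cond <- map$condition[k]
      if (is.null(out$M[[cond]])) out$M[[cond]] <- matrix(0, n, n)
      out$M[[cond]][map$row[k], map$col[k]] <- out$M[[cond]][map$row[k], map$col[k]] + theta[k]
    } else if (b == "I") {
      out$I[map$row[k], map$field[k]] <- out$I[map$row[k], map$field[k]] + theta[k]
    }
  }
  out
}

#' Flatten a structured parameter view back to the flat vector
#'
#' Inverse of [theta_to_structured()] (duplicated-prior intrinsic copies are
#' refilled into the first copy, which represents the same model).
#'
#' @param spec an `erpdcm_spec`
#' @param structured list as returned by [theta_to_structured()]
#' @export
structured_to_theta <- function(spec, structured) {
  map <- parameter_map(spec)
  theta <- stats::setNames(rep(0, nrow(map)), map$name)
  seen_intr <- character()
  for (k in seq_len(nrow(map))) {
    b <- map$block[k]
    if (b %in% c("F", "B", "L")) theta[k] <- structured[[b]][map$row[k], map$col[k]]
    else if (b == "U") theta[k] <- structured$U[map$row[k]]
    else if (b == "M") theta[k] <- structured$M[[map$condition[k]]][map$row[k], map$col[k]]
    else if (b == "I") {
      key <- paste(map$field[k], map$row[k])
      if (!(key %in% seen_intr)) {
        theta[k] <- structured$I[map$row[k], map$field[k]]
        seen_intr <- c(seen_intr, key)
      }
    }
  }
  theta
}

#' Default priors over the free parameters
#'
#' Independent Gaussian priors on the log-scalings: variance 1/16 for
#' extrinsic couplings and input gains, 1/32 for condition modulations and
#' 1/128 for intrinsic deviations. Zero variance freezes a parameter at its
#' prior mean.
#'
#' @param spec an `erpdcm_spec`
#' @param sd_scale optional multiplier applied to all prior standard
#'   deviations
#' @return list with `mean` (named vector) and `var` (named vector of prior
#'   variances)
#' @export
default_priors <- function(spec, sd_scale = 1) {
  map <- parameter_map(spec)
  list(mean = stats::setNames(map$prior_mean, map$name),
       var = stats::setNames((map$prior_sd * sd_scale)^2, map$name))
}
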