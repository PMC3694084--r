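#' Lead-field (gain) matrix
#'
#' Wraps or samples the linear mapping from source pyramidal activity to
#' sensors. When `L` is missing, a lead field is sampled with seeded standard
#' normal entries and unit column norms — a stand-in for a head model, which
#' is out of scope.
#'
#' @param n_channels number of sensors
#' @param n_sources number of sources
#' @param L optional explicit gain matrix (`n_channels` x `n_sources`)
#' @param seed seed used when sampling
#' @return matrix of class `erpdcm_leadfield`
#' @export
lead_field <- function(n_channels, n_sources, L = NULL, seed = 1L) {
  if (is.null(L)) {
    L <- with_local_seed(seed, matrix(stats::rnorm(n_channels * n_sources),
                                      n_channels, n_sources))
    L <- sweep(L, 2, sqrt(colSums(L^2)), "/")
  }
  L <- as.matrix(L)
  if (!all(is.finite(L))) stop("lead field contains non-finite entries")
  if (any(colSums(abs(L)) == 0))
    stop("lead field has an all-zero column: every source must be observable")
  class(L) <- c("erpdcm_leadfield", class(L))
  L
}

#' Read a lead field from a TSV/CSV matrix file
#'
#' @param path delimited file of numeric gains (channels x sources), no header
#' @param sep field separator (tab by default)
#' @export
read_lead_field <- function(path, sep = "\t") {
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(m) <- NULL
  lead_field(nrow(m), ncol(m), L = m)
}

#' Predicted sensor response
#'
#' The observation function: source pyramidal depolarization from
#' [integrate_states()] mapped through the lead field, for each condition.
#'
#' @param spec an `erpdcm_spec`
#' @param theta flat parameter vector
#' @param leadfield gain matrix (`n_channels` x `n_sources`)
#' @param input an `erpdcm_input`
#' @param grid time points (ms)
#' @param conditions conditions to predict (defaults to all in the spec)
#' @return named list, one `n_channels` x `n_time` matrix per condition
#' @export
predict_response <- function(spec, theta = prior_mean_theta(spec),
                             leadfield, input = stimulus_input(),
                             grid = seq(0, 500, by = 1),
                             conditions = spec$conditions) {
  leadfield <- unclass(leadfield)
  if (ncol(leadfield) != spec$n_sources)
    stop("lead field has ", ncol(leadfield), " columns but the model has ",
         spec$n_sources, " sources")
  out <- lapply(conditions, function(cond) {
    leadfield %*% integrate_states(spec, theta, cond, input, grid)
  })
  names(out) <- conditions
  out
}

# stack a per-condition response list into one vector (column-major within
# each condition, conditions concatenated in order)
stack_response <- function(h) as.numeric(unlist(lapply(h, as.numeric), use.names = FALSE))
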