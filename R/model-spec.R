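#' Intrinsic parameters of a Jansen-type neural-mass source
#'
#' Returns the biophysical constants of one cortical source: synaptic gains,
#' synaptic time constants, the four intrinsic coupling constants between the
#' pyramidal, spiny-stellate and inhibitory populations, and the firing-rate
#' sigmoid shape. Defaults are the standard values used for ERP modelling.
#'
#' @param H_e excitatory synaptic gain (mV)
#' @param H_i inhibitory synaptic gain (mV)
#' @param tau_e excitatory synaptic time constant (ms)
#' @param tau_i inhibitory synaptic time constant (ms)
#' @param gamma intrinsic coupling constants \eqn{\gamma_1..\gamma_4}
#'   (dimensionless, nonnegative)
#' @param r sigmoid slope (1/mV)
#' @param eta sigmoid threshold (mV)
#' @return an object of class `erpdcm_source_params`
#' @export
source_parameters <- function(H_e = 4, H_i = 32, tau_e = 8, tau_i = 16,
                              gamma = 128 * c(1, 0.8, 0.25, 0.25),
                              r = 0.56, eta = 6) {
  stopifnot(H_e > 0, H_i > 0, tau_e > 0, tau_i > 0,
            length(gamma) == 4, all(gamma >= 0), r > 0)
  structure(list(H_e = H_e, H_i = H_i, tau_e = tau_e, tau_i = tau_i,
                 gamma = gamma, r = r, eta = eta),
            class = "erpdcm_source_params")
}

# base coupling strengths multiplied by exp(theta) for enabled connections;
# forward > backward > lateral, matching the usual ERP-model conventions
.default_base_strengths <- c(F = 32, B = 16, L = 4, U = 32)

#' Specify a neural-mass network model
#'
#' A model specification names the sources, the enabled extrinsic connections
#' (forward, backward, lateral) between them, which sources receive the
#' stimulus input, and which connections are allowed to change between
#' experimental conditions (modulation). Entry `(i, j)` of an adjacency mask
#' enables a connection from source `j` to source `i`.
#'
#' @param n_sources number of sources
#' @param F_mask,B_mask,L_mask logical/0-1 adjacency masks (`n_sources` x
#'   `n_sources`) for forward, backward and lateral connections; diagonals
#'   must be zero
#' @param U_mask logical/0-1 vector marking the sources that receive the
#'   stimulus input
#' @param M_mask logical/0-1 mask of condition-modulated connections; must be
#'   a subset of the union of the extrinsic masks
#' @param conditions character vector of condition labels; the first label is
#'   the baseline against which modulations are expressed
#' @param source_names optional source labels
#' @param params `source_parameters()` shared by all sources
#' @param base_strengths named vector of baseline coupling strengths for the
#'   `F`, `B`, `L` connection types and the input gain `U`
#' @param targets population targets of each extrinsic connection type; each
#'   element is a subset of `c("stellate", "pyramidal", "inhibitory")`
#' @param intrinsic character vector of per-source intrinsic constants to
#'   estimate as log-deviations (subset of `c("H_e","H_i","tau_e","tau_i")`);
#'   empty by default
#' @param intrinsic_copies number of duplicated-prior copies of each enabled
#'   intrinsic deviation (used to force a given parameter count)
#' @param intrinsic_partial number of entries of one further partial copy,
#'   letting [scale_model_complexity()] hit a parameter count exactly
#' @param estimate_input logical: estimate one log-gain per input source?
#' @return an object of class `erpdcm_spec`
#' @export
model_spec <- function(n_sources,
                       F_mask = matrix(FALSE, n_sources, n_sources),
                       B_mask = matrix(FALSE, n_sources, n_sources),
                       L_mask = matrix(FALSE, n_sources, n_sources),
                       U_mask = c(TRUE, rep(FALSE, n_sources - 1)),
                       M_mask = matrix(FALSE, n_sources, n_sources),
                       conditions = "standard",
                       source_names = paste0("S", seq_len(n_sources)),
                       params = source_parameters(),
                       base_strengths = .default_base_strengths,
                       targets = list(F = "stellate",
                                      B = c("pyramidal", "inhibitory"),
                                      L = c("pyramidal", "inhibitory")),
                       intrinsic = character(),
                       intrinsic_copies = 1L,
                       intrinsic_partial = 0L,
                       estimate_input = TRUE) {
  as_mask <- function(m, nm) {
    m <- matrix(as.logical(m), n_sources, n_sources)
    if (any(is.na(m))) stop(nm, " contains non-logical entries")
    if (any(diag(m))) stop(nm, " must have a zero diagonal")
    m
  }
  F_mask <- as_mask(F_mask, "F_mask")
  B_mask <- as_mask(B_mask, "B_mask")
  L_mask <- as_mask(L_mask, "L_mask")
  M_mask <- as_mask(M_mask, "M_mask")
  U_mask <- as.logical(U_mask)
  if (length(U_mask) != n_sources) stop("U_mask must have one entry per source")
  if (any(M_mask & !(F_mask | B_mask | L_mask)))
    stop("M_mask must be a subset of the enabled extrinsic connections")
  stopifnot(length(conditions) >= 1, !anyDuplicated(conditions))
  stopifnot(all(intrinsic %in% c("H_e", "H_i", "tau_e", "tau_i")))
  bs <- .default_base_strengths
  bs[names(base_strengths)] <- base_strengths
  structure(list(n_sources = as.integer(n_sources),
                 F_mask = F_mask, B_mask = B_mask, L_mask = L_mask,
                 U_mask = U_mask, M_mask = M_mask,
                 conditions = conditions, source_names = source_names,
                 params = params, base_strengths = bs, targets = targets,
                 intrinsic = intrinsic,
                 intrinsic_copies = as.integer(intrinsic_copies),
                 intrinsic_partial = as.integer(intrinsic_partial),
                 estimate_input = isTRUE(estimate_input)),
            class = "erpdcm_spec")
}

#' @export
print.erpdcm_spec <- function(x, ...) {
  cat("ERP network model:", x$n_sources, "sources,",
      sum(x$F_mask), "forward /", sum(x$B_mask), "backward /",
      sum(x$L_mask), "lateral connections,",
      sum(x$M_mask), "modulated;",
      length(x$conditions), "condition(s)\n")
  cat("free parameters:", n_parameters(x), "\n")
  invisible(x)
}

#' Serialize a model specification to JSON
#'
#' @param spec an `erpdcm_spec`
#' @param path output file; if `NULL` the JSON string is returned
#' @export
write_model_spec <- function(spec, path = NULL) {
  obj <- list(n_sources = spec$n_sources,
              source_names = spec$source_names,
              F_mask = spec$F_mask * 1L, B_mask = spec$B_mask * 1L,
              L_mask = spec$L_mask * 1L, M_mask = spec$M_mask * 1L,
              U_mask = spec$U_mask * 1L,
              conditions = spec$conditions,
              params = unclass(spec$params),
              base_strengths = as.list(spec$base_strengths),
              targets = spec$targets,
              intrinsic = spec$intrinsic,
              intrinsic_copies = spec$intrinsic_copies,
              intrinsic_partial = spec$intrinsic_partial,
              estimate_input = spec$estimate_input)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a model specification from JSON
#'
#' @param path file written by [write_model_spec()] (or a JSON string)
#' @export
read_model_spec <- function(path) {
  o <- jsonlite::fromJSON(path)
  model_spec(n_sources = o$n_sources,
             F_mask = o$F_mask, B_mask = o$B_mask, L_mask = o$L_mask,
             U_mask = o$U_mask, M_mask = o$M_mask,
             conditions = o$conditions, source_names = o$source_names,
             params = do.call(source_parameters, as.list(o$params)),
             base_strengths = unlist(o$base_strengths),
             targets = lapply(o$targets, as.character),
             intrinsic = as.character(o$intrinsic),
             intrinsic_copies = o$intrinsic_copies,
             intrinsic_partial = o$intrinsic_partial,
             estimate_input = o$estimate_input)
}
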