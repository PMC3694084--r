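#' Decompose a response-Jacobian computation into per-parameter tasks
#'
#' Each free parameter yields one independent integration task: predict the
#' response at `theta` perturbed in that coordinate. Task ids are `0..N-1`.
#'
#' @param theta flat parameter vector (length N >= 1)
#' @param step finite-difference step; either a scalar applied to every
#'   parameter or a vector of length N
#' @return list of tasks, each with `id`, `index`, `step` and the perturbed
#'   parameter vector
#' @export
make_jacobian_tasks <- function(theta, step = 1e-4) {
  N <- length(theta)
  if (N == 0) stop("cannot build Jacobian tasks for an empty parameter vector")
  step <- rep_len(step, N)
  lapply(seq_len(N), function(i) {
    th <- theta
    th[i] <- th[i] + step[i]
    list(id = i - 1L, index = i, step = step[i], theta = th)
  })
}

# core one-sided forward-difference Jacobian over an arbitrary forward map;
# base response h(theta) is computed once and shared by all tasks
fd_jacobian <- function(forward, theta, step = 1e-4, base = NULL,
                        runner = lapply) {
  tasks <- make_jacobian_tasks(theta, step)
  if (is.null(base)) base <- forward(theta)
  base <- as.numeric(base)
  cols <- runner(tasks, function(task) {
    h <- tryCatch(as.numeric(forward(task$theta)), error = function(e)
      stop("Jacobian task for parameter index ", task$index,
           " failed: ", conditionMessage(e), call. = FALSE))
    (h - base) / task$step
  })
  J <- do.call(cbind, cols)
  colnames(J) <- names(theta)
  structure(list(J = J, step = vapply(tasks, `[[`, numeric(1), "step"),
                 base = base), class = "erpdcm_jacobian")
}

#' Response Jacobian by serial finite differences
#'
#' Sensitivity of the stacked predicted sensor response to every free
#' parameter: column i is the one-sided forward difference
#' `(h(theta + d e_i) - h(theta)) / d`. This is the computation each EM
#' iteration repeats N + 1 times, and the unit of work the parallel engine
#' distributes.
#'
#' @inheritParams predict_response
#' @param step finite-difference step on the log-scale parameters
#' @param base optional precomputed base response (stacked)
#' @return object of class `erpdcm_jacobian`: `J` (stacked response length x
#'   N), the `step` sizes used, and the `base` response
#' @export
response_jacobian_serial <- function(spec, theta, leadfield,
                                     input = stimulus_input(),
                                     grid = seq(0, 500, by = 1),
                                     conditions = spec$conditions,
                                     step = 1e-4, base = NULL) {
  forward <- function(th)
    stack_response(predict_response(spec, th, leadfield, input, grid, conditions))
  fd_jacobian(forward, theta, step, base)
}

#' Response Jacobian on a parallel worker fabric
#'
#' Identical numerical contract to [response_jacobian_serial()] — the same
#' per-task arithmetic in the same within-task order — with the task-to-block
#' mapping delegated to [assign_tasks()] and blocks executed on a fork-based
#' worker pool. If the pool cannot be used, the computation falls back to the
#' serial path with a warning.
#'
#' @inheritParams response_jacobian_serial
#' @param strategy task arrangement: `"thread"`, `"block"` or `"blockX"`
#' @param fabric a [fabric_descriptor()]
#' @param workers number of pool workers
#' @return object of class `erpdcm_jacobian`
#' @export
response_jacobian_parallel <- function(spec, theta, leadfield,
                                       input = stimulus_input(),
                                       grid = seq(0, 500, by = 1),
                                       conditions = spec$conditions,
                                       step = 1e-4, base = NULL,
                                       strategy = "blockX",
                                       fabric = fabric_descriptor(),
                                       workers = 1L) {
  forward <- function(th)
    stack_response(predict_response(spec, th, leadfield, input, grid, conditions))
  fd_jacobian(forward, theta, step, base,
              runner = pool_runner(length(theta), strategy, fabric, workers))
}

# build a lapply-compatible runner that groups tasks into blocks via the
# scheduler and evaluates blocks on a fork pool (mclapply); task results are
# reassembled in task order regardless of execution order
pool_runner <- function(n_tasks, strategy, fabric, workers) {
  assignment <- assign_tasks(n_tasks, strategy, fabric)
  function(tasks, fun) {
    run_block <- function(block_ids) lapply(tasks[block_ids + 1L], fun)
    block_results <- tryCatch({
      if (workers > 1L && .Platform$OS.type == "unix") {
        res <- parallel::mclapply(assignment$blocks, run_block,
                                  mc.cores = workers)
        bad <- vapply(res, inherits, logical(1), "try-error")
        if (any(bad)) stop(attr(res[[which(bad)[1]]], "condition")$message)
        res
      } else {
        lapply(assignment$blocks, run_block)
      }
    }, error = function(e) {
      if (grepl("Jacobian task", conditionMessage(e))) stop(e)
      warning("worker pool failed (", conditionMessage(e),
              "); falling back to serial execution", call. = FALSE)
      lapply(assignment$blocks, run_block)
    })
    out <- vector("list", n_tasks)
    for (b in seq_along(assignment$blocks))
      out[assignment$blocks[[b]] + 1L] <- block_results[[b]]
    out
  }
}
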