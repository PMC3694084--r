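#' Resident-block limit of a streaming multiprocessor
#'
#' Maximum number of thread blocks resident on one streaming multiprocessor,
#' by device capability class: 8 for classes "1.x" and "2.x", 16 for "3.x".
#'
#' @param capability_class one of `"1.x"`, `"2.x"`, `"3.x"`
#' @return integer resident-block limit
#' @export
resident_block_limit <- function(capability_class) {
  switch(as.character(capability_class),
         "1.x" = 8L, "2.x" = 8L, "3.x" = 16L,
         stop("unknown capability class: ", capability_class))
}

#' Describe an execution fabric
#'
#' An abstract GPU-style fabric: groups of tasks (blocks) run on streaming
#' multiprocessors, each of which can host a limited number of resident
#' blocks; within a block, tasks execute in warps of fixed width. The
#' concurrency limit X — the number of blocks that can run simultaneously —
#' is the product of the multiprocessor count and the per-multiprocessor
#' resident-block limit.
#'
#' @param n_sm number of streaming multiprocessors
#' @param capability_class device class passed to [resident_block_limit()];
#'   ignored when `per_sm_resident_limit` is given directly
#' @param per_sm_resident_limit resident blocks per multiprocessor
#' @param block_capacity maximum tasks per block
#' @param warp_width tasks executed in lockstep
#' @return object of class `erpdcm_fabric` with the derived `concurrency_limit`
#' @export
fabric_descriptor <- function(n_sm = 8L, capability_class = "2.x",
                              per_sm_resident_limit = resident_block_limit(capability_class),
                              block_capacity = 1024L, warp_width = 32L) {
  f <- list(n_sm = as.integer(n_sm),
            per_sm_resident_limit = as.integer(per_sm_resident_limit),
            block_capacity = as.integer(block_capacity),
            warp_width = as.integer(warp_width))
  stopifnot(f$n_sm >= 1, f$per_sm_resident_limit >= 1,
            f$block_capacity >= 1, f$warp_width >= 1)
  f$concurrency_limit <- f$n_sm * f$per_sm_resident_limit
  structure(f, class = "erpdcm_fabric")
}

#' Concurrency limit X of a fabric
#'
#' @param fabric a [fabric_descriptor()]
#' @return X = `n_sm * per_sm_resident_limit`
#' @export
concurrency_limit <- function(fabric) fabric$n_sm * fabric$per_sm_resident_limit

#' Arrange tasks into blocks
#'
#' The three task-arrangement strategies:
#' \describe{
#'   \item{thread}{thread-first — fill a block to capacity before opening the
#'     next; `ceiling(n / capacity)` blocks.}
#'   \item{block}{block-first — one task per block; `n` blocks.}
#'   \item{blockX}{round-robin over exactly X blocks (X = the fabric's
#'     concurrency limit), one task per block per pass, until all X blocks
#'     reach capacity; tasks beyond `X * capacity` start another set of X
#'     blocks. With fewer than X tasks only the nonempty blocks are emitted.}
#' }
#'
#' @param n_tasks number of tasks (>= 1); ids are `0..n_tasks-1`
#' @param strategy `"thread"`, `"block"` or `"blockX"`
#' @param fabric a [fabric_descriptor()]
#' @return object of class `erpdcm_assignment`: the `strategy`, a list
#'   `blocks` of task-id vectors, and `sizes`
#' @export
assign_tasks <- function(n_tasks, strategy = c("thread", "block", "blockX"),
                         fabric = fabric_descriptor()) {
  n_tasks <- as.integer(n_tasks)
  if (is.na(n_tasks) || n_tasks < 1) stop("n_tasks must be a positive integer")
  strategy <- match.arg(strategy)
  cap <- fabric$block_capacity
  ids <- 0:(n_tasks - 1L)
  blocks <- switch(strategy,
    thread = split(ids, ids %/% cap),
    block = as.list(ids),
    blockX = {
      X <- concurrency_limit(fabric)
      set <- ids %/% (X * cap)           # which set of X blocks
      blk <- set * X + (ids %% (X * cap)) %% X
      split(ids, blk)
    })
  blocks <- unname(lapply(blocks, as.integer))
  structure(list(strategy = strategy, blocks = blocks,
                 sizes = lengths(blocks)),
            class = "erpdcm_assignment")
}

#' Deterministic makespan of a task assignment
#'
#' Cost model of the fabric: blocks execute in waves of at most X concurrent
#' blocks, taken in block-index order; a block's duration is the number of
#' warps it needs, `ceiling(size / warp_width)`, in abstract time units; a
#' wave lasts as long as its slowest block; the makespan is the sum of wave
#' durations.
#'
#' @param assignment an [assign_tasks()] result
#' @param fabric a [fabric_descriptor()]
#' @return object of class `erpdcm_cost`: `makespan`, `n_waves`,
#'   `wave_durations`
#' @export
makespan <- function(assignment, fabric = fabric_descriptor()) {
  X <- concurrency_limit(fabric)
  dur <- ceiling(assignment$sizes / fabric$warp_width)
  wave <- (seq_along(dur) - 1L) %/% X
  wd <- as.numeric(tapply(dur, wave, max))
  structure(list(makespan = sum(wd), n_waves = length(wd),
                 wave_durations = wd),
            class = "erpdcm_cost")
}

#' Detect the concurrency limit X of a fabric
#'
#' Mimics probing a device with a small benchmark: launch an increasing
#' number of single-warp blocks and find where the cost first steps up. In
#' `"simulated"` mode the probe runs against the deterministic [makespan()]
#' model of a given fabric and recovers its X exactly. In `"wallclock"` mode
#' a fixed numeric workload is timed on the host per candidate worker-group
#' count and the edge of the first timing plateau is returned — environment
#' dependent and best-effort.
#'
#' @param probe_mode `"simulated"` or `"wallclock"`
#' @param candidates increasing candidate block counts to probe
#' @param fabric fabric probed in simulated mode
#' @param seed seed for the wallclock workload
#' @param reps wallclock repetitions per candidate
#' @return detected X (positive integer); if no step is found, the largest
#'   candidate, with a warning
#' @export
detect_concurrency_limit <- function(probe_mode = c("simulated", "wallclock"),
                                     candidates = 1:256,
                                     fabric = fabric_descriptor(),
                                     seed = 1L, reps = 3L) {
  probe_mode <- match.arg(probe_mode)
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) == 0) stop("candidate list is empty")
  cost <- if (probe_mode == "simulated") {
    vapply(candidates, function(b) {
      a <- structure(list(strategy = "probe",
                          blocks = rep(list(0L), b),
                          sizes = rep(fabric$warp_width, b)),
                     class = "erpdcm_assignment")
      makespan(a, fabric)$makespan
    }, numeric(1))
  } else {
    workload <- with_local_seed(seed, stats::rnorm(2000))
    vapply(candidates, function(b) {
      min(vapply(seq_len(reps), function(r) {
        t0 <- proc.time()[["elapsed"]]
        for (i in seq_len(b)) sum(log(abs(workload) + 1))
        proc.time()[["elapsed"]] - t0
      }, numeric(1)))
    }, numeric(1))
  }
  steps <- which(diff(cost) > if (probe_mode == "simulated") 0 else
    stats::median(cost) * 0.5 + 1e-9)
  if (length(steps) == 0) {
    warning("no cost step detected; returning the largest candidate")
    return(candidates[length(candidates)])
  }
  candidates[steps[1]]
}

#' Simulate the arrangement strategies over a range of task counts
#'
#' @param n_tasks vector of task counts
#' @param strategies subset of `c("thread", "block", "blockX")`
#' @param fabric a [fabric_descriptor()]
#' @param path optional TSV output file
#' @return data frame with columns `n_tasks`, `strategy`, `blocks`,
#'   `makespan`
#' @export
schedule_table <- function(n_tasks, strategies = c("thread", "block", "blockX"),
                           fabric = fabric_descriptor(), path = NULL) {
  rows <- expand.grid(n_tasks = n_tasks, strategy = strategies,
                      stringsAsFactors = FALSE)
  res <- mapply(function(n, s) {
    a <- assign_tasks(n, s, fabric)
    c(blocks = length(a$blocks), makespan = makespan(a, fabric)$makespan)
  }, rows$n_tasks, rows$strategy)
  out <- cbind(rows, t(res))
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
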