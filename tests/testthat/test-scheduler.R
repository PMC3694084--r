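test_that("resident-block limits follow the device capability class", {
  expect_identical(resident_block_limit("1.x"), 8L)
  expect_identical(resident_block_limit("2.x"), 8L)
  expect_identical(resident_block_limit("3.x"), 16L)
  expect_error(resident_block_limit("9.x"), "unknown capability")
})

test_that("the concurrency limit is the SM count times the resident limit", {
  expect_equal(concurrency_limit(fabric_descriptor(n_sm = 8,
                                                   capability_class = "2.x")),
               64L)
  expect_equal(concurrency_limit(fabric_descriptor(n_sm = 1,
                                                   per_sm_resident_limit = 1)),
               1L)
  expect_equal(concurrency_limit(fabric_descriptor(n_sm = 13,
                                                   capability_class = "3.x")),
               208L)
})

test_that("arrangement strategies produce the documented block structures", {
  fab <- fabric_descriptor()  # X = 64, capacity 1024, warp 32
  # thread-first: 2048 tasks -> 2 fully occupied blocks
  a <- assign_tasks(2048, "thread", fab)
  expect_length(a$blocks, 2L)
  expect_equal(a$sizes, c(1024L, 1024L))
  expect_equal(a$blocks[[1]], 0:1023)
  # block-first: one task per block
  b <- assign_tasks(2048, "block", fab)
  expect_length(b$blocks, 2048L)
  expect_true(all(b$sizes == 1L))
  # blockX round-robin: 130 tasks over 64 blocks -> two blocks of 3, rest 2
  x <- assign_tasks(130, "blockX", fab)
  expect_length(x$blocks, 64L)
  expect_equal(x$sizes[1:2], c(3L, 3L))
  expect_true(all(x$sizes[3:64] == 2L))
  expect_equal(x$blocks[[1]], c(0L, 64L, 128L))
  expect_error(assign_tasks(0, "thread", fab), "positive")
  expect_error(assign_tasks(10, "warp", fab))
})

test_that("assignments conserve tasks, respect capacity and blockX fairness", {
  fab <- fabric_descriptor()
  X <- concurrency_limit(fab)
  set.seed(9)
  for (n in c(1:5, 63, 64, 65, 1024, 1025, sample(2:4096, 25))) {
    for (strat in c("thread", "block", "blockX")) {
      a <- assign_tasks(n, strat, fab)
      ids <- sort(unlist(a$blocks))
      expect_equal(ids, 0:(n - 1))                 # every task exactly once
      expect_true(all(a$sizes >= 1L))              # no empty blocks
      expect_true(all(a$sizes <= fab$block_capacity))
      if (strat == "blockX" && n <= X * fab$block_capacity) {
        expect_length(a$blocks, min(n, X))
        if (n >= X)
          expect_true(all(a$sizes %in% c(n %/% X, n %/% X + 1L)))
        expect_lte(max(a$sizes) - min(a$sizes), 1L)
      }
    }
  }
})

test_that("the makespan model reproduces the canonical costs", {
  fab <- fabric_descriptor()
  # 2 blocks of 1024: one wave, 32 warps each
  c1 <- makespan(assign_tasks(2048, "thread", fab), fab)
  expect_equal(c1$makespan, 32)
  expect_equal(c1$n_waves, 1L)
  # 2048 singleton blocks: 32 waves of 64 blocks, 1 unit each
  c2 <- makespan(assign_tasks(2048, "block", fab), fab)
  expect_equal(c2$makespan, 32)
  expect_equal(c2$n_waves, 32L)
  # 64 blocks of 32: one wave, one warp
  c3 <- makespan(assign_tasks(2048, "blockX", fab), fab)
  expect_equal(c3$makespan, 1)
  expect_equal(c3$makespan, sum(c3$wave_durations))
})

test_that("simulated probing recovers the hidden concurrency limit exactly", {
  expect_equal(detect_concurrency_limit("simulated", 1:256,
                                        fabric_descriptor()), 64L)
  expect_equal(detect_concurrency_limit(
    "simulated", 1:4, fabric_descriptor(n_sm = 1, per_sm_resident_limit = 1)),
    1L)
  expect_equal(detect_concurrency_limit(
    "simulated", 1:256, fabric_descriptor(n_sm = 13, capability_class = "3.x")),
    208L)
  expect_warning(
    x <- detect_concurrency_limit("simulated", 1:32, fabric_descriptor()),
    "no cost step")
  expect_equal(x, 32L)
  expect_error(detect_concurrency_limit("simulated", integer(0)), "empty")
})

test_that("wall-clock probing returns a positive integer", {
  x <- suppressWarnings(
    detect_concurrency_limit("wallclock", c(1, 4, 16, 64), seed = 1, reps = 1))
  expect_true(is.numeric(x) && length(x) == 1 && x >= 1)
})

test_that("the schedule table reports one row per task count and strategy", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- schedule_table(c(64, 130), fabric = fabric_descriptor(), path = path)
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$makespan >= 1))
  back <- read.delim(path)
  expect_equal(back$makespan, tab$makespan)
})
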