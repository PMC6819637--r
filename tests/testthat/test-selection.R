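test_that("scatter criterion matches two-point hand computation", {
  X <- matrix(c(0, 1), ncol = 1L)
  y <- c(1L, 0L)
  sr <- scatter_criterion(X, y, 1L)
  # m1 = 0, m2 = 1, m = 0.5; S_w = 0; S_b = 0.5*0.25 + 0.5*0.25 = 0.25
  expect_equal(sr$S_w_trace, 0)
  expect_equal(sr$S_b_trace, 0.25)
  expect_equal(sr$J_d, 0.25)
})

test_that("identical class distributions have zero between-class scatter", {
  X <- matrix(rep(c(1, 2, 3), 2L), ncol = 1L)
  y <- c(1L, 1L, 1L, 0L, 0L, 0L)
  sr <- scatter_criterion(X, y, 1L)
  expect_equal(sr$S_b_trace, 0)
  expect_equal(sr$J_d, sr$S_w_trace)
})

test_that("scatter criterion equals element-wise brute force sums", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(10:40, 1L); d <- sample(2:6, 1L)
    X <- matrix(rnorm(n * d), n, d)
    y <- c(1L, 0L, sample(0:1, n - 2L, replace = TRUE))
    subset <- sort(sample(d, sample(seq_len(d), 1L)))
    sr <- scatter_criterion(X, y, subset)
    or <- oracle_scatter(X, y, subset)
    expect_equal(sr$S_b_trace, or$S_b_trace, tolerance = 1e-13)
    expect_equal(sr$S_w_trace, or$S_w_trace, tolerance = 1e-13)
    expect_equal(sr$J_d, or$J_d, tolerance = 1e-13)
  }
})

test_that("tr(S_w + S_b) equals the label-independent total scatter", {
  set.seed(22)
  for (rep in 1:10) {
    n <- 30L; d <- 3L
    X <- matrix(rnorm(n * d), n, d)
    y <- c(1L, 0L, sample(0:1, n - 2L, replace = TRUE))
    sr <- scatter_criterion(X, y)
    m <- colMeans(X)
    total <- 0
    for (cls in c(1L, 0L)) {
      rows <- y == cls
      total <- total + (sum(rows) / n) *
        sum(sweep(X[rows, , drop = FALSE], 2L, m)^2) / sum(rows)
    }
    expect_equal(sr$J_d, total, tolerance = 1e-12)
    # hence permuting the labels leaves J_d unchanged
    expect_equal(scatter_criterion(X, sample(y))$J_d, sr$J_d,
                 tolerance = 1e-12)
  }
})

test_that("scatter criterion validates its inputs", {
  X <- matrix(rnorm(20), 10L)
  expect_error(scatter_criterion(X, rep(1L, 10L)), "both classes")
  expect_error(scatter_criterion(X, rep(0:1, 5L), integer()), "subset")
  expect_error(scatter_criterion(X, rep(0:1, 5L), 3L), "subset")
})

test_that("annealer finds the high-variance columns", {
  set.seed(30)
  n <- 80L
  X <- cbind(matrix(rnorm(n * 2L, sd = 10), n),
             matrix(rnorm(n * 4L, sd = 0.1), n))
  y <- rep(0:1, n / 2L)
  hits <- 0L
  for (s in 1:20) {
    res <- anneal_select(X, y, 2L, schedule = anneal_schedule(seed = s))
    if (identical(res$subset, c(1L, 2L))) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("annealer bookkeeping: best-visited, reproducibility, degeneracy", {
  set.seed(31)
  X <- matrix(rnorm(40L * 6L), 40L)
  y <- rep(0:1, 20L)
  sched <- anneal_schedule(T_max = 1, T_min = 0.01, r = 0.99, seed = 7L)
  res <- anneal_select(X, y, 3L, schedule = sched)

  # returned J_d is the best value ever visited along the trajectory
  expect_equal(res$J_d, max(res$trajectory$J_d))
  # and matches scatter_criterion recomputed on the returned subset
  expect_equal(res$J_d, scatter_criterion(X, y, res$subset)$J_d,
               tolerance = 1e-12)
  # temperatures follow the geometric schedule
  expect_equal(res$trajectory$T[1:3], 1 * 0.99^(0:2))

  res2 <- anneal_select(X, y, 3L, schedule = sched)
  expect_identical(res$subset, res2$subset)
  expect_identical(res$trajectory, res2$trajectory)

  # N_fea = pool size: the full pool, no iterations
  full <- anneal_select(X, y, 6L, schedule = sched)
  expect_equal(full$subset, 1:6)
  expect_equal(nrow(full$trajectory), 0L)
  expect_equal(full$J_d, scatter_criterion(X, y, 1:6)$J_d, tolerance = 1e-12)

  expect_error(anneal_select(X, y, 7L, schedule = sched), "exceeds pool")
})

test_that("a worsening move is always accepted in the high-T limit", {
  # with T -> Inf the acceptance probability exp(-|dJ|/T) -> 1; at the
  # schedule's first step with huge T_max every proposal is accepted
  set.seed(32)
  X <- matrix(rnorm(40L * 5L), 40L)
  y <- rep(0:1, 20L)
  sched <- anneal_schedule(T_max = 1e12, T_min = 1e11, r = 0.5, seed = 3L)
  res <- anneal_select(X, y, 2L, schedule = sched)
  expect_true(all(res$trajectory$accepted))
})

test_that("candidate_sweep is deterministic and spans the size range", {
  set.seed(33)
  X <- matrix(rnorm(40L * 8L), 40L)
  y <- rep(0:1, 20L)
  sched <- anneal_schedule(T_max = 1, T_min = 0.05, r = 0.97, seed = 5L)
  sw <- candidate_sweep(X, y, N_fea_range = 3:5, schedule = sched)
  expect_named(sw, c("3", "4", "5"))
  expect_equal(vapply(sw, function(r) length(r$subset), integer(1)),
               c(`3` = 3L, `4` = 4L, `5` = 5L))
  sw2 <- candidate_sweep(X, y, N_fea_range = 3:5, schedule = sched)
  expect_identical(lapply(sw, `[[`, "subset"), lapply(sw2, `[[`, "subset"))

  one <- candidate_sweep(X, y, N_fea_range = 4L, schedule = sched)
  expect_length(one, 1L)
  expect_equal(length(one[["4"]]$subset), 4L)
})
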