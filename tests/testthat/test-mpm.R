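test_that("class_stats: hand arithmetic, ridge, brute-force covariance", {
  X <- matrix(c(0, 2, 4, 6), ncol = 1L)
  y <- c(1L, 1L, 0L, 0L)
  cs <- class_stats(X, y)
  expect_equal(unname(cs[[1L]]$mu), 1)
  expect_equal(unname(cs[[2L]]$mu), 5)
  expect_equal(drop(cs[[1L]]$R), 2 + 1e-6 * 2)   # unbiased var + ridge
  expect_equal(drop(cs[[2L]]$R), 2 + 1e-6 * 2)

  # identical points within a class: R = ridge only, invertible
  Xd <- matrix(c(1, 1, 1, 0, 2, 4), ncol = 1L)
  csd <- class_stats(Xd, c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(drop(csd[[1L]]$R), 1e-6)
  expect_true(drop(csd[[1L]]$R) > 0)

  # random data: covariance matches the naive two-pass oracle
  set.seed(41)
  Xr <- matrix(rnorm(60L), 20L, 3L)
  yr <- rep(0:1, 10L)
  csr <- class_stats(Xr, yr)
  rows <- yr == 1L
  mu <- colMeans(Xr[rows, ])
  R <- matrix(0, 3L, 3L)
  for (r in which(rows)) R <- R + tcrossprod(Xr[r, ] - mu)
  R <- R / (sum(rows) - 1L)
  expect_equal(unname(csr[[1L]]$R), R + 1e-6 * mean(diag(R)) * diag(3L),
               tolerance = 1e-12)

  expect_error(class_stats(Xr, rep(1L, 20L)), "both classes")
})

make_stats <- function(mu, R) list(mu = mu, R = R)

test_that("equal-covariance instances have the closed-form solution", {
  s1 <- make_stats(c(1, 0), diag(2))
  s2 <- make_stats(c(-1, 0), diag(2))
  sol <- solve_mpm(s1, s2)
  expect_equal(sol$W, c(0.5, 0), tolerance = 1e-9)
  expect_equal(sol$kappa, 1, tolerance = 1e-9)
  expect_equal(sol$b, 0, tolerance = 1e-9)

  # randomized equal-covariance instances: W = R^{-1} a / (a' R^{-1} a)
  set.seed(42)
  for (rep in 1:10) {
    d <- sample(2:5, 1L)
    R <- random_cov(d)
    mu1 <- rnorm(d); mu2 <- rnorm(d)
    a <- mu1 - mu2
    Wstar <- drop(solve(R, a)) / drop(t(a) %*% solve(R, a))
    sol <- solve_mpm(make_stats(mu1, R), make_stats(mu2, R))
    expect_equal(sol$W, Wstar, tolerance = 1e-6)
  }
})

test_that("solver satisfies the constraint and internal consistency", {
  set.seed(43)
  for (rep in 1:10) {
    d <- sample(2:5, 1L)
    s1 <- make_stats(rnorm(d), random_cov(d))
    s2 <- make_stats(rnorm(d), random_cov(d))
    sol <- solve_mpm(s1, s2)
    # constraint residual
    expect_lt(abs(sum(sol$W * (s1$mu - s2$mu)) - 1), 1e-8)
    # kappa recomputed from W matches
    expect_lt(abs(sol$kappa - 1 / mpm_objective_of(sol$W, s1, s2)), 1e-8)
    # both offset expressions agree
    expect_lt(abs(sol$b_class1 - sol$b_class2), 1e-8)
    # worst-case bound diagnostic
    expect_equal(sol$worst_case_error, 1 / (1 + sol$kappa^2))
  }
})

test_that("solver objective matches an independent convex optimizer", {
  set.seed(44)
  for (rep in 1:10) {
    d <- sample(2:5, 1L)
    s1 <- make_stats(rnorm(d), random_cov(d))
    s2 <- make_stats(rnorm(d), random_cov(d))
    sol <- solve_mpm(s1, s2)
    orc <- oracle_mpm(s1, s2)
    expect_lt(abs(sol$objective - orc$objective) / orc$objective, 1e-6)
  }
})

test_that("covariance scaling: kappa scales as 1/t, W unchanged", {
  set.seed(45)
  s1 <- make_stats(c(2, 1, 0), random_cov(3L))
  s2 <- make_stats(c(0, 0, 1), random_cov(3L))
  sol <- solve_mpm(s1, s2)
  for (t in c(0.5, 3)) {
    sol_t <- solve_mpm(make_stats(s1$mu, t^2 * s1$R),
                       make_stats(s2$mu, t^2 * s2$R))
    expect_equal(sol_t$W, sol$W, tolerance = 1e-7)
    expect_equal(sol_t$kappa, sol$kappa / t, tolerance = 1e-7)
  }
})

test_that("identical class means are infeasible", {
  mu <- c(1, 2)
  expect_error(solve_mpm(make_stats(mu, diag(2)), make_stats(mu, diag(2))),
               "infeasible")
})

test_that("scores at the class means and midpoint follow the geometry", {
  # with R1 = R2, the midpoint of the means scores exactly 0
  set.seed(46)
  R <- random_cov(3L)
  mu1 <- c(2, 0, 1); mu2 <- c(-1, 1, 0)
  sol <- solve_mpm(make_stats(mu1, R), make_stats(mu2, R))
  s_mid <- sum(sol$W * (mu1 + mu2) / 2) - sol$b
  expect_equal(s_mid, 0, tolerance = 1e-8)
  # mu1 scores positive by kappa * sqrt(W'R1W); mu2 the mirror
  expect_equal(sum(sol$W * mu1) - sol$b,
               sol$kappa * sqrt(drop(t(sol$W) %*% R %*% sol$W)),
               tolerance = 1e-8)
  expect_equal(sum(sol$W * mu2) - sol$b,
               -sol$kappa * sqrt(drop(t(sol$W) %*% R %*% sol$W)),
               tolerance = 1e-8)
})

gaussian_data <- function(n, mu1, mu2, seed) {
  set.seed(seed)
  d <- length(mu1)
  X <- rbind(matrix(rnorm(n * d, sd = 1), n) + rep(mu1, each = n),
             matrix(rnorm(n * d, sd = 1), n) + rep(mu2, each = n))
  list(X = X, y = rep(c(1L, 0L), each = n))
}

test_that("fit on separated Gaussians honours the MPM guarantee", {
  dat <- gaussian_data(400L, c(3, 0), c(0, 0), seed = 47)
  model <- mpm_fit(dat$X, dat$y)
  s <- mpm_score(model, dat$X)
  tpr <- mean(s[dat$y == 1L] > 0)
  tnr <- mean(s[dat$y == 0L] <= 0)
  guarantee <- 1 - model$worst_case_error
  expect_gte(tpr, guarantee)
  expect_gte(tnr, guarantee)
})

test_that("flipping the labels negates weights and scores", {
  dat <- gaussian_data(200L, c(2, 1), c(0, 0), seed = 48)
  m1 <- mpm_fit(dat$X, dat$y)
  m2 <- mpm_fit(dat$X, 1L - dat$y)
  expect_equal(m2$W, -m1$W, tolerance = 1e-6)
  s1 <- mpm_score(m1, dat$X)
  s2 <- mpm_score(m2, dat$X)
  expect_equal(s2, -s1, tolerance = 1e-6)
})

test_that("constant columns are dropped with a warning; NA labels skipped", {
  dat <- gaussian_data(100L, c(2, 0), c(0, 0), seed = 49)
  Xc <- cbind(dat$X, 7)
  expect_warning(model <- mpm_fit(Xc, dat$y), "constant")
  expect_equal(sum(model$kept), 2L)
  expect_length(mpm_score(model, Xc), nrow(Xc))

  yna <- dat$y; yna[1:10] <- NA
  expect_silent(mpm_fit(dat$X, yna))
})

test_that("scores are invariant to affine rescaling of raw columns", {
  dat <- gaussian_data(200L, c(2, 1), c(0, 0), seed = 50)
  m1 <- mpm_fit(dat$X, dat$y)
  Xr <- sweep(sweep(dat$X, 2L, c(10, 0.1), "*"), 2L, c(-3, 5), "+")
  m2 <- mpm_fit(Xr, dat$y)
  expect_equal(mpm_score(m2, Xr), mpm_score(m1, dat$X), tolerance = 1e-6)
})

test_that("mpm_score validates the feature dimension", {
  dat <- gaussian_data(50L, c(2, 0), c(0, 0), seed = 51)
  model <- mpm_fit(dat$X, dat$y)
  expect_error(mpm_score(model, dat$X[, 1L, drop = FALSE]), "dimension mismatch")
})

test_that("threshold calibration: enumerated cut points and boundaries", {
  scores <- c(-1, -0.5, 0.2, 0.4, 0.6)
  labels <- c(0L, 0L, 0L, 1L, 1L)
  cal <- calibrate_thresholds(scores, labels, 0.34)
  expect_equal(cal$threshold, -0.5)        # admits 1/3 of the negatives
  expect_equal(cal$fpr, 1 / 3)
  expect_equal(cal$tpr, 1)

  cal0 <- calibrate_thresholds(scores, labels, 0)
  expect_gte(cal0$threshold, 0.2)          # above the max negative
  expect_equal(cal0$fpr, 0)

  cal1 <- calibrate_thresholds(scores, labels, 1)
  expect_equal(cal1$threshold, min(scores))
  expect_equal(cal1$tpr, 1)

  expect_error(calibrate_thresholds(c(1, 2), c(1L, 1L), 0.5), "no negative")
})

test_that("calibration respects FPR <= target and minimality on random data", {
  set.seed(52)
  for (rep in 1:20) {
    n <- 60L
    scores <- round(rnorm(n), 2)   # force ties
    labels <- sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3))
    if (!any(labels == 0L) || !any(labels == 1L)) next
    targets <- c(0, 0.05, 0.25, 1)
    cal <- calibrate_thresholds(scores, labels, targets)
    neg <- scores[labels == 0L]
    for (k in seq_along(targets)) {
      expect_lte(cal$fpr[k], cal$target_fpr[k])
      expect_equal(cal$fpr[k], mean(neg > cal$threshold[k]))
      # no smaller observed cut point also satisfies the target
      smaller <- sort(unique(scores))
      smaller <- smaller[smaller < cal$threshold[k]]
      if (length(smaller))
        expect_true(all(vapply(smaller, function(t) mean(neg > t),
                               numeric(1)) > cal$target_fpr[k]))
    }
  }
})

test_that("model files round-trip and reproduce predictions", {
  dat <- generate_morf_data(synthetic_config(n_sequences = 6L,
                                             length_range = c(40L, 80L),
                                             seed = 53L))
  model <- train_morf(dat$sequences, spec = window_spec(c(5L, 11L)))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(model, f)
  back <- read_model(f)
  expect_equal(back$W, model$W)
  expect_equal(back$b, model$b)
  expect_equal(back$kappa, model$kappa)
  expect_equal(back$window_sizes, model$window_sizes)
  expect_equal(feature_names(back$feature_set), feature_names(model$feature_set))
  p1 <- predict_morf(model, dat$sequences[[1L]])
  p2 <- predict_morf(back, dat$sequences[[1L]])
  expect_equal(p2, p1)
})
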