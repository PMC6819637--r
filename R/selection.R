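#' Scatter-matrix separability criterion
#'
#' Computes `J_d = tr(S_w + S_b)` on the selected feature columns, with
#' the between-class scatter `S_b = sum_i P_i (m_i - m)(m_i - m)^T` and
#' the within-class scatter
#' `S_w = sum_i P_i (1/N_i) sum_j (x_j - m_i)(x_j - m_i)^T`, class priors
#' `P_i = N_i / (N_1 + N_2)`, class means `m_i` and total mean `m`.
#'
#' Note that `tr(S_w) + tr(S_b)` equals the trace of the prior-weighted
#' total scatter around `m`, which does not depend on the labels; the
#' criterion is used as printed, and the label-aware alternative
#' `tr(S_b)` alone is available via `criterion = "between"` in
#' [anneal_select()].
#'
#' @param X numeric matrix (rows = samples)
#' @param y binary labels (0/1), both classes present
#' @param subset column indices to evaluate
#' @return object of class `scatter_result` with `J_d`, `S_b_trace`,
#'   `S_w_trace`
#' @export
scatter_criterion <- function(X, y, subset = seq_len(ncol(X))) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in 'y'", call. = FALSE)
  if (length(subset) == 0L || any(subset < 1L) || any(subset > ncol(X)))
    stop("'subset' must be a nonempty set of valid column indices",
         call. = FALSE)
  Xs <- X[, subset, drop = FALSE]
  n <- nrow(Xs)
  m <- colMeans(Xs)
  sb <- 0; sw <- 0
  for (cls in c(1L, 0L)) {
    rows <- y == cls
    Ni <- sum(rows)
    Pi <- Ni / n
    mi <- colMeans(Xs[rows, , drop = FALSE])
    sb <- sb + Pi * sum((mi - m)^2)
    dev <- sweep(Xs[rows, , drop = FALSE], 2L, mi)
    sw <- sw + Pi * sum(dev^2) / Ni
  }
  structure(list(J_d = sb + sw, S_b_trace = sb, S_w_trace = sw),
            class = "scatter_result")
}

#' @export
print.scatter_result <- function(x, ...) {
  cat("<scatter_result> J_d =", format(x$J_d),
      "(S_b =", format(x$S_b_trace), ", S_w =", format(x$S_w_trace), ")\n")
  invisible(x)
}

#' Simulated-annealing schedule
#'
#' @param T_max initial temperature (default 1)
#' @param T_min stopping temperature (default 1e-4)
#' @param r cooling rate in (0, 1), `T <- T * r` per step (default 0.9995)
#' @param seed RNG seed for a reproducible run
#' @return object of class `anneal_schedule`
#' @export
anneal_schedule <- function(T_max = 1, T_min = 1e-4, r = 0.9995, seed = 1L) {
  if (!(T_max > T_min && T_min > 0)) stop("need T_max > T_min > 0", call. = FALSE)
  if (!(r > 0 && r < 1)) stop("cooling rate r must be in (0, 1)", call. = FALSE)
  structure(list(T_max = T_max, T_min = T_min, r = r, seed = as.integer(seed)),
            class = "anneal_schedule")
}

## Per-column criterion contributions. The trace criteria are additive
## over coordinates, so J_d of a subset is the sum of its columns'
## contributions; the annealer exploits this for O(1) move evaluation.
.column_criteria <- function(X, y, pool, criterion) {
  vapply(pool, function(cc) {
    sr <- scatter_criterion(X, y, cc)
    if (criterion == "between") sr$S_b_trace else sr$J_d
  }, numeric(1))
}

#' Simulated-annealing feature-subset selection
#'
#' Searches subsets of size `N_fea` of the candidate column `pool`,
#' maximizing the scatter criterion. One move per temperature level:
#' a random selected feature is replaced by a random unselected one;
#' an improving move is always accepted, a worsening move with
#' probability `exp(-|J_d - J_d'| / T)`; then `T <- T * r` until
#' `T <= T_min`. The best state visited (not the final state) is
#' returned, together with the full trajectory.
#'
#' @param X numeric feature matrix
#' @param y binary labels (0/1)
#' @param N_fea number of features to select
#' @param pool candidate column indices (default: all columns)
#' @param schedule an [anneal_schedule]
#' @param criterion `"trace"` for the printed `J_d = tr(S_w + S_b)`
#'   (label-independent; see [scatter_criterion()]) or `"between"` for
#'   `tr(S_b)` alone
#' @return list with `subset` (sorted column indices of the best state),
#'   `J_d`, and `trajectory` (data.frame iter, T, J_d, accepted)
#' @export
anneal_select <- function(X, y, N_fea, pool = seq_len(ncol(X)),
                          schedule = anneal_schedule(),
                          criterion = c("trace", "between")) {
  criterion <- match.arg(criterion)
  pool <- as.integer(pool)
  if (N_fea > length(pool))
    stop("N_fea (", N_fea, ") exceeds pool size (", length(pool), ")",
         call. = FALSE)
  jd <- .column_criteria(X, y, pool, criterion)
  names(jd) <- as.character(pool)
  np <- length(pool)

  if (N_fea == np) {
    return(list(subset = sort(pool), J_d = sum(jd),
                trajectory = data.frame(iter = integer(), T = numeric(),
                                        J_d = numeric(), accepted = logical())))
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(schedule$seed)

  sel <- sample.int(np, N_fea)               # positions within pool
  J <- sum(jd[sel])
  best_sel <- sel; best_J <- J
  n_iter <- max(1L, ceiling(log(schedule$T_min / schedule$T_max) /
                              log(schedule$r)))
  iter_v <- seq_len(n_iter)
  T_v <- numeric(n_iter); J_v <- numeric(n_iter); acc_v <- logical(n_iter)
  Tt <- schedule$T_max
  for (it in iter_v) {
    out_i <- sel[sample.int(N_fea, 1L)]
    cand <- setdiff(seq_len(np), sel)
    in_i <- cand[sample.int(length(cand), 1L)]
    new_sel <- c(setdiff(sel, out_i), in_i)
    J_new <- sum(jd[new_sel])
    accept <- J_new > J || stats::runif(1L) < exp(-abs(J - J_new) / Tt)
    if (accept) {
      sel <- new_sel; J <- J_new
      if (J > best_J) { best_J <- J; best_sel <- sel }
    }
    T_v[it] <- Tt; J_v[it] <- J; acc_v[it] <- accept
    Tt <- Tt * schedule$r
  }
  list(subset = sort(pool[best_sel]), J_d = best_J,
       trajectory = data.frame(iter = iter_v, T = T_v, J_d = J_v,
                               accepted = acc_v))
}

#' Sweep of subset sizes
#'
#' Runs [anneal_select()] once per subset size in `N_fea_range`
#' (the candidate-set construction: sizes 10..20 give 11 candidate
#' feature sets). Per-run seeds are derived deterministically from the
#' schedule's master seed.
#'
#' @param X numeric feature matrix
#' @param y binary labels
#' @param pool candidate column indices
#' @param N_fea_range integer vector of subset sizes
#' @param schedule an [anneal_schedule]; its seed is the master seed
#' @param criterion passed to [anneal_select()]
#' @return named list mapping each size to its [anneal_select()] result
#' @export
candidate_sweep <- function(X, y, pool = seq_len(ncol(X)),
                            N_fea_range = 10:20,
                            schedule = anneal_schedule(),
                            criterion = "trace") {
  if (length(N_fea_range) == 0L) stop("empty N_fea_range", call. = FALSE)
  res <- lapply(seq_along(N_fea_range), function(k) {
    sched_k <- anneal_schedule(schedule$T_max, schedule$T_min, schedule$r,
                               seed = (schedule$seed * 131L + k) %% .Machine$integer.max)
    anneal_select(X, y, N_fea_range[k], pool, sched_k, criterion)
  })
  stats::setNames(res, as.character(N_fea_range))
}
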