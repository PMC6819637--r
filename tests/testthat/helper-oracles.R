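# Independent brute-force oracles used to pin the implementation.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "W", "Y", "V", "S", "T")

random_residues <- function(L) paste(sample(AA20, L, replace = TRUE),
                                     collapse = "")

# a small feature set exercising all three feature kinds
small_feature_set <- function() {
  feature_set(list(
    feature_descriptor("scale-average", scale_ref = "CIDH920101"),
    feature_descriptor("shannon-entropy"),
    feature_descriptor("topological-entropy")
  ))
}

# Accumulate-and-divide oracle for the per-residue averaging: every
# window's feature vector is assigned to each residue the window covers,
# then each residue divides by its coverage count. Window values come
# from evaluate_features(); sums run over ascending window index.
oracle_residue_vectors <- function(residues, N, fs, registry) {
  ps <- pad_and_slice(residues, N)
  L <- nchar(residues)
  K <- length(fs)
  V <- t(vapply(seq_len(ps$n_windows), function(i)
    unname(evaluate_features(ps$windows[i], ps$pad_counts[i], fs, registry)),
    numeric(K)))
  cover <- vector("list", L)
  for (i in seq_len(ps$n_windows)) {
    js <- (i - ps$N0):(i + ps$N - 1L - ps$N0)   # residues under window i
    for (j in js[js >= 1L & js <= L]) cover[[j]] <- c(cover[[j]], i)
  }
  out <- matrix(0, L, K)
  for (j in seq_len(L)) {
    rows <- cover[[j]]
    for (k in seq_len(K)) out[j, k] <- sum(V[rows, k]) / length(rows)
  }
  out
}

# Element-wise scatter criterion, written directly from the definitions
# (no matrix shortcuts, explicit double loops).
oracle_scatter <- function(X, y, subset) {
  Xs <- X[, subset, drop = FALSE]
  n <- nrow(Xs); d <- ncol(Xs)
  m <- numeric(d)
  for (k in seq_len(d)) m[k] <- mean(Xs[, k])
  sb <- 0; sw <- 0
  for (cls in c(1, 0)) {
    rows <- which(y == cls)
    Ni <- length(rows); Pi <- Ni / n
    mi <- numeric(d)
    for (k in seq_len(d)) mi[k] <- mean(Xs[rows, k])
    for (k in seq_len(d)) sb <- sb + Pi * (mi[k] - m[k])^2
    acc <- 0
    for (r in rows) for (k in seq_len(d)) acc <- acc + (Xs[r, k] - mi[k])^2
    sw <- sw + Pi * acc / Ni
  }
  list(S_b_trace = sb, S_w_trace = sw, J_d = sb + sw)
}

# Pairwise-comparison AUC: P(score_pos > score_neg) + 0.5 P(tie).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

mpm_objective_of <- function(W, s1, s2) {
  sqrt(drop(t(W) %*% s1$R %*% W)) + sqrt(drop(t(W) %*% s2$R %*% W))
}

# Independent convex solution of the MPM program: multi-start BFGS with
# analytic gradients on the constraint-reduced objective.
oracle_mpm <- function(s1, s2, n_starts = 6L) {
  a <- s1$mu - s2$mu
  d <- length(a)
  w0 <- a / sum(a^2)
  if (d == 1L) return(list(W = w0, objective = mpm_objective_of(w0, s1, s2)))
  Fn <- qr.Q(qr(matrix(a, ncol = 1L)), complete = TRUE)[, -1L, drop = FALSE]
  fobj <- function(u) mpm_objective_of(w0 + drop(Fn %*% u), s1, s2)
  fgrad <- function(u) {
    W <- w0 + drop(Fn %*% u)
    g <- drop(s1$R %*% W) / sqrt(drop(t(W) %*% s1$R %*% W)) +
         drop(s2$R %*% W) / sqrt(drop(t(W) %*% s2$R %*% W))
    drop(crossprod(Fn, g))
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    u0 <- if (s == 1L) numeric(d - 1L) else stats::rnorm(d - 1L)
    r <- stats::optim(u0, fobj, fgrad, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
    if (is.null(best) || r$value < best$value) best <- r
  }
  list(W = w0 + drop(Fn %*% best$par), objective = best$value)
}

# random positive-definite covariance
random_cov <- function(d) {
  A <- matrix(stats::rnorm(d * d), d)
  crossprod(A) + 0.1 * diag(d)
}
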