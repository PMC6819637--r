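#' Per-class moment estimates
#'
#' Means and unbiased covariance matrices of the two classes, with a
#' ridge `delta = 1e-6 * mean(diag(R))` (absolute 1e-6 when the diagonal
#' vanishes, e.g. identical points) added so `R` is always positive
#' definite. Class 1 is the MoRF class (`y == 1`).
#'
#' @param X numeric matrix (rows = samples)
#' @param y binary labels (0/1); each class needs >= 2 samples
#' @return list of two `class_stats` (class 1 first), each with `mu`, `R`
#' @export
class_stats <- function(X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in 'y'", call. = FALSE)
  one <- function(cls) {
    Xi <- X[y == cls, , drop = FALSE]
    if (nrow(Xi) < 2L)
      stop("class ", cls, " needs at least 2 samples", call. = FALSE)
    R <- stats::cov(Xi)
    delta <- 1e-6 * mean(diag(R))
    if (!is.finite(delta) || delta <= 0) delta <- 1e-6
    structure(list(mu = colMeans(Xi), R = R + delta * diag(ncol(Xi)),
                   n = nrow(Xi)),
              class = "class_stats")
  }
  list(one(1L), one(0L))
}

## Sum-of-norms objective sqrt(W'R1W) + sqrt(W'R2W)
.mpm_objective <- function(W, R1, R2) {
  sqrt(max(0, drop(crossprod(W, R1 %*% W)))) +
    sqrt(max(0, drop(crossprod(W, R2 %*% W))))
}

#' Solve the minimax probability machine program
#'
#' Minimizes `sqrt(W' R1 W) + sqrt(W' R2 W)` subject to
#' `W' (mu1 - mu2) = 1` by constraint elimination and iterative least
#' squares: writing `W = w0 + F u` with `w0` the minimum-norm solution of
#' the constraint and `F` an orthonormal basis of its null space, each
#' iteration minimizes the quadratic majorant
#' `W' R1 W / beta + W' R2 W / eta` (with `beta`, `eta` the current
#' norms), a plain least-squares solve in `u`. The scheme is monotone
#' (majorize-minimize) and stops when the relative objective change is
#' below `tol`.
#'
#' The optimal margin is `kappa = 1 / objective`; the offset `b` is
#' recovered from both classes (`W'mu1 - kappa sqrt(W'R1W)` and
#' `W'mu2 + kappa sqrt(W'R2W)`, equal under the constraint) and the
#' worst-case misclassification bound `1 / (1 + kappa^2)` reported as a
#' diagnostic.
#'
#' @param stats1,stats2 `class_stats` of class 1 (MoRF) and class 2
#' @param tol relative objective-change tolerance (default 1e-9)
#' @param max_iter iteration cap (default 1000); non-convergence is an
#'   error carrying the last objective
#' @return object of class `mpm_solution` with `W`, `b`, `kappa`,
#'   `objective`, `worst_case_error`, `iterations`, `converged`
#' @export
solve_mpm <- function(stats1, stats2, tol = 1e-9, max_iter = 1000L) {
  a <- stats1$mu - stats2$mu
  d <- length(a)
  a2 <- sum(a^2)
  if (a2 < .Machine$double.eps)
    stop("infeasible: class means are identical (mu1 == mu2)", call. = FALSE)
  R1 <- stats1$R; R2 <- stats2$R
  w0 <- a / a2
  if (d == 1L) {
    W <- w0
    obj <- .mpm_objective(W, R1, R2)
    iters <- 0L
  } else {
    Fn <- qr.Q(qr(matrix(a, ncol = 1L)), complete = TRUE)[, -1L, drop = FALSE]
    W <- w0
    obj <- .mpm_objective(W, R1, R2)
    iters <- 0L
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      beta <- max(sqrt(max(0, drop(crossprod(W, R1 %*% W)))), 1e-300)
      eta  <- max(sqrt(max(0, drop(crossprod(W, R2 %*% W)))), 1e-300)
      G <- R1 / beta + R2 / eta
      u <- -solve(crossprod(Fn, G %*% Fn), crossprod(Fn, G %*% w0))
      W <- w0 + drop(Fn %*% u)
      obj_new <- .mpm_objective(W, R1, R2)
      iters <- it
      if (abs(obj - obj_new) <= tol * max(1, abs(obj))) {
        obj <- obj_new
        converged <- TRUE
        break
      }
      obj <- obj_new
    }
    if (!converged)
      stop("MPM solver did not converge in ", max_iter,
           " iterations (last objective ", format(obj), ")", call. = FALSE)
  }
  s1 <- sqrt(max(0, drop(crossprod(W, R1 %*% W))))
  s2 <- sqrt(max(0, drop(crossprod(W, R2 %*% W))))
  kappa <- 1 / (s1 + s2)
  b1 <- drop(crossprod(W, stats1$mu)) - kappa * s1
  b2 <- drop(crossprod(W, stats2$mu)) + kappa * s2
  structure(list(W = W, b = (b1 + b2) / 2, kappa = kappa,
                 objective = s1 + s2,
                 b_class1 = b1, b_class2 = b2,
                 worst_case_error = 1 / (1 + kappa^2),
                 iterations = iters, converged = TRUE),
            class = "mpm_solution")
}

#' Fit an MPM MoRF model
#'
#' Standardizes each column to zero mean and unit variance (training
#' statistics; zero-variance columns are dropped with a warning),
#' estimates per-class moments with `y == 1` as the MoRF class, and
#' solves the MPM program. The full training set is used as-is: class
#' imbalance only enters through the per-class moment estimates, so no
#' subsampling is performed.
#'
#' @param X numeric feature matrix (rows = residues)
#' @param y binary labels, 1 = MoRF; NA rows are dropped
#' @param tol,max_iter passed to [solve_mpm()]
#' @param spec,fs provenance: the [window_spec] and [feature_set] that
#'   produced `X` (stored so the model can score raw sequences)
#' @param registry a [scale_registry]; referenced scales are embedded in
#'   the model so it is self-contained
#' @return object of class `morf_model`
#' @export
mpm_fit <- function(X, y, tol = 1e-9, max_iter = 1000L,
                    spec = NULL, fs = NULL,
                    registry = default_scale_registry()) {
  X <- as.matrix(X)
  keep_rows <- !is.na(y)
  X <- X[keep_rows, , drop = FALSE]
  y <- as.integer(y[keep_rows])
  center <- colMeans(X)
  scale_ <- apply(X, 2L, stats::sd)
  kept <- scale_ > 0
  if (!all(kept))
    warning("dropping ", sum(!kept), " constant feature column(s): ",
            paste(colnames(X)[!kept], collapse = ", "), call. = FALSE)
  if (!any(kept)) stop("no non-constant feature columns", call. = FALSE)
  Xs <- sweep(sweep(X[, kept, drop = FALSE], 2L, center[kept]), 2L,
              scale_[kept], "/")
  cs <- class_stats(Xs, y)
  sol <- solve_mpm(cs[[1L]], cs[[2L]], tol = tol, max_iter = max_iter)
  scales <- NULL
  if (!is.null(fs)) {
    refs <- unlist(lapply(fs$descriptors, function(d) d$scale_ref))
    scales <- lapply(unique(refs), function(a) registry[[a]])
  }
  structure(list(
    W = sol$W, b = sol$b, kappa = sol$kappa,
    objective = sol$objective, worst_case_error = sol$worst_case_error,
    center = center, scale = scale_, kept = kept,
    n_features = ncol(X), feature_columns = colnames(X),
    window_sizes = if (!is.null(spec)) spec$sizes else NULL,
    feature_set = fs, scales = scales,
    threshold = 0, class1 = "MoRF"
  ), class = "morf_model")
}

#' @export
print.morf_model <- function(x, ...) {
  cat("<morf_model> linear MPM,", sum(x$kept), "of", x$n_features,
      "feature columns\n")
  cat("  kappa =", format(x$kappa, digits = 4),
      " worst-case error bound =", format(x$worst_case_error, digits = 4), "\n")
  if (!is.null(x$window_sizes))
    cat("  windows:", paste(x$window_sizes, collapse = "/"),
        " features:", length(x$feature_set), "\n")
  invisible(x)
}

#' Score residues with a fitted model
#'
#' Returns the signed decision value `s = W' x_std - b` for each row of
#' `X`; the MoRF call is `s > threshold` (default threshold 0).
#'
#' @param model a [mpm_fit()] model
#' @param X feature matrix with the same columns the model was fit on
#' @return numeric score vector
#' @export
mpm_score <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop("feature dimension mismatch: model expects ", model$n_features,
         " columns, got ", ncol(X), call. = FALSE)
  Xs <- sweep(sweep(X[, model$kept, drop = FALSE], 2L,
                    model$center[model$kept]), 2L,
              model$scale[model$kept], "/")
  drop(Xs %*% model$W) - model$b
}

#' Train a MoRF predictor from annotated sequences
#'
#' Convenience wrapper: builds the per-residue feature matrix for the
#' corpus ([corpus_features()]) and fits the MPM on it.
#'
#' @param sequences list of [annotated_sequence] with masks set
#' @param spec a [window_spec]
#' @param fs a [feature_set]
#' @param registry a [scale_registry]
#' @param ... passed to [mpm_fit()]
#' @return a `morf_model`
#' @export
train_morf <- function(sequences, spec = window_spec(),
                       fs = default_feature_set(),
                       registry = default_scale_registry(), ...) {
  cf <- corpus_features(sequences, spec, fs, registry)
  mpm_fit(cf$X, cf$y, spec = spec, fs = fs, registry = registry, ...)
}

#' Per-residue MoRF scores for sequences
#'
#' Rebuilds the feature matrix from the model's stored window sizes,
#' feature set and embedded scales, and scores every residue.
#'
#' @param model a `morf_model` trained with provenance ([train_morf()])
#' @param sequences list of [annotated_sequence] (or a single one)
#' @return named list of numeric score vectors, one per sequence
#' @export
predict_morf <- function(model, sequences) {
  if (inherits(sequences, "annotated_sequence")) sequences <- list(sequences)
  if (is.null(model$window_sizes) || is.null(model$feature_set))
    stop("model lacks window/feature provenance; use mpm_score() on a matrix",
         call. = FALSE)
  registry <- if (length(model$scales)) scale_registry(model$scales)
              else default_scale_registry()
  spec <- window_spec(model$window_sizes)
  out <- lapply(sequences, function(s)
    mpm_score(model, build_feature_matrix(s, spec, model$feature_set, registry)))
  stats::setNames(out, vapply(sequences, function(s) s$id, character(1)))
}

#' Calibrate decision thresholds at fixed false-positive rates
#'
#' For each target FPR, returns the smallest threshold whose achieved
#' FPR (with the strict call `score > threshold`) does not exceed the
#' target, plus the operating point achieved there.
#'
#' @param scores numeric score vector
#' @param labels binary labels (NA = ignore); negatives must be present
#' @param fpr_targets numeric vector of target FPRs in \[0, 1\]
#' @return data.frame with columns target_fpr, threshold, fpr, tpr
#' @export
calibrate_thresholds <- function(scores, labels, fpr_targets) {
  keep <- !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  neg <- scores[labels == 0L]
  pos <- scores[labels == 1L]
  if (length(neg) == 0L) stop("no negative residues to calibrate on",
                              call. = FALSE)
  if (any(fpr_targets < 0 | fpr_targets > 1))
    stop("FPR targets must lie in [0, 1]", call. = FALSE)
  cand <- sort(unique(scores))
  rows <- lapply(fpr_targets, function(tgt) {
    for (th in cand) {
      fpr <- mean(neg > th)
      if (fpr <= tgt) {
        return(data.frame(target_fpr = tgt, threshold = th, fpr = fpr,
                          tpr = if (length(pos)) mean(pos > th) else NA_real_))
      }
    }
    data.frame(target_fpr = tgt, threshold = max(cand), fpr = 0,
               tpr = if (length(pos)) mean(pos > max(cand)) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Write a model file
#'
#' Serializes a `morf_model` (weights, offset, margin, standardizer,
#' feature set, window sizes and embedded scales) as versioned JSON text.
#'
#' @param model a `morf_model`
#' @param path output path
#' @export
write_model <- function(model, path) {
  fs_json <- if (!is.null(model$feature_set))
    lapply(model$feature_set$descriptors, function(d)
      list(kind = d$kind, name = d$name, scale_ref = d$scale_ref))
  scales_json <- if (length(model$scales))
    lapply(model$scales, function(s)
      list(accession = s$accession, description = s$description,
           values = as.list(s$values)))
  obj <- list(
    format = "morfmpm-model", version = 1L,
    W = unname(model$W), b = model$b, kappa = model$kappa,
    objective = model$objective, worst_case_error = model$worst_case_error,
    center = unname(model$center), scale = unname(model$scale),
    kept = unname(model$kept), n_features = model$n_features,
    feature_columns = model$feature_columns,
    window_sizes = model$window_sizes,
    feature_set = fs_json, scales = scales_json,
    threshold = model$threshold, class1 = model$class1
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a model file written by [write_model()]
#'
#' @param path path to the JSON model file
#' @return a `morf_model`
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$format, "morfmpm-model"))
    stop("not a morfmpm model file: ", path, call. = FALSE)
  fs <- NULL
  if (!is.null(obj$feature_set))
    fs <- feature_set(lapply(obj$feature_set, function(d)
      feature_descriptor(d$kind, d$name, d$scale_ref)))
  scales <- NULL
  if (!is.null(obj$scales))
    scales <- lapply(obj$scales, function(s)
      property_scale(s$accession, unlist(s$values), s$description))
  kept <- as.logical(obj$kept)
  fcols <- unlist(obj$feature_columns)
  structure(list(
    W = stats::setNames(as.numeric(obj$W), fcols[kept]), b = obj$b,
    kappa = obj$kappa,
    objective = obj$objective, worst_case_error = obj$worst_case_error,
    center = stats::setNames(as.numeric(obj$center), fcols),
    scale = stats::setNames(as.numeric(obj$scale), fcols),
    kept = stats::setNames(kept, fcols), n_features = obj$n_features,
    feature_columns = fcols,
    window_sizes = if (!is.null(obj$window_sizes)) as.integer(obj$window_sizes),
    feature_set = fs, scales = scales,
    threshold = obj$threshold, class1 = obj$class1
  ), class = "morf_model")
}
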