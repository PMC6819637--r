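#' Window specification
#'
#' Ordered, strictly increasing window sizes. The defaults follow the
#' three-window scheme: a short window of 10 highlighting MoRF-local
#' composition, a long window of 90 capturing the disordered context
#' (flanks), and a middle window of half the long size (45) damping the
#' noise the long window introduces.
#'
#' @param sizes positive, strictly increasing integer window sizes
#' @return object of class `window_spec`
#' @export
window_spec <- function(sizes = c(10L, 45L, 90L)) {
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L || any(sizes < 1L))
    stop("window sizes must be positive integers", call. = FALSE)
  if (is.unsorted(sizes, strictly = TRUE))
    stop("window sizes must be strictly increasing", call. = FALSE)
  structure(list(sizes = sizes), class = "window_spec")
}

#' Zero-pad a sequence and slice it into windows
#'
#' Pads the sequence with `N0 = floor((N - 1) / 2)` virtual zero
#' positions on each side (total padded length `L0 = L + 2 N0`) and
#' slides a window of length `N` with step 1, yielding `L0 - N + 1`
#' windows. Each window is returned as its residue part plus the count
#' of pad positions it covers. A window longer than the sequence is
#' clamped to `N = L` for that sequence (with a message when
#' `options(morfmpm.verbose = TRUE)`).
#'
#' @param sequence an [annotated_sequence] or a residue string
#' @param N window length (>= 1)
#' @return list with elements `windows` (character vector), `pad_counts`
#'   (integer vector), and the geometry `N`, `N0`, `L0`, `n_windows`
#' @export
pad_and_slice <- function(sequence, N) {
  residues <- if (inherits(sequence, "annotated_sequence"))
    sequence$residues else sequence
  L <- nchar(residues)
  if (L == 0L) stop("empty sequence", call. = FALSE)
  N <- as.integer(N)
  if (N < 1L) stop("window length must be >= 1", call. = FALSE)
  if (N > L) {
    if (isTRUE(getOption("morfmpm.verbose")))
      message("window ", N, " longer than sequence (L = ", L, "); clamped to L")
    N <- L
  }
  N0 <- (N - 1L) %/% 2L
  L0 <- L + 2L * N0
  n_windows <- L0 - N + 1L
  starts <- seq_len(n_windows)                 # start in padded coordinates
  real_lo <- pmax(starts, N0 + 1L)             # overlap with real positions
  real_hi <- pmin(starts + N - 1L, N0 + L)
  windows <- substring(residues, real_lo - N0, real_hi - N0)
  pad_counts <- N - (real_hi - real_lo + 1L)
  list(windows = windows, pad_counts = as.integer(pad_counts),
       N = N, N0 = N0, L0 = L0, n_windows = n_windows)
}

## Feature vectors of every window of one sequence: (n_windows x K) matrix.
.window_matrix <- function(residues, N, ctx) {
  ps <- pad_and_slice(residues, N)
  idx_all <- .aa_codes(residues)
  N0 <- ps$N0
  V <- matrix(0, nrow = ps$n_windows, ncol = ctx$K)
  for (i in seq_len(ps$n_windows)) {
    lo <- max(i, N0 + 1L) - N0
    hi <- min(i + ps$N - 1L, N0 + nchar(residues)) - N0
    V[i, ] <- .window_features(idx_all[lo:hi], ps$pad_counts[i], ctx)
  }
  list(V = V, N = ps$N, N0 = N0, n_windows = ps$n_windows)
}

## Coverage range of residue j (1..L) over window indices: residue j sits
## at padded position j + N0 and is covered by windows i in
## [j + N0 - N + 1, j + N0] intersected with [1, n_windows].
.coverage_range <- function(j, N, N0, n_windows) {
  c(max(1L, j + N0 - N + 1L), min(j + N0, n_windows))
}

#' Per-residue feature vectors for one window size
#'
#' Every window's feature vector is assigned to each residue it covers;
#' each residue then averages the vectors assigned to it (divide by the
#' coverage count). For interior residues this is the mean over the `N`
#' windows containing the residue; near the ends the count shrinks. For
#' odd `N` this reproduces the three-branch closed form (left edge,
#' interior, right edge) exactly; for even `N` the closed form's interior
#' branch would index one window past the last, so the coverage-count
#' definition is used uniformly (see the methods vignette).
#'
#' @param sequence an [annotated_sequence] or residue string
#' @param N window length
#' @param fs a [feature_set]
#' @param registry a [scale_registry]
#' @return `L x length(fs)` matrix, one row per residue
#' @export
residue_vectors <- function(sequence, N, fs,
                            registry = default_scale_registry()) {
  residues <- if (inherits(sequence, "annotated_sequence"))
    sequence$residues else sequence
  ctx <- .feature_context(fs, registry)
  wm <- .window_matrix(residues, N, ctx)
  L <- nchar(residues)
  X <- matrix(0, nrow = L, ncol = ctx$K,
              dimnames = list(NULL, feature_names(fs)))
  for (j in seq_len(L)) {
    r <- .coverage_range(j, wm$N, wm$N0, wm$n_windows)
    # colSums/n, not colMeans: the division must round in double
    # precision so the result is bit-identical to summing the assigned
    # window vectors and dividing by the coverage count
    X[j, ] <- colSums(wm$V[r[1L]:r[2L], , drop = FALSE]) / (r[2L] - r[1L] + 1L)
  }
  X
}

#' Per-residue feature matrix over all windows
#'
#' Horizontal concatenation of [residue_vectors()] for each window size
#' in `spec` order: an `L x (K * n_windows)` matrix (48 columns for the
#' 16-feature, three-window defaults). Columns are named
#' `w<size>.<feature>`.
#'
#' @param sequence an [annotated_sequence] or residue string
#' @param spec a [window_spec]
#' @param fs a [feature_set]
#' @param registry a [scale_registry]
#' @return matrix with attributes `sequence_id`, `window_sizes`,
#'   `feature_names`
#' @export
build_feature_matrix <- function(sequence, spec = window_spec(),
                                 fs = default_feature_set(),
                                 registry = default_scale_registry()) {
  blocks <- lapply(spec$sizes, function(N)
    residue_vectors(sequence, N, fs, registry))
  X <- do.call(cbind, blocks)
  fn <- feature_names(fs)
  colnames(X) <- unlist(lapply(spec$sizes, function(N) paste0("w", N, ".", fn)))
  if (any(!is.finite(X)))
    stop("non-finite feature values computed", call. = FALSE)
  attr(X, "sequence_id") <- if (inherits(sequence, "annotated_sequence"))
    sequence$id else NA_character_
  attr(X, "window_sizes") <- spec$sizes
  attr(X, "feature_names") <- fn
  X
}

#' Stacked feature matrix and labels for a corpus
#'
#' Runs [build_feature_matrix()] on every sequence and stacks the rows,
#' carrying along the per-residue mask as the label vector (NA = ignore).
#'
#' @param sequences list of [annotated_sequence] objects
#' @param spec a [window_spec]
#' @param fs a [feature_set]
#' @param registry a [scale_registry]
#' @return list with `X` (matrix), `y` (integer labels with NA),
#'   `seq_id` (character), `pos` (integer, 1-based residue position)
#' @export
corpus_features <- function(sequences, spec = window_spec(),
                            fs = default_feature_set(),
                            registry = default_scale_registry()) {
  mats <- lapply(sequences, build_feature_matrix, spec = spec, fs = fs,
                 registry = registry)
  X <- do.call(rbind, mats)
  y <- unlist(lapply(sequences, function(s) s$mask))
  seq_id <- unlist(lapply(sequences, function(s)
    rep(s$id, nchar(s$residues))))
  pos <- unlist(lapply(sequences, function(s) seq_len(nchar(s$residues))))
  list(X = X, y = y, seq_id = seq_id, pos = pos)
}
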