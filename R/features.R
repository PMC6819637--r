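#' Feature descriptor
#'
#' One entry of a feature set: a property-scale average, Shannon entropy,
#' or topological entropy.
#'
#' @param kind one of `"scale-average"`, `"shannon-entropy"`,
#'   `"topological-entropy"`
#' @param name unique feature name; defaults to `scale_ref` for
#'   scale-averages and to `kind` otherwise
#' @param scale_ref accession of the underlying scale (required iff
#'   `kind == "scale-average"`)
#' @return object of class `feature_descriptor`
#' @export
feature_descriptor <- function(kind, name = NULL, scale_ref = NULL) {
  kind <- match.arg(kind, c("scale-average", "shannon-entropy",
                            "topological-entropy"))
  if (kind == "scale-average") {
    if (is.null(scale_ref) || !nzchar(scale_ref))
      stop("scale-average features need a 'scale_ref' accession", call. = FALSE)
  } else if (!is.null(scale_ref)) {
    stop("'scale_ref' only applies to scale-average features", call. = FALSE)
  }
  if (is.null(name)) name <- if (kind == "scale-average") scale_ref else kind
  structure(list(kind = kind, name = name, scale_ref = scale_ref),
            class = "feature_descriptor")
}

#' Feature set
#'
#' An ordered list of [feature_descriptor]s defining the per-window
#' feature vector layout.
#'
#' @param descriptors list of [feature_descriptor] objects with unique names
#' @return object of class `morf_feature_set`
#' @export
feature_set <- function(descriptors) {
  if (inherits(descriptors, "feature_descriptor")) descriptors <- list(descriptors)
  stopifnot(length(descriptors) > 0L,
            all(vapply(descriptors, inherits, logical(1), "feature_descriptor")))
  nm <- vapply(descriptors, function(d) d$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate feature name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  structure(list(descriptors = descriptors), class = "morf_feature_set")
}

#' @export
length.morf_feature_set <- function(x) length(x$descriptors)

#' @export
print.morf_feature_set <- function(x, ...) {
  cat("<morf_feature_set> with", length(x), "features:\n")
  for (d in x$descriptors) cat("  ", d$name, " (", d$kind, ")\n", sep = "")
  invisible(x)
}

#' Feature names of a feature set
#' @param fs a [feature_set]
#' @return character vector
#' @export
feature_names <- function(fs) {
  vapply(fs$descriptors, function(d) d$name, character(1))
}

#' The default 16-feature set
#'
#' Thirteen AAindex physicochemical scale averages (CIDH920101,
#' EISD860103, NISK860101, QIAN880105, ROBB760101/08/12/13,
#' CORJ870103/06/07/08, MIYS990104), topological entropy, and the
#' Remark 465 and Deleage/Roux disorder-propensity averages.
#'
#' @return a [feature_set] with 16 descriptors
#' @export
default_feature_set <- function() {
  table2 <- c("CIDH920101", "EISD860103", "NISK860101", "QIAN880105",
              "ROBB760101", "ROBB760108", "ROBB760112", "ROBB760113",
              "CORJ870103", "CORJ870106", "CORJ870107", "CORJ870108",
              "MIYS990104")
  descs <- c(
    lapply(table2, function(a) feature_descriptor("scale-average", scale_ref = a)),
    list(feature_descriptor("topological-entropy"),
         feature_descriptor("scale-average", name = "remark465",
                            scale_ref = "SYNR465101"),
         feature_descriptor("scale-average", name = "deleage_roux",
                            scale_ref = "SYNDLRX101"))
  )
  feature_set(descs)
}

## Resolve a feature set against a registry into a fast evaluation context:
## a 21 x S lookup matrix for the scale-average features (row 21 = X,
## imputed as the mean of the 20 values) plus the output positions of each
## feature kind.
.feature_context <- function(fs, registry) {
  kinds <- vapply(fs$descriptors, function(d) d$kind, character(1))
  scale_pos <- which(kinds == "scale-average")
  SM <- NULL
  if (length(scale_pos)) {
    cols <- lapply(fs$descriptors[scale_pos], function(d) {
      sc <- registry[[d$scale_ref]]
      if (is.null(sc))
        stop("feature '", d$name, "': scale '", d$scale_ref,
             "' not in registry", call. = FALSE)
      v <- unname(sc$values)
      if (!all(is.finite(v)))
        stop("feature '", d$name, "': scale '", d$scale_ref,
             "' has missing values", call. = FALSE)
      c(v, mean(v))
    })
    SM <- do.call(cbind, cols)
  }
  list(K = length(fs), SM = SM, scale_pos = scale_pos,
       shannon_pos = which(kinds == "shannon-entropy"),
       topo_pos = which(kinds == "topological-entropy"))
}

## Shannon entropy (bits) over integer residue codes, X (21) excluded.
.shannon_codes <- function(idx) {
  idx <- idx[idx != AA_X]
  if (length(idx) == 0L) return(0)
  f <- tabulate(idx, nbins = 20L)
  f <- f[f > 0L] / length(idx)
  -sum(f * log2(f))
}

## Finite-sequence topological entropy over integer residue codes, X
## excluded. Sub-word length n is the largest n with 20^n + n - 1 <= len
## (n = 1 when len < 20); p counts distinct n-sub-words of the first
## min(len, 20^n + n - 1) positions; the result log(p)/(n log(min(20^n,
## len - n + 1))) is clamped to [0, 1].
.topo_codes <- function(idx) {
  idx <- idx[idx != AA_X]
  len <- length(idx)
  if (len == 0L) return(0)
  n <- 1L
  if (len >= 20L) {
    while (20^(n + 1L) + n <= len) n <- n + 1L
  }
  plen <- min(len, as.integer(20^n + n - 1))
  if (n == 1L) {
    p <- length(unique(idx[seq_len(plen)]))
  } else {
    nsub <- plen - n + 1L
    subs <- vapply(seq_len(nsub),
                   function(i) paste(idx[i:(i + n - 1L)], collapse = "."),
                   character(1))
    p <- length(unique(subs))
  }
  if (p <= 1L) return(0)
  base <- min(20^n, len - n + 1)
  if (base <= 1) return(0)
  min(1, max(0, log(p) / (n * log(base))))
}

## Per-window feature vector from integer codes; pads contribute zero to
## the scale-average numerator but count in the denominator, and are
## excluded from the entropy alphabet.
.window_features <- function(idx, pad_count, ctx) {
  out <- numeric(ctx$K)
  n <- length(idx)
  N <- n + pad_count
  if (length(ctx$scale_pos) && n > 0L && N > 0L)
    out[ctx$scale_pos] <- colSums(ctx$SM[idx, , drop = FALSE]) / N
  if (length(ctx$shannon_pos) && n > 0L)
    out[ctx$shannon_pos] <- .shannon_codes(idx)
  if (length(ctx$topo_pos) && n > 0L)
    out[ctx$topo_pos] <- .topo_codes(idx)
  out
}

#' Average property-scale value over a window
#'
#' Pad positions contribute zero to the numerator but are counted in the
#' denominator `N = nchar(window_text) + pad_count`. Unknown residues (X)
#' take the mean of the 20 scale values.
#'
#' @param window_text residue letters of the window (may be empty)
#' @param scale a [property_scale]
#' @param pad_count number of zero-pad positions in the window
#' @return the windowed average, a single real
#' @export
scale_average <- function(window_text, scale, pad_count = 0L) {
  n <- nchar(window_text)
  N <- n + pad_count
  if (N <= 0) stop("empty window: nchar + pad_count must be positive",
                   call. = FALSE)
  if (n == 0L) return(0)
  v <- c(unname(scale$values), mean(scale$values))
  sum(v[.aa_codes(window_text)]) / N
}

#' Shannon entropy of a window (bits)
#'
#' Entropy of the observed residue frequencies; X residues are excluded
#' from the alphabet, and an empty window has entropy 0 by convention.
#' Bounded by `log2(20)`.
#'
#' @param window_text residue letters of the window
#' @return entropy in bits
#' @export
shannon_entropy <- function(window_text) {
  .shannon_codes(.aa_codes(window_text))
}

#' Topological entropy of a window
#'
#' Finite-sequence topological entropy over the 20-letter alphabet,
#' normalized to `[0, 1]`: with sub-word length `n` the largest integer
#' such that `20^n + n - 1` fits in the window (falling back to `n = 1`
#' for windows shorter than 20), the number `p` of distinct `n`-sub-words
#' of the first `min(len, 20^n + n - 1)` positions is counted and
#' `log(p) / (n log(min(20^n, len - n + 1)))` returned. Homopolymers have
#' entropy 0; X residues are excluded.
#'
#' @param window_text residue letters of the window
#' @return a value in `[0, 1]`
#' @export
topological_entropy <- function(window_text) {
  .topo_codes(.aa_codes(window_text))
}

#' Evaluate all features of a feature set on one window
#'
#' @param window_text residue letters of the window (pads excluded)
#' @param pad_count number of zero-pad positions
#' @param fs a [feature_set]
#' @param registry a [scale_registry] resolving the scale references
#' @return numeric vector of length `length(fs)`, named by feature
#' @export
evaluate_features <- function(window_text, pad_count, fs,
                              registry = default_scale_registry()) {
  ctx <- .feature_context(fs, registry)
  v <- .window_features(.aa_codes(window_text), pad_count, ctx)
  stats::setNames(v, feature_names(fs))
}
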