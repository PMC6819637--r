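## UniProt-like background amino-acid frequencies (canonical AAindex order)
.BACKGROUND_COMP <- c(
  A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545, C = 0.0138,
  Q = 0.0393, E = 0.0675, G = 0.0707, H = 0.0227, I = 0.0596,
  L = 0.0966, K = 0.0584, M = 0.0242, F = 0.0386, P = 0.0470,
  W = 0.0108, Y = 0.0292, V = 0.0687, S = 0.0656, T = 0.0534
)

## disorder-enriched target composition for planted MoRF segments
.MORF_TARGET_COMP <- c(
  A = 0.10, R = 0, N = 0, D = 0.08, C = 0,
  Q = 0.12, E = 0.16, G = 0.10, H = 0, I = 0,
  L = 0, K = 0.12, M = 0, F = 0, P = 0.18,
  W = 0, Y = 0, V = 0, S = 0.14, T = 0
)

#' Configuration for the synthetic MoRF corpus generator
#'
#' Sequences are drawn i.i.d. from a background residue composition;
#' planted MoRF segments are drawn from a divergent composition
#' `(1 - effect_size) * background + effect_size * target`, where the
#' target composition is concentrated on disorder-promoting residues
#' (P, E, S, Q, K, G, D, A). `effect_size = 0` gives the null
#' (indistinguishable) case; `effect_size = 1` gives segments supported
#' on 8 letters only.
#'
#' @param n_sequences number of sequences (default 100)
#' @param length_range min/max sequence length (default 50-250)
#' @param morf_length_range min/max planted MoRF length (default 5-25,
#'   the usual MoRF length convention)
#' @param morfs_per_sequence planted segments per sequence (default 1)
#' @param background_composition 20-simplex over the residues (canonical
#'   order), default UniProt-like frequencies
#' @param morf_composition 20-simplex for MoRF residues; default is the
#'   `effect_size` blend described above
#' @param effect_size blend weight in \[0, 1+\] (default 0.8)
#' @param seed RNG seed
#' @return object of class `synthetic_config`
#' @export
synthetic_config <- function(n_sequences = 100L,
                             length_range = c(50L, 250L),
                             morf_length_range = c(5L, 25L),
                             morfs_per_sequence = 1L,
                             background_composition = .BACKGROUND_COMP,
                             morf_composition = NULL,
                             effect_size = 0.8,
                             seed = 1L) {
  stopifnot(n_sequences >= 1L, length(length_range) == 2L,
            length_range[1L] <= length_range[2L], length_range[1L] >= 1L,
            length(morf_length_range) == 2L,
            morf_length_range[1L] <= morf_length_range[2L],
            morf_length_range[1L] >= 1L,
            morfs_per_sequence >= 0L, effect_size >= 0)
  norm_comp <- function(p, what) {
    if (length(p) != 20L || any(p < 0) || sum(p) <= 0)
      stop(what, " must be 20 non-negative values with positive sum",
           call. = FALSE)
    if (!is.null(names(p))) p <- p[AA_ORDER]
    p / sum(p)
  }
  bg <- norm_comp(background_composition, "background_composition")
  if (is.null(morf_composition)) {
    e <- min(effect_size, 1)
    morf_composition <- (1 - e) * bg + e * .MORF_TARGET_COMP
  }
  mc <- norm_comp(morf_composition, "morf_composition")
  structure(list(n_sequences = as.integer(n_sequences),
                 length_range = as.integer(length_range),
                 morf_length_range = as.integer(morf_length_range),
                 morfs_per_sequence = as.integer(morfs_per_sequence),
                 background_composition = stats::setNames(bg, AA_ORDER),
                 morf_composition = stats::setNames(mc, AA_ORDER),
                 effect_size = effect_size, seed = as.integer(seed)),
            class = "synthetic_config")
}

## sample non-overlapping segment starts; prefer keeping segments at
## least `margin` residues from the sequence ends when length permits
.place_segments <- function(L, lens, margin = 10L) {
  lo_all <- rep(1L, length(lens)); hi_all <- L - lens + 1L
  fits_margin <- L >= lens + 2L * margin
  lo_all[fits_margin] <- margin + 1L
  hi_all[fits_margin] <- L - margin - lens[fits_margin] + 1L
  if (any(hi_all < lo_all))
    stop("MoRF segment(s) of length ", paste(lens[hi_all < lo_all], collapse = ","),
         " cannot fit in a sequence of length ", L, call. = FALSE)
  for (attempt in seq_len(200L)) {
    starts <- integer(length(lens))
    for (k in seq_along(lens)) {
      starts[k] <- lo_all[k] + sample.int(hi_all[k] - lo_all[k] + 1L, 1L) - 1L
    }
    ends <- starts + lens - 1L
    o <- order(starts)
    if (all(starts[o][-1L] > ends[o][-length(lens)])) return(starts)
  }
  stop("could not place ", length(lens), " non-overlapping MoRF segment(s) ",
       "in a sequence of length ", L, call. = FALSE)
}

#' Generate a synthetic annotated corpus
#'
#' Draws sequences and planted MoRF segments per the configuration.
#' Reproducible: the same config (including seed) gives a byte-identical
#' corpus; the caller's RNG state is left untouched.
#'
#' @param config a [synthetic_config]
#' @return list with `sequences` (list of [annotated_sequence]) and
#'   `labels` (data.frame seq_id, start, end; 0-based half-open)
#' @export
generate_morf_data <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  lr <- config$length_range; mr <- config$morf_length_range
  seqs <- vector("list", config$n_sequences)
  lab_rows <- list()
  rint <- function(n, a, b) a + sample.int(b - a + 1L, n, replace = TRUE) - 1L
  for (s in seq_len(config$n_sequences)) {
    L <- rint(1L, lr[1L], lr[2L])
    chars <- sample(AA_ORDER, L, replace = TRUE,
                    prob = config$background_composition)
    mask <- integer(L)
    if (config$morfs_per_sequence > 0L) {
      lens <- rint(config$morfs_per_sequence, mr[1L], mr[2L])
      starts <- .place_segments(L, lens)
      for (k in seq_along(lens)) {
        idx <- starts[k]:(starts[k] + lens[k] - 1L)
        chars[idx] <- sample(AA_ORDER, lens[k], replace = TRUE,
                             prob = config$morf_composition)
        mask[idx] <- 1L
      }
      lab_rows[[length(lab_rows) + 1L]] <- data.frame(
        seq_id = sprintf("synth%04d", s),
        start = starts - 1L, end = starts + lens - 1L)
    }
    seqs[[s]] <- annotated_sequence(sprintf("synth%04d", s),
                                    paste(chars, collapse = ""), mask)
  }
  labels <- if (length(lab_rows)) do.call(rbind, lab_rows) else
    data.frame(seq_id = character(), start = integer(), end = integer())
  list(sequences = seqs, labels = labels)
}

#' Mask MoRF regions by length (EXP53-style protocol)
#'
#' Splits evaluation by MoRF length: with `keep = "short"` only MoRF
#' regions of up to `cutoff` residues count as positives and longer
#' regions are flagged as ignored (NA); with `keep = "long"` the
#' complement. Non-MoRF residues stay negative either way.
#'
#' @param sequences list of [annotated_sequence]
#' @param keep `"short"` or `"long"`
#' @param cutoff region-length cutoff (default 30)
#' @return the sequences with masks updated (excluded regions = NA)
#' @export
mask_regions <- function(sequences, keep = c("short", "long"), cutoff = 30L) {
  keep <- match.arg(keep)
  if (cutoff < 1L) stop("cutoff must be >= 1", call. = FALSE)
  lapply(sequences, function(s) {
    iv <- mask_intervals(s$mask)
    if (nrow(iv) == 0L) return(s)
    len <- iv$end - iv$start
    drop <- if (keep == "short") len > cutoff else len <= cutoff
    for (k in which(drop)) s$mask[(iv$start[k] + 1L):iv$end[k]] <- NA_integer_
    s
  })
}
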