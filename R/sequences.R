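#' Annotated protein sequence
#'
#' Couples a protein sequence with a per-residue MoRF mask. Mask values
#' are 1 (MoRF residue), 0 (non-MoRF residue) or NA (ignored in
#' evaluation, e.g. after [mask_regions()]).
#'
#' @param id nonempty sequence identifier
#' @param residues string over the 20-letter amino-acid alphabet plus X
#' @param mask integer vector of length `nchar(residues)` with entries in
#'   \{0, 1, NA\}; defaults to all zero
#' @return object of class `annotated_sequence`
#' @export
annotated_sequence <- function(id, residues, mask = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a nonempty string", call. = FALSE)
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("sequence '", id, "': residues must be a nonempty string", call. = FALSE)
  L <- nchar(residues)
  if (is.null(mask)) mask <- integer(L)
  mask <- as.integer(mask)
  if (length(mask) != L)
    stop("sequence '", id, "': mask length ", length(mask),
         " != sequence length ", L, call. = FALSE)
  if (!all(mask %in% c(0L, 1L, NA_integer_)))
    stop("sequence '", id, "': mask entries must be 0, 1 or NA", call. = FALSE)
  structure(list(id = id, residues = residues, mask = mask),
            class = "annotated_sequence")
}

#' @export
print.annotated_sequence <- function(x, ...) {
  L <- nchar(x$residues)
  cat("<annotated_sequence>", x$id, "-", L, "residues,",
      sum(x$mask == 1L, na.rm = TRUE), "MoRF,",
      sum(is.na(x$mask)), "ignored\n")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Record order is preserved, letters are uppercased, and any letter
#' outside the 20-residue alphabet (B, Z, U, ...) is mapped to X with a
#' warning. The returned masks are all zero; attach labels with
#' [read_labels()].
#'
#' @param path path to a (multi-record) FASTA file
#' @return list of [annotated_sequence] objects
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  aset <- Biostrings::readAAStringSet(path)
  if (length(aset) == 0L)
    stop("FASTA format error: no records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(aset))
  if (any(!nzchar(ids)))
    stop("FASTA format error: record with empty id in ", path, call. = FALSE)
  if (anyDuplicated(ids))
    stop("FASTA format error: duplicate id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(aset))
  if (any(nchar(seqs) == 0L))
    stop("FASTA format error: empty record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  bad_pat <- paste0("[^", paste(AA_ORDER, collapse = ""), "X]")
  has_bad <- grepl(bad_pat, seqs)
  if (any(has_bad)) {
    warning("non-standard residue letters mapped to X in: ",
            paste(ids[has_bad], collapse = ", "), call. = FALSE)
    seqs[has_bad] <- gsub(bad_pat, "X", seqs[has_bad])
  }
  unname(Map(annotated_sequence, ids, seqs))
}

#' Write sequences to a FASTA file
#'
#' @param path output path
#' @param sequences list of [annotated_sequence] objects
#' @export
write_fasta <- function(path, sequences) {
  strings <- vapply(sequences, function(s) s$residues, character(1))
  ids <- vapply(sequences, function(s) s$id, character(1))
  aset <- Biostrings::AAStringSet(stats::setNames(strings, ids))
  Biostrings::writeXStringSet(aset, path)
  invisible(path)
}

#' Read per-residue MoRF interval labels
#'
#' The label file is tab-separated with columns `seq_id`, `start`, `end`
#' in 0-based half-open coordinates (BED-like). Overlapping intervals are
#' unioned. Every `seq_id` must name a sequence in `sequences` and every
#' interval must lie within the sequence.
#'
#' @param path path to the labels TSV
#' @param sequences list of [annotated_sequence] objects
#' @return the sequences, with masks set from the intervals
#' @export
read_labels <- function(path, sequences) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ids <- vapply(sequences, function(s) s$id, character(1))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(sequences)
  lab <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                           col.names = c("seq_id", "start", "end"),
                           colClasses = c("character", "integer", "integer"))
  unknown <- setdiff(unique(lab$seq_id), ids)
  if (length(unknown))
    stop("labels reference unknown sequence id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (r in seq_len(nrow(lab))) {
    k <- match(lab$seq_id[r], ids)
    L <- nchar(sequences[[k]]$residues)
    s0 <- lab$start[r]; e0 <- lab$end[r]
    if (is.na(s0) || is.na(e0) || s0 < 0L || e0 > L || s0 >= e0)
      stop("invalid interval [", s0, ", ", e0, ") for sequence '",
           lab$seq_id[r], "' of length ", L, call. = FALSE)
    sequences[[k]]$mask[(s0 + 1L):e0] <- 1L
  }
  sequences
}

#' Write MoRF interval labels
#'
#' Writes the maximal runs of mask value 1 as 0-based half-open intervals
#' in the tab-separated format read by [read_labels()].
#'
#' @param path output path
#' @param sequences list of [annotated_sequence] objects
#' @export
write_labels <- function(path, sequences) {
  rows <- lapply(sequences, function(s) {
    iv <- mask_intervals(s$mask)
    if (nrow(iv) == 0L) return(NULL)
    data.frame(seq_id = s$id, start = iv$start, end = iv$end)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(seq_id = character(), start = integer(),
                                      end = integer())
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Maximal runs of positive mask values as 0-based half-open intervals
#'
#' @param mask integer vector over \{0, 1, NA\}
#' @return data.frame with columns start, end (0-based half-open)
#' @export
mask_intervals <- function(mask) {
  pos <- !is.na(mask) & mask == 1L
  r <- rle(pos)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  keep <- r$values
  data.frame(start = lo[keep] - 1L, end = hi[keep])
}

#' Write a per-residue score table
#'
#' Tab-separated columns: `seq_id`, 1-based position, residue letter,
#' score (fixed decimal places), and the binary MoRF call
#' `score > threshold`.
#'
#' @param path output path
#' @param sequence an [annotated_sequence]
#' @param scores numeric vector, one score per residue
#' @param threshold decision threshold (default 0)
#' @param digits decimal places for the printed score
#' @export
write_scores <- function(path, sequence, scores, threshold = 0, digits = 6L) {
  L <- nchar(sequence$residues)
  if (length(scores) != L)
    stop("scores length ", length(scores), " != sequence length ", L,
         call. = FALSE)
  tab <- data.frame(
    seq_id = sequence$id,
    pos = seq_len(L),
    residue = strsplit(sequence$residues, "", fixed = TRUE)[[1L]],
    score = sprintf(paste0("%.", digits, "f"), scores),
    call = as.integer(scores > threshold)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-residue score table written by [write_scores()]
#'
#' @param path path to the scores TSV
#' @return data.frame with columns seq_id, pos, residue, score, call
#' @export
read_scores <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "character",
                                   "numeric", "integer"))
}
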