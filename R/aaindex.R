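#' Amino-acid property scale
#'
#' A `property_scale` maps each of the 20 standard amino acids to a real
#' number, addressed by an AAindex-style accession (e.g. `CIDH920101`).
#' Values are stored in the canonical AAindex order
#' `A R N D C Q E G H I L K M F P W Y V S T`.
#'
#' @param accession nonempty accession string, unique within a registry
#' @param values numeric vector of length 20; either unnamed in canonical
#'   order or named by one-letter residue codes
#' @param description free-text description
#' @param allow_na permit missing values (used by the AAindex1 parser;
#'   scales with missing values cannot be used in a feature set)
#' @return an object of class `property_scale`
#' @export
property_scale <- function(accession, values, description = "", allow_na = FALSE) {
  if (!is.character(accession) || length(accession) != 1L || !nzchar(accession))
    stop("'accession' must be a nonempty string", call. = FALSE)
  if (length(values) != 20L)
    stop("scale '", accession, "': expected 20 values, got ", length(values),
         call. = FALSE)
  nms <- names(values)
  values <- stats::setNames(as.numeric(values), nms)   # as.numeric drops names
  if (!is.null(nms)) {
    if (!setequal(nms, AA_ORDER))
      stop("scale '", accession, "': value names must be the 20 residue letters",
           call. = FALSE)
    values <- values[AA_ORDER]
  } else {
    names(values) <- AA_ORDER
  }
  if (!allow_na && !all(is.finite(values)))
    stop("scale '", accession, "': all 20 values must be finite", call. = FALSE)
  structure(
    list(accession = accession, values = values, description = description),
    class = "property_scale"
  )
}

#' @export
print.property_scale <- function(x, ...) {
  cat("<property_scale>", x$accession, "\n")
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  print(round(x$values, 3))
  invisible(x)
}

#' Read an AAindex1 flat file
#'
#' Parses entries in the AAindex1 flat-file format: an `H` accession line,
#' a `D` description line, and an `I` header line followed by two rows of
#' ten values in the order `A R N D C Q E G H I / L K M F P W Y V S T`.
#' Literal `NA` values are retained as missing; such scales are rejected
#' later if referenced by an active feature set.
#'
#' @param path path to an AAindex1-format file
#' @return list of [property_scale] objects, file order preserved
#' @export
read_aaindex1 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//", lines)
  if (length(ends) == 0L) stop("not an AAindex1 file (no // separators): ", path,
                               call. = FALSE)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  scales <- vector("list", length(ends))
  for (k in seq_along(ends)) {
    block <- lines[starts[k]:(ends[k] - 1L)]
    block <- block[nzchar(trimws(block))]
    hline <- grep("^H ", block, value = TRUE)
    acc <- if (length(hline)) trimws(sub("^H ", "", hline[1L])) else
      paste0("<entry ", k, ">")
    dline <- grep("^D ", block, value = TRUE)
    descr <- if (length(dline)) trimws(sub("^D ", "", dline[1L])) else ""
    ipos <- grep("^I ", block)
    if (length(hline) == 0L || length(ipos) == 0L)
      stop("AAindex1 parse error in entry ", acc, ": missing H or I block",
           call. = FALSE)
    vlines <- block[seq.int(ipos[1L] + 1L, length.out = length(block) - ipos[1L])]
    toks <- unlist(strsplit(trimws(paste(vlines, collapse = " ")), "\\s+"))
    if (length(toks) != 20L)
      stop("AAindex1 parse error in entry ", acc, ": expected 20 values, got ",
           length(toks), call. = FALSE)
    vals <- suppressWarnings(as.numeric(ifelse(toks == "NA", NA, toks)))
    if (any(is.na(vals) & toks != "NA"))
      stop("AAindex1 parse error in entry ", acc, ": non-numeric value",
           call. = FALSE)
    scales[[k]] <- property_scale(acc, vals, descr, allow_na = TRUE)
  }
  scales
}

#' Build a scale registry
#'
#' A registry is a named list of [property_scale] objects keyed by
#' accession; accessions must be unique.
#'
#' @param scales list of [property_scale] objects
#' @return named list of class `scale_registry`
#' @export
scale_registry <- function(scales) {
  if (inherits(scales, "property_scale")) scales <- list(scales)
  acc <- vapply(scales, function(s) s$accession, character(1))
  if (anyDuplicated(acc))
    stop("duplicate accession(s) in registry: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  structure(stats::setNames(scales, acc), class = "scale_registry")
}

#' Default scale registry
#'
#' The 13 AAindex physicochemical scales of the default feature set plus
#' the synthetic stand-ins for the GlobPlot Remark 465, Deleage/Roux and
#' B-factor(2STD) disorder propensities, loaded from the AAindex1 fixture
#' files shipped with the package.
#'
#' @return a `scale_registry` with 16 scales
#' @export
default_scale_registry <- function() {
  if (is.null(.pkg_env$default_registry)) {
    f13 <- system.file("extdata", "aaindex_morf13.aaindex1", package = "morfmpm",
                       mustWork = TRUE)
    fgp <- system.file("extdata", "globplot_synthetic.aaindex1",
                       package = "morfmpm", mustWork = TRUE)
    .pkg_env$default_registry <- scale_registry(c(read_aaindex1(f13),
                                                  read_aaindex1(fgp)))
  }
  .pkg_env$default_registry
}

#' Full AAindex pool
#'
#' The 544-scale AAindex1 pool (as bundled with the seqinr package) as a
#' `scale_registry`, for running feature selection against the full
#' database. Scales with missing values are retained but cannot enter a
#' feature set.
#'
#' @return a `scale_registry` with 544 scales
#' @export
aaindex_pool <- function() {
  if (!requireNamespace("seqinr", quietly = TRUE))
    stop("aaindex_pool() needs the 'seqinr' package", call. = FALSE)
  aaindex <- NULL
  utils::data("aaindex", package = "seqinr", envir = environment())
  seqinr_letters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  scale_registry(lapply(aaindex, function(e) {
    v <- stats::setNames(unname(e$I), seqinr_letters)
    property_scale(e$H, v, e$D, allow_na = TRUE)
  }))
}
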