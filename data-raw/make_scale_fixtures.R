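# Regenerates the AAindex1-format scale fixtures under inst/extdata/.
#
# aaindex_morf13.aaindex1: the 13 AAindex physicochemical scales of the
# default feature set, exported from the AAindex1 database as bundled with
# seqinr (release with 544 entries). Values are reordered from seqinr's
# alphabetical (3-letter) order to the canonical AAindex1 flat-file order
# A R N D C Q E G H I / L K M F P W Y V S T.
#
# globplot_synthetic.aaindex1: SYNTHETIC stand-ins for the GlobPlot
# Remark 465, Deleage/Roux and B-factor(2STD) disorder propensities. The
# published tables are not redistributed here; these values encode the
# usual disorder-promoting (P E S Q K G D A) vs order-promoting
# (W C F I Y V L M H) residue ranking and exist only so the pipeline is
# self-contained. Nothing in the package or tests depends on their values.

library(seqinr)
data(aaindex)

# seqinr order -> canonical AAindex1 flat-file order
seqinr_letters <- c("A","R","N","D","C","Q","E","G","H","I",
                    "L","K","M","F","P","S","T","W","Y","V")
canon <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","W","Y","V","S","T")
reord <- match(canon, seqinr_letters)

fmt_entry <- function(accession, description, values) {
  stopifnot(length(values) == 20, !anyNA(values))
  row1 <- paste(sprintf("%8.3f", values[1:10]), collapse = "")
  row2 <- paste(sprintf("%8.3f", values[11:20]), collapse = "")
  c(paste("H", accession),
    paste("D", description),
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    row1, row2, "//")
}

table2 <- c("CIDH920101", "EISD860103", "NISK860101", "QIAN880105",
            "ROBB760101", "ROBB760108", "ROBB760112", "ROBB760113",
            "CORJ870103", "CORJ870106", "CORJ870107", "CORJ870108",
            "MIYS990104")

lines13 <- unlist(lapply(table2, function(a) {
  e <- aaindex[[a]]
  fmt_entry(a, e$D, unname(e$I)[reord])
}))
writeLines(lines13, "inst/extdata/aaindex_morf13.aaindex1")

# synthetic propensities, canonical order A R N D C Q E G H I L K M F P W Y V S T
syn <- list(
  SYNR465101 = list(
    d = "SYNTHETIC stand-in for GlobPlot Remark 465 disorder propensity (constructed values)",
    v = c(0.06, 0.18, 0.01, 0.19, -0.60, 0.32, 0.30, 0.17, -0.30, -0.49,
          -0.33, 0.22, -0.23, -0.44, 0.55, -0.88, -0.51, -0.42, 0.14, 0.06)),
  SYNDLRX101 = list(
    d = "SYNTHETIC stand-in for GlobPlot Deleage/Roux coil-vs-structure propensity (constructed values)",
    v = c(-0.28, -0.10, 0.25, 0.22, -0.02, -0.21, -0.33, 0.55, -0.12, -0.35,
          -0.38, -0.18, -0.30, -0.32, 0.52, -0.27, 0.05, -0.35, 0.34, 0.12)),
  SYNBF2S101 = list(
    d = "SYNTHETIC stand-in for GlobPlot B-factor(2STD) flexibility propensity (constructed values)",
    v = c(-0.12, 0.18, 0.16, 0.25, -0.63, 0.30, 0.45, 0.28, -0.08, -0.48,
          -0.38, 0.40, -0.31, -0.55, 0.32, -0.60, -0.35, -0.45, 0.22, 0.05))
)
linesyn <- unlist(lapply(names(syn), function(a) fmt_entry(a, syn[[a]]$d, syn[[a]]$v)))
writeLines(linesyn, "inst/extdata/globplot_synthetic.aaindex1")
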