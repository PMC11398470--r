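#' Directional collapse of sequencing-error barcode variants
#'
#' Builds the directional error network over equal-length sequences: a
#' directed edge `a -> b` exists when `Hamming(a, b) <= maxDist` and
#' `reads(a) >= 2 * reads(b) - 1`. Each sequence is absorbed into the root
#' of its best absorber (highest read count, then lexicographically
#' smallest sequence), processing nodes in decreasing-count order so
#' absorption chains resolve deterministically. `maxDist = 0` returns the
#' identity map. Neighbour candidates are found with exact-match buckets
#' over `maxDist + 1` disjoint sequence segments, so results equal the
#' all-pairs construction at near-linear cost.
#'
#' @param barcodes character vector of equal-length sequences.
#' @param reads read count per sequence (summed over UMIs).
#' @param maxDist maximum Hamming distance for an edge.
#' @param method collapse rule; only `"directional"` is implemented.
#' @return Named character vector mapping each input sequence to its
#'   canonical sequence (idempotent: canonical sequences map to
#'   themselves).
#' @examples
#' collapseBarcodes(c("AAAA", "AAAT"), reads = c(100, 1))
#' @export
collapseBarcodes <- function(barcodes, reads, maxDist = 1L,
                             method = "directional") {
  method <- match.arg(method, "directional")
  stopifnot(length(barcodes) == length(reads), maxDist >= 0L)
  if (anyDuplicated(barcodes)) stop("barcodes must be unique")
  if (length(barcodes) == 0L)
    return(setNames(character(0), character(0)))
  idx <- .cpp_directional_collapse(barcodes, as.numeric(reads),
                                   as.integer(maxDist))
  setNames(barcodes[idx], barcodes)
}

#' Deduplicate UMIs to a molecule count
#'
#' Applies the same directional criterion as [collapseBarcodes()] to the
#' UMIs observed for one barcode and returns the number of canonical UMIs —
#' the molecule count. With `maxDist = 0` this is the number of distinct
#' UMIs; the empty input gives 0.
#'
#' @param umiReads named integer vector: read count per distinct UMI.
#' @param maxDist maximum Hamming distance for an edge.
#' @return Integer molecule count.
#' @examples
#' dedupUmis(c(AAAAATTTTT = 5, AAAAATTTTG = 1))
#' @export
dedupUmis <- function(umiReads, maxDist = 1L) {
  stopifnot(maxDist >= 0L)
  if (length(umiReads) == 0L) return(0L)
  umis <- names(umiReads)
  if (is.null(umis)) stop("umiReads must be named by UMI sequence")
  map <- collapseBarcodes(umis, as.numeric(umiReads), maxDist = maxDist)
  length(unique(map))
}

#' Collapse barcodes and deduplicate UMIs to molecule counts
#'
#' The per-library counting step: collapses error-variant barcodes with
#' [collapseBarcodes()], merges the UMI tables of absorbed barcodes
#' (summing read counts of identical UMIs), then deduplicates UMIs per
#' canonical barcode with [dedupUmis()]. Read counts are conserved by the
#' collapse, and for every canonical barcode
#' `molecules <= distinct UMIs <= reads`.
#'
#' @param tags per-(barcode, UMI) read counts from [tagCounts()], or any
#'   data frame with columns `barcode`, `umi`, `reads`.
#' @param bcMaxDist,umiMaxDist Hamming-distance thresholds for the barcode
#'   and UMI networks.
#' @return A [S4Vectors::DataFrame] with one row per canonical barcode:
#'   `barcode`, `molecules`, `reads` (total absorbed reads), sorted by
#'   barcode. Metadata carries over from `tags` plus the `collapse_map`.
#' @examples
#' tc <- DataFrame(barcode = rep(strrep("A", 25), 2),
#'                 umi = c("AAAAAAAAAA", "CCCCCCCCCC"), reads = c(2L, 1L))
#' countMolecules(tc)
#' @export
countMolecules <- function(tags, bcMaxDist = 1L, umiMaxDist = 1L) {
  stopifnot(all(c("barcode", "umi", "reads") %in% colnames(tags)))
  if (nrow(tags) == 0L) {
    out <- DataFrame(barcode = character(0), molecules = integer(0),
                     reads = integer(0))
    if (is(tags, "Annotated")) metadata(out) <- metadata(tags)
    return(out)
  }
  bc_reads <- tapply(as.numeric(tags$reads), tags$barcode, sum)
  map <- collapseBarcodes(names(bc_reads), as.numeric(bc_reads),
                          maxDist = bcMaxDist)
  canon <- unname(map[tags$barcode])
  # merge UMI tables of absorbed barcodes, summing identical UMIs
  key <- paste(canon, tags$umi, sep = "\t")
  merged_reads <- tapply(as.numeric(tags$reads), key, sum)
  nm <- names(merged_reads)
  mdf <- data.frame(barcode = sub("\t.*$", "", nm),
                    umi = sub("^.*\t", "", nm),
                    reads = as.numeric(merged_reads),
                    stringsAsFactors = FALSE)
  mols <- vapply(split(setNames(mdf$reads, mdf$umi), mdf$barcode),
                 dedupUmis, integer(1), maxDist = umiMaxDist)
  total_reads <- tapply(mdf$reads, mdf$barcode, sum)
  bcs <- sort(names(mols))
  out <- DataFrame(barcode = bcs, molecules = as.integer(mols[bcs]),
                   reads = as.integer(total_reads[bcs]))
  rownames(out) <- NULL
  md <- if (is(tags, "Annotated")) metadata(tags) else list()
  md$collapse_map <- map
  metadata(out) <- md
  out
}
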