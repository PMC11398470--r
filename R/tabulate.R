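#' Tabulate per-library molecule counts into a barcode count matrix
#'
#' Takes the union of barcodes across libraries (a barcode absent from a
#' library gets 0) and assembles a [BarcodeCountMatrix-class] whose columns
#' follow the sample manifest. Rows are sorted lexicographically by
#' barcode; column names are `sample_id.channel`.
#'
#' @param countsList named list of per-library counts — each element the
#'   output of [countMolecules()] (or any data frame with `barcode` and
#'   `molecules`) — with names `sample_id.channel` matching the manifest,
#'   or in manifest row order if unnamed.
#' @param manifest data frame with columns `sample_id`, `condition`,
#'   `replicate`, `channel` (one row per library).
#' @return A [BarcodeCountMatrix-class].
#' @examples
#' man <- data.frame(sample_id = "s1", condition = "a", replicate = 1,
#'                   channel = "red")
#' cl <- list(s1.red = DataFrame(barcode = "AAA", molecules = 5L))
#' tabulateCounts(cl, man)
#' @export
tabulateCounts <- function(countsList, manifest) {
  .check_manifest(manifest)
  keys <- .lib_key(manifest$sample_id, manifest$channel)
  if (is.null(names(countsList))) {
    if (length(countsList) != nrow(manifest))
      stop("unnamed countsList must have one element per manifest row")
    names(countsList) <- keys
  }
  missing <- setdiff(keys, names(countsList))
  if (length(missing))
    stop("no counts for manifest libraries: ",
         paste(missing, collapse = ", "))
  barcodes <- sort(unique(unlist(
    lapply(countsList[keys], function(x) x$barcode), use.names = FALSE)))
  m <- matrix(0L, nrow = length(barcodes), ncol = length(keys),
              dimnames = list(barcodes, keys))
  for (k in keys) {
    x <- countsList[[k]]
    if (nrow(x) > 0L) m[x$barcode, k] <- as.integer(x$molecules)
  }
  cd <- DataFrame(sample_id = as.character(manifest$sample_id),
                  condition = as.character(manifest$condition),
                  replicate = as.character(manifest$replicate),
                  channel = as.character(manifest$channel),
                  row.names = keys)
  new("BarcodeCountMatrix",
      SummarizedExperiment(assays = list(counts = m), colData = cd))
}

#' Discard low-abundance barcodes
#'
#' Retains exactly the rows whose arithmetic mean count across all columns
#' (both channels, all samples) is at least `minMean`; a row with mean
#' exactly `minMean` is kept. The default of 32 molecules reproduces the
#' screen-processing rule that barcodes averaging fewer than 32 counts
#' across samples are dropped. The operation is idempotent. Column sums of
#' the removed rows are recorded in `metadata()$filtered_colsums` for the
#' conservation ledger.
#'
#' @param x a [BarcodeCountMatrix-class].
#' @param minMean minimum row mean (molecules).
#' @return The filtered [BarcodeCountMatrix-class].
#' @examples
#' man <- data.frame(sample_id = "s1", condition = "a", replicate = 1,
#'                   channel = "red")
#' m <- tabulateCounts(list(s1.red = DataFrame(barcode = c("AAA", "CCC"),
#'   molecules = c(40L, 2L))), man)
#' filterLowAbundance(m)
#' @export
filterLowAbundance <- function(x, minMean = 32) {
  stopifnot(is(x, "BarcodeCountMatrix"), minMean >= 0)
  m <- assay(x, "counts")
  keep <- rowMeans(m) >= minMean
  out <- x[keep, ]
  md <- metadata(x)
  md$filtered_n <- sum(!keep) + (md$filtered_n %||% 0L)
  base <- md$filtered_colsums %||% setNames(numeric(ncol(m)), colnames(m))
  md$filtered_colsums <- base + colSums(m[!keep, , drop = FALSE])
  metadata(out) <- md
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Annotate barcodes with their constructs
#'
#' Joins each barcode row to the lookup table, adding `construct_id`,
#' `channel` (the lookup channel), `pair`, and `negative_control` to the
#' row data. Barcodes absent from the lookup keep `NA` annotation and are
#' listed in `metadata()$unmatched` (with their column sums for the
#' conservation ledger). Rows whose lookup channel conflicts with the
#' library channel of every nonzero column are flagged `channel_conflict`.
#'
#' @param x a [BarcodeCountMatrix-class].
#' @param lookup a [LookupTable-class].
#' @return `x` with annotated row data.
#' @examples
#' ## see vignette for a worked pipeline
#' @export
matchToConstructs <- function(x, lookup) {
  stopifnot(is(x, "BarcodeCountMatrix"), is(lookup, "LookupTable"))
  idx <- barcodeIndex(lookup)
  hit <- match(rownames(x), idx$barcode)
  rd <- rowData(x)
  rd$construct_id <- idx$construct_id[hit]
  rd$channel <- idx$channel[hit]
  rd$pair <- idx$pair[hit]
  rd$negative_control <- idx$negative_control[hit]

  m <- assay(x, "counts")
  lib_channel <- colData(x)$channel
  conflict <- logical(nrow(x))
  matched <- !is.na(hit)
  if (any(matched)) {
    nz_red <- rowSums(m[, lib_channel == "red", drop = FALSE] > 0) > 0
    nz_ir <- rowSums(m[, lib_channel == "ir", drop = FALSE] > 0) > 0
    any_nz <- nz_red | nz_ir
    same <- ifelse(rd$channel == "red", nz_red, nz_ir)
    conflict <- matched & any_nz & !same
  }
  rd$channel_conflict <- conflict
  rowData(x) <- rd

  md <- metadata(x)
  md$unmatched <- rownames(x)[!matched]
  md$unmatched_colsums <- colSums(m[!matched, , drop = FALSE])
  metadata(x) <- md
  x
}

#' Aggregate barcode counts per construct
#'
#' Sums molecule counts over each construct's member barcodes, separately
#' per channel, producing a [ConstructCountMatrix-class] with rows
#' `(construct_id, channel)`. Unannotated rows (see [matchToConstructs()])
#' are excluded. `barcode_n` records the contributing barcodes per row;
#' constructs observed in only one channel are flagged `single_channel`.
#'
#' @param x an annotated [BarcodeCountMatrix-class].
#' @return A [ConstructCountMatrix-class].
#' @examples
#' ## see vignette for a worked pipeline
#' @export
aggregateByConstruct <- function(x) {
  stopifnot(is(x, "BarcodeCountMatrix"))
  rd <- rowData(x)
  if (!"construct_id" %in% colnames(rd))
    stop("run matchToConstructs() first")
  keep <- !is.na(rd$construct_id)
  m <- assay(x, "counts")[keep, , drop = FALSE]
  rd <- rd[keep, , drop = FALSE]
  grp <- paste(rd$construct_id, rd$channel, sep = "\t")
  agg <- rowsum(m, grp)
  parts <- do.call(rbind, strsplit(rownames(agg), "\t", fixed = TRUE))
  barcode_n <- as.integer(table(grp)[rownames(agg)])
  nc <- tapply(rd$negative_control, grp, any)[rownames(agg)]
  n_chan <- table(parts[, 1L])
  rowdat <- DataFrame(
    construct_id = parts[, 1L], channel = parts[, 2L],
    barcode_n = barcode_n, negative_control = unname(nc),
    single_channel = unname(n_chan[parts[, 1L]] == 1L))
  rownames(agg) <- .lib_key(parts[, 1L], parts[, 2L])
  out <- new("ConstructCountMatrix",
             SummarizedExperiment(assays = list(counts = agg),
                                  colData = colData(x),
                                  rowData = rowdat))
  metadata(out) <- metadata(x)
  out
}

#' Reshape a construct matrix to one row per construct
#'
#' For reporter-channel contrasts the unit of analysis is the construct
#' (or barcode pair) with counts from both channels: column
#' `(sample, red)` takes the construct's red-channel sum, `(sample, ir)`
#' its ir-channel sum. Constructs present in only one channel are dropped
#' (a channel ratio is undefined for them) and reported in
#' `metadata()$single_channel`.
#'
#' @param x a [ConstructCountMatrix-class].
#' @return A [SummarizedExperiment::SummarizedExperiment] with one row per
#'   construct; row data carries `barcode_n` (total) and
#'   `negative_control`.
#' @examples
#' ## see vignette for a worked pipeline
#' @export
channelPairMatrix <- function(x) {
  stopifnot(is(x, "ConstructCountMatrix"))
  rd <- rowData(x)
  m <- assay(x, "counts")
  lib_channel <- colData(x)$channel
  both <- names(which(table(unique(
    data.frame(c = rd$construct_id, ch = rd$channel))$c) == 2L))
  constructs <- sort(intersect(unique(rd$construct_id), both))
  dropped <- setdiff(unique(rd$construct_id), constructs)
  out <- matrix(0, nrow = length(constructs), ncol = ncol(m),
                dimnames = list(constructs, colnames(m)))
  for (ch in c("red", "ir")) {
    rows <- which(rd$channel == ch & rd$construct_id %in% constructs)
    cols <- which(lib_channel == ch)
    out[rd$construct_id[rows], cols] <- m[rows, cols, drop = FALSE]
  }
  first <- match(constructs, rd$construct_id)
  bn <- tapply(rd$barcode_n, rd$construct_id, sum)
  rowdat <- DataFrame(construct_id = constructs,
                      barcode_n = as.integer(bn[constructs]),
                      negative_control = rd$negative_control[first])
  se <- SummarizedExperiment(assays = list(counts = out),
                             colData = colData(x), rowData = rowdat)
  metadata(se) <- c(metadata(x), list(single_channel = dropped))
  se
}

#' Reshape an annotated barcode matrix to one row per barcode pair
#'
#' The barcode-pair analogue of [channelPairMatrix()]: each row is a
#' (bc_red, bc_ir) pair from the lookup, red-channel columns carrying the
#' red barcode's counts and ir columns the ir barcode's. Pairs with only
#' one member barcode present are dropped and reported.
#'
#' @param x an annotated [BarcodeCountMatrix-class].
#' @return A [SummarizedExperiment::SummarizedExperiment] with one row per
#'   pair; row data carries `pair`, `construct_id`, `negative_control`.
#' @examples
#' ## see vignette for a worked pipeline
#' @export
barcodePairMatrix <- function(x) {
  stopifnot(is(x, "BarcodeCountMatrix"))
  rd <- rowData(x)
  if (!"pair" %in% colnames(rd)) stop("run matchToConstructs() first")
  keep <- !is.na(rd$pair)
  m <- assay(x, "counts")[keep, , drop = FALSE]
  rd <- rd[keep, , drop = FALSE]
  cnt <- table(rd$pair)
  pairs <- sort(names(cnt)[cnt == 2L])
  dropped <- setdiff(unique(rd$pair), pairs)
  lib_channel <- colData(x)$channel
  out <- matrix(0, nrow = length(pairs), ncol = ncol(m),
                dimnames = list(pairs, colnames(m)))
  for (ch in c("red", "ir")) {
    rows <- which(rd$channel == ch & rd$pair %in% pairs)
    cols <- which(lib_channel == ch)
    out[rd$pair[rows], cols] <- m[rows, cols, drop = FALSE]
  }
  first <- match(pairs, rd$pair)
  rowdat <- DataFrame(pair = pairs, construct_id = rd$construct_id[first],
                      negative_control = rd$negative_control[first])
  se <- SummarizedExperiment(assays = list(counts = out),
                             colData = colData(x), rowData = rowdat)
  metadata(se) <- c(metadata(x), list(single_member_pairs = dropped))
  se
}
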