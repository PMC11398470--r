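#' Parse long reads of the barcoded plasmid library
#'
#' Locates the anchor pairs of `layout` in each read by leftmost-best
#' Hamming-distance scan (at most `max_anchor_mismatch` substitutions per
#' anchor), trying the forward orientation first and then the reverse
#' complement, and extracts the two reporter barcodes and the dual-sgRNA
#' cassette. The cassette is canonicalized to a guide key
#' `protospacerA|protospacerB` (uppercase, cassette order) when its length
#' equals twice `guide_len`; otherwise the raw cassette is used as the key.
#'
#' @param reads character vector of read sequences, a
#'   [Biostrings::DNAStringSet], or a FASTQ(.gz) path.
#' @param layout a [LongReadLayout-class].
#' @return A [S4Vectors::DataFrame] with one row per read: `bc_red`,
#'   `bc_ir`, `guide_key`, `orientation` (`"forward"` or
#'   `"reverse-complement"`) and `reason` — `NA` for parsed reads, else one
#'   of `"anchor_missing"`, `"length_mismatch"`, `"ambiguous_base"`.
#' @examples
#' lay <- longReadLayout()
#' seq <- paste0(lay@anchor_up_red, strrep("A", 25), lay@anchor_down_red,
#'               lay@anchor_guide_up, strrep("G", 40), lay@anchor_guide_down,
#'               lay@anchor_up_ir, strrep("C", 25), lay@anchor_down_ir)
#' parseLongReads(seq, lay)
#' @export
parseLongReads <- function(reads, layout = longReadLayout()) {
  stopifnot(is(layout, "LongReadLayout"))
  validObject(layout)
  seqs <- .as_read_seqs(reads)
  res <- .cpp_parse_long_reads(
    seqs, layout@anchor_up_red, layout@anchor_down_red,
    layout@anchor_up_ir, layout@anchor_down_ir,
    layout@anchor_guide_up, layout@anchor_guide_down,
    layout@barcode_len, layout@max_anchor_mismatch)
  guide_key <- .canonical_guide_key(res$cassette, layout@guide_len)
  DataFrame(bc_red = res$bc_red, bc_ir = res$bc_ir, guide_key = guide_key,
            orientation = res$orientation, reason = res$reason)
}

.canonical_guide_key <- function(cassette, guide_len) {
  key <- toupper(cassette)
  two <- !is.na(key) & nchar(key) == 2L * guide_len
  key[two] <- paste0(substr(key[two], 1L, guide_len), "|",
                     substr(key[two], guide_len + 1L, 2L * guide_len))
  key
}

#' Build the barcode-to-sgRNA lookup table
#'
#' Groups parsed reads by exact (bc_red, bc_ir) barcode-pair identity,
#' assigns each pair the majority guide key, and emits a link when the pair
#' has at least `minSupport` reads of which a fraction of at least
#' `minPurity` agree with the majority. After assembly, any barcode string
#' occurring in more than one link (collision or chimera) removes all links
#' involving it. Removed pairs are recorded with a category of
#' `"low_support"`, `"low_purity"` or `"barcode_collision"` and are
#' available through [discardReport()].
#'
#' Construct identifiers are assigned deterministically: unique guide keys
#' are sorted and numbered `C000001`, `C000002`, ... Error-containing
#' barcode reads are expected to fail the support/purity thresholds rather
#' than be corrected; with 25-nt random barcodes, near-collisions are
#' negligible.
#'
#' Sequencing errors inside the guide cassette would otherwise make every
#' error-bearing read a distinct minority key and depress purity in
#' proportion to the per-read error rate. Before voting, observed guide
#' keys are therefore collapsed over their global read counts with the
#' same directional error-network rule used for barcodes
#' ([collapseBarcodes()]), with Hamming tolerance `guideKeyDist`: a true
#' cassette key recurs across all of its construct's barcode pairs while
#' an error key is nearly always a global singleton. Cassettes of
#' different constructs differ at many positions, so genuine chimeras are
#' never absorbed and still fail the purity threshold.
#'
#' @param parsed output of [parseLongReads()] (unparsed rows are ignored).
#' @param minSupport minimum supporting reads per barcode pair.
#' @param minPurity minimum majority fraction, in (0.5, 1].
#' @param guideKeyDist Hamming tolerance for merging error-variant guide
#'   keys within a pair (same-length keys only; 0 disables merging).
#' @param nontargetingKeys optional guide keys of non-targeting controls;
#'   matching entries are flagged `negative_control`.
#' @return A [LookupTable-class].
#' @examples
#' p <- DataFrame(bc_red = rep(strrep("A", 25), 3),
#'                bc_ir = rep(strrep("C", 25), 3),
#'                guide_key = rep("G1", 3),
#'                orientation = "forward", reason = NA_character_)
#' buildLookup(p, minSupport = 3)
#' @export
buildLookup <- function(parsed, minSupport = 3L, minPurity = 0.9,
                        guideKeyDist = 3L,
                        nontargetingKeys = character(0)) {
  stopifnot(minSupport >= 1L, minPurity > 0.5, minPurity <= 1,
            guideKeyDist >= 0L)
  ok <- is.na(parsed$reason)
  df <- as.data.frame(parsed[ok, c("bc_red", "bc_ir", "guide_key")])
  empty <- DataFrame(bc_red = character(0), bc_ir = character(0),
                     category = character(0), support = integer(0),
                     purity = numeric(0))
  if (nrow(df) == 0L) {
    return(new("LookupTable",
               entries = DataFrame(construct_id = character(0),
                                   guide_key = character(0),
                                   bc_red = character(0),
                                   bc_ir = character(0),
                                   support = integer(0),
                                   purity = numeric(0),
                                   negative_control = logical(0)),
               discards = empty))
  }

  pair <- paste(df$bc_red, df$bc_ir, sep = "\t")
  # majority vote per pair, via sparse (pair, guide) combination counts
  comb <- table(paste(pair, df$guide_key, sep = "\r"))
  parts <- strsplit(names(comb), "\r", fixed = TRUE)
  pair_c <- vapply(parts, `[`, "", 1L)
  guide_c <- vapply(parts, `[`, "", 2L)
  n <- as.integer(comb)
  if (guideKeyDist > 0L) {
    merged <- .merge_guide_keys(pair_c, guide_c, n, guideKeyDist)
    pair_c <- merged$pair
    guide_c <- merged$guide
    n <- merged$n
  }
  support_by_pair <- tapply(n, pair_c, sum)
  ord <- order(pair_c, -n, guide_c)  # majority; ties to smaller guide key
  top <- ord[!duplicated(pair_c[ord])]
  pr <- do.call(rbind, strsplit(pair_c[top], "\t", fixed = TRUE))
  support <- as.integer(support_by_pair[pair_c[top]])
  links <- data.frame(bc_red = pr[, 1L], bc_ir = pr[, 2L],
                      guide_key = guide_c[top], support = support,
                      purity = n[top] / support,
                      stringsAsFactors = FALSE)

  keep <- links$support >= minSupport & links$purity >= minPurity
  category <- rep(NA_character_, nrow(links))
  category[links$support < minSupport] <- "low_support"
  category[links$support >= minSupport &
             links$purity < minPurity] <- "low_purity"

  kept <- links[keep, , drop = FALSE]
  bcs <- c(kept$bc_red, kept$bc_ir)
  dup <- unique(bcs[duplicated(bcs)])
  collides <- kept$bc_red %in% dup | kept$bc_ir %in% dup
  category[keep][collides] <- "barcode_collision"
  keep[keep] <- !collides
  kept <- links[keep, , drop = FALSE]

  discards <- links[!keep, , drop = FALSE]
  discards <- DataFrame(bc_red = discards$bc_red, bc_ir = discards$bc_ir,
                        category = category[!keep],
                        support = discards$support,
                        purity = discards$purity)

  keys <- sort(unique(kept$guide_key))
  cid <- setNames(sprintf("C%06d", seq_along(keys)), keys)
  ord <- order(kept$guide_key, kept$bc_red)
  kept <- kept[ord, , drop = FALSE]
  entries <- DataFrame(
    construct_id = unname(cid[kept$guide_key]),
    guide_key = kept$guide_key, bc_red = kept$bc_red, bc_ir = kept$bc_ir,
    support = kept$support, purity = kept$purity,
    negative_control = kept$guide_key %in% nontargetingKeys)
  rownames(entries) <- NULL
  new("LookupTable", entries = entries, discards = discards)
}

# Absorb error-variant guide keys into their source key by directional
# collapse over GLOBAL key read counts: a true cassette key recurs across
# all of its construct's barcode pairs, an error key is (nearly) a global
# singleton, so absorption is overwhelmingly into the true key. Keys of
# unequal length never merge.
.merge_guide_keys <- function(pair_c, guide_c, n, dist) {
  glob <- tapply(n, guide_c, sum)
  canon <- setNames(names(glob), names(glob))
  for (len in unique(nchar(names(glob)))) {
    keys <- names(glob)[nchar(names(glob)) == len]
    if (length(keys) < 2L) next
    idx <- .cpp_directional_collapse(keys, as.numeric(glob[keys]),
                                     as.integer(dist))
    canon[keys] <- keys[idx]
  }
  guide_new <- unname(canon[guide_c])
  key2 <- paste(pair_c, guide_new, sep = "\r")
  n2 <- tapply(n, key2, sum)
  parts <- strsplit(names(n2), "\r", fixed = TRUE)
  list(pair = vapply(parts, `[`, "", 1L),
       guide = vapply(parts, `[`, "", 2L),
       n = as.integer(n2))
}

#' Access lookup-table contents
#'
#' `lookupEntries()` returns the link table (one row per barcode pair);
#' `discardReport()` the pairs removed during [buildLookup()];
#' `barcodeIndex()` the flat barcode index, one row per barcode with its
#' construct, channel and pair key.
#'
#' @param x a [LookupTable-class].
#' @return A [S4Vectors::DataFrame].
#' @examples
#' lookupEntries(buildLookup(DataFrame(bc_red = character(0),
#'   bc_ir = character(0), guide_key = character(0),
#'   orientation = character(0), reason = character(0))))
#' @export
lookupEntries <- function(x) {
  stopifnot(is(x, "LookupTable"))
  x@entries
}

#' @rdname lookupEntries
#' @export
discardReport <- function(x) {
  stopifnot(is(x, "LookupTable"))
  x@discards
}

#' @rdname lookupEntries
#' @export
barcodeIndex <- function(x) {
  e <- lookupEntries(x)
  nc <- if ("negative_control" %in% colnames(e)) e$negative_control
        else rep(FALSE, nrow(e))
  DataFrame(
    barcode = c(e$bc_red, e$bc_ir),
    construct_id = rep(e$construct_id, 2L),
    channel = rep(c("red", "ir"), each = nrow(e)),
    pair = rep(.pair_key(e$bc_red, e$bc_ir), 2L),
    negative_control = rep(nc, 2L))
}

#' Write and read a lookup table as TSV
#'
#' Columns: `construct_id`, `guide_key`, `bc_red`, `bc_ir`, `support`,
#' `purity`, `negative_control`. The round trip
#' `readLookup(writeLookup(x, p))` reproduces `x`'s entries exactly
#' (purity is written at full precision). Files with a wrong column set or
#' a barcode appearing in more than one row are rejected with an error
#' naming the offending line.
#'
#' @param x a [LookupTable-class].
#' @param path output TSV path.
#' @return `writeLookup()` returns `path` invisibly; `readLookup()` a
#'   [LookupTable-class] (with an empty discard report).
#' @examples
#' tab <- buildLookup(DataFrame(bc_red = rep(strrep("A", 25), 3),
#'   bc_ir = rep(strrep("C", 25), 3), guide_key = "G1",
#'   orientation = "forward", reason = NA_character_))
#' p <- tempfile(fileext = ".tsv")
#' writeLookup(tab, p)
#' readLookup(p)
#' @export
writeLookup <- function(x, path) {
  stopifnot(is(x, "LookupTable"))
  e <- as.data.frame(lookupEntries(x))
  if (!"negative_control" %in% colnames(e))
    e$negative_control <- rep(FALSE, nrow(e))
  e$purity <- sprintf("%.17g", e$purity)
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLookup
#' @export
readLookup <- function(path) {
  need <- c("construct_id", "guide_key", "bc_red", "bc_ir", "support",
            "purity", "negative_control")
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (!identical(header, need))
    stop("lookup file must have columns: ", paste(need, collapse = ", "))
  e <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(construct_id = "character",
                                 guide_key = "character",
                                 bc_red = "character", bc_ir = "character",
                                 support = "integer", purity = "numeric",
                                 negative_control = "logical"))
  bcs <- c(e$bc_red, e$bc_ir)
  if (anyDuplicated(bcs)) {
    bad <- bcs[duplicated(bcs)][1L]
    line <- which(e$bc_red == bad | e$bc_ir == bad)[2L] + 1L
    stop("barcode ", bad, " appears in more than one row (line ", line, ")")
  }
  new("LookupTable",
      entries = DataFrame(e),
      discards = DataFrame(bc_red = character(0), bc_ir = character(0),
                           category = character(0), support = integer(0),
                           purity = numeric(0)))
}
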