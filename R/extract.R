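#' Extract barcode/UMI tags from amplicon reads
#'
#' Takes the UMI from the fixed 5' positions of each read, locates the
#' layout anchor by leftmost-best Hamming scan downstream of the UMI, and
#' excises the barcode according to the layout's offset policy. Reads
#' failing any step are tallied by reason (`"too_short"`,
#' `"anchor_missing"`, `"ambiguous_base"` — the last covers `N` inside the
#' UMI or barcode). Base qualities are ignored: molecule counting is made
#' robust downstream by UMI deduplication and barcode collapse.
#'
#' Extraction is deterministic and order-preserving, and conserves reads:
#' `nrow(tags) + sum(rejects) == number of input reads`.
#'
#' @param reads character vector, [Biostrings::DNAStringSet], or FASTQ(.gz)
#'   path.
#' @param layout a [ShortReadLayout-class].
#' @param sample_id,channel library identity recorded in the result's
#'   metadata (from the sample manifest; channel is per amplicon library).
#' @return A [S4Vectors::DataFrame] with columns `barcode` and `umi`, one
#'   row per successfully extracted read. `metadata()` carries `sample_id`,
#'   `channel`, `n_reads` and `rejects` (named integer vector by reason).
#' @examples
#' lay <- shortReadLayout()
#' read <- paste0(strrep("T", 10), lay@anchor, strrep("A", 25), "ACGT")
#' extractTags(read, lay, "s1", "red")
#' @export
extractTags <- function(reads, layout = shortReadLayout(),
                        sample_id = NA_character_,
                        channel = NA_character_) {
  stopifnot(is(layout, "ShortReadLayout"))
  validObject(layout)
  if (is.character(reads) && length(reads) == 1L && !file.exists(reads) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads, ignore.case = TRUE))
    stop("FASTQ file not found: ", reads)
  seqs <- .as_read_seqs(reads)
  res <- .cpp_extract_tags(
    seqs, layout@anchor, layout@barcode_len, layout@umi_len,
    layout@max_anchor_mismatch,
    layout@barcode_offset_policy == "anchor_then_barcode")
  ok <- is.na(res$reason)
  rejects <- c(too_short = 0L, anchor_missing = 0L, ambiguous_base = 0L)
  if (any(!ok)) {
    tal <- table(res$reason[!ok])
    rejects[names(tal)] <- as.integer(tal)
  }
  out <- DataFrame(barcode = res$barcode[ok], umi = res$umi[ok])
  metadata(out) <- list(sample_id = sample_id, channel = channel,
                        n_reads = length(seqs), rejects = rejects)
  out
}

#' Summarize extracted tags to per-(barcode, UMI) read counts
#'
#' @param tags output of [extractTags()] (or any data frame with `barcode`
#'   and `umi` columns).
#' @return A [S4Vectors::DataFrame] with columns `barcode`, `umi`, `reads`,
#'   sorted by barcode then UMI; metadata is carried over.
#' @examples
#' t <- DataFrame(barcode = c("AA", "AA", "CC"), umi = c("T", "T", "G"))
#' tagCounts(t)
#' @export
tagCounts <- function(tags) {
  key <- paste(tags$barcode, tags$umi, sep = "\t")
  tab <- table(key)
  nm <- names(tab)
  out <- DataFrame(barcode = sub("\t.*$", "", nm),
                   umi = sub("^.*\t", "", nm),
                   reads = as.integer(tab))
  out <- out[order(out$barcode, out$umi, method = "radix"), ]
  rownames(out) <- NULL
  if (is(tags, "Annotated")) metadata(out) <- metadata(tags)
  out
}
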