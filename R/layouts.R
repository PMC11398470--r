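#' Construct a long-read layout
#'
#' The default anchors describe the packaged plasmid architecture used by
#' the simulator; for a real library, supply the flanking sequences of your
#' vector (each at least 12 nt, mutually distinct). Layouts can also be
#' loaded from YAML with [readLayout()].
#'
#' @param anchor_up_red,anchor_down_red anchors flanking the red-channel
#'   barcode.
#' @param anchor_up_ir,anchor_down_ir anchors flanking the ir-channel
#'   barcode.
#' @param anchor_guide_up,anchor_guide_down anchors flanking the dual-sgRNA
#'   cassette.
#' @param barcode_len barcode length in nt.
#' @param guide_len protospacer length (used to place the `"|"` separator in
#'   the canonical guide key).
#' @param max_anchor_mismatch maximum substitutions tolerated per anchor.
#' @return A [LongReadLayout-class] object.
#' @examples
#' longReadLayout()
#' @export
longReadLayout <- function(anchor_up_red = "ACGTGTCCTGGACA",
                           anchor_down_red = "GTACTGACCGGTTC",
                           anchor_up_ir = "TGCTAGGACCTTGA",
                           anchor_down_ir = "CAGTTCGGATACCT",
                           anchor_guide_up = "TTGGCACCAGTTAA",
                           anchor_guide_down = "CCATTGAGTCGGTA",
                           barcode_len = 25L, guide_len = 20L,
                           max_anchor_mismatch = 2L) {
  new("LongReadLayout",
      anchor_up_red = toupper(anchor_up_red),
      anchor_down_red = toupper(anchor_down_red),
      anchor_up_ir = toupper(anchor_up_ir),
      anchor_down_ir = toupper(anchor_down_ir),
      anchor_guide_up = toupper(anchor_guide_up),
      anchor_guide_down = toupper(anchor_guide_down),
      barcode_len = as.integer(barcode_len),
      guide_len = as.integer(guide_len),
      max_anchor_mismatch = as.integer(max_anchor_mismatch))
}

#' Construct a short-read (amplicon) layout
#'
#' Amplicon reads begin with the UMI introduced at reverse transcription;
#' the barcode is located relative to a constant anchor sequence. The
#' default layout is `UMI (10 nt) + anchor + barcode (25 nt)`.
#'
#' @param anchor constant sequence adjacent to the barcode.
#' @param barcode_len,umi_len element lengths in nt.
#' @param barcode_offset_policy `"anchor_then_barcode"` (barcode follows the
#'   anchor) or `"barcode_then_anchor"`.
#' @param max_anchor_mismatch maximum substitutions tolerated in the anchor.
#' @return A [ShortReadLayout-class] object.
#' @examples
#' shortReadLayout()
#' @export
shortReadLayout <- function(anchor = "CTAGGTCACTGCAG", barcode_len = 25L,
                            umi_len = 10L,
                            barcode_offset_policy = "anchor_then_barcode",
                            max_anchor_mismatch = 1L) {
  new("ShortReadLayout",
      anchor = toupper(anchor),
      barcode_len = as.integer(barcode_len),
      umi_len = as.integer(umi_len),
      barcode_offset_policy = barcode_offset_policy,
      max_anchor_mismatch = as.integer(max_anchor_mismatch))
}

#' Read or write a layout as YAML
#'
#' @param path YAML file. Keys mirror the constructor arguments; the `type`
#'   key selects `"long"` or `"short"`.
#' @return `readLayout()` returns a layout object; `writeLayout()` returns
#'   `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' writeLayout(shortReadLayout(), p)
#' readLayout(p)
#' @export
readLayout <- function(path) {
  y <- yaml::read_yaml(path)
  type <- y$type
  y$type <- NULL
  if (identical(type, "long")) do.call(longReadLayout, y)
  else if (identical(type, "short")) do.call(shortReadLayout, y)
  else stop("layout YAML must have type: 'long' or 'short'")
}

#' @rdname readLayout
#' @param layout a [LongReadLayout-class] or [ShortReadLayout-class].
#' @export
writeLayout <- function(layout, path) {
  sl <- slotNames(class(layout))
  y <- lapply(setNames(sl, sl), function(s) {
    v <- slot(layout, s)
    if (is.integer(v)) as.integer(v) else v
  })
  y$type <- if (is(layout, "LongReadLayout")) "long" else "short"
  yaml::write_yaml(y, path)
  invisible(path)
}
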