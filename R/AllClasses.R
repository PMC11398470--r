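#' Long-read layout of the barcoded plasmid library
#'
#' Describes where the two reporter barcodes and the dual-sgRNA cassette sit
#' on a linearized plasmid read: each element is flanked by a pair of fixed
#' anchor sequences. Anchors are located by Hamming-distance substring scan
#' with at most `max_anchor_mismatch` substitutions.
#'
#' @slot anchor_up_red,anchor_down_red anchors flanking the red (mCherry)
#'   channel barcode.
#' @slot anchor_up_ir,anchor_down_ir anchors flanking the ir (iRFP) channel
#'   barcode.
#' @slot anchor_guide_up,anchor_guide_down anchors flanking the dual-sgRNA
#'   cassette.
#' @slot barcode_len barcode length in nt (25 for this library design).
#' @slot guide_len protospacer length used to canonicalize the guide key.
#' @slot max_anchor_mismatch maximum substitutions tolerated per anchor.
#' @exportClass LongReadLayout
setClass("LongReadLayout",
  representation(
    anchor_up_red = "character", anchor_down_red = "character",
    anchor_up_ir = "character", anchor_down_ir = "character",
    anchor_guide_up = "character", anchor_guide_down = "character",
    barcode_len = "integer", guide_len = "integer",
    max_anchor_mismatch = "integer"
  )
)

setValidity("LongReadLayout", function(object) {
  anchors <- c(object@anchor_up_red, object@anchor_down_red,
               object@anchor_up_ir, object@anchor_down_ir,
               object@anchor_guide_up, object@anchor_guide_down)
  if (length(anchors) != 6L || anyNA(anchors))
    return("all six anchors must be single non-NA strings")
  if (any(nchar(anchors) < 12L))
    return("anchors must be at least 12 nt long")
  if (anyDuplicated(anchors))
    return("anchors must be mutually non-identical")
  if (any(!grepl("^[ACGT]+$", anchors)))
    return("anchors must be over {A,C,G,T}")
  if (object@barcode_len <= 0L) return("barcode_len must be positive")
  if (object@guide_len <= 0L) return("guide_len must be positive")
  if (object@max_anchor_mismatch < 0L)
    return("max_anchor_mismatch must be non-negative")
  TRUE
})

#' Short-read layout of barcode/UMI amplicon reads
#'
#' Amplicon reads start with a `umi_len` UMI added at reverse transcription;
#' the 25-nt expression barcode is located relative to a fixed anchor
#' sequence (the primer-adjacent constant region), either immediately after
#' it (`anchor_then_barcode`) or immediately before it
#' (`barcode_then_anchor`).
#'
#' @slot anchor constant sequence adjacent to the barcode.
#' @slot barcode_len,umi_len element lengths in nt.
#' @slot barcode_offset_policy `"anchor_then_barcode"` or
#'   `"barcode_then_anchor"`.
#' @slot max_anchor_mismatch maximum substitutions tolerated in the anchor.
#' @exportClass ShortReadLayout
setClass("ShortReadLayout",
  representation(
    anchor = "character", barcode_len = "integer", umi_len = "integer",
    barcode_offset_policy = "character", max_anchor_mismatch = "integer"
  )
)

setValidity("ShortReadLayout", function(object) {
  if (length(object@anchor) != 1L || is.na(object@anchor) ||
      !grepl("^[ACGT]+$", object@anchor))
    return("anchor must be a single string over {A,C,G,T}")
  if (object@barcode_len <= 0L) return("barcode_len must be positive")
  if (object@umi_len <= 0L) return("umi_len must be positive")
  if (!object@barcode_offset_policy %in%
      c("anchor_then_barcode", "barcode_then_anchor"))
    return("unknown barcode_offset_policy")
  if (object@max_anchor_mismatch < 0L)
    return("max_anchor_mismatch must be non-negative")
  TRUE
})

#' Barcode-to-construct lookup table
#'
#' Maps each reporter barcode to its dual-sgRNA construct and reporter
#' channel, as established by long-read sequencing of the plasmid pool.
#' Each entry (a "link") is one barcoded plasmid isolate: a (bc_red, bc_ir)
#' barcode pair tied to a guide cassette, with the number of supporting
#' reads and the fraction agreeing with the majority assignment.
#'
#' @slot entries a [S4Vectors::DataFrame] with columns `construct_id`,
#'   `guide_key`, `bc_red`, `bc_ir`, `support`, `purity` and optionally
#'   `negative_control`.
#' @slot discards a DataFrame describing barcode pairs removed during
#'   assembly (`bc_red`, `bc_ir`, `category`, `support`, `purity`).
#' @exportClass LookupTable
setClass("LookupTable",
  representation(entries = "DataFrame", discards = "DataFrame")
)

setValidity("LookupTable", function(object) {
  e <- object@entries
  need <- c("construct_id", "guide_key", "bc_red", "bc_ir", "support",
            "purity")
  if (!all(need %in% colnames(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) == 0L) return(TRUE)
  bcs <- c(e$bc_red, e$bc_ir)
  if (anyDuplicated(bcs))
    return("a barcode maps to more than one (construct, channel)")
  if (any(e$support < 1L)) return("support must be >= 1")
  if (any(e$purity < 0 | e$purity > 1)) return("purity must be in [0, 1]")
  if (any(!nzchar(e$guide_key))) return("guide_key must be non-empty")
  TRUE
})

#' Barcode-level molecule count matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose rows are canonical
#' barcodes and whose columns are sequencing libraries, one per
#' (sample, reporter channel). The `"counts"` assay holds deduplicated
#' molecule counts. Column data carries `sample_id`, `condition`,
#' `replicate` and `channel`; after [matchToConstructs()], row data carries
#' the lookup annotation.
#'
#' @exportClass BarcodeCountMatrix
setClass("BarcodeCountMatrix", contains = "SummarizedExperiment")

setValidity("BarcodeCountMatrix", function(object) {
  cd <- colData(object)
  need <- c("sample_id", "condition", "replicate", "channel")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(paste(cd$sample_id, cd$channel)))
    return("duplicate (sample_id, channel) column")
  if (!all(cd$channel %in% c("red", "ir")))
    return("channel must be 'red' or 'ir'")
  if (!"counts" %in% names(assays(object)))
    return("a 'counts' assay is required")
  if (any(assay(object, "counts") < 0))
    return("counts must be non-negative")
  TRUE
})

#' Construct-level count matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose rows are
#' (construct, channel) pairs — the sum of molecule counts over the
#' construct's member barcodes in that channel — and whose columns are the
#' same libraries as the parent [BarcodeCountMatrix]. Row data records
#' `construct_id`, `channel`, `barcode_n` (contributing barcodes),
#' `negative_control` and `single_channel` flags.
#'
#' @exportClass ConstructCountMatrix
setClass("ConstructCountMatrix", contains = "SummarizedExperiment")

setValidity("ConstructCountMatrix", function(object) {
  rd <- rowData(object)
  need <- c("construct_id", "channel", "barcode_n")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must have columns:", paste(need, collapse = ", ")))
  if (nrow(rd) > 0L && any(rd$barcode_n < 1L))
    return("barcode_n must be >= 1")
  TRUE
})

#' Ground truth of a simulated screen
#'
#' Holds everything the simulator decided: the barcoded library, construct
#' abundances, per-pair baseline (channel bias) effects, planted condition
#' effects, and the pre-error molecule count table against which pipeline
#' output can be compared exactly.
#'
#' @slot library DataFrame with one row per barcode pair (`construct_id`,
#'   `guide_key`, `bc_red`, `bc_ir`, `negative_control`).
#' @slot config the [simConfig()] list used.
#' @slot abundance numeric relative abundance per construct.
#' @slot baseline numeric per-pair baseline log2 red:ir bias.
#' @slot effects data.frame (`construct_id`, `condition`, `log2fc`) of
#'   planted red-channel effects; zero rows for a null screen.
#' @slot counts integer matrix of true molecule counts, barcodes x
#'   libraries (filled by [simulateScreen()]).
#' @slot libraries DataFrame describing the columns of `counts`
#'   (`sample_id`, `condition`, `replicate`, `channel`).
#' @exportClass SimTruth
setClass("SimTruth",
  representation(
    library = "DataFrame", config = "list", abundance = "numeric",
    baseline = "numeric", effects = "data.frame", counts = "matrix",
    libraries = "DataFrame"
  )
)

setValidity("SimTruth", function(object) {
  lib <- object@library
  need <- c("construct_id", "guide_key", "bc_red", "bc_ir",
            "negative_control")
  if (!all(need %in% colnames(lib)))
    return(paste("library must have columns:", paste(need, collapse = ", ")))
  if (nrow(lib) > 0L && anyDuplicated(c(lib$bc_red, lib$bc_ir)))
    return("barcodes must be globally distinct")
  TRUE
})

setMethod("show", "LongReadLayout", function(object) {
  cat("LongReadLayout: barcode", object@barcode_len, "nt, guide",
      object@guide_len, "nt, <=", object@max_anchor_mismatch,
      "anchor mismatches\n")
  cat("  red barcode:  ", object@anchor_up_red, "[bc]",
      object@anchor_down_red, "\n")
  cat("  ir barcode:   ", object@anchor_up_ir, "[bc]",
      object@anchor_down_ir, "\n")
  cat("  guide cassette:", object@anchor_guide_up, "[guides]",
      object@anchor_guide_down, "\n")
})

setMethod("show", "ShortReadLayout", function(object) {
  cat("ShortReadLayout: UMI", object@umi_len, "nt + barcode",
      object@barcode_len, "nt,", object@barcode_offset_policy, "\n")
  cat("  anchor:", object@anchor, "(<=", object@max_anchor_mismatch,
      "mismatches)\n")
})

setMethod("show", "LookupTable", function(object) {
  e <- object@entries
  cat("LookupTable:", nrow(e), "barcode pairs,",
      length(unique(e$construct_id)), "constructs;",
      nrow(object@discards), "discarded pairs\n")
  if (nrow(e) > 0L) {
    cat("  support: median", median(e$support), " purity: median",
        round(median(e$purity), 3), "\n")
  }
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@library), "barcode pairs,",
      length(unique(object@library$construct_id)), "constructs\n")
  if (length(object@counts))
    cat("  counts:", nrow(object@counts), "barcodes x",
        ncol(object@counts), "libraries\n")
  if (nrow(object@effects))
    cat("  planted effects on", length(unique(object@effects$construct_id)),
        "constructs\n")
})
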