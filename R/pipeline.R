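#' Run extraction and molecule counting for every manifest library
#'
#' Applies [extractTags()], [tagCounts()] and [countMolecules()] to each
#' FASTQ in the sample manifest, collecting the per-library read ledger as
#' it goes.
#'
#' @param manifest data frame with columns `fastq_path`, `sample_id`,
#'   `condition`, `replicate`, `channel`.
#' @param layout a [ShortReadLayout-class].
#' @param bcMaxDist,umiMaxDist collapse thresholds, see
#'   [countMolecules()].
#' @return Named list of per-library molecule-count tables (inputs to
#'   [tabulateCounts()]); attribute `"ledger"` holds the per-library read
#'   accounting.
#' @examples
#' ## see vignette for a worked pipeline
#' @export
countLibraries <- function(manifest, layout = shortReadLayout(),
                           bcMaxDist = 1L, umiMaxDist = 1L) {
  .check_manifest(manifest)
  if (!"fastq_path" %in% colnames(manifest))
    stop("manifest needs a fastq_path column")
  missing <- manifest$fastq_path[!file.exists(manifest$fastq_path)]
  if (length(missing))
    stop("manifest references missing files: ",
         paste(missing, collapse = ", "))
  keys <- .lib_key(manifest$sample_id, manifest$channel)
  counts <- vector("list", nrow(manifest))
  names(counts) <- keys
  ledger <- data.frame(library = keys, reads_in = 0L, tags = 0L,
                       rejects = 0L, reads_counted = 0L, molecules = 0L)
  for (i in seq_len(nrow(manifest))) {
    tags <- extractTags(manifest$fastq_path[i], layout,
                        sample_id = manifest$sample_id[i],
                        channel = manifest$channel[i])
    md <- metadata(tags)
    tc <- tagCounts(tags)
    mc <- countMolecules(tc, bcMaxDist = bcMaxDist,
                         umiMaxDist = umiMaxDist)
    counts[[i]] <- mc
    ledger$reads_in[i] <- md$n_reads
    ledger$tags[i] <- nrow(tags)
    ledger$rejects[i] <- sum(md$rejects)
    ledger$reads_counted[i] <- sum(mc$reads)
    ledger$molecules[i] <- sum(mc$molecules)
  }
  attr(counts, "ledger") <- ledger
  counts
}

#' Run the count-level pipeline
#'
#' From per-library molecule counts to tested results: tabulation,
#' low-abundance filtering (mean below `minMean` across all libraries),
#' barcode-to-construct matching, per-construct aggregation, and the
#' requested contrast at barcode-pair or construct level. Filtering
#' precedes matching and aggregation.
#'
#' @param countsList named per-library counts (from [countLibraries()] or
#'   the simulator truth via [truthCounts()]).
#' @param manifest the sample manifest (one row per library).
#' @param lookup a [LookupTable-class].
#' @param minMean abundance filter threshold, see [filterLowAbundance()].
#' @param level `"construct"` (channel contrasts use
#'   [channelPairMatrix()]) or `"barcode"`.
#' @param contrast,channel,conditionA,conditionB,baseline,alpha,lfcThreshold
#'   passed to [screenContrast()]; `contrast = NULL` skips testing.
#' @param ... further arguments to [screenContrast()].
#' @return A list with `bcm` (filtered, annotated
#'   [BarcodeCountMatrix-class]), `ccm` ([ConstructCountMatrix-class]),
#'   `results` (or `NULL`), and `ledger` (see [conservationLedger()]).
#' @examples
#' ## see vignette for a worked pipeline
#' @export
runCounts <- function(countsList, manifest, lookup, minMean = 32,
                      level = c("construct", "barcode"), contrast = NULL,
                      channel = NULL, conditionA = NULL, conditionB = NULL,
                      baseline = NULL, alpha = 0.01, lfcThreshold = 1.5,
                      ...) {
  level <- match.arg(level)
  bcm_raw <- tabulateCounts(countsList, manifest)
  bcm <- filterLowAbundance(bcm_raw, minMean = minMean)
  bcm <- matchToConstructs(bcm, lookup)
  ccm <- aggregateByConstruct(bcm)
  ledger <- conservationLedger(bcm_raw, bcm, ccm,
                               attr(countsList, "ledger"))
  results <- NULL
  if (!is.null(contrast)) {
    x <- if (contrast == "condition_effect") {
      if (level == "construct") ccm else bcm
    } else {
      if (level == "construct") channelPairMatrix(ccm)
      else barcodePairMatrix(bcm)
    }
    results <- screenContrast(x, contrast = contrast, channel = channel,
                              conditionA = conditionA,
                              conditionB = conditionB, baseline = baseline,
                              alpha = alpha, lfcThreshold = lfcThreshold,
                              ...)
  }
  list(bcm = bcm, ccm = ccm, results = results, ledger = ledger)
}

#' Per-library conservation ledger
#'
#' Balances molecule counts across pipeline stages, per library: the raw
#' matrix column sum must equal the aggregated construct sums plus the
#' filtered-row and unmatched-row sums. When the read-level ledger from
#' [countLibraries()] is supplied, reads are also balanced
#' (`reads_in = tags + rejects`).
#'
#' @param bcm_raw the unfiltered [BarcodeCountMatrix-class].
#' @param bcm the filtered, annotated matrix.
#' @param ccm the [ConstructCountMatrix-class].
#' @param read_ledger optional read-level ledger.
#' @return A data frame, one row per library, with a logical `balanced`
#'   column; attribute `"balanced"` is the overall verdict.
#' @examples
#' ## see vignette for a worked pipeline
#' @export
conservationLedger <- function(bcm_raw, bcm, ccm, read_ledger = NULL) {
  raw <- colSums(assay(bcm_raw, "counts"))
  filtered <- metadata(bcm)$filtered_colsums %||% 0
  unmatched <- metadata(bcm)$unmatched_colsums %||% 0
  agg <- colSums(assay(ccm, "counts"))
  led <- data.frame(library = names(raw), raw = as.numeric(raw),
                    aggregated = as.numeric(agg[names(raw)]),
                    filtered = as.numeric(filtered),
                    unmatched = as.numeric(unmatched))
  led$balanced <- led$raw == led$aggregated + led$filtered + led$unmatched
  if (!is.null(read_ledger)) {
    led <- merge(read_ledger, led, by = "library", sort = FALSE)
    led$balanced <- led$balanced &
      led$reads_in == led$tags + led$rejects &
      led$molecules == led$raw
  }
  attr(led, "balanced") <- all(led$balanced)
  led
}

#' Extract the simulator's true per-library counts
#'
#' Converts a [SimTruth-class] count matrix into the per-library list
#' format consumed by [tabulateCounts()]/[runCounts()] — the counts the
#' FASTQ stages would recover with error-free reads.
#'
#' @param truth a [SimTruth-class] after [simulateScreen()].
#' @param dropZero drop zero-count barcodes per library (as real
#'   libraries would).
#' @return Named list of DataFrames (`barcode`, `molecules`), plus the
#'   manifest as attribute `"manifest"`.
#' @examples
#' truth <- simulateScreen(simulateLibrary(simConfig(n_constructs = 5,
#'   n_nontargeting = 0, depth = 2000, seed = 1)),
#'   conditions = c("a", "b"), nReplicates = 2)
#' names(truthCounts(truth))[1:2]
#' @export
truthCounts <- function(truth, dropZero = TRUE) {
  stopifnot(is(truth, "SimTruth"), length(truth@counts) > 0L)
  m <- truth@counts
  out <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    if (dropZero) v <- v[v > 0]
    DataFrame(barcode = names(v), molecules = as.integer(v))
  })
  names(out) <- colnames(m)
  attr(out, "manifest") <- as.data.frame(truth@libraries)
  out
}

#' Convert simulator truth to a lookup table
#'
#' @param truth a [SimTruth-class].
#' @return The true [LookupTable-class] (support 1, purity 1 placeholders),
#'   with non-targeting constructs flagged.
#' @examples
#' truthLookup(simulateLibrary(simConfig(n_constructs = 3,
#'   n_nontargeting = 1, seed = 1)))
#' @export
truthLookup <- function(truth) {
  lib <- truth@library
  entries <- DataFrame(
    construct_id = lib$construct_id, guide_key = lib$guide_key,
    bc_red = lib$bc_red, bc_ir = lib$bc_ir,
    support = rep(1L, nrow(lib)), purity = rep(1, nrow(lib)),
    negative_control = lib$negative_control)
  ord <- order(entries$guide_key, entries$bc_red)
  entries <- entries[ord, ]
  rownames(entries) <- NULL
  new("LookupTable", entries = entries,
      discards = DataFrame(bc_red = character(0), bc_ir = character(0),
                           category = character(0), support = integer(0),
                           purity = numeric(0)))
}

#' Run the full pipeline from a configuration
#'
#' File-level orchestration: builds (or reads) the lookup table, extracts
#' and counts every manifest library, tabulates, filters, matches,
#' aggregates and tests, then writes results, the conservation ledger and
#' a machine-readable run manifest (parameters plus input checksums) to
#' the output directory. Re-running with identical inputs reproduces
#' identical outputs — no stage is stochastic.
#'
#' @param config a list or YAML path with entries: `manifest` (TSV path),
#'   `outdir`; one of `lookup` (TSV path) or `long_reads` (FASTQ path, with
#'   optional `min_support`, `min_purity`); optional `layout`
#'   (YAML path), `long_layout`, `bc_max_dist`, `umi_max_dist`,
#'   `min_mean`, `level`, and a `test` block (`contrast`, `channel`,
#'   `condition_a`, `condition_b`, `baseline` TSV of `key`/`beta0`,
#'   `alpha`, `lfc_threshold`).
#' @return Invisibly, the [runCounts()] result list.
#' @examples
#' ## see vignette for a worked pipeline
#' @export
runAll <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$manifest), !is.null(config$outdir))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- read.delim(config$manifest, stringsAsFactors = FALSE)

  inputs <- c(config$manifest, manifest$fastq_path)
  if (!is.null(config$lookup)) {
    lookup <- readLookup(config$lookup)
    inputs <- c(inputs, config$lookup)
  } else if (!is.null(config$long_reads)) {
    llay <- if (!is.null(config$long_layout))
      readLayout(config$long_layout) else longReadLayout()
    parsed <- parseLongReads(config$long_reads, llay)
    lookup <- buildLookup(parsed,
                          minSupport = config$min_support %||% 3L,
                          minPurity = config$min_purity %||% 0.9)
    writeLookup(lookup, file.path(outdir, "lookup.tsv"))
    inputs <- c(inputs, config$long_reads)
  } else stop("config needs 'lookup' or 'long_reads'")

  slay <- if (!is.null(config$layout)) readLayout(config$layout)
          else shortReadLayout()
  counts <- countLibraries(manifest, slay,
                           bcMaxDist = config$bc_max_dist %||% 1L,
                           umiMaxDist = config$umi_max_dist %||% 1L)

  tst <- config$test %||% list()
  baseline <- NULL
  if (!is.null(tst$baseline)) {
    b <- read.delim(tst$baseline, stringsAsFactors = FALSE)
    baseline <- setNames(b$beta0, b$key)
    inputs <- c(inputs, tst$baseline)
  }
  res <- runCounts(counts, manifest, lookup,
                   minMean = config$min_mean %||% 32,
                   level = config$level %||% "construct",
                   contrast = tst$contrast,
                   channel = tst$channel,
                   conditionA = tst$condition_a,
                   conditionB = tst$condition_b,
                   baseline = baseline,
                   alpha = tst$alpha %||% 0.01,
                   lfcThreshold = tst$lfc_threshold %||% 1.5)

  write.table(res$ledger, file.path(outdir, "ledger.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(res$results)) {
    out <- data.frame(feature_id = rownames(res$results),
                      as.data.frame(res$results))
    write.table(out, file.path(outdir, "results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  run <- list(package_version = as.character(utils::packageVersion("ciberseq")),
              parameters = config,
              input_md5 = as.list(tools::md5sum(unique(inputs))),
              balanced = attr(res$ledger, "balanced"))
  jsonlite::write_json(run, file.path(outdir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!attr(res$ledger, "balanced"))
    stop("conservation ledger does not balance; see ",
         file.path(outdir, "ledger.tsv"))
  invisible(res)
}
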