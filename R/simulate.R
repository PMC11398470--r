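#' Simulation configuration
#'
#' Collects the generative parameters of a synthetic dual-barcoded screen.
#' The defaults are a desk-scale version of the screen the package is
#' built for: 2,000 dual-sgRNA constructs (of which 100 non-targeting
#' controls; the full library has 21,554 and 989), each carrying on
#' average 8 barcode pairs of two random 25-nt barcodes, log-normal
#' construct abundance, negative-binomial molecule counts (dispersion
#' 0.05), UMI labelling followed by geometric PCR duplication (rate 0.5)
#' and per-base substitution errors.
#'
#' @param n_constructs total constructs, including non-targeting.
#' @param n_nontargeting non-targeting (negative-control) constructs.
#' @param barcode_len,umi_len,guide_len element lengths in nt.
#' @param mean_barcodes_per_construct mean barcode pairs per construct
#'   (zero-truncated Poisson).
#' @param abundance_sdlog SD of log construct abundance (log-normal).
#' @param dispersion NB dispersion alpha (variance `mu + alpha*mu^2`);
#'   0 gives Poisson counts.
#' @param depth expected molecules per library.
#' @param pcr_duplication_rate geometric PCR duplication rate d: a
#'   molecule yields `1 + Geom(1 - d)` reads (mean `1/(1-d)`).
#' @param substitution_error_rate per-base substitution rate on short
#'   reads.
#' @param long_read_error_rate per-base substitution rate on long reads.
#' @param baseline_bias_sd SD of the per-pair baseline log2 red:ir bias.
#' @param effects planted red-channel effects: named list
#'   `condition -> named numeric vector of log2 effects by construct_id`.
#' @param seed RNG seed (mandatory; all simulator randomness derives from
#'   it).
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- simConfig(n_constructs = 10, n_nontargeting = 2, seed = 1)
#' @export
simConfig <- function(n_constructs = 2000L, n_nontargeting = 100L,
                      barcode_len = 25L, mean_barcodes_per_construct = 8,
                      umi_len = 10L, guide_len = 20L,
                      abundance_sdlog = 0.5, dispersion = 0.05,
                      depth = 2e6, pcr_duplication_rate = 0.5,
                      substitution_error_rate = 0.005,
                      long_read_error_rate = 0.01,
                      baseline_bias_sd = 0.35, effects = list(),
                      seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("a numeric seed is mandatory")
  cfg <- list(n_constructs = as.integer(n_constructs),
              n_nontargeting = as.integer(n_nontargeting),
              barcode_len = as.integer(barcode_len),
              mean_barcodes_per_construct = mean_barcodes_per_construct,
              umi_len = as.integer(umi_len),
              guide_len = as.integer(guide_len),
              abundance_sdlog = abundance_sdlog, dispersion = dispersion,
              depth = depth, pcr_duplication_rate = pcr_duplication_rate,
              substitution_error_rate = substitution_error_rate,
              long_read_error_rate = long_read_error_rate,
              baseline_bias_sd = baseline_bias_sd, effects = effects,
              seed = as.integer(seed))
  rates <- c(cfg$pcr_duplication_rate, cfg$substitution_error_rate,
             cfg$long_read_error_rate)
  stopifnot(cfg$n_constructs >= 1L,
            cfg$n_nontargeting >= 0L,
            cfg$n_nontargeting <= cfg$n_constructs,
            cfg$barcode_len > 0L, cfg$umi_len > 0L,
            cfg$mean_barcodes_per_construct >= 1,
            all(rates >= 0 & rates <= 1),
            cfg$dispersion >= 0, cfg$depth > 0,
            cfg$baseline_bias_sd >= 0)
  if (4^cfg$barcode_len <
      20 * cfg$n_constructs * cfg$mean_barcodes_per_construct)
    stop("barcode space too small for rejection sampling")
  class(cfg) <- "sim_config"
  cfg
}

# globally distinct random k-mers by rejection sampling
.distinct_dna <- function(n, len, forbid = character(0)) {
  out <- .random_dna(n, len)
  repeat {
    bad <- duplicated(out) | out %in% forbid
    if (!any(bad)) return(out)
    out[bad] <- .random_dna(sum(bad), len)
  }
}

#' Simulate a barcoded dual-sgRNA library
#'
#' Draws the construct set (with non-targeting controls), a zero-truncated
#' Poisson number of barcode pairs per construct, globally distinct random
#' barcodes, per-construct log-normal abundances and per-pair baseline
#' channel biases. Deterministic under `cfg$seed`.
#'
#' @param cfg a [simConfig()].
#' @return A [SimTruth-class] with the library, abundances and baselines
#'   filled (counts are filled later by [simulateScreen()]).
#' @examples
#' truth <- simulateLibrary(simConfig(n_constructs = 5,
#'   n_nontargeting = 1, seed = 1))
#' truth
#' @export
simulateLibrary <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nC <- cfg$n_constructs
  nNT <- cfg$n_nontargeting
  cid <- sprintf("C%06d", seq_len(nC))
  is_nt <- c(rep(FALSE, nC - nNT), rep(TRUE, nNT))
  gA <- .distinct_dna(nC, cfg$guide_len)
  gB <- .distinct_dna(nC, cfg$guide_len, forbid = gA)
  guide_key <- paste(gA, gB, sep = "|")

  lambda <- cfg$mean_barcodes_per_construct
  npairs <- rpois(nC, lambda)
  zero <- npairs == 0L
  while (any(zero)) {  # zero-truncated Poisson
    npairs[zero] <- rpois(sum(zero), lambda)
    zero <- npairs == 0L
  }
  total <- sum(npairs)
  bc_red <- .distinct_dna(total, cfg$barcode_len)
  bc_ir <- .distinct_dna(total, cfg$barcode_len, forbid = bc_red)

  lib <- DataFrame(
    construct_id = rep(cid, npairs),
    guide_key = rep(guide_key, npairs),
    bc_red = bc_red, bc_ir = bc_ir,
    negative_control = rep(is_nt, npairs))
  abundance <- setNames(rlnorm(nC, meanlog = 0,
                               sdlog = cfg$abundance_sdlog), cid)
  baseline <- setNames(rnorm(total, 0, cfg$baseline_bias_sd),
                       .pair_key(bc_red, bc_ir))
  new("SimTruth", library = lib, config = unclass(cfg),
      abundance = abundance, baseline = baseline,
      effects = data.frame(construct_id = character(0),
                           condition = character(0), log2fc = numeric(0)),
      counts = matrix(numeric(0), 0, 0), libraries = DataFrame())
}

#' Simulate long reads of the plasmid library
#'
#' Emits reads in the [longReadLayout()] architecture — each barcode pair's
#' plasmid read with both barcodes and the guide cassette between their
#' anchors — with i.i.d. per-base substitutions and random strand. With
#' zero error rate, [parseLongReads()] inverts the simulation exactly.
#'
#' @param truth a [SimTruth-class] from [simulateLibrary()].
#' @param readsPerPair long reads per barcode pair.
#' @param errorRate per-base substitution rate (default from the config).
#' @param layout a [LongReadLayout-class].
#' @param fastq optional path; when given, reads are written as FASTQ and
#'   the path returned invisibly.
#' @param seed RNG seed (default derived from the config seed).
#' @return A character vector of read sequences (or the `fastq` path).
#' @examples
#' truth <- simulateLibrary(simConfig(n_constructs = 2,
#'   n_nontargeting = 0, seed = 1))
#' reads <- simulateLongReads(truth, readsPerPair = 2, errorRate = 0)
#' length(reads)
#' @export
simulateLongReads <- function(truth, readsPerPair = 5,
                              errorRate = truth@config$long_read_error_rate,
                              layout = longReadLayout(), fastq = NULL,
                              seed = truth@config$seed + 1L) {
  stopifnot(is(truth, "SimTruth"))
  set.seed(seed)
  lib <- truth@library
  cassette <- sub("|", "", lib$guide_key, fixed = TRUE)
  template <- paste0(
    "GGAT", layout@anchor_up_red, lib$bc_red, layout@anchor_down_red,
    "TTCA", layout@anchor_guide_up, cassette, layout@anchor_guide_down,
    "AGGT", layout@anchor_up_ir, lib$bc_ir, layout@anchor_down_ir, "CCTA")
  reads <- rep(template, each = readsPerPair)
  if (errorRate > 0) reads <- .cpp_mutate_seqs(reads, errorRate)
  flip <- runif(length(reads)) < 0.5
  if (any(flip))
    reads[flip] <- as.character(reverseComplement(DNAStringSet(reads[flip])))
  reads <- reads[sample.int(length(reads))]
  if (!is.null(fastq)) {
    .write_fastq(reads, fastq)
    return(invisible(fastq))
  }
  reads
}

# expected molecule matrix (barcodes x libraries) for a design
.screen_mu <- function(truth, libraries, effects_df) {
  lib <- truth@library
  cfg <- truth@config
  set.seed(cfg$seed + 2L)  # Dirichlet shares are part of the screen draw
  g <- rgamma(nrow(lib), shape = 1)
  w <- truth@abundance[lib$construct_id] * g
  share <- w / sum(w)
  pair <- .pair_key(lib$bc_red, lib$bc_ir)
  beta0 <- truth@baseline[pair]

  eff <- matrix(0, nrow(lib), nrow(libraries))
  if (nrow(effects_df)) {
    for (i in seq_len(nrow(effects_df))) {
      rows <- lib$construct_id == effects_df$construct_id[i]
      cols <- libraries$condition == effects_df$condition[i]
      eff[rows, cols] <- eff[rows, cols] + effects_df$log2fc[i]
    }
  }
  mu_base <- cfg$depth * share
  mu <- matrix(0, 2L * nrow(lib), nrow(libraries))
  rn <- c(lib$bc_red, lib$bc_ir)
  for (j in seq_len(nrow(libraries))) {
    if (libraries$channel[j] == "red") {
      mu[seq_len(nrow(lib)), j] <- mu_base * 2^(eff[, j] + beta0)
    } else {
      mu[nrow(lib) + seq_len(nrow(lib)), j] <- mu_base
    }
  }
  rownames(mu) <- rn
  mu
}

#' Simulate a dual-reporter screen
#'
#' Generates true molecule counts for every barcode and library under the
#' generative model: construct abundance ~ log-normal, within-construct
#' barcode share ~ symmetric Dirichlet, expected molecules
#' `mu = depth * share`, red-channel expectation multiplied by
#' `2^(planted effect + baseline bias)`, and counts ~ NB(mu, dispersion).
#' Optionally renders each library as FASTQ: every molecule receives a
#' distinct UMI, is PCR-duplicated geometrically (duplicates share the
#' molecule's UMI) and every read acquires i.i.d. substitution errors —
#' truth counts are recorded pre-error, so dedup truth is well defined.
#'
#' @param truth a [SimTruth-class] from [simulateLibrary()].
#' @param conditions character vector of condition names.
#' @param nReplicates replicates per condition.
#' @param effects planted red-channel effects: named list
#'   `condition -> named numeric log2 vector by construct_id` (default
#'   from the config).
#' @param emitFastq write per-library FASTQ files.
#' @param dir output directory for FASTQ and manifest (required when
#'   `emitFastq`).
#' @param layout a [ShortReadLayout-class] used to render reads.
#' @param seed RNG seed (default derived from the config seed).
#' @return The [SimTruth-class] with `counts` (true molecules, barcodes x
#'   libraries, rows lexicographic) and `libraries` filled. When
#'   `emitFastq`, the manifest data frame (with `fastq_path`) is stored in
#'   the `libraries` metadata and written to `dir/manifest.tsv`.
#' @examples
#' truth <- simulateLibrary(simConfig(n_constructs = 5,
#'   n_nontargeting = 1, depth = 2000, seed = 1))
#' truth <- simulateScreen(truth, conditions = c("a", "b"),
#'                         nReplicates = 2)
#' dim(truth@counts)
#' @export
simulateScreen <- function(truth, conditions = c("uninduced", "induced"),
                           nReplicates = 3L,
                           effects = truth@config$effects,
                           emitFastq = FALSE, dir = NULL,
                           layout = shortReadLayout(),
                           seed = truth@config$seed + 3L) {
  stopifnot(is(truth, "SimTruth"), length(conditions) >= 1L,
            nReplicates >= 1L)
  cfg <- truth@config
  effects_df <- .normalize_effects(effects)

  grid <- expand.grid(replicate = seq_len(nReplicates),
                      condition = conditions, channel = c("red", "ir"),
                      stringsAsFactors = FALSE)
  grid$sample_id <- paste0(grid$condition, "_r", grid$replicate)
  libraries <- DataFrame(
    sample_id = grid$sample_id, condition = grid$condition,
    replicate = as.character(grid$replicate), channel = grid$channel,
    row.names = .lib_key(grid$sample_id, grid$channel))

  mu <- .screen_mu(truth, libraries, effects_df)
  set.seed(seed)
  counts <- matrix(0L, nrow(mu), ncol(mu), dimnames = dimnames(mu))
  for (j in seq_len(ncol(mu))) {
    counts[, j] <- if (cfg$dispersion > 0)
      rnbinom(nrow(mu), mu = mu[, j], size = 1 / cfg$dispersion)
    else rpois(nrow(mu), mu[, j])
  }
  ord <- order(rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  colnames(counts) <- rownames(libraries)

  truth@counts <- counts
  truth@libraries <- libraries
  truth@effects <- effects_df

  if (emitFastq) {
    if (is.null(dir)) stop("emitFastq needs an output directory")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(nrow(libraries))
    for (j in seq_len(nrow(libraries))) {
      paths[j] <- file.path(dir, paste0(rownames(libraries)[j], ".fastq"))
      .emit_library_fastq(counts[, j], cfg, layout, paths[j])
    }
    manifest <- data.frame(fastq_path = paths,
                           sample_id = libraries$sample_id,
                           condition = libraries$condition,
                           replicate = libraries$replicate,
                           channel = libraries$channel,
                           stringsAsFactors = FALSE)
    write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    metadata(truth@libraries) <- list(manifest = manifest, dir = dir)
  }
  truth
}

.normalize_effects <- function(effects) {
  if (is.data.frame(effects)) return(effects)
  if (length(effects) == 0L)
    return(data.frame(construct_id = character(0),
                      condition = character(0), log2fc = numeric(0)))
  do.call(rbind, lapply(names(effects), function(cond) {
    v <- effects[[cond]]
    data.frame(construct_id = names(v), condition = cond, log2fc = unname(v),
               stringsAsFactors = FALSE)
  }))
}

# UMIs from a parity-check code (last base = sum of the others mod 4), so
# any two distinct molecule UMIs differ at >= 2 positions and directional
# single-substitution dedup cannot merge distinct molecules: molecule
# truth stays well defined under the collapse rule.
.umi_code <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(0:3, n * (len - 1L), replace = TRUE), nrow = n)
  chk <- rowSums(m) %% 4
  bases <- c("A", "C", "G", "T")
  do.call(paste0, c(as.data.frame(matrix(bases[m + 1L], nrow = n),
                                  stringsAsFactors = FALSE),
                    list(bases[chk + 1L])))
}

# render one library's molecules as UMI-tagged, PCR-duplicated, error-
# bearing reads
.emit_library_fastq <- function(mols, cfg, layout, path) {
  nz <- mols > 0
  bcs <- rep(names(mols)[nz], mols[nz])
  n <- length(bcs)
  if (n == 0L) return(.write_fastq(character(0), path))
  umi <- .umi_code(n, cfg$umi_len)
  repeat {  # UMIs distinct within each barcode
    dup <- duplicated(paste(bcs, umi))
    if (!any(dup)) break
    umi[dup] <- .umi_code(sum(dup), cfg$umi_len)
  }
  copies <- 1L + rgeom(n, prob = 1 - cfg$pcr_duplication_rate)
  idx <- rep.int(seq_len(n), copies)
  reads <- paste0(umi[idx], layout@anchor, bcs[idx], "ACGTACGT")
  if (cfg$substitution_error_rate > 0)
    reads <- .cpp_mutate_seqs(reads, cfg$substitution_error_rate)
  reads <- reads[sample.int(length(reads))]
  .write_fastq(reads, path)
}
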