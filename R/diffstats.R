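#' Median-of-ratios size factors
#'
#' For each library j, the size factor is the median over features of
#' `count[i, j] / geomean(count[i, ])`, taken over features with strictly
#' positive counts in every library, then rescaled so the size factors
#' have geometric mean 1. When no feature is positive everywhere, set
#' `pseudoReference = TRUE` to compute the reference geometric mean with a
#' 0.5 pseudo-count over all features instead.
#'
#' @param m numeric count matrix, features x libraries.
#' @param pseudoReference fall back to a pseudo-count reference.
#' @return Positive numeric vector of length `ncol(m)`.
#' @examples
#' m <- rbind(c(10, 20), c(100, 200))
#' medianOfRatios(m)  # c(1/sqrt(2), sqrt(2))
#' @export
medianOfRatios <- function(m, pseudoReference = FALSE) {
  m <- as.matrix(m)
  if (pseudoReference) {
    ref <- exp(rowMeans(log(m + 0.5)))
    use <- ref > 0
  } else {
    pos <- rowSums(m > 0) == ncol(m)
    if (!any(pos))
      stop("no feature has positive counts in all libraries; ",
           "set pseudoReference = TRUE to use a pseudo-count reference")
    ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
    m <- m[pos, , drop = FALSE]
    use <- rep(TRUE, nrow(m))
  }
  s <- apply(m[use, , drop = FALSE] / ref[use], 2L, median)
  s / exp(mean(log(s)))
}

#' Method-of-moments dispersion estimation with a calibrated trend
#'
#' Estimates the negative-binomial dispersion (variance `mu + alpha*mu^2`)
#' per feature and stabilizes it across features, in three steps:
#'
#' 1. *Per-feature estimate.* On size-factor-normalized counts, the
#'    variance is pooled within design cells (groups of columns expected
#'    to share a mean) and converted by method of moments:
#'    `alpha_hat = (s^2 - mu) / mu^2`.
#' 2. *Mean-dispersion trend.* A power-law trend `alpha = a0 * mu^a1` is
#'    fit by least squares of `log(alpha_hat)` on `log(mu)` over features
#'    with positive estimates; because that regression is biased by the
#'    truncation at zero, the trend's scale is re-calibrated by moment
#'    matching so that its mean equals the mean of the raw (untruncated)
#'    per-feature estimates. With fewer than 10 positive estimates the
#'    trend falls back to the global median dispersion, with a warning.
#' 3. *Shrinkage.* The final dispersion combines trend and per-feature
#'    estimate on the log scale,
#'    `exp(w*log(trend) + (1 - w)*log(max(alpha_hat, trend)))`. Estimates
#'    below the trend are raised to it first: at screen-scale replication
#'    (2-3 replicates) the per-feature estimate is so noisy that a value
#'    below the trend is better explained by sampling than by genuinely
#'    low dispersion, and testing at under-estimated dispersion inflates
#'    the Wald statistic. `alphaFloor` bounds everything from below.
#'
#' @param m count matrix, features x libraries.
#' @param sizeFactors library size factors (default [medianOfRatios()]).
#' @param cells factor over columns grouping libraries that share an
#'   expected mean (e.g. condition, or condition x channel); cells with a
#'   single column contribute no degrees of freedom.
#' @param w trend weight in the log-scale combination.
#' @param alphaFloor absolute lower bound on any dispersion.
#' @return A [S4Vectors::DataFrame] with per-feature columns `mean`
#'   (normalized), `dispRaw` (untruncated method-of-moments), `dispMoM`
#'   (truncated at 0), `dispTrend` and `dispersion` (final).
#'   `metadata()$trend` holds the trend coefficients.
#' @examples
#' m <- matrix(rpois(600, 50), ncol = 6)
#' d <- fitDispersions(m, cells = factor(rep(1:2, each = 3)))
#' head(d$dispersion)
#' @export
fitDispersions <- function(m, sizeFactors = medianOfRatios(m), cells,
                           w = 0.5, alphaFloor = 1e-8) {
  m <- as.matrix(m)
  stopifnot(length(sizeFactors) == ncol(m), length(cells) == ncol(m),
            w >= 0, w <= 1, alphaFloor > 0)
  cells <- as.factor(cells)
  k <- sweep(m, 2L, sizeFactors, "/")
  mu <- rowMeans(k)

  ss <- 0
  df <- 0L
  for (cl in levels(cells)) {
    j <- which(cells == cl)
    if (length(j) < 2L) next
    kc <- k[, j, drop = FALSE]
    ss <- ss + rowSums((kc - rowMeans(kc))^2)
    df <- df + length(j) - 1L
  }
  if (df < 1L)
    stop("dispersion estimation needs at least one cell with >= 2 columns")
  s2 <- ss / df
  raw <- (s2 - mu) / mu^2
  raw[!is.finite(raw)] <- NA_real_
  mom <- pmax(raw, 0)

  usable <- which(!is.na(mom) & mom > 0 & mu > 0)
  if (length(usable) >= 10L) {
    fit <- lm(log(mom[usable]) ~ log(mu[usable]))
    a1 <- unname(coef(fit)[2L])
    shape <- mu^a1
    shape[!is.finite(shape) | shape <= 0] <- NA_real_
    # moment-matched scale: mean of trend equals mean of raw estimates
    target <- max(mean(raw, na.rm = TRUE), alphaFloor)
    a0 <- target / mean(shape, na.rm = TRUE)
    trend <- pmax(a0 * shape, alphaFloor)
    trend[is.na(trend)] <- alphaFloor
    coefs <- c(a0 = a0, a1 = a1)
  } else {
    warning("fewer than 10 positive dispersion estimates; ",
            "using the global median dispersion")
    glob <- max(median(mom, na.rm = TRUE), alphaFloor)
    trend <- rep(glob, nrow(m))
    coefs <- c(a0 = glob, a1 = 0)
  }

  final <- exp(w * log(trend) +
               (1 - w) * log(pmax(mom, trend, alphaFloor, na.rm = TRUE)))
  final[is.na(final)] <- trend[is.na(final)]
  out <- DataFrame(mean = mu, dispRaw = raw, dispMoM = mom,
                   dispTrend = trend, dispersion = final)
  rownames(out) <- rownames(m)
  metadata(out) <- list(trend = coefs, df = df, w = w,
                        alphaFloor = alphaFloor)
  out
}

#' Per-feature negative-binomial Wald test
#'
#' Fits, for every feature, a negative-binomial log-link regression with
#' fixed per-feature dispersion and per-observation offsets (log size
#' factors, plus any baseline offset), and reports the Wald test of one
#' model coefficient or contrast vector. The variance model is
#' `mu + alpha*mu^2`; coefficients are estimated by IRLS.
#'
#' Features with all-zero counts, or whose fit does not converge within
#' `maxit` iterations, get `NA` statistics; their `log2FC` column is still
#' filled for reporting from a least-squares fit on
#' `log2(normalized + 0.5)` (the pseudo-count is never used for testing).
#'
#' @param m count matrix, features x libraries.
#' @param colData data frame of column covariates (factors referenced by
#'   `design`).
#' @param design model formula over `colData`, e.g. `~ replicate +
#'   condition`.
#' @param contrast coefficient name (a column of the model matrix) or a
#'   numeric contrast vector of that length.
#' @param sizeFactors library size factors (default [medianOfRatios()]).
#' @param dispersions per-feature dispersions; default
#'   `fitDispersions(m, sizeFactors, cells)$dispersion`.
#' @param cells design cells for dispersion estimation; defaults to the
#'   distinct rows of the model matrix.
#' @param baseline optional named vector (by feature) of baseline log2
#'   red:ir ratios from a control screen (see [estimateBaseline()]);
#'   `baseline[i] * log(2)` is added to the offset of feature i in
#'   red-channel columns, which requires a `channel` column in `colData`.
#' @param maxit,tol IRLS iteration cap and convergence tolerance.
#' @return A [S4Vectors::DataFrame] (one row per feature, same order as
#'   `m`): `baseMean`, `log2FC`, `lfcSE`, `stat`, `pvalue`, `padj`
#'   (Benjamini-Hochberg over non-NA p), `converged`.
#' @examples
#' m <- matrix(rnbinom(120, mu = 100, size = 20), ncol = 6)
#' cd <- data.frame(condition = rep(c("a", "b"), each = 3))
#' res <- nbWaldTest(m, cd, ~ condition, "conditionb")
#' head(res$log2FC)
#' @export
nbWaldTest <- function(m, colData, design, contrast,
                       sizeFactors = medianOfRatios(m),
                       dispersions = NULL, cells = NULL, baseline = NULL,
                       maxit = 100L, tol = 1e-8) {
  m <- as.matrix(m)
  colData <- as.data.frame(colData)
  X <- model.matrix(design, colData)
  if (qr(X)$rank < ncol(X)) stop("design is not full rank")
  if (is.character(contrast)) {
    if (!contrast %in% colnames(X))
      stop("contrast '", contrast, "' is not a model coefficient; ",
           "available: ", paste(colnames(X), collapse = ", "))
    cvec <- as.numeric(colnames(X) == contrast)
  } else {
    cvec <- as.numeric(contrast)
    if (length(cvec) != ncol(X))
      stop("numeric contrast must have length ncol(model matrix)")
  }

  if (is.null(cells))
    cells <- factor(apply(X, 1L, paste, collapse = ","))
  if (is.null(dispersions))
    dispersions <- fitDispersions(m, sizeFactors, cells)$dispersion
  if (length(dispersions) == 1L)
    dispersions <- rep(dispersions, nrow(m))
  stopifnot(length(dispersions) == nrow(m))

  offset <- matrix(rep(log(sizeFactors), each = nrow(m)), nrow = nrow(m))
  if (!is.null(baseline)) {
    if (!"channel" %in% colnames(colData))
      stop("baseline normalization needs a 'channel' column in colData")
    b <- baseline[rownames(m)]
    b[is.na(b)] <- 0
    red <- colData$channel == "red"
    offset[, red] <- offset[, red] + b * log(2)
  }

  fit <- .cpp_nb_irls(m, X, offset, as.numeric(dispersions), cvec,
                      as.integer(maxit), tol)
  fit$converged <- as.logical(fit$converged)
  log2FC <- as.numeric(fit$estimate) / log(2)
  lfcSE <- as.numeric(fit$se) / log(2)
  stat <- log2FC / lfcSE
  pvalue <- 2 * pnorm(-abs(stat))

  # descriptive log2FC for features without a converged fit
  need <- which(!fit$converged)
  if (length(need)) {
    k2 <- log2(sweep(m, 2L, sizeFactors, "/") + 0.5)
    beta_ls <- solve(crossprod(X), crossprod(X, t(k2[need, , drop = FALSE])))
    log2FC[need] <- as.numeric(cvec %*% beta_ls)
  }

  out <- DataFrame(
    baseMean = rowMeans(sweep(m, 2L, sizeFactors, "/")),
    log2FC = log2FC, lfcSE = lfcSE, stat = stat, pvalue = pvalue,
    padj = bhAdjust(pvalue), converged = fit$converged)
  rownames(out) <- rownames(m)
  metadata(out) <- list(design = design, contrast = contrast,
                        sizeFactors = sizeFactors,
                        coefficients = colnames(X))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: with `m` non-NA p-values sorted ascending,
#' `padj_(i) = min over k >= i of min(1, p_(k) * m / k)`, returned in the
#' input order. `NA` values are excluded from `m` and stay `NA`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must be in [0, 1]")
  n <- length(pv)
  o <- order(pv)
  adj <- pmin(1, pv[o] * n / seq_len(n))
  adj <- rev(cummin(rev(adj)))
  out[ok][o] <- adj
  out
}

#' Call screen hits
#'
#' A feature is *significant* when `padj < alpha` and a *hit* when it is
#' significant and `|log2FC| > lfcThreshold` (the screen rule: adjusted
#' p below 0.01 and log2 fold change beyond +/-1.5).
#'
#' @param results a result table from [nbWaldTest()] (needs `log2FC` and
#'   `padj`).
#' @param alpha adjusted-p cutoff.
#' @param lfcThreshold absolute log2 fold-change cutoff (strict).
#' @return `results` with added `significant`, `hit` and `direction`
#'   (`"up"`, `"down"`, or `NA`) columns.
#' @examples
#' r <- DataFrame(log2FC = c(-2, 1, 3), padj = c(0.005, 0.005, 0.02))
#' callHits(r)$hit
#' @export
callHits <- function(results, alpha = 0.01, lfcThreshold = 1.5) {
  sig <- !is.na(results$padj) & results$padj < alpha
  hit <- sig & abs(results$log2FC) > lfcThreshold
  results$significant <- sig
  results$hit <- hit
  results$direction <- ifelse(hit, ifelse(results$log2FC > 0, "up", "down"),
                              NA_character_)
  results
}

#' Estimate per-feature baseline channel bias from a control screen
#'
#' In a control screen both reporters are driven by the same constitutive
#' promoter, so any red:ir log-ratio is barcode-intrinsic (sequence
#' effects on expression or capture, observed up to ~8-fold). This
#' function fits the channel ratio per feature (construct or barcode
#' pair) with [nbWaldTest()] under a paired design (`~ sample_id +
#' channel`) and returns the estimated log2 red:ir ratio and its SE, to be
#' supplied as `baseline` in later screens.
#'
#' @param x a pair-level matrix from [channelPairMatrix()] or
#'   [barcodePairMatrix()] of the control screen.
#' @param ... passed to [nbWaldTest()].
#' @return A [S4Vectors::DataFrame] with `beta0` (log2 red:ir), `se`, and
#'   `converged`; rownames are the feature keys. Features without a
#'   converged fit (e.g. a channel absent) carry `NA` and are counted in
#'   `metadata()$n_excluded`.
#' @examples
#' ## see vignette for a worked pipeline
#' @export
estimateBaseline <- function(x, ...) {
  m <- assay(x, "counts")
  if (nrow(m) == 0L) stop("empty control screen")
  cd <- as.data.frame(colData(x))
  cd$channel <- factor(cd$channel, levels = c("ir", "red"))
  res <- nbWaldTest(m, cd, ~ sample_id + channel, "channelred",
                    cells = interaction(cd$condition, cd$channel), ...)
  out <- DataFrame(beta0 = ifelse(res$converged, res$log2FC, NA_real_),
                   se = res$lfcSE, converged = res$converged)
  rownames(out) <- rownames(m)
  metadata(out) <- list(n_excluded = sum(!res$converged))
  out
}

#' Test a screen contrast
#'
#' High-level wrapper around [nbWaldTest()] for the three screen
#' contrasts:
#'
#' * `"condition_effect"` — difference between two conditions within one
#'   reporter channel (per barcode or per construct-channel row), design
#'   `~ replicate + condition`.
#' * `"channel_ratio"` — red:ir ratio within one condition (or all
#'   columns), per construct / barcode pair, paired design
#'   `~ sample_id + channel`.
#' * `"interaction"` — change of the red:ir ratio between two conditions
#'   (the reporter-specific response), design
#'   `~ sample_id + channel + channel:condition`.
#'
#' For channel contrasts, `x` must be a pair-level matrix
#' ([channelPairMatrix()] / [barcodePairMatrix()]); a `baseline` from
#' [estimateBaseline()] is applied as a fixed red-channel offset.
#'
#' @param x a [BarcodeCountMatrix-class], [ConstructCountMatrix-class], or
#'   pair-level SummarizedExperiment.
#' @param contrast one of `"condition_effect"`, `"channel_ratio"`,
#'   `"interaction"`.
#' @param channel for `condition_effect`: restrict to this channel
#'   (`"red"` or `"ir"`; `NULL` keeps all rows/columns of a single-channel
#'   matrix).
#' @param conditionA,conditionB conditions compared (A vs B; B is the
#'   reference). For `channel_ratio`, `conditionA` optionally restricts to
#'   one condition.
#' @param baseline optional baseline table from [estimateBaseline()] (its
#'   `beta0` column, matched by rowname) or a named numeric vector.
#' @param alpha,lfcThreshold hit-calling cutoffs, see [callHits()].
#' @param ... passed to [nbWaldTest()].
#' @return A [callHits()]-annotated result table; `metadata()` records the
#'   design and contrast.
#' @examples
#' ## see vignette for a worked pipeline
#' @export
screenContrast <- function(x,
                           contrast = c("condition_effect", "channel_ratio",
                                        "interaction"),
                           channel = NULL, conditionA = NULL,
                           conditionB = NULL, baseline = NULL,
                           alpha = 0.01, lfcThreshold = 1.5, ...) {
  contrast <- match.arg(contrast)
  cd <- as.data.frame(colData(x))
  m <- assay(x, "counts")
  if (!is.null(baseline) && is(baseline, "DataFrame"))
    baseline <- setNames(baseline$beta0, rownames(baseline))

  if (contrast == "condition_effect") {
    cols <- seq_len(ncol(m))
    if (!is.null(channel)) cols <- which(cd$channel == channel)
    if (!length(cols)) stop("no libraries in channel ", channel)
    cdc <- cd[cols, , drop = FALSE]
    mc <- m[, cols, drop = FALSE]
    if (!is.null(channel) && "channel" %in% colnames(rowData(x))) {
      rows <- which(rowData(x)$channel == channel)
      mc <- mc[rows, , drop = FALSE]
    }
    if (is.null(conditionA) || is.null(conditionB))
      stop("condition_effect needs conditionA and conditionB")
    keep <- cdc$condition %in% c(conditionA, conditionB)
    cdc <- cdc[keep, , drop = FALSE]
    mc <- mc[, keep, drop = FALSE]
    cdc$condition <- factor(cdc$condition,
                            levels = c(conditionB, conditionA))
    res <- nbWaldTest(mc, cdc, ~ replicate + condition,
                      paste0("condition", conditionA),
                      cells = cdc$condition, baseline = NULL, ...)
  } else {
    if (!"channel" %in% colnames(cd))
      stop("channel contrasts need a 'channel' column in colData")
    if (any(table(rownames(m)) > 1L))
      stop("channel contrasts need a pair-level matrix ",
           "(channelPairMatrix()/barcodePairMatrix())")
    if (contrast == "channel_ratio") {
      cols <- seq_len(ncol(m))
      if (!is.null(conditionA)) cols <- which(cd$condition == conditionA)
      cdc <- cd[cols, , drop = FALSE]
      mc <- m[, cols, drop = FALSE]
      cdc$channel <- factor(cdc$channel, levels = c("ir", "red"))
      res <- nbWaldTest(mc, cdc, ~ sample_id + channel, "channelred",
                        cells = interaction(cdc$condition, cdc$channel),
                        baseline = baseline, ...)
    } else {
      if (is.null(conditionA) || is.null(conditionB))
        stop("interaction needs conditionA and conditionB")
      keep <- cd$condition %in% c(conditionA, conditionB)
      cdc <- cd[keep, , drop = FALSE]
      mc <- m[, keep, drop = FALSE]
      cdc$channel <- factor(cdc$channel, levels = c("ir", "red"))
      # red-channel-in-condition-A indicator; sample_id absorbs the
      # condition main effect, channel the shared red:ir ratio
      cdc$redA <- as.numeric(cdc$channel == "red" &
                               cdc$condition == conditionA)
      res <- nbWaldTest(mc, cdc, ~ sample_id + channel + redA, "redA",
                        cells = interaction(cdc$condition, cdc$channel),
                        baseline = baseline, ...)
    }
  }
  res <- callHits(res, alpha = alpha, lfcThreshold = lfcThreshold)
  md <- metadata(res)
  md$screen_contrast <- contrast
  if ("barcode_n" %in% colnames(rowData(x)) &&
      nrow(rowData(x)) == nrow(res))
    res$barcode_n <- rowData(x)$barcode_n
  metadata(res) <- md
  res
}
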