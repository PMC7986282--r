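# Fitness inference from timepoint count tables.
#
# Model: per barcode, counts ~ NB(mu, dispersion) with
#   log mu = log(size_factor) + b0 + b_gens * gens + b_culture * culture
# The gens coefficient, divided by ln 2, is the fitness score: the log2
# change in relative abundance per population doubling (0 = neutral,
# -1 = non-replicating lineage).

#' Build a screen count container
#'
#' @param counts Integer matrix, barcodes x samples.
#' @param meta data.frame with one row per sample: `sample_id`, `gens`
#'   (population doublings since induction; 0 for pre-induction), `culture`
#'   (replicate label).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"counts"`.
#' @export
makeScreenExperiment <- function(counts, meta) {
  stopifnot(ncol(counts) == nrow(meta))
  if (any(meta$gens < 0)) stop("gens must be >= 0")
  meta$culture <- as.character(meta$culture)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = as.matrix(counts)),
    colData = S4Vectors::DataFrame(meta, row.names = meta$sample_id))
}

.countsAndMeta <- function(x, meta = NULL) {
  if (is(x, "SummarizedExperiment")) {
    list(counts = SummarizedExperiment::assay(x, "counts"),
         meta = as.data.frame(SummarizedExperiment::colData(x)))
  } else {
    stopifnot(!is.null(meta))
    list(counts = as.matrix(x), meta = as.data.frame(meta))
  }
}

#' Filter barcodes on pre-induction abundance
#'
#' Keeps barcodes with at least `minReads` reads in the pre-induction
#' (`gens == 0`) sample of at least one replicate culture.
#'
#' @param x Count matrix or SummarizedExperiment.
#' @param meta Sample metadata (ignored for a SummarizedExperiment).
#' @param minReads Threshold (default 64).
#' @return The filtered object, same class as the input.
#' @export
filterPreinduction <- function(x, meta = NULL, minReads = 64L) {
  cm <- .countsAndMeta(x, meta)
  pre <- which(cm$meta$gens == 0)
  if (!length(pre)) stop("no pre-induction (gens == 0) sample present")
  keep <- apply(cm$counts[, pre, drop = FALSE] >= minReads, 1L, any)
  if (is(x, "SummarizedExperiment")) x[keep, ] else x[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median across barcodes of the
#' ratio of each count to its barcode's geometric mean across samples
#' (barcodes with any zero count excluded), rescaled so the factors have
#' geometric mean 1. Falls back to total-count ratios (with a warning) when
#' no barcode is nonzero in every sample.
#'
#' @param counts Count matrix, barcodes x samples.
#' @return Named numeric vector of size factors.
#' @export
screenSizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (!any(use)) {
    warning("no barcode has nonzero counts in all samples; ",
            "falling back to total-count size factors")
    sf <- colSums(counts)
  } else {
    sf <- apply(counts[use, , drop = FALSE], 2L, function(col) {
      exp(median(log(col) - logGeo[use]))
    })
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

# Method-of-moments NB dispersion from a Poisson fit: var = mu + a * mu^2.
.momDispersion <- function(y, mu, floor = 1e-8) {
  a <- sum((y - mu)^2 - mu) / sum(mu^2)
  max(a, floor)
}

#' Fit the fitness GLM for one barcode
#'
#' Negative-binomial regression of counts on `gens` plus a culture
#' indicator, with log link and log size factors as offset. Dispersion is a
#' per-barcode method-of-moments estimate from an initial Poisson fit,
#' floored at 1e-8 (so clean data reduce to the Poisson limit). The fitted
#' gens coefficient and its Wald standard error are divided by ln 2 to give
#' the fitness score on the log2-per-doubling scale.
#'
#' @param y Integer count vector (one barcode, all samples).
#' @param meta Sample metadata with `gens` and `culture`.
#' @param sizeFactors Per-sample size factors (default: all 1).
#' @return List with `slope`, `se`, `dispersion`, `converged`.
#' @export
fitBarcodeGlm <- function(y, meta, sizeFactors = NULL) {
  if (length(y) < 4L || length(unique(meta$gens)) < 2L)
    stop("need >= 4 samples spanning >= 2 gens values")
  if (is.null(sizeFactors)) sizeFactors <- rep(1, length(y))
  df <- data.frame(y = as.numeric(y), gens = meta$gens,
                   culture = factor(meta$culture))
  off <- log(sizeFactors)
  form <- if (nlevels(df$culture) > 1L) y ~ gens + culture else y ~ gens
  res <- tryCatch({
    pois <- glm(form, family = poisson(), data = df, offset = off,
                control = list(maxit = 50))
    disp <- .momDispersion(df$y, pois$fitted.values)
    fit <- suppressWarnings(
      glm(form, family = MASS::negative.binomial(theta = 1 / disp),
          data = df, offset = off, start = coef(pois),
          control = list(maxit = 50)))
    sm <- summary(fit, dispersion = 1)
    slope <- coef(fit)[["gens"]] / log(2)
    se <- sm$coefficients["gens", "Std. Error"] / log(2)
    list(slope = slope, se = se, dispersion = disp,
         converged = isTRUE(fit$converged) && is.finite(se) && se > 0)
  }, error = function(e) {
    list(slope = NA_real_, se = NA_real_, dispersion = NA_real_,
         converged = FALSE)
  })
  res
}

#' Size factors computed within each replicate culture
#'
#' Applies [screenSizeFactors()] to each culture's samples separately, then
#' rescales the combined factors to geometric mean 1. Replicate cultures
#' are independent pools whose barcode frequencies differ by transformation
#' bottlenecks; normalizing within a culture keeps the median-of-ratios
#' reference pinned to the same (neutral) lineages at every timepoint,
#' while any constant between-culture scale is absorbed by the culture
#' term of the fitness GLM.
#'
#' @param counts Count matrix, barcodes x samples.
#' @param meta Sample metadata with a `culture` column.
#' @return Named numeric vector of size factors (sample order of `counts`).
#' @export
cultureSizeFactors <- function(counts, meta) {
  sf <- rep(NA_real_, ncol(counts))
  for (cu in unique(meta$culture)) {
    j <- which(meta$culture == cu)
    sf[j] <- screenSizeFactors(counts[, j, drop = FALSE])
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Barcode-level fitness for a whole screen
#'
#' Applies [filterPreinduction()], computes per-culture size factors, and
#' fits the per-barcode negative-binomial GLM.
#'
#' @param x Count matrix or SummarizedExperiment.
#' @param meta Sample metadata (ignored for a SummarizedExperiment).
#' @param minPre Pre-induction read threshold (default 64).
#' @param sizeFactors Optional precomputed size factors.
#' @return data.frame: barcode, slope, se, dispersion, converged.
#' @export
fitAllBarcodes <- function(x, meta = NULL, minPre = 64L, sizeFactors = NULL) {
  x <- filterPreinduction(x, meta, minPre)
  cm <- .countsAndMeta(x, meta)
  if (is.null(sizeFactors)) sizeFactors <- cultureSizeFactors(cm$counts, cm$meta)
  rows <- lapply(seq_len(nrow(cm$counts)), function(i) {
    f <- fitBarcodeGlm(cm$counts[i, ], cm$meta, sizeFactors)
    data.frame(barcode = rownames(cm$counts)[i], slope = f$slope, se = f$se,
               dispersion = f$dispersion, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate barcode fitness to guide level
#'
#' Inverse-variance weighted mean of the converged barcode slopes sharing a
#' guide: fitness = sum(slope/se^2)/sum(1/se^2), se = sqrt(1/sum(1/se^2)).
#' Guides with no converged barcode are omitted.
#'
#' @param barcodeFits data.frame from [fitAllBarcodes()].
#' @param map data.frame with `barcode`, `guide_id`.
#' @return data.frame: guide_id, fitness, se, n_barcodes.
#' @export
aggregateGuideFitness <- function(barcodeFits, map) {
  d <- merge(barcodeFits[barcodeFits$converged, , drop = FALSE], map,
             by = "barcode")
  if (!nrow(d)) {
    return(data.frame(guide_id = character(0), fitness = numeric(0),
                      se = numeric(0), n_barcodes = integer(0)))
  }
  rows <- lapply(split(d, d$guide_id), function(g) {
    w <- 1 / g$se^2
    data.frame(guide_id = g$guide_id[1],
               fitness = sum(w * g$slope) / sum(w),
               se = sqrt(1 / sum(w)), n_barcodes = nrow(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Activity threshold from negative-control fitness values
#'
#' The 5th percentile (by default) of the fitness scores of scaffold-only
#' negative-control barcodes; guides with fitness below it are called
#' active.
#'
#' @param controlFits Numeric vector of control fitness scores.
#' @param percentile Percentile in (0, 100) (default 5).
#' @param minControls Minimum number of controls required (default 20).
#' @return The threshold (log2-per-doubling scale).
#' @export
controlThreshold <- function(controlFits, percentile = 5, minControls = 20L) {
  controlFits <- controlFits[is.finite(controlFits)]
  if (length(controlFits) < minControls)
    stop("need at least ", minControls, " negative-control fitness values")
  unname(quantile(controlFits, percentile / 100))
}

#' End-to-end fitness inference
#'
#' Runs the pre-induction filter, size factors, per-barcode GLM fits,
#' guide-level aggregation, and (when scaffold-only control barcodes are
#' present in the map under guide id `"__empty__"`) the negative-control
#' activity threshold and per-guide active calls.
#'
#' @param x Count matrix or SummarizedExperiment.
#' @param map data.frame with `barcode`, `guide_id` (controls mapped to
#'   `"__empty__"`).
#' @param meta Sample metadata (ignored for a SummarizedExperiment).
#' @param minPre Pre-induction read threshold (default 64).
#' @param percentile Control percentile for the activity threshold.
#' @return List: `barcodes` (barcode-level fits), `guides` (guide-level
#'   fitness with `active` when a threshold is available), `threshold`.
#' @export
screenFitness <- function(x, map, meta = NULL, minPre = 64L, percentile = 5) {
  fits <- fitAllBarcodes(x, meta, minPre)
  controls <- merge(fits[fits$converged, ], map, by = "barcode")
  ctl <- controls$slope[controls$guide_id == EMPTY_GUIDE_ID]
  agg <- aggregateGuideFitness(fits, map)
  agg <- agg[agg$guide_id != EMPTY_GUIDE_ID, , drop = FALSE]
  thr <- if (length(ctl) >= 20L) controlThreshold(ctl, percentile) else NA_real_
  if (is.finite(thr)) agg$active <- agg$fitness < thr
  list(barcodes = fits, guides = agg, threshold = thr)
}
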