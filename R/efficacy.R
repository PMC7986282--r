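# Guide-activity model: position curve, feature construction, logistic
# regression, cross-validation, scoring and calibration.

#' Fit the position-activity curve
#'
#' Local regression (tricube-weighted, locally linear, span `alpha`) of
#' guide fitness against target-center offset from the TSS. Predictions
#' outside the fitted offset range clamp to the boundary.
#'
#' @param offset Integer offsets of target centers from the TSS.
#' @param fitness Guide fitness scores (log2 per doubling).
#' @param alpha Span: fraction of points in each local window (default 0.25).
#' @return A [PositionCurve-class].
#' @export
fitPositionCurve <- function(offset, fitness, alpha = 0.25) {
  ok <- is.finite(offset) & is.finite(fitness)
  offset <- offset[ok]; fitness <- fitness[ok]
  if (length(offset) * alpha < 4 || length(offset) < 10)
    stop("too few points (", length(offset), ") for span alpha = ", alpha)
  df <- data.frame(offset = offset, fitness = fitness)
  fit <- loess(fitness ~ offset, data = df, span = alpha, degree = 1,
               family = "gaussian",
               control = loess.control(surface = "direct"))
  new("PositionCurve", fit = fit, range = range(offset), alpha = alpha)
}

#' Evaluate a position curve
#'
#' @param curve A [PositionCurve-class].
#' @param offset Offsets to evaluate; values beyond the fitted range are
#'   clamped to the boundary.
#' @return Predicted fitness at each offset.
#' @export
predictCurve <- function(curve, offset) {
  stopifnot(is(curve, "PositionCurve"))
  x <- .clamp(offset, curve@range[1], curve@range[2])
  as.numeric(predict(curve@fit, data.frame(offset = x)))
}

# Columns of the activity design matrix (intercept first). Sequence factors
# are dummy-coded with base A as reference: 3 contrasts per position.
.activityColumns <- function(useOdm, useSeq) {
  cols <- c("(Intercept)", "offset_pred")
  if (useOdm) cols <- c(cols, "odm")
  if (useSeq) {
    cols <- c(cols, as.vector(t(outer(sprintf("nt%02d", 1:20), c("C", "G", "T"),
                                      paste0))))
  }
  cols
}

# Build the model matrix for a feature table.
.activityMatrix <- function(features, useOdm, useSeq, warnUnseen = FALSE) {
  n <- nrow(features)
  cols <- .activityColumns(useOdm, useSeq)
  X <- matrix(0, nrow = n, ncol = length(cols), dimnames = list(NULL, cols))
  X[, "(Intercept)"] <- 1
  X[, "offset_pred"] <- features$offset_pred
  if (useOdm) X[, "odm"] <- features$odm
  if (useSeq) {
    bases <- do.call(rbind, strsplit(features$protospacer, "", fixed = TRUE))
    if (warnUnseen && any(!bases %in% c("A", "C", "G", "T")))
      warning("unseen base category scored at the reference level")
    for (p in 1:20) {
      for (b in c("C", "G", "T")) {
        X[, paste0(sprintf("nt%02d", p), b)] <- as.numeric(bases[, p] == b)
      }
    }
  }
  X
}

#' Build efficacy features for a guide set
#'
#' Per guide: the position-curve prediction at its TSS offset, the minimum
#' nucleosome occupancy in the 33-nt window (target +/- 5 nt; missing
#' occupancy counts as 1 = occupied), the protospacer sequence, and the
#' activity label `fitness < threshold`.
#'
#' @param guideTable Guide design table (guide_id, chrom, start0, end0,
#'   center_offset, protospacer, strand).
#' @param fitnessTable data.frame with guide_id, fitness.
#' @param occTrack Occupancy [AccessibilityTrack-class].
#' @param curve A fitted [PositionCurve-class].
#' @param threshold Activity threshold on the fitness scale.
#' @return data.frame of features (one row per guide present in both
#'   inputs): guide_id, offset, offset_pred, odm, protospacer, strand,
#'   fitness, active.
#' @export
buildEfficacyFeatures <- function(guideTable, fitnessTable, occTrack, curve,
                                  threshold) {
  d <- merge(guideTable, fitnessTable[, c("guide_id", "fitness")],
             by = "guide_id")
  if (!nrow(d)) stop("no guides shared between design and fitness tables")
  odm <- vapply(seq_len(nrow(d)), function(i) {
    minOccupancy(occTrack, d$chrom[i], d$start0[i], d$end0[i])
  }, numeric(1))
  data.frame(guide_id = d$guide_id, offset = d$center_offset,
             offset_pred = predictCurve(curve, d$center_offset),
             odm = odm, protospacer = d$protospacer, strand = d$strand,
             fitness = d$fitness, active = d$fitness < threshold,
             stringsAsFactors = FALSE)
}

# Logistic ML fit with Wald SEs; weak L2 ridge fallback under separation.
.logisticFit <- function(X, y, ridgeLambda = 1e-4) {
  keep <- apply(X, 2L, function(col) stats::var(col) > 0)
  keep["(Intercept)"] <- TRUE
  Xk <- X[, keep, drop = FALSE]
  fit <- suppressWarnings(glm.fit(Xk, y, family = binomial()))
  separated <- !fit$converged || any(abs(fit$coefficients) > 15)
  coefs <- setNames(rep(0, ncol(X)), colnames(X))
  ses <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  if (separated && requireNamespace("glmnet", quietly = TRUE)) {
    warning("separation detected; refitting with weak L2 penalty")
    gf <- glmnet::glmnet(Xk[, -1, drop = FALSE], y, family = "binomial",
                         alpha = 0, lambda = ridgeLambda,
                         standardize = FALSE)
    b <- as.numeric(coef(gf))
    coefs[colnames(Xk)] <- b
    return(list(coef = coefs, se = ses, ridge = TRUE))
  }
  w <- fit$weights
  XtWX <- crossprod(Xk * sqrt(w))
  vc <- tryCatch(solve(XtWX), error = function(e) NULL)
  coefs[colnames(Xk)] <- fit$coefficients
  if (!is.null(vc)) ses[colnames(Xk)] <- sqrt(diag(vc))
  list(coef = coefs, se = ses, ridge = FALSE)
}

#' Fit the guide-activity logistic model
#'
#' Maximum-likelihood logistic regression of the activity label on the
#' position-curve prediction, minimum occupancy, and dummy-coded protospacer
#' sequence. Perfect separation triggers a weak L2 penalty (lambda = 1e-4)
#' with a warning.
#'
#' @param features Feature table from [buildEfficacyFeatures()].
#' @param curve The [PositionCurve-class] used to build the features
#'   (stored with the model so held-out guides can be scored).
#' @param useOdm Include the occupancy feature (default TRUE).
#' @param useSeq Include the 20 sequence factors (default TRUE).
#' @param meta Extra metadata stored on the model.
#' @return An [ActivityModel-class].
#' @export
fitActivityModel <- function(features, curve, useOdm = TRUE, useSeq = TRUE,
                             meta = list()) {
  if (length(unique(features$active)) < 2L)
    stop("both activity classes must be present")
  X <- .activityMatrix(features, useOdm, useSeq)
  fit <- .logisticFit(X, as.numeric(features$active))
  new("ActivityModel", curve = curve, coef = fit$coef, se = fit$se,
      meta = c(list(useOdm = useOdm, useSeq = useSeq, ridge = fit$ridge),
               meta))
}

#' Score guides with an activity model
#'
#' Returns the linear predictor (logit of activity odds) for each guide.
#' A logit of 0 corresponds to even odds of activity.
#'
#' @param model An [ActivityModel-class].
#' @param features Feature table; `offset_pred` is recomputed from the
#'   model's own curve when a raw `offset` column is present.
#' @return Numeric logit scores.
#' @export
scoreGuides <- function(model, features) {
  if (!is.null(features[["offset"]]) && is(model@curve, "PositionCurve")) {
    features$offset_pred <- predictCurve(model@curve, features[["offset"]])
  }
  X <- .activityMatrix(features, model@meta$useOdm, model@meta$useSeq,
                       warnUnseen = TRUE)
  as.numeric(X %*% model@coef)
}

#' Area under the ROC curve (rank formulation)
#'
#' Mann-Whitney AUC: the probability that a random positive outscores a
#' random negative, with ties counted half.
#'
#' @param score Numeric scores.
#' @param label Logical (or 0/1) class labels.
#' @return AUC in \[0,1\].
#' @export
rankAuc <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUC of the full activity pipeline
#'
#' Random k-way partition of guides (fixed seed). In each fold, both the
#' position curve and the logistic model are refitted on the training folds
#' only; held-out guides are scored with those refits and the pooled
#' held-out scores give a single AUC. Folds containing a single class are
#' merged with the next fold with a warning.
#'
#' @param guideData data.frame with offset, fitness, odm, protospacer,
#'   active (label).
#' @param k Number of folds (default 10).
#' @param seed RNG seed for the partition.
#' @param useOdm,useSeq Feature flags.
#' @param alpha Loess span (default 0.25).
#' @param strandSpecific Fit separate position curves per guide strand
#'   (needs a `strand` column); off by default, matching the retained
#'   strand-independent model.
#' @return List with `auc`, `scores` (pooled held-out logits), `labels`,
#'   `fold` assignment, and `fitness` (for calibration checks).
#' @export
crossvalidateActivity <- function(guideData, k = 10L, seed = 1L,
                                  useOdm = TRUE, useSeq = TRUE,
                                  alpha = 0.25, strandSpecific = FALSE) {
  n <- nrow(guideData)
  if (n < k) stop("need at least k guides")
  fold <- .withSeed(seed, sample(rep_len(seq_len(k), n)))
  # merge single-class folds into their neighbor
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 2L * k || length(unique(fold)) < 2L)
      stop("cannot form folds with both classes present")
    bad <- which(vapply(seq_len(k), function(f) {
      length(unique(guideData$active[fold == f])) < 2L && any(fold == f)
    }, logical(1)))
    if (!length(bad)) break
    warning("fold with a single class merged with neighbor")
    f <- bad[1]
    nb <- if (f < max(fold)) f + 1L else f - 1L
    fold[fold == f] <- nb
  }
  scores <- numeric(n)
  for (f in unique(fold)) {
    test <- fold == f
    train <- !test
    scoreFold <- function(dTrain, dTest) {
      curve <- fitPositionCurve(dTrain$offset, dTrain$fitness, alpha)
      dTrain$offset_pred <- predictCurve(curve, dTrain$offset)
      dTest$offset_pred <- predictCurve(curve, dTest$offset)
      model <- fitActivityModel(dTrain, curve, useOdm, useSeq)
      as.numeric(.activityMatrix(dTest, useOdm, useSeq) %*% model@coef)
    }
    if (strandSpecific) {
      for (st in unique(guideData$strand)) {
        sel <- guideData$strand == st
        scores[test & sel] <- scoreFold(guideData[train & sel, ],
                                        guideData[test & sel, ])
      }
    } else {
      scores[test] <- scoreFold(guideData[train, ], guideData[test, ])
    }
  }
  list(auc = rankAuc(scores, guideData$active), scores = scores,
       labels = guideData$active, fold = fold, fitness = guideData$fitness)
}

#' Calibration of activity scores against observed fitness
#'
#' Bins logit scores and reports, per bin, the number of guides, the median
#' fitness and the empirical active fraction. The bin containing logit 0 is
#' flagged: for a well-calibrated model its active fraction is close to
#' 0.5.
#'
#' @param scores Logit scores of (ideally held-out) guides.
#' @param fitness Their fitness scores.
#' @param active Logical activity labels.
#' @param binWidth Bin width on the logit scale (default 1).
#' @param inSample Set TRUE when scoring the training set itself; the
#'   result is then flagged as in-sample.
#' @return data.frame of bins with attributes `logit0_fraction` (active
#'   fraction in the bin containing 0) and `in_sample`.
#' @export
calibrationCheck <- function(scores, fitness, active, binWidth = 1,
                             inSample = FALSE) {
  # bins centered on multiples of binWidth, so the logit-0 bin straddles 0
  lo <- (round(min(scores) / binWidth) - 0.5) * binWidth
  breaks <- seq(lo, max(scores) + binWidth, by = binWidth)
  bin <- cut(scores, breaks, include.lowest = TRUE, right = FALSE)
  rows <- lapply(levels(bin), function(b) {
    idx <- which(bin == b)
    if (!length(idx)) return(NULL)  # empty bins skipped
    data.frame(bin = b,
               mid = mean(breaks[match(b, levels(bin)) + 0:1]),
               n = length(idx),
               median_fitness = median(fitness[idx]),
               active_fraction = mean(active[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  zero <- out[abs(out$mid) < binWidth / 2, ]
  attr(out, "logit0_fraction") <-
    if (nrow(zero)) zero$active_fraction[1] else NA_real_
  attr(out, "in_sample") <- inSample
  out
}
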