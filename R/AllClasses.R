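#' @import methods
#' @importFrom stats glm glm.fit coef vcov predict median quantile rnorm runif
#'   rlnorm rpois rmultinom rbinom plogis qlogis binomial poisson loess
#'   loess.control offset sd setNames aggregate as.formula
#' @importFrom utils adist read.table write.table head
NULL

#' Reference genome with a k-mer occurrence index
#'
#' Holds chromosome sequences as an uppercase [Biostrings::DNAStringSet] plus
#' a lazily built hash index of fixed-length substrings used for fast
#' perfect-match occurrence counting on both strands (`N` bases never match).
#'
#' @slot sequences A [Biostrings::DNAStringSet], one entry per chromosome.
#' @slot cache Environment caching character sequences and k-mer indexes.
#' @seealso [loadGenome()], [countKmer()]
#' @export
setClass("CrisprGenome",
         representation(sequences = "ANY", cache = "environment"))

setValidity("CrisprGenome", function(object) {
  s <- object@sequences
  if (!is(s, "DNAStringSet")) return("sequences must be a DNAStringSet")
  if (length(s) == 0L) return("genome has no sequences")
  nm <- names(s)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    return("all chromosomes must be named")
  if (anyDuplicated(nm)) return("duplicate chromosome names")
  if (any(Biostrings::width(s) == 0L)) return("empty chromosome sequence")
  bad <- Biostrings::alphabetFrequency(s, baseOnly = TRUE)[, "other"]
  n <- Biostrings::vcountPattern("N", s, fixed = TRUE)
  if (any(bad - n > 0)) return("sequences must contain only A,C,G,T,N")
  TRUE
})

#' Per-base accessibility or occupancy track
#'
#' Numeric signal in \[0,1\] along each chromosome. `kind` distinguishes
#' ATAC-style accessibility (1 = fully accessible; missing data read as 0,
#' i.e. inaccessible) from ODM-style nucleosome occupancy (1 = fully
#' occupied; missing data read as 1). The two kinds are never mixed.
#'
#' @slot kind `"accessibility"` or `"occupancy"`.
#' @slot values Named list of per-chromosome numeric vectors; `NA` = missing.
#' @seealso [accessibilityTrack()], [trackWindow()]
#' @export
setClass("AccessibilityTrack",
         representation(kind = "character", values = "list"))

setValidity("AccessibilityTrack", function(object) {
  if (!object@kind %in% c("accessibility", "occupancy"))
    return("kind must be 'accessibility' or 'occupancy'")
  if (length(object@values) == 0L || is.null(names(object@values)))
    return("values must be a named list of numeric vectors")
  v <- unlist(object@values, use.names = FALSE)
  v <- v[!is.na(v)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    return("track values must lie in [0,1]")
  TRUE
})

#' Designed guide RNA library
#'
#' Per-gene rank-ordered selections of candidate guides (at most ten per
#' gene), with uniqueness/specificity flags, accessibility scores, zone ids
#' and alternative-target records for ambiguous guides at divergent promoters.
#'
#' @slot guides data.frame with one row per selected guide.
#' @seealso [designGuides()], [writeGuideLibrary()]
#' @export
setClass("GuideLibrary", representation(guides = "data.frame"))

setValidity("GuideLibrary", function(object) {
  g <- object@guides
  need <- c("gene_id", "chrom", "strand", "protospacer", "pam", "start0",
            "end0", "center_offset", "unique", "specific", "accessibility",
            "zone", "rank", "alt_targets")
  miss <- setdiff(need, names(g))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(g) && any(table(g$gene_id) > 10L)) return("more than 10 guides for a gene")
  if (nrow(g) && any(nchar(g$protospacer) != 20L)) return("protospacers must be 20 nt")
  if (nrow(g) && any(substr(g$pam, 2, 3) != "GG")) return("PAM must match NGG")
  TRUE
})

#' Local-regression curve of fitness effect versus target position
#'
#' Tricube-weighted local linear regression of guide fitness against the
#' offset of the 23-nt target center from the transcription start site,
#' fitted over the design window. Predictions outside the fitted offset
#' range clamp to the boundary fit.
#'
#' @slot fit The underlying [stats::loess] fit.
#' @slot range Offset range covered by the data.
#' @slot alpha Span parameter (fraction of points in each local window).
#' @seealso [fitPositionCurve()], [predictCurve()]
#' @export
setClass("PositionCurve",
         representation(fit = "ANY", range = "numeric", alpha = "numeric"))

#' Guide activity model
#'
#' A position curve plus logistic-regression coefficients over the predicted
#' position effect, minimum nucleosome occupancy near the target, and
#' dummy-coded protospacer sequence (reference base A, 3 contrasts per
#' position). Scores are logits: 0 corresponds to even odds of activity.
#'
#' @slot curve A [PositionCurve-class] (or list of two for the strand-specific variant).
#' @slot coef Named coefficient vector (includes intercept).
#' @slot se Standard errors matching `coef` (NA under the ridge fallback).
#' @slot meta List of training metadata (feature flags, k, seed, separation flag).
#' @seealso [fitActivityModel()], [scoreGuides()]
#' @export
setClass("ActivityModel",
         representation(curve = "ANY", coef = "numeric", se = "numeric",
                        meta = "list"))

setMethod("show", "CrisprGenome", function(object) {
  w <- Biostrings::width(object@sequences)
  cat("CrisprGenome with", length(w), "sequence(s),",
      format(sum(as.numeric(w)), big.mark = ","), "bp total\n")
  invisible(object)
})

setMethod("show", "AccessibilityTrack", function(object) {
  cat("AccessibilityTrack kind =", object@kind, "over",
      length(object@values), "chromosome(s)\n")
  invisible(object)
})

setMethod("show", "GuideLibrary", function(object) {
  g <- object@guides
  cat("GuideLibrary:", nrow(g), "guides across",
      length(unique(g$gene_id)), "genes\n")
  if (nrow(g))
    cat("  unique:", sum(g$unique), " specific:", sum(g$specific),
        " ambiguous:", sum(!g$specific), "\n")
  invisible(object)
})

setMethod("show", "PositionCurve", function(object) {
  cat(sprintf("PositionCurve: span alpha = %.2f over offsets [%d, %d]\n",
              object@alpha, object@range[1], object@range[2]))
  invisible(object)
})

setMethod("show", "ActivityModel", function(object) {
  cat("ActivityModel with", length(object@coef), "coefficients",
      if (isTRUE(object@meta$ridge)) "(ridge fallback)" else "", "\n")
  invisible(object)
})

#' Extract the guide table from a GuideLibrary
#' @param x A [GuideLibrary-class].
#' @return data.frame of selected guides.
#' @export
guides <- function(x) {
  stopifnot(is(x, "GuideLibrary"))
  x@guides
}

#' Extract genome sequences
#' @param x A `CrisprGenome`.
#' @return The underlying [Biostrings::DNAStringSet].
#' @export
genomeSeqs <- function(x) {
  stopifnot(is(x, "CrisprGenome"))
  x@sequences
}

#' Chromosome lengths of a genome
#' @param x A `CrisprGenome`.
#' @return Named integer vector of sequence lengths.
#' @export
seqLens <- function(x) {
  stopifnot(is(x, "CrisprGenome"))
  setNames(Biostrings::width(x@sequences), names(x@sequences))
}
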