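# Accessibility / occupancy tracks: construction, bedGraph I/O, window access.

#' Construct an accessibility or occupancy track
#'
#' @param values Named list of per-chromosome numeric vectors (one value per
#'   base; `NA` marks missing data). Values are clamped to \[0,1\].
#' @param kind `"accessibility"` (ATAC-style, 1 = open) or `"occupancy"`
#'   (ODM-style nucleosome occupancy, 1 = occupied).
#' @return An [AccessibilityTrack-class].
#' @export
accessibilityTrack <- function(values, kind = c("accessibility", "occupancy")) {
  kind <- match.arg(kind)
  stopifnot(is.list(values), !is.null(names(values)))
  values <- lapply(values, function(v) .clamp(as.numeric(v), 0, 1))
  new("AccessibilityTrack", kind = kind, values = values)
}

#' Read a track from bedGraph
#'
#' Intervals are 0-based half-open (bedGraph convention). An optional
#' `track ...` header line may declare the kind via a `kind=` field; an
#' explicit `kind` argument overrides it.
#'
#' @param path bedGraph file.
#' @param genome A [CrisprGenome-class] supplying chromosome lengths.
#' @param kind Optional track kind; taken from the header when absent.
#' @return An [AccessibilityTrack-class].
#' @export
readBedGraphTrack <- function(path, genome, kind = NULL) {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1], "track")) {
    if (is.null(kind)) {
      m <- regmatches(lines[1], regexec("kind=(\\w+)", lines[1]))[[1]]
      if (length(m) == 2L) kind <- m[2]
    }
    lines <- lines[-1]
  }
  if (is.null(kind)) kind <- "accessibility"
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no data lines in bedGraph: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4L))
    stop("malformed bedGraph line in ", path, " (line ",
         which(lengths(parts) < 4L)[1], ")")
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start <- as.integer(vapply(parts, `[[`, character(1), 2L))
  end <- as.integer(vapply(parts, `[[`, character(1), 3L))
  val <- as.numeric(vapply(parts, `[[`, character(1), 4L))
  lens <- seqLens(genome)
  vals <- lapply(lens, function(L) rep(NA_real_, L))
  for (i in seq_along(chrom)) {
    if (!chrom[i] %in% names(vals))
      stop("bedGraph chromosome not in genome: ", chrom[i])
    L <- lens[[chrom[i]]]
    s <- max(start[i], 0L); e <- min(end[i], L)
    if (e > s) vals[[chrom[i]]][(s + 1L):e] <- val[i]
  }
  accessibilityTrack(vals, kind = kind)
}

#' Write a track to bedGraph
#'
#' Runs of equal values are merged into intervals; missing (`NA`) positions
#' are omitted. A header line records the track kind.
#'
#' @param track An [AccessibilityTrack-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedGraphTrack <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph kind=%s", track@kind), con)
  for (chrom in names(track@values)) {
    v <- track@values[[chrom]]
    if (!length(v)) next
    key <- ifelse(is.na(v), "NA", format(v, digits = 10))
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != "NA"
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                       format(v[ends[keep]], digits = 10)), con)
  }
  invisible(path)
}

#' Per-base track values over a genomic window
#'
#' Returns one value per position of the 0-based half-open window
#' `[start0, end0)`. Missing positions are filled with 0 for accessibility
#' tracks (no evidence of openness) and 1 for occupancy tracks (assumed
#' occupied). Windows extending beyond the chromosome are truncated with a
#' warning.
#'
#' @param track An [AccessibilityTrack-class].
#' @param chrom Chromosome name.
#' @param start0,end0 0-based half-open window.
#' @return Numeric vector of per-position values.
#' @export
trackWindow <- function(track, chrom, start0, end0) {
  if (!chrom %in% names(track@values))
    stop("unknown chromosome in track: ", chrom)
  v <- track@values[[chrom]]
  L <- length(v)
  if (start0 < 0L || end0 > L) {
    warning("window [", start0, ",", end0, ") truncated to chromosome ",
            chrom, " bounds [0,", L, ")")
    start0 <- max(start0, 0L)
    end0 <- min(end0, L)
  }
  if (end0 <= start0) return(numeric(0))
  out <- v[(start0 + 1L):end0]
  fill <- if (track@kind == "accessibility") 0 else 1
  out[is.na(out)] <- fill
  out
}

#' Minimum occupancy in a window around a guide target
#'
#' The efficacy model uses the lowest occupancy value in a 33-nt window:
#' the 23-nt target plus `flank` nucleotides on each side.
#'
#' @param track An occupancy [AccessibilityTrack-class].
#' @param chrom Chromosome name.
#' @param start0,end0 0-based half-open target span.
#' @param flank Flank width on each side (default 5).
#' @return Minimum occupancy over the window.
#' @export
minOccupancy <- function(track, chrom, start0, end0, flank = 5L) {
  if (track@kind != "occupancy")
    stop("minOccupancy requires an occupancy track")
  L <- length(track@values[[chrom]])
  s <- max(start0 - flank, 0L)
  e <- min(end0 + flank, L)
  min(trackWindow(track, chrom, s, e))
}
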