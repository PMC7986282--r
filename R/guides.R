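# Guide enumeration, classification, scoring and selection.
#
# A candidate guide is a 23-nt target (20-nt protospacer + NGG PAM) on either
# strand. Its position is summarized by the offset of the central (12th)
# base of the target span from the gene anchor (TSS when annotated, else the
# first CDS base), signed in the gene's transcription direction: negative
# offsets are upstream of the anchor.

# Association windows for the target-sequence center.
.designWindow <- function(mode) {
  if (mode == "TSS") c(-220L, 20L) else c(-350L, 0L)
}

# Zone systems used to guarantee positional spread of selected guides.
.designZones <- function(mode) {
  if (mode == "TSS") {
    list(c(-220L, -141L), c(-140L, -61L), c(-60L, 20L))
  } else {
    list(c(-350L, -271L), c(-270L, -191L), c(-190L, -111L), c(-110L, -30L))
  }
}

.zoneOf <- function(offset, mode) {
  zones <- .designZones(mode)
  z <- rep(NA_integer_, length(offset))
  for (i in seq_along(zones)) {
    z[offset >= zones[[i]][1] & offset <= zones[[i]][2]] <- i
  }
  z
}

#' Enumerate candidate guides for one gene
#'
#' Scans both strands for 23-nt windows ending in GG (protospacer
#' orientation) whose target center falls inside the gene's association
#' window: \[-220, +20\] around the TSS for TSS-annotated genes, \[-350, 0\]
#' around the CDS start otherwise. Windows running off the chromosome or
#' containing `N` in the protospacer/PAM are dropped.
#'
#' @param genome A [CrisprGenome-class].
#' @param gene One-row gene data.frame (see [readGeneModels()]).
#' @return data.frame of candidates with genomic span (0-based half-open),
#'   strand, protospacer, PAM and `center_offset`.
#' @export
enumerateCandidates <- function(genome, gene) {
  gene <- as.data.frame(gene)
  if (nrow(gene) != 1L) stop("enumerateCandidates expects a single gene")
  a <- .anchor(gene)
  if (is.na(a)) stop("gene ", gene$gene_id, " has no resolvable anchor")
  mode <- if (!is.na(gene$tss)) "TSS" else "CDS"
  win <- .designWindow(mode)
  dir <- if (gene$strand == "+") 1L else -1L
  L <- seqLens(genome)[[gene$chrom]]
  offs <- win[1]:win[2]
  cen <- a + dir * offs
  ok <- cen - 11L >= 0L & cen + 11L <= L - 1L
  offs <- offs[ok]; cen <- cen[ok]
  if (!length(cen)) return(.emptyCandidates())
  s <- .chr(genome, gene$chrom)

  # plus-strand guides: forward GG at 0-based positions cen+10, cen+11
  pamGG <- substring(s, cen + 11L, cen + 12L) == "GG"
  # minus-strand guides: forward CC at 0-based positions cen-11, cen-10
  pamCC <- substring(s, cen - 10L, cen - 9L) == "CC"

  res <- list()
  if (any(pamGG)) {
    c1 <- cen[pamGG]
    proto <- substring(s, c1 - 10L, c1 + 9L)
    pam <- substring(s, c1 + 10L, c1 + 12L)
    res[[1]] <- data.frame(gene_id = gene$gene_id, chrom = gene$chrom,
                           strand = "+", start0 = c1 - 11L, end0 = c1 + 12L,
                           center0 = c1, center_offset = offs[pamGG],
                           protospacer = proto, pam = pam,
                           stringsAsFactors = FALSE)
  }
  if (any(pamCC)) {
    c2 <- cen[pamCC]
    proto <- .revcomp(substring(s, c2 - 7L, c2 + 12L))
    pam <- .revcomp(substring(s, c2 - 10L, c2 - 8L))
    res[[length(res) + 1L]] <-
      data.frame(gene_id = gene$gene_id, chrom = gene$chrom,
                 strand = "-", start0 = c2 - 11L, end0 = c2 + 12L,
                 center0 = c2, center_offset = offs[pamCC],
                 protospacer = proto, pam = pam, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(.emptyCandidates())
  out <- out[!grepl("N", paste0(out$protospacer, out$pam), fixed = TRUE), ,
             drop = FALSE]
  out[order(out$center_offset, out$strand), , drop = FALSE]
}

.emptyCandidates <- function() {
  data.frame(gene_id = character(0), chrom = character(0),
             strand = character(0), start0 = integer(0), end0 = integer(0),
             center0 = integer(0), center_offset = integer(0),
             protospacer = character(0), pam = character(0),
             stringsAsFactors = FALSE)
}

#' Classify genomic uniqueness of candidate targets
#'
#' A target is unique when its 20-nt protospacer followed by any NGG PAM
#' occurs exactly once in the genome, counting both strands.
#'
#' @param genome A [CrisprGenome-class].
#' @param protospacer Character vector of 20-nt protospacers.
#' @return Logical vector.
#' @export
classifyUniqueness <- function(genome, protospacer) {
  stopifnot(all(nchar(protospacer) == 20L))
  uniq <- unique(protospacer)
  counts <- integer(length(uniq))
  for (b in c("A", "C", "G", "T")) {
    counts <- counts + countKmer(genome, paste0(uniq, b, "GG"))
  }
  (counts == 1L)[match(protospacer, uniq)]
}

#' Classify promoter specificity of candidates
#'
#' A candidate is specific when its target center lies in the association
#' window of exactly one gene. At divergent promoters a center can fall in
#' two genes' windows; all genes other than the candidate's own are recorded
#' as alternative targets.
#'
#' @param cands Candidate data.frame (needs chrom, center0, gene_id).
#' @param genes Gene table with TSS annotation applied.
#' @return `cands` with added logical `specific` and character `alt_targets`
#'   (comma-separated gene ids, empty when none).
#' @export
classifySpecificity <- function(cands, genes) {
  genes <- .checkGenes(genes)
  n <- nrow(cands)
  assoc <- vector("list", n)
  for (j in seq_len(nrow(genes))) {
    g <- genes[j, , drop = FALSE]
    win <- .designWindow(g$mode)
    dir <- if (g$strand == "+") 1L else -1L
    offs <- dir * (cands$center0 - .anchor(g))
    hit <- cands$chrom == g$chrom & offs >= win[1] & offs <= win[2]
    for (i in which(hit)) assoc[[i]] <- c(assoc[[i]], g$gene_id)
  }
  nAssoc <- lengths(assoc)
  cands$specific <- nAssoc == 1L
  cands$alt_targets <- vapply(seq_len(n), function(i) {
    paste(setdiff(assoc[[i]], cands$gene_id[i]), collapse = ",")
  }, character(1))
  cands
}

#' Mean chromatin accessibility over a target span
#'
#' Averages accessibility across all 23 target positions and across
#' replicate tracks (each replicate's positional mean is averaged).
#' Positions without data count as 0.
#'
#' @param tracks List of accessibility [AccessibilityTrack-class] replicates.
#' @param chrom Chromosome name.
#' @param start0,end0 0-based half-open target span.
#' @return Accessibility score in \[0,1\].
#' @export
scoreAccessibility <- function(tracks, chrom, start0, end0) {
  if (!length(tracks)) return(0)
  for (t in tracks) {
    if (t@kind != "accessibility")
      stop("scoreAccessibility requires accessibility tracks")
  }
  mean(vapply(tracks, function(t) mean(trackWindow(t, chrom, start0, end0)),
              numeric(1)))
}

# Deterministic priority ordering: unique first, then specific, then more
# accessible; ties broken by closeness to the empirically best position
# (-50), then smaller genomic coordinate, then + strand.
.priorityOrder <- function(cands) {
  order(!cands$unique, !cands$specific, -cands$accessibility,
        abs(cands$center_offset + 50L), cands$start0, cands$strand != "+")
}

#' Select up to ten guides for one gene
#'
#' First takes the highest-priority candidate in each positional zone (zones
#' without candidates are skipped), then fills the remaining slots with the
#' highest-priority unselected candidates until ten guides are chosen or
#' candidates are exhausted. Priority is uniqueness, then specificity, then
#' accessibility, with deterministic tie-breaks.
#'
#' @param cands Candidates of a single gene, carrying `unique`, `specific`
#'   and `accessibility` columns.
#' @param mode `"TSS"` or `"CDS"` (controls the zone system).
#' @param maxGuides Selection cap (default 10).
#' @return Selected candidates with `zone` and `rank` columns, rank-ordered.
#' @export
selectGuides <- function(cands, mode = c("TSS", "CDS"), maxGuides = 10L) {
  mode <- match.arg(mode)
  if (!nrow(cands)) {
    cands$zone <- integer(0); cands$rank <- integer(0)
    return(cands)
  }
  if (length(unique(cands$gene_id)) > 1L)
    stop("selectGuides expects candidates of a single gene")
  cands$zone <- .zoneOf(cands$center_offset, mode)
  ord <- .priorityOrder(cands)
  picked <- integer(0)
  for (z in seq_along(.designZones(mode))) {
    inZone <- ord[cands$zone[ord] %in% z]
    if (length(inZone)) picked <- c(picked, inZone[1])
    if (length(picked) >= maxGuides) break
  }
  rest <- setdiff(ord, picked)
  room <- maxGuides - length(picked)
  if (room > 0L && length(rest)) picked <- c(picked, head(rest, room))
  out <- cands[picked, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Design a guide library for a gene set
#'
#' Full design pass: enumerate candidates per gene, classify genomic
#' uniqueness and promoter specificity, score ATAC accessibility, and apply
#' the zone-guaranteed priority selection.
#'
#' @param genome A [CrisprGenome-class].
#' @param genes Gene table (after [annotateTss()] when TSS data exist).
#' @param atacTracks List of replicate accessibility tracks (may be empty;
#'   accessibility then scores 0 for all guides).
#' @param maxGuides Cap per gene (default 10).
#' @return A [GuideLibrary-class].
#' @export
designGuides <- function(genome, genes, atacTracks = list(), maxGuides = 10L) {
  genes <- .checkGenes(genes)
  allCands <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    enumerateCandidates(genome, genes[i, , drop = FALSE])
  }))
  if (is.null(allCands) || !nrow(allCands)) {
    lib <- .emptyCandidates()
    lib$unique <- logical(0); lib$specific <- logical(0)
    lib$accessibility <- numeric(0); lib$alt_targets <- character(0)
    lib$zone <- integer(0); lib$rank <- integer(0)
    return(new("GuideLibrary", guides = lib))
  }
  allCands$unique <- classifyUniqueness(genome, allCands$protospacer)
  allCands <- classifySpecificity(allCands, genes)
  allCands$accessibility <- if (length(atacTracks)) {
    vapply(seq_len(nrow(allCands)), function(i) {
      scoreAccessibility(atacTracks, allCands$chrom[i],
                         allCands$start0[i], allCands$end0[i])
    }, numeric(1))
  } else 0
  sel <- do.call(rbind, lapply(split(allCands, allCands$gene_id), function(cc) {
    mode <- genes$mode[match(cc$gene_id[1], genes$gene_id)]
    selectGuides(cc, mode, maxGuides)
  }))
  sel <- sel[order(match(sel$gene_id, genes$gene_id), sel$rank), , drop = FALSE]
  rownames(sel) <- NULL
  sel <- cbind(guide_id = sprintf("%s_g%02d", sel$gene_id, sel$rank), sel,
               stringsAsFactors = FALSE)
  new("GuideLibrary", guides = sel)
}

#' Resolve the likely target of an ambiguous guide at a divergent promoter
#'
#' Evaluates the fitted position-activity curve at the guide's offset from
#' each associated gene's TSS and assigns the guide to the gene with the
#' higher predicted activity, provided the activity ratio exceeds `margin`.
#' Offsets outside the curve's design window count as predicted-inactive.
#'
#' @param offsets Named numeric vector: offset of the guide center from each
#'   candidate gene's anchor (names are gene ids).
#' @param curve A fitted [PositionCurve-class] (fitness vs offset; more
#'   negative fitness = more active, so activity = max(0, -prediction)).
#' @param margin Required odds ratio of best to second-best activity
#'   (default 2).
#' @return The assigned gene id, or `NA_character_` when unresolved.
#' @export
resolveDivergentTargets <- function(offsets, curve, margin = 2) {
  stopifnot(length(offsets) >= 1L, !is.null(names(offsets)))
  win <- .designWindow("TSS")
  act <- vapply(offsets, function(o) {
    if (is.na(o) || o < win[1] || o > win[2]) return(0)
    max(0, -predictCurve(curve, o))
  }, numeric(1))
  ord <- order(-act, names(offsets))
  best <- act[ord[1]]
  second <- if (length(act) > 1L) act[ord[2]] else 0
  if (best <= 0) return(NA_character_)
  if (best >= margin * second && best > second) return(names(offsets)[ord[1]])
  NA_character_
}

#' Write a guide library as TSV
#'
#' Emitted coordinates are 1-based inclusive (`start`, `end`).
#'
#' @param x A [GuideLibrary-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGuideLibrary <- function(x, path) {
  g <- guides(x)
  if (is.null(g$guide_id))
    g$guide_id <- sprintf("%s_g%02d", g$gene_id, g$rank)
  out <- data.frame(guide_id = g$guide_id,
                    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                    protospacer = g$protospacer, pam = g$pam,
                    start = g$start0 + 1L, end = g$end0,
                    center_offset = g$center_offset, unique = g$unique,
                    specific = g$specific,
                    accessibility = round(g$accessibility, 6),
                    zone = ifelse(is.na(g$zone), ".", g$zone),
                    rank = g$rank,
                    alt_targets = ifelse(g$alt_targets == "", ".",
                                         g$alt_targets),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a guide library TSV written by [writeGuideLibrary()]
#' @param path Input file.
#' @return A [GuideLibrary-class].
#' @export
readGuideLibrary <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  na.strings = character(0))
  g <- data.frame(guide_id = d$guide_id,
                  gene_id = d$gene_id, chrom = d$chrom, strand = d$strand,
                  start0 = d$start - 1L, end0 = d$end,
                  center0 = d$start - 1L + 11L,
                  center_offset = d$center_offset,
                  protospacer = d$protospacer, pam = d$pam,
                  unique = as.logical(d$unique),
                  specific = as.logical(d$specific),
                  accessibility = d$accessibility,
                  zone = suppressWarnings(as.integer(d$zone)),
                  rank = d$rank,
                  alt_targets = ifelse(d$alt_targets == ".", "",
                                       d$alt_targets),
                  stringsAsFactors = FALSE)
  new("GuideLibrary", guides = g)
}
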