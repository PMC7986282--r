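# Barcode read processing: trimming, single-mismatch collapsing, count
# filtering, and barcode-to-guide assignment.

BC_COUNT_ADAPTER <- "GCATGCGTGAAGTGGCGCGCCTGATA"
BC_ASSIGN_ADAPTER <- "GCATGCGTGAAGTGGCGCGCCTGATAGCTCGTTTAAACTG"
GUIDE_ADAPTER_5 <- "CGAAAC"
GUIDE_ADAPTER_3 <- "AAGTTAAAAT"
XHOI_SITE <- "CTCGAG"
EMPTY_GUIDE_ID <- "__empty__"

#' Reference sequence read in place of a guide by scaffold-only constructs
#'
#' Constructs lacking a guide insert ("empty" expression plasmids) yield a
#' constant scaffold-derived sequence between the guide adapters. Matching
#' against this entry lets the assignment workflow report such barcodes as
#' negative controls rather than discarding them.
#'
#' @return A 20-nt character scalar.
#' @export
emptyGuideSequence <- function() "GTTTTAGAGCTAGAAATAGC"

#' Read a FASTQ file
#'
#' @param path FASTQ path (uncompressed or gzipped).
#' @return data.frame with `id`, `seq`, `qual` (Phred+33 strings).
#' @export
readFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a FASTQ file
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  out <- character(4L * nrow(reads))
  out[seq(1, length(out), 4)] <- paste0("@", reads$id)
  out[seq(2, length(out), 4)] <- reads$seq
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

# Phred+33 quality string -> integer vector.
.qualInts <- function(qual) as.integer(charToRaw(qual)) - 33L

#' Trim barcode reads at the 3' adapter
#'
#' The barcode is the sequence 5' of the first adapter occurrence. Reads
#' lacking the adapter, or whose residual barcode is shorter than `minLen`,
#' are rejected with a reason.
#'
#' @param seqs Character vector of read sequences.
#' @param adapter 3' adapter sequence (default: the barcode-counting
#'   adapter; the assignment workflow uses the longer the assignment adapter
#'   with `minLen = 12`).
#' @param minLen Minimum barcode length (default 10).
#' @return data.frame with `barcode` (NA when rejected) and `reason`
#'   (`NA`, `"no_adapter"` or `"too_short"`).
#' @export
trimBarcodeRead <- function(seqs, adapter = BC_COUNT_ADAPTER, minLen = 10L) {
  pos <- regexpr(adapter, seqs, fixed = TRUE)
  barcode <- ifelse(pos > 0L, substr(seqs, 1L, pos - 1L), NA_character_)
  reason <- rep(NA_character_, length(seqs))
  reason[pos < 0L] <- "no_adapter"
  tooShort <- pos > 0L & nchar(barcode) < minLen
  reason[tooShort] <- "too_short"
  barcode[!is.na(reason)] <- NA_character_
  data.frame(barcode = barcode, reason = reason, stringsAsFactors = FALSE)
}

#' Collapse single-nucleotide barcode mismatches
#'
#' Greedy directional collapsing: barcodes are processed by descending total
#' count (ties lexicographic); each either founds a record or is absorbed
#' into an already-founded record of equal length at Hamming distance 1
#' (ties broken toward the higher-count founder, then lexicographic).
#' Absorbed counts are summed, so total counts are conserved, and the
#' operation is idempotent (founders end up pairwise at distance >= 2).
#'
#' @param counts Named non-negative integer vector, or a matrix with barcode
#'   rownames and one column per sample/library.
#' @return List with `counts` (matrix, rownames = representative barcodes)
#'   and `map` (named character: input barcode -> representative).
#' @export
collapseBarcodes <- function(counts) {
  if (is.table(counts)) counts <- setNames(as.integer(counts), names(counts))
  if (is.null(dim(counts)) || length(dim(counts)) < 2L) {
    counts <- matrix(as.integer(counts), ncol = 1,
                     dimnames = list(names(counts), "count"))
  }
  if (is.null(rownames(counts))) stop("counts must have barcode names")
  total <- rowSums(counts)
  ord <- order(-total, rownames(counts))
  bcs <- rownames(counts)[ord]
  founders <- new.env(hash = TRUE, parent = emptyenv())
  rep <- character(length(bcs))
  names(rep) <- bcs
  bases <- c("A", "C", "G", "T", "N")
  for (i in seq_along(bcs)) {
    bc <- bcs[i]
    n <- nchar(bc)
    hits <- character(0)
    chars <- strsplit(bc, "", fixed = TRUE)[[1]]
    for (p in seq_len(n)) {
      for (b in bases) {
        if (b == chars[p]) next
        cand <- bc
        substr(cand, p, p) <- b
        if (!is.null(get0(cand, envir = founders))) hits <- c(hits, cand)
      }
    }
    if (length(hits)) {
      ht <- total[hits]
      hits <- hits[order(-ht, hits)]
      rep[bc] <- hits[1]
    } else {
      assign(bc, TRUE, envir = founders)
      rep[bc] <- bc
    }
  }
  agg <- rowsum(counts[bcs, , drop = FALSE], group = rep)
  agg <- agg[order(-rowSums(agg), rownames(agg)), , drop = FALSE]
  list(counts = agg, map = rep)
}

#' Filter a barcode count table
#'
#' Keeps barcodes observed (count > 0) in at least `minLibraries` libraries,
#' with at least `minTotal` reads across all libraries, and whose sequence
#' does not contain `motif` (default the XhoI site, which would be cut
#' during library preparation).
#'
#' @param counts Count matrix with barcode rownames.
#' @param minLibraries Minimum number of libraries with nonzero count.
#' @param minTotal Minimum total read count.
#' @param motif Forbidden subsequence.
#' @return The filtered count matrix.
#' @export
filterCountTable <- function(counts, minLibraries = 2L, minTotal = 33L,
                             motif = XHOI_SITE) {
  keep <- rowSums(counts > 0) >= minLibraries &
    rowSums(counts) >= minTotal &
    !grepl(motif, rownames(counts), fixed = TRUE)
  counts[keep, , drop = FALSE]
}

#' Trim a guide read between its flanking adapters
#'
#' Extracts the sequence between the first occurrence of the 5' adapter and
#' the following 3' adapter. Reads missing either adapter or with fewer than
#' `minLen` residual bases are rejected.
#'
#' @param seqs Character vector of R2 sequences.
#' @param quals Matching Phred+33 quality strings (trimmed in parallel).
#' @param adapter5,adapter3 Flanking adapters.
#' @param minLen Minimum residual guide length (default 20).
#' @return data.frame with `guide`, `gqual` (NA when rejected) and `reason`.
#' @export
trimGuideRead <- function(seqs, quals, adapter5 = GUIDE_ADAPTER_5,
                          adapter3 = GUIDE_ADAPTER_3, minLen = 20L) {
  n <- length(seqs)
  guide <- rep(NA_character_, n)
  gqual <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  p5 <- regexpr(adapter5, seqs, fixed = TRUE)
  for (i in seq_len(n)) {
    if (p5[i] < 0L) { reason[i] <- "no_adapter5"; next }
    from <- p5[i] + nchar(adapter5)
    rest <- substr(seqs[i], from, nchar(seqs[i]))
    p3 <- regexpr(adapter3, rest, fixed = TRUE)
    if (p3 < 0L) { reason[i] <- "no_adapter3"; next }
    if (p3 - 1L < minLen) { reason[i] <- "too_short"; next }
    guide[i] <- substr(rest, 1L, p3 - 1L)
    gqual[i] <- substr(quals[i], from, from + p3 - 2L)
  }
  data.frame(guide = guide, gqual = gqual, reason = reason,
             stringsAsFactors = FALSE)
}

#' Match trimmed guide sequences against the guide library
#'
#' Reads containing any base below `minQ` are discarded as low quality.
#' Remaining sequences are compared to every library guide (plus the
#' scaffold-only "empty" entry) by Levenshtein distance; the best match is
#' reported as `perfect` (distance 0) or `imperfect`. Reads farther than
#' `maxEdits` from every guide are `unmatched`; reads tied between two or
#' more guides are `ambiguous` and excluded from majority computations.
#'
#' @param seqs Trimmed guide sequences.
#' @param quals Matching trimmed quality strings (Phred+33).
#' @param libSeqs Named character vector of guide sequences; an entry named
#'   `"__empty__"` holding [emptyGuideSequence()] is added when absent.
#' @param minQ Quality floor (default 30).
#' @param maxEdits Maximum edit distance to call a match (default 3).
#' @return data.frame with `outcome` in \{perfect, imperfect, lowquality,
#'   unmatched, ambiguous\}, `guide` and `edits`.
#' @export
matchGuide <- function(seqs, quals, libSeqs, minQ = 30L, maxEdits = 3L) {
  stopifnot(!is.null(names(libSeqs)))
  if (!EMPTY_GUIDE_ID %in% names(libSeqs))
    libSeqs <- c(libSeqs, setNames(emptyGuideSequence(), EMPTY_GUIDE_ID))
  n <- length(seqs)
  outcome <- rep("lowquality", n)
  guide <- rep(NA_character_, n)
  edits <- rep(NA_integer_, n)
  minq <- vapply(quals, function(q) min(.qualInts(q)), integer(1), USE.NAMES = FALSE)
  hq <- which(minq >= minQ)
  if (length(hq)) {
    useqs <- unique(seqs[hq])
    d <- adist(useqs, libSeqs)
    rownames(d) <- useqs
    for (i in hq) {
      di <- d[seqs[i], ]
      m <- min(di)
      if (m > maxEdits) { outcome[i] <- "unmatched"; next }
      best <- which(di == m)
      if (length(best) > 1L) { outcome[i] <- "ambiguous"; next }
      outcome[i] <- if (m == 0L) "perfect" else "imperfect"
      guide[i] <- names(libSeqs)[best]
      edits[i] <- m
    }
  }
  data.frame(outcome = outcome, guide = guide, edits = edits,
             stringsAsFactors = FALSE)
}

# Classify one barcode's high-quality read outcomes into a fate.
.classifyGroup <- function(outcome, guide, edits, minReads = 3L,
                           majorityFrac = 0.9, emptyId = EMPTY_GUIDE_ID) {
  hq <- outcome != "lowquality"
  nHq <- sum(hq)
  if (nHq < minReads) {
    return(list(fate = "insufficient", guide = NA_character_,
                n_hq = nHq, majority_fraction = NA_real_))
  }
  elig <- outcome %in% c("perfect", "imperfect")
  nElig <- sum(elig)
  if (nElig == 0L) {
    return(list(fate = "heterogeneous", guide = NA_character_,
                n_hq = nHq, majority_fraction = 0))
  }
  tab <- sort(table(guide[elig]), decreasing = TRUE)
  frac <- as.numeric(tab[1]) / nElig
  if (frac < majorityFrac || (length(tab) > 1L && tab[1] == tab[2])) {
    return(list(fate = "heterogeneous", guide = NA_character_,
                n_hq = nHq, majority_fraction = frac))
  }
  maj <- names(tab)[1]
  ed <- edits[elig & guide == maj]
  edTab <- sort(table(ed), decreasing = TRUE)
  modal <- as.integer(names(edTab)[edTab == max(edTab)])
  modalEdits <- min(modal)  # tie toward the cleaner alignment
  if (modalEdits > 0L) {
    return(list(fate = "defective", guide = maj,
                n_hq = nHq, majority_fraction = frac))
  }
  fate <- if (maj == emptyId) "empty" else "assigned"
  list(fate = fate, guide = maj, n_hq = nHq, majority_fraction = frac)
}

#' Assign barcodes to guides from grouped read matches
#'
#' Applies the assignment fate rules per collapsed barcode: fewer than
#' `minReads` high-quality reads is `insufficient`; a majority guide
#' fraction below `majorityFrac` is `heterogeneous`; a majority whose modal
#' alignment contains edits is `defective`; otherwise the barcode is
#' `assigned` (or `empty` when the majority matches the scaffold-only
#' entry). Fates are exhaustive and mutually exclusive.
#'
#' @param reads data.frame with one row per read: `barcode`, `outcome`,
#'   `guide`, `edits` (as from [matchGuide()]).
#' @param minReads Minimum high-quality read support (default 3).
#' @param majorityFrac Required majority fraction (default 0.9).
#' @return List with `assignments` (one row per barcode: fate, guide_id,
#'   n_hq, majority_fraction) and `fates` (tally data.frame).
#' @export
assignBarcodes <- function(reads, minReads = 3L, majorityFrac = 0.9) {
  groups <- split(seq_len(nrow(reads)), reads$barcode)
  rows <- lapply(names(groups), function(bc) {
    idx <- groups[[bc]]
    cl <- .classifyGroup(reads$outcome[idx], reads$guide[idx],
                         reads$edits[idx], minReads, majorityFrac)
    data.frame(barcode = bc, fate = cl$fate, guide_id = cl$guide,
               n_hq = cl$n_hq, majority_fraction = cl$majority_fraction,
               stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  lv <- c("assigned", "empty", "defective", "heterogeneous", "insufficient")
  fates <- data.frame(fate = lv,
                      n = as.integer(table(factor(assignments$fate, levels = lv))),
                      stringsAsFactors = FALSE)
  list(assignments = assignments, fates = fates)
}

#' Barcode-to-guide assignment from paired FASTQ
#'
#' Full workflow: trim R1 barcodes at the assignment adapter (>= 12 nt),
#' collapse single-mismatch barcode variants, trim R2 guide sequences
#' (>= 20 nt between the flanking adapters), match guides against the
#' library with the Q30 filter, and classify each collapsed barcode's fate.
#'
#' @param r1Path,r2Path Paired FASTQ files (reads in matching order).
#' @param libSeqs Named character vector guide_id -> guide sequence.
#' @param minBarcodeLen Minimum barcode length (default 12).
#' @param minGuideLen Minimum trimmed guide length (default 20).
#' @param minQ Guide-base quality floor (default 30).
#' @param maxEdits Maximum edit distance for a guide match (default 3).
#' @param minReads Minimum high-quality reads per barcode (default 3).
#' @param majorityFrac Required majority fraction (default 0.9).
#' @return List with `assignments`, `fates` (see [assignBarcodes()]) and
#'   `good` (the assigned/empty subset as barcode -> guide_id).
#' @export
assignGuideReads <- function(r1Path, r2Path, libSeqs,
                             minBarcodeLen = 12L, minGuideLen = 20L,
                             minQ = 30L, maxEdits = 3L, minReads = 3L,
                             majorityFrac = 0.9) {
  r1 <- readFastq(r1Path)
  r2 <- readFastq(r2Path)
  if (nrow(r1) != nrow(r2))
    stop("R1 and R2 have different read counts")
  bc <- trimBarcodeRead(r1$seq, BC_ASSIGN_ADAPTER, minBarcodeLen)
  keep <- !is.na(bc$barcode)
  gd <- trimGuideRead(r2$seq[keep], r2$qual[keep],
                      minLen = minGuideLen)
  ok <- !is.na(gd$guide)
  barcodes <- bc$barcode[keep][ok]
  col <- collapseBarcodes(table(barcodes))
  matches <- matchGuide(gd$guide[ok], gd$gqual[ok], libSeqs,
                        minQ = minQ, maxEdits = maxEdits)
  reads <- data.frame(barcode = unname(col$map[barcodes]), matches,
                      stringsAsFactors = FALSE)
  res <- assignBarcodes(reads, minReads, majorityFrac)
  goodIdx <- res$assignments$fate %in% c("assigned", "empty")
  res$good <- res$assignments[goodIdx, c("barcode", "guide_id")]
  res
}

#' Count barcodes across sequencing libraries
#'
#' Per library: trim reads at the counting adapter and tabulate barcodes.
#' Tables are then collated across libraries and collapsed jointly (on total
#' counts) so that a single representative is used in every library.
#'
#' @param fastqPaths Named character vector of FASTQ paths (names become
#'   sample names).
#' @param adapter 3' adapter (default: the counting adapter).
#' @param minLen Minimum barcode length (default 10).
#' @return List with `counts` (collapsed matrix) and `map`.
#' @export
countBarcodes <- function(fastqPaths, adapter = BC_COUNT_ADAPTER,
                          minLen = 10L) {
  if (is.null(names(fastqPaths)))
    names(fastqPaths) <- paste0("sample", seq_along(fastqPaths))
  tabs <- lapply(fastqPaths, function(p) {
    reads <- readFastq(p)
    bc <- trimBarcodeRead(reads$seq, adapter, minLen)
    table(bc$barcode[!is.na(bc$barcode)])
  })
  all <- sort(unique(unlist(lapply(tabs, names))))
  counts <- vapply(tabs, function(t) {
    v <- integer(length(all)); names(v) <- all
    v[names(t)] <- as.integer(t)
    v
  }, integer(length(all)))
  counts <- matrix(counts, nrow = length(all),
                   dimnames = list(all, names(fastqPaths)))
  collapseBarcodes(counts)
}
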