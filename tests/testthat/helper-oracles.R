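# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths (string scans instead of hash indexes,
# pairwise loops instead of neighbor enumeration, explicit DP instead of
# adist, pair counting instead of ranks).

# Both-strand occurrence count via Biostrings pattern matching.
oracleCountKmer <- function(seqs, kmer) {
  subject <- Biostrings::DNAStringSet(seqs)
  fwd <- sum(Biostrings::vcountPattern(kmer, subject, fixed = TRUE))
  rcp <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(kmer)))
  rev <- sum(Biostrings::vcountPattern(rcp, subject, fixed = TRUE))
  fwd + rev
}

revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Brute-force candidate enumeration: test every 23-mer window on both
# strands for the NGG suffix and the center-offset window.
oracleEnumerate <- function(seq, anchor, strand, mode) {
  win <- if (mode == "TSS") c(-220, 20) else c(-350, 0)
  dir <- if (strand == "+") 1 else -1
  L <- nchar(seq)
  out <- list()
  for (s0 in 0:(L - 23)) {               # 0-based window start
    target <- substr(seq, s0 + 1, s0 + 23)
    center <- s0 + 11
    off <- dir * (center - anchor)
    if (off < win[1] || off > win[2]) next
    if (grepl("N", target, fixed = TRUE)) next
    if (substr(target, 22, 23) == "GG") {
      out[[length(out) + 1]] <- data.frame(
        start0 = s0, strand = "+", center_offset = off,
        protospacer = substr(target, 1, 20), pam = substr(target, 21, 23))
    }
    if (substr(target, 1, 2) == "CC") {
      rc <- revcompChr(target)
      out[[length(out) + 1]] <- data.frame(
        start0 = s0, strand = "-", center_offset = off,
        protospacer = substr(rc, 1, 20), pam = substr(rc, 21, 23))
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Reference guide selection: repeated argmax under explicit pairwise
# comparison, zone guarantee first, then fill.
oracleSelect <- function(cands, mode, maxGuides = 10) {
  zones <- if (mode == "TSS") {
    list(c(-220, -141), c(-140, -61), c(-60, 20))
  } else {
    list(c(-350, -271), c(-270, -191), c(-190, -111), c(-110, -30))
  }
  better <- function(a, b) {  # TRUE when candidate a outranks candidate b
    ka <- c(-a$unique, -a$specific, -a$accessibility,
            abs(a$center_offset + 50), a$start0, a$strand != "+")
    kb <- c(-b$unique, -b$specific, -b$accessibility,
            abs(b$center_offset + 50), b$start0, b$strand != "+")
    d <- ka - kb
    nz <- which(d != 0)
    if (!length(nz)) FALSE else d[nz[1]] < 0
  }
  argbest <- function(idx) {
    best <- idx[1]
    for (i in idx[-1]) {
      if (better(cands[i, ], cands[best, ])) best <- i
    }
    best
  }
  picked <- integer(0)
  for (z in zones) {
    idx <- setdiff(which(cands$center_offset >= z[1] &
                           cands$center_offset <= z[2]), picked)
    if (length(idx)) picked <- c(picked, argbest(idx))
    if (length(picked) >= maxGuides) break
  }
  while (length(picked) < maxGuides) {
    idx <- setdiff(seq_len(nrow(cands)), picked)
    if (!length(idx)) break
    picked <- c(picked, argbest(idx))
  }
  picked
}

# Exhaustive greedy Hamming-1 clustering by pairwise comparison.
oracleCollapse <- function(counts) {
  hamm <- function(a, b) {
    if (nchar(a) != nchar(b)) return(Inf)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  bcs <- names(sort(counts, decreasing = TRUE))
  bcs <- bcs[order(-counts[bcs], bcs)]
  rep <- setNames(character(length(bcs)), bcs)
  founders <- character(0)
  for (bc in bcs) {
    near <- founders[vapply(founders, function(f) hamm(bc, f) == 1, logical(1))]
    if (length(near)) {
      near <- near[order(-counts[near], near)]
      rep[bc] <- near[1]
    } else {
      founders <- c(founders, bc)
      rep[bc] <- bc
    }
  }
  tapply(counts[names(rep)], rep, sum)
}

# Textbook Levenshtein DP.
oracleLevenshtein <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  m <- length(a); n <- length(b)
  d <- matrix(0L, m + 1, n + 1)
  d[, 1] <- 0:m; d[1, ] <- 0:n
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (a[i] != b[j]))
    }
  }
  d[m + 1, n + 1]
}

# Direct rule-table fate classifier over per-read (guide, edits) pairs.
# lowquality reads are NA guide with NA edits and hq = FALSE.
oracleFate <- function(hq, guide, edits, emptyId = "__empty__") {
  if (sum(hq) < 3) return("insufficient")
  ok <- hq & !is.na(guide)
  if (!sum(ok)) return("heterogeneous")
  tab <- table(guide[ok])
  top <- max(tab)
  if (sum(tab == top) > 1) return("heterogeneous")
  maj <- names(tab)[which.max(tab)]
  if (top / sum(ok) < 0.9) return("heterogeneous")
  ed <- edits[ok & guide == maj]
  et <- table(ed)
  modal <- min(as.integer(names(et)[et == max(et)]))
  if (modal > 0) return("defective")
  if (maj == emptyId) "empty" else "assigned"
}

# All-pairs concordance AUC (ties count half).
oracleAuc <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Sort-based 5th percentile with linear interpolation (type-7 arithmetic
# done by hand on the sorted values).
oracleQuantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Closed-form log-linear least squares of log(count/sf) on gens (+ culture).
oracleLogLinearSlope <- function(y, gens, culture, sf) {
  d <- data.frame(ly = log(y / sf), gens = gens, culture = factor(culture))
  f <- if (nlevels(d$culture) > 1) ly ~ gens + culture else ly ~ gens
  unname(coef(lm(f, data = d))["gens"]) / log(2)
}
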