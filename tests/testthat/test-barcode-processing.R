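# Read trimming, barcode collapsing, count filtering, guide matching and
# assignment fate rules.

ADAPTER <- "GCATGCGTGAAGTGGCGCGCCTGATA"

test_that("barcode trimming keeps the sequence 5' of the adapter", {
  r <- trimBarcodeRead(paste0("ACGTACGTACGT", ADAPTER, "TTTT"))
  expect_equal(r$barcode, "ACGTACGTACGT")
  expect_true(is.na(r$reason))
  # missing adapter
  r2 <- trimBarcodeRead("ACGTACGTACGTACGTACGT")
  expect_true(is.na(r2$barcode))
  expect_equal(r2$reason, "no_adapter")
  # 9-nt residual with min 10
  r3 <- trimBarcodeRead(paste0("ACGTACGTA", ADAPTER), minLen = 10)
  expect_equal(r3$reason, "too_short")
  # 10-nt residual kept
  r4 <- trimBarcodeRead(paste0("ACGTACGTAC", ADAPTER), minLen = 10)
  expect_equal(r4$barcode, "ACGTACGTAC")
})

test_that("single-mismatch collapsing absorbs into the larger record", {
  col <- collapseBarcodes(c(AAAAAAAAAA = 10L, AAAAAAAAAT = 2L))
  expect_equal(nrow(col$counts), 1L)
  expect_equal(rownames(col$counts), "AAAAAAAAAA")
  expect_equal(unname(col$counts[1, 1]), 12L)
  # Hamming distance 2: two records
  col2 <- collapseBarcodes(c(AAAAAAAAAA = 10L, AAAAAAAACC = 2L))
  expect_equal(nrow(col2$counts), 2L)
  # different lengths never collapse
  col3 <- collapseBarcodes(c(AAAAAAAAAA = 10L, AAAAAAAAA = 2L))
  expect_equal(nrow(col3$counts), 2L)
})

test_that("collapsing matches exhaustive Hamming-1 clustering on random sets", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(50:120, 1)
    core <- vapply(seq_len(max(8, n %/% 6)), function(i)
      paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = ""),
      character(1))
    # derive variants of the cores so that distance-1 pairs are common
    bcs <- unique(c(core, vapply(seq_len(n), function(i) {
      b <- strsplit(sample(core, 1), "")[[1]]
      p <- sample(8, 1)
      b[p] <- sample(c("A", "C", "G", "T"), 1)
      paste(b, collapse = "")
    }, character(1))))
    counts <- setNames(sample(1:100, length(bcs), TRUE), bcs)
    got <- collapseBarcodes(counts)
    want <- oracleCollapse(counts)
    expect_equal(sort(rownames(got$counts)), sort(names(want)))
    expect_equal(got$counts[names(want), 1], unname(want)[match(names(want), names(want))],
                 ignore_attr = TRUE)
    # count conservation and idempotence
    expect_equal(sum(got$counts), sum(counts))
    again <- collapseBarcodes(got$counts)
    expect_equal(again$counts, got$counts)
  }
})

test_that("count-table filtering applies library, total and motif rules", {
  counts <- rbind(
    onelib = c(40L, 0L, 0L, 0L),     # one library only
    low = c(10L, 10L, 6L, 6L),       # total 32 < 33
    xhoi = c(20L, 20L, 20L, 20L),    # carries the forbidden site
    keep = c(10L, 10L, 7L, 6L))      # total 33, 4 libraries
  rownames(counts) <- c("AAAAAAAAAA", "CCCCCCCCCC",
                        paste0("AA", "CTCGAG", "AA"), "GGGGGGGGGG")
  out <- filterCountTable(counts)
  expect_equal(rownames(out), "GGGGGGGGGG")
  # boundary: total exactly 33 in exactly 2 libraries is kept
  b <- matrix(c(17L, 16L, 0L, 0L), 1,
              dimnames = list("TTTTTTTTTT", NULL))
  expect_equal(nrow(filterCountTable(b)), 1L)
})

test_that("guide trimming requires both adapters and 20 residual bases", {
  guide20 <- paste(rep("ACGT", 5), collapse = "")
  read <- paste0("TTG", "CGAAAC", guide20, "AAGTTAAAAT", "CC")
  qual <- paste(rep("I", nchar(read)), collapse = "")
  r <- trimGuideRead(read, qual)
  expect_equal(r$guide, guide20)
  expect_equal(nchar(r$gqual), 20L)
  # 19-nt residual rejected
  r19 <- trimGuideRead(paste0("CGAAAC", substr(guide20, 1, 19), "AAGTTAAAAT"),
                       paste(rep("I", 35), collapse = ""))
  expect_equal(r19$reason, "too_short")
  # missing 3' adapter rejected
  rna <- trimGuideRead(paste0("CGAAAC", guide20), paste(rep("I", 26), collapse = ""))
  expect_equal(rna$reason, "no_adapter3")
})

test_that("guide matching enforces Q30 and reports edit distances", {
  lib <- c(gA = "ACGTACGTACGTACGTACGT", gB = "TTTTGGGGCCCCAAAATTTT")
  q37 <- function(n) paste(rep("F", n), collapse = "")  # Phred 37
  m <- matchGuide(lib[["gA"]], q37(20), lib)
  expect_equal(m$outcome, "perfect")
  expect_equal(m$guide, "gA")
  # one substitution: imperfect with 1 edit
  sub1 <- paste0("CCGTACGTACGTACGTACGT")
  m1 <- matchGuide(sub1, q37(20), lib)
  expect_equal(m1$outcome, "imperfect")
  expect_equal(m1$edits, 1L)
  # any base below Q30 discards the read (Phred 29 = '>')
  qbad <- paste0(">", paste(rep("F", 19), collapse = ""))
  expect_equal(matchGuide(lib[["gA"]], qbad, lib)$outcome, "lowquality")
  # far from every guide: unmatched
  far <- paste(rep("AC", 10), collapse = "")
  expect_equal(matchGuide("GGGGGGGGGGGGGGGGGGGG", q37(20), lib)$outcome,
               "unmatched")
})

test_that("edit distances agree with an independent DP implementation", {
  set.seed(31)
  lib <- setNames(vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""),
    character(1)), paste0("g", 1:6))
  q37 <- paste(rep("F", 25), collapse = "")
  for (i in 1:25) {
    base <- sample(lib, 1)
    s <- strsplit(base, "")[[1]]
    nEdit <- sample(0:3, 1)
    for (e in seq_len(nEdit)) {
      op <- sample(c("sub", "del", "ins"), 1)
      p <- sample(length(s), 1)
      if (op == "sub") s[p] <- sample(c("A", "C", "G", "T"), 1)
      else if (op == "del" && length(s) > 18) s <- s[-p]
      else s <- append(s, sample(c("A", "C", "G", "T"), 1), p)
    }
    seq <- paste(s, collapse = "")
    m <- matchGuide(seq, substr(q37, 1, nchar(seq)), lib)
    dists <- vapply(c(lib, "__empty__" = emptyGuideSequence()),
                    function(g) oracleLevenshtein(seq, g), numeric(1))
    if (m$outcome %in% c("perfect", "imperfect")) {
      expect_equal(m$edits, unname(min(dists)))
      expect_equal(unname(dists[m$guide]), m$edits)
      expect_equal(sum(dists == min(dists)), 1L)
    } else if (m$outcome == "unmatched") {
      expect_gt(min(dists), 3)
    } else {
      expect_gt(sum(dists == min(dists)), 1L)
    }
  }
})

test_that("assignment fate rules follow the support/majority/perfection table", {
  mkReads <- function(outcomes, guides, edits) {
    data.frame(barcode = "BC", outcome = outcomes, guide = guides,
               edits = edits, stringsAsFactors = FALSE)
  }
  # 2 HQ reads -> insufficient
  r <- assignBarcodes(mkReads(c("perfect", "perfect"), c("gA", "gA"), c(0L, 0L)))
  expect_equal(r$assignments$fate, "insufficient")
  # 10 reads, 8 to guide A -> heterogeneous (0.8 < 0.9)
  r2 <- assignBarcodes(mkReads(rep("perfect", 10),
                               c(rep("gA", 8), rep("gB", 2)), rep(0L, 10)))
  expect_equal(r2$assignments$fate, "heterogeneous")
  # 5 perfect reads -> assigned
  r3 <- assignBarcodes(mkReads(rep("perfect", 5), rep("gA", 5), rep(0L, 5)))
  expect_equal(r3$assignments$fate, "assigned")
  expect_equal(r3$assignments$guide_id, "gA")
  # 5 reads with the same 1-nt deletion -> defective
  r4 <- assignBarcodes(mkReads(rep("imperfect", 5), rep("gA", 5), rep(1L, 5)))
  expect_equal(r4$assignments$fate, "defective")
  # scaffold-only majority -> empty, with the guide id retained
  r5 <- assignBarcodes(mkReads(rep("perfect", 4), rep("__empty__", 4), rep(0L, 4)))
  expect_equal(r5$assignments$fate, "empty")
  expect_equal(r5$assignments$guide_id, "__empty__")
  # a lone sequencing error does not flip an otherwise perfect barcode
  r6 <- assignBarcodes(mkReads(c(rep("perfect", 4), "imperfect"),
                               rep("gA", 5), c(rep(0L, 4), 1L)))
  expect_equal(r6$assignments$fate, "assigned")
})

test_that("fates agree with the brute-force classifier on an exhaustive grid", {
  # all combinations of read count, majority split and majority perfection
  for (n in 1:12) {
    for (nMaj in 0:n) {
      for (perfect in c(TRUE, FALSE)) {
        outcomes <- c(rep(if (perfect) "perfect" else "imperfect", nMaj),
                      rep("perfect", n - nMaj))
        guides <- c(rep("gA", nMaj), rep("gB", n - nMaj))
        edits <- c(rep(if (perfect) 0L else 1L, nMaj), rep(0L, n - nMaj))
        reads <- data.frame(barcode = "BC", outcome = outcomes,
                            guide = guides, edits = edits,
                            stringsAsFactors = FALSE)
        got <- assignBarcodes(reads)$assignments$fate
        want <- oracleFate(rep(TRUE, n), guides, edits)
        expect_equal(got, want, info = sprintf("n=%d nMaj=%d perf=%d",
                                               n, nMaj, perfect))
      }
    }
  }
})

test_that("fates partition the barcodes and tallies sum to the total", {
  set.seed(41)
  reads <- data.frame(
    barcode = sample(paste0("BC", 1:40), 400, TRUE),
    outcome = sample(c("perfect", "imperfect", "lowquality", "unmatched"),
                     400, TRUE, c(0.6, 0.2, 0.1, 0.1)),
    guide = sample(c("gA", "gB", "__empty__"), 400, TRUE),
    edits = sample(0:2, 400, TRUE), stringsAsFactors = FALSE)
  reads$guide[!reads$outcome %in% c("perfect", "imperfect")] <- NA
  reads$edits[!reads$outcome %in% c("perfect", "imperfect")] <- NA
  reads$edits[reads$outcome == "perfect"] <- 0L
  reads$edits[reads$outcome == "imperfect"] <-
    pmax(1L, reads$edits[reads$outcome == "imperfect"])
  res <- assignBarcodes(reads)
  expect_equal(sum(res$fates$n), length(unique(reads$barcode)))
  expect_equal(nrow(res$assignments), length(unique(reads$barcode)))
  expect_false(any(is.na(res$assignments$fate)))
})

test_that("noise-free assignment reads are recovered perfectly end to end", {
  set.seed(51)
  lib <- setNames(vapply(1:12, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""),
    character(1)), sprintf("g%02d", 1:12))
  spec <- simScreenSpec(nGuides = 12, synthErrorRate = 0, chimeraRate = 0,
                        emptyFraction = 0.05, seqErrorRate = 0,
                        lowQualRate = 0, seed = 8)
  sim <- simulateAssignmentReads(lib, spec, dir = tempdir())
  res <- assignGuideReads(sim$r1, sim$r2, lib)
  truth <- sim$truth
  got <- res$assignments
  m <- merge(truth, got, by = "barcode")
  expect_equal(nrow(m), nrow(truth))
  expect_true(all(m$fate[m$type == "clean"] == "assigned"))
  expect_true(all(m$fate[m$type == "empty"] == "empty"))
  expect_equal(m$guide_id.y[m$type == "clean"], m$guide_id.x[m$type == "clean"])
  expect_equal(sort(res$good$barcode), sort(truth$barcode))
})

test_that("FASTQ round trip preserves sequences and qualities", {
  reads <- data.frame(id = c("r1", "r2"),
                      seq = c("ACGTACGT", "TTTTCCCC"),
                      qual = c("FFFF::FF", "IIIIIIII"))
  path <- tempfile(fileext = ".fastq")
  writeFastq(reads, path)
  back <- readFastq(path)
  expect_equal(back$seq, reads$seq)
  expect_equal(back$qual, reads$qual)
})
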