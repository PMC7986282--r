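# Candidate enumeration, uniqueness/specificity, accessibility scoring,
# priority selection and divergent-promoter resolution.

mkGene <- function(id = "g1", chrom = "chr", strand = "+", cds = c(600L, 900L),
                   tss = NA_integer_) {
  data.frame(gene_id = id, chrom = chrom, strand = strand,
             cds_start = cds[1], cds_end = cds[2], tss = tss,
             essential = NA, mode = ifelse(is.na(tss), "CDS", "TSS"),
             stringsAsFactors = FALSE)
}

randSeq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

test_that("enumeration matches the brute-force scan in both anchor modes", {
  for (seed in 1:4) {
    seq <- randSeq(1500, seed)
    gn <- crisprGenome(c(chr = seq))
    for (mode in c("TSS", "CDS")) {
      gene <- if (mode == "TSS") mkGene(tss = 700L) else mkGene()
      got <- enumerateCandidates(gn, gene)
      anchor <- if (mode == "TSS") 700L else 600L
      want <- oracleEnumerate(seq, anchor, "+", mode)
      key <- function(d) sort(paste(d$start0, d$strand, d$protospacer, d$pam,
                                    d$center_offset))
      expect_equal(key(got), key(want), info = paste(mode, seed))
    }
  }
})

test_that("enumeration honors strand direction on minus-strand genes", {
  seq <- randSeq(1500, 9)
  gn <- crisprGenome(c(chr = seq))
  gene <- mkGene(strand = "-", cds = c(300L, 600L), tss = 650L)
  got <- enumerateCandidates(gn, gene)
  want <- oracleEnumerate(seq, 650L, "-", "TSS")
  expect_equal(sort(paste(got$start0, got$strand, got$center_offset)),
               sort(paste(want$start0, want$strand, want$center_offset)))
  expect_true(all(got$center_offset >= -220 & got$center_offset <= 20))
})

test_that("a promoter with no GG or CC dinucleotides yields no candidates", {
  seq <- paste(rep("AT", 600), collapse = "")
  gn <- crisprGenome(c(chr = seq))
  expect_equal(nrow(enumerateCandidates(gn, mkGene(tss = 700L))), 0L)
})

test_that("the TSS association window is inclusive at both edges", {
  # plant a plus-strand PAM site with target center exactly at offset -220:
  # with TSS t, center c = t - 220; GG must sit at c+10, c+11.
  base <- strsplit(randSeq(1200, 21), "")[[1]]
  base[base == "G"] <- "A"  # remove stray PAMs
  tss <- 800L
  cen <- tss - 220L
  base[(cen + 10L):(cen + 11L) + 1L] <- "G"
  gn1 <- crisprGenome(c(chr = paste(base, collapse = "")))
  got <- enumerateCandidates(gn1, mkGene(tss = tss))
  expect_true(-220L %in% got$center_offset)

  # shift the same site one base upstream: center offset -221, excluded
  base2 <- strsplit(randSeq(1200, 21), "")[[1]]
  base2[base2 == "G"] <- "A"
  cen2 <- tss - 221L
  base2[(cen2 + 10L):(cen2 + 11L) + 1L] <- "G"
  gn2 <- crisprGenome(c(chr = paste(base2, collapse = "")))
  got2 <- enumerateCandidates(gn2, mkGene(tss = tss))
  expect_false(any(got2$center_offset < -220L))
  expect_false(any(got2$start0 == cen2 - 11L & got2$strand == "+"))
})

test_that("uniqueness counts perfect occurrences over both strands and PAM Ns", {
  proto <- "ACGTTACGGATCCATTGACA"
  site1 <- paste0(proto, "TGG")
  spacer <- function(n, seed) randSeq(n, seed)
  # single site: unique
  gn <- crisprGenome(c(chr = paste0(spacer(50, 31), site1, spacer(50, 32))))
  expect_true(classifyUniqueness(gn, proto))
  # second copy with a different PAM N base: non-unique
  site2 <- paste0(proto, "CGG")
  gn2 <- crisprGenome(c(chr = paste0(spacer(50, 31), site1, spacer(50, 32),
                                     site2, spacer(30, 33))))
  expect_false(classifyUniqueness(gn2, proto))
  # second copy on the reverse strand: non-unique
  gn3 <- crisprGenome(c(chr = paste0(spacer(50, 31), site1, spacer(50, 32),
                                     revcompChr(site2), spacer(30, 33))))
  expect_false(classifyUniqueness(gn3, proto))
  # the reverse-strand copy alone is still one perfect site
  gn4 <- crisprGenome(c(chr = paste0(spacer(50, 31), revcompChr(site1),
                                     spacer(50, 32))))
  expect_true(classifyUniqueness(gn4, proto))
})

test_that("specificity labels match an exhaustive all-genes window test", {
  seq <- randSeq(3000, 41)
  gn <- crisprGenome(c(chr = seq))
  # divergent pair: minus-strand gene with TSS 900, plus-strand gene TSS 1080
  gA <- mkGene("gA", strand = "-", cds = c(400L, 850L), tss = 900L)
  gB <- mkGene("gB", strand = "+", cds = c(1150L, 1600L), tss = 1080L)
  genes <- rbind(gA, gB)
  cands <- rbind(enumerateCandidates(gn, gA), enumerateCandidates(gn, gB))
  got <- classifySpecificity(cands, genes)
  inWin <- function(center, g) {
    dir <- if (g$strand == "+") 1 else -1
    off <- dir * (center - g$tss)
    off >= -220 && off <= 20
  }
  for (i in seq_len(nrow(got))) {
    n <- inWin(got$center0[i], gA) + inWin(got$center0[i], gB)
    expect_equal(got$specific[i], n == 1L)
    if (!got$specific[i]) {
      expect_equal(got$alt_targets[i],
                   setdiff(c("gA", "gB"), got$gene_id[i]))
    }
  }
  # shared region between the TSSs contains ambiguous guides
  expect_true(any(!got$specific))
  # a center at -100 from one TSS and inside the partner window is ambiguous
  amb <- got[!got$specific, ]
  expect_true(all(amb$alt_targets != ""))
})

test_that("accessibility is the mean over target positions and replicates", {
  gn <- crisprGenome(c(chr = randSeq(200, 51)))
  v1 <- runif(200); v2 <- runif(200)
  t1 <- accessibilityTrack(list(chr = v1), "accessibility")
  t2 <- accessibilityTrack(list(chr = v2), "accessibility")
  # positionwise hand computation for span [60, 83)
  byHand <- mean(c(mean(v1[61:83]), mean(v2[61:83])))
  expect_equal(scoreAccessibility(list(t1, t2), "chr", 60, 83), byHand)
  # uniform 1.0 -> 1.0
  u <- accessibilityTrack(list(chr = rep(1, 200)), "accessibility")
  expect_equal(scoreAccessibility(list(u), "chr", 60, 83), 1)
  # no data -> 0
  nd <- accessibilityTrack(list(chr = rep(NA_real_, 200)), "accessibility")
  expect_equal(scoreAccessibility(list(nd), "chr", 60, 83), 0)
  expect_error(scoreAccessibility(list(accessibilityTrack(list(chr = v1),
                                                          "occupancy")),
                                  "chr", 60, 83), "accessibility")
})

randCandSet <- function(n, mode, seed) {
  set.seed(seed)
  win <- if (mode == "TSS") c(-220L, 20L) else c(-350L, 0L)
  data.frame(gene_id = "g", chrom = "chr",
             strand = sample(c("+", "-"), n, TRUE),
             start0 = sample(1:5000, n),
             end0 = 0L, center0 = 0L,
             center_offset = sample(win[1]:win[2], n, TRUE),
             protospacer = vapply(seq_len(n), function(i)
               paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""),
               character(1)),
             pam = "AGG",
             unique = sample(c(TRUE, FALSE), n, TRUE, c(0.8, 0.2)),
             specific = sample(c(TRUE, FALSE), n, TRUE, c(0.8, 0.2)),
             # coarse grid so accessibility ties are frequent
             accessibility = sample(seq(0, 1, 0.25), n, TRUE),
             stringsAsFactors = FALSE)
}

test_that("selection equals the reference procedure on randomized sets", {
  for (seed in 1:200) {
    mode <- if (seed %% 2) "TSS" else "CDS"
    cands <- randCandSet(sample(1:40, 1), mode, seed)
    sel <- selectGuides(cands, mode)
    want <- oracleSelect(cands, mode)
    expect_equal(nrow(sel), length(want))
    expect_equal(paste(sel$start0, sel$strand),
                 paste(cands$start0[want], cands$strand[want]),
                 info = paste("seed", seed))
  }
})

test_that("selection guarantees zone coverage and caps at ten", {
  set.seed(77)
  cands <- randCandSet(30, "TSS", 301)
  sel <- selectGuides(cands, "TSS")
  expect_equal(nrow(sel), 10L)
  expect_equal(sel$rank, 1:10)
  expect_false(any(duplicated(paste(sel$start0, sel$strand))))
  # each nonempty zone is represented in the selection
  zones <- list(c(-220, -141), c(-140, -61), c(-60, 20))
  for (z in seq_along(zones)) {
    hasCand <- any(cands$center_offset >= zones[[z]][1] &
                     cands$center_offset <= zones[[z]][2])
    if (hasCand) expect_true(z %in% sel$zone)
  }
  # single candidate: selection of size 1
  one <- randCandSet(1, "TSS", 302)
  expect_equal(nrow(selectGuides(one, "TSS")), 1L)
  # empty: empty selection
  empty <- randCandSet(2, "TSS", 303)[0, ]
  expect_equal(nrow(selectGuides(empty, "TSS")), 0L)
})

test_that("no selected guide is dominated by an unselected candidate beyond zone picks", {
  prio <- function(d) order(!d$unique, !d$specific, -d$accessibility,
                            abs(d$center_offset + 50), d$start0,
                            d$strand != "+")
  zones <- list(c(-220, -141), c(-140, -61), c(-60, 20))
  for (seed in 401:420) {
    cands <- randCandSet(25, "TSS", seed)
    sel <- selectGuides(cands, "TSS")
    ranks <- prio(cands)
    key <- function(d) paste(d$start0, d$strand)
    # the first k ranked selections are the per-zone guarantees
    k <- sum(vapply(zones, function(z)
      any(cands$center_offset >= z[1] & cands$center_offset <= z[2]),
      logical(1)))
    filler <- sel[sel$rank > k, , drop = FALSE]
    unsel <- cands[!key(cands) %in% key(sel), , drop = FALSE]
    if (nrow(unsel) && nrow(filler)) {
      prioPos <- match(key(cands)[ranks], key(cands))
      fillerRank <- match(match(key(filler), key(cands)), prioPos)
      unselRank <- match(match(key(unsel), key(cands)), prioPos)
      expect_true(max(fillerRank) < min(unselRank))
    }
  }
})

test_that("designed libraries are deterministic and respect the windows", {
  sim <- simulateGenome(simGenomeSpec(nGenes = 12, seed = 21))
  lib1 <- designGuides(sim$genome, sim$genes, sim$atac)
  lib2 <- designGuides(sim$genome, sim$genes, sim$atac)
  expect_identical(guides(lib1), guides(lib2))
  g <- guides(lib1)
  expect_true(all(table(g$gene_id) <= 10))
  tssGenes <- sim$genes$gene_id[sim$genes$mode == "TSS"]
  gt <- g[g$gene_id %in% tssGenes, ]
  expect_true(all(gt$center_offset >= -220 & gt$center_offset <= 20))
  gc <- g[!g$gene_id %in% tssGenes, ]
  expect_true(all(gc$center_offset >= -350 & gc$center_offset <= 0))
  # zone picks lie in their zones
  zones <- list(c(-220, -141), c(-140, -61), c(-60, 20))
  for (i in which(!is.na(gt$zone))) {
    z <- zones[[gt$zone[i]]]
    expect_true(gt$center_offset[i] >= z[1] && gt$center_offset[i] <= z[2])
  }
})

test_that("guide library TSV round trip preserves the table", {
  sim <- simulateGenome(simGenomeSpec(nGenes = 8, seed = 22))
  lib <- designGuides(sim$genome, sim$genes, sim$atac)
  path <- tempfile(fileext = ".tsv")
  writeGuideLibrary(lib, path)
  back <- guides(readGuideLibrary(path))
  orig <- guides(lib)
  expect_equal(back$guide_id, orig$guide_id)
  expect_equal(back$start0, orig$start0)
  expect_equal(back$protospacer, orig$protospacer)
  expect_equal(back$alt_targets, orig$alt_targets)
  expect_equal(back$accessibility, round(orig$accessibility, 6))
})

test_that("divergent targets resolve by predicted activity with a margin", {
  # monotone-peaked curve: strongly active near -50, inactive far upstream
  set.seed(91)
  off <- rep(-220:20, 3)
  fit <- -0.9 * exp(-((off + 50)^2) / (2 * 40^2)) + rnorm(length(off), 0, 0.02)
  curve <- fitPositionCurve(off, fit)
  # offsets -50 (gene A) vs -215 (gene B): curve peaked near -50 -> A
  expect_equal(resolveDivergentTargets(c(A = -50, B = -215), curve), "A")
  # equal offsets -> equal predictions -> unresolved
  expect_true(is.na(resolveDivergentTargets(c(A = -120, B = -120), curve)))
  # outside the window counts as inactive
  expect_equal(resolveDivergentTargets(c(A = -60, B = -500), curve), "A")
  # assignment matches argmax computed by direct evaluation
  for (i in 1:20) {
    oA <- sample(-220:20, 1); oB <- sample(-220:20, 1)
    got <- resolveDivergentTargets(c(A = oA, B = oB), curve, margin = 2)
    act <- pmax(0, -predictCurve(curve, c(oA, oB)))
    want <- if (max(act) > 0 && max(act) >= 2 * min(act) && act[1] != act[2]) {
      c("A", "B")[which.max(act)]
    } else NA_character_
    expect_equal(got, want)
  }
})
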