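# Synthetic-data generators: genomes with divergent promoters and
# accessibility tracks, barcoded assignment read libraries with synthesis
# errors and chimeras, and exponential competitive-growth count tables.

#' Specification for a synthetic genome
#'
#' Defaults emulate a compact yeast-like genome: genes packed on one
#' chromosome, a configurable fraction arranged as divergent pairs whose
#' TSSs share an intergenic region of a few hundred base pairs, per-gene
#' TSS isoform tables, and replicate accessibility plus occupancy tracks
#' with a nucleosome-free region extending ~150 bp upstream of each TSS.
#'
#' @param nGenes Number of genes (default 50).
#' @param fractionDivergent Fraction of genes arranged in divergent pairs
#'   (default 0.4).
#' @param divergentGap Range of TSS-to-TSS distances within a divergent
#'   pair, in bp (default c(200, 600)).
#' @param tandemGap Range of gaps between independent gene units (default
#'   c(700, 1100)).
#' @param tssOffset Range of TSS-to-CDS-start distances (default c(40, 120)).
#' @param cdsLength Range of CDS lengths (default c(300, 900)).
#' @param fractionCdsMode Fraction of genes with no isoform evidence, left
#'   in CDS-anchored design mode (default 0.15).
#' @param fractionEssential Fraction flagged essential (default 0.35).
#' @param gc GC content of the random sequence (default 0.38, yeast-like).
#' @param seed RNG seed.
#' @return A list spec for [simulateGenome()].
#' @export
simGenomeSpec <- function(nGenes = 50L, fractionDivergent = 0.4,
                          divergentGap = c(200L, 600L),
                          tandemGap = c(700L, 1100L),
                          tssOffset = c(40L, 120L),
                          cdsLength = c(300L, 900L),
                          fractionCdsMode = 0.15,
                          fractionEssential = 0.35,
                          gc = 0.38, seed = 1L) {
  stopifnot(nGenes >= 1L, fractionDivergent >= 0, fractionDivergent <= 1)
  as.list(environment())
}

#' Simulate a genome with annotation and chromatin tracks
#'
#' Deterministic under the spec seed. Divergent pairs place two genes
#' head-to-head with their promoters in a shared intergenic region, so
#' guides in the overlap are ambiguous. Accessibility is high (and
#' occupancy low) over \[-150, 0\] upstream of each TSS, emulating the
#' nucleosome-free region of active promoters; elsewhere the genome is
#' mostly closed. Two replicate accessibility tracks carry independent
#' jitter.
#'
#' @param spec A [simGenomeSpec()] list.
#' @return List: `genome` ([CrisprGenome-class]), `genes` (gene table with
#'   TSS annotation applied), `tss` (isoform table), `atac` (list of two
#'   accessibility tracks), `occupancy` (occupancy track).
#' @export
simulateGenome <- function(spec = simGenomeSpec()) {
  .withSeed(spec$seed, {
    nDivPairs <- floor(spec$nGenes * spec$fractionDivergent / 2)
    layout <- list()
    cursor <- 400L  # leading margin
    gi <- 0L
    mkGene <- function(strand, cdsStart, cdsEnd, tssPos) {
      gi <<- gi + 1L
      data.frame(gene_id = sprintf("GENE%03d", gi), chrom = "chrS",
                 strand = strand, cds_start = cdsStart, cds_end = cdsEnd,
                 tssTrue = tssPos, stringsAsFactors = FALSE)
    }
    rint <- function(rng) sample(rng[1]:rng[2], 1L)
    while (gi < spec$nGenes) {
      if (length(layout) < nDivPairs && gi + 1L < spec$nGenes) {
        # divergent pair: minus-strand gene, shared promoter, plus-strand gene
        lenA <- rint(spec$cdsLength); lenB <- rint(spec$cdsLength)
        offA <- rint(spec$tssOffset); offB <- rint(spec$tssOffset)
        gap <- rint(spec$divergentGap)  # TSS-to-TSS distance
        aEnd <- cursor + lenA           # gene A on '-': CDS [cursor, aEnd)
        tssA <- aEnd - 1L + offA
        tssB <- tssA + gap
        bStart <- tssB + offB
        layout[[length(layout) + 1L]] <-
          rbind(mkGene("-", cursor, aEnd, tssA),
                mkGene("+", bStart, bStart + lenB, tssB))
        cursor <- bStart + lenB + rint(spec$tandemGap)
      } else {
        len <- rint(spec$cdsLength); off <- rint(spec$tssOffset)
        tss <- cursor
        cdsStart <- tss + off
        layout[[length(layout) + 1L]] <-
          mkGene("+", cdsStart, cdsStart + len, tss)
        cursor <- cdsStart + len + rint(spec$tandemGap)
      }
    }
    genes <- do.call(rbind, layout)
    L <- cursor + 400L
    seq <- .randomDna(1L, L, gc = spec$gc)
    genome <- crisprGenome(c(chrS = seq))

    # isoform table: modal TSS plus up to two minor isoforms per gene
    cdsMode <- runif(nrow(genes)) < spec$fractionCdsMode
    tssRows <- list()
    for (i in seq_len(nrow(genes))) {
      if (cdsMode[i]) next
      g <- genes[i, ]
      dirg <- if (g$strand == "+") 1L else -1L
      nMinor <- sample(0:2, 1L)
      minor <- g$tssTrue - dirg * sample(5:30, nMinor)
      tssRows[[length(tssRows) + 1L]] <- data.frame(
        gene_id = g$gene_id, chrom = g$chrom,
        position = c(g$tssTrue, minor),
        count = c(100L + sample(0:200, 1L),
                  if (nMinor) sample(1:60, nMinor) else integer(0)),
        stringsAsFactors = FALSE)
    }
    tss <- if (length(tssRows)) do.call(rbind, tssRows) else
      data.frame(gene_id = character(0), chrom = character(0),
                 position = integer(0), count = integer(0))

    # chromatin: closed baseline, nucleosome-free region over [-150, 0]
    base <- rep(0.05, L)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      dirg <- if (g$strand == "+") 1L else -1L
      nfr <- sort(c(g$tssTrue, g$tssTrue - dirg * 150L))
      idx <- max(nfr[1], 0L):min(nfr[2], L - 1L) + 1L
      base[idx] <- pmax(base[idx], 0.85)
    }
    jitterTrack <- function() {
      accessibilityTrack(list(chrS = .clamp(base + rnorm(L, 0, 0.04), 0, 1)),
                         "accessibility")
    }
    atac <- list(jitterTrack(), jitterTrack())
    occ <- accessibilityTrack(
      list(chrS = .clamp(1 - base + rnorm(L, 0, 0.04), 0, 1)), "occupancy")

    genes$essential <- runif(nrow(genes)) < spec$fractionEssential
    genes$tss <- NA_integer_
    genes$tssTrue <- NULL
    genes <- annotateTss(genes, tss)
    list(genome = genome, genes = genes, tss = tss, atac = atac,
         occupancy = occ)
  })
}

#' Specification for a simulated pooled growth screen
#'
#' Defaults follow the study conditions: an average of 4 barcodes per
#' guide, gens sampled at 0/3.75/7.5/11.25 in two replicate cultures,
#' ~10% of barcodes linked to guides with synthesis errors, ~5% chimeric
#' barcode-guide swaps, and ~1% scaffold-only (empty) barcodes that act as
#' neutral negative controls.
#'
#' @param guides data.frame with `guide_id` and true `fitness` (log2 per
#'   doubling, in \[-1, 0\]); default: a bimodal mixture in which a fraction
#'   `activeFraction` of guides is active with fitness Uniform(-1, -0.2) and
#'   the rest are ineffective (fitness 0). The neutral majority is what
#'   anchors median-of-ratios normalization to absolute fitness, as in a
#'   real screen where most guides are inactive.
#' @param nGuides Number of guides when `guides` is NULL (default 100).
#' @param activeFraction Fraction of active guides in the default draw
#'   (default 0.35).
#' @param barcodeMean Mean barcodes per guide (default 4; 1 + Poisson(3)).
#' @param depth Reads per sample (default 1e6).
#' @param gens Doubling schedule (default c(0, 3.75, 7.5, 11.25)).
#' @param nCultures Replicate cultures (default 2).
#' @param initSdlog Log-normal sd of initial barcode abundances (default 1).
#' @param cultureJitter Log-normal sd of between-culture initial-frequency
#'   jitter (default 0.2).
#' @param synthErrorRate Fraction of barcodes whose guide carries a
#'   synthesis/cloning error (default 0.10).
#' @param chimeraRate Fraction of chimeric barcodes linked to two guides
#'   (default 0.05).
#' @param emptyFraction Fraction of scaffold-only barcodes (default 0.01).
#' @param seqErrorRate Per-base sequencing error rate in simulated reads
#'   (default 0.002).
#' @param lowQualRate Rate of random low-quality (correct) bases (default
#'   0.005).
#' @param readsPerBarcode Mean assignment reads per barcode (default 9;
#'   4 + Poisson(5)).
#' @param barcodeLen Barcode length in nt (default 14).
#' @param seed RNG seed.
#' @return A list spec.
#' @export
simScreenSpec <- function(guides = NULL, nGuides = 100L,
                          activeFraction = 0.35, barcodeMean = 4,
                          depth = 1e6, gens = c(0, 3.75, 7.5, 11.25),
                          nCultures = 2L, initSdlog = 1, cultureJitter = 0.2,
                          synthErrorRate = 0.10, chimeraRate = 0.05,
                          emptyFraction = 0.01, seqErrorRate = 0.002,
                          lowQualRate = 0.005, readsPerBarcode = 9,
                          barcodeLen = 14L, seed = 1L) {
  rates <- c(synthErrorRate, chimeraRate, emptyFraction, seqErrorRate,
             lowQualRate)
  stopifnot(all(rates >= 0 & rates <= 1), barcodeMean >= 1)
  as.list(environment())
}

# Draw the barcode table for a spec: barcode sequences, guides, true
# fitness (0 for empty barcodes) and planted assignment type.
.simBarcodeTable <- function(spec) {
  guides <- spec$guides
  if (is.null(guides)) {
    active <- runif(spec$nGuides) < spec$activeFraction
    guides <- data.frame(guide_id = sprintf("guide%04d", seq_len(spec$nGuides)),
                         fitness = ifelse(active, runif(spec$nGuides, -1, -0.2), 0),
                         stringsAsFactors = FALSE)
  }
  nPer <- 1L + rpois(nrow(guides), spec$barcodeMean - 1)
  bcGuide <- rep(guides$guide_id, nPer)
  bcFit <- rep(guides$fitness, nPer)
  nEmpty <- max(1L, round(spec$emptyFraction * length(bcGuide)))
  bcGuide <- c(bcGuide, rep(EMPTY_GUIDE_ID, nEmpty))
  bcFit <- c(bcFit, rep(0, nEmpty))  # empty constructs are neutral
  n <- length(bcGuide)
  repeat {
    seqs <- .randomDna(n, spec$barcodeLen)
    if (!anyDuplicated(seqs)) break
  }
  type <- rep("clean", n)
  isEmpty <- bcGuide == EMPTY_GUIDE_ID
  r <- runif(n)
  type[!isEmpty & r < spec$synthErrorRate] <- "defective"
  type[!isEmpty & r >= spec$synthErrorRate &
         r < spec$synthErrorRate + spec$chimeraRate] <- "chimera"
  type[isEmpty] <- "empty"
  data.frame(barcode = seqs, guide_id = bcGuide, fitness = bcFit,
             type = type, stringsAsFactors = FALSE)
}

#' Simulate competitive-growth barcode counts
#'
#' Lineage frequencies follow exponential dynamics,
#' f_i(g) proportional to f_i(0) * 2^(fitness_i * g), renormalized at each
#' timepoint; counts are drawn multinomially at the given depth per sample
#' (or taken as rounded expected counts with `sampling = "expected"` for
#' noise-free trajectories). Deterministic under the spec seed.
#'
#' @param spec A [simScreenSpec()] list.
#' @param sampling `"multinomial"` (default) or `"expected"`.
#' @return List: `se` (SummarizedExperiment of counts with sample
#'   metadata), `truth` (barcode table with true fitness and guide),
#'   `map` (barcode -> guide_id).
#' @export
simulateGrowthCounts <- function(spec = simScreenSpec(),
                                 sampling = c("multinomial", "expected")) {
  sampling <- match.arg(sampling)
  .withSeed(spec$seed, {
    bc <- .simBarcodeTable(spec)
    n <- nrow(bc)
    init <- rlnorm(n, 0, spec$initSdlog)
    cultures <- paste0("culture", seq_len(spec$nCultures))
    samples <- expand.grid(culture = cultures, gens = spec$gens,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    samples$sample_id <- sprintf("%s_t%02d", samples$culture,
                                 match(samples$gens, sort(unique(samples$gens))))
    counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                     dimnames = list(bc$barcode, samples$sample_id))
    for (cu in cultures) {
      f0 <- init * rlnorm(n, 0, spec$cultureJitter)
      for (j in which(samples$culture == cu)) {
        g <- samples$gens[j]
        f <- f0 * 2^(bc$fitness * g)
        f <- f / sum(f)
        counts[, j] <- if (sampling == "multinomial") {
          as.integer(rmultinom(1, size = spec$depth, prob = f))
        } else {
          as.integer(round(f * spec$depth))
        }
      }
    }
    meta <- data.frame(sample_id = samples$sample_id, gens = samples$gens,
                       culture = samples$culture, stringsAsFactors = FALSE)
    list(se = makeScreenExperiment(counts, meta), truth = bc,
         map = bc[, c("barcode", "guide_id")])
  })
}

# Corrupt a guide sequence with one synthesis error: a substitution or a
# 1-nt insertion. Deletions are not planted because a 19-nt residual guide
# is discarded at trimming, so a deletion-bearing construct is lost from
# the data (eliminated at the read-support step) rather than observed as a
# defective assignment.
.corruptGuide <- function(seq) {
  n <- nchar(seq)
  kind <- sample(c("sub", "sub", "ins"), 1L)
  p <- sample(n, 1L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (kind == "sub") {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  } else {
    chars <- append(chars, sample(c("A", "C", "G", "T"), 1L), after = p - 1L)
  }
  paste(chars, collapse = "")
}

# Apply per-base sequencing errors and build a quality string. Planted
# errors get Q20 (80%) or Q37 (20%, confidently miscalled); random
# low-quality positions keep the correct base at Q25; everything else Q37.
.sequenceRead <- function(seq, seqErrorRate, lowQualRate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  qual <- rep(37L, n)
  err <- runif(n) < seqErrorRate
  if (any(err)) {
    chars[err] <- vapply(chars[err], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
    qual[err] <- ifelse(runif(sum(err)) < 0.8, 20L, 37L)
  }
  lowq <- runif(n) < lowQualRate & !err
  qual[lowq] <- 25L
  list(seq = paste(chars, collapse = ""),
       qual = rawToChar(as.raw(qual + 33L)))
}

#' Simulate paired assignment reads for a barcoded guide library
#'
#' Emits R1 (barcode + assignment adapter) and R2 (guide between its
#' flanking adapters) FASTQ files with planted synthesis errors (the
#' barcode's plasmid carries a corrupted guide), chimeric barcodes whose
#' reads split between two guides, scaffold-only empty constructs, and
#' per-base sequencing errors with matching quality strings.
#'
#' @param libSeqs Named character vector guide_id -> 20-nt guide sequence.
#' @param spec A [simScreenSpec()] list (rates, read counts, seed).
#' @param dir Output directory for `assign_R1.fastq` / `assign_R2.fastq`.
#' @return List: `r1`, `r2` (paths), `truth` (barcode, guide_id, type).
#' @export
simulateAssignmentReads <- function(libSeqs, spec = simScreenSpec(),
                                    dir = tempdir()) {
  stopifnot(!is.null(names(libSeqs)), length(libSeqs) >= 2L)
  .withSeed(spec$seed + 1L, {
    guides <- data.frame(guide_id = names(libSeqs), fitness = 0,
                         stringsAsFactors = FALSE)
    specBc <- spec
    specBc$guides <- guides
    bc <- .simBarcodeTable(specBc)
    r1 <- character(0); r2 <- character(0)
    q1 <- character(0); q2 <- character(0)
    truthBarcode <- character(0)
    for (i in seq_len(nrow(bc))) {
      nReads <- 4L + rpois(1L, spec$readsPerBarcode - 4)
      plasmidGuide <- switch(bc$type[i],
        empty = emptyGuideSequence(),
        defective = .corruptGuide(libSeqs[[bc$guide_id[i]]]),
        libSeqs[[bc$guide_id[i]]])
      altGuide <- if (bc$type[i] == "chimera") {
        unname(sample(libSeqs[names(libSeqs) != bc$guide_id[i]], 1L))
      } else NA_character_
      for (r in seq_len(nReads)) {
        gseq <- plasmidGuide
        if (bc$type[i] == "chimera" && r %% 2L == 0L) gseq <- altGuide
        read1 <- .sequenceRead(paste0(bc$barcode[i], BC_ASSIGN_ADAPTER, "AC"),
                               spec$seqErrorRate, spec$lowQualRate)
        read2 <- .sequenceRead(paste0("TTG", GUIDE_ADAPTER_5, gseq,
                                      GUIDE_ADAPTER_3, "CTG"),
                               spec$seqErrorRate, spec$lowQualRate)
        r1 <- c(r1, read1$seq); q1 <- c(q1, read1$qual)
        r2 <- c(r2, read2$seq); q2 <- c(q2, read2$qual)
        truthBarcode <- c(truthBarcode, bc$barcode[i])
      }
    }
    ids <- sprintf("read%06d", seq_along(r1))
    r1Path <- file.path(dir, "assign_R1.fastq")
    r2Path <- file.path(dir, "assign_R2.fastq")
    writeFastq(data.frame(id = ids, seq = r1, qual = q1), r1Path)
    writeFastq(data.frame(id = ids, seq = r2, qual = q2), r2Path)
    list(r1 = r1Path, r2 = r2Path,
         truth = bc[, c("barcode", "guide_id", "type")])
  })
}

#' Simulate guides under a planted position + occupancy activity law
#'
#' Generates guide-level data whose activity follows a known logistic law:
#' logit P(active) = b0 + b1 * bump(offset) + b2 * odm, where bump is a
#' Gaussian activity peak centered at offset -50 (width 45 nt). Fitness is
#' drawn around -0.8 for active guides and around 0 for inactive ones, so
#' the fitness-derived labels reproduce the planted ones almost surely.
#' The Bayes-optimal score is the true probability, whose AUC bounds any
#' fitted model.
#'
#' @param n Number of guides (default 2000).
#' @param beta Coefficients c(b0, b1, b2) of the planted law
#'   (default c(-2.2, 4, -2)).
#' @param threshold Activity threshold on the fitness scale (default -0.38).
#' @param seed RNG seed.
#' @return data.frame with guide_id, offset, odm, protospacer, strand,
#'   fitness, active, trueProb.
#' @export
simulateEfficacyGuides <- function(n = 2000L, beta = c(-2.2, 4, -2),
                                   threshold = -0.38, seed = 1L) {
  .withSeed(seed, {
    offset <- sample(-220:20, n, replace = TRUE)
    odm <- runif(n)
    bump <- exp(-((offset + 50)^2) / (2 * 45^2))
    p <- plogis(beta[1] + beta[2] * bump + beta[3] * odm)
    activeTrue <- runif(n) < p
    fitness <- ifelse(activeTrue, rnorm(n, -0.8, 0.15), rnorm(n, 0, 0.12))
    data.frame(guide_id = sprintf("simguide%04d", seq_len(n)),
               offset = offset, odm = odm,
               protospacer = .randomDna(n, 20L),
               strand = sample(c("+", "-"), n, replace = TRUE),
               fitness = fitness, active = fitness < threshold,
               trueProb = p, stringsAsFactors = FALSE)
  })
}
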