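# Genome loading and k-mer occurrence counting.
#
# Coordinates are 0-based half-open everywhere inside the package; emitted
# TSVs use 1-based inclusive coordinates.

#' Construct a CrisprGenome
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences. Lowercase input is uppercased.
#' @return A [CrisprGenome-class] object.
#' @examples
#' gn <- crisprGenome(c(chr1 = "ACGTACGTACGGTT"))
#' seqLens(gn)
#' @export
crisprGenome <- function(sequences) {
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  } else if (is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  } else {
    stop("sequences must be a named character vector or DNAStringSet")
  }
  new("CrisprGenome", sequences = sequences, cache = new.env(parent = emptyenv()))
}

#' Load a genome from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A [CrisprGenome-class].
#' @export
loadGenome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  # FASTA descriptions: keep the first whitespace-delimited word as the name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome names in ", path)
  crisprGenome(seqs)
}

#' Write a genome to FASTA
#' @param x A [CrisprGenome-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(x, path) {
  Biostrings::writeXStringSet(genomeSeqs(x), path)
  invisible(path)
}

# Cached character sequence of one chromosome.
.chr <- function(genome, chrom) {
  key <- paste0("seq_", chrom)
  val <- get0(key, envir = genome@cache)
  if (is.null(val)) {
    if (!chrom %in% names(genome@sequences))
      stop("unknown chromosome: ", chrom)
    val <- as.character(genome@sequences[[chrom]])
    assign(key, val, envir = genome@cache)
  }
  val
}

# 0-based half-open subsequence of a chromosome.
.seqWindow <- function(genome, chrom, start0, end0) {
  substr(.chr(genome, chrom), start0 + 1L, end0)
}

# Forward-strand k-mer count index (environment kmer -> count), built lazily.
.kmerIndex <- function(genome, k) {
  key <- paste0("k", k)
  idx <- get0(key, envir = genome@cache)
  if (is.null(idx)) {
    idx <- new.env(hash = TRUE, parent = emptyenv())
    for (chrom in names(genome@sequences)) {
      s <- .chr(genome, chrom)
      n <- nchar(s) - k + 1L
      if (n < 1L) next
      km <- substring(s, seq_len(n), seq_len(n) + k - 1L)
      km <- km[!grepl("N", km, fixed = TRUE)]  # N never matches a guide base
      if (!length(km)) next
      tab <- table(km)
      nm <- names(tab)
      for (i in seq_along(tab)) {
        prev <- get0(nm[i], envir = idx, ifnotfound = 0L)
        assign(nm[i], prev + as.integer(tab[[i]]), envir = idx)
      }
    }
    assign(key, idx, envir = genome@cache)
  }
  idx
}

#' Count perfect occurrences of a k-mer on both genome strands
#'
#' Counts forward-strand occurrences of `kmer` plus forward-strand
#' occurrences of its reverse complement, so a site is found regardless of
#' the strand it lies on. Genomic `N` bases never match.
#'
#' @param genome A [CrisprGenome-class].
#' @param kmer Character vector of equal-length DNA strings over A,C,G,T.
#' @return Integer vector of occurrence counts.
#' @examples
#' gn <- crisprGenome(c(chr1 = "ACGTACGT"))
#' countKmer(gn, "ACGT")   # 2 forward + 2 reverse-complement
#' @export
countKmer <- function(genome, kmer) {
  stopifnot(is(genome, "CrisprGenome"), is.character(kmer), length(kmer) >= 1L)
  k <- unique(nchar(kmer))
  if (length(k) != 1L) stop("all kmers must have equal length")
  idx <- .kmerIndex(genome, k)
  rc <- .revcomp(kmer)
  fwd <- vapply(kmer, function(x) get0(x, envir = idx, ifnotfound = 0L), integer(1))
  rev <- vapply(rc, function(x) get0(x, envir = idx, ifnotfound = 0L), integer(1))
  unname(fwd + rev)
}
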