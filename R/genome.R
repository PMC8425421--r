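#' Construct a Genome
#'
#' @param id record identifier.
#' @param seq nucleotide string or `DNAString`; lowercase is accepted and
#'   uppercased, characters outside `A,C,G,T,N` are mapped to `N` with a
#'   warning.
#' @return a [Genome-class].
#' @examples
#' g <- genome("chr", "acgtACGT")
#' genomeLength(g)
#' @export
genome <- function(id, seq) {
  if (is(seq, "DNAString")) seq <- as.character(seq)
  seq <- toupper(as.character(seq))
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    warning(sprintf("%d non-ACGTN character(s) mapped to N (e.g. '%s')",
                    nchar(bad), substr(bad, 1, 1)))
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  new("Genome", id = as.character(id), seq = Biostrings::DNAString(seq))
}

#' Construct a TssSet
#'
#' Entries are sorted by strand then position and deduplicated.
#'
#' @param pos integer vector of 0-based positions.
#' @param strand character vector of `"+"`/`"-"`, recycled to `pos`.
#' @param sourceName,priority source tag and priority rank.
#' @return a [TssSet-class].
#' @export
tssSet <- function(pos, strand, sourceName, priority) {
  e <- unique(data.frame(pos = as.integer(pos),
                         strand = rep_len(as.character(strand), length(pos))))
  e <- e[order(e$strand, e$pos), , drop = FALSE]
  rownames(e) <- NULL
  new("TssSet", sourceName = as.character(sourceName),
      priority = as.integer(priority), entries = e)
}

#' Construct a RegionSet
#'
#' @param start,end 0-based half-open interval bounds.
#' @param strand `"+"`/`"-"` per interval.
#' @param kind one of `cds`, `operon_gap`, `pseudogene`, `intergenic`.
#' @return a [RegionSet-class].
#' @export
regionSet <- function(start, end, strand, kind) {
  iv <- data.frame(start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), kind = as.character(kind))
  iv <- iv[order(iv$strand, iv$start, iv$end), , drop = FALSE]
  rownames(iv) <- NULL
  new("RegionSet", intervals = iv)
}

#' Construct a PredictionTrack
#'
#' @param fwd,rev per-position probabilities for the two strands, in
#'   plus-strand coordinates.
#' @return a [PredictionTrack-class].
#' @export
predictionTrack <- function(fwd, rev) {
  new("PredictionTrack", fwd = as.numeric(fwd), rev = as.numeric(rev))
}

# --- strand-local coordinate helpers ------------------------------------
#
# A feature on the minus strand at plus-coordinate p sits at strand-local
# coordinate L-1-p of the reverse-complemented sequence. "Downstream" of a
# minus-strand site means decreasing plus coordinates.

.revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Extract a strand-local subsequence
#'
#' Returns the sequence read in the 5'->3' direction of `strand`,
#' starting at strand-local offset `from` relative to the stranded
#' anchor position `pos` (plus-strand coordinate), of length `width`.
#' Offsets increase downstream on the feature's own strand.
#'
#' @param g a [Genome-class].
#' @param pos anchor position, 0-based plus-strand coordinate.
#' @param strand `"+"` or `"-"`.
#' @param from signed strand-local offset of the first base.
#' @param width number of bases.
#' @return a character string, or `NA` if out of bounds.
#' @export
strandLocalSeq <- function(g, pos, strand, from, width) {
  L <- genomeLength(g)
  .check_strand(strand)
  if (strand == "+") {
    a <- pos + from
    b <- a + width - 1L
    if (a < 0L || b >= L) return(NA_character_)
    as.character(Biostrings::subseq(g@seq, a + 1L, b + 1L))
  } else {
    # strand-local [pos_local+from, ... width) maps to plus coords
    # [pos - from - width + 1, pos - from]
    b <- pos - from
    a <- b - width + 1L
    if (a < 0L || b >= L) return(NA_character_)
    .revcomp_chr(as.character(Biostrings::subseq(g@seq, a + 1L, b + 1L)))
  }
}

# integer tokens A=0 C=1 G=2 T=3 N=4, in strand-local order for the given
# strand (minus strand = reverse complement of the whole genome)
.tokenize <- function(g, strand = "+") {
  s <- g@seq
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  codes <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L)
  unname(codes[strsplit(as.character(s), "", fixed = TRUE)[[1]]])
}
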