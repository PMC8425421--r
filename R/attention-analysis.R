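# Characterisation of attention heads: where along the upstream window a
# head looks (positional profile), which 7-mer it rewards (top-scoring
# motif) and how its scores relate to the model output. Offsets are
# query-relative: offset 0 is the query position itself, offset -o the
# position o nt upstream (strand-local). Since labels sit 20 nt
# downstream of the TSS, TSS-relative coordinates are offset + 20.

#' AttentionRecords: collected attention score vectors
#'
#' @slot scores numeric array `[query, offsetIndex, layer*heads+head]`;
#'   offset index `i` corresponds to upstream offset `i - l` (the last
#'   index is offset 0, the query itself). Masked offsets (queries with
#'   partial context) hold 0.
#' @slot queries `data.frame` with `pos`, `strand`, `output` (the model
#'   probability at the query).
#' @slot config the model configuration the records came from.
#' @exportClass AttentionRecords
setClass("AttentionRecords", representation(scores = "array",
                                            queries = "data.frame",
                                            config = "list"))

setMethod("show", "AttentionRecords", function(object) {
  d <- dim(object@scores)
  cat(sprintf("AttentionRecords: %d queries x %d offsets x %d heads (%d layers)\n",
              d[1], d[2], d[3], object@config$num_layers))
})

#' Pfm: position frequency matrix of an attention head
#'
#' @slot counts 4 x width integer matrix (rows `A,C,G,T`).
#' @slot nSequences number of sequences counted.
#' @slot anchor the query-relative offset the motif is anchored at.
#' @exportClass Pfm
setClass("Pfm", representation(counts = "matrix", nSequences = "integer",
                               anchor = "integer"))

setValidity("Pfm", function(object) {
  if (!identical(rownames(object@counts), c("A", "C", "G", "T")))
    return("counts rows must be A,C,G,T")
  if (any(colSums(object@counts) != object@nSequences))
    return("column sums must equal nSequences")
  TRUE
})

setMethod("show", "Pfm", function(object) {
  cat(sprintf("Pfm: width %d, %d sequences, anchored at offset %d\n",
              ncol(object@counts), object@nSequences, object@anchor))
  cat("consensus:", pfmConsensus(object), "\n")
})

#' Build a position frequency matrix from equal-length sequences
#'
#' @param seqs character vector of equal-length sequences over
#'   `A,C,G,T` (`N` positions are dropped from the column counts —
#'   callers avoid them).
#' @param anchor query-relative anchor offset (bookkeeping).
#' @return a [Pfm-class].
#' @export
pfmFromSeqs <- function(seqs, anchor = 0L) {
  stopifnot(length(seqs) >= 1L, length(unique(nchar(seqs))) == 1L)
  w <- nchar(seqs[1])
  m <- matrix(0L, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  ch <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  for (j in seq_len(w)) {
    t <- table(factor(ch[, j], levels = c("A", "C", "G", "T")))
    m[, j] <- as.integer(t)
  }
  new("Pfm", counts = m, nSequences = length(seqs), anchor = as.integer(anchor))
}

#' Per-column information content of a Pfm, in bits
#'
#' `2 + sum(f * log2(f))` per column; ranges from 0 (uniform) to 2
#' (single base).
#'
#' @param pfm a [Pfm-class].
#' @return numeric vector, one value per column.
#' @export
informationContent <- function(pfm) {
  f <- sweep(pfm@counts, 2, colSums(pfm@counts), "/")
  apply(f, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' @rdname informationContent
#' @export
pfmConsensus <- function(pfm)
  paste(rownames(pfm@counts)[apply(pfm@counts, 2, which.max)], collapse = "")

#' Match a Pfm against a consensus sequence
#'
#' Slides the consensus over the Pfm — including partial overlaps at
#' the edges, since a fixed-width extraction window may clip a motif by
#' a frame or two — and returns, for the best alignment with at least
#' `minOverlap` overlapping columns, the mean per-column frequency of
#' the consensus base over those columns.
#'
#' @param pfm a [Pfm-class].
#' @param consensus consensus string, length at most the Pfm width.
#' @param minOverlap minimum number of overlapping columns an
#'   alignment must have (default 4).
#' @return list with `match` (mean per-column frequency, in `[0,1]`),
#'   `shift` (signed column offset of the consensus start relative to
#'   the first Pfm column) and `overlap` (columns compared).
#' @export
pfmConsensusMatch <- function(pfm, consensus, minOverlap = 4L) {
  f <- sweep(pfm@counts, 2, colSums(pfm@counts), "/")
  b <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  w <- ncol(f); m <- length(b)
  stopifnot(m <= w, minOverlap <= m)
  best <- -Inf; bestShift <- 0L; bestOv <- 0L
  for (s in seq.int(-(m - minOverlap), w - minOverlap)) {
    j <- which(s + seq_len(m) >= 1L & s + seq_len(m) <= w)
    if (length(j) < minOverlap) next
    sc <- mean(f[cbind(match(b[j], rownames(f)), s + j)])
    if (sc > best) { best <- sc; bestShift <- s; bestOv <- length(j) }
  }
  list(match = best, shift = bestShift, overlap = bestOv)
}

#' Sample query positions from a split for attention analysis
#'
#' Draws a uniform random sample (without replacement) of about
#' `fraction` of the split's positions over both strands, plus the
#' `nExtreme` positions with the highest and lowest model output
#' probabilities (ties broken by coordinate). Top and bottom sets are
#' disjoint.
#'
#' @param track a [PredictionTrack-class].
#' @param split `data.frame(start, end)` (e.g. `splits$test`).
#' @param fraction sampling fraction for the random set.
#' @param nExtreme size of each extreme group.
#' @param seed RNG seed.
#' @return list with `data.frame`s `random`, `top`, `bottom` (columns
#'   `pos`, `strand`, `output`).
#' @export
buildSampleFrame <- function(track, split, fraction = 0.01, nExtreme = 500L,
                             seed = 1L) {
  pos <- .split_positions(split)
  all <- data.frame(pos = rep(pos, 2L),
                    strand = rep(c("+", "-"), each = length(pos)),
                    output = c(track@fwd[pos + 1L], track@rev[pos + 1L]))
  n <- nrow(all)
  if (2L * nExtreme > n)
    stop("nExtreme exceeds half the split size")
  n_rand <- max(1L, round(fraction * n))
  rand <- .with_seed(seed, all[sample.int(n, n_rand), , drop = FALSE])
  o <- order(-all$output, all$strand, all$pos)
  top <- all[o[seq_len(nExtreme)], , drop = FALSE]
  o2 <- order(all$output, all$strand, all$pos)
  bottom <- all[o2[seq_len(nExtreme)], , drop = FALSE]
  rownames(rand) <- rownames(top) <- rownames(bottom) <- NULL
  list(random = rand, top = top, bottom = bottom, seed = as.integer(seed))
}

#' Collect attention records at query positions
#'
#' Re-runs the forward pass in inference mode over the given intervals
#' (memory carried across consecutive segments, reset at interval
#' starts, exactly as in [predictTrack()]) and harvests each head's
#' attention score vector at every query position.
#'
#' @param model a trained [TransformerModel-class].
#' @param g the [Genome-class].
#' @param queries `data.frame` with columns `pos` (plus-strand
#'   coordinates) and `strand`.
#' @param intervals plus-strand `data.frame(start, end)` giving the
#'   processing context (default: whole genome).
#' @return an [AttentionRecords-class].
#' @export
collectAttention <- function(model, g, queries, intervals = NULL) {
  L <- genomeLength(g)
  cfg <- model@config
  l <- cfg$segment_length
  nH <- cfg$num_layers * cfg$heads_per_layer
  if (is.null(intervals)) intervals <- data.frame(start = 0L, end = L)
  if (any(queries$pos < 0L | queries$pos >= L))
    stop("query position outside the genome")
  scores <- array(0, dim = c(nrow(queries), l, nH))
  output <- numeric(nrow(queries))
  for (st in c("+", "-")) {
    qi <- which(queries$strand == st)
    if (!length(qi)) next
    loc <- if (st == "+") queries$pos[qi] else L - 1L - queries$pos[qi]
    iv <- if (st == "+") intervals else .mirror_intervals(intervals, L)
    tokens <- .tokenize(g, st)
    for (i in seq_len(nrow(iv))) {
      a <- iv$start[i]; b <- iv$end[i]
      inside <- which(loc >= a & loc < b)
      if (!length(inside)) next
      mem <- list()
      s <- a
      while (s < b) {
        e <- min(s + l, b)
        hit <- inside[loc[inside] >= s & loc[inside] < e]
        res <- .tx_segment_forward(model@params, cfg, tokens[(s + 1L):e],
                                   mem, length(hit) > 0L)
        if (length(hit)) {
          at <- res$attention   # (Lc, l, nH)
          for (q in hit) {
            t <- loc[q] - s + 1L
            scores[qi[q], , ] <- at[t, , ]
            output[qi[q]] <- res$prob[t]
          }
        }
        mem <- res$new_mem
        s <- e
      }
    }
  }
  qdf <- data.frame(pos = queries$pos, strand = queries$strand,
                    output = output)
  new("AttentionRecords", scores = scores, queries = qdf,
      config = cfg)
}

.head_index <- function(records, layer, head) {
  H <- records@config$heads_per_layer
  k <- records@config$num_layers
  stopifnot(layer >= 1L, layer <= k, head >= 1L, head <= H)
  (layer - 1L) * H + head
}

.offsets_of <- function(records) {
  l <- records@config$segment_length
  seq.int(-l + 1L, 0L)
}

#' Positional profile of one attention head
#'
#' Offset-wise mean and maximum of the head's attention scores over all
#' collected queries. The mean profile of full-context records sums
#' to 1 (averaging preserves the per-record softmax normalisation).
#'
#' @param records an [AttentionRecords-class].
#' @param layer,head 1-based indices.
#' @return `data.frame(offset, mean, max)` plus attribute `n_samples`.
#' @export
headProfile <- function(records, layer, head) {
  s <- records@scores[, , .head_index(records, layer, head), drop = FALSE]
  dim(s) <- dim(records@scores)[1:2]
  out <- data.frame(offset = .offsets_of(records),
                    mean = colMeans(s),
                    max = apply(s, 2, max))
  attr(out, "n_samples") <- nrow(s)
  out
}

#' Min-max normalise a profile for display
#'
#' Display aid only; statistics always use raw profiles.
#'
#' @param profile output of [headProfile()].
#' @export
normalizeProfile <- function(profile) {
  r <- range(profile$mean)
  profile$mean_norm <- if (diff(r) > 0) (profile$mean - r[1]) / diff(r) else 0
  profile
}

#' Top-scoring sequence motif of an attention head
#'
#' Finds the upstream offset with the highest mean attention score (the
#' anchor, unless overridden), selects the `nTop` queries with the
#' highest score at that offset (ties broken by strand/coordinate), and
#' counts the strand-local 7-mers centred at query + anchor into a
#' position frequency matrix. Queries whose extraction window leaves
#' the genome are skipped (with a message) and replaced by the next
#' best.
#'
#' @param records an [AttentionRecords-class].
#' @param g the [Genome-class] the records were collected from.
#' @param layer,head 1-based indices.
#' @param nTop number of sequences (default 50).
#' @param width motif width (default 7, the conv receptive field).
#' @param anchor optional query-relative offset overriding the profile
#'   peak.
#' @return a [Pfm-class].
#' @export
topScoringMotif <- function(records, g, layer, head, nTop = 50L, width = 7L,
                            anchor = NULL) {
  s <- records@scores[, , .head_index(records, layer, head), drop = FALSE]
  dim(s) <- dim(records@scores)[1:2]
  if (nrow(s) < nTop) stop("fewer records than nTop")
  offs <- .offsets_of(records)
  if (is.null(anchor)) anchor <- offs[which.max(colMeans(s))]
  anchor <- as.integer(anchor)
  sc <- s[, match(anchor, offs)]
  q <- records@queries
  ord <- order(-sc, q$strand, q$pos)
  half <- (width - 1L) %/% 2L
  seqs <- character(0)
  skipped <- 0L
  for (i in ord) {
    sq <- strandLocalSeq(g, q$pos[i], q$strand[i], anchor - half, width)
    if (is.na(sq)) { skipped <- skipped + 1L; next }
    seqs <- c(seqs, sq)
    if (length(seqs) == nTop) break
  }
  if (skipped > 0L)
    message(skipped, " extraction window(s) out of bounds; replacements drawn")
  if (length(seqs) < nTop)
    stop("not enough in-bounds records for nTop sequences")
  pfmFromSeqs(seqs, anchor)
}

.spearman <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Correlation of attention scores with the model output
#'
#' For every (layer, head, offset), the Spearman rank correlation
#' across queries between the attention score at that offset and the
#' model output probability. Ties get average ranks; zero-variance
#' score vectors yield `NA`.
#'
#' @param records an [AttentionRecords-class].
#' @return long `data.frame(layer, head, offset, rho)`.
#' @export
headOutputCorrelation <- function(records) {
  if (nrow(records@queries) < 3L) stop("need at least 3 samples")
  cfg <- records@config
  offs <- .offsets_of(records)
  out <- records@queries$output
  res <- list()
  for (layer in seq_len(cfg$num_layers)) for (head in seq_len(cfg$heads_per_layer)) {
    s <- records@scores[, , .head_index(records, layer, head), drop = FALSE]
    dim(s) <- dim(records@scores)[1:2]
    rho <- apply(s, 2, .spearman, y = out)
    res[[length(res) + 1L]] <- data.frame(layer = layer, head = head,
                                          offset = offs, rho = rho)
  }
  do.call(rbind, res)
}

#' Contrast attention scores between two query groups
#'
#' Per offset: difference of group mean scores (top minus bottom) and a
#' two-sample Wilcoxon rank-sum test, with Benjamini-Hochberg
#' correction across offsets.
#'
#' @param recordsTop,recordsBottom [AttentionRecords-class] objects for
#'   the two groups (same model).
#' @param layer,head 1-based indices.
#' @return `data.frame(offset, diff, p, p_adj)`.
#' @export
compareScoreGroups <- function(recordsTop, recordsBottom, layer, head) {
  hi <- .head_index(recordsTop, layer, head)
  a <- recordsTop@scores[, , hi, drop = FALSE]
  b <- recordsBottom@scores[, , hi, drop = FALSE]
  dim(a) <- dim(recordsTop@scores)[1:2]
  dim(b) <- dim(recordsBottom@scores)[1:2]
  if (!nrow(a) || !nrow(b)) stop("both groups must be non-empty")
  offs <- .offsets_of(recordsTop)
  p <- vapply(seq_along(offs), function(j) {
    if (stats::sd(c(a[, j], b[, j])) == 0) return(1)
    suppressWarnings(stats::wilcox.test(a[, j], b[, j], exact = FALSE)$p.value)
  }, numeric(1))
  data.frame(offset = offs, diff = colMeans(a) - colMeans(b),
             p = p, p_adj = stats::p.adjust(p, method = "BH"))
}

#' Head-to-head correlation matrix
#'
#' Flattens each head's (query x offset) score matrix over a common
#' query set and rank-correlates every pair of heads; symmetric with
#' unit diagonal.
#'
#' @param records an [AttentionRecords-class].
#' @return numeric matrix with `L<layer>H<head>` dimnames.
#' @export
headHeadCorrelation <- function(records) {
  cfg <- records@config
  nH <- cfg$num_layers * cfg$heads_per_layer
  flat <- sapply(seq_len(nH), function(h) as.vector(records@scores[, , h]))
  m <- stats::cor(flat, method = "spearman")
  nm <- as.vector(t(outer(seq_len(cfg$num_layers), seq_len(cfg$heads_per_layer),
                          function(l, h) sprintf("L%dH%d", l, h))))
  dimnames(m) <- list(nm, nm)
  m
}

#' Write motifs in MEME minimal format
#'
#' @param pfms named list of [Pfm-class] objects.
#' @param path output path.
#' @export
writeMeme <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", ""), con)
  for (nm in names(pfms)) {
    p <- pfms[[nm]]
    f <- sweep(p@counts, 2, colSums(p@counts), "/")
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(f), p@nSequences), con)
    for (j in seq_len(ncol(f)))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         f["A", j], f["C", j], f["G", j], f["T", j]), con)
    writeLines("", con)
  }
  invisible(path)
}
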