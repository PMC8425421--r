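# Genome splitting, label shifting and ranking metrics. The genome is cut
# into contiguous train/test/validation arcs; sense and antisense of the
# same arc always land in the same split so no information leaks between
# sets through the complementary strand.

#' Split a genome into contiguous train/test/validation intervals
#'
#' Fraction mode cuts `[0, L)` into three consecutive arcs of the given
#' fractions (train, test, validation). Boundary mode takes three
#' explicit coordinates `p1 < p2 < p3`: train is `[0, p1)`, test
#' `[p1, p2)`, validation `[p2, p3)`, and the residual `[p3, L)` joins
#' the training set (three cut points on a circular genome leave three
#' arcs). Both strands of an interval belong to the same split.
#'
#' @param genomeLength total length `L`.
#' @param fractions numeric of length 3 `(train, test, val)` summing
#'   to 1.
#' @param boundaries optional increasing integer vector of length 3
#'   (activates boundary mode).
#' @return named list of `data.frame(start, end)` interval tables with
#'   elements `train`, `test`, `val`.
#' @examples
#' makeSplits(100)   # [0,70) [70,90) [90,100)
#' @export
makeSplits <- function(genomeLength, fractions = c(0.7, 0.2, 0.1),
                       boundaries = NULL) {
  L <- as.integer(genomeLength)
  if (!is.null(boundaries)) {
    b <- as.integer(boundaries)
    if (length(b) != 3L || is.unsorted(b, strictly = TRUE) ||
        b[1] < 0L || b[3] > L)
      stop("boundaries must be three strictly increasing in-range positions")
    train <- data.frame(start = c(0L, b[3]), end = c(b[1], L))
    train <- train[train$start < train$end, , drop = FALSE]
    return(list(train = train,
                test = data.frame(start = b[1], end = b[2]),
                val = data.frame(start = b[2], end = b[3])))
  }
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three numbers summing to 1")
  b1 <- as.integer(floor(L * fractions[1] + 1e-9))
  b2 <- as.integer(floor(L * (fractions[1] + fractions[2]) + 1e-9))
  list(train = data.frame(start = 0L, end = b1),
       test = data.frame(start = b1, end = b2),
       val = data.frame(start = b2, end = L))
}

.split_positions <- function(split) {
  if (!nrow(split)) return(integer())
  unlist(lapply(seq_len(nrow(split)), function(i)
    seq.int(split$start[i], split$end[i] - 1L)), use.names = FALSE)
}

#' Build the binary label track from TSS annotations
#'
#' Positives are placed `offset` nt downstream (strand-local) of each
#' TSS: a plus-strand TSS at `p` labels `p + offset`, a minus-strand
#' TSS at `p` labels `p - offset`. The shift lets a causal model see
#' `offset` nt past the TSS before it must answer. Shifted positions
#' falling outside the genome are dropped with a warning.
#'
#' @param tss a [TssSet-class] or [CuratedSet-class].
#' @param genomeLength genome length.
#' @param offset downstream shift in nt (default 20).
#' @return a [LabelTrack-class].
#' @export
shiftLabels <- function(tss, genomeLength, offset = 20L) {
  if (is(tss, "CuratedSet")) tss <- curatedToTssSet(tss)
  stopifnot(offset >= 0L)
  L <- as.integer(genomeLength)
  e <- tssEntries(tss)
  fwd <- integer(L); rev <- integer(L)
  pf <- e$pos[e$strand == "+"] + as.integer(offset)
  pr <- e$pos[e$strand == "-"] - as.integer(offset)
  drop <- sum(pf < 0L | pf >= L) + sum(pr < 0L | pr >= L)
  if (drop > 0L)
    warning(drop, " shifted label(s) fell outside the genome and were dropped")
  fwd[pf[pf >= 0L & pf < L] + 1L] <- 1L
  rev[pr[pr >= 0L & pr < L] + 1L] <- 1L
  new("LabelTrack", fwd = fwd, rev = rev, shiftOffset = as.integer(offset))
}

#' Ranking metrics: ROC AUC and PR AUC
#'
#' `rocAuc()` is the probability that a uniformly drawn positive
#' outranks a uniformly drawn negative, with ties counting 1/2
#' (computed from mean ranks). `prAuc()` sums precision over recall
#' steps (step-wise, not trapezoidal, interpolation: equal scores are
#' processed as one threshold group), which avoids optimistic
#' interpolation under heavy class imbalance.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 labels.
#' @return a single number in `[0, 1]`.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("need at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname rocAuc
#' @export
prAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1L)
  if (P == 0L || all(labels == 1L))
    stop("need at least one positive and one negative")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp_last <- c(which(diff(s) != 0), length(s))   # last index of each group
  tp <- cumsum(y)[grp_last]
  n_seen <- grp_last
  prec <- tp / n_seen
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate a prediction track against labels over a split
#'
#' Pools the positions of both strands inside the split intervals and
#' computes [rocAuc()] and [prAuc()].
#'
#' @param track a [PredictionTrack-class].
#' @param labels a [LabelTrack-class].
#' @param split a `data.frame(start, end)` from [makeSplits()].
#' @return named list with `roc_auc`, `pr_auc`, `n`, `n_pos`.
#' @export
evaluateTrack <- function(track, labels, split) {
  idx <- .split_positions(split) + 1L
  sc <- c(track@fwd[idx], track@rev[idx])
  y <- c(labels@fwd[idx], labels@rev[idx])
  list(roc_auc = rocAuc(sc, y), pr_auc = prAuc(sc, y),
       n = length(y), n_pos = sum(y))
}

#' PR AUC at reduced (k-mer) resolution
#'
#' Per strand, each split interval is tiled into consecutive
#' non-overlapping k-mers starting at the interval's first coordinate
#' (a shorter remainder tile is kept if it has at least one position).
#' A tile's score is the mean output probability over its positions and
#' its label is positive if any position in it is positive; [prAuc()]
#' is computed on the tiles. `kmer = 1` reduces to the per-nucleotide
#' PR AUC of [evaluateTrack()].
#'
#' @inheritParams evaluateTrack
#' @param kmer tile width (>= 1).
#' @return the PR AUC over tiles.
#' @export
kmerResolutionEval <- function(track, labels, split, kmer = 4L) {
  kmer <- as.integer(kmer)
  stopifnot(kmer >= 1L)
  sc <- numeric(0); y <- integer(0)
  for (i in seq_len(nrow(split))) {
    pos <- seq.int(split$start[i], split$end[i] - 1L)
    tile <- (pos - split$start[i]) %/% kmer
    for (v in list(c("fwd"), c("rev"))) {
      slot_sc <- slot(track, v)[pos + 1L]
      slot_y <- slot(labels, v)[pos + 1L]
      sc <- c(sc, tapply(slot_sc, tile, mean))
      y <- c(y, as.integer(tapply(slot_y, tile, max)))
    }
  }
  prAuc(sc, y)
}
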