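# Synthetic genomes with planted promoter architecture. These generators
# define the study conditions for every downstream stage: an i.i.d.
# background sequence, TSSs planted on both strands with fixed upstream
# sequence elements, and noisy multi-source annotation sets derived from
# the ground truth by jitter, dropout and false-positive insertion.

# run code under a fixed seed without clobbering the caller's RNG stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Construct a MotifSpec
#'
#' @param name label for bookkeeping.
#' @param consensus consensus sequence over `A,C,G,T`.
#' @param offset signed start position of the motif relative to the TSS
#'   (strand-local; negative = upstream).
#' @param mutationRate per-base probability of substitution by a
#'   different random base.
#' @param jitter maximal uniform shift (nt) of the planted offset.
#' @return a [MotifSpec-class].
#' @export
motifSpec <- function(name, consensus, offset, mutationRate = 0, jitter = 0L) {
  new("MotifSpec", name = as.character(name),
      consensus = toupper(as.character(consensus)),
      offset = as.integer(offset), mutationRate = as.numeric(mutationRate),
      jitter = as.integer(jitter))
}

#' Construct a NoiseSpec
#'
#' @param maxShift maximal absolute annotation shift (nt). Defaults to 2
#'   and should stay at or below 5 so noise respects the curation
#'   sharing window.
#' @param dropoutRate probability a true site is missing from the set.
#' @param fpRate expected false annotations per kb of genome.
#' @param seed RNG seed.
#' @return a [NoiseSpec-class].
#' @export
noiseSpec <- function(maxShift = 2L, dropoutRate = 0.1, fpRate = 0.05,
                      seed = 1L) {
  new("NoiseSpec", maxShift = as.integer(maxShift),
      dropoutRate = as.numeric(dropoutRate), fpRate = as.numeric(fpRate),
      seed = as.integer(seed))
}

#' Default planted promoter architecture
#'
#' The canonical sigma-70 elements: a `TATAAT` box starting 12 nt
#' upstream of the TSS (occupying TSS-relative positions -12..-7, the
#' "-10 box") and a `TTGACA` box starting 35 nt upstream (-35..-30, the
#' "-35 box"). Optionally a third, purely position-specific element near
#' -82 ("TGTGAG", -85..-80), mimicking an operator-like box at a fixed
#' upstream distance.
#'
#' @param mutationRate,jitter applied to every box.
#' @param minus82 include the -82 region box?
#' @return list of [MotifSpec-class] objects.
#' @export
promoterMotifs <- function(mutationRate = 0.1, jitter = 1L, minus82 = FALSE) {
  m <- list(minus10 = motifSpec("minus10", "TATAAT", -12L, mutationRate, jitter),
            minus35 = motifSpec("minus35", "TTGACA", -35L, mutationRate, jitter))
  if (minus82)
    m$minus82 <- motifSpec("minus82", "TGTGAG", -85L, mutationRate, 0L)
  m
}

#' Generate an i.i.d. background genome
#'
#' Bases are drawn independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1-gc)/2`. Identical `(length, gc, seed)` give
#' byte-identical sequences.
#'
#' @param length genome length (>= 1).
#' @param gc target G+C fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @param id record identifier.
#' @return a [Genome-class].
#' @export
generateBackground <- function(length, gc = 0.5, seed = 1L, id = "synthetic") {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("'length' must be a positive integer")
  if (gc < 0 || gc > 1) stop("'gc' must lie in [0, 1]")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- .with_seed(seed,
    sample(names(p), length, replace = TRUE, prob = p))
  genome(id, paste(bases, collapse = ""))
}

# feasible strand-local TSS range so that all motif windows fit in-bounds
.tss_margins <- function(motifs) {
  lo <- 0L; hi <- 0L
  for (m in motifs) {
    w <- nchar(m@consensus)
    lo <- min(lo, m@offset - m@jitter)
    hi <- max(hi, m@offset + m@jitter + w - 1L)
  }
  c(upstream = -lo, downstream = max(0L, hi))
}

.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(b)) < rate
  if (any(hit)) {
    alt <- c("A", "C", "G", "T")
    b[hit] <- vapply(b[hit],
                     function(x) sample(setdiff(alt, x), 1L), character(1))
  }
  paste(b, collapse = "")
}

#' Plant promoter architecture into a genome
#'
#' Places `nSites` TSSs on both strands with pairwise same-strand
#' spacing of at least `minSpacing`, then writes each motif at its
#' (jittered) offset with per-base mutation. Minus-strand sites receive
#' the reverse complement of the motif at mirrored plus-strand
#' coordinates, so strand-local extraction recovers the planted
#' sequence. Every realization is recorded.
#'
#' @param g background [Genome-class] (copied, then modified).
#' @param nSites number of TSSs to place.
#' @param motifs list of [MotifSpec-class], e.g. [promoterMotifs()].
#' @param minSpacing minimal same-strand distance between TSSs (nt).
#' @param seed RNG seed.
#' @param maxTries placement attempts before giving up.
#' @return a [SyntheticTruth-class].
#' @export
plantPromoters <- function(g, nSites, motifs = promoterMotifs(),
                           minSpacing = 300L, seed = 1L,
                           maxTries = 200L * nSites) {
  stopifnot(nSites >= 1L)
  L <- genomeLength(g)
  marg <- .tss_margins(motifs)
  lo <- marg[["upstream"]]; hi <- L - 1L - marg[["downstream"]]
  if (hi < lo) stop("genome too short for the motif windows")
  # opposite-strand sites must not let motif windows collide either:
  # a plus site's window spans [p-up, p+down] in plus coordinates, a
  # minus site's [q-down, q+up], so any two windows are disjoint when
  # the plus-coordinate distance exceeds up + down
  cross_margin <- marg[["upstream"]] + marg[["downstream"]] + 1L
  .with_seed(seed, {
    placed <- list(`+` = integer(), `-` = integer())
    tries <- 0L
    while (sum(lengths(placed)) < nSites) {
      if ((tries <- tries + 1L) > maxTries)
        stop("could not place ", nSites, " sites with minSpacing ",
             minSpacing, " after ", maxTries, " tries")
      st <- sample(c("+", "-"), 1L)
      other <- if (st == "+") "-" else "+"
      p_local <- sample(seq.int(lo, hi), 1L)
      p_plus <- if (st == "+") p_local else L - 1L - p_local
      other_plus <- if (other == "+") placed[["+"]] else
        L - 1L - placed[["-"]]
      if ((!length(placed[[st]]) ||
           min(abs(placed[[st]] - p_local)) >= minSpacing) &&
          (!length(other_plus) ||
           min(abs(other_plus - p_plus)) >= cross_margin))
        placed[[st]] <- c(placed[[st]], p_local)
    }
    chars <- strsplit(as.character(genomeSeq(g)), "", fixed = TRUE)[[1]]
    rec <- list()
    for (st in c("+", "-")) {
      for (p_local in placed[[st]]) {
        pos <- if (st == "+") p_local else L - 1L - p_local  # plus coords
        for (m in motifs) {
          off <- m@offset +
            if (m@jitter > 0L) sample(seq.int(-m@jitter, m@jitter), 1L) else 0L
          realized <- .mutate_seq(m@consensus, m@mutationRate)
          w <- nchar(realized)
          if (st == "+") {
            idx <- seq.int(pos + off, length.out = w) + 1L
            chars[idx] <- strsplit(realized, "", fixed = TRUE)[[1]]
          } else {
            idx <- seq.int(pos - off - w + 1L, length.out = w) + 1L
            chars[idx] <- strsplit(.revcomp_chr(realized), "", fixed = TRUE)[[1]]
          }
          rec[[length(rec) + 1L]] <- data.frame(
            tss_pos = pos, strand = st, motif = m@name,
            realized_offset = off, realized_seq = realized)
        }
      }
    }
    planted <- do.call(rbind, rec)
    gg <- genome(genomeId(g), paste(chars, collapse = ""))
    tss <- tssSet(c(placed[["+"]], L - 1L - placed[["-"]]),
                  rep(c("+", "-"), c(length(placed[["+"]]),
                                     length(placed[["-"]]))),
                  "truth", 0L)
    new("SyntheticTruth", genome = gg, tss = tss, plantedSites = planted)
  })
}

#' Derive a noisy "experimental" annotation set from the truth
#'
#' Each true TSS is kept with probability `1 - dropoutRate` and shifted
#' by a uniform integer in `[-maxShift, maxShift]`; false positives are
#' placed uniformly, at least `maxShift + 1` away from any true TSS on
#' the same strand so that ground-truth evaluation stays unambiguous.
#' The output is sorted and deduplicated.
#'
#' @param truth a [SyntheticTruth-class].
#' @param noise a [NoiseSpec-class].
#' @param sourceName,priority metadata of the derived set.
#' @return a [TssSet-class].
#' @export
deriveNoisySet <- function(truth, noise, sourceName, priority) {
  L <- genomeLength(truthGenome(truth))
  e <- tssEntries(truthTss(truth))
  .with_seed(noise@seed, {
    keep <- runif(nrow(e)) >= noise@dropoutRate
    pos <- e$pos[keep]; st <- e$strand[keep]
    if (noise@maxShift > 0L && length(pos))
      pos <- pos + sample(seq.int(-noise@maxShift, noise@maxShift),
                          length(pos), replace = TRUE)
    ok <- pos >= 0L & pos < L
    pos <- pos[ok]; st <- st[ok]
    n_fp <- stats::rpois(1L, noise@fpRate * L / 1000)
    if (n_fp > 0L) {
      fp_pos <- integer(0); fp_st <- character(0)
      guard <- 0L
      while (length(fp_pos) < n_fp && (guard <- guard + 1L) < 50L * n_fp + 100L) {
        cand <- sample.int(L, 1L) - 1L
        cst <- sample(c("+", "-"), 1L)
        true_here <- e$pos[e$strand == cst]
        if (!length(true_here) ||
            min(abs(true_here - cand)) >= noise@maxShift + 1L) {
          fp_pos <- c(fp_pos, cand); fp_st <- c(fp_st, cst)
        }
      }
      pos <- c(pos, fp_pos); st <- c(st, fp_st)
    }
    tssSet(pos, st, sourceName, priority)
  })
}

#' Generate gene-like regions downstream of synthetic TSSs
#'
#' Builds non-overlapping same-strand coding intervals downstream of a
#' subset of the true TSSs (geometrically distributed lengths around
#' `geneLengthMean`), flags a fraction of them as pseudogenes, and
#' labels short same-strand gaps between consecutive genes as operon
#' gaps. Intervals never overlap on the same strand and stay in-bounds.
#'
#' @param truth a [SyntheticTruth-class].
#' @param geneLengthMean mean gene length (nt).
#' @param pseudogeneFraction fraction of genes flagged `pseudogene`.
#' @param seed RNG seed.
#' @param utr distance from TSS to gene start (nt).
#' @param useFraction fraction of TSSs that nucleate a gene.
#' @param operonGapMax same-strand gaps shorter than this between
#'   consecutive genes are labelled `operon_gap`.
#' @return a [RegionSet-class].
#' @export
generateRegions <- function(truth, geneLengthMean = 900L,
                            pseudogeneFraction = 0.1, seed = 1L,
                            utr = 30L, useFraction = 0.8,
                            operonGapMax = 200L) {
  L <- genomeLength(truthGenome(truth))
  e <- tssEntries(truthTss(truth))
  .with_seed(seed, {
    use <- runif(nrow(e)) < useFraction
    out <- list()
    for (st in c("+", "-")) {
      p <- sort(e$pos[use & e$strand == st])
      if (st == "-") p <- rev(p)
      prev_end <- NULL   # strand-local downstream bound of previous gene
      for (pos in p) {
        len <- utr + 1L + stats::rgeom(1L, 1 / geneLengthMean)
        kind <- if (runif(1) < pseudogeneFraction) "pseudogene" else "cds"
        if (st == "+") {
          a <- pos + utr; b <- min(pos + len, L)
          if (!is.null(prev_end) && a < prev_end$b) a <- prev_end$b
          if (a < b) {
            if (!is.null(prev_end) && a - prev_end$b > 0L &&
                a - prev_end$b <= operonGapMax)
              out[[length(out) + 1L]] <- data.frame(
                start = prev_end$b, end = a, strand = st, kind = "operon_gap")
            out[[length(out) + 1L]] <- data.frame(
              start = a, end = b, strand = st, kind = kind)
            prev_end <- list(b = b)
          }
        } else {
          b <- pos - utr + 1L; a <- max(pos - len + 1L, 0L)   # [a, b)
          if (!is.null(prev_end) && b > prev_end$a) b <- prev_end$a
          if (a < b) {
            if (!is.null(prev_end) && prev_end$a - b > 0L &&
                prev_end$a - b <= operonGapMax)
              out[[length(out) + 1L]] <- data.frame(
                start = b, end = prev_end$a, strand = st, kind = "operon_gap")
            out[[length(out) + 1L]] <- data.frame(
              start = a, end = b, strand = st, kind = kind)
            prev_end <- list(a = a)
          }
        }
      }
    }
    if (!length(out))
      return(regionSet(integer(), integer(), character(), character()))
    iv <- do.call(rbind, out)
    regionSet(iv$start, iv$end, iv$strand, iv$kind)
  })
}
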