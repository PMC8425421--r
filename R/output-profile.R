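# Genome-wide characterisation of the prediction track: median metaplots
# around site lists and per-region-class median summaries. Medians (never
# means) are used throughout; even counts take the midpoint.

#' Median metaplot of the prediction track around sites
#'
#' For every site, strand-local windows of `2 * halfWidth + 1`
#' positions are extracted from both strands: the site's own strand is
#' "sense", the opposite strand "antisense", and minus-strand windows
#' are reversed so that offsets increase downstream of the site. The
#' per-offset median across sites is returned. Sites whose window
#' leaves the genome are dropped with a warning.
#'
#' @param track a [PredictionTrack-class].
#' @param sites a [TssSet-class], [CuratedSet-class] or
#'   `data.frame(pos, strand)`.
#' @param halfWidth window half-width (default 600, i.e. a
#'   1201-nucleotide window).
#' @return `data.frame(offset, sense, antisense)` with attribute
#'   `n_sites`.
#' @export
metaplotTrack <- function(track, sites, halfWidth = 600L) {
  if (is(sites, "TssSet")) sites <- tssEntries(sites)
  if (is(sites, "CuratedSet")) sites <- curatedEntries(sites)
  stopifnot(nrow(sites) >= 1L)
  hw <- as.integer(halfWidth)
  L <- length(track@fwd)
  ok <- sites$pos - hw >= 0L & sites$pos + hw < L
  if (!all(ok))
    warning(sum(!ok), " site(s) with out-of-bounds windows dropped")
  sites <- sites[ok, , drop = FALSE]
  if (!nrow(sites)) stop("all sites out of bounds")
  offs <- seq.int(-hw, hw)
  sense <- matrix(NA_real_, nrow(sites), length(offs))
  anti <- matrix(NA_real_, nrow(sites), length(offs))
  for (i in seq_len(nrow(sites))) {
    p <- sites$pos[i]
    if (sites$strand[i] == "+") {
      idx <- (p + offs) + 1L
      sense[i, ] <- track@fwd[idx]
      anti[i, ] <- track@rev[idx]
    } else {
      idx <- (p - offs) + 1L
      sense[i, ] <- track@rev[idx]
      anti[i, ] <- track@fwd[idx]
    }
  }
  out <- data.frame(offset = offs,
                    sense = apply(sense, 2, median),
                    antisense = apply(anti, 2, median))
  attr(out, "n_sites") <- nrow(sites)
  out
}

# positions (0-based) covered by intervals of a kind, on either strand,
# restricted to the split
.covered_positions <- function(iv, split) {
  if (!nrow(iv)) return(integer())
  q <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)  # 1-based closed
  s <- IRanges::IRanges(start = split$start + 1L, end = split$end)
  hits <- IRanges::intersect(IRanges::reduce(q), IRanges::reduce(s))
  if (!length(hits)) return(integer())
  unlist(lapply(seq_along(hits), function(i)
    seq.int(IRanges::start(hits)[i], IRanges::end(hits)[i])), use.names = FALSE) - 1L
}

#' Median output probability per region class
#'
#' Every split position is classified independently per class: `cds` if
#' covered by a coding interval on either strand, `intergenic` if
#' covered by no interval of any kind, `operon_gap` / `pseudogene` if
#' covered by such an interval (classes may overlap). For each class
#' the median probability is reported per strand and combined; empty
#' classes give `NA`.
#'
#' @param track a [PredictionTrack-class].
#' @param regions a [RegionSet-class].
#' @param split `data.frame(start, end)`.
#' @return `data.frame(kind, fwd, rev, combined, n_positions)`.
#' @export
regionMedians <- function(track, regions, split) {
  iv <- regionTable(regions)
  kinds <- c("cds", "operon_gap", "pseudogene", "intergenic")
  res <- lapply(kinds, function(kd) {
    pos <- if (kd == "intergenic") {
      allc <- .covered_positions(iv, split)
      setdiff(.split_positions(split), allc)
    } else {
      .covered_positions(iv[iv$kind == kd, , drop = FALSE], split)
    }
    if (!length(pos))
      return(data.frame(kind = kd, fwd = NA_real_, rev = NA_real_,
                        combined = NA_real_, n_positions = 0L))
    f <- track@fwd[pos + 1L]; r <- track@rev[pos + 1L]
    data.frame(kind = kd, fwd = median(f), rev = median(r),
               combined = median(c(f, r)), n_positions = length(pos))
  })
  do.call(rbind, res)
}

#' Median of per-region maxima
#'
#' For short regions (typically operon gaps) whose peaks matter more
#' than their overall level: per region, the maximum probability on the
#' region's own strand (sense) and the opposite strand (antisense);
#' then the median across regions.
#'
#' @param track a [PredictionTrack-class].
#' @param regions a [RegionSet-class]; only intervals of `kind` are
#'   used.
#' @param kind region class to summarise (default `operon_gap`).
#' @return list with `sense`, `antisense` medians and `n_regions`.
#' @export
peakSummary <- function(track, regions, kind = "operon_gap") {
  iv <- regionTable(regions)
  iv <- iv[iv$kind == kind, , drop = FALSE]
  if (!nrow(iv)) stop("no regions of kind ", kind)
  mx_sense <- numeric(nrow(iv)); mx_anti <- numeric(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    idx <- (iv$start[i] + 1L):iv$end[i]
    own <- if (iv$strand[i] == "+") track@fwd else track@rev
    oth <- if (iv$strand[i] == "+") track@rev else track@fwd
    mx_sense[i] <- max(own[idx]); mx_anti[i] <- max(oth[idx])
  }
  list(sense = median(mx_sense), antisense = median(mx_anti),
       n_regions = nrow(iv))
}
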