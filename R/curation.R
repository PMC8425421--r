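# Merging multiple TSS annotation sources. Two annotations are "shared"
# when they sit within `window` nt of one another on the same strand;
# sharing is extended to connected components, so a cluster may span more
# than `window` nt through chaining (a warning is emitted when it does).

.pool_sets <- function(sets) {
  do.call(rbind, lapply(sets, function(s) {
    e <- tssEntries(s)
    if (!nrow(e)) return(NULL)
    data.frame(source = sourceName(s), pos = e$pos, strand = e$strand)
  }))
}

#' Cluster shared TSS annotations across sources
#'
#' Per strand, clusters are the connected components of the graph that
#' joins any two annotations (from any sources, including the same
#' source) at distance `<= window`. Every annotation lands in exactly
#' one cluster. In one dimension the components are simply maximal runs
#' of sorted positions with consecutive gaps `<= window`.
#'
#' @param sets list of [TssSet-class].
#' @param window sharing distance (nt), default 5.
#' @return list of `data.frame`s with columns `source`, `pos`, `strand`.
#' @export
clusterShared <- function(sets, window = 5L) {
  stopifnot(length(sets) >= 1L, window >= 0L)
  pool <- .pool_sets(sets)
  if (is.null(pool)) return(list())
  out <- list()
  for (st in unique(pool$strand)) {
    p <- pool[pool$strand == st, , drop = FALSE]
    p <- p[order(p$pos, p$source), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(p$pos) > window)))
    for (gid in split(seq_len(nrow(p)), grp)) {
      cl <- p[gid, , drop = FALSE]
      rownames(cl) <- NULL
      if (max(cl$pos) - min(cl$pos) > window)
        message("cluster spans ", max(cl$pos) - min(cl$pos),
                " nt (> window) through chaining at ", st, min(cl$pos))
      out[[length(out) + 1L]] <- cl
    }
  }
  out
}

#' Source-overlap (Venn) counts of shared clusters
#'
#' Each cluster is counted once under the subset of sources present in
#' it; counts over all subsets sum to the number of clusters.
#'
#' @inheritParams clusterShared
#' @return named integer vector over all non-empty source subsets
#'   (subset key = source names sorted and joined with `"&"`).
#' @export
vennCounts <- function(sets, window = 5L) {
  if (length(sets) < 2L || length(sets) > 8L)
    stop("vennCounts expects between 2 and 8 sets")
  srcs <- sort(vapply(sets, sourceName, character(1)))
  if (anyDuplicated(srcs)) stop("duplicate source names")
  keys <- unlist(lapply(seq_along(srcs), function(k)
    apply(utils::combn(srcs, k), 2, paste, collapse = "&")))
  counts <- stats::setNames(integer(length(keys)), keys)
  for (cl in clusterShared(sets, window)) {
    key <- paste(sort(unique(cl$source)), collapse = "&")
    counts[key] <- counts[key] + 1L
  }
  counts
}

#' Histogram of annotation shifts between two sources
#'
#' For every annotation of `setA`, the signed offsets (`pos_b - pos_a`)
#' to all same-strand annotations of `setB` within `window` nt are
#' tallied, centred on `setA`. Swapping the arguments mirrors the
#' histogram (`mass(a->b at +d) == mass(b->a at -d)`).
#'
#' @param setA,setB two [TssSet-class] objects.
#' @param window maximal distance (nt).
#' @return named integer vector over offsets `-window..window`.
#' @export
offsetHistogram <- function(setA, setB, window = 5L) {
  offs <- seq.int(-window, window)
  h <- stats::setNames(integer(length(offs)), offs)
  a <- tssEntries(setA); b <- tssEntries(setB)
  for (st in c("+", "-")) {
    pa <- a$pos[a$strand == st]; pb <- b$pos[b$strand == st]
    if (!length(pa) || !length(pb)) next
    for (p in pa) {
      d <- pb[abs(pb - p) <= window] - p
      if (length(d)) {
        t <- table(d)
        h[names(t)] <- h[names(t)] + as.integer(t)
      }
    }
  }
  h
}

# one vote per source per cluster: a source voting with several positions
# votes with the one closest to the cluster median (ties -> smaller coord)
.cluster_votes <- function(cl) {
  med <- stats::median(cl$pos)
  votes <- lapply(split(cl$pos, cl$source), function(p) {
    d <- abs(p - med)
    cand <- p[d == min(d)]
    min(cand)
  })
  data.frame(source = names(votes), pos = unlist(votes, use.names = FALSE))
}

#' Curate a consensus TSS set from multiple sources
#'
#' Applies three rules. Rule 1: every cluster (see [clusterShared()])
#' containing annotations from at least two distinct sources yields one
#' curated entry. Rule 2: its position is the modal voted position (one
#' vote per source); a tie is broken in favour of the tied position
#' contributed by the source with the highest priority (the newest
#' technique). Rule 3: if a `preferredSource` is named, all of its
#' annotations not already within `window` of a curated entry are added
#' verbatim. The result is deduplicated and sorted.
#'
#' @param sets list of [TssSet-class].
#' @param priorityOrder optional character vector of source names in
#'   decreasing priority; defaults to the sets' own priority ranks.
#'   Every source must be ranked.
#' @param window sharing distance (nt).
#' @param preferredSource optional source whose annotations are added in
#'   full (rule 3); `NULL` skips the rule.
#' @return a [CuratedSet-class].
#' @export
curateTss <- function(sets, priorityOrder = NULL, window = 5L,
                      preferredSource = NULL) {
  srcs <- vapply(sets, sourceName, character(1))
  if (is.null(priorityOrder)) {
    pr <- vapply(sets, sourcePriority, integer(1))
    priorityOrder <- srcs[order(-pr)]
  }
  if (!all(priorityOrder %in% srcs))
    stop("unknown source in priorityOrder: ",
         paste(setdiff(priorityOrder, srcs), collapse = ", "))
  if (!all(srcs %in% priorityOrder))
    stop("priorityOrder must rank every source")
  rank_of <- stats::setNames(seq_along(priorityOrder), priorityOrder)
  if (!is.null(preferredSource) && !preferredSource %in% srcs)
    stop("preferredSource not among the sets")

  rows <- list()
  for (cl in clusterShared(sets, window)) {
    n_src <- length(unique(cl$source))
    if (n_src < 2L) next
    v <- .cluster_votes(cl)
    tab <- table(v$pos)
    top <- as.integer(names(tab)[tab == max(tab)])
    if (length(top) == 1L) {
      pos <- top; how <- "majority"
    } else {
      cand <- v[v$pos %in% top, , drop = FALSE]
      cand <- cand[order(rank_of[cand$source], cand$pos), , drop = FALSE]
      pos <- cand$pos[1]; how <- "priority_tiebreak"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pos = pos, strand = cl$strand[1],
      supporting_sources = paste(sort(unique(cl$source)), collapse = ";"),
      n_sources = n_src, chosen_by = how)
  }
  cur <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos = integer(), strand = character(),
               supporting_sources = character(), n_sources = integer(),
               chosen_by = character())

  if (!is.null(preferredSource)) {
    pref <- tssEntries(sets[[match(preferredSource, srcs)]])
    for (i in seq_len(nrow(pref))) {
      here <- cur$pos[cur$strand == pref$strand[i]]
      if (!length(here) || min(abs(here - pref$pos[i])) > window)
        cur <- rbind(cur, data.frame(
          pos = pref$pos[i], strand = pref$strand[i],
          supporting_sources = preferredSource, n_sources = 1L,
          chosen_by = "preferred_source"))
    }
  }
  cur <- cur[!duplicated(cur[c("pos", "strand")]), , drop = FALSE]
  cur <- cur[order(cur$strand, cur$pos), , drop = FALSE]
  rownames(cur) <- NULL
  new("CuratedSet", entries = cur, window = as.integer(window))
}

#' Convert a CuratedSet to a TssSet
#'
#' @param x a [CuratedSet-class].
#' @param sourceName,priority metadata for the resulting set.
#' @return a [TssSet-class].
#' @export
curatedToTssSet <- function(x, sourceName = "curated", priority = 99L) {
  e <- curatedEntries(x)
  tssSet(e$pos, e$strand, sourceName, priority)
}
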