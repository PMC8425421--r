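#' @import methods
#' @importFrom stats median cor p.adjust runif rnorm wilcox.test quantile
#' @importFrom utils head tail
#' @useDynLib tssformer, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Genome: a single stranded nucleotide sequence
#'
#' Container for one chromosome/replicon. The sequence is stored as a
#' [Biostrings::DNAString] restricted to the alphabet `A,C,G,T,N`; all
#' coordinates in the package are 0-based and refer to the plus strand,
#' with a strand flag where features are stranded.
#'
#' @slot id single identifier string (FASTA record name).
#' @slot seq the sequence, a `DNAString`.
#' @importClassesFrom Biostrings DNAString
#' @exportClass Genome
setClass("Genome", representation(id = "character", seq = "DNAString"))

setValidity("Genome", function(object) {
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    return("'id' must be a single non-empty string")
  freq <- Biostrings::alphabetFrequency(object@seq)
  extra <- sum(freq) - sum(freq[c("A", "C", "G", "T", "N")])
  if (extra > 0)
    return("sequence contains characters outside {A,C,G,T,N}")
  TRUE
})

#' TssSet: one source's transcription start site annotations
#'
#' A set of stranded, single-nucleotide TSS positions from one annotation
#' source (one experimental technique), carrying the source name and a
#' priority rank (higher = newer/more trusted technique, used for
#' tie-breaking during curation).
#'
#' @slot sourceName name of the annotation source.
#' @slot priority integer rank; higher wins ties.
#' @slot entries `data.frame` with integer column `pos` (0-based) and
#'   character column `strand` (`"+"`/`"-"`), sorted by strand then
#'   position, unique per (pos, strand).
#' @exportClass TssSet
setClass("TssSet", representation(sourceName = "character",
                                  priority = "integer",
                                  entries = "data.frame"))

setValidity("TssSet", function(object) {
  e <- object@entries
  if (!identical(colnames(e), c("pos", "strand")))
    return("'entries' must have columns pos, strand")
  if (nrow(e)) {
    if (!is.integer(e$pos) || any(e$pos < 0L))
      return("positions must be non-negative integers")
    if (!all(e$strand %in% c("+", "-")))
      return("strand must be '+' or '-'")
    if (anyDuplicated(e))
      return("duplicate (pos, strand) entries")
    o <- order(e$strand, e$pos)
    if (!identical(o, seq_len(nrow(e))))
      return("entries must be sorted by strand then position")
  }
  if (length(object@priority) != 1L) return("'priority' must be scalar")
  TRUE
})

#' RegionSet: classified genomic intervals
#'
#' Intervals of the kinds used for output-profile summaries: coding
#' sequence (`cds`), non-coding gaps inside operons (`operon_gap`),
#' `pseudogene` and `intergenic`. Coordinates are 0-based half-open.
#'
#' @slot intervals `data.frame` with columns `start`, `end` (integer,
#'   half-open), `strand`, `kind`.
#' @exportClass RegionSet
setClass("RegionSet", representation(intervals = "data.frame"))

.region_kinds <- c("cds", "operon_gap", "pseudogene", "intergenic")

setValidity("RegionSet", function(object) {
  iv <- object@intervals
  need <- c("start", "end", "strand", "kind")
  if (!all(need %in% colnames(iv)))
    return("'intervals' must have columns start, end, strand, kind")
  if (nrow(iv)) {
    if (any(iv$start >= iv$end)) return("start must be < end")
    if (any(iv$start < 0L)) return("negative start")
    if (!all(iv$strand %in% c("+", "-"))) return("bad strand")
    if (!all(iv$kind %in% .region_kinds))
      return(paste("kind must be one of:", paste(.region_kinds, collapse = ", ")))
  }
  TRUE
})

#' LabelTrack: per-position, per-strand binary labels
#'
#' Binary target used for training: one value per genome position per
#' strand, positives at the (shifted) TSS coordinates. Values are stored
#' in plus-strand coordinates for both strands.
#'
#' @slot fwd,rev integer 0/1 vectors of genome length.
#' @slot shiftOffset the downstream label shift (nt) that was applied.
#' @exportClass LabelTrack
setClass("LabelTrack", representation(fwd = "integer", rev = "integer",
                                      shiftOffset = "integer"))

setValidity("LabelTrack", function(object) {
  if (length(object@fwd) != length(object@rev))
    return("strand tracks differ in length")
  if (!all(object@fwd %in% c(0L, 1L)) || !all(object@rev %in% c(0L, 1L)))
    return("labels must be 0/1")
  TRUE
})

#' PredictionTrack: per-position, per-strand output probabilities
#'
#' The model's continuous output probability profile along the genome,
#' one value per position per strand, in plus-strand coordinates.
#'
#' @slot fwd,rev numeric vectors in `[0, 1]`, genome length each.
#' @exportClass PredictionTrack
setClass("PredictionTrack", representation(fwd = "numeric", rev = "numeric"))

setValidity("PredictionTrack", function(object) {
  if (length(object@fwd) != length(object@rev))
    return("strand tracks differ in length")
  rng <- range(c(object@fwd, object@rev), na.rm = TRUE)
  if (length(object@fwd) && (rng[1] < 0 || rng[2] > 1))
    return("probabilities must lie in [0, 1]")
  TRUE
})

#' MotifSpec: a promoter element to plant
#'
#' Describes one sequence element written upstream of synthetic TSSs:
#' its consensus, its offset relative to the TSS (negative = upstream;
#' the offset addresses the motif's first base in strand-local
#' coordinates), a per-base mutation rate and a maximal uniform jitter
#' of the planted offset.
#'
#' @slot name label used in bookkeeping (e.g. `"minus10"`).
#' @slot consensus nucleotide string over `A,C,G,T`.
#' @slot offset signed integer, motif start relative to the TSS.
#' @slot mutationRate probability in `[0,1]` that each base is replaced
#'   by a different random base.
#' @slot jitter non-negative integer, max uniform shift of the offset.
#' @exportClass MotifSpec
setClass("MotifSpec", representation(name = "character", consensus = "character",
                                     offset = "integer", mutationRate = "numeric",
                                     jitter = "integer"))

setValidity("MotifSpec", function(object) {
  if (!grepl("^[ACGT]+$", object@consensus))
    return("consensus must be over {A,C,G,T}")
  if (object@mutationRate < 0 || object@mutationRate > 1)
    return("mutationRate must lie in [0,1]")
  if (object@jitter < 0L) return("jitter must be >= 0")
  TRUE
})

#' NoiseSpec: how to corrupt a ground-truth TSS set
#'
#' Parameters of the noise applied when deriving one "experimental"
#' annotation set from the synthetic truth: positional jitter, dropout
#' and uniformly placed false positives.
#'
#' @slot maxShift max absolute positional shift (nt); the default cap of
#'   5 keeps noise inside the curation sharing window.
#' @slot dropoutRate probability a true site is dropped.
#' @slot fpRate expected false annotations per kb of genome.
#' @slot seed RNG seed for this derivation.
#' @exportClass NoiseSpec
setClass("NoiseSpec", representation(maxShift = "integer", dropoutRate = "numeric",
                                     fpRate = "numeric", seed = "integer"))

setValidity("NoiseSpec", function(object) {
  if (object@maxShift < 0L) return("maxShift must be >= 0")
  if (object@dropoutRate < 0 || object@dropoutRate > 1)
    return("dropoutRate must lie in [0,1]")
  if (object@fpRate < 0) return("fpRate must be >= 0")
  TRUE
})

#' SyntheticTruth: a synthetic genome plus its ground truth
#'
#' @slot genome the generated [Genome-class].
#' @slot tss ground-truth [TssSet-class].
#' @slot plantedSites `data.frame` recording every realized motif:
#'   columns `tss_pos`, `strand`, `motif`, `realized_offset`,
#'   `realized_seq`.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth", representation(genome = "Genome", tss = "TssSet",
                                          plantedSites = "data.frame"))

#' CuratedSet: the merged multi-source TSS annotation
#'
#' Result of applying the three curation rules (shared-by-two,
#' majority-vote position with novelty tie-break, preferred-source
#' top-up) to several [TssSet-class] objects.
#'
#' @slot entries `data.frame` with columns `pos`, `strand`,
#'   `supporting_sources` (`";"`-joined), `n_sources`, `chosen_by`
#'   (`majority`, `priority_tiebreak` or `preferred_source`).
#' @slot window the sharing window (nt) used.
#' @exportClass CuratedSet
setClass("CuratedSet", representation(entries = "data.frame", window = "integer"))

setValidity("CuratedSet", function(object) {
  e <- object@entries
  if (nrow(e) && anyDuplicated(e[c("pos", "strand")]))
    return("duplicate curated (pos, strand)")
  TRUE
})

#' TransformerModel: the attention network and its weights
#'
#' Self-describing model object: the architecture configuration (see
#' [modelConfig()]) and a flat parameter vector whose layout is fixed by
#' the configuration. All numerics run through compiled code; the R
#' object is plain data, so it serialises trivially.
#'
#' @slot config named list, see [modelConfig()].
#' @slot params flat numeric parameter vector.
#' @exportClass TransformerModel
setClass("TransformerModel", representation(config = "list", params = "numeric"))

#' TrainReport: what happened during training
#'
#' @slot history `data.frame` with per-epoch `epoch`, `train_loss`,
#'   `val_loss`.
#' @slot bestEpoch epoch with minimum validation loss (the checkpoint
#'   that is kept).
#' @slot metrics named list of final evaluation numbers (may be empty).
#' @exportClass TrainReport
setClass("TrainReport", representation(history = "data.frame",
                                       bestEpoch = "integer",
                                       metrics = "list"))

setMethod("show", "Genome", function(object) {
  cat(sprintf("Genome '%s': %d bp\n", object@id, length(object@seq)))
})

setMethod("show", "TssSet", function(object) {
  cat(sprintf("TssSet '%s' (priority %d): %d sites (+%d/-%d)\n",
              object@sourceName, object@priority, nrow(object@entries),
              sum(object@entries$strand == "+"),
              sum(object@entries$strand == "-")))
})

setMethod("show", "RegionSet", function(object) {
  tab <- table(object@intervals$kind)
  cat("RegionSet:", nrow(object@intervals), "intervals (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
})

setMethod("show", "CuratedSet", function(object) {
  cat(sprintf("CuratedSet: %d sites (window %d nt)\n",
              nrow(object@entries), object@window))
  print(table(object@entries$chosen_by))
})

setMethod("show", "TransformerModel", function(object) {
  cfg <- object@config
  cat(sprintf(paste0("TransformerModel: l=%d, k=%d layers x %d heads ",
                     "(d_head=%d), embed=%d, conv=%d, %d parameters\n"),
              cfg$segment_length, cfg$num_layers, cfg$heads_per_layer,
              cfg$head_dim, cfg$embed_dim, cfg$conv_width,
              length(object@params)))
})

setMethod("show", "TrainReport", function(object) {
  cat(sprintf("TrainReport: %d epochs, best epoch %d (val loss %.5f)\n",
              nrow(object@history), object@bestEpoch,
              object@history$val_loss[object@bestEpoch]))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:\n  ")
  show(object@genome)
  cat("  ")
  show(object@tss)
  cat(sprintf("  %d planted motif instances (%s)\n",
              nrow(object@plantedSites),
              paste(unique(object@plantedSites$motif), collapse = ", ")))
})
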