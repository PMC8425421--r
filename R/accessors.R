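# Accessor generics for the central containers. Slot access stays internal;
# user code goes through these.

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setGeneric("tssEntries", function(x) standardGeneric("tssEntries"))
#' @rdname accessors
#' @export
setGeneric("sourceName", function(x) standardGeneric("sourceName"))
#' @rdname accessors
#' @export
setGeneric("sourcePriority", function(x) standardGeneric("sourcePriority"))
#' @rdname accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))
#' @rdname accessors
#' @export
setGeneric("trackValues", function(x, strand) standardGeneric("trackValues"))
#' @rdname accessors
#' @export
setGeneric("curatedEntries", function(x) standardGeneric("curatedEntries"))
#' @rdname accessors
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))
#' @rdname accessors
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))
#' @rdname accessors
#' @export
setGeneric("trainHistory", function(x) standardGeneric("trainHistory"))
#' @rdname accessors
#' @export
setGeneric("truthGenome", function(x) standardGeneric("truthGenome"))
#' @rdname accessors
#' @export
setGeneric("truthTss", function(x) standardGeneric("truthTss"))
#' @rdname accessors
#' @export
setGeneric("plantedSites", function(x) standardGeneric("plantedSites"))

#' Accessors for tssformer containers
#'
#' Small read-only accessors: `genomeId()`, `genomeSeq()`,
#' `genomeLength()` for [Genome-class]; `tssEntries()`, `sourceName()`,
#' `sourcePriority()` for [TssSet-class]; `regionTable()` for
#' [RegionSet-class]; `trackValues(x, strand)` for [LabelTrack-class]
#' and [PredictionTrack-class]; `curatedEntries()` for
#' [CuratedSet-class]; `modelConfigOf()` / `modelParams()` for
#' [TransformerModel-class]; `trainHistory()` for [TrainReport-class];
#' `truthGenome()`, `truthTss()`, `plantedSites()` for
#' [SyntheticTruth-class].
#'
#' @param x the object.
#' @param strand `"+"` or `"-"`.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
setMethod("genomeId", "Genome", function(x) x@id)
#' @rdname accessors
setMethod("genomeSeq", "Genome", function(x) x@seq)
#' @rdname accessors
setMethod("genomeLength", "Genome", function(x) length(x@seq))
#' @rdname accessors
setMethod("tssEntries", "TssSet", function(x) x@entries)
#' @rdname accessors
setMethod("sourceName", "TssSet", function(x) x@sourceName)
#' @rdname accessors
setMethod("sourcePriority", "TssSet", function(x) x@priority)
#' @rdname accessors
setMethod("regionTable", "RegionSet", function(x) x@intervals)
#' @rdname accessors
setMethod("curatedEntries", "CuratedSet", function(x) x@entries)
#' @rdname accessors
setMethod("modelConfigOf", "TransformerModel", function(x) x@config)
#' @rdname accessors
setMethod("modelParams", "TransformerModel", function(x) x@params)
#' @rdname accessors
setMethod("trainHistory", "TrainReport", function(x) x@history)
#' @rdname accessors
setMethod("truthGenome", "SyntheticTruth", function(x) x@genome)
#' @rdname accessors
setMethod("truthTss", "SyntheticTruth", function(x) x@tss)
#' @rdname accessors
setMethod("plantedSites", "SyntheticTruth", function(x) x@plantedSites)

.check_strand <- function(strand) {
  if (!is.character(strand) || length(strand) != 1L ||
      !strand %in% c("+", "-"))
    stop("'strand' must be \"+\" or \"-\"")
  strand
}

#' @rdname accessors
setMethod("trackValues", "LabelTrack", function(x, strand) {
  if (.check_strand(strand) == "+") x@fwd else x@rev
})
#' @rdname accessors
setMethod("trackValues", "PredictionTrack", function(x, strand) {
  if (.check_strand(strand) == "+") x@fwd else x@rev
})
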