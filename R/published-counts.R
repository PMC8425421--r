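# Published tallies of the four E. coli MG1655 TSS annotation campaigns
# (RegulonDB's strong-evidence collection and three in vivo sequencing
# techniques), used for bookkeeping arithmetic: shared-site percentages,
# split sizes and the attention-score count of a full-scale analysis.
# The annotation files themselves are not shipped; only the printed
# counts are, as plain inputs.

#' Published TSS annotation source tallies (E. coli MG1655)
#'
#' Positive-label counts per source, the number of sites shared with at
#' least one other source (5-nt sharing window), and derived columns:
#' negatives (`2 * genomeLength - positives`, both strands) and the
#' shared percentage.
#'
#' @param genomeLength reference genome length (NC_000913.3:
#'   4,641,652 nt).
#' @return `data.frame(source, technique, year, positives, shared,
#'   negatives, shared_pct)`.
#' @export
tssSourceOverview <- function(genomeLength = 4641652L) {
  d <- data.frame(
    source = c("RegulonDB", "Cappable-seq", "SMRT-Cappable-seq", "SEnd-seq"),
    technique = c("collection", "Cappable-seq", "SMRT-Cappable-seq",
                  "SEnd-seq"),
    year = c(NA_integer_, 2016L, 2018L, 2019L),
    positives = c(6487L, 16348L, 2574L, 5502L),
    shared = c(2476L, 4631L, 2311L, 4026L))
  d$negatives <- 2L * genomeLength - d$positives
  d$shared_pct <- 100 * d$shared / d$positives
  d
}

#' Sample-count arithmetic for a full-scale genome-wide analysis
#'
#' Derived sizes when a model with the given attention geometry is
#' trained on both strands of a genome: the total sample count, the
#' test-split size at the given fraction, an approximate 1% analysis
#' sample, and the total number of attention scores a full test-set
#' sweep would touch (layers x heads x positions x window).
#'
#' @param genomeLength genome length in nt.
#' @param testFraction test split fraction.
#' @param numLayers,headsPerLayer,segmentLength attention geometry
#'   (defaults: the full-scale 6 x 6 architecture with 512-nt window).
#' @param sampleFraction analysis sampling fraction.
#' @return named list of counts.
#' @export
sampleArithmetic <- function(genomeLength = 4641652L, testFraction = 0.2,
                             numLayers = 6L, headsPerLayer = 6L,
                             segmentLength = 512L, sampleFraction = 0.01) {
  total <- 2 * genomeLength
  test_size <- floor(testFraction * total)
  list(total_samples = total,
       test_set_size = test_size,
       analysis_sample = floor(sampleFraction * test_size),
       attention_scores_total =
         as.numeric(numLayers) * headsPerLayer * test_size * segmentLength)
}
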