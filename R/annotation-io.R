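# On-disk formats. One convention everywhere inside the package: 0-based
# half-open plus-strand coordinates; conversions happen only here, at the
# file boundary (BED/bedGraph are native 0-based, GFF3 is 1-based closed).

#' Read / write a single-record FASTA file
#'
#' Only single-record FASTA is supported (one replicon). Lowercase input
#' is uppercased; characters outside `A,C,G,T,N` become `N` with a
#' warning. `writeFasta()` then `readFasta()` is the identity.
#'
#' @param path file path.
#' @return `readFasta()` returns a [Genome-class].
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty FASTA: ", path)
  if (length(recs) > 1L)
    stop("multi-record FASTA not supported (", length(recs), " records)")
  id <- sub("\\s.*$", "", names(recs)[1])
  genome(id, as.character(recs[[1]]))
}

#' @param g a [Genome-class].
#' @param width line width for the sequence.
#' @rdname readFasta
#' @export
writeFasta <- function(g, path, width = 70L) {
  x <- Biostrings::DNAStringSet(g@seq)
  names(x) <- genomeId(g)
  Biostrings::writeXStringSet(x, path, width = as.integer(width))
  invisible(path)
}

#' Read / write TSS annotations as BED6
#'
#' Features must be single-nucleotide (`end == start + 1`) and stranded.
#' On write, the BED score column carries the source priority. Reading
#' sorts and deduplicates; malformed lines are reported with their line
#' number.
#'
#' @param path file path.
#' @param sourceName,priority metadata attached to the returned set (on
#'   read, `priority = NA` defaults to the BED score of the first line).
#' @return `readTssBed()` returns a [TssSet-class].
#' @export
readTssBed <- function(path, sourceName, priority = NA_integer_) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(tssSet(integer(), character(), sourceName,
                                    if (is.na(priority)) 0L else priority))
  pos <- integer(length(lines)); strand <- character(length(lines))
  score <- integer(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L)
      stop(sprintf("line %d: expected 6 BED fields, got %d", i, length(f)))
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e))
      stop(sprintf("line %d: non-integer coordinates", i))
    if (e != s + 1L)
      stop(sprintf("line %d: feature is not single-nucleotide (width %d)",
                   i, e - s))
    if (!f[6] %in% c("+", "-"))
      stop(sprintf("line %d: strand must be '+' or '-', got '%s'", i, f[6]))
    pos[i] <- s; strand[i] <- f[6]
    score[i] <- suppressWarnings(as.integer(f[5]))
  }
  if (is.na(priority)) priority <- if (!is.na(score[1])) score[1] else 0L
  tssSet(pos, strand, sourceName, priority)
}

#' @param x a [TssSet-class].
#' @param chrom chromosome name to write in column 1.
#' @rdname readTssBed
#' @export
writeTssBed <- function(x, path, chrom = "chr") {
  e <- tssEntries(x)
  lines <- sprintf("%s\t%d\t%d\t%s_%d\t%d\t%s", chrom, e$pos, e$pos + 1L,
                   sourceName(x), seq_len(max(1L, nrow(e)))[seq_len(nrow(e))],
                   sourcePriority(x), e$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write region annotations as GFF3
#'
#' Regions (see [RegionSet-class]) are written one GFF3 feature per
#' interval with the kind in column 3 and a `pseudogene=true` attribute
#' on pseudogene intervals. GFF3 1-based closed coordinates are
#' converted to the internal 0-based half-open convention on read.
#'
#' @param path file path.
#' @return `readRegionsGff()` returns a [RegionSet-class].
#' @export
readRegionsGff <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(regionSet(integer(), integer(), character(), character()))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  if (ncol(f) != 9L) stop("malformed GFF3: expected 9 columns")
  kind <- f[, 3]
  kind[grepl("pseudogene=true", f[, 9], fixed = TRUE)] <- "pseudogene"
  regionSet(as.integer(f[, 4]) - 1L, as.integer(f[, 5]), f[, 7], kind)
}

#' @param x a [RegionSet-class].
#' @param chrom sequence name for column 1.
#' @rdname readRegionsGff
#' @export
writeRegionsGff <- function(x, path, chrom = "chr") {
  iv <- regionTable(x)
  attr9 <- ifelse(iv$kind == "pseudogene",
                  sprintf("ID=region%d;pseudogene=true", seq_len(nrow(iv))),
                  sprintf("ID=region%d", seq_len(nrow(iv))))
  lines <- c("##gff-version 3",
             sprintf("%s\ttssformer\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     chrom, iv$kind, iv$start + 1L, iv$end, iv$strand, attr9))
  writeLines(lines, path)
  invisible(path)
}

#' Write one strand of a prediction track as bedGraph
#'
#' Runs of equal-valued positions are collapsed into single intervals;
#' values are printed with four decimals.
#'
#' @param track a [PredictionTrack-class].
#' @param strand which strand's values to write.
#' @param path output path.
#' @param chrom chromosome name.
#' @export
writeBedGraph <- function(track, strand, path, chrom = "chr") {
  v <- round(trackValues(track, strand), 4)
  n <- length(v)
  if (n == 0L) { writeLines(character(), path); return(invisible(path)) }
  brk <- c(0L, which(diff(v) != 0), n)     # run boundaries
  starts <- brk[-length(brk)]
  ends <- brk[-1]
  writeLines(sprintf("%s\t%d\t%d\t%.4f", chrom, starts, ends, v[starts + 1L]),
             path)
  invisible(path)
}

#' Write a manifest of synthetic-data generation settings
#'
#' Records seeds and specs of a generation run as YAML so a dataset can
#' be regenerated exactly.
#'
#' @param path output path.
#' @param ... named settings (scalars, vectors, nested lists).
#' @export
writeManifest <- function(path, ...) {
  yaml::write_yaml(list(...), path)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) yaml::read_yaml(path)
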