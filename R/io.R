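#' Write a field as multi-page TIFF with a JSON sidecar
#'
#' Pages are written in the order DAPI, CK, CD45 as 16-bit TIFF; the
#' sidecar (`<path>.json`) records channel order and pixel size.
#'
#' @param field a [FluorescentField-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeField <- function(field, path) {
  chn <- c("DAPI", "CK", "CD45")
  pages <- lapply(chn, function(nm) getChannel(field, nm) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(channels = chn, pixel_size_um = field@pixelSize)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a field written by [writeField()]
#'
#' @param path TIFF path (expects `<path>.json` sidecar; falls back to the
#'   default channel order and 1 um/px without it).
#' @return a [FluorescentField-class].
#' @export
readField <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side)
          else list(channels = list("DAPI", "CK", "CD45"),
                    pixel_size_um = 1)
  chn <- unlist(meta$channels)
  ch <- lapply(pages, function(p) round(p * 65535))
  names(ch) <- chn
  FluorescentField(DAPI = ch$DAPI, CK = ch$CK, CD45 = ch$CD45,
                   pixelSize = meta$pixel_size_um)
}

#' Read / write BED-like bin-count tables
#'
#' Tab-separated, header `chrom start end gc count`, 0-based half-open
#' coordinates.
#'
#' @param path TSV path.
#' @param ploidy assumed ploidy of the resulting profile.
#' @return `readBinCounts`: a [CNAProfile-class]; `writeBinCounts`:
#'   `path`, invisibly.
#' @export
readBinCounts <- function(path, ploidy = 2) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  assertCols(df, c("chrom", "start", "end", "gc", "count"), "bin table")
  CNAProfile(df, ploidy = ploidy)
}

#' @rdname readBinCounts
#' @param profile a [CNAProfile-class].
#' @export
writeBinCounts <- function(profile, path) {
  b <- profile@bins
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(b)),
                   start = GenomicRanges::start(b) - 1L,
                   end = GenomicRanges::end(b),
                   gc = S4Vectors::mcols(b)$gc,
                   count = S4Vectors::mcols(b)$count)
  if (!is.null(S4Vectors::mcols(b)$ratio))
    df$ratio <- S4Vectors::mcols(b)$ratio
  if (!is.null(S4Vectors::mcols(b)$cn)) df$cn <- S4Vectors::mcols(b)$cn
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write/read tab-separated tables (feature tables, cohorts, truth)
#'
#' @param table data.frame.
#' @param path TSV path.
#' @return `writeTSV`: `path` invisibly; `readTSV`: data.frame.
#' @export
writeTSV <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTSV
#' @export
readTSV <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Serialize a cohort report to JSON
#'
#' @param report a `CohortReport` from [cohortReport()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeCohortReport <- function(report, path) {
  stripped <- report
  if (!is.null(stripped$survival)) {
    stripped$survival$fit <- NULL  # survfit objects do not serialize
    stripped$survival$curves <- as.list(stripped$survival$curves)
  }
  class(stripped) <- NULL
  jsonlite::write_json(stripped, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(path)
}
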