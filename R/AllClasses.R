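#' @import methods
#' @importFrom S4Vectors mcols mcols<- isSorted
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   pintersect
#' @importFrom IRanges IRanges
NULL

#' FluorescentField: a registered multi-channel immunofluorescence field
#'
#' Container for one microscope field of view: three same-shape intensity
#' grids for the DAPI (nuclear), CK/EpCAM (epithelial) and CD45 (leukocyte)
#' channels, plus the physical pixel size. All downstream image operations
#' (illumination correction, segmentation, feature extraction) consume this
#' class.
#'
#' @slot channels named list of numeric matrices (names `DAPI`, `CK`,
#'   `CD45`), identical dimensions, non-negative intensities.
#' @slot pixelSize physical pixel edge length in micrometers per pixel.
#'
#' @seealso [renderField()], [segmentObjects()], [extractFeatures()]
#' @export
setClass("FluorescentField",
  representation(channels = "list", pixelSize = "numeric"))

setValidity("FluorescentField", function(object) {
  ch <- object@channels
  msg <- character()
  if (!identical(sort(names(ch)), sort(c("DAPI", "CK", "CD45"))))
    msg <- c(msg, "channels must be named DAPI, CK, CD45")
  if (!all(vapply(ch, is.matrix, logical(1))))
    msg <- c(msg, "all channels must be matrices")
  else {
    dims <- vapply(ch, dim, integer(2))
    if (nrow(unique(t(dims))) != 1L)
      msg <- c(msg, "all channels must share the same dimensions")
    if (any(vapply(ch, function(m) any(m < 0), logical(1))))
      msg <- c(msg, "channel intensities must be non-negative")
  }
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a FluorescentField
#'
#' @param DAPI,CK,CD45 numeric matrices of identical dimensions holding the
#'   nuclear, epithelial-marker and leukocyte-marker channel intensities.
#' @param pixelSize pixel edge length, micrometers per pixel.
#' @return a [FluorescentField-class] object.
#' @examples
#' m <- matrix(500, 32, 32)
#' f <- FluorescentField(m, m, m, pixelSize = 0.65)
#' dim(f)
#' @export
FluorescentField <- function(DAPI, CK, CD45, pixelSize = 1) {
  new("FluorescentField",
      channels = list(DAPI = DAPI, CK = CK, CD45 = CD45),
      pixelSize = pixelSize)
}

#' @describeIn FluorescentField-class field dimensions (rows, columns)
#' @param x a `FluorescentField`
#' @export
setMethod("dim", "FluorescentField", function(x) dim(x@channels[[1L]]))

#' Channel accessors for FluorescentField
#'
#' @param x a [FluorescentField-class]
#' @param name one of `"DAPI"`, `"CK"`, `"CD45"`
#' @return `channelNames`: character vector; `getChannel`: numeric matrix;
#'   `pixelSize`: numeric scalar (micrometers/pixel).
#' @export
channelNames <- function(x) names(x@channels)

#' @rdname channelNames
#' @export
getChannel <- function(x, name) {
  stopifnot(is(x, "FluorescentField"))
  if (!name %in% names(x@channels))
    stop("no such channel: ", name)
  x@channels[[name]]
}

#' @rdname channelNames
#' @export
pixelSize <- function(x) x@pixelSize

setMethod("show", "FluorescentField", function(object) {
  d <- dim(object)
  cat("FluorescentField:", d[1], "x", d[2], "px,",
      object@pixelSize, "um/px\n")
  for (nm in names(object@channels)) {
    ch <- object@channels[[nm]]
    cat(sprintf("  %-5s range [%.0f, %.0f]\n", nm, min(ch), max(ch)))
  }
})

#' CNAProfile: a single-cell copy-number profile over genomic bins
#'
#' Ordered fixed-width genomic bins (0-based half-open in the on-disk BED
#' dialect, 1-based closed as `GRanges` in memory) carrying raw read counts,
#' GC fraction, normalized ratios, and -- after segmentation and calling --
#' segments with mean ratios and integer copy numbers.
#'
#' @slot bins `GRanges` with metadata columns `gc` (fraction in `[0,1]`),
#'   `count` (raw reads, >= 0) and optionally `ratio` (normalized, mean 1).
#' @slot segments `GRanges` with metadata columns `mean_ratio` and `cn`
#'   (integer copy number >= 0); empty until [segmentProfile()] /
#'   [callIntegerCN()] are run. Segments never cross chromosome boundaries.
#' @slot ploidy assumed baseline ploidy (default 2).
#'
#' @seealso [normalizeBins()], [segmentProfile()], [callIntegerCN()],
#'   [profileQuality()]
#' @export
setClass("CNAProfile",
  representation(bins = "GRanges", segments = "GRanges", ploidy = "numeric"))

setValidity("CNAProfile", function(object) {
  msg <- character()
  b <- object@bins
  mc <- S4Vectors::mcols(b)
  if (!all(c("gc", "count") %in% names(mc)))
    msg <- c(msg, "bins need 'gc' and 'count' metadata columns")
  else {
    if (any(mc$count < 0)) msg <- c(msg, "counts must be >= 0")
    if (any(mc$gc < 0 | mc$gc > 1)) msg <- c(msg, "gc must be in [0,1]")
  }
  if (length(b) > 1L && !S4Vectors::isSorted(b))
    msg <- c(msg, "bins must be sorted")
  s <- object@segments
  if (length(s)) {
    smc <- S4Vectors::mcols(s)
    if ("cn" %in% names(smc) && any(smc$cn < 0))
      msg <- c(msg, "integer copy numbers must be >= 0")
  }
  if (object@ploidy <= 0) msg <- c(msg, "ploidy must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a CNAProfile from a bin-count table
#'
#' @param bins either a `GRanges` with `gc` and `count` metadata columns, or
#'   a data.frame with columns `chrom`, `start`, `end` (0-based half-open),
#'   `gc`, `count`.
#' @param ploidy assumed baseline ploidy.
#' @return a [CNAProfile-class]
#' @examples
#' df <- data.frame(chrom = "chr1", start = seq(0, 4e6, 5e5),
#'                  end = seq(5e5, 4.5e6, 5e5), gc = 0.4, count = 100)
#' CNAProfile(df)
#' @export
CNAProfile <- function(bins, ploidy = 2) {
  if (is.data.frame(bins)) {
    gr <- GenomicRanges::GRanges(bins$chrom,
      IRanges::IRanges(start = bins$start + 1L, end = bins$end))
    S4Vectors::mcols(gr)$gc <- bins$gc
    S4Vectors::mcols(gr)$count <- bins$count
    bins <- gr
  }
  new("CNAProfile", bins = bins,
      segments = GenomicRanges::GRanges(), ploidy = ploidy)
}

#' Accessors for CNAProfile
#'
#' @param x a [CNAProfile-class]
#' @return `bins`: the bin-level `GRanges`; `cnaSegments`: the segment-level
#'   `GRanges`; `ploidy`: the assumed baseline ploidy.
#' @export
bins <- function(x) x@bins

#' @rdname bins
#' @export
cnaSegments <- function(x) x@segments

#' @rdname bins
#' @export
ploidy <- function(x) x@ploidy

setMethod("show", "CNAProfile", function(object) {
  cat("CNAProfile:", length(object@bins), "bins on",
      length(unique(as.character(GenomicRanges::seqnames(object@bins)))),
      "chromosome(s); ploidy", object@ploidy, "\n")
  if (length(object@segments)) {
    cn <- S4Vectors::mcols(object@segments)$cn
    cat(" ", length(object@segments), "segments",
        if (!is.null(cn)) paste0("(CN range ", min(cn), "-", max(cn), ")"),
        "\n")
  } else cat("  not yet segmented\n")
})
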