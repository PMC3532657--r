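# Minimal baseline-TIFF codec (uncompressed grayscale, little-endian, one
# strip). No R TIFF bindings ship with the target environment, so the subset
# of the format this package emits/consumes is implemented here: 8- or 16-bit
# single-sample frames with acquisition metadata serialized as JSON in the
# ImageDescription tag.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, ImageDescription = 270L,
               StripOffsets = 273L, SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L)

#' Write a grayscale image as an uncompressed TIFF
#'
#' @param img a [raw_image()], a binary/integer matrix, or a numeric matrix of
#'   counts already on the output scale.
#' @param path output file path.
#' @param bits 8 or 16 bits per sample.
#' @param description optional character scalar stored in the ImageDescription
#'   tag; for `raw_image` input the exposure time, pixel pitch and metadata are
#'   serialized as JSON automatically.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path, bits = 16L, description = NULL) {
  if (inherits(img, "raw_image")) {
    if (is.null(description)) {
      description <- jsonlite::toJSON(
        c(list(exposure_time_ms = img$exposure_time, bit_depth = img$bit_depth),
          img$metadata), auto_unbox = TRUE, digits = NA)
    }
    mat <- img$pixels
  } else {
    mat <- img
  }
  stopifnot(is.matrix(mat), bits %in% c(8L, 16L))
  maxv <- 2^bits - 1
  mat <- round(pmin(pmax(mat, 0), maxv))
  h <- nrow(mat); w <- ncol(mat)
  desc <- if (is.null(description)) raw(0) else {
    d <- charToRaw(as.character(description))
    c(d, as.raw(0L))  # NUL-terminated per spec
  }

  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header: II, magic 42, IFD offset 8
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  n_entries <- 9L + (length(desc) > 0)
  ifd_off <- 8L
  ifd_size <- 2L + 12L * n_entries + 4L
  desc_off <- ifd_off + ifd_size
  data_off <- desc_off + length(desc)
  w32(ifd_off)

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    w32(count)
    if (type == 3L && count == 1L) {  # SHORT packed left-justified
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else w32(value)
  }

  writeBin(n_entries, con, size = 2, endian = "little")
  entry(TIFF_TAGS["ImageWidth"], 4L, 1L, w)
  entry(TIFF_TAGS["ImageLength"], 4L, 1L, h)
  entry(TIFF_TAGS["BitsPerSample"], 3L, 1L, bits)
  entry(TIFF_TAGS["Compression"], 3L, 1L, 1L)
  entry(TIFF_TAGS["Photometric"], 3L, 1L, 1L)  # BlackIsZero
  if (length(desc) > 0) entry(TIFF_TAGS["ImageDescription"], 2L, length(desc), desc_off)
  entry(TIFF_TAGS["StripOffsets"], 4L, 1L, data_off)
  entry(TIFF_TAGS["SamplesPerPixel"], 3L, 1L, 1L)
  entry(TIFF_TAGS["RowsPerStrip"], 4L, 1L, h)
  entry(TIFF_TAGS["StripByteCounts"], 4L, 1L, w * h * bits / 8)
  w32(0L)  # next IFD
  if (length(desc) > 0) writeBin(desc, con)
  # pixel data, row-major
  vals <- as.integer(t(mat))
  writeBin(vals, con, size = bits / 8, endian = "little")
  invisible(path)
}

#' Read a grayscale TIFF written by [write_tiff()] (or any uncompressed
#' single-sample baseline TIFF)
#'
#' @param path file path.
#' @param exposure_time ms; overrides/augments the embedded metadata so plain
#'   TIFFs from other tools can be used (`--exposure-ms` on the CLI).
#' @return A [raw_image()] when an exposure time is available (embedded or
#'   supplied), otherwise a bare integer matrix.
#' @export
read_tiff <- function(path, exposure_time = NULL) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 8) stopf("not a TIFF: %s", path)
  order <- rawToChar(raw_all[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stopf("not a TIFF: %s", path)
  rd <- function(off, size, n = 1L) {
    # readBin only honors signed=FALSE for 1- and 2-byte sizes
    readBin(raw_all[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size >= 4)
  }
  if (rd(2, 2) != 42L) stopf("bad TIFF magic in %s", path)
  ifd <- rd(4, 4)
  n <- rd(ifd, 2)
  tags <- list()
  for (i in seq_len(n)) {
    e <- ifd + 2 + (i - 1) * 12
    tag <- rd(e, 2); type <- rd(e + 2, 2); count <- rd(e + 4, 4)
    val <- if (type == 3L && count <= 2L) rd(e + 8, 2, count)
           else rd(e + 8, 4)
    tags[[as.character(tag)]] <- list(type = type, count = count, value = val,
                                      at = e + 8)
  }
  g <- function(tag, default = NULL) {
    t <- tags[[as.character(TIFF_TAGS[tag])]]
    if (is.null(t)) default else t$value[1]
  }
  w <- g("ImageWidth"); h <- g("ImageLength"); bits <- g("BitsPerSample", 8L)
  if (is.null(w) || is.null(h)) stopf("TIFF missing geometry tags: %s", path)
  if (g("Compression", 1L) != 1L) stopf("only uncompressed TIFFs are supported")
  if (g("SamplesPerPixel", 1L) != 1L) stopf("only single-sample grayscale TIFFs are supported")

  so <- tags[[as.character(TIFF_TAGS["StripOffsets"])]]
  sc <- tags[[as.character(TIFF_TAGS["StripByteCounts"])]]
  offs <- if (so$count == 1L) so$value[1] else rd(so$value[1], 4, so$count)
  cnts <- if (is.null(sc)) w * h * bits / 8
          else if (sc$count == 1L) sc$value[1] else rd(sc$value[1], 4, sc$count)
  px <- integer(0)
  for (i in seq_along(offs)) {
    nb <- cnts[min(i, length(cnts))]
    px <- c(px, rd(offs[i], bits / 8, nb / (bits / 8)))
  }
  if (any(px < 0)) px <- as.integer(px + 2^bits)  # undo signed read
  mat <- matrix(px, nrow = h, ncol = w, byrow = TRUE)

  meta <- list()
  dtag <- tags[[as.character(TIFF_TAGS["ImageDescription"])]]
  if (!is.null(dtag)) {
    dr <- raw_all[(dtag$value[1] + 1):(dtag$value[1] + dtag$count)]
    dr <- dr[dr != as.raw(0)]
    txt <- rawToChar(dr)
    meta <- tryCatch(jsonlite::fromJSON(txt), error = function(e) list(text = txt))
  }
  exp_ms <- exposure_time %||% meta$exposure_time_ms
  if (is.null(exp_ms)) return(mat)
  meta$exposure_time_ms <- NULL
  raw_image(mat, exp_ms, bit_depth = meta$bit_depth %||% bits,
            metadata = meta[setdiff(names(meta), "bit_depth")])
}
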