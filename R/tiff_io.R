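# Minimal baseline TIFF codec (little-endian, uncompressed, one strip per
# page, grayscale). No TIFF package ships with this R stack, so the subset
# needed for the pipeline's interchange files is implemented here: 32-bit
# float or 8/16-bit unsigned pages, multi-page, with an ImageDescription tag
# carrying the channel/z layout.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, description = 270L, strip_offsets = 273L,
               rows_per_strip = 278L, strip_byte_counts = 279L,
               sample_format = 339L)

#' Write a multi-page TIFF
#'
#' Pages are written uncompressed, little-endian, 32-bit IEEE float,
#' grayscale, one strip per page. A list of matrices becomes one page each;
#' a 3-D array `[H, W, Z]` becomes Z pages.
#'
#' @param pages list of numeric matrices (or a single matrix / 3-D array).
#' @param path output file path.
#' @param description optional text stored in the first page's
#'   ImageDescription tag (used to record channel/z layout).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, description = NULL) {
  if (is.matrix(pages)) pages <- list(pages)
  if (is.array(pages) && length(dim(pages)) == 3L)
    pages <- lapply(seq_len(dim(pages)[3]), function(z) pages[, , z])
  stopifnot(is.list(pages), length(pages) >= 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  desc <- if (is.null(description)) raw(0) else c(charToRaw(description), as.raw(0))
  if (length(desc) %% 2L == 1L) desc <- c(desc, as.raw(0))

  # layout: header(8) | desc | page data ... | IFDs
  off_desc <- 8L
  off_data <- off_desc + length(desc)
  data_sizes <- vapply(pages, function(p) length(p) * 4L, integer(1))
  off_pages <- off_data + c(0L, cumsum(data_sizes))[seq_along(pages)]
  off_ifd0 <- off_data + sum(data_sizes)
  n_tags <- function(i) if (i == 1L && length(desc) > 0L) 10L else 9L
  ifd_sizes <- vapply(seq_along(pages), function(i) 2L + n_tags(i) * 12L + 4L,
                      integer(1))
  off_ifds <- off_ifd0 + c(0L, cumsum(ifd_sizes))[seq_along(pages)]

  writeChar("II", con, eos = NULL)
  w(42L, 2)
  w(off_ifds[1], 4)
  if (length(desc) > 0L) writeBin(desc, con)
  for (p in pages) w(as.numeric(t(p)), 4)

  entry <- function(tag, type, count, value) {
    w(as.integer(tag), 2)
    w(as.integer(type), 2)
    w(as.integer(count), 4)
    if (type == 3L && count == 1L) { w(as.integer(value), 2); w(0L, 2) }
    else w(as.integer(value), 4)
  }
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    tags <- n_tags(i)
    w(tags, 2)
    entry(256, 3, 1, ncol(p))                 # ImageWidth
    entry(257, 3, 1, nrow(p))                 # ImageLength
    entry(258, 3, 1, 32L)                     # BitsPerSample
    entry(259, 3, 1, 1L)                      # no compression
    entry(262, 3, 1, 1L)                      # BlackIsZero
    if (i == 1L && length(desc) > 0L)
      entry(270, 2, length(desc), off_desc)   # ImageDescription
    entry(273, 4, 1, off_pages[i])            # StripOffsets
    entry(278, 3, 1, nrow(p))                 # RowsPerStrip
    entry(279, 4, 1, data_sizes[i])           # StripByteCounts
    entry(339, 3, 1, 3L)                      # IEEE float
    nxt <- if (i < length(pages)) off_ifds[i + 1] else 0L
    w(as.integer(nxt), 4)
  }
  invisible(path)
}

#' Read a multi-page TIFF written by [write_tiff()] (or any uncompressed
#' little-endian grayscale baseline TIFF with 8/16-bit unsigned or 32-bit
#' float samples)
#'
#' @param path file path.
#' @return list with `pages` (list of numeric matrices) and `description`
#'   (character or `NULL`).
#' @export
read_tiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n, size, what = "integer", signed = TRUE)
    readBin(con, what, n = n, size = size, endian = "little", signed = signed)
  magic <- readChar(con, 2)
  if (magic != "II") stop("only little-endian TIFF supported: ", path)
  if (rd(1, 2) != 42L) stop("not a TIFF file: ", path)
  off <- rd(1, 4)
  pages <- list()
  description <- NULL
  while (off != 0) {
    seek(con, off)
    n <- rd(1, 2)
    tags <- vector("list", n)
    for (i in seq_len(n)) {
      tag <- rd(1, 2, signed = FALSE)
      type <- rd(1, 2)
      count <- rd(1, 4)
      raw4 <- readBin(con, "raw", n = 4)
      tags[[i]] <- list(tag = tag, type = type, count = count, raw = raw4)
    }
    nxt <- rd(1, 4)
    val <- function(tagid, default = NULL) {
      hit <- Filter(function(t) t$tag == tagid, tags)
      if (length(hit) == 0L) return(default)
      t <- hit[[1]]
      if (t$type == 3L)
        readBin(t$raw, "integer", n = 2, size = 2, endian = "little",
                signed = FALSE)[1]
      else readBin(t$raw, "integer", n = 1, size = 4, endian = "little")
    }
    wd <- val(256); ht <- val(257)
    bits <- val(258, 8L); comp <- val(259, 1L)
    fmt <- val(339, 1L)
    soff <- val(273); sbc <- val(279)
    if (comp != 1L) stop("compressed TIFF not supported: ", path)
    dtag <- Filter(function(t) t$tag == 270L, tags)
    if (length(dtag) > 0L && is.null(description)) {
      t <- dtag[[1]]
      doff <- readBin(t$raw, "integer", n = 1, size = 4, endian = "little")
      seek(con, doff)
      dchr <- readBin(con, "raw", n = t$count)
      description <- rawToChar(dchr[dchr != as.raw(0)])
    }
    seek(con, soff)
    npx <- wd * ht
    px <- if (fmt == 3L && bits == 32L) rd(npx, 4, what = "numeric")
          else if (bits == 16L) rd(npx, 2, signed = FALSE)
          else if (bits == 8L) as.integer(readBin(con, "raw", n = npx))
          else stop("unsupported sample layout (bits=", bits, ", fmt=", fmt, ")")
    pages[[length(pages) + 1L]] <- matrix(as.numeric(px), nrow = ht,
                                          ncol = wd, byrow = TRUE)
    off <- nxt
  }
  list(pages = pages, description = description)
}
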