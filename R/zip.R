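# Minimal deterministic ZIP writer (store method only) plus CRC-32.
#
# utils::zip shells out and embeds filesystem timestamps, which breaks the
# "same seed => byte-identical corpus" contract of the synthetic generator,
# so archives are written by hand: fixed DOS timestamp (1980-01-01), no
# compression, members in the order given. Reading uses utils::unzip
# (internal method), which handles both stored and deflated entries.

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L)
            bitwXor(-306674912L, bitwShiftR(c, 1)) # 0xEDB88320
          else bitwShiftR(c, 1)
        }
        t[n + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

#' CRC-32 checksum of a raw vector
#'
#' Standard (IEEE 802.3 / zlib) CRC-32, implemented table-driven in R so that
#' archive writing needs no external tool.
#'
#' @param bytes raw vector.
#' @return Checksum as a double in `[0, 2^32)`.
#' @export
crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  ints <- as.integer(bytes)
  for (b in ints)
    crc <- bitwXor(bitwShiftR(crc, 8), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 4294967296 else as.double(crc)
}

le_bytes <- function(x, n) {
  # little-endian byte encoding of a non-negative double
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

#' Build a ZIP archive in memory
#'
#' @param members named list of raw vectors (names are member paths; a raw
#'   payload ending in `/`-named entries is not supported — directories are
#'   implicit).
#' @return Raw vector holding the archive.
#' @export
zip_build <- function(members) {
  stopifnot(is.list(members), length(names(members)) == length(members))
  locals <- list(); centrals <- list()
  offset <- 0
  for (i in seq_along(members)) {
    name <- charToRaw(enc2utf8(names(members)[i]))
    data <- members[[i]]
    stopifnot(is.raw(data))
    crc <- crc32(data)
    sz <- length(data)
    common <- c(le_bytes(20, 2),            # version needed
                le_bytes(2048, 2),          # flags: UTF-8 names
                le_bytes(0, 2),             # method: store
                le_bytes(0, 2), le_bytes(33, 2),  # fixed DOS time/date
                le_bytes(crc, 4), le_bytes(sz, 4), le_bytes(sz, 4),
                le_bytes(length(name), 2), le_bytes(0, 2))
    locals[[i]] <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), common, name, data)
    centrals[[i]] <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), le_bytes(20, 2),
                       common, le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2),
                       le_bytes(0, 4), le_bytes(offset, 4), name)
    offset <- offset + length(locals[[i]])
  }
  central <- unlist(centrals) %||% raw(0)
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), le_bytes(0, 2), le_bytes(0, 2),
            le_bytes(length(members), 2), le_bytes(length(members), 2),
            le_bytes(length(central), 4), le_bytes(offset, 4), le_bytes(0, 2))
  c(unlist(locals) %||% raw(0), central, eocd)
}

#' List and extract ZIP members from an in-memory payload
#'
#' @param payload raw vector holding a ZIP archive.
#' @return Named list of raw vectors (member path -> bytes). Directory
#'   entries are dropped.
#' @export
zip_members <- function(payload) {
  tmp <- tempfile(fileext = ".zip")
  on.exit(unlink(tmp), add = TRUE)
  writeBin(payload, tmp)
  info <- utils::unzip(tmp, list = TRUE)
  names <- info$Name[!endsWith(info$Name, "/")]
  out <- list()
  if (length(names) > 0) {
    ex <- tempfile("zx")
    on.exit(unlink(ex, recursive = TRUE), add = TRUE)
    utils::unzip(tmp, files = names, exdir = ex, junkpaths = FALSE)
    for (nm in names) {
      f <- file.path(ex, nm)
      out[[nm]] <- readBin(f, "raw", file.size(f))
    }
  }
  out
}

is_zip_payload <- function(payload) {
  length(payload) >= 4 &&
    identical(payload[1:4], as.raw(c(0x50, 0x4b, 0x03, 0x04)))
}

is_gzip_payload <- function(payload) {
  length(payload) >= 2 && identical(payload[1:2], as.raw(c(0x1f, 0x8b)))
}

is_pdf_payload <- function(payload) {
  length(payload) >= 5 &&
    identical(payload[1:5], charToRaw("%PDF-"))
}
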