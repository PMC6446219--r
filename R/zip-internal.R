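# Minimal ZIP writer (stored entries, no compression). R's utils::zip
# shells out to an external `zip` binary, so archives are written here
# directly; reading goes through utils::unzip's internal method. Stored
# entries keep the writer simple and are lossless; bundle tables are small.

.crc32Table <- local({
  tab <- integer(256L)
  for (i in 0:255) {
    crc <- i
    for (k in 1:8) {
      crc <- if (bitwAnd(crc, 1L))
        bitwXor(-306674912L, bitwShiftR(crc, 1L))  # 0xEDB88320 polynomial
      else
        bitwShiftR(crc, 1L)
    }
    tab[i + 1L] <- crc
  }
  tab
})

.crc32 <- function(bytes) {
  crc <- -1L
  tab <- .crc32Table
  for (b in as.integer(bytes)) {
    crc <- bitwXor(tab[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  }
  bitwXor(crc, -1L)
}

.w16 <- function(con, x) writeBin(as.integer(x), con, size = 2L, endian = "little")
.w32 <- function(con, x) writeBin(as.integer(x), con, size = 4L, endian = "little")

# files: paths relative to root; entry names use forward slashes.
.zipCreate <- function(zipfile, files, root) {
  con <- file(zipfile, open = "wb")
  on.exit(close(con))
  offsets <- integer(length(files))
  crcs <- integer(length(files))
  sizes <- integer(length(files))
  pos <- 0L
  for (i in seq_along(files)) {
    f <- files[i]
    data <- readBin(file.path(root, f), what = "raw",
                    n = file.info(file.path(root, f))$size)
    name <- charToRaw(gsub("\\\\", "/", f))
    crcs[i] <- .crc32(data)
    sizes[i] <- length(data)
    offsets[i] <- pos
    .w32(con, 67324752L)           # local file header signature
    .w16(con, 20L); .w16(con, 0L); .w16(con, 0L)   # version, flags, method
    .w16(con, 0L); .w16(con, 0L)   # mod time, mod date (fixed: reproducible)
    .w32(con, crcs[i]); .w32(con, sizes[i]); .w32(con, sizes[i])
    .w16(con, length(name)); .w16(con, 0L)
    writeBin(name, con)
    writeBin(data, con)
    pos <- pos + 30L + length(name) + sizes[i]
  }
  cdStart <- pos
  for (i in seq_along(files)) {
    name <- charToRaw(gsub("\\\\", "/", files[i]))
    .w32(con, 33639248L)           # central directory signature
    .w16(con, 20L); .w16(con, 20L); .w16(con, 0L); .w16(con, 0L)
    .w16(con, 0L); .w16(con, 0L)   # time, date
    .w32(con, crcs[i]); .w32(con, sizes[i]); .w32(con, sizes[i])
    .w16(con, length(name)); .w16(con, 0L); .w16(con, 0L)
    .w16(con, 0L); .w16(con, 0L)   # disk, internal attrs
    .w32(con, 0L)                  # external attrs
    .w32(con, offsets[i])
    writeBin(name, con)
    pos <- pos + 46L + length(name)
  }
  .w32(con, 101010256L)            # end of central directory
  .w16(con, 0L); .w16(con, 0L)
  .w16(con, length(files)); .w16(con, length(files))
  .w32(con, pos - cdStart); .w32(con, cdStart)
  .w16(con, 0L)
  invisible(zipfile)
}
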