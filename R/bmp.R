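# Minimal uncompressed BMP codec (Windows BITMAPINFOHEADER dialect).
# Supports what the PH2-style layout needs: 24-bit colour and 8-bit
# greyscale, no compression. Values returned on the 0..255 scale.

readBMP <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  u16 <- function() readBin(con, "integer", 1L, size = 2L, endian = "little",
                            signed = FALSE)
  u32 <- function() readBin(con, "integer", 1L, size = 4L, endian = "little")
  magic <- readBin(con, "raw", 2L)
  if (!identical(rawToChar(magic), "BM"))
    inputError(sprintf("'%s' is not a BMP file", path))
  u32(); u16(); u16()
  dataOffset <- u32()
  headerSize <- u32()
  if (headerSize < 40L)
    inputError(sprintf("unsupported BMP header in '%s'", path))
  width <- u32(); height <- u32()
  u16()  # planes
  bpp <- u16()
  compression <- u32()
  if (compression != 0L)
    inputError(sprintf("compressed BMP not supported: '%s'", path))
  if (!bpp %in% c(8L, 24L))
    inputError(sprintf("unsupported BMP bit depth %d in '%s'", bpp, path))
  flipped <- height < 0L
  height <- abs(height)
  seek(con, dataOffset)
  bytesPerRow <- ceiling(width * bpp / 8)
  stride <- ((bytesPerRow + 3) %/% 4) * 4
  raw <- readBin(con, "raw", stride * height)
  rows <- matrix(as.integer(raw), nrow = stride)[seq_len(bytesPerRow), ,
                                                 drop = FALSE]
  if (bpp == 24L) {
    # pixel order B, G, R; bottom-up unless height was negative
    px <- array(rows, dim = c(3L, width, height))
    img <- aperm(px[c(3L, 2L, 1L), , , drop = FALSE], c(3L, 2L, 1L))
    if (!flipped) img <- img[height:1, , , drop = FALSE]
    storage.mode(img) <- "double"
    img
  } else {
    m <- t(matrix(rows, nrow = width))
    if (!flipped) m <- m[height:1, , drop = FALSE]
    storage.mode(m) <- "double"
    m
  }
}

writeBMP <- function(x, path) {
  grey <- is.matrix(x)
  h <- dim(x)[1]; w <- dim(x)[2]
  bpp <- if (grey) 8L else 24L
  bytesPerRow <- ceiling(w * bpp / 8)
  stride <- ((bytesPerRow + 3) %/% 4) * 4
  paletteSize <- if (grey) 256L * 4L else 0L
  offset <- 14L + 40L + paletteSize
  fileSize <- offset + stride * h
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  writeBin(charToRaw("BM"), con)
  w32(fileSize); w16(0L); w16(0L); w32(offset)
  w32(40L); w32(w); w32(h); w16(1L); w16(bpp)
  w32(0L); w32(stride * h); w32(2835L); w32(2835L)
  w32(if (grey) 256L else 0L); w32(0L)
  if (grey) {
    pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256)))
    writeBin(pal, con)
  }
  xi <- round(x)
  xi[xi < 0] <- 0; xi[xi > 255] <- 255
  pad <- stride - bytesPerRow
  for (row in h:1) {
    if (grey) {
      bytes <- as.raw(xi[row, ])
    } else {
      bgr <- rbind(xi[row, , 3], xi[row, , 2], xi[row, , 1])
      bytes <- as.raw(as.vector(bgr))
    }
    if (pad > 0) bytes <- c(bytes, raw(pad))
    writeBin(bytes, con)
  }
  invisible(path)
}
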