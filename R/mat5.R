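# Minimal MAT v5 (Level 5 MAT-file) reader/writer for competition-style EEG
# clip containers. Supports the subset those containers use: little-endian
# files holding top-level numeric matrices (written as miDOUBLE; int8/16/32
# and their unsigned variants are converted on read) and character matrices
# (miUINT16 code units), plus zlib-compressed elements on read. Not a general
# MAT-file implementation.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_CHAR <- 4L; MX_DOUBLE <- 6L
MX_NUMERIC <- c(4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L)

pad8 <- function(r) {
  rem <- length(r) %% 8L
  if (rem) c(r, raw(8L - rem)) else r
}

mat5Element <- function(type, payload) {
  c(writeBin(c(as.integer(type), length(payload)), raw(), size = 4L,
             endian = "little"),
    pad8(payload))
}

mat5Matrix <- function(name, x) {
  if (is.character(x)) {
    # Character data: pad strings to equal width, store code units
    # column-major as an n x width char matrix.
    width <- max(nchar(x), 1L)
    padded <- formatC(x, width = -width)
    codes <- integer(0)
    for (j in seq_len(width))
      codes <- c(codes, vapply(padded, function(s)
        utf8ToInt(substr(s, j, j)), integer(1)))
    dims <- c(length(x), width)
    cls <- MX_CHAR
    data <- mat5Element(MI_UINT16, writeBin(codes, raw(), size = 2L,
                                            endian = "little"))
  } else {
    x <- as.matrix(x)
    dims <- dim(x)
    cls <- MX_DOUBLE
    data <- mat5Element(MI_DOUBLE, writeBin(as.numeric(x), raw(), size = 8L,
                                            endian = "little"))
  }
  flags <- mat5Element(MI_UINT32, writeBin(c(cls, 0L), raw(), size = 4L,
                                           endian = "little"))
  dimEl <- mat5Element(MI_INT32, writeBin(as.integer(dims), raw(), size = 4L,
                                          endian = "little"))
  nameEl <- mat5Element(MI_INT8, charToRaw(name))
  mat5Element(MI_MATRIX, c(flags, dimEl, nameEl, data))
}

# Write a named list of numeric matrices / scalars / character vectors as a
# little-endian MAT v5 file.
writeMat5 <- function(path, vars) {
  txt <- "MATLAB 5.0 MAT-file, written by SeizureMViT"
  header <- c(charToRaw(txt), rep(as.raw(0x20), 116L - nchar(txt)),
              raw(8L),
              writeBin(256L, raw(), size = 2L, endian = "little"),
              charToRaw("IM"))
  body <- raw(0)
  for (nm in names(vars)) body <- c(body, mat5Matrix(nm, vars[[nm]]))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, body), con)
  invisible(path)
}

mat5ReadInt <- function(r, pos, size, signed = TRUE) {
  readBin(r[pos:(pos + size - 1L)], integer(), n = 1L, size = size,
          signed = signed, endian = "little")
}

# Parse one data element starting at `pos` in raw vector `r`.
# Returns list(type, data = raw payload, next_pos).
mat5NextElement <- function(r, pos) {
  small <- mat5ReadInt(r, pos + 2L, 2L, signed = FALSE)
  if (small != 0L) { # small data element: 2-byte type, 2-byte size, 4-byte data
    type <- mat5ReadInt(r, pos, 2L)
    nb <- small
    list(type = type, data = r[(pos + 4L):(pos + 3L + nb)],
         next_pos = pos + 8L)
  } else {
    type <- mat5ReadInt(r, pos, 4L)
    nb <- mat5ReadInt(r, pos + 4L, 4L)
    data <- if (nb > 0L) r[(pos + 8L):(pos + 7L + nb)] else raw(0)
    adv <- nb
    if (type != MI_COMPRESSED) adv <- ceiling(nb / 8) * 8 # 8-byte alignment
    list(type = type, data = data, next_pos = pos + 8L + adv)
  }
}

mat5DecodeNumeric <- function(type, data) {
  switch(as.character(type),
    "1" = as.numeric(readBin(data, integer(), n = length(data), size = 1L,
                             signed = TRUE)),
    "2" = as.numeric(readBin(data, integer(), n = length(data), size = 1L,
                             signed = FALSE)),
    "3" = as.numeric(readBin(data, integer(), n = length(data) / 2L, size = 2L,
                             signed = TRUE, endian = "little")),
    "4" = as.numeric(readBin(data, integer(), n = length(data) / 2L, size = 2L,
                             signed = FALSE, endian = "little")),
    "5" = as.numeric(readBin(data, integer(), n = length(data) / 4L, size = 4L,
                             endian = "little")),
    "6" = { # uint32: reinterpret the signed read
      v <- as.numeric(readBin(data, integer(), n = length(data) / 4L,
                              size = 4L, endian = "little"))
      ifelse(v < 0, v + 4294967296, v)
    },
    "7" = readBin(data, numeric(), n = length(data) / 4L, size = 4L,
                  endian = "little"),
    "9" = readBin(data, numeric(), n = length(data) / 8L, size = 8L,
                  endian = "little"),
    stopData("unsupported MAT numeric type ", type)
  )
}

mat5ParseMatrix <- function(payload) {
  pos <- 1L
  el <- mat5NextElement(payload, pos) # array flags
  cls <- as.integer(el$data[1])
  el2 <- mat5NextElement(payload, el$next_pos) # dimensions
  dims <- readBin(el2$data, integer(), n = length(el2$data) / 4L, size = 4L,
                  endian = "little")
  el3 <- mat5NextElement(payload, el2$next_pos) # name
  name <- rawToChar(el3$data[el3$data != as.raw(0)])
  el4 <- mat5NextElement(payload, el3$next_pos) # real part
  if (cls == MX_CHAR) {
    codes <- as.integer(mat5DecodeNumeric(el4$type, el4$data))
    m <- matrix(codes, nrow = dims[1], ncol = dims[2])
    val <- vapply(seq_len(nrow(m)), function(i) {
      row <- m[i, ]
      sub("[ \t]+$", "", intToUtf8(row[row != 0L]))
    }, character(1))
  } else if (cls %in% MX_NUMERIC) {
    v <- mat5DecodeNumeric(el4$type, el4$data)
    val <- if (length(dims) == 2L) matrix(v, dims[1], dims[2]) else array(v, dims)
  } else {
    stopData("unsupported MAT array class ", cls)
  }
  list(name = name, value = val)
}

# Read a little-endian MAT v5 file into a named list.
readMat5 <- function(path) {
  r <- readBin(path, raw(), n = file.size(path))
  if (length(r) < 128L) stopData("not a MAT v5 file: ", path)
  endian <- rawToChar(r[127:128])
  if (endian != "IM")
    stopData("unsupported MAT file (big-endian or pre-v5): ", path)
  out <- list()
  pos <- 129L
  while (pos + 7L <= length(r)) {
    el <- mat5NextElement(r, pos)
    if (el$type == MI_COMPRESSED) {
      inner <- memDecompress(el$data, type = "gzip")
      sub <- mat5NextElement(inner, 1L)
      if (sub$type == MI_MATRIX) {
        m <- mat5ParseMatrix(sub$data)
        out[[m$name]] <- m$value
      }
    } else if (el$type == MI_MATRIX) {
      m <- mat5ParseMatrix(el$data)
      out[[m$name]] <- m$value
    }
    pos <- el$next_pos
  }
  out
}
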