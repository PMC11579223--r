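# Minimal MAT-file (Level 5) I/O for named numeric arrays.
#
# Covers what physiology exports actually contain once reduced to channels:
# real numeric matrices/vectors stored under variable names, in the classic
# (non-HDF5) dialect, little-endian, plain or zlib-compressed elements,
# including the "small data element" packing used for short names.  Complex,
# sparse, cell, struct and char variables are skipped with a warning.  The
# HDF5-based v7.3 dialect is not supported.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L

mat_numeric_classes <- 6:13  # mxDOUBLE .. mxUINT32

#' Read named numeric arrays from a MAT-file (v5 dialect)
#'
#' @param path Path to a `.mat` file written in the classic Level 5 format
#'   (the default of most acquisition/export software; not the HDF5-based
#'   v7.3 dialect).
#' @return Named list of numeric vectors/matrices. 1 x n and n x 1 arrays
#'   are simplified to vectors.
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "scr_config_error")
  }
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 128) {
    abort("Not a MAT-file: shorter than the 128-byte header.",
          class = "scr_parse_error")
  }
  endian_tag <- rawToChar(raw[127:128])
  if (endian_tag == "MI") {
    abort("Big-endian MAT-files are not supported.", class = "scr_parse_error")
  }
  if (endian_tag != "IM") {
    abort("Not a Level 5 MAT-file (bad endian indicator); v7.3/HDF5 files are not supported.",
          class = "scr_parse_error")
  }
  out <- list()
  pos <- 128L
  while (pos + 8L <= length(raw)) {
    el <- mat_read_element(raw, pos)
    pos <- el$next_pos
    if (el$type == MI_COMPRESSED) {
      inner <- memDecompress(el$data, type = "gzip")
      sub <- mat_read_element(inner, 0L)
      el <- sub
    }
    if (el$type != MI_MATRIX) next
    v <- mat_parse_matrix(el$data)
    if (!is.null(v)) out[[v$name]] <- v$value
  }
  out
}

# Reads one tagged element starting at byte offset `pos` (0-based);
# returns type, raw data (without padding), and offset of the next element.
mat_read_element <- function(raw, pos) {
  word1 <- readBin(raw[(pos + 1):(pos + 4)], "integer", size = 4, endian = "little")
  small_len <- bitwAnd(bitwShiftR(word1, 16L), 0xFFFFL)
  if (small_len > 0L) {
    type <- bitwAnd(word1, 0xFFFFL)
    data <- raw[(pos + 5):(pos + 4 + small_len)]
    return(list(type = type, data = data, next_pos = pos + 8L))
  }
  type <- word1
  nbytes <- readBin(raw[(pos + 5):(pos + 8)], "integer", size = 4, endian = "little")
  if (nbytes < 0) abort("MAT element larger than 2 GiB.", class = "scr_parse_error")
  data <- if (nbytes > 0) raw[(pos + 9):(pos + 8 + nbytes)] else raw(0)
  pad <- if (type == MI_COMPRESSED) 0L else (8L - nbytes %% 8L) %% 8L
  list(type = type, data = data, next_pos = pos + 8L + nbytes + pad)
}

mat_read_numeric <- function(type, data) {
  switch(as.character(type),
    "1" = readBin(data, "integer", n = length(data), size = 1, signed = TRUE),
    "2" = readBin(data, "integer", n = length(data), size = 1, signed = FALSE),
    "3" = readBin(data, "integer", n = length(data) / 2, size = 2,
                  signed = TRUE, endian = "little"),
    "4" = readBin(data, "integer", n = length(data) / 2, size = 2,
                  signed = FALSE, endian = "little"),
    "5" = readBin(data, "integer", n = length(data) / 4, size = 4,
                  endian = "little"),
    "6" = {
      v <- readBin(data, "integer", n = length(data) / 4, size = 4,
                   endian = "little")
      ifelse(v < 0, v + 2^32, as.numeric(v))
    },
    "7" = readBin(data, "double", n = length(data) / 4, size = 4,
                  endian = "little"),
    "9" = readBin(data, "double", n = length(data) / 8, size = 8,
                  endian = "little"),
    "12" = readBin(data, "double", n = length(data) / 8, size = 8,
                   endian = "little"),  # int64 approximated as double
    "13" = readBin(data, "double", n = length(data) / 8, size = 8,
                   endian = "little"),
    abort(sprintf("Unsupported MAT data type %d.", type),
          class = "scr_parse_error")
  )
}

mat_parse_matrix <- function(data) {
  flags <- mat_read_element(data, 0L)
  word <- readBin(flags$data[1:4], "integer", size = 4, endian = "little")
  class_id <- bitwAnd(word, 0xFFL)
  is_complex <- bitwAnd(word, bitwShiftL(8L, 8L)) != 0L
  dims_el <- mat_read_element(data, flags$next_pos)
  dims <- readBin(dims_el$data, "integer", n = length(dims_el$data) / 4,
                  size = 4, endian = "little")
  name_el <- mat_read_element(data, dims_el$next_pos)
  name <- rawToChar(name_el$data)
  if (!(class_id %in% mat_numeric_classes) || is_complex) {
    warn(sprintf("Skipping MAT variable '%s': unsupported class %d.",
                 name, class_id))
    return(NULL)
  }
  real_el <- mat_read_element(data, name_el$next_pos)
  value <- as.numeric(mat_read_numeric(real_el$type, real_el$data))
  if (length(dims) == 2 && min(dims) > 1) {
    value <- matrix(value, nrow = dims[1], ncol = dims[2])
  }
  list(name = name, value = value)
}

#' Write named numeric arrays to a MAT-file (v5 dialect)
#'
#' Writes real double arrays under their list names, uncompressed,
#' little-endian.  Used by the simulator to emit sessions in a format the
#' reader round-trips; not intended as a general-purpose MAT writer.
#'
#' @param vars Named list of numeric vectors or matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mat <- function(vars, path) {
  stopifnot(is.list(vars), length(vars) > 0, !is.null(names(vars)),
            all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, created by scrscore on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  hdr <- charToRaw(desc)
  length(hdr) <- 116L
  hdr[is.na(hdr)] <- as.raw(0x20)
  writeBin(hdr, con)
  writeBin(raw(8), con)                       # subsys data offset
  writeBin(c(as.raw(0x00), as.raw(0x01)), con)  # version 0x0100, LE
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars)) {
    writeBin(mat_matrix_bytes(nm, vars[[nm]]), con)
  }
  invisible(path)
}

mat_pad8 <- function(bytes) {
  pad <- (8L - length(bytes) %% 8L) %% 8L
  c(bytes, raw(pad))
}

mat_tag <- function(type, nbytes) {
  c(writeBin(as.integer(type), raw(), size = 4, endian = "little"),
    writeBin(as.integer(nbytes), raw(), size = 4, endian = "little"))
}

mat_matrix_bytes <- function(name, value) {
  dims <- if (is.matrix(value)) dim(value) else c(1L, length(value))
  body <- c(
    mat_tag(MI_UINT32, 8L),
    writeBin(6L, raw(), size = 4, endian = "little"),   # mxDOUBLE_CLASS
    writeBin(0L, raw(), size = 4, endian = "little"),
    mat_tag(MI_INT32, 8L),
    writeBin(as.integer(dims), raw(), size = 4, endian = "little"),
    mat_pad8(c(mat_tag(MI_INT8, length(charToRaw(name))), charToRaw(name))),
    mat_pad8(c(mat_tag(MI_DOUBLE, 8L * length(value)),
               writeBin(as.numeric(value), raw(), size = 8, endian = "little")))
  )
  c(mat_tag(MI_MATRIX, length(body)), body)
}
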