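# Minimal MATLAB Level-5 (.mat) archive support, covering the dialect the
# NinaPro DB2 files use for their numeric streams: named full numeric
# matrices stored as miMATRIX elements. Writing always emits uncompressed
# little-endian double matrices; reading additionally understands the common
# integer element types, the small-data-element form, and zlib-compressed
# elements when the running R supports zlib streams via memDecompress().

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L

mat5_elem_size <- function(type) {
  switch(as.character(type),
    "1" = 1L, "2" = 1L, "3" = 2L, "4" = 2L, "5" = 4L, "6" = 4L,
    "7" = 4L, "9" = 8L, "12" = 8L, "13" = 8L,
    abort_arg("unsupported MAT data type %d", type))
}

pad8 <- function(n) (8L - n %% 8L) %% 8L

write_mat5_element <- function(con, name, value) {
  is_char <- is.character(value)
  if (is_char) {
    chars <- utf8ToInt(value[1])              # mxCHAR, UTF-16 code units
    dims <- c(1L, length(chars))
    data_bytes <- 2L * length(chars)
    mat_class <- 4L; data_type <- MI_UINT16
  } else {
    m <- as.matrix(value)
    storage.mode(m) <- "double"
    dims <- dim(m)
    data_bytes <- 8L * length(m)
    mat_class <- 6L; data_type <- MI_DOUBLE   # mxDOUBLE_CLASS
  }
  nbytes_name <- nchar(name, type = "bytes")
  total <- 16L +                                   # array flags subelement
    8L + 8L +                                      # dims subelement (2 dims)
    8L + nbytes_name + pad8(nbytes_name) +         # name subelement
    8L + data_bytes + pad8(data_bytes)             # data subelement
  writeBin(c(MI_MATRIX, as.integer(total)), con, size = 4, endian = "little")
  writeBin(c(MI_UINT32, 8L), con, size = 4, endian = "little")
  writeBin(c(mat_class, 0L), con, size = 4, endian = "little")
  writeBin(c(MI_INT32, 8L), con, size = 4, endian = "little")
  writeBin(as.integer(dims), con, size = 4, endian = "little")
  writeBin(c(MI_INT8, nbytes_name), con, size = 4, endian = "little")
  writeBin(charToRaw(name), con)
  if (pad8(nbytes_name) > 0) writeBin(raw(pad8(nbytes_name)), con)
  writeBin(c(data_type, data_bytes), con, size = 4, endian = "little")
  if (is_char) writeBin(chars, con, size = 2, endian = "little")
  else writeBin(as.vector(m), con, size = 8, endian = "little")
  if (pad8(data_bytes) > 0) writeBin(raw(pad8(data_bytes)), con)
  invisible(NULL)
}

#' Write named matrices to a MATLAB Level-5 archive
#'
#' Low-level writer used by [write_fixture()]. Numeric elements are stored
#' as uncompressed little-endian double matrices and character scalars as
#' char arrays, readable by MATLAB, Octave and `scipy.io.loadmat`.
#'
#' @param vars named list of numeric vectors/matrices or character scalars.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mat <- function(vars, path) {
  if (is.null(names(vars)) || any(!nzchar(names(vars))))
    abort_arg("all variables must be named")
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
         call. = FALSE))
  on.exit(close(con))
  header <- sprintf("MATLAB 5.0 MAT-file, created by emgfuse %s",
                    as.character(utils::packageVersion("emgfuse")))
  hdr <- charToRaw(header)
  hdr <- c(hdr, rep(charToRaw(" "), 116L - length(hdr)))
  writeBin(hdr, con)
  writeBin(raw(8), con)                               # subsystem offset
  writeBin(256L, con, size = 2, endian = "little")    # version 0x0100
  writeBin(charToRaw("IM"), con)                      # little-endian tag
  for (nm in names(vars)) write_mat5_element(con, nm, vars[[nm]])
  invisible(path)
}

read_mat5_numeric <- function(raw_data, type) {
  sz <- mat5_elem_size(type)
  n <- length(raw_data) %/% sz
  if (type == MI_DOUBLE || type == MI_SINGLE) {
    readBin(raw_data, "double", n = n, size = sz, endian = "little")
  } else {
    signed <- type %in% c(MI_INT8, MI_INT16, MI_INT32, MI_INT64)
    readBin(raw_data, "integer", n = n, size = sz,
            signed = if (sz < 4) signed else TRUE, endian = "little")
  }
}

# parse one tagged data element starting at offset `pos` (1-based) of `buf`;
# returns list(type, data = raw payload, next_pos)
read_mat5_tag <- function(buf, pos) {
  word <- readBin(buf[pos:(pos + 3)], "integer", size = 4, endian = "little")
  small_len <- bitwAnd(bitwShiftR(word, 16), 0xFFFFL)
  if (small_len > 0L) {  # small data element: type+len packed in one word
    type <- bitwAnd(word, 0xFFFFL)
    data <- if (small_len > 0) buf[(pos + 4):(pos + 3 + small_len)] else raw(0)
    list(type = type, data = data, next_pos = pos + 8L)
  } else {
    type <- word
    len <- readBin(buf[(pos + 4):(pos + 7)], "integer", size = 4,
                   endian = "little")
    data <- if (len > 0) buf[(pos + 8):(pos + 7 + len)] else raw(0)
    adv <- 8L + len + if (type == MI_COMPRESSED) 0L else pad8(len)
    list(type = type, data = data, next_pos = pos + adv)
  }
}

read_mat5_matrix <- function(payload) {
  pos <- 1L
  flags <- read_mat5_tag(payload, pos); pos <- flags$next_pos
  dims_el <- read_mat5_tag(payload, pos); pos <- dims_el$next_pos
  name_el <- read_mat5_tag(payload, pos); pos <- name_el$next_pos
  mat_class <- bitwAnd(readBin(flags$data[1:4], "integer", size = 4,
                               endian = "little"), 0xFFL)
  dims <- readBin(dims_el$data, "integer", n = length(dims_el$data) %/% 4L,
                  size = 4, endian = "little")
  name <- rawToChar(name_el$data)
  data_el <- read_mat5_tag(payload, pos)
  if (mat_class == 4L) {                      # mxCHAR: decode to a string
    if (data_el$type == 16L)                  # miUTF8
      return(list(name = name, value = rawToChar(data_el$data)))
    vals <- read_mat5_numeric(data_el$data, data_el$type)
    return(list(name = name, value = intToUtf8(vals[vals > 0])))
  }
  vals <- read_mat5_numeric(data_el$data, data_el$type)
  if (length(vals) != prod(dims))
    abort_arg("corrupt MAT element '%s': %d values for dims %s",
              name, length(vals), paste(dims, collapse = "x"))
  m <- array(as.double(vals), dim = dims)
  list(name = name, value = m)
}

#' Read a MATLAB Level-5 archive of numeric matrices
#'
#' Supports the subset of the format the NinaPro DB2 files use: full real
#' numeric matrices (double or integer storage), optionally inside
#' zlib-compressed elements.
#'
#' @param path path to a `.mat` file.
#' @return named list of numeric matrices.
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) abort_arg("file '%s' does not exist", path)
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 128L) abort_arg("'%s' is not a MAT 5 file (too short)", path)
  endian_tag <- rawToChar(buf[127:128])
  if (endian_tag != "IM")
    abort_arg("'%s': unsupported MAT file (big-endian or not Level 5)", path)
  pos <- 129L
  out <- list()
  while (pos + 7L <= length(buf)) {
    el <- read_mat5_tag(buf, pos)
    payload <- el$data
    if (el$type == MI_COMPRESSED) {
      payload <- tryCatch(
        memDecompress(payload, type = "gzip"),
        error = function(e) abort_arg(
          "'%s': compressed MAT element could not be decompressed (%s)",
          path, conditionMessage(e)))
      el$type <- MI_MATRIX
      # compressed payload itself starts with a miMATRIX tag
      inner <- read_mat5_tag(payload, 1L)
      payload <- inner$data
    }
    if (el$type != MI_MATRIX)
      abort_arg("'%s': unexpected top-level MAT element type %d", path, el$type)
    v <- read_mat5_matrix(payload)
    out[[v$name]] <- v$value
    pos <- el$next_pos
  }
  out
}
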