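# Minimal NumPy .npy v1/v2 reader and writer for 2-D float matrices, enough
# to exchange channel-by-sample matrices with Python pipelines.

#' Read a 2-D numeric .npy file
#'
#' Supports float64/float32 and little-endian integer dtypes, C or Fortran
#' order, format versions 1.0 and 2.0.
#'
#' @param path Path to the .npy file.
#' @return A numeric matrix.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, c(as.raw(0x93), charToRaw("NUMPY")))) {
    stop("not an npy file: ", path, call. = FALSE)
  }
  ver <- readBin(con, "integer", 2, size = 1, signed = FALSE)
  hlen <- if (ver[1] == 1) {
    readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  } else {
    readBin(con, "integer", 1, size = 4, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("[ ]", "", shape_s), ",")[[1]])
  if (length(shape) != 2L) {
    stop("expected a 2-D array, got shape (", shape_s, ")", call. = FALSE)
  }
  n <- prod(shape)
  vals <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4, endian = "little"),
    "<i8" = readBin(con, "double", n, size = 8, endian = "little"),
    "<i4" = as.double(readBin(con, "integer", n, size = 4, endian = "little")),
    "<i2" = as.double(readBin(con, "integer", n, size = 2, endian = "little")),
    stop("unsupported npy dtype '", descr, "'", call. = FALSE))
  if (length(vals) < n) stop("npy data truncated: ", path, call. = FALSE)
  if (fortran) {
    matrix(vals, nrow = shape[1], ncol = shape[2])
  } else {
    t(matrix(vals, nrow = shape[2], ncol = shape[1]))
  }
}

#' Write a numeric matrix as .npy (float64, C order, version 1.0)
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @export
write_npy <- function(m, path) {
  m <- as.matrix(m)
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(m), ncol(m))
  total <- 10L + nchar(header) + 1L
  padding <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", padding), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1, 0))), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.vector(t(m)), con, size = 8, endian = "little")
  invisible(path)
}
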