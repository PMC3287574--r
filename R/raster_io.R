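# Grid conventions: images are numeric matrices [row, col], row 1 = top,
# 0-based pixel (0,0) of the image maps to [1,1]. 8-bit range [0,255] at
# I/O boundaries; float during processing.

#' Round half away from zero
#'
#' The package-wide rounding convention: ties round away from zero
#' (0.5 -> 1, -0.5 -> -1), unlike base [round()]'s banker's rounding.
#' Used for 8-bit quantization and for the 2-decimal metric report.
#'
#' @param x numeric vector or matrix.
#' @param digits integer number of decimal places.
#' @return `x` rounded, same shape.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5), 0)  # 1 2 -1
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.validate_gray <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(arg, " must be a numeric matrix", call. = FALSE)
  if (nrow(image) < 1L || ncol(image) < 1L)
    stop(arg, " has zero size", call. = FALSE)
  if (!all(is.finite(image)))
    stop(arg, " contains non-finite intensities", call. = FALSE)
  invisible(image)
}

.validate_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask))
    stop(arg, " must be a matrix", call. = FALSE)
  if (!all(mask %in% c(0, 1)))
    stop(arg, " must contain only 0 and 1", call. = FALSE)
  invisible(mask)
}

#' Read a grayscale image
#'
#' Reads PNG, TIFF or PGM (P2/P5) rasters into an 8-bit grayscale matrix.
#' RGB images are collapsed by the unweighted channel mean; an alpha channel
#' is dropped. PNG values are scaled from their native full-scale range;
#' TIFF and PGM samples wider than 8 bits are min-max requantized with
#' [quantize_to_256()].
#'
#' @param path file path ending in .png, .tif/.tiff or .pgm.
#' @return numeric matrix with values in `[0, 255]`.
#' @seealso [write_image()], [read_mask()]
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = {
      a <- tryCatch(png::readPNG(path),
                    error = function(e) stop("unreadable PNG: ", path,
                                             " (", conditionMessage(e), ")",
                                             call. = FALSE))
      .collapse_channels(a) * 255
    },
    tif = , tiff = {
      a <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                    error = function(e) stop("unreadable TIFF: ", path,
                                             " (", conditionMessage(e), ")",
                                             call. = FALSE))
      a <- .collapse_channels(a)
      if (max(a) > 255) quantize_to_256(a) else a
    },
    pgm = {
      a <- .read_pgm(path)
      if (max(a) > 255) quantize_to_256(a) else a
    },
    stop("unsupported image format: .", ext, " (", path, ")", call. = FALSE)
  )
  px <- round_half_away(px)
  .validate_gray(px, paste0("image read from ", path))
  storage.mode(px) <- "double"
  px
}

.collapse_channels <- function(a) {
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3]
    if (nch >= 3L) a <- (a[, , 1] + a[, , 2] + a[, , 3]) / 3
    else a <- a[, , 1]
  }
  a
}

.read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM file (magic '", magic, "'): ", path, call. = FALSE)
  # header tokens: width height maxval, '#' comments allowed
  toks <- integer(0)
  buf <- ""
  while (length(toks) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L || ch == "")
      stop("truncated PGM header: ", path, call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (ch == "\n" || ch == "") break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) buf <- paste0(buf, ch)
    else if (nzchar(buf)) { toks <- c(toks, as.integer(buf)); buf <- "" }
  }
  w <- toks[1]; h <- toks[2]; maxval <- toks[3]
  if (w < 1L || h < 1L) stop("zero-sized PGM image: ", path, call. = FALSE)
  n <- w * h
  if (magic == "P5") {
    if (maxval < 256) vals <- as.integer(readBin(con, "raw", n))
    else vals <- readBin(con, "integer", n, size = 2L, signed = FALSE,
                         endian = "big")
  } else {
    vals <- scan(con, integer(0), n = n, quiet = TRUE, comment.char = "#")
  }
  if (length(vals) < n) stop("truncated PGM pixel data: ", path, call. = FALSE)
  matrix(as.numeric(vals), nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale image
#'
#' Writes an 8-bit grayscale PNG, TIFF or ASCII PGM (P2), clipping to
#' `[0, 255]` and rounding half away from zero.
#'
#' @param image numeric matrix of intensities.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  .validate_gray(image)
  px <- round_half_away(pmin(pmax(image, 0), 255))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px / 255, path),
    tif = , tiff = tiff::writeTIFF(px / 255, path, bits.per.sample = 8L),
    pgm = .write_pgm_ascii(px, path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

.write_pgm_ascii <- function(px, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(px), nrow(px)), "255"), con)
  apply(px, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Read / write binary masks
#'
#' Masks are stored as 8-bit PNG with 0 encoding background and 255
#' encoding foreground; any nonzero pixel reads back as 1.
#'
#' @param path PNG file path.
#' @return `read_mask`: integer 0/1 matrix. `write_mask`: `path`, invisibly.
#' @export
read_mask <- function(path) {
  px <- read_image(path)
  m <- matrix(as.integer(px > 0), nrow(px), ncol(px))
  m
}

#' @rdname read_mask
#' @param mask 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  .validate_mask(mask)
  write_image(matrix(as.numeric(mask) * 255, nrow(mask), ncol(mask)), path)
}

#' Requantize an image to 256 gray levels
#'
#' Maps the intensity range `[min, max]` linearly onto `[0, 255]`,
#' rounding half away from zero. A constant image maps to all zeros.
#' Emulates the reduced 256-level representation used for mammographic
#' ROIs.
#'
#' @param image numeric matrix with finite intensities.
#' @return numeric matrix with integer values in `[0, 255]`.
#' @export
#' @examples
#' quantize_to_256(matrix(c(0, 1, 2), 1))  # 0 128 255
quantize_to_256 <- function(image) {
  .validate_gray(image)
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(matrix(0, nrow(image), ncol(image)))
  round_half_away((image - lo) * 255 / (hi - lo))
}

#' Downsample by block averaging
#'
#' Reduces resolution by taking the mean over `factor` x `factor` tiles
#' (trailing partial tiles are averaged over the pixels available), then
#' rounding half away from zero. Block means are preferred over decimation
#' to suppress aliasing before gradient computation. `factor = 1` is the
#' identity.
#'
#' @param image numeric matrix.
#' @param factor integer >= 1; default 4, a typical reduction for
#'   film-digitized mammogram ROIs.
#' @return numeric matrix of size `ceiling(dim(image) / factor)`.
#' @export
downsample <- function(image, factor = 4L) {
  .validate_gray(image)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("factor must be an integer >= 1", call. = FALSE)
  if (factor == 1L) return(image)
  ri <- (seq_len(nrow(image)) - 1L) %/% factor
  ci <- (seq_len(ncol(image)) - 1L) %/% factor
  sums <- rowsum(image, ri)                # rows pooled
  sums <- t(rowsum(t(sums), ci))           # cols pooled
  cnt <- outer(tabulate(ri + 1L), tabulate(ci + 1L))
  unname(round_half_away(sums / cnt))
}

#' Downsample a binary mask by majority vote
#'
#' Companion to [downsample()] for reference masks: each tile becomes 1
#' when at least half of its pixels are 1.
#'
#' @param mask 0/1 matrix.
#' @param factor integer >= 1.
#' @return 0/1 integer matrix.
#' @export
downsample_mask <- function(mask, factor) {
  .validate_mask(mask)
  factor <- as.integer(factor)
  if (factor == 1L) return(mask)
  ri <- (seq_len(nrow(mask)) - 1L) %/% factor
  ci <- (seq_len(ncol(mask)) - 1L) %/% factor
  sums <- t(rowsum(t(rowsum(mask + 0, ri)), ci))
  cnt <- outer(tabulate(ri + 1L), tabulate(ci + 1L))
  unname(matrix(as.integer(sums / cnt >= 0.5), nrow(sums), ncol(sums)))
}
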