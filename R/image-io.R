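#' Read a grayscale image
#'
#' Reads PNG, TIFF or PGM files into a numeric matrix of intensities on the
#' \code{0..max_level} scale (default 8-bit, 0-255). Colour images are
#' converted to grayscale by averaging the channels. PGM files (both the
#' ASCII \code{P2} and binary \code{P5} variants) are parsed directly.
#'
#' @param path File path; format inferred from the extension.
#' @param max_level Intensity of white, i.e. \code{2^bit_depth - 1}.
#' @return A numeric matrix (rows = image rows, top row first) with values in
#'   \code{[0, max_level]}.
#' @export
read_gray <- function(path, max_level = 255) {
  if (!file.exists(path)) {
    stop("image file not found: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
  } else if (ext %in% c("pgm")) {
    return(read_pgm(path, max_level = max_level))
  } else {
    stop("unsupported image format: '", ext, "' (use PNG, TIFF or PGM)")
  }
  if (length(dim(img)) == 3L) {
    img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE], c(1, 2), mean)
  }
  img * max_level
}

#' Write a grayscale image
#'
#' @param img Numeric matrix of intensities in \code{[0, max_level]}.
#' @param path Output path; \code{.png}, \code{.tif}/\code{.tiff} or
#'   \code{.pgm} (ASCII \code{P2}).
#' @param max_level Intensity of white.
#' @return The path, invisibly.
#' @export
write_gray <- function(img, path, max_level = 255) {
  stopifnot(is.matrix(img))
  scaled <- pmin(pmax(img / max_level, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(scaled, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path)
  } else if (ext == "pgm") {
    write_pgm(img, path, max_level = max_level)
  } else {
    stop("unsupported image format: '", ext, "'")
  }
  invisible(path)
}

read_pgm <- function(path, max_level = 255) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  # header tokens: width height maxval, '#' comments allowed
  tokens <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L)
    if (length(ch) == 0L) stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L)
        if (length(ch) == 0L || ch == "\n") break
      }
    } else if (grepl("[0-9]", ch)) {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L)
        if (length(ch) == 0L || !grepl("[0-9]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  if (magic == "P5") {
    size <- if (maxval > 255) 2L else 1L
    raw <- readBin(con, "integer", n = w * h, size = size,
                   signed = FALSE, endian = "big")
  } else {
    raw <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  img <- matrix(raw, nrow = h, ncol = w, byrow = TRUE)
  img / maxval * max_level
}

write_pgm <- function(img, path, max_level = 255) {
  vals <- round(pmin(pmax(img, 0), max_level))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(max_level)), con)
  apply(vals, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Evaluate a function with a temporary RNG state seeded by `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
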