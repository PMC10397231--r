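# Image and graph serialization: PNG (via the png package), plain PPM
# (P3/P6), vessel-graph/profile JSON.

#' Write an image or mask to PNG
#'
#' 3-channel arrays are written as RGB, matrices as grayscale. Intensities
#' are assumed in 0-255 (logical masks become 0/255).
#' @param img array (rows x cols x 3), numeric matrix, or logical mask.
#' @param path output path.
#' @export
write_image_png <- function(img, path) {
  if (is.logical(img)) img <- img * 255
  png::writePNG(clamp(img / 255, 0, 1), path)
  invisible(path)
}

#' Read a PNG, PPM or TIFF image
#' @param path input file.
#' @return rows x cols x 3 array (0-255), or a matrix for grayscale input.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    return(a * 255)
  }
  if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path)
    return(a * 255)
  }
  if (ext %in% c("ppm", "pnm")) return(.read_ppm(path))
  stop("unsupported image format: ", ext)
}

#' Read a binary mask from PNG
#' @param path PNG file.
#' @return logical matrix (pixel > 0.5 of max).
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a > 0.5
}

.read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  tokens <- c()
  while (length(tokens) < 3L) {
    line <- readLines(con, 1L)
    line <- sub("#.*", "", line)
    tokens <- c(tokens, scan(text = line, quiet = TRUE))
  }
  w <- tokens[1L]; h <- tokens[2L]; mx <- tokens[3L]
  if (magic == "P6") {
    vals <- as.integer(readBin(con, "raw", 3L * w * h))
  } else if (magic == "P3") {
    vals <- scan(con, quiet = TRUE)
  } else stop("unsupported PPM magic: ", magic)
  arr <- array(0, c(h, w, 3L))
  v <- array(vals, c(3L, w, h))
  for (ch in 1:3) arr[, , ch] <- t(v[ch, , ]) * 255 / mx
  arr
}

#' Write a PPM (P6) image
#' @param img rows x cols x 3 array, 0-255.
#' @param path output path.
#' @export
write_ppm <- function(img, path) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  v <- array(0L, c(3L, w, h))
  for (ch in 1:3) v[ch, , ] <- t(round(clamp(img[, , ch], 0, 255)))
  writeBin(as.raw(v), con)
  invisible(path)
}

#' Serialize a vessel graph (optionally with its profile) to JSON
#' @param graph a `vessel_graph`.
#' @param path output path.
#' @param profile optional `centerline_profile` whose sampled points,
#'   tangents, normals and radii are attached to the record.
#' @export
write_graph_json <- function(graph, path, profile = NULL) {
  obj <- list(
    image_size = graph$image_size,
    nodes = graph$nodes,
    segments = lapply(graph$segments, function(s) {
      list(from = s$from, to = s$to, points = unname(s$points))
    })
  )
  if (!is.null(profile)) {
    obj$px_size <- profile$px_size
    obj$profile = lapply(profile$segments, function(s) {
      list(from = s$from, to = s$to, points = unname(s$points),
           tangents = unname(s$tangents), normals = unname(s$normals),
           radii_px = s$radii_px)
    })
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
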