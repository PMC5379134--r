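#' Read a color fundus photograph
#'
#' Decodes a PNG/JPEG/TIFF file into the package's raster representation:
#' an H x W x 3 integer array of 0-255 intensities in row (y), column (x),
#' channel order, plus an image id derived from the file name.
#'
#' @param path Path to an 8-bit RGB image file.
#' @return A list of class \code{"fundus_image"} with elements
#'   \code{pixels} (H x W x 3 integer array) and \code{image_id}.
#' @export
read_fundus_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) < 3L || d[3] < 3L)
    stop("image is not 3-channel RGB: ", path)
  px <- array(0L, dim = c(d[2], d[1], 3L))
  dat <- EBImage::imageData(img)
  for (c in 1:3) px[, , c] <- as.integer(round(t(dat[, , c]) * 255))
  fundus_image(px, image_id = sub("\\.[A-Za-z]+$", "", basename(path)))
}

#' Construct a fundus image object from a pixel array
#' @param pixels H x W x 3 array of integers in 0-255.
#' @param image_id Identifier string.
#' @return A \code{"fundus_image"} object.
#' @export
fundus_image <- function(pixels, image_id = "image") {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) stop("pixels must be H x W x 3")
  if (d[1] < 64L || d[2] < 64L) stop("image smaller than 64 x 64")
  if (min(pixels) < 0 || max(pixels) > 255) stop("pixels must lie in 0-255")
  structure(list(pixels = pixels, image_id = as.character(image_id)),
            class = "fundus_image")
}

#' Write a fundus image (or grayscale map) to disk
#' @param x A \code{"fundus_image"}, or an H x W numeric matrix in [0,1]
#'   written as 8-bit grayscale.
#' @param path Output path; format follows the extension (png/jpeg/tiff).
#' @return \code{path}, invisibly.
#' @export
write_fundus_image <- function(x, path) {
  if (inherits(x, "fundus_image")) {
    d <- dim(x$pixels)
    dat <- array(0, dim = c(d[2], d[1], 3L))
    for (c in 1:3) dat[, , c] <- t(x$pixels[, , c]) / 255
    img <- EBImage::Image(dat, colormode = "Color")
  } else {
    img <- EBImage::Image(t(pmin(pmax(x, 0), 1)))
  }
  EBImage::writeImage(img, path)
  invisible(path)
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("fundus image '%s': %d x %d, RGB 0-255\n",
              x$image_id, d[1], d[2]))
  invisible(x)
}

# Annotation and detection tables are plain data.frames with 0-based x
# (column) and y (row) pixel coordinates, as stored on disk. Internal image
# code is 1-based (row, col); conversion happens only here.

#' Read a ground-truth annotation table
#'
#' Comma-delimited UTF-8 with header \code{image_id,x,y}; \code{x} is the
#' 0-based column and \code{y} the 0-based row of each microaneurysm
#' centre.
#'
#' @param path CSV path.
#' @return data.frame with columns image_id (character), x, y (integer)
#'   and label ("MA").
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  df <- utils::read.csv(path, colClasses = "character", comment.char = "#")
  need <- c("image_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("annotation file must have header image_id,x,y: ", path)
  if (nrow(df) == 0L)
    return(data.frame(image_id = character(), x = integer(), y = integer(),
                      label = character(), stringsAsFactors = FALSE))
  xs <- suppressWarnings(as.numeric(df$x))
  ys <- suppressWarnings(as.numeric(df$y))
  bad <- which(is.na(xs) | is.na(ys) | xs != floor(xs) | ys != floor(ys))
  if (length(bad))
    stop(sprintf("malformed annotation row at line %d of %s",
                 bad[1] + 1L, path))
  data.frame(image_id = df$image_id, x = as.integer(xs), y = as.integer(ys),
             label = "MA", stringsAsFactors = FALSE)
}

#' Write an annotation table
#' @param ann data.frame with image_id, x, y (0-based x = column, y = row).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_annotations <- function(ann, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# x = 0-based column, y = 0-based row, pixel-centered", con)
  utils::write.csv(ann[, c("image_id", "x", "y")], con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write detection tables
#'
#' Detections carry the candidate's peak multiscale correlation score and
#' the predicted label; header \code{image_id,x,y,score,label}.
#'
#' @param path CSV path.
#' @return data.frame with image_id, x, y, score, label.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("cannot read detection file: ", path)
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(image_id = "character"))
  need <- c("image_id", "x", "y", "score", "label")
  if (!all(need %in% names(df)))
    stop("detection file must have header image_id,x,y,score,label")
  df$x <- as.integer(df$x); df$y <- as.integer(df$y)
  df
}

#' @rdname read_detections
#' @param det data.frame of detections.
#' @export
write_detections <- function(det, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# x = 0-based column, y = 0-based row, pixel-centered", con)
  utils::write.csv(det[, c("image_id", "x", "y", "score", "label")], con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

empty_detections <- function() {
  data.frame(image_id = character(), x = integer(), y = integer(),
             score = numeric(), label = character(), stringsAsFactors = FALSE)
}
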