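## Image containers and raster I/O.
##
## Pixel data are plain numeric matrices of 8-bit intensities (0-255),
## indexed [row, col].  An rgb_image is three mutually aligned channel
## matrices; a zstack_series is an ordered list of rgb_images.

#' Single-channel 8-bit image
#'
#' Wraps a numeric matrix of intensities in `[0, 255]` with a channel
#' label.  Most functions in the package also accept a plain matrix.
#'
#' @param pixels numeric matrix, intensities in `[0, 255]`.
#' @param label channel label, one of `"red"`, `"green"`, `"blue"`,
#'   `"grayscale"` (red conventionally carries N-Cad, green Cx43, blue
#'   nuclei).
#' @return a `channel_image`: the matrix with class and `label` attributes.
#' @export
channel_image <- function(pixels, label = "grayscale") {
  pixels <- as.matrix(pixels)
  stopifnot(is.numeric(pixels), length(pixels) >= 1)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel intensities must lie in [0, 255] with no missing values")
  structure(pixels, class = c("channel_image", class(pixels)),
            label = label)
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image %dx%d, label=%s, range [%g, %g]>\n",
              nrow(x), ncol(x), attr(x, "label"), min(x), max(x)))
  invisible(x)
}

#' Three-channel aligned 8-bit image
#'
#' @param red,green,blue numeric matrices of identical dimensions with
#'   intensities in `[0, 255]`.
#' @return an `rgb_image` (list with elements `red`, `green`, `blue`).
#' @export
rgb_image <- function(red, green, blue) {
  chans <- list(red = as.matrix(red), green = as.matrix(green),
                blue = as.matrix(blue))
  dims <- vapply(chans, dim, integer(2))
  if (!all(dims == dims[, 1]))
    stop("red, green and blue channels must share identical dimensions")
  for (ch in chans)
    if (anyNA(ch) || min(ch) < 0 || max(ch) > 255)
      stop("channel intensities must lie in [0, 255] with no missing values")
  structure(chans, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %dx%d>\n", nrow(x$red), ncol(x$red)))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$red)

#' Ordered confocal Z-stack of aligned RGB images
#'
#' @param layers list of [rgb_image()] objects, all of the same dimensions,
#'   in acquisition order.
#' @param stack_id identifier carried into reports.
#' @return a `zstack_series`.
#' @export
zstack_series <- function(layers, stack_id = "stack") {
  if (length(layers) < 1) stop("a Z-stack needs at least one layer")
  stopifnot(all(vapply(layers, inherits, logical(1), "rgb_image")))
  dims <- vapply(layers, function(l) dim(l$red), integer(2))
  if (!all(dims == dims[, 1]))
    stop("all Z-stack layers must share identical dimensions")
  structure(list(layers = layers, stack_id = stack_id),
            class = "zstack_series")
}

#' @export
print.zstack_series <- function(x, ...) {
  cat(sprintf("<zstack_series '%s': %d layers of %dx%d>\n", x$stack_id,
              length(x$layers), nrow(x$layers[[1]]$red),
              ncol(x$layers[[1]]$red)))
  invisible(x)
}

#' @export
length.zstack_series <- function(x) length(x$layers)

## Read one page of raster data as an array in [0,1]; multi-page TIFFs
## return a list of arrays.
.read_raster <- function(path, all_pages = FALSE) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, all = all_pages)
  } else if (ext == "png") {
    png::readPNG(path)
  } else stop("unsupported raster format '", ext, "' (expected TIFF or PNG)")
}

.array_to_rgb <- function(a, path = "<array>") {
  if (length(dim(a)) == 2L || (length(dim(a)) == 3L && dim(a)[3] < 3L))
    stop("'", path, "' is a single-channel image; a 3-channel image ",
         "(red = N-Cad, green = Cx43, blue = nuclei) is required")
  # readTIFF/readPNG normalize to [0,1] whatever the container bit depth,
  # so x*255 is the linear rescale of >8-bit data onto [0,255]
  # (container max maps to 255); 8-bit data round-trip exactly.
  rgb_image(red   = round(a[, , 1] * 255),
            green = round(a[, , 2] * 255),
            blue  = round(a[, , 3] * 255))
}

#' Read a 3-channel raster image
#'
#' Reads a TIFF or PNG file into an [rgb_image()].  Inputs with bit depth
#' greater than 8 are linearly rescaled to `[0, 255]` (the container
#' maximum maps to 255), preserving relative intensities.
#'
#' @param path path to a TIFF or PNG file with at least 3 channels.
#' @return an [rgb_image()].
#' @export
read_rgb_image <- function(path) {
  a <- .read_raster(path)
  if (is.list(a)) a <- a[[1]]
  .array_to_rgb(a, path)
}

#' Write an 8-bit 3-channel image
#'
#' Writes an [rgb_image()] to TIFF or PNG (chosen by file extension) at
#' 8-bit depth.  Pixel values round-trip exactly through
#' [read_rgb_image()].
#'
#' @param img an [rgb_image()].
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  a <- array(0, c(dim(img$red), 3L))
  a[, , 1] <- img$red; a[, , 2] <- img$green; a[, , 3] <- img$blue
  a <- a / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(a, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(a, path)
  } else stop("unsupported output format '", ext, "'")
  invisible(path)
}

#' Read an ordered Z-stack
#'
#' Builds a [zstack_series()] from an ordered vector of file paths.  A
#' single path to a multi-page TIFF expands into one layer per page.
#' Layer order follows the order given.
#'
#' @param paths character vector of image paths (or one multi-page TIFF).
#' @param stack_id identifier for the stack; defaults to the common
#'   directory/file prefix.
#' @return a [zstack_series()].
#' @export
read_zstack <- function(paths, stack_id = NULL) {
  if (length(paths) < 1) stop("at least one path is required")
  if (is.null(stack_id))
    stack_id <- tools::file_path_sans_ext(basename(paths[1]))
  layers <- list()
  for (p in paths) {
    a <- .read_raster(p, all_pages = TRUE)
    if (!is.list(a)) a <- list(a)
    layers <- c(layers, lapply(a, .array_to_rgb, path = p))
  }
  zstack_series(layers, stack_id = stack_id)
}

#' Write a Z-stack as a multi-page 8-bit TIFF
#'
#' @param stack a [zstack_series()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack_series"))
  pages <- lapply(stack$layers, function(l) {
    a <- array(0, c(dim(l$red), 3L))
    a[, , 1] <- l$red; a[, , 2] <- l$green; a[, , 3] <- l$blue
    a / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Maximum-intensity projection of a Z-stack
#'
#' Collapses a stack into a single image: for every pixel and channel the
#' projected intensity is the maximum over all layers.
#'
#' @param stack a [zstack_series()].
#' @return an [rgb_image()].
#' @export
max_projection <- function(stack) {
  stopifnot(inherits(stack, "zstack_series"))
  proj <- lapply(c("red", "green", "blue"), function(ch) {
    Reduce(pmax, lapply(stack$layers, `[[`, ch))
  })
  rgb_image(proj[[1]], proj[[2]], proj[[3]])
}
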