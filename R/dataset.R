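#' Count the boxes in an annotation string
#'
#' Box-annotation tables (GWHD convention) store all boxes of an
#' image in one string: boxes separated by `";"`, each box four
#' space-separated numbers, with the sentinel `"no_box"` (or an empty
#' string) for images without objects.  Count supervision needs only
#' the number of boxes, never their geometry.
#'
#' @param s Annotation string (or vector of them).
#' @return Integer count(s) of boxes.
#' @examples
#' parse_boxes_string("1 2 3 4;5 6 7 8;9 9 20 20")  # 3
#' parse_boxes_string("no_box")                     # 0
#' @export
parse_boxes_string <- function(s) {
  one <- function(si) {
    if (is.na(si) || !nzchar(trimws(si)) || trimws(si) == "no_box")
      return(0L)
    toks <- strsplit(si, ";", fixed = TRUE)[[1L]]
    for (tok in toks) {
      nums <- suppressWarnings(as.numeric(strsplit(trimws(tok),
                                                   "\\s+")[[1L]]))
      if (length(nums) != 4L || anyNA(nums))
        stop(sprintf("malformed box token: '%s'", tok))
    }
    length(toks)
  }
  vapply(as.character(s), one, integer(1), USE.NAMES = FALSE)
}

#' Reduce a box-annotation CSV to a count manifest
#'
#' @param path CSV with an image-name column and a boxes-string
#'   column (GWHD dialect).
#' @param image_col,boxes_col Column names.
#' @return Data frame with columns `image` and `count`.
#' @export
load_gwhd_csv <- function(path, image_col = "image_name",
                          boxes_col = "BoxesString") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c(image_col, boxes_col) %in% names(df)))
    stop(sprintf("columns '%s' and '%s' not found in %s",
                 image_col, boxes_col, path))
  data.frame(image = df[[image_col]],
             count = parse_boxes_string(df[[boxes_col]]))
}

#' Load a count manifest
#'
#' @param path CSV file with header `image,count`.
#' @param check_images If `TRUE`, verify that every referenced image
#'   file exists next to the manifest.
#' @return Data frame with columns `image` (character) and `count`
#'   (nonnegative integer); the manifest directory is attached as
#'   attribute `dir`.
#' @export
load_manifest <- function(path, check_images = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image", "count") %in% names(df)))
    stop("manifest must have header 'image,count'")
  if (any(is.na(df$count)) || any(df$count < 0) ||
      any(df$count != round(df$count)))
    stop("manifest counts must be nonnegative integers")
  df$count <- as.integer(df$count)
  dir <- dirname(normalizePath(path))
  if (check_images) {
    missing <- !file.exists(file.path(dir, df$image))
    if (any(missing))
      stop("missing image file(s): ",
           paste(utils::head(df$image[missing], 3L), collapse = ", "))
  }
  attr(df, "dir") <- dir
  df
}

#' Preprocessing specification
#'
#' Images are bilinearly rescaled to a uniform square side (default
#' 512, the network's native input) and normalized per channel.  The
#' default statistics are the ImageNet ones, matching a backbone
#' intended for ImageNet-pretrained weights; `normalize =
#' "identity"` keeps raw \[0, 1\] values for from-scratch desk-scale
#' models.  Counts are invariant under resizing, so labels need no
#' adjustment.
#'
#' @param size Target side S in pixels.
#' @param normalize `"imagenet"` or `"identity"`, or use `mean`/`sd`.
#' @param mean,sd Optional explicit per-channel statistics.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(size = 512L,
                            normalize = c("imagenet", "identity"),
                            mean = NULL, sd = NULL) {
  normalize <- match.arg(normalize)
  if (is.null(mean))
    mean <- if (normalize == "imagenet")
      c(0.485, 0.456, 0.406) else c(0, 0, 0)
  if (is.null(sd))
    sd <- if (normalize == "imagenet")
      c(0.229, 0.224, 0.225) else c(1, 1, 1)
  stopifnot(length(mean) == 3L, length(sd) == 3L, all(sd > 0), size >= 1)
  structure(list(size = as.integer(size), mean = mean, sd = sd),
            class = "preprocess_spec")
}

#' Preprocess one image to the network's input contract
#'
#' @param image H x W x 3 array in \[0, 1\] or a path to a PNG file.
#' @param spec A [preprocess_spec()].
#' @return S x S x 3 array, resized and channel-normalized.
#' @export
preprocess_image <- function(image, spec = preprocess_spec()) {
  if (is.character(image)) image <- read_image(image)
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stop("input must be an RGB image (H x W x 3)")
  if (any(!is.finite(image))) stop("image contains non-finite values")
  if (d[1L] != spec$size || d[2L] != spec$size)
    image <- bilinear_resize(image, spec$size, spec$size)
  for (ch in 1:3)
    image[, , ch] <- (image[, , ch] - spec$mean[ch]) / spec$sd[ch]
  image
}

read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (tolower(tools::file_ext(path)) != "png")
    stop("only PNG images are supported; got: ", basename(path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L)
    stop("non-RGB (grayscale) input: ", basename(path))
  if (dim(img)[3L] == 4L) img <- img[, , 1:3]  # drop alpha
  if (dim(img)[3L] != 3L)
    stop("non-RGB input: ", basename(path))
  img
}

#' Load and preprocess all samples of a manifest
#'
#' @param manifest Data frame from [load_manifest()] (or a path to a
#'   manifest CSV).
#' @param spec A [preprocess_spec()].
#' @param dir Image directory; defaults to the manifest's own.
#' @return A `countnet_samples` object with preprocessed arrays.
#' @export
load_samples <- function(manifest, spec = preprocess_spec(), dir = NULL) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  if (is.null(dir)) dir <- attr(manifest, "dir")
  if (is.null(dir)) dir <- "."
  xs <- lapply(file.path(dir, manifest$image), preprocess_image,
               spec = spec)
  structure(list(x = xs, count = as.integer(manifest$count),
                 paths = file.path(dir, manifest$image)),
            class = "countnet_samples")
}

#' Preprocess in-memory samples
#'
#' @param samples A `countnet_samples` object with raw \[0, 1\]
#'   images (e.g. from [synth_samples()]).
#' @param spec A [preprocess_spec()].
#' @return The samples with every image preprocessed.
#' @export
preprocess_samples <- function(samples, spec = preprocess_spec()) {
  stopifnot(inherits(samples, "countnet_samples"))
  samples$x <- lapply(samples$x, preprocess_image, spec = spec)
  samples
}
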