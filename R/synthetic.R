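#' Configure the synthetic field-image generator
#'
#' The generator emulates the statistical structure of wheat-ear and
#' wheat-grain counting imagery so every stage of the pipeline can be
#' exercised without field data: per-image counts follow a rounded
#' Gaussian clipped to \[min, max\], objects are oriented ellipses
#' (elongated and awn-textured in `ear_field` mode, small rounded
#' kernels in `grain_scatter` mode), partial occlusion is allowed up
#' to a configurable overlap fraction, and the label always equals
#' the number of instances actually rendered.
#'
#' Mode defaults mirror the published dataset statistics: ear fields
#' use mean 42, sd 20, counts 0-190 on 512 px images; grain scatters
#' use mean 40, sd 10, counts 11-68 on 256 px images with plain or
#' gray-striped backgrounds (zero-count background-only negatives are
#' produced by rendering `count = 0`).
#'
#' @param mode `"ear_field"` or `"grain_scatter"`.
#' @param image_size Square image side in pixels.
#' @param count List with `mean`, `sd`, `min`, `max` (objects/image).
#' @param geometry List with `length`, `width` (pixel ranges),
#'   `orientation` (radian range) and `color_jitter`.
#' @param background List with `clutter` (number of soft distractor
#'   blobs), `noise_sd`, and for grain mode `striped` (TRUE, FALSE or
#'   NA = random) and `stripe_period` in pixels.
#' @param occlusion Maximum allowed overlap fraction of a new
#'   instance with already-placed ones.
#' @param seed Integer seed; generation is a pure function of
#'   (config, seed).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(mode = c("ear_field", "grain_scatter"),
                         image_size = NULL, count = list(),
                         geometry = list(), background = list(),
                         occlusion = 0.3, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(image_size))
    image_size <- if (mode == "ear_field") 512L else 256L
  s <- image_size
  def_count <- if (mode == "ear_field")
    list(mean = 42, sd = 20, min = 0L, max = 190L)
  else
    list(mean = 40, sd = 10, min = 11L, max = 68L)
  def_geom <- if (mode == "ear_field")
    list(length = s * c(0.06, 0.11), width = s * c(0.018, 0.030),
         orientation = c(0, pi), color_jitter = 0.10)
  else
    list(length = s * c(0.035, 0.055), width = s * c(0.022, 0.035),
         orientation = c(0, pi), color_jitter = 0.08)
  def_bg <- if (mode == "ear_field")
    list(clutter = 8L, noise_sd = 0.035, striped = FALSE,
         stripe_period = 32L)
  else
    list(clutter = 0L, noise_sd = 0.015, striped = NA,
         stripe_period = 32L)
  count <- utils::modifyList(def_count, count)
  geometry <- utils::modifyList(def_geom, geometry)
  background <- utils::modifyList(def_bg, background)
  if (count$min > count$max)
    stop("count bounds invalid: min exceeds max")
  stopifnot(occlusion >= 0, occlusion < 1)
  structure(list(mode = mode, image_size = as.integer(s), count = count,
                 geometry = geometry, background = background,
                 occlusion = occlusion, seed = as.integer(seed)),
            class = "synth_config")
}

#' Sample per-image object counts
#'
#' Counts are drawn from a Gaussian with the configured mean and sd,
#' rounded to the nearest integer and clipped to \[min, max\], so the
#' boundary values absorb the tail mass.
#'
#' @param config A [synth_config()].
#' @param n Number of draws.
#' @return Integer vector of length `n`, each in \[min, max\].
#' @export
sample_count <- function(config, n = 1L) {
  cc <- config$count
  if (cc$min > cc$max) stop("count bounds invalid: min exceeds max")
  x <- round(stats::rnorm(n, cc$mean, cc$sd))
  as.integer(pmin(pmax(x, cc$min), cc$max))
}

# Pixel indices (into an H x W plane) of an oriented ellipse, plus
# the along-axis coordinate of each pixel (used for awn texture).
ellipse_pixels <- function(cx, cy, len, wid, ang, H, W) {
  h <- len / 2
  x0 <- max(1L, floor(cx - h)); x1 <- min(W, ceiling(cx + h))
  y0 <- max(1L, floor(cy - h)); y1 <- min(H, ceiling(cy + h))
  xs <- x0:x1; ys <- y0:y1
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  u <- (X - cx) * cos(ang) + (Y - cy) * sin(ang)
  v <- -(X - cx) * sin(ang) + (Y - cy) * cos(ang)
  inside <- (u / h)^2 + (v / (wid / 2))^2 <= 1
  idx <- (X[inside] - 1L) * H + Y[inside]
  list(idx = idx, u = u[inside])
}

render_background <- function(config) {
  s <- config$image_size
  bg <- config$background
  if (config$mode == "ear_field") {
    base <- c(0.30, 0.38, 0.18)
    img <- array(rep(base, each = s * s), c(s, s, 3L))
    for (k in seq_len(bg$clutter)) {
      cx <- stats::runif(1, 1, s); cy <- stats::runif(1, 1, s)
      r <- stats::runif(1, s * 0.05, s * 0.18)
      ep <- ellipse_pixels(cx, cy, 2 * r, 2 * r * stats::runif(1, 0.5, 1),
                           stats::runif(1, 0, pi), s, s)
      shade <- stats::rnorm(3, 0, 0.05)
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[ep$idx] <- pl[ep$idx] + shade[ch]
        img[, , ch] <- pl
      }
    }
  } else {
    striped <- bg$striped
    if (is.na(striped)) striped <- stats::runif(1) < 0.5
    if (striped) {
      tone <- 0.62 + 0.10 * sin(2 * pi * seq_len(s) / bg$stripe_period)
      plane <- matrix(tone, s, s, byrow = TRUE)
    } else plane <- matrix(0.92, s, s)
    img <- array(rep(plane, 3L), c(s, s, 3L))
  }
  img + array(stats::rnorm(s * s * 3, 0, bg$noise_sd), c(s, s, 3L))
}

#' Render one field image with an exact count label
#'
#' Places exactly `count` object instances on a freshly rendered
#' background, resampling positions until the overlap with previously
#' placed instances is at most the configured occlusion fraction.  If
#' the requested count exceeds what the image can geometrically hold
#' (or a placement cannot be found), a capacity error is raised.
#'
#' @param count Nonnegative integer number of objects to render.
#' @param config A [synth_config()].
#' @param seed Optional seed; if `NULL`, the current RNG state is
#'   used (as when called from [generate_dataset()]).
#' @return An object of class `image_sample`: list with `image`
#'   (H x W x 3 array in \[0, 1\]), `count`, `positions` (debug
#'   data frame `x, y, angle, len, width` never consumed by the
#'   model), and `mask` (integer H x W instance mask, 0 for
#'   background; overlapping pixels belong to the later instance).
#' @export
render_field <- function(count, config, seed = NULL) {
  stopifnot(count >= 0)
  if (!is.null(seed)) set.seed(seed)
  s <- config$image_size
  g <- config$geometry
  area <- pi / 4 * mean(g$length) * mean(g$width)
  if (count * area * (1 - config$occlusion) > 0.85 * s * s)
    stop(sprintf(paste0("capacity: %d objects of mean area %.0f px^2 ",
                        "cannot be packed into a %d x %d image"),
                 count, area, s, s))
  img <- render_background(config)
  cover <- logical(s * s)
  mask <- matrix(0L, s, s)
  pos <- matrix(0, count, 5L)
  base_col <- if (config$mode == "ear_field")
    c(0.78, 0.66, 0.33) else c(0.80, 0.68, 0.45)
  for (i in seq_len(count)) {
    placed <- FALSE
    for (try in seq_len(60L)) {
      len <- stats::runif(1, g$length[1], g$length[2])
      wid <- stats::runif(1, g$width[1], g$width[2])
      ang <- stats::runif(1, g$orientation[1], g$orientation[2])
      m <- len / 2 + 1
      cx <- stats::runif(1, m, s - m)
      cy <- stats::runif(1, m, s - m)
      ep <- ellipse_pixels(cx, cy, len, wid, ang, s, s)
      if (length(ep$idx) == 0L) next
      if (mean(cover[ep$idx]) <= config$occlusion) { placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf(paste0("capacity: could not place object %d of %d ",
                          "within the occlusion budget"), i, count))
    col <- pmin(pmax(base_col + stats::rnorm(3, 0, g$color_jitter), 0), 1)
    tex <- if (config$mode == "ear_field")
      1 + 0.22 * sin(ep$u * 2 * pi / (len / 6)) +
        stats::rnorm(length(ep$idx), 0, 0.05)
    else
      1 - 0.25 * (abs(ep$u) / (len / 2))^2 +
        stats::rnorm(length(ep$idx), 0, 0.03)
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[ep$idx] <- col[ch] * tex
      img[, , ch] <- pl
    }
    cover[ep$idx] <- TRUE
    mask[ep$idx] <- i
    pos[i, ] <- c(cx, cy, ang, len, wid)
  }
  img <- pmin(pmax(img, 0), 1)
  positions <- data.frame(x = pos[, 1], y = pos[, 2], angle = pos[, 3],
                          len = pos[, 4], width = pos[, 5])
  structure(list(image = img, count = as.integer(count),
                 positions = positions, mask = mask),
            class = "image_sample")
}

#' Generate a synthetic dataset on disk
#'
#' Draws `n` counts, renders each image, and writes PNG files plus a
#' `manifest.csv` (`image,count`) and a `positions.csv` sidecar
#' (`image,x,y,angle,len,width`; debug only, never read by the
#' model).  Generation is fully determined by (config, config$seed).
#'
#' @param n Number of images (>= 1).
#' @param config A [synth_config()].
#' @param outdir Output directory, created if needed.
#' @return The manifest as a data frame, invisibly also written to
#'   `file.path(outdir, "manifest.csv")`.
#' @export
generate_dataset <- function(n, config, outdir) {
  stopifnot(n >= 1)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  set.seed(config$seed)
  counts <- sample_count(config, n)
  files <- sprintf("img_%05d.png", seq_len(n))
  sidecars <- vector("list", n)
  for (i in seq_len(n)) {
    smp <- render_field(counts[i], config)
    png::writePNG(smp$image, file.path(outdir, files[i]))
    if (counts[i] > 0)
      sidecars[[i]] <- cbind(image = files[i], smp$positions)
  }
  manifest <- data.frame(image = files, count = counts)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  side <- do.call(rbind, sidecars)
  if (is.null(side))
    side <- data.frame(image = character(), x = numeric(), y = numeric(),
                       angle = numeric(), len = numeric(),
                       width = numeric())
  utils::write.csv(side, file.path(outdir, "positions.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest
}

#' Generate synthetic samples in memory
#'
#' Same generator as [generate_dataset()] without touching disk;
#' convenient for training and testing.
#'
#' @inheritParams generate_dataset
#' @return A `countnet_samples` object: list with `x` (list of
#'   H x W x 3 arrays), `count`, and `positions`.
#' @export
synth_samples <- function(n, config) {
  stopifnot(n >= 1)
  set.seed(config$seed)
  counts <- sample_count(config, n)
  xs <- vector("list", n)
  pos <- vector("list", n)
  for (i in seq_len(n)) {
    smp <- render_field(counts[i], config)
    xs[[i]] <- smp$image
    pos[[i]] <- smp$positions
  }
  structure(list(x = xs, count = counts, positions = pos),
            class = "countnet_samples")
}

#' @export
length.countnet_samples <- function(x) length(x$x)

#' Split a manifest into train/validation/test partitions
#'
#' Seeded shuffle followed by a disjoint split (default 80/10/10,
#' the conventional division for these datasets).
#'
#' @param manifest Data frame with one row per image.
#' @param fractions Numeric vector summing to 1.
#' @param seed Shuffle seed.
#' @return Named list of data frames (`train`, `val`, `test` for
#'   three fractions; otherwise `split1`, `split2`, ...).
#' @export
split_manifest <- function(manifest, fractions = c(0.8, 0.1, 0.1),
                           seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  n <- nrow(manifest)
  set.seed(seed)
  ord <- sample.int(n)
  sizes <- floor(fractions * n)
  sizes[1L] <- n - sum(sizes[-1L])
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- lapply(seq_along(fractions), function(i)
    manifest[sort(ord[starts[i]:ends[i]]), , drop = FALSE])
  names(out) <- if (length(fractions) == 3L) c("train", "val", "test")
  else paste0("split", seq_along(fractions))
  out
}
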