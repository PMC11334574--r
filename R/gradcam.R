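#' Gradient-weighted attention heatmap for a counting network
#'
#' Regression Grad-CAM: the gradient of the predicted count with
#' respect to a chosen feature layer is averaged over spatial
#' positions to give one weight per channel; the ReLU of the
#' weighted channel sum, bilinearly upsampled to the input size and
#' min-max normalized to \[0, 1\], is the attention heatmap.
#' Registered layers are the backbone's last convolution output
#' (`"backbone"`) and each perception branch's token matrix reshaped
#' to its spatial grid (`"mpm16"`, `"mpm8"`, `"mpm4"`, matching the
#' configured slice sizes).
#'
#' @param model A `countnet` or `countnet_fit`.
#' @param image One preprocessed H x W x 3 array.
#' @param layer Layer tag.
#' @return An object of class `attention_heatmap`: list with `map`
#'   (input-size matrix in \[0, 1\]; all zeros for a degenerate
#'   all-zero cam), `layer`, and `count` (the predicted count the
#'   gradients were taken from).
#' @export
compute_cam <- function(model, image, layer = "backbone") {
  if (inherits(model, "countnet_fit")) model <- model$model
  stopifnot(inherits(model, "countnet"))
  cfg <- model$config
  tags <- c("backbone", paste0("mpm", cfg$mpm$slices))
  if (!layer %in% tags)
    stop(sprintf("unknown layer tag '%s'; registered: %s", layer,
                 paste(tags, collapse = ", ")))
  fw <- countnet_forward(model$params, cfg, image, keep_cache = TRUE)
  bw <- countnet_backward(model$params, cfg, fw, dcount = 1)
  if (layer == "backbone") {
    A <- fw$m_b
    G <- bw$d_mb
  } else {
    s <- as.integer(sub("mpm", "", layer))
    i <- match(s, cfg$mpm$slices)
    g <- cfg$feature_side %/% s
    tok_to_grid <- function(T) {
      # tokens are row-major over the g x g patch grid
      a <- array(0, c(g, g, ncol(T)))
      for (r in seq_len(g))
        a[r, , ] <- T[(r - 1L) * g + seq_len(g), ]
      a
    }
    A <- tok_to_grid(fw$branch_T[[i]])
    G <- tok_to_grid(bw$branch_grads[[i]])
  }
  d <- dim(A)
  w <- colMeans(matrix(G, d[1L] * d[2L], d[3L]))
  cam <- matrix(matrix(A, d[1L] * d[2L], d[3L]) %*% w, d[1L], d[2L])
  cam[cam < 0] <- 0
  cam <- bilinear_resize(cam, dim(image)[1L], dim(image)[2L])
  cam[cam < 0] <- 0  # interpolation guard
  rng <- max(cam) - min(cam)
  cam <- if (rng > 0) (cam - min(cam)) / rng else cam * 0
  structure(list(map = cam, layer = layer, count = fw$count),
            class = "attention_heatmap")
}

#' Overlay a heatmap on its image
#'
#' Alpha-blends a colormapped heatmap with the original image:
#' `alpha = 0` returns the image, `alpha = 1` the pure colormap, and
#' intermediate values the pixelwise convex combination.
#'
#' @param image H x W x 3 array in \[0, 1\] (the un-normalized
#'   image).
#' @param heatmap An `attention_heatmap` (or a \[0, 1\] matrix of
#'   matching size).
#' @param alpha Blend weight in \[0, 1\].
#' @param palette Color ramp function mapping \[0, 1\] to colors;
#'   defaults to a blue-green-yellow-red heat ramp.
#' @return H x W x 3 composite array in \[0, 1\].
#' @export
overlay_cam <- function(image, heatmap, alpha = 0.5, palette = NULL) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]")
  map <- if (inherits(heatmap, "attention_heatmap")) heatmap$map
  else heatmap
  d <- dim(image)
  if (!all(dim(map) == d[1:2]))
    stop("heatmap size does not match the image")
  if (is.null(palette))
    palette <- grDevices::colorRamp(c("navy", "cyan", "yellow", "red"))
  cols <- palette(as.vector(map)) / 255
  heat <- array(cols, c(d[1L], d[2L], 3L))
  (1 - alpha) * image + alpha * heat
}

#' Write a heatmap overlay to a PNG file
#'
#' @inheritParams overlay_cam
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
save_cam <- function(image, heatmap, path, alpha = 0.5) {
  png::writePNG(pmin(pmax(overlay_cam(image, heatmap, alpha), 0), 1),
                path)
  invisible(path)
}
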