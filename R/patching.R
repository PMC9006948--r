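# Tiling of large RGB images into fixed-size patches and the two-stage
# tissue filter: a brightness rule that drops background tiles, then a
# connected-component rule that drops near-empty or fractal tiles.

#' Filter configuration for patch extraction
#'
#' @param intensity_threshold 8-bit grayscale value above which a pixel
#'   counts as "bright" (default 220).
#' @param intensity_fraction a tile is rejected as background when the
#'   fraction of bright pixels is >= this value (default 0.5; the
#'   boundary is inclusive).
#' @param min_components minimum number of foreground connected
#'   components a tile must contain (default 10).
#' @param binarization_method `"otsu"` (grayscale Otsu threshold,
#'   foreground = darker side) or `"fixed:<value>"` for a fixed 8-bit
#'   threshold.
#' @param connectivity component connectivity, 8 (default) or 4.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(intensity_threshold = 220,
                          intensity_fraction = 0.5,
                          min_components = 10L,
                          binarization_method = "otsu",
                          connectivity = 8L) {
  stopifnot(intensity_fraction > 0, intensity_fraction <= 1,
            min_components >= 0,
            connectivity %in% c(4L, 8L))
  if (!(identical(binarization_method, "otsu") ||
        grepl("^fixed:[0-9.]+$", binarization_method)))
    stop("binarization_method must be \"otsu\" or \"fixed:<value>\"")
  structure(list(intensity_threshold = intensity_threshold,
                 intensity_fraction = intensity_fraction,
                 min_components = as.integer(min_components),
                 binarization_method = binarization_method,
                 connectivity = as.integer(connectivity)),
            class = "filter_config")
}

#' Tile an image into non-overlapping patches
#'
#' Produces the floor(H/p) x floor(W/p) grid of patch positions; partial
#' border strips are discarded.  Coordinates are 0-based half-open pixel
#' intervals.
#' @param image H x W x 3 RGB array.
#' @param patch_size patch side in pixels (default 512).
#' @return a `tile_grid`: data.frame with `row_index`, `col_index`
#'   (0-based), `row_off`, `col_off` (0-based pixel offsets), `accepted`,
#'   `rejection_reason`, plus attributes `patch_size` and `image_dim`.
#' @export
tile_image <- function(image, patch_size = 512L) {
  check_rgb(image, "image")
  h <- dim(image)[1]; w <- dim(image)[2]; p <- as.integer(patch_size)
  if (h < p || w < p)
    stop(sprintf("image (%d x %d) is smaller than one %d x %d patch",
                 h, w, p, p))
  nr <- h %/% p; nc <- w %/% p
  grid <- expand.grid(row_index = 0:(nr - 1L), col_index = 0:(nc - 1L))
  grid$row_off <- grid$row_index * p
  grid$col_off <- grid$col_index * p
  grid$accepted <- TRUE
  grid$rejection_reason <- NA_character_
  attr(grid, "patch_size") <- p
  attr(grid, "image_dim") <- c(h, w)
  class(grid) <- c("tile_grid", "data.frame")
  grid
}

#' Background filter for one patch
#'
#' Rejects a patch when the fraction of pixels whose grayscale luma
#' exceeds `intensity_threshold` is at least `intensity_fraction`
#' (bright, tissue-poor tiles).
#' @param patch H x W x 3 RGB array (0-255).
#' @param cfg a `filter_config`.
#' @return list with `accept` (logical), `bright_fraction`, `reason`.
#' @export
filter_background <- function(patch, cfg = filter_config()) {
  check_rgb(patch)
  luma <- rgb_to_luma(patch)
  frac <- mean(luma > cfg$intensity_threshold)
  accept <- frac < cfg$intensity_fraction
  list(accept = accept, bright_fraction = frac,
       reason = if (accept) NA_character_ else "background")
}

# Otsu threshold on an 8-bit grayscale matrix (256-bin histogram,
# between-class variance maximization).  Returns the threshold value;
# foreground is <= threshold (dark nuclei).
otsu_threshold <- function(gray) {
  g <- clamp(round(gray), 0, 255)
  h <- tabulate(g + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  denom[denom < 1e-12] <- NA
  sigma_b <- (mu_t * omega - mu)^2 / denom
  which.max(sigma_b) - 1L
}

#' Connected-component (fractal) filter for one patch
#'
#' Binarizes the patch (foreground = pixels darker than the threshold),
#' counts foreground connected components, and accepts the patch when the
#' count reaches `min_components`.  Tiles with few components are either
#' empty background or large undifferentiated structures.
#' @param patch H x W x 3 RGB array (0-255).
#' @param cfg a `filter_config`.
#' @return list with `accept`, `component_count`, `threshold`, `reason`.
#' @export
filter_fractal <- function(patch, cfg = filter_config()) {
  check_rgb(patch)
  gray <- rgb_to_luma(patch)
  thr <- if (identical(cfg$binarization_method, "otsu")) otsu_threshold(gray)
         else as.numeric(sub("^fixed:", "", cfg$binarization_method))
  fg <- gray <= thr
  cnt <- if (!any(fg)) 0L else max(label_components(fg, cfg$connectivity))
  accept <- cnt >= cfg$min_components
  list(accept = accept, component_count = cnt, threshold = thr,
       reason = if (accept) NA_character_ else "too_few_components")
}

#' Extract accepted tissue patches from a large image
#'
#' Pipeline of [tile_image()], [filter_background()] and
#' [filter_fractal()].  The returned manifest keeps every tile with its
#' rejection reason and component count.
#' @param image H x W x 3 RGB array.
#' @param patch_size patch side in pixels.
#' @param cfg a `filter_config`.
#' @return list with `patches` (list of `patch_record`s carrying tile
#'   coordinates) and `manifest` (the annotated `tile_grid` plus
#'   `component_count` and `bright_fraction` columns).
#' @export
extract_patches <- function(image, patch_size = 512L, cfg = filter_config()) {
  grid <- tile_image(image, patch_size)
  p <- attr(grid, "patch_size")
  grid$bright_fraction <- NA_real_
  grid$component_count <- NA_integer_
  patches <- list()
  for (i in seq_len(nrow(grid))) {
    rows <- grid$row_off[i] + seq_len(p)
    cols <- grid$col_off[i] + seq_len(p)
    tile <- image[rows, cols, , drop = FALSE]
    bg <- filter_background(tile, cfg)
    grid$bright_fraction[i] <- bg$bright_fraction
    if (!bg$accept) {
      grid$accepted[i] <- FALSE
      grid$rejection_reason[i] <- bg$reason
      next
    }
    fr <- filter_fractal(tile, cfg)
    grid$component_count[i] <- fr$component_count
    if (!fr$accept) {
      grid$accepted[i] <- FALSE
      grid$rejection_reason[i] <- fr$reason
      next
    }
    rec <- structure(list(image = tile, nuclei = NULL, params = NULL,
                          seed = NA_integer_,
                          tile = c(row = grid$row_index[i],
                                   col = grid$col_index[i])),
                     class = "patch_record")
    patches[[length(patches) + 1L]] <- rec
  }
  list(patches = patches, manifest = grid)
}
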