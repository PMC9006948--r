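# GradCAM attention analysis: class activation maps from gradients at
# the final convolutional layer, thresholded high-attention masks,
# bounding boxes, and overlap quantification between models (IoU of box
# rasterizations, Jaccard of pixel masks).

#' Gradient-weighted class activation map
#'
#' Gradients of the target-class logit with respect to the named
#' convolutional activation are averaged over space into channel
#' weights; the weighted activation sum is rectified, bilinearly
#' upsampled to patch resolution, and min-max normalized to [0, 1]
#' (an all-zero map stays all-zero).
#'
#' @param model a `patch_classifier`.
#' @param patch H x W x 3 image (0-255) or `patch_record`.
#' @param target_class `"cancer"` (default), `"normal"`, or index 0/1.
#' @param layer activation layer name; default the model's registered CAM
#'   layer (its final convolutional stage).
#' @return H x W matrix in [0, 1].
#' @export
gradcam <- function(model, patch, target_class = "cancer", layer = NULL) {
  stopifnot(inherits(model, "patch_classifier"))
  net <- model$net
  if (is.null(layer)) layer <- net$cam_layer
  if (!layer %in% layer_names(net))
    stop("unknown layer \"", layer, "\"; available layers: ",
         paste(layer_names(net), collapse = ", "))
  k <- if (is.character(target_class))
    match.arg(target_class, c("normal", "cancer")) == "cancer"
  else as.logical(target_class)
  x <- as_image_batch(patch, model$norm_stats)
  fw <- nn_forward(net, x, train = FALSE, want_cache = TRUE, collect = layer)
  act <- fw$collected[[layer]]            # (h, w, C, 1)
  dlog <- matrix(c(if (k) c(0, 1) else c(1, 0)), 2L, 1L)
  bk <- nn_backward(net, fw$caches, dlog, upto = layer)
  grad <- bk$d_out                        # same shape as act
  alpha <- apply(grad[, , , 1, drop = FALSE], 3, mean)
  cam <- matrix(0, dim(act)[1], dim(act)[2])
  for (c in seq_along(alpha)) cam <- cam + alpha[c] * act[, , c, 1]
  cam <- pmax(cam, 0)
  d <- dim(x)
  cam <- resize_bilinear(cam, d[1], d[2])
  cam <- pmax(cam, 0)                     # bilinear keeps >= 0; be explicit
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  cam
}

#' Threshold a CAM into a high-attention mask
#'
#' Mode `"value"` thresholds the normalized map directly (default
#' t = 0.6).  Mode `"quantile"` keeps the top `1 - quantile` fraction of
#' pixels, giving every mask the same pixel coverage — the convention
#' used when masks from different models are compared, since per-patch
#' min-max normalization makes value-thresholded mask sizes reflect CAM
#' flatness rather than attention placement.  Mode `"hsv"` mirrors the
#' colormap route: the map is rendered through a colormap, converted to
#' hue/saturation/value, and pixels whose hue falls in the configured
#' high-attention band are kept.
#'
#' @param cam H x W matrix in [0, 1].
#' @param mode `"value"`, `"quantile"` or `"hsv"`.
#' @param threshold value-mode cutoff.
#' @param quantile quantile-mode coverage cutoff (default 0.7: top 30%
#'   of pixels).
#' @param colormap function mapping values in [0, 1] to an n x 3 RGB
#'   matrix (0-255); default ramps blue (no attention) through red
#'   (moderate) to green (high).
#' @param hue_band high-attention hue interval in degrees.
#' @return logical H x W mask.
#' @export
threshold_high_attention <- function(cam, mode = c("value", "quantile", "hsv"),
                                     threshold = 0.6,
                                     quantile = 0.7,
                                     colormap = NULL,
                                     hue_band = c(80, 160)) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(cam), min(cam) >= 0, max(cam) <= 1)
  if (mode == "value") return(cam >= threshold)
  if (mode == "quantile") {
    if (max(cam) == 0) return(cam > 0)   # no attention anywhere
    return(cam >= stats::quantile(cam, quantile))
  }
  if (hue_band[2] <= hue_band[1]) stop("empty hue band")
  if (is.null(colormap))
    colormap <- function(v) grDevices::colorRamp(c("blue", "red", "green"))(v)
  rgb <- colormap(as.vector(cam))
  hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 255)
  hue <- hsv[1, ] * 360
  # keep saturated, bright pixels in the hue band (greys have no hue)
  keep <- hue >= hue_band[1] & hue <= hue_band[2] & hsv[2, ] > 0.2
  matrix(keep, nrow(cam), ncol(cam))
}

#' Bounding boxes of a binary mask
#'
#' Extracts mask boundaries (pixels with a 4-neighbor outside the mask),
#' traces their connected contours, and returns the tight axis-aligned
#' bounding rectangle of each contour, deduplicating boxes nested inside
#' another.  Coordinates are 0-based, half-open `[min, max)`.
#'
#' @param mask logical matrix.
#' @return integer matrix with columns `row_min`, `col_min`, `row_max`,
#'   `col_max` (possibly 0 rows).
#' @export
boxes_from_mask <- function(mask) {
  mask <- mask != 0
  empty <- matrix(integer(0), 0, 4,
                  dimnames = list(NULL, c("row_min", "col_min",
                                          "row_max", "col_max")))
  if (!any(mask)) return(empty)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  interior <- pad[2:(nr + 1), 2:(nc + 1)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  edge <- mask & !interior
  lab <- label_components(edge, 8L)
  n <- max(lab)
  boxes <- matrix(0L, n, 4,
                  dimnames = list(NULL, c("row_min", "col_min",
                                          "row_max", "col_max")))
  for (k in seq_len(n)) {
    px <- which(lab == k, arr.ind = TRUE)
    boxes[k, ] <- c(min(px[, 1]) - 1L, min(px[, 2]) - 1L,
                    max(px[, 1]), max(px[, 2]))
  }
  # drop boxes nested inside (or equal to) an earlier/larger box
  if (n > 1L) {
    area <- (boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2])
    ord <- order(-area)
    keep <- rep(TRUE, n)
    for (ii in seq_len(n)) for (jj in seq_len(n)) {
      a <- ord[ii]; b <- ord[jj]
      if (a == b || !keep[b] || !keep[a] || ii > jj) next
      if (boxes[b, 1] >= boxes[a, 1] && boxes[b, 2] >= boxes[a, 2] &&
          boxes[b, 3] <= boxes[a, 3] && boxes[b, 4] <= boxes[a, 4])
        keep[b] <- FALSE
    }
    boxes <- boxes[keep, , drop = FALSE]
  }
  boxes
}

#' IoU of two box sets
#'
#' Each box set is rasterized to the union of its rectangles on a common
#' pixel grid; IoU is intersection over union of the two rasterizations,
#' which reduces to the usual single-box IoU for one box per side.
#' Zero-area boxes are dropped with a warning; two empty sets give 0 with
#' a warning.
#'
#' @param boxes_a,boxes_b matrices with columns row_min, col_min,
#'   row_max, col_max (0-based, half-open).
#' @return IoU in [0, 1].
#' @export
iou_boxes <- function(boxes_a, boxes_b) {
  clean <- function(b) {
    b <- rbind(b)
    if (!nrow(b)) return(b)
    ok <- b[, 3] > b[, 1] & b[, 4] > b[, 2]
    if (!all(ok)) warning("dropping ", sum(!ok), " zero-area box(es)")
    b[ok, , drop = FALSE]
  }
  a <- clean(boxes_a); b <- clean(boxes_b)
  if (!nrow(a) && !nrow(b)) {
    warning("both box sets empty; IoU defined as 0")
    return(0)
  }
  all_ <- rbind(a, b)
  r0 <- min(all_[, 1]); c0 <- min(all_[, 2])
  r1 <- max(all_[, 3]); c1 <- max(all_[, 4])
  rast <- function(bx) {
    m <- matrix(FALSE, r1 - r0, c1 - c0)
    for (k in seq_len(nrow(bx)))
      m[(bx[k, 1] - r0 + 1):(bx[k, 3] - r0),
        (bx[k, 2] - c0 + 1):(bx[k, 4] - c0)] <- TRUE
    m
  }
  A <- rast(a); B <- rast(b)
  inter <- sum(A & B); uni <- sum(A | B)
  if (uni == 0) 0 else inter / uni
}

#' Jaccard index of two pixel masks
#' @param mask_a,mask_b logical matrices of the same shape.
#' @return |A intersect B| / |A union B|; 0 with a warning when both are
#'   empty.
#' @export
jaccard_masks <- function(mask_a, mask_b) {
  stopifnot(all(dim(mask_a) == dim(mask_b)))
  a <- mask_a != 0; b <- mask_b != 0
  uni <- sum(a | b)
  if (uni == 0) {
    warning("both masks empty; Jaccard defined as 0")
    return(0)
  }
  sum(a & b) / uni
}

#' Partition two attention masks into overlap and specific regions
#'
#' Overlap = A AND B; A-specific = A minus overlap; B-specific = B minus
#' overlap.  The three masks are pairwise disjoint, and overlap together
#' with each specific mask reconstructs the corresponding input.
#'
#' @param mask_a,mask_b logical matrices of the same shape.
#' @return list with `overlap`, `a_specific`, `b_specific`.
#' @export
partition_regions <- function(mask_a, mask_b) {
  stopifnot(all(dim(mask_a) == dim(mask_b)))
  a <- mask_a != 0; b <- mask_b != 0
  ov <- a & b
  list(overlap = ov, a_specific = a & !ov, b_specific = b & !ov)
}

#' Attention-overlap report for a model pair
#'
#' Restricts to high-confidence cancer patches — those the organ's own
#' model assigns cancer probability above `cancer_prob_min` — then
#' computes, per patch, the GradCAM masks of both models for the cancer
#' class, their bounding-box IoU and pixel Jaccard index.
#'
#' @param model_a,model_b `patch_classifier`s of the two organs compared.
#' @param patches patches from one organ (list or `patch_dataset`; for a
#'   dataset, its cancer-class test patches are used).
#' @param own_model the model trained on the patches' organ, used for the
#'   probability gate; defaults to `model_b`.
#' @param cancer_prob_min gate on the own-model cancer probability
#'   (default 0.98).
#' @param threshold,mode forwarded to [threshold_high_attention()].
#' @return an object of class `overlap_report`: data.frame `scores`
#'   (patch_id, iou_boxes, jaccard_pixels), means, and the model pair.
#' @export
overlap_report <- function(model_a, model_b, patches, own_model = model_b,
                           cancer_prob_min = 0.98, threshold = 0.6,
                           mode = "value") {
  if (inherits(patches, "patch_dataset")) {
    idx <- which(patches$meta$class == "cancer" & patches$meta$split == "test")
    ids <- patches$meta$id[idx]
    patches <- patches$records[idx]
  } else ids <- sprintf("patch_%03d", seq_along(patches))
  pair <- c(model_a$organ, model_b$organ)
  if (!length(patches)) {
    warning("no patches supplied")
    return(.empty_overlap_report(pair))
  }
  prob <- predict(own_model, patches, type = "prob")[, "cancer"]
  qual <- which(prob > cancer_prob_min)
  if (!length(qual)) {
    warning("no patches pass the cancer probability gate (",
            cancer_prob_min, ")")
    return(.empty_overlap_report(pair))
  }
  scores <- data.frame(patch_id = ids[qual], iou_boxes = NA_real_,
                       jaccard_pixels = NA_real_)
  for (s in seq_along(qual)) {
    p <- patches[[qual[s]]]
    cam_a <- gradcam(model_a, p, "cancer")
    cam_b <- gradcam(model_b, p, "cancer")
    ma <- threshold_high_attention(cam_a, mode, threshold)
    mb <- threshold_high_attention(cam_b, mode, threshold)
    scores$iou_boxes[s] <- suppressWarnings(
      iou_boxes(boxes_from_mask(ma), boxes_from_mask(mb)))
    scores$jaccard_pixels[s] <- suppressWarnings(jaccard_masks(ma, mb))
  }
  structure(list(model_pair = pair, scores = scores,
                 mean_iou = mean(scores$iou_boxes),
                 mean_jaccard = mean(scores$jaccard_pixels),
                 n_qualifying = length(qual), n_total = length(patches),
                 cancer_prob_min = cancer_prob_min),
            class = "overlap_report")
}

.empty_overlap_report <- function(pair) {
  structure(list(model_pair = pair,
                 scores = data.frame(patch_id = character(0),
                                     iou_boxes = numeric(0),
                                     jaccard_pixels = numeric(0)),
                 mean_iou = NA_real_, mean_jaccard = NA_real_,
                 n_qualifying = 0L, n_total = 0L,
                 cancer_prob_min = NA_real_),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Attention overlap %s vs %s: %d/%d qualifying patches\n",
              x$model_pair[1], x$model_pair[2], x$n_qualifying, x$n_total))
  if (x$n_qualifying > 0)
    cat(sprintf("  mean box IoU %.3f | mean pixel Jaccard %.3f\n",
                x$mean_iou, x$mean_jaccard))
  invisible(x)
}

#' Four-panel attention visualization
#'
#' Input patch, CAM heatmap, thresholded mask, and the patch with
#' bounding boxes.
#' @param patch H x W x 3 image (0-255) or `patch_record`.
#' @param cam H x W CAM matrix.
#' @param mask logical mask.
#' @param boxes box matrix from [boxes_from_mask()].
#' @export
plot_attention <- function(patch, cam, mask, boxes = boxes_from_mask(mask)) {
  img <- if (inherits(patch, "patch_record")) patch$image else patch
  op <- graphics::par(mfrow = c(1, 4), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  show <- function(m, main, col = grDevices::gray.colors(64, 0, 1)) {
    graphics::image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE,
                    main = main, col = col, useRaster = TRUE)
  }
  lum <- rgb_to_luma(img)
  show(lum / 255, "patch")
  show(cam, "GradCAM", col = grDevices::hcl.colors(64, "Viridis"))
  show(mask * 1, "high attention")
  show(lum / 255, "boxes")
  if (nrow(boxes)) {
    nr <- nrow(lum); nc <- ncol(lum)
    for (k in seq_len(nrow(boxes))) {
      # image() maps the matrix to [0,1] x [0,1]
      x0 <- boxes[k, 2] / nc; x1 <- boxes[k, 4] / nc
      y0 <- 1 - boxes[k, 3] / nr; y1 <- 1 - boxes[k, 1] / nr
      graphics::rect(x0, y0, x1, y1, border = "red", lwd = 2)
    }
  }
  invisible(NULL)
}
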