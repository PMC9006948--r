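# Nucleus segmentation inside attention regions and the shape /
# inter-nucleus density features computed from the labelled components.

#' Multilevel Otsu thresholds
#'
#' Exhaustive search for the `levels - 1` thresholds that maximize the
#' between-class variance of the grayscale histogram (256 bins).
#' @param gray numeric matrix on the 0-255 scale.
#' @param levels number of classes (2 or 3).
#' @return increasing numeric vector of thresholds.
#' @export
multilevel_otsu <- function(gray, levels = 3L) {
  stopifnot(levels %in% c(2L, 3L))
  g <- clamp(round(as.vector(gray)), 0, 255)
  h <- tabulate(g + 1L, nbins = 256L)
  p <- h / sum(h)
  cs <- cumsum(p)
  cm <- cumsum(p * (0:255))
  if (levels == 2L) return(otsu_threshold(gray))
  # exhaustive (t1, t2) search, vectorized over t2 for each t1; the
  # criterion sum_k m_k^2 / w_k is equivalent to maximizing the
  # between-class variance
  mT <- cm[256]
  best <- -Inf; bt <- c(85, 170)
  for (t1 in 0:253) {
    w1 <- cs[t1 + 1L]
    if (w1 < 1e-12) next
    m1 <- cm[t1 + 1L]
    t2 <- (t1 + 1L):254
    w2 <- cs[t2 + 1L] - w1
    w3 <- 1 - cs[t2 + 1L]
    m2 <- cm[t2 + 1L] - m1
    m3 <- mT - cm[t2 + 1L]
    ok <- w2 > 1e-12 & w3 > 1e-12
    if (!any(ok)) next
    v <- rep(-Inf, length(t2))
    v[ok] <- m1^2 / w1 + m2[ok]^2 / w2[ok] + m3[ok]^2 / w3[ok]
    j <- which.max(v)
    if (v[j] > best) { best <- v[j]; bt <- c(t1, t2[j]) }
  }
  bt
}

#' Segment nuclei inside a region mask
#'
#' Grayscale conversion, 3-class multilevel thresholding (darkest class =
#' candidate nuclei), one guarded recursive re-threshold within the
#' candidates to split clumps when their intensities are strongly
#' bimodal, then 8-connected labelling restricted to `region_mask` with
#' small components discarded.
#'
#' @param patch H x W x 3 RGB image (0-255) or `patch_record`.
#' @param region_mask logical matrix (NULL = whole patch).
#' @param levels thresholding classes (default 3).
#' @param min_area minimum nucleus area in pixels (default 15).
#' @param refine_eta bimodality gate for the recursive pass: re-threshold
#'   only when the within-candidate Otsu split explains at least this
#'   fraction of the intensity variance (default 0.75).
#' @return an object of class `nucleus_segmentation`: `label_grid`
#'   (0 = background), `n_nuclei`, `region_mask`, `thresholds`.
#' @export
segment_nuclei <- function(patch, region_mask = NULL, levels = 3L,
                           min_area = 15L, refine_eta = 0.75) {
  img <- if (inherits(patch, "patch_record")) patch$image else patch
  check_rgb(img)
  gray <- rgb_to_luma(img)
  if (is.null(region_mask)) region_mask <- matrix(TRUE, nrow(gray), ncol(gray))
  stopifnot(all(dim(region_mask) == dim(gray)))
  region_mask <- region_mask != 0
  out <- function(lab) structure(
    list(label_grid = lab, n_nuclei = max(lab), region_mask = region_mask),
    class = "nucleus_segmentation")
  if (!any(region_mask))
    return(out(matrix(0L, nrow(gray), ncol(gray))))
  vals <- gray[region_mask]
  if (length(vals) < 2L || stats::sd(vals) < 1e-9)  # degenerate region
    return(out(matrix(0L, nrow(gray), ncol(gray))))
  thr <- multilevel_otsu(gray[region_mask], levels)
  cand <- gray <= thr[1] & region_mask
  if (any(cand)) {
    cv <- gray[cand]
    if (length(unique(round(cv))) > 2L) {
      t2 <- otsu_threshold(cv)
      lo <- cv[cv <= t2]; hi <- cv[cv > t2]
      if (length(lo) >= min_area && length(hi) > 0) {
        eta <- 1 - (sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) /
          sum((cv - mean(cv))^2)
        if (eta >= refine_eta) cand <- cand & gray <= t2
      }
    }
  }
  lab <- label_components(cand, 8L)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_area)
    lab[!(lab %in% keep)] <- 0L
    lab[lab > 0L] <- match(lab[lab > 0L], keep)
  }
  seg <- out(lab)
  seg$thresholds <- thr
  seg
}

#' @export
print.nucleus_segmentation <- function(x, ...) {
  cat("Nucleus segmentation:", x$n_nuclei, "nuclei inside",
      sum(x$region_mask), "region pixels\n")
  invisible(x)
}

# ---- per-component geometry ----------------------------------------------

# Contour length of one component: the closed polygon through its
# 8-connected boundary pixel centers (axial step 1, diagonal sqrt(2)).
# Exact for axis-aligned rectangles (4 * (side - 1) for a square of
# `side` pixels); within ~5% of the continuous perimeter for smooth
# shapes.  A lone pixel counts its unit-square boundary, 4.
.trace_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  sum(vapply(oc, function(pts) {
    if (nrow(pts) < 2L) return(4)
    sum(sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2)))
  }, numeric(1)))
}

# Convex hull area over pixel corner points (shoelace).  Using corners
# rather than centers guarantees hull area >= pixel count, so solidity
# stays in (0, 1].
.convex_area <- function(px) {
  pts <- rbind(cbind(px[, 1] - 0.5, px[, 2] - 0.5),
               cbind(px[, 1] - 0.5, px[, 2] + 0.5),
               cbind(px[, 1] + 0.5, px[, 2] - 0.5),
               cbind(px[, 1] + 0.5, px[, 2] + 0.5))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3L) return(nrow(px))
  i2 <- c(2:n, 1)
  abs(sum(hp[, 1] * hp[i2, 2] - hp[i2, 1] * hp[, 2])) / 2
}

# Measurements for one labelled component.
.component_features <- function(lab, k) {
  mask <- lab == k
  px <- which(mask, arr.ind = TRUE)
  area <- nrow(px)
  y <- px[, 1]; x <- px[, 2]
  cy <- mean(y); cx <- mean(x)
  # second central moments with the 1/12 pixel-variance correction
  mu20 <- mean((x - cx)^2) + 1 / 12
  mu02 <- mean((y - cy)^2) + 1 / 12
  mu11 <- mean((x - cx) * (y - cy))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- max((mu20 + mu02 - common) / 2, 1e-12)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- sqrt(pmax(1 - l2 / l1, 0))
  # orientation of the major axis, degrees in [-90, 90)
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (ang >= 90) ang <- ang - 180
  if (ang < -90) ang <- ang + 180
  bbox_area <- (max(y) - min(y) + 1) * (max(x) - min(x) + 1)
  conv <- .convex_area(px)
  per <- .trace_perimeter(mask)
  filled <- sum(EBImage::imageData(EBImage::fillHull(
    EBImage::Image(mask * 1))) > 0)
  list(area = area, convex_area = conv, perimeter = per,
       filled_area = filled, major_axis = major, minor_axis = minor,
       eccentricity = ecc, angle = ang,
       extent = area / bbox_area,
       solidity = min(area / conv, 1),
       peri_by_area = per / area,
       equiv_diameter = 2 * sqrt(area / pi),
       centroid = c(row = cy, col = cx))
}

#' Canonical nucleus feature names
#'
#' The 18 shape features and 3 density features in their reporting order,
#' mapping internal column ids to display labels.
#' @return named character vector (names = column ids).
#' @export
nucleus_feature_names <- function() {
  c(total_area = "Total area",
    total_convex_area = "Total convex area",
    total_perimeter = "Total perimeter",
    total_filled_area = "Total filled area",
    total_major_axis = "Total major axis",
    total_minor_axis = "Total minor axis",
    total_peri_by_area = "Total peri by area",
    main_region_area = "Main region area",
    main_region_convex_area = "Main region convex area",
    main_region_eccentricity = "Main region eccentricity",
    main_extent = "Main extent",
    main_region_solidity = "Main region solidity",
    main_region_perimeter = "Main region perimeter",
    main_region_angle = "Main region angle",
    main_region_peri_by_area = "Main region peri by area",
    main_region_major_axis = "Main region major axis",
    main_region_minor_axis = "Main region minor axis",
    total_diameter = "Total diameter",
    neighbor_count_10px = "Neighbor count within a 10-pixel radius",
    neighbor_count_20px = "Neighbor count within a 20-pixel radius",
    neighbor_count_30px = "Neighbor count within a 30-pixel radius")
}

#' Shape features of a segmented region
#'
#' Per-nucleus measurements aggregated to one row: "total" features sum
#' over all nuclei in the region, "main region" features describe the
#' largest-area nucleus.
#'
#' @param seg a `nucleus_segmentation`.
#' @param region_kind label stored with the row ("total", "overlap",
#'   "specific", ...).
#' @return one-row data.frame with the 18 shape feature columns plus
#'   `n_nuclei` and `region_kind`; all-NA feature values when the region
#'   holds no nuclei.
#' @export
shape_features <- function(seg, region_kind = "total") {
  stopifnot(inherits(seg, "nucleus_segmentation"))
  ids <- names(nucleus_feature_names())[1:18]
  row <- as.data.frame(stats::setNames(as.list(rep(NA_real_, 18)), ids))
  row$n_nuclei <- seg$n_nuclei
  row$region_kind <- region_kind
  if (seg$n_nuclei == 0L) return(row)
  feats <- lapply(seq_len(seg$n_nuclei), .component_features,
                  lab = seg$label_grid)
  g <- function(f) vapply(feats, `[[`, numeric(1), f)
  main <- which.max(g("area"))
  row$total_area <- sum(g("area"))
  row$total_convex_area <- sum(g("convex_area"))
  row$total_perimeter <- sum(g("perimeter"))
  row$total_filled_area <- sum(g("filled_area"))
  row$total_major_axis <- sum(g("major_axis"))
  row$total_minor_axis <- sum(g("minor_axis"))
  row$total_peri_by_area <- sum(g("peri_by_area"))
  row$total_diameter <- sum(g("equiv_diameter"))
  row$main_region_area <- feats[[main]]$area
  row$main_region_convex_area <- feats[[main]]$convex_area
  row$main_region_eccentricity <- feats[[main]]$eccentricity
  row$main_extent <- feats[[main]]$extent
  row$main_region_solidity <- feats[[main]]$solidity
  row$main_region_perimeter <- feats[[main]]$perimeter
  row$main_region_angle <- feats[[main]]$angle
  row$main_region_peri_by_area <- feats[[main]]$peri_by_area
  row$main_region_major_axis <- feats[[main]]$major_axis
  row$main_region_minor_axis <- feats[[main]]$minor_axis
  row
}

#' Nucleus centroids of a segmentation
#' @param seg a `nucleus_segmentation`.
#' @return n x 2 matrix (row, col), one row per nucleus.
#' @export
nucleus_centroids <- function(seg) {
  stopifnot(inherits(seg, "nucleus_segmentation"))
  if (seg$n_nuclei == 0L) return(matrix(numeric(0), 0, 2,
                                        dimnames = list(NULL, c("row", "col"))))
  t(vapply(seq_len(seg$n_nuclei), function(k) {
    px <- which(seg$label_grid == k, arr.ind = TRUE)
    c(row = mean(px[, 1]), col = mean(px[, 2]))
  }, numeric(2)))
}

#' Inter-nucleus density and architecture features
#'
#' Per-nucleus neighbor counts within the given radii (region value =
#' mean over nuclei), discrete Voronoi cell areas clipped to the region
#' bounding box, Delaunay-graph edge statistics (adjacency read off the
#' Voronoi partition), and the total/mean edge length of the minimum
#' spanning tree over centroids.
#'
#' @param seg a `nucleus_segmentation`, or an n x 2 centroid matrix.
#' @param radii neighbor radii in pixels.
#' @return list with `neighbor_counts` (per-nucleus matrix),
#'   `neighbor_means` (named per-radius means), `voronoi_areas`,
#'   `delaunay` (edge data.frame + length stats), `mst_total`,
#'   `mst_mean`; graph entries NA with fewer than 2 nuclei.
#' @export
density_features <- function(seg, radii = c(10, 20, 30)) {
  if (inherits(seg, "nucleus_segmentation")) {
    cent <- nucleus_centroids(seg)
    bbox <- if (any(seg$region_mask)) {
      px <- which(seg$region_mask, arr.ind = TRUE)
      c(min(px[, 1]), min(px[, 2]), max(px[, 1]), max(px[, 2]))
    } else NULL
  } else {
    cent <- as.matrix(seg)
    bbox <- NULL
  }
  n <- nrow(cent)
  means <- stats::setNames(rep(0, length(radii)),
                           paste0("neighbor_count_", radii, "px"))
  if (n == 0L)
    return(list(neighbor_counts = matrix(0, 0, length(radii)),
                neighbor_means = means, voronoi_areas = numeric(0),
                delaunay = NULL, mst_total = NA_real_, mst_mean = NA_real_))
  D <- as.matrix(stats::dist(cent))
  counts <- vapply(radii, function(r) colSums(D <= r) - 1L,
                   numeric(n))
  counts <- matrix(counts, n, length(radii),
                   dimnames = list(NULL, names(means)))
  means[] <- colMeans(counts)
  if (n < 2L)
    return(list(neighbor_counts = counts, neighbor_means = means,
                voronoi_areas = NA_real_, delaunay = NULL,
                mst_total = NA_real_, mst_mean = NA_real_))
  if (is.null(bbox))
    bbox <- c(floor(min(cent[, 1])) - 1, floor(min(cent[, 2])) - 1,
              ceiling(max(cent[, 1])) + 1, ceiling(max(cent[, 2])) + 1)
  # discrete Voronoi assignment over the region bounding box
  rows <- bbox[1]:bbox[3]; cols <- bbox[2]:bbox[4]
  gr <- expand.grid(row = rows, col = cols)
  d2 <- outer(gr$row, cent[, 1], "-")^2 + outer(gr$col, cent[, 2], "-")^2
  assign <- max.col(-d2, ties.method = "first")
  vor_areas <- tabulate(assign, nbins = n)
  amat <- matrix(assign, length(rows), length(cols))
  # Delaunay edges = Voronoi cells sharing a boundary (4-adjacent pixels)
  pair_h <- cbind(as.vector(amat[-nrow(amat), ]), as.vector(amat[-1, ]))
  pair_v <- cbind(as.vector(amat[, -ncol(amat)]), as.vector(amat[, -1]))
  pairs <- rbind(pair_h, pair_v)
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- unique(t(apply(pairs, 1, sort)))
  del <- if (nrow(pairs)) {
    len <- D[pairs]
    data.frame(from = pairs[, 1], to = pairs[, 2], length = len)
  } else NULL
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g)
  mst_len <- igraph::E(mst)$weight
  list(neighbor_counts = counts, neighbor_means = means,
       voronoi_areas = vor_areas, delaunay = del,
       delaunay_mean_edge = if (is.null(del)) NA_real_ else mean(del$length),
       mst_total = sum(mst_len), mst_mean = mean(mst_len))
}

#' Nucleus features for the regions defined by two attention masks
#'
#' Partitions the two masks into overlap and model-specific regions,
#' segments nuclei in each region (and in each model's full mask), and
#' emits one feature row per region combining the 18 shape features with
#' the 3 neighbor-count density features.
#'
#' @param patch H x W x 3 image or `patch_record`.
#' @param mask_a,mask_b high-attention masks of the two models.
#' @param patch_id identifier recorded in the rows.
#' @param include_totals also emit each model's full-mask ("a_total",
#'   "b_total") rows (default TRUE; these are the distributions compared
#'   between models).
#' @param min_area forwarded to [segment_nuclei()].
#' @return data.frame of feature rows, one per region kind.
#' @export
region_feature_pipeline <- function(patch, mask_a, mask_b,
                                    patch_id = "patch", include_totals = TRUE,
                                    min_area = 15L) {
  parts <- partition_regions(mask_a, mask_b)
  regions <- list(overlap = parts$overlap,
                  a_specific = parts$a_specific,
                  b_specific = parts$b_specific)
  if (include_totals)
    regions <- c(list(a_total = mask_a != 0, b_total = mask_b != 0), regions)
  rows <- NULL
  for (kind in names(regions)) {
    seg <- segment_nuclei(patch, regions[[kind]], min_area = min_area)
    row <- shape_features(seg, region_kind = kind)
    dens <- density_features(seg)
    for (nm in names(dens$neighbor_means))
      row[[nm]] <- if (seg$n_nuclei > 0) dens$neighbor_means[[nm]] else NA_real_
    row$patch_id <- patch_id
    rows <- rbind(rows, row)
  }
  rows
}
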