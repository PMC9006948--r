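# Nucleus segmentation against generator ground truth, shape features
# against analytic values, density/architecture features against
# exhaustive oracles.

label_from_mask <- function(mask) {
  structure(list(label_grid = matrix(as.integer(mask), nrow(mask)),
                 n_nuclei = 1L,
                 region_mask = matrix(TRUE, nrow(mask), ncol(mask))),
            class = "nucleus_segmentation")
}

test_that("multilevel thresholds recover a trimodal intensity mixture", {
  set.seed(71)
  gray <- c(stats::rnorm(2000, 40, 5), stats::rnorm(2000, 130, 5),
            stats::rnorm(2000, 210, 5))
  thr <- multilevel_otsu(matrix(gray, 60), 3)
  # boundaries fall in the inter-mode gaps (ties broken to the gap's
  # left edge, just above the lower mode's tail)
  expect_gt(thr[1], 45); expect_lt(thr[1], 125)
  expect_gt(thr[2], 135); expect_lt(thr[2], 205)
})

test_that("segmentation finds constructed nuclei and respects the mask", {
  expect_equal(segment_nuclei(flat_patch(64, 180))$n_nuclei, 0)

  p <- morphology_params(noise_sd = 0, brightness_sd = 0)
  centers <- expand.grid(cy = c(10, 30, 50), cx = c(10, 30, 50))[1:8, ]
  nuc <- data.frame(cx = centers$cx, cy = centers$cy, a = 4, b = 4, angle = 0)
  rec <- generate_patch(p, 64, seed = 1, nuclei = nuc)
  seg <- segment_nuclei(rec)
  expect_equal(seg$n_nuclei, 8)
  # each component's pixel count within 10% of the rasterized disk
  for (k in seq_len(8)) {
    area <- sum(seg$label_grid == k)
    expect_lt(abs(area - pi * 16) / (pi * 16), 0.1)
  }

  half <- matrix(FALSE, 64, 64)
  half[, 1:20] <- TRUE   # covers the three nuclei at cx = 10
  seg3 <- segment_nuclei(rec, half)
  expect_equal(seg3$n_nuclei, 3)
  expect_true(all(seg3$label_grid[!half] == 0))
  expect_equal(sum(tabulate(seg3$label_grid[seg3$label_grid > 0])),
               sum(seg3$label_grid > 0))
})

test_that("segmentation recovers generator nuclei with high fidelity", {
  p <- morphology_params(nucleus_density = 8, noise_sd = 0, brightness_sd = 0,
                         radius_mean = 3.5, radius_sd = 0.3)
  hits <- 0; total_true <- 0; total_found <- 0
  for (s in 1:60) {
    if (total_true >= 30) break
    rec <- generate_patch(p, 64, seed = 800 + s)
    # keep only patches whose nuclei do not overlap
    if (nrow(rec$nuclei) < 2) next
    d <- as.matrix(stats::dist(rec$nuclei[, c("cx", "cy")]))
    diag(d) <- Inf
    if (min(d) < 12) next
    seg <- segment_nuclei(rec)
    cent <- nucleus_centroids(seg)
    total_true <- total_true + nrow(rec$nuclei)
    total_found <- total_found + seg$n_nuclei
    for (k in seq_len(nrow(rec$nuclei))) {
      dd <- sqrt((cent[, "col"] - rec$nuclei$cx[k])^2 +
                   (cent[, "row"] - rec$nuclei$cy[k])^2)
      if (length(dd) && min(dd) < 3) hits <- hits + 1
    }
  }
  expect_gt(total_true, 10)
  expect_gte(hits / total_true, 0.9)          # recall
  expect_gte(hits / total_found, 0.9)         # precision
})

test_that("shape features match analytic values for square and ellipse", {
  sq <- matrix(FALSE, 30, 30); sq[10:19, 10:19] <- TRUE
  row <- shape_features(label_from_mask(sq))
  expect_equal(row$total_area, 100)
  expect_equal(row$main_extent, 1.0)
  expect_equal(row$main_region_solidity, 1.0)
  expect_equal(row$total_filled_area, 100)
  expect_equal(row$main_region_perimeter, 36)  # pixel-centre contour of side 10

  el <- outer(1:64, 1:64, function(i, j)
    ((i - 32) / 10)^2 + ((j - 32) / 20)^2 <= 1)
  re <- shape_features(label_from_mask(el))
  expect_lt(abs(re$main_region_major_axis - 40) / 40, 0.05)
  expect_lt(abs(re$main_region_minor_axis - 20) / 20, 0.05)
  expect_lt(abs(re$main_region_eccentricity - sqrt(1 - 0.25)), 0.05)
  expect_lt(abs(re$main_region_angle), 5)
  expect_lt(abs(re$total_area - pi * 200) / (pi * 200), 0.05)
  ram <- pi * (3 * 30 - sqrt((3 * 20 + 10) * (20 + 3 * 10)))
  expect_lt(abs(re$main_region_perimeter - ram) / ram, 0.05)
  expect_lt(abs(re$total_diameter - 2 * sqrt(re$total_area / pi)), 1e-9)

  empty <- structure(list(label_grid = matrix(0L, 10, 10), n_nuclei = 0L,
                          region_mask = matrix(TRUE, 10, 10)),
                     class = "nucleus_segmentation")
  row0 <- shape_features(empty)
  expect_true(all(is.na(row0[names(nucleus_feature_names())[1:18]])))
  expect_equal(row0$n_nuclei, 0L)
})

test_that("totals sum over nuclei and the main region is the largest", {
  lab <- matrix(0L, 40, 40)
  lab[5:14, 5:10] <- 1L    # area 60
  lab[25:32, 25:29] <- 2L  # area 40
  seg <- structure(list(label_grid = lab, n_nuclei = 2L,
                        region_mask = matrix(TRUE, 40, 40)),
                   class = "nucleus_segmentation")
  row <- shape_features(seg)
  expect_equal(row$total_area, 100)
  expect_equal(row$main_region_area, 60)
  expect_equal(row$n_nuclei, 2L)
})

test_that("shape measurements scale correctly with image size", {
  small <- outer(1:40, 1:40, function(i, j)
    ((i - 20) / 6)^2 + ((j - 20) / 10)^2 <= 1)
  big <- outer(1:80, 1:80, function(i, j)
    ((i - 40) / 12)^2 + ((j - 40) / 20)^2 <= 1)
  rs <- shape_features(label_from_mask(small))
  rb <- shape_features(label_from_mask(big))
  expect_lt(abs(rb$total_area / rs$total_area - 4), 4 * 0.05)
  expect_lt(abs(rb$main_region_major_axis / rs$main_region_major_axis - 2),
            2 * 0.05)
  expect_lt(abs(rb$main_region_perimeter / rs$main_region_perimeter - 2),
            2 * 0.05)
})

test_that("neighbor counts and graph features match exhaustive oracles", {
  one <- matrix(c(5, 5), 1, dimnames = list(NULL, c("row", "col")))
  d1 <- density_features(one)
  expect_true(all(d1$neighbor_means == 0))
  expect_true(is.na(d1$mst_total))

  tri <- cbind(row = c(0, 0, 0), col = c(0, 8, 16))
  dt <- density_features(tri, radii = c(10, 20))
  expect_equal(unname(dt$neighbor_counts[, 1]), c(1, 2, 1))
  expect_equal(unname(dt$neighbor_means[1]), 4 / 3)
  expect_equal(unname(dt$neighbor_counts[, 2]), c(2, 2, 2))

  square <- cbind(row = c(0, 0, 10, 10), col = c(0, 10, 0, 10))
  expect_equal(density_features(square)$mst_total, 30)
  expect_equal(density_features(square)$mst_total, brute_mst_weight(square))

  set.seed(81)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    pts <- cbind(row = stats::runif(n, 0, 50), col = stats::runif(n, 0, 50))
    df <- density_features(pts, radii = c(10, 25))
    # literal O(n^2) neighbor loop
    for (k in seq_len(n)) for (ri in 1:2) {
      r <- c(10, 25)[ri]
      cnt <- 0
      for (m in seq_len(n)) if (m != k &&
        sqrt(sum((pts[k, ] - pts[m, ])^2)) <= r) cnt <- cnt + 1
      expect_equal(unname(df$neighbor_counts[k, ri]), cnt)
    }
    expect_equal(df$mst_total, brute_mst_weight(pts), tolerance = 1e-9)
  }
})

test_that("voronoi and delaunay structures are consistent", {
  pts <- cbind(row = c(10, 10, 30), col = c(10, 30, 20))
  df <- density_features(pts)
  expect_length(df$voronoi_areas, 3)
  expect_true(all(df$voronoi_areas > 0))
  expect_equal(nrow(df$delaunay), 3)  # triangle: all three cells adjacent
})

test_that("the region pipeline emits rows per region kind as constructed", {
  p <- morphology_params(noise_sd = 0, brightness_sd = 0)
  nuc <- data.frame(cx = c(12, 52), cy = c(12, 52), a = 4, b = 4, angle = 0)
  rec <- generate_patch(p, 64, seed = 2, nuclei = nuc)
  left <- matrix(FALSE, 64, 64); left[1:24, 1:24] <- TRUE
  right <- matrix(FALSE, 64, 64); right[40:64, 40:64] <- TRUE

  rows <- region_feature_pipeline(rec, left, right, patch_id = "t1")
  get <- function(kind) rows[rows$region_kind == kind, ]
  expect_equal(get("overlap")$n_nuclei, 0L)
  expect_equal(get("a_specific")$n_nuclei, 1L)
  expect_equal(get("b_specific")$n_nuclei, 1L)

  same <- region_feature_pipeline(rec, left, left, patch_id = "t2")
  expect_equal(same[same$region_kind == "overlap", ]$n_nuclei, 1L)
  expect_equal(same[same$region_kind == "a_specific", ]$n_nuclei, 0L)
  expect_true(is.na(same[same$region_kind == "a_specific", ]$total_area))

  only_a <- region_feature_pipeline(rec, left, right & FALSE, patch_id = "t3")
  expect_gt(only_a[only_a$region_kind == "a_total", ]$n_nuclei, 0)
  expect_equal(only_a[only_a$region_kind == "b_total", ]$n_nuclei, 0L)
})
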