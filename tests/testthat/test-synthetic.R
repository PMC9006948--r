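# Synthetic patch generator: determinism, rendering geometry, split
# arithmetic, shared-morphology construction, pseudo-WSI composition.

test_that("patch generation is deterministic and respects the density limit", {
  p <- morphology_params()
  a <- generate_patch(p, 64, seed = 42)
  b <- generate_patch(p, 64, seed = 42)
  expect_identical(a$image, b$image)
  expect_identical(a$nuclei, b$nuclei)
  cc <- generate_patch(p, 64, seed = 43)
  expect_false(identical(a$image, cc$image))

  sparse <- morphology_params(nucleus_density = 1e-4)
  empty <- generate_patch(sparse, 128, seed = 1)
  expect_lte(nrow(empty$nuclei), 1)
})

test_that("a forced centered disk rasterizes to the expected pixel count", {
  p <- morphology_params(radius_mean = 10, radius_sd = 0,
                         eccentricity_mean = 0, noise_sd = 0,
                         brightness_sd = 0)
  rec <- generate_patch(p, 64, seed = 1,
                        nuclei = data.frame(cx = 32, cy = 32, a = 10, b = 10,
                                            angle = 0))
  nuc_col <- p$stain_palette$nucleus
  hit <- rec$image[, , 1] == nuc_col[1] & rec$image[, , 2] == nuc_col[2] &
    rec$image[, , 3] == nuc_col[3]
  expect_lt(abs(sum(hit) - pi * 100) / (pi * 100), 0.05)
})

test_that("patch size too small for the morphology is rejected", {
  p <- morphology_params(radius_mean = 40, radius_sd = 2)
  expect_error(generate_patch(p, 64), "radius_mean")
})

test_that("organ datasets split 70/20/10 per class with stratification", {
  base <- morphology_params()
  cancer <- morphology_params(nucleus_density = 30)
  sp100 <- organ_spec("X", cancer, base, n_patches_per_class = 100, seed = 3)
  ds <- generate_organ_dataset(sp100)
  tab <- table(ds$meta$class, ds$meta$split)
  for (cls in c("cancer", "normal")) {
    expect_equal(unname(tab[cls, "train"]), 70)
    expect_equal(unname(tab[cls, "val"]), 20)
    expect_equal(unname(tab[cls, "test"]), 10)
  }

  sp10 <- organ_spec("X", cancer, base, n_patches_per_class = 10, seed = 3)
  tab10 <- table(generate_organ_dataset(sp10)$meta$class,
                 generate_organ_dataset(sp10)$meta$split)
  expect_equal(unname(tab10["cancer", ]), c(1, 7, 2),
               ignore_attr = TRUE)  # test, train, val (alphabetical)

  sp9 <- organ_spec("X", cancer, base, n_patches_per_class = 9, seed = 3)
  expect_error(generate_organ_dataset(sp9), "empty split")
})

test_that("datasets with different seeds share split sizes, not pixels", {
  base <- morphology_params()
  cancer <- morphology_params(nucleus_density = 30)
  d1 <- generate_organ_dataset(organ_spec("X", cancer, base, 20, seed = 1))
  d2 <- generate_organ_dataset(organ_spec("X", cancer, base, 20, seed = 2))
  expect_equal(table(d1$meta$split), table(d2$meta$split))
  expect_false(identical(d1$records[[1]]$image, d2$records[[1]]$image))
})

test_that("shared-morphology studies share and separate cancer params", {
  specs <- generate_shared_morphology_study(3, list(c("A", "B")), base_seed = 5)
  num <- function(p) unlist(p[c("nucleus_density", "radius_mean", "radius_sd",
                                "eccentricity_mean", "cluster_factor")])
  expect_identical(num(specs$A$cancer_morphology),
                   num(specs$B$cancer_morphology))
  diffs <- num(specs$A$cancer_morphology) != num(specs$C$cancer_morphology)
  expect_gte(sum(diffs), 2)
  expect_gte(morphology_distance(specs$A$cancer_morphology,
                                 specs$C$cancer_morphology), 2)

  two <- generate_shared_morphology_study(2, list(), base_seed = 5)
  expect_gte(morphology_distance(two$A$cancer_morphology,
                                 two$B$cancer_morphology), 2)

  expect_error(generate_shared_morphology_study(2, list(c("A", "Z"))),
               "unknown organ")
})

test_that("generated morphology matches its parameters over many patches", {
  p <- morphology_params(nucleus_density = 18, eccentricity_mean = 0.5,
                         radius_mean = 3.5)
  counts <- numeric(200); eccs <- NULL
  for (i in 1:200) {
    rec <- generate_patch(p, 64, seed = 9000 + i)
    counts[i] <- nrow(rec$nuclei)
    eccs <- c(eccs, rec$nuclei$eccentricity)
  }
  expect_lt(abs(mean(counts) - 18) / 18, 0.15)
  expect_lt(abs(mean(eccs) - 0.5), 0.1)
})

test_that("class labels are not readable from mean brightness alone", {
  specs <- generate_shared_morphology_study(2, list(), base_seed = 21,
                                            n_patches_per_class = 60)
  ds <- generate_organ_dataset(specs$A)
  lum <- vapply(ds$records, function(r) mean(rgb_to_luma(r$image)), numeric(1))
  y <- ds$meta$class == "cancer"
  # best single threshold on mean intensity, either direction
  accs <- vapply(sort(lum), function(t)
    max(mean((lum > t) == y), mean((lum <= t) == y)), numeric(1))
  expect_lte(max(accs), 0.9)
  # while the underlying nucleus counts are clearly separated
  tt <- stats::t.test(ds$meta$n_nuclei[y], ds$meta$n_nuclei[!y])
  expect_lt(tt$p.value, 1e-6)
})

test_that("pseudo-WSI composition returns a faithful ground-truth map", {
  p <- morphology_params(nucleus_density = 30)
  patches <- lapply(1:4, function(i) generate_patch(p, 64, seed = i))
  full <- compose_pseudo_wsi(patches, background_fraction = 0, seed = 1)
  expect_equal(dim(full$tissue_map), c(2, 2))
  expect_true(all(full$tissue_map))
  expect_equal(dim(full$image)[1:2], c(128, 128))

  allbg <- compose_pseudo_wsi(list(), background_fraction = 1,
                              dim = c(2, 2), tile_size = 64, seed = 1)
  expect_false(any(allbg$tissue_map))

  mix <- compose_pseudo_wsi(patches[1:3], background_fraction = 0.25,
                            dim = c(2, 2), seed = 7)
  expect_equal(sum(mix$tissue_map), 3)
  # the tissue tiles hold exactly the supplied patches
  for (k in 1:3) {
    t_ <- mix$tiles[which(mix$tiles$patch_index == k), ]
    rows <- (t_$row - 1) * 64 + 1:64; cols <- (t_$col - 1) * 64 + 1:64
    expect_identical(mix$image[rows, cols, ], patches[[k]]$image)
  }

  expect_error(compose_pseudo_wsi(patches, background_fraction = 1.2),
               "background_fraction")
})

test_that("datasets round-trip through the PNG directory layout", {
  base <- morphology_params()
  cancer <- morphology_params(nucleus_density = 30)
  ds <- generate_organ_dataset(organ_spec("LIV", cancer, base, 10, seed = 4))
  root <- withr::local_tempdir()
  write_patch_dataset(ds, root)
  expect_true(file.exists(file.path(root, "LIV", "metadata.json")))
  back <- read_patch_dataset(root, "LIV")
  expect_equal(nrow(back$meta), 20)
  i <- match(ds$meta$id[1], back$meta$id)
  expect_equal(back$records[[i]]$image, ds$records[[1]]$image,
               tolerance = 1e-6)
  expect_equal(nrow(back$records[[i]]$nuclei), nrow(ds$records[[1]]$nuclei))
})
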