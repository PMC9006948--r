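# Synthetic multi-organ histology-like patch generator.
#
# Patches are 8-bit RGB images of a light stained background carrying
# elliptical nuclei (dark chromatin core plus a lighter cytoplasm halo).
# The morphology of the "cancer" and "normal" populations of each organ
# is fully parametric, and every patch retains its ground-truth nucleus
# table, so downstream segmentation and morphometry can be scored against
# a known answer.

#' Morphology parameters for one patch population
#'
#' @param nucleus_density expected nuclei per patch (Poisson mean).
#' @param radius_mean,radius_sd nucleus radius scale in pixels: the
#'   geometric-mean semi-axis of each ellipse is drawn from
#'   N(radius_mean, radius_sd), truncated at 1 px.
#' @param eccentricity_mean target elongation in [0, 1); per-nucleus
#'   eccentricities are drawn around this with sd 0.08 and clamped to
#'   [0, 0.95].
#' @param cluster_factor probability in [0, 1] that a nucleus is placed
#'   near one of a few cluster centres rather than uniformly.
#' @param stain_palette list with `background`, `nucleus`, `cytoplasm`
#'   RGB triplets on the 0-255 scale.
#' @param noise_sd additive per-pixel Gaussian noise scale (intensity units).
#' @param brightness_sd per-patch global stain-intensity jitter (sd of a
#'   single offset added to all pixels).  Emulates slide-to-slide staining
#'   variability and prevents overall brightness from being a shortcut
#'   label for class.
#' @param second_population optional second `morphology_params` rendered
#'   into the same patches (no nesting).  Real tissue patches are nucleus
#'   mixtures — tumor nuclei embedded among stromal/immune nuclei — and a
#'   mixture is what lets two models attend morphologically different
#'   sub-populations within one patch.
#' @return an object of class `morphology_params`.
#' @export
morphology_params <- function(nucleus_density = 12,
                              radius_mean = 3, radius_sd = 0.4,
                              eccentricity_mean = 0.15,
                              cluster_factor = 0,
                              stain_palette = default_stain_palette(),
                              noise_sd = 6,
                              brightness_sd = 12,
                              second_population = NULL) {
  stopifnot(nucleus_density > 0,
            radius_mean > radius_sd, radius_sd >= 0,
            eccentricity_mean >= 0, eccentricity_mean < 1,
            cluster_factor >= 0, cluster_factor <= 1,
            noise_sd >= 0, brightness_sd >= 0)
  stopifnot(is.list(stain_palette),
            all(c("background", "nucleus", "cytoplasm") %in% names(stain_palette)))
  if (!is.null(second_population)) {
    stopifnot(inherits(second_population, "morphology_params"),
              is.null(second_population$second_population))
  }
  structure(list(nucleus_density = nucleus_density,
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 eccentricity_mean = eccentricity_mean,
                 cluster_factor = cluster_factor,
                 stain_palette = stain_palette,
                 noise_sd = noise_sd,
                 brightness_sd = brightness_sd,
                 second_population = second_population),
            class = "morphology_params")
}

#' @export
print.morphology_params <- function(x, ...) {
  cat("Morphology: density", x$nucleus_density,
      "| radius", x$radius_mean, "+/-", x$radius_sd,
      "| ecc", x$eccentricity_mean,
      "| clustering", x$cluster_factor, "\n")
  invisible(x)
}

#' Default H&E-like stain palette (8-bit RGB)
#' @export
default_stain_palette <- function() {
  list(background = c(205, 172, 200),  # eosin-pink stroma
       nucleus    = c(72, 42, 112),    # hematoxylin-purple chromatin
       cytoplasm  = c(152, 112, 168))
}

#' Specification of one synthetic organ
#'
#' @param organ_id short organ label.
#' @param cancer_morphology,normal_morphology `morphology_params` for the
#'   two classes; they must differ in at least one parameter.
#' @param n_patches_per_class patches generated per class.
#' @param patch_size square patch side in pixels (>= 64).
#' @param seed integer seed governing the organ's entire patch stream.
#' @return an object of class `organ_spec`.
#' @export
organ_spec <- function(organ_id, cancer_morphology, normal_morphology,
                       n_patches_per_class = 100, patch_size = 64, seed = 1L) {
  stopifnot(is.character(organ_id), nchar(organ_id) > 0,
            inherits(cancer_morphology, "morphology_params"),
            inherits(normal_morphology, "morphology_params"),
            n_patches_per_class >= 1, patch_size >= 64)
  num <- function(p) unlist(p[c("nucleus_density", "radius_mean", "radius_sd",
                                "eccentricity_mean", "cluster_factor")])
  if (isTRUE(all.equal(num(cancer_morphology), num(normal_morphology))))
    stop("cancer and normal morphologies must differ in at least one parameter")
  structure(list(organ_id = organ_id,
                 cancer_morphology = cancer_morphology,
                 normal_morphology = normal_morphology,
                 n_patches_per_class = as.integer(n_patches_per_class),
                 patch_size = as.integer(patch_size),
                 seed = as.integer(seed)),
            class = "organ_spec")
}

#' Generate one synthetic patch
#'
#' Renders nuclei as filled rotated ellipses (cytoplasm halo first, then
#' the darker chromatin core) over a noisy stained background, and keeps
#' the ground-truth nucleus table as metadata.  Deterministic given `seed`.
#'
#' @param params a `morphology_params` object.
#' @param size patch side in pixels.
#' @param seed integer seed (NULL uses the current RNG stream).
#' @param nuclei optional data.frame with columns `cx`, `cy`, `a`, `b`,
#'   `angle` that overrides random placement (used for ground-truth
#'   constructions in tests).
#' @return a `patch_record`: list with `image` (size x size x 3, 0-255),
#'   `nuclei` (ground-truth table with centres, semi-axes, angle,
#'   eccentricity), `params`, `seed`.
#' @export
generate_patch <- function(params, size = 64L, seed = NULL, nuclei = NULL) {
  stopifnot(inherits(params, "morphology_params"))
  size <- as.integer(size)
  min_side <- ceiling(2 * (params$radius_mean + 2 * params$radius_sd)) + 2L
  if (size < min_side)
    stop(sprintf(paste0("`size` (%d) is too small to place one nucleus with ",
                        "radius_mean = %.1f (need >= %d)"),
                 size, params$radius_mean, min_side))
  with_seed(seed, {
    if (is.null(nuclei)) {
      nuclei <- .sample_nuclei(params, size)
      nuclei$population <- rep("primary", nrow(nuclei))
      if (!is.null(params$second_population)) {
        extra <- .sample_nuclei(params$second_population, size)
        extra$population <- rep("second", nrow(extra))
        nuclei <- rbind(nuclei, extra)
      }
    } else {
      nuclei <- as.data.frame(nuclei)
      stopifnot(all(c("cx", "cy", "a", "b", "angle") %in% names(nuclei)))
      if (is.null(nuclei$population))
        nuclei$population <- rep("primary", nrow(nuclei))
    }
    nuclei$eccentricity <- if (nrow(nuclei))
      sqrt(1 - (nuclei$b / nuclei$a)^2) else numeric(0)

    pal <- params$stain_palette
    img <- array(0, c(size, size, 3))
    offset <- stats::rnorm(1, 0, params$brightness_sd)
    for (ch in 1:3) img[, , ch] <- pal$background[ch] + offset
    # halo then core so overlapping cores stay dark
    img <- .paint_ellipses(img, nuclei, scale = 1.6, col = pal$cytoplasm)
    img <- .paint_ellipses(img, nuclei, scale = 1.0, col = pal$nucleus)
    if (params$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, params$noise_sd), dim(img))
    img <- round(clamp(img, 0, 255))
    structure(list(image = img, nuclei = nuclei, params = params,
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
              class = "patch_record")
  })
}

# Draw one nucleus population: Poisson count, cluster-biased or uniform
# placement, ellipse axes from the radius/eccentricity distributions.
# Consumes the current RNG stream.
.sample_nuclei <- function(params, size) {
  n <- stats::rpois(1L, params$nucleus_density)
  if (n == 0L)
    return(data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                      b = numeric(0), angle = numeric(0)))
  n_centers <- max(1L, ceiling(n / 8))
  ctr <- cbind(stats::runif(n_centers, size * 0.2, size * 0.8),
               stats::runif(n_centers, size * 0.2, size * 0.8))
  use_cluster <- stats::runif(n) < params$cluster_factor
  pick <- sample.int(n_centers, n, replace = TRUE)
  cx <- ifelse(use_cluster, ctr[pick, 1] + stats::rnorm(n, 0, size / 16),
               stats::runif(n, 1, size))
  cy <- ifelse(use_cluster, ctr[pick, 2] + stats::rnorm(n, 0, size / 16),
               stats::runif(n, 1, size))
  cx <- clamp(cx, 2, size - 1); cy <- clamp(cy, 2, size - 1)
  r <- pmax(1, stats::rnorm(n, params$radius_mean, params$radius_sd))
  e <- clamp(stats::rnorm(n, params$eccentricity_mean, 0.08), 0, 0.95)
  shrink <- (1 - e^2)^(1/4)   # keeps a*b = r^2 at eccentricity e
  data.frame(cx = cx, cy = cy, a = r / shrink, b = r * shrink,
             angle = stats::runif(n, 0, pi))
}

# Paint filled ellipses (semi-axes scaled by `scale`) in colour `col`.
.paint_ellipses <- function(img, nuclei, scale, col) {
  if (!nrow(nuclei)) return(img)
  size_y <- dim(img)[1]; size_x <- dim(img)[2]
  for (k in seq_len(nrow(nuclei))) {
    a <- nuclei$a[k] * scale; b <- nuclei$b[k] * scale
    cx <- nuclei$cx[k]; cy <- nuclei$cy[k]; th <- nuclei$angle[k]
    rmax <- ceiling(max(a, b))
    xs <- max(1L, floor(cx - rmax)):min(size_x, ceiling(cx + rmax))
    ys <- max(1L, floor(cy - rmax)):min(size_y, ceiling(cy + rmax))
    if (!length(xs) || !length(ys)) next
    X <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx
    Y <- matrix(ys, length(ys), length(xs)) - cy
    u <- cos(th) * X + sin(th) * Y
    v <- -sin(th) * X + cos(th) * Y
    inside <- (u / a)^2 + (v / b)^2 <= 1
    if (!any(inside)) next
    idx <- which(inside, arr.ind = TRUE)
    rows <- ys[idx[, 1]]; cols <- xs[idx[, 2]]
    for (ch in 1:3) img[cbind(rows, cols, ch)] <- col[ch]
  }
  img
}

#' @export
print.patch_record <- function(x, ...) {
  cat("Synthetic patch", dim(x$image)[1], "x", dim(x$image)[2],
      "with", nrow(x$nuclei), "nuclei\n")
  invisible(x)
}

#' Generate a stratified, split patch dataset for one organ
#'
#' Generates `n_patches_per_class` patches per class and partitions each
#' class independently into train/validation/test splits (default
#' 0.70/0.20/0.10).  Validation and test sizes are `floor(fraction * n)`;
#' the remainder goes to train.
#'
#' @param spec an `organ_spec`.
#' @param split named fractions for `train`, `val`, `test` (must sum to 1).
#' @return a `patch_dataset`: list with `records` (list of
#'   `patch_record`s) and `meta` (data.frame of id, organ, class, split,
#'   n_nuclei).
#' @export
generate_organ_dataset <- function(spec,
                                   split = c(train = 0.7, val = 0.2, test = 0.1)) {
  stopifnot(inherits(spec, "organ_spec"),
            all(c("train", "val", "test") %in% names(split)),
            abs(sum(split) - 1) < 1e-8)
  n <- spec$n_patches_per_class
  n_val <- floor(split[["val"]] * n)
  n_test <- floor(split[["test"]] * n)
  n_train <- n - n_val - n_test
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stop(sprintf(paste0("n_patches_per_class = %d leaves an empty split ",
                        "(train %d / val %d / test %d); increase it"),
                 n, n_train, n_val, n_test))
  classes <- c("normal", "cancer")
  records <- list(); meta <- NULL
  for (cls in classes) {
    par <- if (cls == "cancer") spec$cancer_morphology else spec$normal_morphology
    cls_seed <- derive_seed(spec$seed, paste0("patches_", cls))
    recs <- lapply(seq_len(n), function(i)
      generate_patch(par, spec$patch_size, seed = cls_seed + i))
    perm <- with_seed(derive_seed(spec$seed, paste0("split_", cls)),
                      sample.int(n))
    lab <- character(n)
    lab[perm[seq_len(n_train)]] <- "train"
    lab[perm[n_train + seq_len(n_val)]] <- "val"
    lab[perm[n_train + n_val + seq_len(n_test)]] <- "test"
    meta <- rbind(meta, data.frame(
      id = sprintf("%s_%s_%03d", spec$organ_id, cls, seq_len(n)),
      organ = spec$organ_id, class = cls, split = lab,
      n_nuclei = vapply(recs, function(r) nrow(r$nuclei), integer(1)),
      stringsAsFactors = FALSE))
    records <- c(records, recs)
  }
  structure(list(records = records, meta = meta, spec = spec),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat("Patch dataset:", x$meta$organ[1], "-", nrow(x$meta), "patches\n")
  print(table(x$meta$class, x$meta$split))
  invisible(x)
}

# Organ archetypes used to separate organs that do not share cancer
# morphology.  Each archetype pairs a cancer morphology with the organ's
# normal-parenchyma baseline (organs differ in normal cellularity too).
# Archetype 1 is the dense / pleomorphic / strongly clustered default
# over a cellular normal; archetype 2 is a sparser organ whose tumors
# show large elongated nuclei scattered among stroma-like small round
# nuclei, with overall chromatin coverage close to archetype 1's NORMAL
# — so a classifier keyed to archetype 1 cannot recognise archetype 2
# cancer through tissue darkness or cluster texture.
.cancer_archetypes <- function() {
  list(
    list(cancer = morphology_params(nucleus_density = 34, radius_mean = 3.6,
                                    radius_sd = 1.0, eccentricity_mean = 0.55,
                                    cluster_factor = 0.8),
         normal_density = 24, normal_radius = 3.1),
    list(cancer = morphology_params(nucleus_density = 13, radius_mean = 2.8,
                                    radius_sd = 0.3, eccentricity_mean = 0.15,
                                    cluster_factor = 0,
                                    second_population = morphology_params(
                                      nucleus_density = 8, radius_mean = 4.4,
                                      radius_sd = 0.8,
                                      eccentricity_mean = 0.85,
                                      cluster_factor = 0.2)),
         normal_density = 15, normal_radius = 2.9),
    list(cancer = morphology_params(nucleus_density = 28, radius_mean = 2.4,
                                    radius_sd = 0.3, eccentricity_mean = 0.3,
                                    cluster_factor = 0.4),
         normal_density = 18, normal_radius = 3.3),
    list(cancer = morphology_params(nucleus_density = 14, radius_mean = 5.2,
                                    radius_sd = 1.4, eccentricity_mean = 0.2,
                                    cluster_factor = 0.6),
         normal_density = 22, normal_radius = 2.8),
    list(cancer = morphology_params(nucleus_density = 45, radius_mean = 2.8,
                                    radius_sd = 0.5, eccentricity_mean = 0.55,
                                    cluster_factor = 0.95),
         normal_density = 26, normal_radius = 3.2))
}

#' Normalized distance between two morphologies
#'
#' Euclidean distance over (density, radius mean/sd, eccentricity,
#' clustering) after dividing each by a typical variation scale, so one
#' unit roughly means "one clearly visible parameter difference".
#' @param p1,p2 `morphology_params` objects.
#' @return non-negative scalar.
#' @export
morphology_distance <- function(p1, p2) {
  sc <- c(nucleus_density = 10, radius_mean = 1, radius_sd = 0.5,
          eccentricity_mean = 0.2, cluster_factor = 0.25)
  v1 <- unlist(p1[names(sc)]); v2 <- unlist(p2[names(sc)])
  d <- sqrt(sum(((v1 - v2) / sc)^2))
  s1 <- p1$second_population; s2 <- p2$second_population
  if (is.null(s1) != is.null(s2)) d <- d + 3      # mixture vs single
  else if (!is.null(s1)) d <- d + morphology_distance(s1, s2)
  d
}

#' Build organ specs for a shared-morphology study
#'
#' Organs named in `shared_pairs` receive identical cancer morphology;
#' all remaining organs receive cancer morphologies drawn from distinct
#' archetypes separated by at least `min_distance` in
#' [morphology_distance()] units.  Normal morphologies are jittered per
#' organ around the sparse/round default.
#'
#' @param n_organs number of organs (>= 2); labelled A, B, C, ...
#' @param shared_pairs list of length-2 character vectors of organ ids
#'   whose cancer morphology must match.
#' @param base_seed master seed.
#' @param n_patches_per_class,patch_size forwarded to [organ_spec()].
#' @param min_distance minimum morphology distance between non-shared
#'   cancer morphologies.
#' @return list of `organ_spec`s, named by organ id.
#' @export
generate_shared_morphology_study <- function(n_organs, shared_pairs = list(),
                                             base_seed = 1L,
                                             n_patches_per_class = 100,
                                             patch_size = 64,
                                             min_distance = 2) {
  stopifnot(n_organs >= 2)
  ids <- LETTERS[seq_len(n_organs)]
  for (p in shared_pairs) {
    stopifnot(length(p) == 2L)
    bad <- setdiff(p, ids)
    if (length(bad))
      stop("shared pair references unknown organ id: ", paste(bad, collapse = ", "))
  }
  # union-find shared groups
  grp <- stats::setNames(seq_len(n_organs), ids)
  for (p in shared_pairs) {
    g <- range(grp[p])
    grp[grp == g[2]] <- g[1]
  }
  arch <- .cancer_archetypes()
  groups <- unique(grp)
  if (length(groups) > length(arch))
    stop("at most ", length(arch), " distinct cancer morphology groups supported")
  arch_of_group <- stats::setNames(seq_along(groups), groups)
  # archetypes are mutually distant by construction; verify the contract
  for (i in seq_along(groups)) for (j in seq_len(i - 1L)) {
    d <- morphology_distance(arch[[arch_of_group[i]]]$cancer,
                             arch[[arch_of_group[j]]]$cancer)
    if (d < min_distance)
      stop("cancer morphology archetypes closer than min_distance")
  }
  specs <- lapply(seq_len(n_organs), function(k) {
    id <- ids[k]
    a <- arch[[arch_of_group[[as.character(grp[[id]])]]]]
    # normal tissue: round, uniformly placed nuclei at the archetype's
    # organ-specific cellularity, jittered per organ
    normal <- with_seed(derive_seed(base_seed, paste0("normal_", id)), {
      morphology_params(
        nucleus_density = a$normal_density * stats::runif(1, 0.9, 1.1),
        radius_mean = a$normal_radius * stats::runif(1, 0.95, 1.05),
        radius_sd = 0.4, eccentricity_mean = 0.15, cluster_factor = 0)
    })
    organ_spec(id, a$cancer, normal,
               n_patches_per_class = n_patches_per_class,
               patch_size = patch_size,
               seed = derive_seed(base_seed, paste0("organ_", id)))
  })
  stats::setNames(specs, ids)
}

#' Compose a pseudo whole-slide image from patches
#'
#' Tiles the given patches into a grid and replaces the requested
#' fraction of tiles with bright near-white background, returning the
#' ground-truth map of which tile positions hold tissue.  Serves as a
#' fixture source for the tiling and filtering stage.
#'
#' @param patches list of `patch_record`s or H x W x 3 arrays (all the
#'   same size).
#' @param background_fraction fraction of grid tiles that are background.
#' @param dim optional c(nrow, ncol) grid; derived from the patch count
#'   and `background_fraction` when NULL.
#' @param tile_size required when `patches` is empty.
#' @param seed integer seed for tile placement and background noise.
#' @return list with `image`, `tissue_map` (logical nrow x ncol matrix),
#'   and `tiles` (data.frame of row, col, tissue, patch_index).
#' @export
compose_pseudo_wsi <- function(patches, background_fraction = 0, dim = NULL,
                               tile_size = NULL, seed = 1L) {
  if (background_fraction < 0 || background_fraction > 1)
    stop("background_fraction must be in [0, 1]")
  imgs <- lapply(patches, function(p) if (inherits(p, "patch_record")) p$image else p)
  n_tissue <- length(imgs)
  if (n_tissue > 0) {
    sizes <- vapply(imgs, function(im) dim(im)[1], numeric(1))
    widths <- vapply(imgs, function(im) dim(im)[2], numeric(1))
    if (length(unique(c(sizes, widths))) != 1L)
      stop("all patches must be square and the same size")
    tile_size <- sizes[1]
  } else if (is.null(tile_size)) {
    stop("tile_size must be given when no patches are supplied")
  }
  if (is.null(dim)) {
    if (background_fraction >= 1 && n_tissue > 0)
      stop("background_fraction = 1 is incompatible with tissue patches")
    if (n_tissue == 0)
      stop("grid `dim` must be given when no patches are supplied")
    total <- ceiling(n_tissue / max(1 - background_fraction, 1e-9))
    nr <- floor(sqrt(total)); nc <- ceiling(total / nr)
  } else {
    nr <- dim[1]; nc <- dim[2]
    if (nr * nc < n_tissue) stop("grid too small for the given patches")
  }
  total <- nr * nc
  with_seed(seed, {
    pos <- sample.int(total, n_tissue)  # tissue tile positions
    tissue_map <- matrix(FALSE, nr, nc)
    tissue_map[pos] <- TRUE
    img <- array(0, c(nr * tile_size, nc * tile_size, 3))
    # background tiles: bright, lightly noisy
    for (ch in 1:3)
      img[, , ch] <- round(clamp(245 + stats::rnorm(nr * nc * tile_size^2, 0, 2.5),
                                 0, 255))
    tiles <- data.frame(row = rep(seq_len(nr), nc), col = rep(seq_len(nc), each = nr),
                        tissue = as.vector(tissue_map), patch_index = NA_integer_)
    for (k in seq_len(n_tissue)) {
      p <- pos[k]
      r <- (p - 1L) %% nr + 1L; cl <- (p - 1L) %/% nr + 1L
      rows <- (r - 1L) * tile_size + seq_len(tile_size)
      cols <- (cl - 1L) * tile_size + seq_len(tile_size)
      img[rows, cols, ] <- imgs[[k]]
      tiles$patch_index[tiles$row == r & tiles$col == cl] <- k
    }
    list(image = img, tissue_map = tissue_map, tiles = tiles,
         tile_size = tile_size)
  })
}

#' Write a patch dataset to disk as PNG files
#'
#' Layout: `<root>/<organ>/<split>/<class>/patch_<i>.png`, with one JSON
#' sidecar per organ holding the generator parameters, seed and the
#' ground-truth nucleus tables.
#' @param dataset a `patch_dataset`.
#' @param root output directory.
#' @return invisibly, the vector of written file paths.
#' @export
write_patch_dataset <- function(dataset, root) {
  stopifnot(inherits(dataset, "patch_dataset"))
  meta <- dataset$meta
  paths <- character(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    dir <- file.path(root, meta$organ[i], meta$split[i], meta$class[i])
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(dir, paste0(meta$id[i], ".png"))
    png::writePNG(dataset$records[[i]]$image / 255, paths[i])
  }
  sidecar <- list(
    organ = meta$organ[1],
    seed = dataset$spec$seed,
    patch_size = dataset$spec$patch_size,
    cancer_morphology = unclass(dataset$spec$cancer_morphology),
    normal_morphology = unclass(dataset$spec$normal_morphology),
    patches = lapply(seq_len(nrow(meta)), function(i)
      list(id = meta$id[i], class = meta$class[i], split = meta$split[i],
           nuclei = dataset$records[[i]]$nuclei)))
  jsonlite::write_json(sidecar, file.path(root, meta$organ[1], "metadata.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(paths)
}

#' Read a patch dataset written by [write_patch_dataset()]
#' @param root dataset root directory.
#' @param organ organ subdirectory name.
#' @return a `patch_dataset` (ground-truth nucleus tables restored from
#'   the JSON sidecar when present).
#' @export
read_patch_dataset <- function(root, organ) {
  base <- file.path(root, organ)
  if (!dir.exists(base)) stop("no such organ directory: ", base)
  side <- file.path(base, "metadata.json")
  nuclei_by_id <- list()
  if (file.exists(side)) {
    side_data <- jsonlite::read_json(side, simplifyVector = FALSE)
    for (p in side_data$patches) {
      nuc <- p$nuclei
      nuclei_by_id[[p$id]] <- if (length(nuc) && length(nuc[[1]]))
        as.data.frame(lapply(nuc, unlist), stringsAsFactors = FALSE)
      else data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                      b = numeric(0), angle = numeric(0))
    }
  }
  files <- list.files(base, pattern = "\\.png$", recursive = TRUE, full.names = TRUE)
  if (!length(files)) stop("no PNG patches under ", base)
  parts <- strsplit(sub(paste0("^", base, "/"), "", files), "/")
  meta <- data.frame(
    id = sub("\\.png$", "", basename(files)),
    organ = organ,
    class = vapply(parts, `[`, "", 2L),
    split = vapply(parts, `[`, "", 1L),
    stringsAsFactors = FALSE)
  records <- lapply(seq_along(files), function(i) {
    img <- png::readPNG(files[i]) * 255
    nuc <- nuclei_by_id[[meta$id[i]]]
    structure(list(image = img, nuclei = nuc, params = NULL, seed = NA_integer_),
              class = "patch_record")
  })
  meta$n_nuclei <- vapply(records, function(r)
    if (is.null(r$nuclei)) NA_integer_ else nrow(r$nuclei), integer(1))
  structure(list(records = records, meta = meta, spec = NULL),
            class = "patch_dataset")
}
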