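# Independent brute-force oracles and fixture builders.  These
# deliberately re-derive quantities by the most literal method available
# (pixel enumeration, exhaustive search) so they share no code with the
# package implementation.

# Pixel-enumeration IoU of two box sets (0-based half-open boxes).
brute_iou_boxes <- function(boxes_a, boxes_b, extent = 64L) {
  in_any <- function(r, c, boxes) {
    for (k in seq_len(nrow(boxes)))
      if (r >= boxes[k, 1] && r < boxes[k, 3] &&
          c >= boxes[k, 2] && c < boxes[k, 4]) return(TRUE)
    FALSE
  }
  inter <- 0L; union <- 0L
  for (r in 0:(extent - 1L)) for (c in 0:(extent - 1L)) {
    a <- in_any(r, c, boxes_a); b <- in_any(r, c, boxes_b)
    if (a && b) inter <- inter + 1L
    if (a || b) union <- union + 1L
  }
  if (union == 0L) 0 else inter / union
}

# Literal per-pixel Jaccard.
brute_jaccard <- function(a, b) {
  inter <- 0L; union <- 0L
  for (i in seq_along(a)) {
    if (a[i] && b[i]) inter <- inter + 1L
    if (a[i] || b[i]) union <- union + 1L
  }
  if (union == 0L) 0 else inter / union
}

# AUC by counting all positive/negative score pairs (ties 1/2).
brute_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Welch / pooled t statistic and p-value from the textbook formulas.
brute_t <- function(xs, ys, pooled = FALSE) {
  nx <- length(xs); ny <- length(ys)
  vx <- sum((xs - mean(xs))^2) / (nx - 1)
  vy <- sum((ys - mean(ys))^2) / (ny - 1)
  if (pooled) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mean(xs) - mean(ys)) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

# Weighted cross entropy by direct probability arithmetic.
brute_wce <- function(logits, labels, weights) {
  total <- 0; wsum <- 0
  for (i in seq_len(nrow(logits))) {
    p <- exp(logits[i, ]) / sum(exp(logits[i, ]))
    w <- weights[labels[i] + 1]
    total <- total + w * (-log(p[labels[i] + 1]))
    wsum <- wsum + w
  }
  total / wsum
}

# Minimum spanning tree weight by exhaustive enumeration over Pruefer
# sequences (all n^(n-2) labelled spanning trees; n <= 6).
brute_mst_weight <- function(pts) {
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts))
  if (n == 2L) return(D[1, 2])
  pruefer_to_edges <- function(seq_) {
    n <- length(seq_) + 2L
    degree <- rep(1L, n)
    for (s in seq_) degree[s] <- degree[s] + 1L
    edges <- matrix(0L, n - 1L, 2L)
    for (i in seq_along(seq_)) {
      leaf <- min(which(degree == 1L))
      edges[i, ] <- c(leaf, seq_[i])
      degree[leaf] <- degree[leaf] - 1L
      degree[seq_[i]] <- degree[seq_[i]] - 1L
    }
    edges[n - 1L, ] <- which(degree == 1L)
    edges
  }
  combos <- do.call(expand.grid, rep(list(seq_len(n)), n - 2L))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    e <- pruefer_to_edges(as.integer(combos[r, ]))
    w <- sum(D[e])
    if (w < best) best <- w
  }
  best
}

# 8-connected component count via an adjacency graph (igraph), an
# implementation route the package's own pixel labelling does not use.
brute_count_components <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(0L)
  nr <- nrow(mask)
  pos <- matrix(0L, length(mask), 1); pos[idx] <- seq_along(idx)
  edges <- NULL
  rows <- (idx - 1L) %% nr + 1L; cols <- (idx - 1L) %/% nr + 1L
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r2 <- rows + d[1]; c2 <- cols + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    j <- (c2[ok] - 1L) * nr + r2[ok]
    has <- pos[j] > 0L
    edges <- rbind(edges, cbind(pos[idx[ok]][has], pos[j][has]))
  }
  if (is.null(edges) || !nrow(edges)) return(length(idx))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  igraph::components(g)$no
}

# Literal Otsu search: try every threshold, maximize between-class
# variance computed from first principles.
brute_otsu <- function(gray) {
  g <- round(pmin(pmax(gray, 0), 255))
  best <- -Inf; bt <- 0
  for (t in 0:255) {
    lo <- g[g <= t]; hi <- g[g > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(g); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best) { best <- v; bt <- t }
  }
  bt
}

# Draw a filled disk into a matrix (used to build patches with a known
# component count).
draw_disk <- function(img, cy, cx, r, value = 40) {
  for (i in seq_len(dim(img)[1])) for (j in seq_len(dim(img)[2]))
    if ((i - cy)^2 + (j - cx)^2 <= r^2) img[i, j, ] <- value
  img
}

# Tissue patches verified to pass both extraction filters, so that
# pseudo-WSI ground-truth recovery is exact by construction.
passing_tissue_patches <- function(n, seed0,
                                   params = morphology_params(nucleus_density = 30),
                                   cfg = filter_config()) {
  out <- list(); s <- seed0
  while (length(out) < n) {
    rec <- generate_patch(params, 64, seed = s)
    s <- s + 1L
    if (filter_background(rec$image, cfg)$accept &&
        filter_fractal(rec$image, cfg)$accept)
      out[[length(out) + 1L]] <- rec
    if (s - seed0 > 50L * n) stop("could not build passing tissue patches")
  }
  out
}

# A patch image that is pure background at the given brightness.
flat_patch <- function(size, value) array(value, c(size, size, 3))

# Random box set (0-based half-open, inside a 64 px frame).
random_boxes <- function(n) {
  out <- matrix(0L, n, 4)
  for (k in seq_len(n)) {
    r0 <- sample(0:50, 1); c0 <- sample(0:50, 1)
    out[k, ] <- c(r0, c0, r0 + sample(1:12, 1), c0 + sample(1:12, 1))
  }
  colnames(out) <- c("row_min", "col_min", "row_max", "col_max")
  out
}

# Tiny linearly separable dataset: bright vs dark noisy patches, built
# directly as a patch_dataset.
separable_dataset <- function(n_per_class = 30, size = 64, seed = 1) {
  set.seed(seed)
  records <- list(); meta <- NULL
  n_val <- floor(0.2 * n_per_class); n_test <- floor(0.1 * n_per_class)
  n_train <- n_per_class - n_val - n_test
  splits <- c(rep("train", n_train), rep("val", n_val), rep("test", n_test))
  for (cls in c("normal", "cancer")) {
    base <- if (cls == "cancer") 80 else 170
    for (i in seq_len(n_per_class)) {
      img <- array(pmin(pmax(base + stats::rnorm(size * size * 3, 0, 20), 0), 255),
                   c(size, size, 3))
      records[[length(records) + 1L]] <-
        structure(list(image = img, nuclei = NULL, params = NULL,
                       seed = NA_integer_), class = "patch_record")
      meta <- rbind(meta, data.frame(
        id = sprintf("sep_%s_%03d", cls, i), organ = "SEP", class = cls,
        split = splits[i], n_nuclei = NA_integer_))
    }
  }
  structure(list(records = records, meta = meta, spec = NULL),
            class = "patch_dataset")
}
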