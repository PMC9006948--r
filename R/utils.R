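# Internal helpers shared across modules: seeded RNG scoping, image
# conversions, resizing, and connected-component labelling.

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores `.Random.seed` so that seeded operations inside the
#' package never disturb the caller's random stream.
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a stage tag.  Keeps results
# < 2^31 so the value is always a valid R integer.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((((as.numeric(seed) %% 50021) * 69621) + (h %% 69621) * 31 + h) %%
               2147483563) + 1L
}

#' Convert an RGB image to grayscale luma
#'
#' Standard Rec. 601 luma (0.299 R + 0.587 G + 0.114 B) on the image's own
#' intensity scale (0-255 for the 8-bit arrays used throughout).
#' @param img H x W x 3 numeric array.
#' @return H x W numeric matrix.
#' @export
rgb_to_luma <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Validate an 8-bit RGB patch array.
check_rgb <- function(img, arg = "patch") {
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L &&
        is.numeric(img)))
    stop(sprintf("`%s` must be an H x W x 3 numeric RGB array", arg),
         call. = FALSE)
  invisible(img)
}

#' Bilinear resize of a matrix or RGB array
#'
#' Used both for data-augmentation crops and for upsampling class
#' activation maps back to patch resolution.
#' @param x matrix or H x W x C array.
#' @param out_h,out_w output dimensions in pixels.
#' @return resized matrix or array.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  if (is.matrix(x)) return(.resize_mat(x, out_h, out_w))
  stopifnot(length(dim(x)) == 3L)
  out <- array(0, c(out_h, out_w, dim(x)[3]))
  for (c in seq_len(dim(x)[3])) out[, , c] <- .resize_mat(x[, , c], out_h, out_w)
  out
}

.resize_mat <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  if (h == out_h && w == out_w) return(m)
  # align-corners mapping; degenerate single-row/col handled by clamping
  ys <- if (out_h == 1L) rep(1, 1) else seq(1, h, length.out = out_h)
  xs <- if (out_w == 1L) rep(1, 1) else seq(1, w, length.out = out_w)
  y0 <- pmin(floor(ys), h - 1L); y0 <- pmax(y0, 1L); fy <- ys - y0
  x0 <- pmin(floor(xs), w - 1L); x0 <- pmax(x0, 1L); fx <- xs - x0
  if (h == 1L) { y0 <- rep(1L, out_h); fy <- rep(0, out_h) }
  if (w == 1L) { x0 <- rep(1L, out_w); fx <- rep(0, out_w) }
  a <- m[y0, x0, drop = FALSE]; b <- m[pmin(y0 + 1, h), x0, drop = FALSE]
  cc <- m[y0, pmin(x0 + 1, w), drop = FALSE]
  d <- m[pmin(y0 + 1, h), pmin(x0 + 1, w), drop = FALSE]
  fyM <- matrix(fy, out_h, out_w); fxM <- matrix(fx, out_h, out_w, byrow = TRUE)
  a * (1 - fyM) * (1 - fxM) + b * fyM * (1 - fxM) +
    cc * (1 - fyM) * fxM + d * fyM * fxM
}

#' Label connected components of a binary mask
#'
#' 8-connectivity by default (the convention used for blob counting in the
#' patch filter and the nucleus segmentation); 4-connectivity available.
#' Built on EBImage's flood-fill labelling with a union-find merge of
#' diagonal touches.
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels (0 = background, 1..n components).
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m)) # 4-connected labels
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8L && max(lab) > 1L) {
    n <- max(lab)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
    nr <- nrow(lab); nc <- ncol(lab)
    # diagonal neighbour pairs: (r, c) with (r+1, c+1) and (r+1, c-1)
    a <- lab[-nr, -nc]; b <- lab[-1, -1]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) for (k in which(sel)) unite(a[k], b[k])
    a <- lab[-nr, -1]; b <- lab[-1, -nc]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) for (k in which(sel)) unite(a[k], b[k])
    root <- vapply(seq_len(n), find, integer(1))
    dense <- match(root, sort(unique(root)))
    lab[lab > 0L] <- dense[lab[lab > 0L]]
  }
  lab
}

# Clamp numeric values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Format a numeric matrix as a TSV string with stable formatting, so that
# reruns with identical inputs are byte-identical on disk.
format_tsv_matrix <- function(m, digits = 6) {
  rn <- rownames(m); cn <- colnames(m)
  body <- apply(m, 1, function(r) paste(formatC(r, digits = digits, format = "f"),
                                        collapse = "\t"))
  paste0(paste(c("", cn), collapse = "\t"), "\n",
         paste(paste(rn, body, sep = "\t"), collapse = "\n"), "\n")
}
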