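# Model specification and construction: a backbone (compact 3-block CNN
# for desk-scale work, or an 18-layer residual network for full-scale
# runs) topped by a configurable fully connected head ending in 2 logits
# (normal vs cancer).

#' Specify a patch classifier architecture
#'
#' @param backbone `"small_cnn"` (three conv/pool blocks, the default for
#'   desk-scale datasets) or `"resnet18"` (standard 18-layer residual
#'   network).
#' @param pretrained logical; request externally pretrained backbone
#'   weights.  No weight files ship with this package, so
#'   [build_model()] refuses with advice to fall back to random
#'   initialization.
#' @param fcn_layers number of hidden fully connected layers (1-3).
#' @param fcn_widths hidden widths, one per layer, each in [4, 128].
#' @param fcn_dropouts dropout probabilities, one per layer, each in
#'   [0.2, 0.5] (0 allowed to disable).
#' @param input_size expected square input side in pixels.
#' @param channels convolutional widths of the small_cnn blocks.
#' @return an object of class `model_spec` (output dimension fixed at 2).
#' @export
model_spec <- function(backbone = c("small_cnn", "resnet18"),
                       pretrained = FALSE,
                       fcn_layers = 1L,
                       fcn_widths = 16L,
                       fcn_dropouts = 0.25,
                       input_size = 64L,
                       channels = c(6L, 12L, 24L)) {
  backbone <- match.arg(backbone)
  fcn_layers <- as.integer(fcn_layers)
  stopifnot(fcn_layers >= 1L, fcn_layers <= 3L,
            length(fcn_widths) == fcn_layers,
            length(fcn_dropouts) == fcn_layers,
            all(fcn_widths >= 4), all(fcn_widths <= 128),
            all(fcn_dropouts >= 0), all(fcn_dropouts <= 0.5),
            input_size >= 32, length(channels) == 3L)
  structure(list(backbone = backbone, pretrained = pretrained,
                 fcn_layers = fcn_layers,
                 fcn_widths = as.integer(fcn_widths),
                 fcn_dropouts = fcn_dropouts,
                 output_dim = 2L,
                 input_size = as.integer(input_size),
                 channels = as.integer(channels)),
            class = "model_spec")
}

#' Build a classifier network from a specification
#'
#' @param spec a `model_spec`.
#' @param seed integer seed for weight initialization (NULL = current
#'   RNG stream).
#' @return an object of class `nn_net`: the layer graph, the name of the
#'   final convolutional activation used for class-activation maps
#'   (`cam_layer`), the name of the pooled embedding layer
#'   (`embed_layer`), and the trainable parameter count.
#' @export
build_model <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (isTRUE(spec$pretrained))
    stop("pretrained backbone weights are not available offline; ",
         "build with pretrained = FALSE to use random initialization")
  with_seed(seed, {
    if (spec$backbone == "small_cnn") {
      ch <- spec$channels
      layers <- list(
        layer_conv("conv1", 3L, ch[1]), layer_relu("relu1"), layer_pool("pool1"),
        layer_conv("conv2", ch[1], ch[2]), layer_relu("relu2"), layer_pool("pool2"),
        layer_conv("conv3", ch[2], ch[3]), layer_relu("relu3"), layer_pool("pool3"),
        layer_gap("gap"))
      feat <- ch[3]
      cam_layer <- "relu3"
    } else {
      layers <- list(
        layer_conv("stem", 3L, 64L, k = 7L, stride = 2L, pad = 3L),
        layer_bn("stem_bn", 64L), layer_relu("stem_relu"),
        layer_pool("stem_pool", k = 3L, stride = 2L, pad = 1L),
        layer_resblock("l1b1", 64L, 64L), layer_resblock("l1b2", 64L, 64L),
        layer_resblock("l2b1", 64L, 128L, stride = 2L),
        layer_resblock("l2b2", 128L, 128L),
        layer_resblock("l3b1", 128L, 256L, stride = 2L),
        layer_resblock("l3b2", 256L, 256L),
        layer_resblock("l4b1", 256L, 512L, stride = 2L),
        layer_resblock("l4b2", 512L, 512L),
        layer_gap("gap"))
      feat <- 512L
      cam_layer <- "l4b2"
    }
    in_f <- feat
    for (j in seq_len(spec$fcn_layers)) {
      layers <- c(layers, list(
        layer_dense(paste0("fc", j), in_f, spec$fcn_widths[j]),
        layer_relu(paste0("fc", j, "_relu")),
        layer_dropout(paste0("fc", j, "_drop"), spec$fcn_dropouts[j])))
      in_f <- spec$fcn_widths[j]
    }
    layers <- c(layers, list(layer_dense("logits", in_f, 2L,
                                         init_scale = sqrt(1 / in_f))))
    net <- structure(list(layers = layers, spec = spec,
                          cam_layer = cam_layer, embed_layer = "gap"),
                     class = "nn_net")
    net$n_params <- sum(vapply(nn_params(net), length, numeric(1)))
    net
  })
}

#' @export
print.nn_net <- function(x, ...) {
  cat("CNN patch classifier (", x$spec$backbone, ")\n", sep = "")
  cat("  input:", x$spec$input_size, "x", x$spec$input_size, "x 3\n")
  cat("  head:", paste(x$spec$fcn_widths, collapse = "-"), "-> 2 logits\n")
  cat("  parameters:", format(x$n_params, big.mark = ","),
      "| CAM layer:", x$cam_layer, "\n")
  invisible(x)
}

#' Layer names of a network
#' @param net an `nn_net`.
#' @return character vector of layer names in forward order.
#' @export
layer_names <- function(net) vapply(net$layers, `[[`, "", "name")

# Stack a list of H x W x 3 images (0-255) into a (H, W, 3, N) batch,
# standardized to [0, 1] and then by per-channel statistics when given.
as_image_batch <- function(images, norm_stats = NULL) {
  if (inherits(images, "patch_record")) images <- list(images)
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  imgs <- lapply(images, function(p)
    if (inherits(p, "patch_record")) p$image else p)
  d <- dim(imgs[[1]])
  x <- array(0, c(d[1], d[2], 3L, length(imgs)))
  for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]] / 255
  if (!is.null(norm_stats))
    for (ch in 1:3)
      x[, , ch, ] <- (x[, , ch, ] - norm_stats$mean[ch]) / norm_stats$sd[ch]
  x
}

# Per-channel mean/sd over a list of images (0-255 scale mapped to [0,1]).
channel_stats <- function(images) {
  imgs <- lapply(images, function(p)
    if (inherits(p, "patch_record")) p$image else p)
  m <- s <- numeric(3)
  for (ch in 1:3) {
    v <- unlist(lapply(imgs, function(im) as.vector(im[, , ch]))) / 255
    m[ch] <- mean(v); s[ch] <- stats::sd(v)
  }
  list(mean = m, sd = pmax(s, 1e-6))
}
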