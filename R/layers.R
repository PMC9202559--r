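# VGG19 architecture registry and exact parameter accounting.
# The standard ImageNet configuration: conv blocks of (2, 2, 4, 4, 4)
# layers with (64, 128, 256, 512, 512) channels, all 3x3 kernels with
# padding 1, five 2x2/stride-2 max-pools, then FC 4096-4096-1000 and a
# softmax.  16 convolutional + 3 fully connected = 19 weight-bearing
# layers; 143,667,240 trainable parameters in total, of which the conv
# stack holds 20,024,384.

VGG_BLOCKS <- list(c(2L, 64L), c(2L, 128L), c(4L, 256L), c(4L, 512L), c(4L, 512L))

#' Build the standard VGG19 ImageNet classifier (layer registry)
#'
#' Returns an enumerable registry of the 19-weight-layer VGG19
#' architecture.  Weight values are not bundled; `pretrained` is a hook for
#' loading externally obtained ImageNet weights from an RDS file.
#'
#' @param pretrained if TRUE, attach weights from `weights_path`.
#' @param weights_path optional RDS file with a named list of weight arrays.
#' @param input_size input edge length in pixels (default 224).
#' @param in_channels input channels (default 3).
#' @return object of class `vgg19_classifier` with a `layers` data.frame
#'   (name, type, kernel, c_in, c_out, n_params).
#' @export
build_vgg19_classifier <- function(pretrained = FALSE, weights_path = NULL,
                                   input_size = 224L, in_channels = 3L) {
  rows <- list()
  cin <- as.integer(in_channels)
  res <- as.integer(input_size)
  for (b in seq_along(VGG_BLOCKS)) {
    nconv <- VGG_BLOCKS[[b]][1]; cout <- VGG_BLOCKS[[b]][2]
    for (k in seq_len(nconv)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("conv%d_%d", b, k), type = "conv", kernel = 3L,
        c_in = cin, c_out = cout, n_params = 9L * cin * cout + cout)
      cin <- cout
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("pool%d", b), type = "maxpool", kernel = 2L,
      c_in = cin, c_out = cin, n_params = 0L)
    res <- res %/% 2L
  }
  fc_in <- res * res * cin          # 7*7*512 = 25088 at 224
  fc_dims <- c(fc_in, 4096L, 4096L, 1000L)
  for (k in 1:3) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("fc%d", k), type = "fc", kernel = NA_integer_,
      c_in = fc_dims[k], c_out = fc_dims[k + 1],
      n_params = fc_dims[k] * fc_dims[k + 1] + fc_dims[k + 1])
  }
  rows[[length(rows) + 1L]] <- data.frame(
    name = "softmax", type = "softmax", kernel = NA_integer_,
    c_in = 1000L, c_out = 1000L, n_params = 0L)
  layers <- do.call(rbind, rows)
  weights <- NULL
  if (isTRUE(pretrained)) {
    if (is.null(weights_path)) {
      warning("ImageNet weight values are not bundled; returning architecture only")
    } else {
      weights <- readRDS(weights_path)
    }
  }
  structure(list(layers = layers, weights = weights,
                 input_size = as.integer(input_size)),
            class = "vgg19_classifier")
}

#' @export
print.vgg19_classifier <- function(x, ...) {
  cat(sprintf("<vgg19_classifier> %d layers (%d conv, %d fc), %s parameters\n",
              nrow(x$layers), sum(x$layers$type == "conv"),
              sum(x$layers$type == "fc"),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact integer count of trainable scalars, decomposable per layer via the
#' `by_layer` attribute / registry.
#'
#' @param x a `vgg19_classifier` or `attnseg_net`.
#' @param ... passed to methods.
#' @return numeric scalar (counts can exceed 32-bit integer range).
#' @export
count_parameters <- function(x, ...) UseMethod("count_parameters")

#' @rdname count_parameters
#' @param conv_only for `vgg19_classifier`: count only the convolutional
#'   stack (the fully connected layers discarded, as in the segmenter
#'   encoder).
#' @export
count_parameters.vgg19_classifier <- function(x, conv_only = FALSE, ...) {
  keep <- if (conv_only) x$layers$type == "conv" else TRUE
  sum(as.numeric(x$layers$n_params[keep]))
}
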