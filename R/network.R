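# The segmentation network: VGG19 convolutional encoder (FC layers
# discarded), five-stage U-Net decoder whose skip connections pass through
# softmax-normalized spatial attention gates, and a 1x1-conv + per-pixel
# softmax head over K classes.
#
# Implementation notes.  Feature maps live as (B*H*W) x C matrices in
# column-major pixel order (see src/kernels.cpp); convolution is im2col +
# matrix multiply.  Per the source description each conv is followed by
# ReLU and then batch normalization; BN statistics are taken over
# batch-and-space (population variance) with running buffers for
# inference.  The attention gate computes, per skip feature map,
#   score_j = V' tanh(U e_j + W o_j),   alpha = softmax(score),
# with sum(alpha) = 1 over the n spatial locations; the gated skip is
# (n * alpha_j) * e_j so a uniform alpha is the identity, and the context
# C_t = sum_j alpha_j e_j is exposed by attention_gate().

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

.ch <- function(c, w) max(1L, as.integer(round(c * w)))

#' Network configuration
#'
#' @param input_size input edge length, pixels; must be divisible by 32
#'   (five pooling stages). Default 224.
#' @param in_channels input channels (the four MRI modalities). Default 4.
#' @param num_classes K, number of output classes. Default 4.
#' @param width_factor channel multiplier in (0, 1] for desk-scale runs.
#' @param pretrained_encoder hook for ImageNet-initialized encoder weights
#'   (channel-averaged then replicated first conv); requires
#'   `encoder_weights_path`.
#' @param attention_enabled gate the skip connections (default TRUE).
#' @param encoder_weights_path optional RDS file of encoder weights.
#' @return object of class `network_config`.
#' @export
network_config <- function(input_size = 224L, in_channels = 4L,
                           num_classes = 4L, width_factor = 1,
                           pretrained_encoder = FALSE,
                           attention_enabled = TRUE,
                           encoder_weights_path = NULL) {
  input_size <- as.integer(input_size)
  if (input_size %% 32L != 0L)
    validation_error("input_size must be divisible by 32 (five pooling stages)")
  if (num_classes < 2L) validation_error("num_classes must be >= 2")
  if (width_factor <= 0 || width_factor > 1)
    validation_error("width_factor must be in (0, 1]")
  structure(list(input_size = input_size, in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 width_factor = width_factor,
                 pretrained_encoder = isTRUE(pretrained_encoder),
                 attention_enabled = isTRUE(attention_enabled),
                 encoder_weights_path = encoder_weights_path),
            class = "network_config")
}

# architecture table: every conv layer (name, cin, cout, kernel), the
# attention gates (ce = skip channels, cd = decoder channels, m = inner
# dim), and the head
segmenter_arch <- function(config) {
  w <- config$width_factor
  convs <- list(); gates <- list()
  cin <- config$in_channels
  skip_ch <- integer(5)
  for (b in 1:5) {
    nconv <- VGG_BLOCKS[[b]][1]; cout <- .ch(VGG_BLOCKS[[b]][2], w)
    for (k in seq_len(nconv)) {
      convs[[length(convs) + 1L]] <-
        list(name = sprintf("enc%d_%d", b, k), cin = cin, cout = cout, kernel = 3L)
      cin <- cout
    }
    skip_ch[b] <- cout
  }
  bottom <- skip_ch[5]
  x_ch <- bottom
  for (d in 5:1) {
    ce <- skip_ch[d]
    if (config$attention_enabled)
      gates[[length(gates) + 1L]] <-
        list(name = sprintf("gate%d", d), ce = ce, cd = x_ch,
             m = max(4L, ce %/% 2L))
    cat_ch <- x_ch + ce
    convs[[length(convs) + 1L]] <-
      list(name = sprintf("dec%d_1", d), cin = cat_ch, cout = ce, kernel = 3L)
    convs[[length(convs) + 1L]] <-
      list(name = sprintf("dec%d_2", d), cin = ce, cout = ce, kernel = 3L)
    x_ch <- ce
  }
  list(convs = convs, gates = gates, skip_ch = skip_ch,
       head = list(cin = x_ch, cout = config$num_classes))
}

#' Build the attention-gated VGG19 U-Net segmenter
#'
#' @param config a [network_config()].
#' @param seed RNG seed for weight initialization.
#' @param init allocate and initialize weights (default TRUE).  With
#'   `init = FALSE` only the architecture is built; parameter counts are
#'   still exact.
#' @return object of class `attnseg_net`.
#' @export
build_segmenter <- function(config = network_config(), seed = 1L, init = TRUE) {
  if (!inherits(config, "network_config"))
    validation_error("config must be a network_config")
  arch <- segmenter_arch(config)
  params <- NULL; bn <- NULL
  if (init) {
    set.seed(as.integer(seed))
    params <- list(); bn <- list()
    for (cv in arch$convs) {
      fan_in <- cv$kernel^2 * cv$cin
      params[[paste0(cv$name, ".W")]] <-
        matrix(rnorm(cv$kernel^2 * cv$cin * cv$cout, 0, sqrt(2 / fan_in)),
               cv$kernel^2 * cv$cin, cv$cout)
      params[[paste0(cv$name, ".b")]] <- numeric(cv$cout)
      params[[paste0(cv$name, ".gamma")]] <- rep(1, cv$cout)
      params[[paste0(cv$name, ".beta")]] <- numeric(cv$cout)
      bn[[paste0(cv$name, ".mean")]] <- numeric(cv$cout)
      bn[[paste0(cv$name, ".var")]] <- rep(1, cv$cout)
    }
    for (g in arch$gates) {
      params[[paste0(g$name, ".U")]] <-
        matrix(rnorm(g$ce * g$m, 0, sqrt(1 / g$ce)), g$ce, g$m)
      params[[paste0(g$name, ".Wg")]] <-
        matrix(rnorm(g$cd * g$m, 0, sqrt(1 / g$cd)), g$cd, g$m)
      # V starts at zero: uniform attention, the gate is the identity
      params[[paste0(g$name, ".V")]] <- matrix(0, g$m, 1L)
    }
    params[["head.W"]] <- matrix(rnorm(arch$head$cin * arch$head$cout, 0,
                                       sqrt(2 / arch$head$cin)),
                                 arch$head$cin, arch$head$cout)
    params[["head.b"]] <- numeric(arch$head$cout)
    if (config$pretrained_encoder && !is.null(config$encoder_weights_path)) {
      pre <- readRDS(config$encoder_weights_path)
      for (nm in intersect(names(pre), names(params))) params[[nm]] <- pre[[nm]]
    }
  }
  structure(list(config = config, arch = arch, params = params, bn = bn,
                 opt = NULL, step = 0L),
            class = "attnseg_net")
}

#' @export
print.attnseg_net <- function(x, ...) {
  cat(sprintf(
    "<attnseg_net> input %dx%dx%d, K=%d, width %.3g, attention %s\n  conv layers: %d, parameters: %s%s\n",
    x$config$input_size, x$config$input_size, x$config$in_channels,
    x$config$num_classes, x$config$width_factor,
    if (x$config$attention_enabled) "on" else "off",
    length(x$arch$convs), format(count_parameters(x), big.mark = ","),
    if (is.null(x$params)) " (not initialized)" else ""))
  invisible(x)
}

#' @rdname count_parameters
#' @param encoder_only for `attnseg_net`: count only the VGG19 encoder
#'   conv stack (excluding its batch-norm scale/shift).
#' @param include_bn include batch-norm gamma/beta (default TRUE; ignored
#'   when `encoder_only`).
#' @export
count_parameters.attnseg_net <- function(x, encoder_only = FALSE,
                                         include_bn = TRUE, ...) {
  total <- 0
  for (cv in x$arch$convs) {
    if (encoder_only && !startsWith(cv$name, "enc")) next
    total <- total + cv$kernel^2 * cv$cin * cv$cout + cv$cout
    if (!encoder_only && include_bn) total <- total + 2 * cv$cout
  }
  if (!encoder_only) {
    for (g in x$arch$gates) total <- total + g$ce * g$m + g$cd * g$m + g$m
    total <- total + x$arch$head$cin * x$arch$head$cout + x$arch$head$cout
  }
  total
}

# ---- forward ----

.conv_fwd <- function(params, bn, name, X, H, W, B, training, cache) {
  Wm <- params[[paste0(name, ".W")]]
  Z <- conv3x3_forward(X, Wm, params[[paste0(name, ".b")]], H, W, B)
  A <- Z * (Z > 0)                                   # ReLU
  if (training) {
    mu <- colMeans(A)
    v <- colMeans(A * A) - mu^2
    bn[[paste0(name, ".mean")]] <- (1 - BN_MOMENTUM) * bn[[paste0(name, ".mean")]] +
      BN_MOMENTUM * mu
    bn[[paste0(name, ".var")]] <- (1 - BN_MOMENTUM) * bn[[paste0(name, ".var")]] +
      BN_MOMENTUM * v
  } else {
    mu <- bn[[paste0(name, ".mean")]]
    v <- bn[[paste0(name, ".var")]]
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  ba <- bn_apply(A, mu, invstd, params[[paste0(name, ".gamma")]],
                 params[[paste0(name, ".beta")]])
  cache[[name]] <- list(X = X, relu = Z > 0, xhat = ba$xhat,
                        invstd = invstd, training = training)
  list(out = ba$out, bn = bn, cache = cache)
}

.attn_fwd <- function(params, name, e, o, B, cache) {
  U <- params[[paste0(name, ".U")]]
  Wg <- params[[paste0(name, ".Wg")]]
  V <- params[[paste0(name, ".V")]]
  h <- e %*% U + o %*% Wg
  tt <- tanh(h)
  s <- tt %*% V                    # (B*N) x 1
  N <- nrow(e) / B
  alpha <- numeric(nrow(e))
  for (b in seq_len(B)) {
    rows <- ((b - 1) * N + 1):(b * N)
    sb <- s[rows, 1]
    ex <- exp(sb - max(sb))
    alpha[rows] <- ex / sum(ex)
  }
  a <- N * alpha
  gated <- e * a
  cache[[name]] <- list(tt = tt, alpha = alpha, a = a, e = e, o = o, N = N)
  list(gated = gated, cache = cache)
}

# X: (B*H*W) x in_channels stacked input.  Returns probs plus the caches
# needed for the backward pass.
net_forward <- function(net, X, B, training = FALSE) {
  cfg <- net$config; arch <- net$arch
  H <- W <- as.integer(sqrt(nrow(X) / B))
  if (H * W * B != nrow(X) || ncol(X) != cfg$in_channels)
    contract_error("input shape does not match the network configuration")
  if (H %% 32L != 0L) contract_error("input size must be divisible by 32")
  params <- net$params; bn <- net$bn
  cache <- list(); skips <- list(); pool_idx <- list(); dims <- list()
  x <- X; h <- H; w <- W
  ci <- 1L
  for (b5 in 1:5) {
    nconv <- VGG_BLOCKS[[b5]][1]
    for (k in seq_len(nconv)) {
      cv <- arch$convs[[ci]]; ci <- ci + 1L
      r <- .conv_fwd(params, bn, cv$name, x, h, w, B, training, cache)
      x <- r$out; bn <- r$bn; cache <- r$cache
    }
    skips[[b5]] <- x; dims[[b5]] <- c(h, w)
    pl <- maxpool2(x, h, w, B)
    x <- pl$out; pool_idx[[b5]] <- pl$idx
    h <- h %/% 2L; w <- w %/% 2L
  }
  gi <- 1L
  att <- list()
  for (d in 5:1) {
    xu <- upsample2(x, h, w, B); h <- 2L * h; w <- 2L * w
    e <- skips[[d]]
    if (cfg$attention_enabled) {
      g <- arch$gates[[gi]]; gi <- gi + 1L
      r <- .attn_fwd(params, g$name, e, xu, B, cache)
      gated <- r$gated; cache <- r$cache
    } else gated <- e
    xc <- cbind(xu, gated)
    for (k in 1:2) {
      cv <- arch$convs[[ci]]; ci <- ci + 1L
      r <- .conv_fwd(params, bn, cv$name, xc, h, w, B, training, cache)
      xc <- r$out; bn <- r$bn; cache <- r$cache
    }
    x <- xc
  }
  logits <- sweep(x %*% params[["head.W"]], 2L, params[["head.b"]], `+`)
  mx <- logits[, 1L]
  for (k in seq_len(ncol(logits))[-1L]) mx <- pmax(mx, logits[, k])
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(probs = probs, logits = logits, cache = cache, skip_cache = skips,
       pool_idx = pool_idx, dims = dims, head_in = x, bn = bn, H = H, B = B)
}

.conv_bwd <- function(params, name, dOut, cache, h, w, B, grads) {
  cc <- cache[[name]]
  bb <- bn_backward(dOut, cc$xhat, params[[paste0(name, ".gamma")]],
                    cc$invstd, cc$training)
  grads[[paste0(name, ".gamma")]] <- bb$dgamma
  grads[[paste0(name, ".beta")]] <- bb$dbeta
  dZ <- bb$dA * cc$relu
  Wm <- params[[paste0(name, ".W")]]
  r <- conv3x3_backward(dZ, cc$X, Wm, h, w, B)
  grads[[paste0(name, ".W")]] <- r$dW
  grads[[paste0(name, ".b")]] <- r$db
  list(dX = r$dX, grads = grads)
}

.attn_bwd <- function(params, name, dgated, cache, B, grads) {
  cc <- cache[[name]]
  U <- params[[paste0(name, ".U")]]
  Wg <- params[[paste0(name, ".Wg")]]
  V <- params[[paste0(name, ".V")]]
  N <- cc$N
  de <- dgated * cc$a
  dalpha <- N * rowSums(dgated * cc$e)
  ds <- numeric(length(dalpha))
  for (b in seq_len(B)) {
    rows <- ((b - 1) * N + 1):(b * N)
    ab <- cc$alpha[rows]; dab <- dalpha[rows]
    ds[rows] <- ab * (dab - sum(ab * dab))
  }
  dtt <- ds %*% t(V)                       # outer product, (BN) x m
  grads[[paste0(name, ".V")]] <- crossprod(cc$tt, matrix(ds, ncol = 1L))
  dh <- dtt * (1 - cc$tt^2)
  grads[[paste0(name, ".U")]] <- crossprod(cc$e, dh)
  grads[[paste0(name, ".Wg")]] <- crossprod(cc$o, dh)
  de <- de + dh %*% t(U)
  do <- dh %*% t(Wg)
  list(de = de, do = do, grads = grads)
}

# dlogits: gradient of the loss w.r.t. the pre-softmax head output.
net_backward <- function(net, fwd, dlogits) {
  cfg <- net$config; arch <- net$arch
  params <- net$params
  B <- fwd$B
  grads <- list()
  grads[["head.W"]] <- crossprod(fwd$head_in, dlogits)
  grads[["head.b"]] <- colSums(dlogits)
  dx <- dlogits %*% t(params[["head.W"]])

  ci <- length(arch$convs)
  gi <- length(arch$gates)
  dskip <- vector("list", 5L)
  # decoder stages were run d = 5..1; reverse: d = 1..5
  for (d in 1:5) {
    hw <- fwd$dims[[d]]
    for (k in 2:1) {
      cv <- arch$convs[[ci]]; ci <- ci - 1L
      r <- .conv_bwd(params, cv$name, dx, fwd$cache, hw[1], hw[2], B, grads)
      dx <- r$dX; grads <- r$grads
    }
    cd <- if (d == 5) arch$skip_ch[5] else arch$skip_ch[d + 1L]
    dxu <- dx[, seq_len(cd), drop = FALSE]
    dgated <- dx[, cd + seq_len(arch$skip_ch[d]), drop = FALSE]
    if (cfg$attention_enabled) {
      g <- arch$gates[[gi]]; gi <- gi - 1L
      r <- .attn_bwd(params, g$name, dgated, fwd$cache, B, grads)
      dskip[[d]] <- r$de
      dxu <- dxu + r$do
      grads <- r$grads
    } else {
      dskip[[d]] <- dgated
    }
    dx <- upsample2_backward(dxu, hw[1] %/% 2L, hw[2] %/% 2L, B)
  }
  # encoder, stages 5..1
  for (b5 in 5:1) {
    hw <- fwd$dims[[b5]]
    nrowX <- hw[1] * hw[2] * B
    dx <- maxpool2_backward(dx, fwd$pool_idx[[b5]], nrowX) + dskip[[b5]]
    for (k in seq_len(VGG_BLOCKS[[b5]][1])) {
      cv <- arch$convs[[ci]]; ci <- ci - 1L
      r <- .conv_bwd(params, cv$name, dx, fwd$cache, hw[1], hw[2], B, grads)
      dx <- r$dX; grads <- r$grads
    }
  }
  grads
}

#' Run the segmenter forward on a stack of patches
#'
#' @param net an initialized `attnseg_net`.
#' @param images list of H x W x C arrays (H = W = `input_size`), or a
#'   single such array.
#' @param training use batch statistics and keep caches (internal).
#' @return list of H x W x K probability arrays (per-pixel softmax).
#' @export
segmenter_forward <- function(net, images, training = FALSE) {
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  B <- length(images)
  H <- dim(images[[1]])[1]
  X <- do.call(rbind, lapply(images, function(im) {
    matrix(im, nrow = prod(dim(im)[1:2]), ncol = dim(im)[3])
  }))
  fwd <- net_forward(net, X, B, training = training)
  lapply(seq_len(B), function(b) {
    rows <- ((b - 1) * H * H + 1):(b * H * H)
    array(fwd$probs[rows, ], dim = c(H, H, net$config$num_classes))
  })
}

# ---- standalone attention gate (Algorithm-level op) ----

#' Attention gate parameters
#'
#' @param U matrix (Ce x m): transform of the encoder feature.
#' @param W matrix (Cd x m): transform of the decoder state.
#' @param V matrix (m x 1) or length-m vector: projection to a scalar
#'   score per location.
#' @return object of class `attention_gate_params`.
#' @export
attention_gate_params <- function(U, W, V) {
  U <- as.matrix(U); W <- as.matrix(W); V <- matrix(as.numeric(V), ncol = 1L)
  if (ncol(U) != ncol(W) || ncol(U) != nrow(V))
    validation_error("U and W must map into a common dimensionality matched by V")
  structure(list(U = U, W = W, V = V), class = "attention_gate_params")
}

#' Softmax spatial attention gate
#'
#' Computes per-location scores `score_j = V' tanh(U e_j + W o_j)`,
#' normalizes them with a softmax over the spatial locations
#' (`alpha_j >= 0`, `sum_j alpha_j = 1`), and returns the weighted context
#' `C_t = sum_j alpha_j e_j` together with the gated skip feature
#' `(n * alpha_j) * e_j` (`n` = number of locations, so uniform attention
#' is the identity).
#'
#' The "previously predicted label" input of the sequential formulation has
#' no wiring in a feed-forward pass and is not an argument here; the
#' decoder state `o` plays the conditioning role.
#'
#' @param e encoder feature map, H x W x Ce array (or n x Ce matrix).
#' @param o decoder state aligned to `e`'s grid, H x W x Cd array (or
#'   n x Cd matrix).
#' @param params an [attention_gate_params()].
#' @return list with `alphas` (H x W matrix or length-n vector),
#'   `context` (length-Ce vector) and `gated` (same shape as `e`).
#' @export
attention_gate <- function(e, o, params) {
  if (!inherits(params, "attention_gate_params"))
    validation_error("params must be attention_gate_params")
  spatial <- NULL
  if (is.array(e) && length(dim(e)) == 3L) {
    spatial <- dim(e)[1:2]
    if (!is.array(o) || length(dim(o)) != 3L ||
        !identical(dim(o)[1:2], spatial))
      contract_error("e and o must be spatially aligned")
    e <- matrix(e, prod(spatial), dim(e)[3])
    o <- matrix(o, prod(spatial), dim(o)[3])
  } else {
    e <- as.matrix(e); o <- as.matrix(o)
    if (nrow(e) != nrow(o)) contract_error("e and o must be spatially aligned")
  }
  if (ncol(e) != nrow(params$U) || ncol(o) != nrow(params$W))
    contract_error("channel dimensions do not match the gate parameters")
  s <- tanh(e %*% params$U + o %*% params$W) %*% params$V
  ex <- exp(s - max(s))
  alpha <- as.numeric(ex / sum(ex))
  context <- as.numeric(crossprod(e, alpha))
  gated <- e * (length(alpha) * alpha)
  if (!is.null(spatial)) {
    alphas <- matrix(alpha, spatial[1], spatial[2])
    gated <- array(gated, dim = c(spatial, ncol(e)))
  } else alphas <- alpha
  list(alphas = alphas, context = context, gated = gated)
}
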