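# Training: per-pixel categorical cross-entropy minimized with Adam.
# Everything is seeded; a run with the same RunConfig and seed reproduces
# the same loss curve and weights bit-for-bit.

ADAM_BETA1 <- 0.9
ADAM_BETA2 <- 0.999
ADAM_EPS <- 1e-8

# cross-entropy over pixels; targets are 0-based class labels
.ce_loss <- function(probs, targets) {
  n <- nrow(probs)
  idx <- cbind(seq_len(n), targets + 1L)
  p <- pmax(probs[idx], 1e-12)
  loss <- -mean(log(p))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n)
}

.adam_step <- function(net, grads, lr) {
  if (is.null(net$opt))
    net$opt <- list(m = lapply(net$params, function(p) p * 0),
                    v = lapply(net$params, function(p) p * 0))
  net$step <- net$step + 1L
  t <- net$step
  for (nm in names(grads)) {
    g <- grads[[nm]]
    net$opt$m[[nm]] <- ADAM_BETA1 * net$opt$m[[nm]] + (1 - ADAM_BETA1) * g
    net$opt$v[[nm]] <- ADAM_BETA2 * net$opt$v[[nm]] + (1 - ADAM_BETA2) * g * g
    mhat <- net$opt$m[[nm]] / (1 - ADAM_BETA1^t)
    vhat <- net$opt$v[[nm]] / (1 - ADAM_BETA2^t)
    net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + ADAM_EPS)
  }
  net
}

# stack a list of H x W x C arrays into the (B*H*W) x C layout
.stack_images <- function(images) {
  do.call(rbind, lapply(images, function(im)
    matrix(im, prod(dim(im)[1:2]), dim(im)[3])))
}

#' Take one optimization step on a batch of patches
#'
#' @param net an initialized `attnseg_net`.
#' @param images list of H x W x C input arrays.
#' @param masks list of H x W integer label matrices (0-based classes).
#' @param lr Adam learning rate.
#' @return list with the updated `net` and the batch `loss`.
#' @export
train_step <- function(net, images, masks, lr = 1e-3) {
  X <- .stack_images(images)
  targets <- unlist(lapply(masks, as.integer), use.names = FALSE)
  fwd <- net_forward(net, X, length(images), training = TRUE)
  net$bn <- fwd$bn
  l <- .ce_loss(fwd$probs, targets)
  if (!is.finite(l$loss))
    numerical_error(sprintf(
      "non-finite training loss at step %d (lr=%g); inspect inputs or lower lr",
      net$step + 1L, lr))
  grads <- net_backward(net, fwd, l$dlogits)
  net <- .adam_step(net, grads, lr)
  list(net = net, loss = l$loss)
}

#' Train the segmenter on a set of patches
#'
#' @param net an initialized `attnseg_net` (fresh or resumed).
#' @param patches a `patch_set` (or list with `images`/`masks`).
#' @param steps number of optimization steps.
#' @param batch_size patches per step (sampled with replacement from the
#'   set each step).
#' @param lr Adam learning rate.
#' @param seed RNG seed for batch sampling.
#' @param verbose print loss every 20 steps.
#' @return list with `net` and `log` (data.frame step, loss).
#' @export
fit_segmenter <- function(net, patches, steps = 200L, batch_size = 8L,
                          lr = 1e-3, seed = 1L, verbose = FALSE) {
  n <- length(patches$images)
  if (n < 1L) data_error("empty patch set")
  set.seed(as.integer(seed))
  losses <- numeric(steps)
  for (s in seq_len(steps)) {
    ix <- if (n == 1L) rep(1L, batch_size) else
      sample.int(n, min(batch_size, n), replace = batch_size > n)
    r <- train_step(net, patches$images[ix], patches$masks[ix], lr = lr)
    net <- r$net
    losses[s] <- r$loss
    if (verbose && s %% 20L == 0L)
      message(sprintf("step %4d  loss %.4f", s, r$loss))
  }
  list(net = net, log = data.frame(step = seq_len(steps), loss = losses))
}

#' Save / load a network checkpoint
#'
#' The checkpoint is an RDS file with a JSON sidecar
#' (`<path>.config.json`) recording the network configuration.
#'
#' @param net an `attnseg_net`.
#' @param path checkpoint file path (`.rds`).
#' @return `path` (save) or the restored `attnseg_net` (load).
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(net, path)
  jsonlite::write_json(net$config[!vapply(net$config, is.null, TRUE)],
                       paste0(path, ".config.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "attnseg_net")) format_error("not an attnseg checkpoint")
  net
}
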