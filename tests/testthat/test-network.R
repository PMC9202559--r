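test_that("config invariants are enforced", {
  expect_error(network_config(input_size = 100L), class = "attnseg_validation_error")
  expect_error(network_config(num_classes = 1L), class = "attnseg_validation_error")
  expect_error(network_config(width_factor = 0), class = "attnseg_validation_error")
})

test_that("forward pass emits per-pixel probability distributions", {
  net <- tiny_net()
  set.seed(20)
  im <- array(rnorm(32 * 32 * 4), dim = c(32, 32, 4))
  p <- segmenter_forward(net, im)[[1]]
  expect_identical(dim(p), c(32L, 32L, 4L))
  expect_true(all(p >= 0))
  sums <- apply(p, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
})

test_that("attention-off variant preserves the output shape contract", {
  set.seed(21)
  im <- array(rnorm(32 * 32 * 4), dim = c(32, 32, 4))
  p_on <- segmenter_forward(tiny_net(attention = TRUE), im)[[1]]
  p_off <- segmenter_forward(tiny_net(attention = FALSE), im)[[1]]
  expect_identical(dim(p_off), dim(p_on))
})

test_that("softmax head is invariant to a constant logit shift", {
  net <- tiny_net()
  set.seed(22)
  im <- array(rnorm(32 * 32 * 4), dim = c(32, 32, 4))
  p1 <- segmenter_forward(net, im)[[1]]
  net$params[["head.b"]] <- net$params[["head.b"]] + 3.7
  p2 <- segmenter_forward(net, im)[[1]]
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("one optimization step decreases the loss on a phantom patch", {
  cs <- generate_phantom(small_spec(seed = 23L))
  ps <- extract_patches(cs, size = 32L, tumor_fraction = 1, seed = 23L)
  net <- build_segmenter(network_config(input_size = 32L, width_factor = 0.1),
                         seed = 23L)
  im <- ps$images[1]; mk <- ps$masks[1]
  r1 <- train_step(net, im, mk, lr = 1e-3)
  r2 <- train_step(r1$net, im, mk, lr = 1e-3)
  expect_lt(r2$loss, r1$loss)
})

test_that("network gradients match finite differences on smooth parameters", {
  set.seed(24)
  net <- build_segmenter(network_config(input_size = 32L, width_factor = 0.05),
                         seed = 24L)
  im <- array(rnorm(32 * 32 * 4), dim = c(32, 32, 4))
  mk <- matrix(sample(0:3, 32 * 32, TRUE), 32, 32)
  X <- matrix(im, 1024, 4)
  targets <- as.integer(mk)
  lossfn <- function(net) {
    fwd <- attnseg:::net_forward(net, X, 1L, training = TRUE)
    idx <- cbind(seq_len(nrow(fwd$probs)), targets + 1L)
    -mean(log(pmax(fwd$probs[idx], 1e-12)))
  }
  fwd <- attnseg:::net_forward(net, X, 1L, training = TRUE)
  idx <- cbind(seq_len(nrow(fwd$probs)), targets + 1L)
  dlog <- fwd$probs; dlog[idx] <- dlog[idx] - 1; dlog <- dlog / nrow(dlog)
  grads <- attnseg:::net_backward(net, fwd, dlog)
  # head and gate-V parameters have a smooth path to the loss; expect
  # near-exact agreement there (conv parameters cross ReLU kinks under
  # finite differences, checked during development with an h-sweep)
  for (nm in c("head.W", "head.b", "gate1.V", "dec1_2.beta")) {
    p <- net$params[[nm]]
    i <- which.max(abs(grads[[nm]]))
    h <- 1e-6
    n2 <- net; n2$params[[nm]][i] <- p[i] + h; lp <- lossfn(n2)
    n2$params[[nm]][i] <- p[i] - h; lm <- lossfn(n2)
    num <- (lp - lm) / (2 * h)
    expect_equal(as.numeric(grads[[nm]][i]), num, tolerance = 1e-4,
                 label = nm)
  }
})

test_that("checkpoints round-trip through RDS + JSON sidecar", {
  dir <- withr::local_tempdir()
  net <- tiny_net()
  p <- file.path(dir, "ckpt.rds")
  save_checkpoint(net, p)
  expect_true(file.exists(paste0(p, ".config.json")))
  back <- load_checkpoint(p)
  expect_identical(back$params, net$params)
  side <- jsonlite::read_json(paste0(p, ".config.json"))
  expect_equal(as.numeric(side$input_size), 32)
})
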