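# RunConfig and the end-to-end train/predict/evaluate orchestration.

#' Pipeline run configuration
#'
#' Bundles the network, MRF and training settings with the data source.
#' Serializable to/from JSON (see [read_run_config()]).
#'
#' @param network a [network_config()].
#' @param mrf an [mrf_config()].
#' @param training list: `lr` (Adam learning rate, default 1e-3 -- see the
#'   methods vignette), `batch_size` (8), `max_steps` (200), `loss`
#'   ("ce"), `seed`.
#' @param data list: either `case_dir` (directory of NIfTI cases) or
#'   `n_phantoms` + `phantom` (a [phantom_spec()]); plus `tumor_fraction`
#'   for patch sampling (default 0.5) and `patches_per_case`.
#' @param noise_in_training inject bipolar Gaussian noise onto training
#'   label maps as augmentation (default FALSE).
#' @param polish_at_inference run the MRF polish inside predict (default
#'   TRUE; no noise injection at inference).
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(network = network_config(),
                       mrf = mrf_config(),
                       training = list(),
                       data = list(),
                       noise_in_training = FALSE,
                       polish_at_inference = TRUE,
                       seed = 1L) {
  training <- modifyList(list(lr = 1e-3, batch_size = 8L, max_steps = 200L,
                              loss = "ce", seed = as.integer(seed)), training)
  data <- modifyList(list(n_phantoms = 3L, phantom = NULL, case_dir = NULL,
                          tumor_fraction = 0.5, patches_per_case = NULL),
                     data)
  if (!identical(training$loss, "ce"))
    validation_error("only the cross-entropy loss is implemented")
  structure(list(network = network, mrf = mrf, training = training,
                 data = data, noise_in_training = isTRUE(noise_in_training),
                 polish_at_inference = isTRUE(polish_at_inference),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file path.
#' @param config a [run_config()].
#' @return a `run_config` (read) or `path` invisibly (write).
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- do.call(network_config, as.list(j$network %||% list()))
  mrf <- do.call(mrf_config, as.list(j$mrf %||% list()))
  dat <- as.list(j$data %||% list())
  if (!is.null(dat$phantom)) {
    ph <- as.list(dat$phantom)
    if (!is.null(ph$tissue_means) && !is.matrix(ph$tissue_means))
      ph$tissue_means <- matrix(unlist(ph$tissue_means), 4L, 4L, byrow = TRUE)
    dat$phantom <- do.call(phantom_spec, ph)
  }
  run_config(network = net, mrf = mrf,
             training = as.list(j$training %||% list()),
             data = dat,
             noise_in_training = isTRUE(j$noise_in_training),
             polish_at_inference = !isFALSE(j$polish_at_inference),
             seed = j$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  drop_null <- function(x) {
    if (!is.list(x)) return(x)
    x <- x[!vapply(x, is.null, TRUE)]
    lapply(x, drop_null)
  }
  jsonlite::write_json(drop_null(unclass(lapply(config, function(x)
    if (inherits(x, c("network_config", "mrf_config"))) unclass(x) else x))),
    path, auto_unbox = TRUE)
  invisible(path)
}

# load the training cases named by a run_config
.load_cases <- function(config) {
  d <- config$data
  if (!is.null(d$case_dir)) {
    segs <- list.files(d$case_dir, pattern = "_seg\\.nii(\\.gz)?$",
                       full.names = TRUE)
    if (length(segs) == 0L) data_error("no *_seg.nii[.gz] cases found")
    lapply(segs, function(s) {
      id <- sub("_seg\\.nii(\\.gz)?$", "", s)
      ext <- sub(".*_seg", "", s)
      read_case(paste0(id, "_t1", ext), paste0(id, "_t1ce", ext),
                paste0(id, "_t2", ext), paste0(id, "_flair", ext),
                mask = s)
    })
  } else {
    spec <- d$phantom %||%
      phantom_spec(grid_shape = c(config$network$input_size,
                                  config$network$input_size, 16L))
    phantom_cohort(d$n_phantoms, spec, seed = config$seed)
  }
}

# pool class-balanced patches from every case
.build_patchset <- function(cases, config) {
  size <- config$network$input_size
  sets <- lapply(seq_along(cases), function(i)
    extract_patches(cases[[i]], size = size,
                    tumor_fraction = config$data$tumor_fraction,
                    n_patches = config$data$patches_per_case,
                    seed = config$seed + i))
  structure(list(
    images = do.call(c, lapply(sets, `[[`, "images")),
    masks = do.call(c, lapply(sets, `[[`, "masks")),
    provenance = do.call(rbind, lapply(sets, `[[`, "provenance"))
  ), class = "patch_set")
}

#' Train the full pipeline from a run configuration
#'
#' Loads (or generates) the cases, extracts class-balanced patches, builds
#' the network and optimizes it; optionally writes a checkpoint.
#'
#' @param config a [run_config()].
#' @param checkpoint optional path to save the trained network.
#' @param verbose print progress.
#' @return list with `net`, `log` (loss per step), `cases`, `patches`.
#' @export
train_pipeline <- function(config = run_config(), checkpoint = NULL,
                           verbose = FALSE) {
  cases <- .load_cases(config)
  if (length(cases) == 0L) data_error("empty dataset")
  patches <- .build_patchset(cases, config)
  if (config$noise_in_training) {
    # training-time regularizer: flip label-map pixels through the bipolar
    # Gaussian noise channel, class-wise
    for (i in seq_along(patches$masks)) {
      lab <- patches$masks[[i]]
      noisy <- lab
      for (cls in c(2L, 1L, 3L)) {
        bip <- matrix(ifelse(lab == cls, 1L, -1L), nrow(lab), ncol(lab))
        bip <- inject_noise(bip, config$mrf$sigma, seed = config$seed + 7L * i + cls)
        noisy[bip > 0 & lab == 0L] <- cls
        noisy[bip < 0 & lab == cls] <- 0L
      }
      patches$masks[[i]] <- noisy
    }
  }
  net <- build_segmenter(config$network, seed = config$seed)
  fit <- fit_segmenter(net, patches, steps = config$training$max_steps,
                       batch_size = config$training$batch_size,
                       lr = config$training$lr,
                       seed = config$training$seed, verbose = verbose)
  if (!is.null(checkpoint)) save_checkpoint(fit$net, checkpoint)
  list(net = fit$net, log = fit$log, cases = cases, patches = patches)
}

#' Predict and evaluate a trained pipeline on a set of cases
#'
#' @param net a trained `attnseg_net`.
#' @param cases list of `case_bundle`s with masks.
#' @param config a [run_config()] (controls the polish flags).
#' @return list with `predictions` (named list of label arrays) and
#'   `metrics` (the [evaluate_cases()] table).
#' @export
evaluate_pipeline <- function(net, cases, config = run_config()) {
  preds <- lapply(cases, function(cs)
    predict_segmentation(net, cs, polish = config$polish_at_inference,
                         mrf = config$mrf))
  names(preds) <- vapply(cases, `[[`, "", "case_id")
  truths <- lapply(cases, `[[`, "mask")
  names(truths) <- names(preds)
  list(predictions = preds, metrics = evaluate_cases(preds, truths))
}
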