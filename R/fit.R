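# Model-fitting front end.
#
# `lesion_segmenter()` is the package's main entry point in the classic
# fit-then-method idiom: it trains the two-stage model on a cohort and
# returns a classed object with print / summary / predict / plot / coef
# methods.

#' Fit a lesion segmentation model
#'
#' Builds the hybrid encoder-ViT-decoder network and trains it with the
#' two-stage schedule: contrastive latent pretraining of encoder + ViT,
#' then decoder fine-tuning with the composite Dice + CE + patch-focal
#' loss. Fully deterministic given `seed`.
#'
#' @param cohort A cohort: the manifest from [generate_cohort()], a
#'   `manifest.json` path, or a list of `list(image, mask)` patients.
#' @param net A [net_config()]; defaults to a desk-scale network sized
#'   to the first volume.
#' @param loss A [loss_config()].
#' @param clp A [clp_config()].
#' @param train A [train_config()].
#' @param seed Seed controlling initialization, sampling and shuffling.
#' @param verbose Print per-epoch losses.
#' @return An object of class `"lesion_segmenter"`.
#' @export
lesion_segmenter <- function(cohort, net = NULL, loss = loss_config(),
                             clp = clp_config(), train = train_config(),
                             seed = 1L, verbose = FALSE) {
  cl <- match.call()
  if (!is.list(cohort[[1]]) || is.null(cohort[[1]]$mask))
    cohort <- load_cohort(cohort)
  if (is.null(net))
    net <- net_config(input_shape = dim(cohort[[1]]$image)[1])
  network <- build_network(net, seed = seed)
  train$seed <- as.integer(seed)
  res <- run_two_stage(network, cohort, train, loss, clp, verbose = verbose)
  structure(list(net = res$net, traces = res$traces,
                 checkpoints = res$checkpoints,
                 config = list(net = net, loss = loss, clp = clp, train = train),
                 spacing = cohort[[1]]$spacing %||% c(1, 1, 1),
                 n_patients = length(cohort), seed = seed, call = cl),
            class = "lesion_segmenter")
}

#' @export
print.lesion_segmenter <- function(x, ...) {
  cat("Two-stage lesion segmentation model\n")
  cat("  call: ", deparse(x$call), "\n")
  cat(sprintf("  trained on %d volumes (seed %d)\n", x$n_patients, x$seed))
  print(x$net)
  pt <- x$traces$pretrain; ft <- x$traces$finetune
  if (!is.null(pt))
    cat(sprintf("  pretrain:  %d epochs, contrastive loss %.4f -> %.4f\n",
                nrow(pt), pt$loss[1], pt$loss[nrow(pt)]))
  if (!is.null(ft))
    cat(sprintf("  finetune:  %d epochs, composite loss %.4f -> %.4f\n",
                nrow(ft), ft$loss[1], ft$loss[nrow(ft)]))
  invisible(x)
}

#' Predict segmentations from a fitted model
#'
#' @param object A `"lesion_segmenter"`.
#' @param newdata A 3D array, a NIfTI path, or a list/cohort of
#'   patients.
#' @param type `"prob"` for per-voxel class probabilities, `"mask"` for
#'   the thresholded binary mask.
#' @param threshold Foreground threshold for `type = "mask"`.
#' @param ... Unused.
#' @return A single array, or a list of arrays for multiple inputs.
#' @export
predict.lesion_segmenter <- function(object, newdata, type = c("prob", "mask"),
                                     threshold = 0.5, ...) {
  type <- match.arg(type)
  one <- function(vol) {
    if (is.character(vol)) vol <- read_volume(vol)$data
    if (type == "prob") forward_segment(object$net, vol)
    else predict_mask(object$net, vol, threshold)
  }
  if (is.list(newdata) && !is.null(newdata[[1]]$image))
    return(lapply(newdata, function(p) one(p$image)))
  if (is.list(newdata) && !is.data.frame(newdata))
    return(lapply(newdata, one))
  one(newdata)
}

#' Summarize a fitted model on a cohort
#'
#' Runs inference on a cohort (by default nothing; pass `cohort`) and
#' reports lesion-level and patient-level metrics.
#'
#' @param object A `"lesion_segmenter"`.
#' @param cohort Optional cohort to evaluate on (manifest or patient
#'   list). Without it only training traces are summarized.
#' @param ... Unused.
#' @return A list of class `"summary.lesion_segmenter"`.
#' @export
summary.lesion_segmenter <- function(object, cohort = NULL, ...) {
  out <- list(object = object, metrics = NULL)
  if (!is.null(cohort)) {
    if (!is.list(cohort[[1]]) || is.null(cohort[[1]]$mask))
      cohort <- load_cohort(cohort)
    records <- lapply(cohort, function(p) {
      pm <- predict_mask(object$net, p$image)
      evaluate_masks(pm, p$mask, p$spacing %||% object$spacing)
    })
    out$metrics <- list(lesion = lesion_level_report(records),
                        patient = patient_level_report(records))
  }
  class(out) <- "summary.lesion_segmenter"
  out
}

#' @export
print.summary.lesion_segmenter <- function(x, ...) {
  print(x$object)
  if (!is.null(x$metrics)) {
    cat("\n")
    print(x$metrics$lesion)
    cat("\n")
    print(x$metrics$patient)
  }
  invisible(x)
}

#' Plot training loss curves
#'
#' @param x A `"lesion_segmenter"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lesion_segmenter <- function(x, ...) {
  pt <- x$traces$pretrain; ft <- x$traces$finetune
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  if (!is.null(pt))
    graphics::plot(pt$epoch, pt$loss, type = "l", xlab = "epoch",
                   ylab = "contrastive loss", main = "stage 1: pretraining", ...)
  if (!is.null(ft))
    graphics::plot(ft$epoch, ft$loss, type = "l", xlab = "epoch",
                   ylab = "composite loss", main = "stage 2: fine-tuning", ...)
  invisible(x)
}

#' @export
coef.lesion_segmenter <- function(object, ...) object$net$params
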