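# NIfTI input/output and experiment configuration.
#
# Volumes and masks travel as NIfTI (.nii / .nii.gz) with voxel spacing
# in the header; reading returns 0-based-free plain R arrays plus the
# per-axis spacing from the pixdim fields.

#' Read / write volumes and masks
#'
#' `read_volume()` returns the voxel data and per-axis spacing (mm)
#' from the NIfTI header; `read_mask()` additionally rejects any value
#' other than 0/1. Write-then-read round trips preserve data and
#' spacing.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param data 3D numeric array.
#' @param spacing Per-axis voxel spacing in mm.
#' @return `read_volume`/`read_mask`: a list with `data` (3D array) and
#'   `spacing`; writers return the path invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D volume in ", path)
  attributes(arr) <- list(dim = dim(arr))  # plain array, no NIfTI handles
  list(data = arr, spacing = as.numeric(sp))
}

#' @rdname read_volume
#' @export
write_volume <- function(data, spacing, path) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  img <- RNifti::asNifti(data, reference = NULL)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  vals <- unique(as.numeric(v$data))
  bad <- setdiff(vals, c(0, 1))
  if (length(bad))
    stop("mask ", path, " contains non-binary values: ",
         paste(utils::head(bad, 5), collapse = ", "))
  v
}

#' @rdname read_volume
#' @export
write_mask <- function(data, spacing, path) {
  vals <- unique(as.numeric(data))
  bad <- setdiff(vals, c(0, 1))
  if (length(bad))
    stop("refusing to write non-binary mask values: ",
         paste(utils::head(bad, 5), collapse = ", "))
  write_volume(data, spacing, path)
}

#' Assemble an experiment configuration
#'
#' Bundles the phantom, network, loss, contrastive and training blocks
#' plus a global seed; round-trips losslessly through YAML.
#'
#' @param phantom,net,loss,clp,train Block configurations (defaults
#'   used when omitted).
#' @param seed Global seed; all RNG streams derive from it.
#' @param out_root Output directory root.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(phantom = phantom_config(), net = net_config(),
                              loss = loss_config(), clp = clp_config(),
                              train = train_config(), seed = 1L,
                              out_root = "runs") {
  structure(list(phantom = phantom, net = net, loss = loss, clp = clp,
                 train = train, seed = as.integer(seed), out_root = out_root),
            class = "experiment_config")
}

#' Write / read an experiment configuration as YAML
#'
#' @param config An [experiment_config()].
#' @param path YAML file path.
#' @return `read_experiment_config` returns the config with block
#'   classes restored.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(b)
    if (is.list(b)) unclass(b) else b), path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  experiment_config(
    phantom = do.call(phantom_config, raw$phantom[
      intersect(names(raw$phantom), names(formals(phantom_config)))]),
    net = do.call(net_config, raw$net[
      intersect(names(raw$net), names(formals(net_config)))]),
    loss = do.call(loss_config, raw$loss[
      intersect(names(raw$loss), names(formals(loss_config)))]),
    clp = do.call(clp_config, raw$clp[
      intersect(names(raw$clp), names(formals(clp_config)))]),
    train = do.call(train_config, raw$train[
      intersect(names(raw$train), names(formals(train_config)))]),
    seed = raw$seed, out_root = raw$out_root)
}

# run manifest written next to outputs for reproducibility
write_run_manifest <- function(dir, config, seed, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obj <- c(list(seed = seed,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                r_version = R.version.string,
                config = lapply(unclass(config), function(b)
                  if (is.list(b)) unclass(b) else b)),
           extra)
  jsonlite::write_json(obj, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "run_manifest.json"))
}

#' Evaluate directories of predicted and ground-truth masks
#'
#' Pairs files by sorted name order, applies the lesion-wise protocol
#' and writes a JSON report with lesion-level and patient-level blocks.
#'
#' @param gt_dir,pred_dir Directories of NIfTI masks (same count,
#'   matching sorted order).
#' @param report Optional path for the JSON report.
#' @param close Apply 1 mm closing to predictions (default TRUE).
#' @return A list with `lesion` and `patient` metric reports,
#'   invisibly.
#' @export
evaluate_dirs <- function(gt_dir, pred_dir, report = NULL, close = TRUE) {
  gfiles <- sort(list.files(gt_dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  pfiles <- sort(list.files(pred_dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  gfiles <- grep("mask", gfiles, value = TRUE)
  if (!length(gfiles)) gfiles <- sort(list.files(gt_dir, pattern = "\\.nii(\\.gz)?$",
                                                 full.names = TRUE))
  if (length(gfiles) != length(pfiles))
    stop("ground-truth and prediction directories differ in file count")
  records <- Map(function(g, p) {
    gm <- read_mask(g)
    pm <- read_mask(p)
    evaluate_masks(pm$data, gm$data, gm$spacing, close = close)
  }, gfiles, pfiles)
  res <- list(lesion = lesion_level_report(records),
              patient = patient_level_report(records))
  if (!is.null(report)) {
    li <- res$lesion; pa <- res$patient
    out <- list(
      lesion_level = list(tp = li$tp, fp = li$fp, fn = li$fn,
                          sensitivity = li$sensitivity, precision = li$precision,
                          sensitivity_by_stratum = as.list(li$sensitivity_by_stratum),
                          precision_by_stratum = as.list(li$precision_by_stratum),
                          mean_dice = li$mean_dice, n_dice = li$n_dice),
      patient_level = list(sensitivity = as.list(pa$sensitivity),
                           precision = as.list(pa$precision),
                           mean_dice = as.list(pa$mean_dice),
                           n_patients = pa$n_patients))
    jsonlite::write_json(out, report, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(res)
}
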