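# Synthetic lesion phantoms.
#
# The generator emulates contrast-enhanced T1-weighted volumes carrying
# multiple small ellipsoidal enhancing lesions.  Defaults mirror the
# clinical picture the toolkit targets: lesion longest-axis sizes drawn
# from a three-stratum mixture (small <3 mm 25.73%, medium [3,6] mm
# 40.92%, large >6 mm 33.35%) and per-patient lesion counts following a
# decreasing law truncated at 50.

#' Phantom configuration
#'
#' @param shape Integer vector of voxels per axis (default `c(64,64,64)`).
#' @param spacing Numeric voxel spacing in mm per axis (default 1 mm
#'   isotropic).
#' @param n_lesions Either a fixed lesion count per patient or `NULL` to
#'   draw counts from a truncated geometric law (`1 + rgeom(p = 0.2)`,
#'   capped at 50), a decreasing distribution over 1..50.
#' @param size_mixture Probabilities of the (small, medium, large) size
#'   strata; must sum to 1. Defaults `c(0.2573, 0.4092, 0.3335)`.
#' @param d_max Largest allowed lesion diameter in mm (default 12).
#' @param bg_level Background intensity (default 100).
#' @param contrast_range Range of the per-lesion additive contrast
#'   multiplier; lesion intensity is `bg_level * (1 + contrast)`.
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (default 5, i.e. 5% of background).
#' @param bias_field Add a smooth multiplicative intensity field
#'   (default `FALSE`).
#' @param seed RNG seed used by [generate_cohort()].
#' @return A list of class `"phantom_config"`.
#' @export
phantom_config <- function(shape = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                           n_lesions = NULL,
                           size_mixture = c(0.2573, 0.4092, 0.3335),
                           d_max = 12, bg_level = 100,
                           contrast_range = c(0.4, 0.8), noise_sd = 5,
                           bias_field = FALSE, seed = 1L) {
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, all(spacing > 0),
            length(size_mixture) == 3L, all(size_mixture >= 0))
  if (abs(sum(size_mixture) - 1) > 1e-8) stop("size_mixture must sum to 1")
  if (size_mixture[3] > 0 && d_max <= 6)
    stop("d_max must exceed 6 mm when the large stratum has positive mass")
  if (d_max >= min(shape * spacing))
    stop("volume too small to contain the largest allowed lesion (d_max = ",
         d_max, " mm)")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_lesions = n_lesions, size_mixture = size_mixture,
                 d_max = d_max, bg_level = bg_level,
                 contrast_range = contrast_range, noise_sd = noise_sd,
                 bias_field = bias_field, seed = as.integer(seed)),
            class = "phantom_config")
}

.sample_lesion_count <- function(config) {
  if (!is.null(config$n_lesions)) return(as.integer(config$n_lesions))
  min(1L + stats::rgeom(1, 0.2), 50L)
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
.random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Sample lesion specifications
#'
#' Draws lesion diameters from the three-stratum mixture (uniform within
#' stratum: small `[1, 3)` mm, medium `[3, 6]` mm, large `(6, d_max]`
#' mm), random orientations and non-overlapping centers inside the
#' volume. Deterministic given the RNG seed.
#'
#' @param config A [phantom_config()].
#' @param seed Optional seed set before sampling; `NULL` uses the
#'   current RNG state.
#' @return A list of lesion specs, each with fields `center` (mm),
#'   `semi_axes` (mm), `rotation` (3x3 matrix), `contrast`,
#'   `target_diameter` (mm) and `stratum`.
#' @export
sample_lesions <- function(config, seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- .sample_lesion_count(config)
  extent <- config$shape * config$spacing
  strata <- sample.int(3L, n, replace = TRUE, prob = config$size_mixture)
  specs <- vector("list", n)
  placed_centers <- matrix(numeric(0), 0, 3)
  placed_radii <- numeric(0)
  margin_vox <- max(config$spacing)  # one voxel of slack at the border
  for (i in seq_len(n)) {
    d <- switch(strata[i],
                runif(1, 1, 3 - 1e-9),
                runif(1, 3, 6),
                runif(1, 6 + 1e-9, config$d_max))
    a1 <- d / 2
    semi <- c(a1, a1 * runif(1, 0.6, 1), a1 * runif(1, 0.6, 1))
    ok <- FALSE
    for (try in seq_len(200L)) {
      rmax <- semi[1]
      lo <- rmax + margin_vox
      hi <- extent - rmax - margin_vox
      if (any(hi <= lo)) break
      ctr <- runif(3, lo, hi)
      if (nrow(placed_centers)) {
        dists <- sqrt(colSums((t(placed_centers) - ctr)^2))
        if (any(dists <= placed_radii + rmax + max(config$spacing))) next
      }
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place lesion ", i, " after bounded retries: ",
           "volume too small for the requested lesion load")
    placed_centers <- rbind(placed_centers, ctr)
    placed_radii <- c(placed_radii, semi[1])
    specs[[i]] <- list(center = ctr, semi_axes = semi,
                       rotation = .random_rotation(),
                       contrast = runif(1, config$contrast_range[1],
                                        config$contrast_range[2]),
                       target_diameter = d,
                       stratum = c("small", "medium", "large")[strata[i]])
  }
  specs
}

# smooth multiplicative bias field: exponential of a low-order polynomial
.bias_field <- function(shape) {
  co <- rnorm(6, sd = 0.1)
  u <- (seq_len(shape[1]) - 0.5) / shape[1] - 0.5
  v <- (seq_len(shape[2]) - 0.5) / shape[2] - 0.5
  w <- (seq_len(shape[3]) - 0.5) / shape[3] - 0.5
  fx <- co[1] * u + co[4] * u^2
  fy <- co[2] * v + co[5] * v^2
  fz <- co[3] * w + co[6] * w^2
  exp(outer(outer(fx, fy, "+"), fz, "+"))
}

#' Render a phantom volume and mask
#'
#' Voxelizes each lesion by the voxel-center-in-ellipsoid rule (a voxel
#' belongs to the mask iff its center lies inside the rotated
#' ellipsoid). The image is background level plus each lesion's additive
#' contrast (`bg_level * contrast`), optionally a smooth multiplicative
#' bias field, plus Gaussian noise. The mask is noise-free.
#'
#' @param specs Lesion specs from [sample_lesions()] (may be empty).
#' @param config A [phantom_config()].
#' @return A list with `image` (3D numeric array), `mask` (3D 0/1
#'   array) and `spacing`.
#' @export
render_phantom <- function(specs, config) {
  stopifnot(inherits(config, "phantom_config"))
  shp <- config$shape
  sp <- config$spacing
  mask <- array(0, dim = shp)
  image <- array(config$bg_level, dim = shp)
  # voxel-center coordinates in mm along each axis
  ax <- lapply(1:3, function(k) (seq_len(shp[k]) - 0.5) * sp[k])
  for (spec in specs) {
    rmax <- max(spec$semi_axes) + max(sp)
    rng <- lapply(1:3, function(k) {
      which(ax[[k]] >= spec$center[k] - rmax & ax[[k]] <= spec$center[k] + rmax)
    })
    if (any(vapply(rng, length, integer(1)) == 0L)) next
    gx <- ax[[1]][rng[[1]]] - spec$center[1]
    gy <- ax[[2]][rng[[2]]] - spec$center[2]
    gz <- ax[[3]][rng[[3]]] - spec$center[3]
    pts <- cbind(rep(gx, times = length(gy) * length(gz)),
                 rep(rep(gy, each = length(gx)), times = length(gz)),
                 rep(gz, each = length(gx) * length(gy)))
    local_ <- pts %*% spec$rotation           # rotate into lesion frame
    q <- (local_[, 1] / spec$semi_axes[1])^2 +
         (local_[, 2] / spec$semi_axes[2])^2 +
         (local_[, 3] / spec$semi_axes[3])^2
    inside <- array(q <= 1, dim = c(length(gx), length(gy), length(gz)))
    sub <- mask[rng[[1]], rng[[2]], rng[[3]]]
    sub[inside] <- 1
    mask[rng[[1]], rng[[2]], rng[[3]]] <- sub
    subi <- image[rng[[1]], rng[[2]], rng[[3]]]
    subi[inside] <- config$bg_level * (1 + spec$contrast)
    image[rng[[1]], rng[[2]], rng[[3]]] <- subi
  }
  if (isTRUE(config$bias_field)) image <- image * .bias_field(shp)
  if (config$noise_sd > 0)
    image <- image + array(rnorm(prod(shp), sd = config$noise_sd), dim = shp)
  list(image = image, mask = mask, spacing = sp)
}

#' Perturb a ground-truth mask into a synthetic prediction
#'
#' Builds evaluation fixtures with known lesion-wise outcomes: each
#' ground-truth lesion is kept, eroded to a requested coverage fraction
#' (removing its outermost voxels first), or dropped; spurious
#' components disjoint from the ground truth can be added.
#'
#' @param gt Binary ground-truth mask (3D array).
#' @param plan A list with `actions`: one entry per GT component (in
#'   [extract_components()] order), each either the string `"keep"` /
#'   `"drop"` or `list(action = "erode", coverage = f)`; and optionally
#'   `n_spurious` (count) and `spurious_radius` (voxels, default 1).
#' @param spacing Voxel spacing (mm), used only for component ordering.
#' @param seed Optional RNG seed for spurious placement.
#' @return Binary prediction mask of the same shape.
#' @export
perturb_prediction <- function(gt, plan, spacing = c(1, 1, 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  comps <- extract_components(gt, spacing = spacing)
  acts <- plan$actions %||% rep("keep", length(comps))
  if (length(acts) != length(comps))
    stop("plan$actions has ", length(acts), " entries but the mask has ",
         length(comps), " components")
  pred <- array(0, dim = dim(gt))
  for (i in seq_along(comps)) {
    act <- acts[[i]]
    comp <- comps[[i]]
    if (identical(act, "drop")) next
    if (identical(act, "keep")) {
      pred[comp$lin_idx] <- 1
      next
    }
    if (!is.list(act) || !identical(act$action, "erode"))
      stop("unknown action for lesion ", i)
    f <- act$coverage
    n <- length(comp$lin_idx)
    keep_n <- round(f * n)
    if (keep_n < 1)
      stop("unreachable coverage fraction ", f, " for a ", n, "-voxel lesion")
    ctr <- colMeans(comp$voxels)
    d2 <- colSums((t(comp$voxels) - ctr)^2)
    ord <- order(d2)  # innermost voxels first
    pred[comp$lin_idx[ord[seq_len(keep_n)]]] <- 1
  }
  n_sp <- plan$n_spurious %||% 0L
  if (n_sp > 0) {
    r <- plan$spurious_radius %||% 1L
    forbidden <- .dilate_vox(gt, r + 2L)
    shp <- dim(gt)
    placed <- 0L
    for (try in seq_len(500L)) {
      if (placed >= n_sp) break
      ctr <- vapply(shp, function(s) sample.int(s - 2L * r, 1L) + r, numeric(1))
      xs <- (ctr[1] - r):(ctr[1] + r)
      ys <- (ctr[2] - r):(ctr[2] + r)
      zs <- (ctr[3] - r):(ctr[3] + r)
      blob <- expand.grid(x = xs, y = ys, z = zs)
      keep <- rowSums(sweep(as.matrix(blob), 2, ctr)^2) <= r^2
      blob <- as.matrix(blob[keep, , drop = FALSE])
      lin <- blob[, 1] + shp[1] * (blob[, 2] - 1) + shp[1] * shp[2] * (blob[, 3] - 1)
      if (any(forbidden[lin] > 0) || any(pred[lin] > 0)) next
      pred[lin] <- 1
      placed <- placed + 1L
    }
    if (placed < n_sp)
      stop("could not place ", n_sp, " spurious components disjoint from GT")
  }
  pred
}

#' Generate a cohort of phantom patients on disk
#'
#' Writes paired image/mask NIfTI files and a JSON manifest holding the
#' configuration and per-patient seeds; re-running with the same
#' configuration reproduces identical volumes.
#'
#' @param config A [phantom_config()]; its `seed` drives everything.
#' @param n_patients Number of phantoms to generate.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly: a list with `config`, and `patients`
#'   (id, seed, image/mask paths, lesion count).
#' @export
generate_cohort <- function(config, n_patients, out_dir) {
  stopifnot(inherits(config, "phantom_config"), n_patients >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  patients <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    pseed <- config$seed + 1000L * p
    set.seed(pseed)
    specs <- sample_lesions(config)
    ph <- render_phantom(specs, config)
    id <- sprintf("pat%03d", p)
    img_path <- file.path(out_dir, paste0(id, "_img.nii.gz"))
    msk_path <- file.path(out_dir, paste0(id, "_mask.nii.gz"))
    write_volume(ph$image, config$spacing, img_path)
    write_volume(ph$mask, config$spacing, msk_path)
    patients[[p]] <- list(id = id, seed = pseed, image = img_path,
                          mask = msk_path, n_lesions = length(specs))
  }
  manifest <- list(config = unclass(config), patients = patients)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a cohort manifest and its volumes
#'
#' @param manifest A manifest list from [generate_cohort()] or the path
#'   to a `manifest.json`.
#' @return A list of patients, each `list(image, mask, spacing, id)`.
#' @export
load_cohort <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE)
  lapply(manifest$patients, function(p) {
    img <- read_volume(p$image)
    msk <- read_mask(p$mask)
    list(id = p$id, image = img$data, mask = msk$data, spacing = img$spacing)
  })
}
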