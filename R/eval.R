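# Lesion-wise evaluation protocol.
#
# Predicted masks are post-processed with a morphological closing (1 mm
# ball), grouped into 26-connected components, and matched one-to-one
# against ground-truth lesions by coverage CV = |A n B| / |B| with a
# CV >= 0.5 acceptance rule.  Sensitivity and precision are reported per
# size stratum (small <3 mm, medium [3,6] mm, large >6 mm by longest 3D
# diameter) and pooled; per-lesion Dice is reported for true positives
# whose ground-truth lesion is >= 3 mm.

# ---- morphology -------------------------------------------------------------

# offsets of the discrete structuring element with per-axis voxel radii
# r: the full box (Chebyshev ball), so that a radius-1 kernel bridges
# diagonal gaps the way 26-connectivity treats diagonals as adjacent
.ball_offsets <- function(r) {
  g <- as.matrix(expand.grid(-r[1]:r[1], -r[2]:r[2], -r[3]:r[3]))
  dimnames(g) <- NULL
  g
}

# binary dilation by integer voxel radius (isotropic), used internally
.dilate_vox <- function(mask, r) {
  .morph_shift(mask, .ball_offsets(rep(as.integer(r), 3L)), "or")
}

# OR/AND of shifted copies of a padded mask
.morph_shift <- function(mask, offsets, op = c("or", "and")) {
  op <- match.arg(op)
  d <- dim(mask)
  r <- apply(abs(offsets), 2, max)
  pd <- d + 2L * r
  pad <- array(if (op == "or") 0 else 1, dim = pd)
  core1 <- (r[1] + 1):(r[1] + d[1])
  core2 <- (r[2] + 1):(r[2] + d[2])
  core3 <- (r[3] + 1):(r[3] + d[3])
  pad[core1, core2, core3] <- mask
  acc <- NULL
  for (i in seq_len(nrow(offsets))) {
    sh <- pad[core1 - offsets[i, 1], core2 - offsets[i, 2], core3 - offsets[i, 3]]
    acc <- if (is.null(acc)) sh else if (op == "or") pmax(acc, sh) else pmin(acc, sh)
  }
  acc
}

#' Morphological closing of a binary mask
#'
#' Binary closing (dilation then erosion) with a discrete structuring
#' element of physical radius `radius_mm`: the box of voxels within
#' that radius per axis (`max(1, round(radius_mm / spacing))` voxels),
#' the same diagonal-inclusive neighborhood notion as 26-connectivity.
#' Closing fills gaps up to the kernel size and is idempotent.
#'
#' @param mask Binary 3D array.
#' @param spacing Voxel spacing in mm per axis.
#' @param radius_mm Kernel radius in mm (default 1).
#' @return Closed binary mask of the same shape.
#' @export
close_mask <- function(mask, spacing = c(1, 1, 1), radius_mm = 1) {
  stopifnot(all(spacing > 0))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (!any(mask > 0)) return(mask)
  r <- pmax(1L, as.integer(round(radius_mm / spacing)))
  off <- .ball_offsets(r)
  d <- dim(mask)
  # dilate on a padded canvas so the dilation can grow past the border,
  # then erode (background padding) and crop back
  pd <- d + 2L * r
  canvas <- array(0, dim = pd)
  core1 <- (r[1] + 1):(r[1] + d[1])
  core2 <- (r[2] + 1):(r[2] + d[2])
  core3 <- (r[3] + 1):(r[3] + d[3])
  canvas[core1, core2, core3] <- mask
  dil <- .morph_shift(canvas, off, "or")
  ero <- .morph_shift(dil, off, "and")
  out <- ero[core1, core2, core3]
  storage.mode(out) <- storage.mode(mask)
  out
}

# ---- connected components ---------------------------------------------------

.neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  else if (connectivity != 26) stop("connectivity must be 6 or 26")
  # half neighborhood (lexicographically positive) is enough for edges
  g[g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0))), ,
    drop = FALSE]
}

#' Extract connected lesion components
#'
#' Groups positive voxels into maximal connected components
#' (26-neighborhood by default) and annotates each with its volume and
#' longest 3D diameter.
#'
#' @param mask Binary 3D array.
#' @param spacing Voxel spacing in mm per axis.
#' @param connectivity 26 (faces, edges and corners) or 6 (faces only).
#' @return A list of components ordered by first voxel in raster order;
#'   each has `id`, `voxels` (n x 3 integer matrix of 1-based indices),
#'   `lin_idx`, `volume_mm3` and `longest_axis_mm`.
#' @export
extract_components <- function(mask, spacing = c(1, 1, 1), connectivity = 26) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  d <- dim(mask)
  lin <- which(mask > 0)
  if (!length(lin)) return(list())
  rank <- integer(prod(d))
  rank[lin] <- seq_along(lin)
  co <- arrayInd(lin, d)
  edges <- NULL
  for (off in asplit(.neighbor_offsets(connectivity), 1)) {
    nb <- sweep(co, 2, off, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nl <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    hit <- rank[nl] > 0
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], rank[nl[hit]]))
  }
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  ids <- sort(unique(memb))
  # order components by their first voxel in raster order
  first <- vapply(ids, function(i) min(lin[memb == i]), numeric(1))
  ids <- ids[order(first)]
  out <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    sel <- memb == ids[j]
    vox <- co[sel, , drop = FALSE]
    out[[j]] <- list(id = j, voxels = vox, lin_idx = lin[sel],
                     volume_mm3 = sum(sel) * prod(spacing),
                     longest_axis_mm = longest_axis_mm(vox, spacing))
  }
  out
}

#' Longest 3D diameter of a component
#'
#' Maximum pairwise Euclidean distance between voxel centers in mm
#' (Feret-style). A single voxel has diameter 0. For large components
#' the search is restricted to surface voxels.
#'
#' @param comp A component from [extract_components()] or an n x 3
#'   matrix of voxel indices.
#' @param spacing Voxel spacing in mm per axis.
#' @return Diameter in mm.
#' @export
longest_axis_mm <- function(comp, spacing = c(1, 1, 1)) {
  vox <- if (is.list(comp)) comp$voxels else comp
  if (is.null(dim(vox))) vox <- matrix(vox, ncol = 3)
  if (!nrow(vox)) stop("empty component")
  if (nrow(vox) == 1L) return(0)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (nrow(vox) > 800L) {
    # keep voxels missing at least one 6-neighbor (surface voxels)
    key <- paste(vox[, 1], vox[, 2], vox[, 3])
    keyset <- new.env(parent = emptyenv())
    for (k in key) keyset[[k]] <- TRUE
    surf <- vapply(seq_len(nrow(vox)), function(i) {
      v <- vox[i, ]
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        nb <- v; nb[ax] <- nb[ax] + s
        if (is.null(keyset[[paste(nb[1], nb[2], nb[3])]])) return(TRUE)
      }
      FALSE
    }, logical(1))
    vox <- vox[surf, , drop = FALSE]
  }
  pts <- sweep(vox, 2, spacing, "*")
  max(dist(pts))
}

#' Size stratum of a lesion
#'
#' @param mm Longest-axis diameter(s) in mm.
#' @return Factor with levels `small` (`< 3` mm), `medium` (`[3, 6]`
#'   mm; both boundaries inclusive) and `large` (`> 6` mm).
#' @export
size_stratum <- function(mm) {
  cut(mm, breaks = c(-Inf, 3, 6, Inf), labels = c("small", "medium", "large"),
      right = FALSE) -> f
  # the printed convention is a closed [3, 6] interval: 6 is medium
  f[mm == 6] <- "medium"
  f
}

# ---- matching ---------------------------------------------------------------

#' Coverage of a ground-truth component by a prediction
#'
#' `CV = |A n B| / |B|` where `B` is the ground-truth voxel set.
#'
#' @param pred_comp,gt_comp Components from [extract_components()] on
#'   the same grid.
#' @return Coverage in `[0, 1]`.
#' @export
coverage <- function(pred_comp, gt_comp) {
  if (!length(gt_comp$lin_idx)) stop("empty ground-truth component")
  length(intersect(pred_comp$lin_idx, gt_comp$lin_idx)) / length(gt_comp$lin_idx)
}

#' Match predicted components to ground-truth lesions
#'
#' Computes all pairwise coverages and assigns candidate pairs with
#' `CV >= 0.5` one-to-one so that the number of matched pairs is
#' maximal; among maximum-cardinality assignments the one with the
#' largest total coverage is chosen (maximum-weight bipartite matching
#' on the candidate graph). A prediction covering half of two lesions
#' can therefore only claim one of them, and a plain greedy pass can
#' never out-match the result. Unmatched predictions are false
#' positives, unmatched ground-truth lesions false negatives.
#'
#' @param pred_comps,gt_comps Component lists from
#'   [extract_components()].
#' @param cv_threshold Acceptance threshold on coverage (default 0.5).
#' @return A list of class `"match_result"` with `pairs` (data frame of
#'   `pred_id`, `gt_id`, `cv`), `fp_ids`, `fn_ids` and the counts
#'   `tp`, `fp`, `fn`.
#' @export
match_lesions <- function(pred_comps, gt_comps, cv_threshold = 0.5) {
  np <- length(pred_comps); ng <- length(gt_comps)
  cand <- NULL
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    cv <- coverage(pred_comps[[i]], gt_comps[[j]])
    if (cv >= cv_threshold) cand <- rbind(cand, c(i, j, cv))
  }
  pairs <- data.frame(pred_id = integer(), gt_id = integer(), cv = numeric())
  if (!is.null(cand)) {
    # bipartite graph: predictions then GT lesions; weights shifted so
    # cardinality dominates and coverage breaks ties
    g <- igraph::make_empty_graph(n = np + ng, directed = FALSE)
    g <- igraph::add_edges(g, rbind(cand[, 1], np + cand[, 2]))
    types <- c(rep(FALSE, np), rep(TRUE, ng))
    mm <- igraph::max_bipartite_match(g, types = types,
                                      weights = cand[, 3] + 10)$matching
    for (i in seq_len(np)) {
      j <- mm[i] - np
      if (!is.na(j) && j >= 1) {
        cv <- cand[cand[, 1] == i & cand[, 2] == j, 3]
        pairs <- rbind(pairs, data.frame(pred_id = i, gt_id = j, cv = cv))
      }
    }
  }
  structure(list(pairs = pairs,
                 fp_ids = setdiff(seq_len(np), pairs$pred_id),
                 fn_ids = setdiff(seq_len(ng), pairs$gt_id),
                 tp = nrow(pairs),
                 fp = np - nrow(pairs),
                 fn = ng - nrow(pairs)),
            class = "match_result")
}

#' Per-lesion Dice coefficients of matched pairs
#'
#' `DC = 2|A n B| / (|A| + |B|)` for each true-positive pair whose
#' ground-truth lesion has longest diameter `>= min_gt_mm` (default
#' 3 mm); false positives, false negatives and small ground-truth
#' lesions are excluded.
#'
#' @param match A [match_lesions()] result.
#' @param pred_comps,gt_comps The component lists that were matched.
#' @param min_gt_mm Minimum ground-truth diameter for inclusion.
#' @return Data frame with `gt_id`, `pred_id`, `gt_mm`, `dice`.
#' @export
dice_per_lesion <- function(match, pred_comps, gt_comps, min_gt_mm = 3) {
  out <- data.frame(gt_id = integer(), pred_id = integer(),
                    gt_mm = numeric(), dice = numeric())
  for (r in seq_len(nrow(match$pairs))) {
    j <- match$pairs$gt_id[r]; i <- match$pairs$pred_id[r]
    gmm <- gt_comps[[j]]$longest_axis_mm
    if (gmm < min_gt_mm) next
    A <- pred_comps[[i]]$lin_idx; B <- gt_comps[[j]]$lin_idx
    dc <- 2 * length(intersect(A, B)) / (length(A) + length(B))
    out <- rbind(out, data.frame(gt_id = j, pred_id = i, gt_mm = gmm, dice = dc))
  }
  out
}

#' Evaluate one predicted mask against its ground truth
#'
#' Applies the full lesion-wise protocol to one patient: closing of the
#' predicted mask (ground truth used as-is), component extraction,
#' coverage matching and per-lesion Dice.
#'
#' @param pred Binary predicted mask.
#' @param gt Binary ground-truth mask.
#' @param spacing Voxel spacing in mm per axis.
#' @param close Apply the 1 mm closing to the prediction (default TRUE).
#' @return A list with `match`, `pred_comps`, `gt_comps`, `dice` (per
#'   lesion) and per-component strata.
#' @export
evaluate_masks <- function(pred, gt, spacing = c(1, 1, 1), close = TRUE) {
  if (close) pred <- close_mask(pred, spacing)
  pc <- extract_components(pred, spacing)
  gc_ <- extract_components(gt, spacing)
  m <- match_lesions(pc, gc_)
  list(match = m, pred_comps = pc, gt_comps = gc_,
       dice = dice_per_lesion(m, pc, gc_),
       gt_strata = size_stratum(vapply(gc_, `[[`, numeric(1), "longest_axis_mm")),
       pred_strata = size_stratum(vapply(pc, `[[`, numeric(1), "longest_axis_mm")))
}

.safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Lesion-level metrics report
#'
#' Pools true/false positives and negatives across patients.
#' Sensitivity is stratified by the ground-truth lesion's size; false
#' positives are assigned to strata by the predicted component's own
#' longest axis (they have no ground-truth size). Mean Dice pools the
#' medium and large strata.
#'
#' @param records List of per-patient results from [evaluate_masks()].
#' @return A list of class `"metrics_report"` (level `"lesion"`) with
#'   pooled and per-stratum sensitivity/precision, counts and mean
#'   Dice. Metrics with empty denominators are `NA`.
#' @export
lesion_level_report <- function(records) {
  strata <- c("small", "medium", "large")
  tp_g <- fp_p <- fn_g <- setNames(numeric(3), strata)
  dice_all <- numeric(0)
  for (rec in records) {
    gtst <- as.character(rec$gt_strata)
    prst <- as.character(rec$pred_strata)
    for (r in seq_len(nrow(rec$match$pairs)))
      tp_g[gtst[rec$match$pairs$gt_id[r]]] <- tp_g[gtst[rec$match$pairs$gt_id[r]]] + 1
    for (i in rec$match$fn_ids) fn_g[gtst[i]] <- fn_g[gtst[i]] + 1
    for (i in rec$match$fp_ids) fp_p[prst[i]] <- fp_p[prst[i]] + 1
    dice_all <- c(dice_all, rec$dice$dice)
  }
  sens <- vapply(strata, function(s) .safe_ratio(tp_g[s], tp_g[s] + fn_g[s]),
                 numeric(1))
  prec <- vapply(strata, function(s) .safe_ratio(tp_g[s], tp_g[s] + fp_p[s]),
                 numeric(1))
  structure(list(level = "lesion",
                 tp = sum(tp_g), fp = sum(fp_p), fn = sum(fn_g),
                 sensitivity = .safe_ratio(sum(tp_g), sum(tp_g) + sum(fn_g)),
                 precision = .safe_ratio(sum(tp_g), sum(tp_g) + sum(fp_p)),
                 sensitivity_by_stratum = sens,
                 precision_by_stratum = prec,
                 counts = list(tp = tp_g, fp = fp_p, fn = fn_g),
                 mean_dice = if (length(dice_all)) mean(dice_all) else NA_real_,
                 n_dice = length(dice_all)),
            class = "metrics_report")
}

#' Patient-level metrics report
#'
#' Per-patient sensitivity, precision (no size stratification) and mean
#' per-lesion Dice, summarized across patients as mean and SD over
#' patients with defined values.
#'
#' @param records List of per-patient results from [evaluate_masks()].
#' @return A list of class `"metrics_report"` (level `"patient"`).
#' @export
patient_level_report <- function(records) {
  per <- lapply(records, function(rec) {
    m <- rec$match
    c(sensitivity = .safe_ratio(m$tp, m$tp + m$fn),
      precision = .safe_ratio(m$tp, m$tp + m$fp),
      dice = if (nrow(rec$dice)) mean(rec$dice$dice) else NA_real_)
  })
  tab <- do.call(rbind, per)
  summ <- function(x) c(mean = mean(x, na.rm = TRUE),
                        sd = if (sum(!is.na(x)) > 1) sd(x, na.rm = TRUE) else NA_real_)
  structure(list(level = "patient",
                 per_patient = as.data.frame(tab),
                 sensitivity = summ(tab[, "sensitivity"]),
                 precision = summ(tab[, "precision"]),
                 mean_dice = summ(tab[, "dice"]),
                 n_patients = length(records)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  if (x$level == "lesion") {
    cat("Lesion-level metrics (pooled over", sum(unlist(x$counts$tp) + unlist(x$counts$fn)),
        "GT lesions)\n")
    cat(sprintf("  TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
    cat(sprintf("  sensitivity %.4f  precision %.4f\n", x$sensitivity, x$precision))
    cat("  by stratum (sensitivity / precision):\n")
    for (s in c("small", "medium", "large"))
      cat(sprintf("    %-6s %.4f / %.4f\n", s,
                  x$sensitivity_by_stratum[s], x$precision_by_stratum[s]))
    cat(sprintf("  mean Dice (GT >= 3 mm, n = %d): %.4f\n", x$n_dice, x$mean_dice))
  } else {
    cat("Patient-level metrics over", x$n_patients, "patients (mean +/- SD)\n")
    cat(sprintf("  sensitivity %.4f +/- %.4f\n", x$sensitivity["mean"], x$sensitivity["sd"]))
    cat(sprintf("  precision   %.4f +/- %.4f\n", x$precision["mean"], x$precision["sd"]))
    cat(sprintf("  mean Dice   %.4f +/- %.4f\n", x$mean_dice["mean"], x$mean_dice["sd"]))
  }
  invisible(x)
}
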