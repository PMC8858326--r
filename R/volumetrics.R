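# CSF volumetric biomarkers from paired CT volumes -----------------------

#' Default volumetric extraction parameters
#'
#' Standard CT contrast bands: CSF window `[0, 20]` HU (the upper edge sits
#' midway between CSF and parenchymal attenuation, which keeps
#' partial-volume boundary crossings unbiased), bone threshold 200 HU,
#' median filter radius 1 voxel (in-plane).
#' @return A named list of parameters.
#' @export
volumetrics_config <- function(bone_hu = 200, csf_window = c(0, 20),
                               median_radius = 1L) {
  list(bone_hu = bone_hu, csf_window = csf_window,
       median_radius = as.integer(median_radius))
}

#' Segment the intracranial cavity
#'
#' Thresholds bone, then takes as cavity the non-bone voxels enclosed by
#' bone along all three grid axes (an interior-betweenness fill, exact for a
#' convex skull); the skull shell itself is excluded. The returned mask is a
#' single connected component.
#'
#' @param ct a `ct_volume` with HU-like intensities.
#' @param config a [volumetrics_config()].
#' @return Logical 3-D array: the intracranial cavity mask.
#' @export
segment_cranial_cavity <- function(ct, config = volumetrics_config()) {
  stopifnot(inherits(ct, "ct_volume"))
  bone <- ct$data >= config$bone_hu
  if (!any(bone)) stop_config("no skull detected (no voxels >= %g HU)",
                              config$bone_hu)
  enclosed <- between_bone(bone, 1) & between_bone(bone, 2) &
    between_bone(bone, 3)
  mask <- enclosed & !bone
  # keep the largest in-plane component per slice is unnecessary: the
  # betweenness construction cannot produce disconnected cavity pieces for a
  # closed shell; tiny threshold speckle outside is removed by the AND.
  mask
}

# TRUE where a voxel has bone both before and after it along axis `a`.
between_bone <- function(bone, a) {
  n <- dim(bone)
  perm <- c(a, setdiff(1:3, a))
  b <- aperm(bone, perm)
  nb <- dim(b)[1]
  m <- matrix(b, nrow = nb)
  before <- m
  for (i in 2:nb) before[i, ] <- before[i - 1L, ] | m[i, ]
  after <- m
  for (i in (nb - 1L):1L) after[i, ] <- after[i + 1L, ] | m[i, ]
  res <- array(before & after, dim = dim(b))
  aperm(res, order(perm))
}

#' Segment CSF within the cranial cavity
#'
#' In-plane median filtering (3x3, per axial slice), intensity windowing to
#' the CSF band inside the cranial mask, then in-plane morphological opening
#' with a 1-voxel cross element to remove speckle. Filtering and opening are
#' applied in-plane because axial CT voxels are strongly anisotropic.
#'
#' @param ct a `ct_volume`.
#' @param cranial logical cranial cavity mask from
#'   [segment_cranial_cavity()].
#' @param config a [volumetrics_config()].
#' @return Logical 3-D CSF mask, a subset of `cranial`.
#' @export
segment_csf <- function(ct, cranial, config = volumetrics_config()) {
  if (!any(cranial)) stop_config("empty cranial mask")
  vol <- ct$data
  if (config$median_radius > 0) vol <- median_filter_inplane(vol)
  m <- cranial & vol >= config$csf_window[1] & vol <= config$csf_window[2]
  m <- open_inplane(m)
  m & cranial
}

# 3x3 in-plane median filter applied slice-wise, vectorised across slices.
median_filter_inplane <- function(vol) {
  n <- dim(vol)
  shifts <- expand.grid(dx = -1:1, dy = -1:1)
  stack <- vapply(seq_len(nrow(shifts)), function(s) {
    shift2(vol, shifts$dx[s], shifts$dy[s])
  }, numeric(length(vol)))
  array(apply_median9(stack), dim = n)
}

# median of 9 values per row of an n x 9 matrix, via column sorting network
apply_median9 <- function(m) {
  swap <- function(i, j) {
    lo <- pmin(m[, i], m[, j])
    hi <- pmax(m[, i], m[, j])
    m[, i] <<- lo
    m[, j] <<- hi
  }
  # Batcher-style network for 9 elements; final median in column 5
  pairs <- list(c(1,2),c(4,5),c(7,8),c(2,3),c(5,6),c(8,9),c(1,2),c(4,5),
                c(7,8),c(1,4),c(4,7),c(2,5),c(5,8),c(3,6),c(6,9),c(2,4),
                c(6,8),c(3,5),c(5,7),c(3,4),c(5,6),c(4,5))
  for (p in pairs) swap(p[1], p[2])
  m[, 5]
}

# shift a 3-D array in-plane by (dx, dy), replicating edges
shift2 <- function(vol, dx, dy) {
  n <- dim(vol)
  ix <- clamp(seq_len(n[1]) - dx, 1L, n[1])
  iy <- clamp(seq_len(n[2]) - dy, 1L, n[2])
  as.vector(vol[ix, iy, , drop = FALSE])
}

erode_inplane <- function(m) {
  m & shift2l(m, 1, 0) & shift2l(m, -1, 0) & shift2l(m, 0, 1) &
    shift2l(m, 0, -1)
}

dilate_inplane <- function(m) {
  m | shift2l(m, 1, 0) | shift2l(m, -1, 0) | shift2l(m, 0, 1) |
    shift2l(m, 0, -1)
}

open_inplane <- function(m) dilate_inplane(erode_inplane(m))

# logical in-plane shift with FALSE padding
shift2l <- function(m, dx, dy) {
  n <- dim(m)
  out <- array(FALSE, n)
  xs <- seq_len(n[1]) ; ys <- seq_len(n[2])
  xd <- xs + dx ; yd <- ys + dy
  okx <- xd >= 1 & xd <= n[1] ; oky <- yd >= 1 & yd <= n[2]
  out[xd[okx], yd[oky], ] <- m[xs[okx], ys[oky], , drop = FALSE]
  out
}

#' Estimate the midline plane by reflective symmetry of the cranial mask
#'
#' Searches over in-plane rotation and lateral translation for the vertical
#' plane maximising the overlap of the cranial mask with its mirror image
#' (coarse grid search, then Nelder-Mead refinement). Because the mask
#' derives from the fixed skull, the estimate is invariant to brain content
#' shift — the property that makes the hemispheric split stable under mass
#' effect.
#'
#' @param cranial logical cranial mask.
#' @param spacing voxel spacing (mm).
#' @param n_sample number of mask voxels used to score a candidate plane.
#' @param seed seed for the scoring subsample.
#' @return A `midline_plane`: list with `origin_vox` (1-based voxel
#'   coordinates of a point on the plane), unit `normal` (in-plane),
#'   `theta_deg`, `offset_mm`, `score`, and `per_slice` (a data.frame of the
#'   plane-slice intersection lines).
#' @export
estimate_midline <- function(cranial, spacing = c(1.5, 1.5, 3.0),
                             n_sample = 40000L, seed = 11L) {
  n <- dim(cranial)
  idx <- which(cranial)
  if (length(idx) == 0L) stop_config("empty cranial mask")
  if (length(idx) > n_sample) {
    idx <- withr::with_seed(seed, sample(idx, n_sample))
  }
  i <- ((idx - 1L) %% n[1]) + 1L
  j <- ((idx - 1L) %/% n[1]) %% n[2] + 1L
  k <- (idx - 1L) %/% (n[1] * n[2]) + 1L
  ctr <- (n + 1) / 2
  px <- (i - ctr[1]) * spacing[1]
  py <- (j - ctr[2]) * spacing[2]

  score <- function(theta_deg, t_mm) {
    th <- theta_deg * pi / 180
    nx <- cos(th) ; ny <- sin(th)
    s <- px * nx + py * ny - t_mm
    rx <- px - 2 * s * nx
    ry <- py - 2 * s * ny
    ri <- as.integer(round(rx / spacing[1] + ctr[1]))
    rj <- as.integer(round(ry / spacing[2] + ctr[2]))
    ok <- ri >= 1 & ri <= n[1] & rj >= 1 & rj <= n[2]
    hit <- logical(length(ri))
    lin <- (k[ok] - 1L) * (n[1] * n[2]) + (rj[ok] - 1L) * n[1] + ri[ok]
    hit[ok] <- cranial[lin]
    mean(hit)
  }

  init <- c(0, 0)
  best <- c(theta = 0, t = 0, s = score(0, 0))
  for (theta in seq(-10, 10, by = 2)) {
    for (t_mm in seq(-12, 12, by = 2)) {
      sc <- score(theta, t_mm)
      if (sc > best["s"]) best <- c(theta = theta, t = t_mm, s = sc)
    }
  }
  opt <- stats::optim(c(best[["theta"]], best[["t"]]),
                      function(p) -score(p[1], p[2]),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-6, maxit = 200))
  theta <- opt$par[1] ; t_mm <- opt$par[2] ; sc <- -opt$value
  if (sc < score(init[1], init[2]) - 1e-12) {
    warning("midline optimisation failed to improve on the mid-sagittal ",
            "initialisation; returning the initialisation")
    theta <- 0 ; t_mm <- 0 ; sc <- score(0, 0)
  }
  th <- theta * pi / 180
  normal <- c(cos(th), sin(th), 0)
  origin <- c(ctr[1] + (t_mm * cos(th)) / spacing[1],
              ctr[2] + (t_mm * sin(th)) / spacing[2], ctr[3])
  per_slice <- data.frame(
    slice = seq_len(n[3]),
    px = origin[1], py = origin[2],
    nx = normal[1], ny = normal[2]
  )
  structure(list(origin_vox = origin, normal = normal, theta_deg = theta,
                 offset_mm = t_mm, score = sc, per_slice = per_slice,
                 spacing = spacing),
            class = "midline_plane")
}

#' Split a CSF mask into hemispheric volumes
#'
#' Assigns each CSF voxel by its signed distance to the midline plane
#' (positive side = patient-left); voxels within half a voxel of the plane
#' are split equally between the hemispheres. Left + right equals the total
#' CSF volume exactly.
#'
#' @param csf logical CSF mask.
#' @param plane a `midline_plane`.
#' @param spacing voxel spacing (mm).
#' @return Named numeric: `left_ml`, `right_ml`.
#' @export
hemispheric_csf_volumes <- function(csf, plane, spacing = plane$spacing) {
  if (sqrt(sum(plane$normal^2)) < 1e-9) stop_config("degenerate plane normal")
  n <- dim(csf)
  idx <- which(csf)
  vv <- voxel_volume_ml(spacing)
  if (length(idx) == 0L) return(c(left_ml = 0, right_ml = 0))
  i <- ((idx - 1L) %% n[1]) + 1L
  j <- ((idx - 1L) %/% n[1]) %% n[2] + 1L
  s <- (i - plane$origin_vox[1]) * spacing[1] * plane$normal[1] +
    (j - plane$origin_vox[2]) * spacing[2] * plane$normal[2]
  half <- 0.5 * (abs(plane$normal[1]) * spacing[1] +
                   abs(plane$normal[2]) * spacing[2])
  on_plane <- abs(s) <= half / 2
  left <- sum(s > 0 & !on_plane) + 0.5 * sum(on_plane)
  right <- sum(s < 0 & !on_plane) + 0.5 * sum(on_plane)
  c(left_ml = left * vv, right_ml = right * vv)
}

#' Determine the stroke-affected hemisphere
#'
#' Uses the visible lesion side when available; otherwise the hemisphere
#' with less CSF. Ties resolve to left with a warning.
#'
#' @param left_ml,right_ml hemispheric CSF volumes (ml).
#' @param lesion_side optional `"left"`/`"right"` override from a visible
#'   stroke lesion.
#' @return `"left"` or `"right"`.
#' @export
determine_affected_side <- function(left_ml, right_ml, lesion_side = NULL) {
  if (!is.null(lesion_side)) {
    return(match.arg(lesion_side, c("left", "right")))
  }
  if (left_ml < 0 || right_ml < 0) stop_config("volumes must be >= 0")
  if (left_ml == 0 && right_ml == 0)
    stop_config("both hemispheric CSF volumes are zero")
  if (left_ml == right_ml) {
    warning("hemispheric CSF volumes tie; affected side set to left")
    return("left")
  }
  if (left_ml < right_ml) "left" else "right"
}

#' Compute volumetric features from paired hemispheric volumes
#'
#' Intracranial reserve = baseline CSF / cranial volume; hemispheric CSF
#' ratio = affected / contralateral CSF at each timepoint; delta_csf =
#' 100 * (follow-up total CSF - baseline total CSF) / baseline total CSF.
#'
#' @param base_vols named numeric with `left_ml`, `right_ml`, `cranial_ml`.
#' @param fu_vols named numeric with `left_ml`, `right_ml`.
#' @param affected `"left"` or `"right"` (fixed across timepoints).
#' @return A one-row `data.frame` of `volumetric_features`.
#' @export
compute_features <- function(base_vols, fu_vols, affected) {
  affected <- match.arg(affected, c("left", "right"))
  aff <- function(v) unname(if (affected == "left") v["left_ml"] else v["right_ml"])
  con <- function(v) unname(if (affected == "left") v["right_ml"] else v["left_ml"])
  tot <- function(v) unname(v["left_ml"] + v["right_ml"])
  if (tot(base_vols) <= 0 || base_vols[["cranial_ml"]] <= 0)
    stop_config("baseline volumes must be positive")
  if (con(base_vols) == 0 || con(fu_vols) == 0)
    stop_config("ratio undefined: zero contralateral CSF volume")
  structure(data.frame(
    cranial_ml = base_vols[["cranial_ml"]],
    csf_base_ml = tot(base_vols),
    csf_fu_ml = tot(fu_vols),
    intracranial_reserve = tot(base_vols) / base_vols[["cranial_ml"]],
    affected = affected,
    csf_ratio_baseline = aff(base_vols) / con(base_vols),
    csf_ratio_24h = aff(fu_vols) / con(fu_vols),
    delta_csf = 100 * (tot(fu_vols) - tot(base_vols)) / tot(base_vols)
  ), class = c("volumetric_features", "data.frame"))
}

#' Extract all volumetric biomarkers from a paired scan
#'
#' End-to-end per-subject imaging path: cranial and CSF segmentation on both
#' scans, midline estimation per scan, hemispheric splitting, affected-side
#' call on the baseline (or from a visible lesion), and feature computation.
#' The affected side never flips between timepoints.
#'
#' @param baseline,followup `ct_volume`s.
#' @param lesion_side optional visible-lesion override.
#' @param config a [volumetrics_config()].
#' @return A one-row `data.frame` of volumetric features.
#' @export
extract_volumetrics <- function(baseline, followup, lesion_side = NULL,
                                config = volumetrics_config()) {
  cr_b <- segment_cranial_cavity(baseline, config)
  cr_f <- segment_cranial_cavity(followup, config)
  csf_b <- segment_csf(baseline, cr_b, config)
  csf_f <- segment_csf(followup, cr_f, config)
  pl_b <- estimate_midline(cr_b, baseline$spacing)
  pl_f <- estimate_midline(cr_f, followup$spacing)
  vb <- hemispheric_csf_volumes(csf_b, pl_b, baseline$spacing)
  vf <- hemispheric_csf_volumes(csf_f, pl_f, followup$spacing)
  affected <- determine_affected_side(vb["left_ml"], vb["right_ml"],
                                      lesion_side)
  base_vols <- c(vb, cranial_ml = unname(sum(cr_b) *
                                           voxel_volume_ml(baseline$spacing)))
  compute_features(base_vols, vf, affected)
}

# Dice overlap between two binary masks (used by the validation suite).
#' Dice coefficient of two binary masks
#' @param a,b logical arrays of identical shape.
#' @return Dice overlap in `[0, 1]`.
#' @export
dice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
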