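# Procedural head-CT phantom ---------------------------------------------

# Label codes used in the phantom label field.
.lab <- c(air = 0L, skull = 1L, parenchyma = 2L, csf = 3L, lesion = 4L)
# Compartment codes for CSF bookkeeping.
.cmp <- c(none = 0L, vent_left = 1L, vent_right = 2L,
          sulcal_left = 3L, sulcal_right = 4L)

#' Phantom specification
#'
#' Geometry and rendering parameters for the synthetic head CT: an
#' ellipsoidal cranial cavity inside a high-intensity skull shell, filled
#' with parenchyma, paired ventricles, and a sulcal CSF rim whose pattern is
#' a thresholded smooth random field. Defaults give an intracranial reserve
#' (CSF/cranial volume) of roughly 0.10-0.13, bracketing typical stroke
#' cohorts.
#'
#' @param shape voxels per axis.
#' @param spacing voxel spacing in mm.
#' @param skull_thickness skull shell thickness (mm).
#' @param ventricle_scale multiplicative size scale of the ventricles.
#' @param sulcal_fraction fraction of the sulcal rim shell occupied by CSF,
#'   in `[0, 1]`.
#' @param asymmetry baseline left/right sulcal CSF imbalance (1 = symmetric;
#'   the left:right CSF target ratio).
#' @param intensities named list of HU-like means for air, csf, parenchyma,
#'   lesion, skull; must satisfy air < csf < parenchyma < skull.
#' @param noise_sd additive Gaussian noise sd (HU).
#' @param smooth_fwhm Gaussian smoothing FWHM in mm (partial-volume proxy).
#' @param rotation_deg in-plane (axial) rotation of the head geometry.
#' @param seed integer seed controlling the sulcal pattern and noise.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 64L),
                         spacing = c(1.5, 1.5, 3.0),
                         skull_thickness = 6,
                         ventricle_scale = 1,
                         sulcal_fraction = 0.45,
                         asymmetry = 1,
                         intensities = list(air = -1000, csf = 5,
                                            parenchyma = 35, lesion = 24,
                                            skull = 600),
                         noise_sd = 4,
                         smooth_fwhm = 2,
                         rotation_deg = 0,
                         seed = 1L) {
  spec <- structure(list(
    shape = as.integer(shape), spacing = as.numeric(spacing),
    skull_thickness = skull_thickness, ventricle_scale = ventricle_scale,
    sulcal_fraction = sulcal_fraction, asymmetry = asymmetry,
    intensities = intensities, noise_sd = noise_sd,
    smooth_fwhm = smooth_fwhm, rotation_deg = rotation_deg,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  with(spec$intensities, {
    if (!(air < csf && csf < parenchyma && parenchyma < skull))
      stop_config("intensities must be ordered air < CSF < parenchyma < skull")
  })
  if (spec$sulcal_fraction < 0 || spec$sulcal_fraction > 1)
    stop_config("sulcal_fraction must be in [0, 1]")
  if (any(spec$spacing <= 0) || spec$skull_thickness <= 0 ||
      spec$ventricle_scale <= 0 || spec$asymmetry <= 0)
    stop_config("all phantom scales must be positive")
  spec
}

#' Edema specification for the follow-up scan
#'
#' @param side affected hemisphere, `"left"` or `"right"`.
#' @param effacement fraction of the affected hemisphere's sulcal CSF
#'   converted to parenchyma (sulcal effacement), in `[0, 1]`.
#' @param compression fraction of the ipsilateral ventricle eroded,
#'   in `[0, 1]`.
#' @param shift_mm midline shift: peak lateral displacement of midline
#'   structures towards the contralateral side (mm, >= 0).
#' @param lesion_ml volume of the hypodense lesion painted into the affected
#'   hemisphere (ml).
#' @param lesion_offset_hu (negative) intensity offset is not used directly;
#'   the lesion renders at the `lesion` intensity of the phantom spec.
#' @return A list of class `edema_spec`.
#' @export
edema_spec <- function(side = c("left", "right"), effacement = 0,
                       compression = 0, shift_mm = 0, lesion_ml = 0) {
  side <- match.arg(side)
  if (effacement < 0 || effacement > 1 || compression < 0 || compression > 1)
    stop_config("effacement and compression fractions must be in [0, 1]")
  if (shift_mm < 0 || lesion_ml < 0)
    stop_config("shift_mm and lesion_ml must be >= 0")
  structure(list(side = side, effacement = effacement,
                 compression = compression, shift_mm = shift_mm,
                 lesion_ml = lesion_ml), class = "edema_spec")
}

# Head-frame coordinates (mm, rotated by rotation_deg about the axial axis)
# for every voxel; returned as vectors of length prod(shape).
phantom_coords <- function(spec) {
  n <- spec$shape
  sp <- spec$spacing
  x <- (seq_len(n[1]) - (n[1] + 1) / 2) * sp[1]
  y <- (seq_len(n[2]) - (n[2] + 1) / 2) * sp[2]
  z <- (seq_len(n[3]) - (n[3] + 1) / 2) * sp[3]
  X <- rep(x, times = n[2] * n[3])
  Y <- rep(rep(y, each = n[1]), times = n[3])
  Z <- rep(z, each = n[1] * n[2])
  th <- spec$rotation_deg * pi / 180
  list(xr = cos(th) * X + sin(th) * Y,
       yr = -sin(th) * X + cos(th) * Y,
       z = Z)
}

phantom_axes <- function(spec) {
  fov <- spec$shape * spec$spacing
  c(0.34 * fov[1], 0.42 * fov[2], 0.375 * fov[3])
}

#' Generate a baseline head phantom with ground truth
#'
#' Builds the label field (skull shell, parenchyma, paired ventricles,
#' sulcal CSF rim), renders it to HU-like intensities (smoothing as a
#' partial-volume proxy, additive noise), and returns the rendered volume
#' together with the ground truth computed from the pre-noise label field.
#' Deterministic per seed.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `ct` (a `ct_volume`) and `truth` (a
#'   `phantom_truth`: label/compartment fields, cranial and CSF masks,
#'   per-hemisphere CSF volumes in ml, the true midline plane, lesion mask
#'   and true midline shift).
#' @export
generate_head_phantom <- function(spec = phantom_spec()) {
  n <- spec$shape
  ax <- phantom_axes(spec)
  half_fov <- n * spec$spacing / 2
  th <- spec$rotation_deg * pi / 180
  need <- abs(cos(th)) * (ax[1] + spec$skull_thickness) +
    abs(sin(th)) * (ax[2] + spec$skull_thickness)
  if (need > half_fov[1] || ax[2] + spec$skull_thickness > half_fov[2] ||
      ax[3] + spec$skull_thickness > half_fov[3])
    stop_config("skull does not fit inside the voxel grid")

  co <- phantom_coords(spec)
  rho2_in <- (co$xr / ax[1])^2 + (co$yr / ax[2])^2 + (co$z / ax[3])^2
  axo <- ax + spec$skull_thickness
  rho2_out <- (co$xr / axo[1])^2 + (co$yr / axo[2])^2 + (co$z / axo[3])^2

  labels <- rep(.lab[["air"]], prod(n))
  labels[rho2_out <= 1] <- .lab[["skull"]]
  interior <- rho2_in <= 1
  labels[interior] <- .lab[["parenchyma"]]
  comp <- rep(.cmp[["none"]], prod(n))

  # paired lateral ventricles
  vs <- spec$ventricle_scale
  for (side in c(1, -1)) {
    vr2 <- ((co$xr - side * 14) / (9 * vs))^2 +
      ((co$yr - 6) / (25 * vs))^2 + (co$z / (11 * vs))^2
    sel <- vr2 <= 1 & interior
    labels[sel] <- .lab[["csf"]]
    comp[sel] <- if (side > 0) .cmp[["vent_left"]] else .cmp[["vent_right"]]
  }

  withr::with_seed(spec$seed, {
    # sulcal CSF rim: smooth random field thresholded per hemisphere
    field <- array(stats::rnorm(prod(n)), dim = n)
    field <- gauss_smooth(field, sigma_mm = 6, spacing = spec$spacing)
    field <- as.vector(field)
    shell <- rho2_in >= 0.87^2 & rho2_in <= 0.96^2 &
      labels == .lab[["parenchyma"]]
    f_l <- min(1, spec$sulcal_fraction * 2 * spec$asymmetry /
                 (1 + spec$asymmetry))
    f_r <- min(1, spec$sulcal_fraction * 2 / (1 + spec$asymmetry))
    for (side in c("left", "right")) {
      hemi <- if (side == "left") co$xr > 0 else co$xr < 0
      f <- if (side == "left") f_l else f_r
      sel_shell <- shell & hemi
      if (f > 0 && any(sel_shell)) {
        thr <- stats::quantile(field[sel_shell], 1 - f, names = FALSE)
        sel <- sel_shell & field > thr
        labels[sel] <- .lab[["csf"]]
        comp[sel] <- .cmp[[paste0("sulcal_", side)]]
      }
    }

    labels <- array(labels, dim = n)
    comp <- array(comp, dim = n)
    ct <- render_phantom(labels, spec)
    truth <- make_truth(labels, comp, array(field, dim = n),
                        array(rho2_in, dim = n), spec, true_shift = 0,
                        xr = co$xr)
    list(ct = ct, truth = truth)
  })
}

# Render a label field to intensities: LUT, Gaussian smoothing, noise.
render_phantom <- function(labels, spec, noise_seed = NULL) {
  lut <- with(spec$intensities, c(air, skull, parenchyma, csf, lesion))
  vol <- array(lut[as.vector(labels) + 1L], dim = dim(labels))
  if (spec$smooth_fwhm > 0)
    vol <- gauss_smooth(vol, spec$smooth_fwhm / 2.355, spec$spacing)
  if (spec$noise_sd > 0) {
    noise <- if (is.null(noise_seed)) {
      stats::rnorm(length(vol), 0, spec$noise_sd)
    } else {
      withr::with_seed(noise_seed, stats::rnorm(length(vol), 0, spec$noise_sd))
    }
    vol <- vol + noise
  }
  ct_volume(vol, spec$spacing)
}

make_truth <- function(labels, comp, field, rho2, spec, true_shift, xr) {
  vv <- voxel_volume_ml(spec$spacing)
  csf <- labels == .lab[["csf"]]
  cranial <- rho2 <= 1
  lesion <- labels == .lab[["lesion"]]
  left <- xr > 0
  th <- spec$rotation_deg * pi / 180
  structure(list(
    labels = labels, compartments = comp, field = field, rho2 = rho2,
    cranial_mask = cranial, csf_mask = csf, lesion_mask = lesion,
    cranial_ml = sum(cranial) * vv,
    csf_total_ml = sum(csf) * vv,
    csf_left_ml = sum(csf & left) * vv,
    csf_right_ml = sum(csf & !left) * vv,
    midline = list(
      origin_vox = (dim(labels) + 1) / 2,
      normal = c(cos(th), sin(th), 0),
      theta_deg = spec$rotation_deg
    ),
    true_shift_mm = true_shift,
    spacing = spec$spacing,
    spec = spec
  ), class = "phantom_truth")
}

#' Apply unilateral edema to a baseline phantom
#'
#' Produces the follow-up appearance of evolving hemispheric edema on the
#' label field of a baseline phantom: sulcal CSF in the affected hemisphere
#' is effaced (converted to parenchyma) at the given fraction, the
#' ipsilateral ventricle is eroded, midline structures are displaced
#' laterally by a smooth field peaking centrally and vanishing at the fixed
#' skull, and a hypodense lesion is painted. The follow-up volume is
#' re-rendered and a new ground truth is computed from the modified labels.
#'
#' Effacement and compression removals are nested (ordered by the sulcal
#' pattern field / distance from the ventricle centroid), so increasing the
#' fraction always removes a superset of voxels.
#'
#' @param baseline the `ct` element of [generate_head_phantom()] (unused
#'   except for shape checks; the label field lives in `truth`).
#' @param truth the matching `phantom_truth`.
#' @param edema an [edema_spec()].
#' @param noise_seed seed for the follow-up rendering noise (defaults to a
#'   seed derived from the phantom seed).
#' @return A list with elements `ct` and `truth` for the follow-up scan.
#' @export
apply_edema <- function(baseline, truth, edema,
                        noise_seed = derive_seed(truth$spec$seed, "followup")) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(edema, "edema_spec"))
  spec <- truth$spec
  n <- dim(truth$labels)
  labels <- truth$labels
  comp <- truth$compartments
  field <- truth$field
  sgn <- if (edema$side == "left") 1 else -1

  co <- phantom_coords(spec)

  # 1. midline shift: content moves toward the contralateral side; the
  # displacement peaks at the centre and decays to zero at the skull.
  if (edema$shift_mm > 0) {
    w <- pmax(0, 1 - as.vector(truth$rho2))
    interior <- as.vector(truth$rho2) <= 1
    idx <- which(interior)
    i <- ((idx - 1L) %% n[1]) + 1L
    jk <- (idx - 1L) %/% n[1]
    # source voxel lies upstream of the displacement direction
    th <- spec$rotation_deg * pi / 180
    shift_vox <- edema$shift_mm * cos(th) / spec$spacing[1]
    si <- as.integer(round(i + sgn * shift_vox * w[idx]))
    si <- pmin(pmax(si, 1L), n[1])
    src <- si + jk * n[1]
    ok <- truth$rho2[src] <= 1
    dest <- idx[ok]
    src <- src[ok]
    labels[dest] <- truth$labels[src]
    comp[dest] <- truth$compartments[src]
    field[dest] <- truth$field[src]
  }

  hemi_code <- if (edema$side == "left") .cmp[["sulcal_left"]] else .cmp[["sulcal_right"]]
  vent_code <- if (edema$side == "left") .cmp[["vent_left"]] else .cmp[["vent_right"]]
  if (!any(comp == hemi_code | comp == vent_code))
    stop_config("affected side '%s' has no CSF compartments in truth",
                edema$side)

  # 2. sulcal effacement: remove the lowest-field fraction (nested removal)
  if (edema$effacement > 0) {
    sul <- which(comp == hemi_code)
    k <- round(edema$effacement * length(sul))
    if (k > 0) {
      drop <- sul[order(field[sul])[seq_len(k)]]
      labels[drop] <- .lab[["parenchyma"]]
      comp[drop] <- .cmp[["none"]]
    }
  }

  # 3. ventricle compression: erode outermost voxels first
  if (edema$compression > 0) {
    ven <- which(comp == vent_code)
    k <- round(edema$compression * length(ven))
    if (k > 0) {
      vi <- ((ven - 1L) %% n[1]) + 1L
      vj <- ((ven - 1L) %/% n[1]) %% n[2] + 1L
      vk <- (ven - 1L) %/% (n[1] * n[2]) + 1L
      cx <- c(mean(vi), mean(vj), mean(vk))
      d2 <- ((vi - cx[1]) * spec$spacing[1])^2 +
        ((vj - cx[2]) * spec$spacing[2])^2 +
        ((vk - cx[3]) * spec$spacing[3])^2
      drop <- ven[order(-d2)[seq_len(k)]]
      labels[drop] <- .lab[["parenchyma"]]
      comp[drop] <- .cmp[["none"]]
    }
  }

  # 4. hypodense lesion in the affected hemisphere
  if (edema$lesion_ml > 0) {
    ax <- phantom_axes(spec)
    r <- (edema$lesion_ml * 1000 / (4 / 3 * pi * 0.8 * 1.4 * 1.1))^(1 / 3)
    cx_les <- sgn * 0.45 * ax[1]
    if (0.8 * r > 0.42 * ax[1] || 1.4 * r > 0.8 * ax[2] ||
        1.1 * r > 0.8 * ax[3])
      stop_config("lesion of %.0f ml does not fit in the affected hemisphere",
                  edema$lesion_ml)
    lr2 <- ((co$xr - cx_les) / (0.8 * r))^2 + ((co$yr - 6) / (1.4 * r))^2 +
      (co$z / (1.1 * r))^2
    sel <- lr2 <= 1 & as.vector(labels) == .lab[["parenchyma"]]
    labels[array(sel, dim = n)] <- .lab[["lesion"]]
  }

  ct <- render_phantom(labels, spec, noise_seed = noise_seed)
  truth_fu <- make_truth(labels, comp, field, truth$rho2, spec,
                         true_shift = edema$shift_mm, xr = co$xr)
  list(ct = ct, truth = truth_fu)
}

# Separable Gaussian smoothing of a 3-D array; sigma in mm.
gauss_smooth <- function(arr, sigma_mm, spacing) {
  n <- dim(arr)
  for (a in 1:3) {
    sv <- sigma_mm / spacing[a]
    if (sv < 0.05) next
    r <- max(1L, as.integer(ceiling(3 * sv)))
    k <- stats::dnorm(-r:r, sd = sv)
    nb <- n[a]
    K <- matrix(0, nb, nb)
    for (off in -r:r) {
      d <- seq_len(nb)
      s <- d + off
      ok <- s >= 1 & s <= nb
      K[cbind(d[ok], s[ok])] <- k[off + r + 1]
    }
    K <- K / rowSums(K)
    perm <- c(a, setdiff(1:3, a))
    ap <- aperm(arr, perm)
    m <- K %*% matrix(ap, nrow = nb)
    arr <- aperm(array(m, dim = dim(ap)), order(perm))
  }
  arr
}
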