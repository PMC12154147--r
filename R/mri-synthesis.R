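#' MRI phantom specification
#'
#' Synthetic contrast-enhanced T1 volume: Gaussian background plus an
#' ellipsoidal enhancing lesion of additive contrast, on an anisotropic
#' voxel grid (default 0.1 x 0.1 x 0.4 mm, 15 coronal slices, mirroring a
#' small-animal gadolinium protocol). The brain mask is the in-plane
#' inscribed ellipse extruded through all slices; the contralateral
#' reference ROI is a box mirrored across the midline from the lesion.
#'
#' @param grid_shape Integer triple, voxels (x, y, slices).
#' @param voxel_size mm triple.
#' @param background_mean,background_sd Background intensity distribution
#'   (a.u.); `background_sd` must be >= 0 (0 gives a noiseless phantom).
#' @param lesion_center mm triple; default places the lesion in the
#'   "ipsilateral" half of the grid.
#' @param lesion_radii mm triple (ellipsoid semi-axes).
#' @param lesion_contrast Additive enhancement inside the lesion (a.u.).
#' @param contra_size Contralateral ROI box half-sizes in mm.
#' @param seed Integer seed.
#' @return An object of class `mri_phantom_spec`.
#' @export
mri_phantom_spec <- function(grid_shape = c(96, 96, 15),
                             voxel_size = c(0.1, 0.1, 0.4),
                             background_mean = 100,
                             background_sd = 5,
                             lesion_center = NULL,
                             lesion_radii = c(1.5, 1.5, 2.0),
                             lesion_contrast = 50,
                             contra_size = c(1.0, 1.0, 1.2),
                             seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 4))
    stop_field("grid_shape", "must be a triple of >= 4 voxels")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_field("voxel_size", "must be a positive mm triple")
  if (background_sd < 0) stop_field("background_sd", "must be >= 0")
  check_nonneg_vec(lesion_radii, "lesion_radii")
  extent <- grid_shape * voxel_size
  if (is.null(lesion_center))
    lesion_center <- c(extent[1] * 0.30, extent[2] * 0.5, extent[3] * 0.5)
  if (any(lesion_center - lesion_radii < 0) || any(lesion_center + lesion_radii > extent))
    stop_field("lesion_radii", "lesion must fit inside the grid")
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 background_mean = background_mean, background_sd = background_sd,
                 lesion_center = lesion_center, lesion_radii = lesion_radii,
                 lesion_contrast = lesion_contrast, contra_size = contra_size,
                 seed = as.integer(seed)),
            class = "mri_phantom_spec")
}

#' 3-D volume with physical voxel dimensions
#'
#' @param voxels 3-D numeric array.
#' @param voxel_size mm triple; the third axis is the slice axis.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, voxel_size) {
  if (length(dim(voxels)) != 3L) stop_field("voxels", "must be a 3-D array")
  if (any(voxel_size <= 0)) stop_field("voxel_size", "components must be > 0")
  structure(list(voxels = voxels, voxel_size = voxel_size), class = "volume_image")
}

#' Generate a synthetic contrast-enhanced MRI volume with ground truth
#'
#' @param spec An [mri_phantom_spec()].
#' @return List with `volume` ([volume_image()]), `brain_mask` and
#'   `contra_roi` (logical arrays), `lesion_mask` (ground-truth logical
#'   array), `true_volume_mm3` (lesion voxel count x voxel volume), `spec`.
#' @export
gen_mri_volume <- function(spec) {
  stopifnot(inherits(spec, "mri_phantom_spec"))
  set.seed(spec$seed)
  g <- spec$grid_shape; vs <- spec$voxel_size
  # voxel center coordinates in mm
  cx <- (seq_len(g[1]) - 0.5) * vs[1]
  cy <- (seq_len(g[2]) - 0.5) * vs[2]
  cz <- (seq_len(g[3]) - 0.5) * vs[3]
  X <- array(rep(cx, times = g[2] * g[3]), dim = g)
  Y <- array(rep(rep(cy, each = g[1]), times = g[3]), dim = g)
  Z <- array(rep(cz, each = g[1] * g[2]), dim = g)

  lc <- spec$lesion_center; lr <- spec$lesion_radii
  lesion <- ((X - lc[1]) / lr[1])^2 + ((Y - lc[2]) / lr[2])^2 + ((Z - lc[3]) / lr[3])^2 <= 1

  extent <- g * vs
  # brain: inscribed in-plane ellipse through all slices
  brain <- ((X - extent[1] / 2) / (extent[1] / 2))^2 +
    ((Y - extent[2] / 2) / (extent[2] / 2))^2 <= 1

  # contralateral ROI: lesion center mirrored across the in-plane midline
  cc <- c(extent[1] - lc[1], lc[2], lc[3])
  cs <- spec$contra_size
  contra <- abs(X - cc[1]) <= cs[1] & abs(Y - cc[2]) <= cs[2] &
    abs(Z - cc[3]) <= cs[3] & brain
  if (any(contra & lesion))
    stop("lesion overlaps the contralateral ROI; move the lesion or shrink the ROI",
         call. = FALSE)
  if (!any(contra)) stop("contralateral ROI is empty", call. = FALSE)

  vox <- array(rnorm(prod(g), spec$background_mean, spec$background_sd), dim = g)
  vox[lesion] <- vox[lesion] + spec$lesion_contrast
  list(volume = volume_image(vox, vs),
       brain_mask = brain & array(TRUE, g),
       contra_roi = contra,
       lesion_mask = lesion & brain,
       true_volume_mm3 = sum(lesion & brain) * prod(vs),
       spec = spec)
}
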