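#' Grid geometry of a volume set
#'
#' @param pvs A [PatientVolumeSet-class].
#' @return List with `dim`, `spacing` (mm), `origin` (mm; world coordinate of
#'   the center of voxel (1,1,1)).
#' @export
gridGeometry <- function(pvs) {
  cv <- pvs@contrasts[[1L]]
  list(dim = dim(cv@data), spacing = cv@spacing, origin = cv@origin)
}

#' Sphere radius implied by a biopsy-core volume
#'
#' Inverts the volume of a sphere: `radius = (3 V / 4 pi)^(1/3)`. The pathology
#' report's core volume defines the sampling sphere centered at the needle tip.
#'
#' @param coreVolume Volume in mm^3, positive.
#' @return Radius in mm.
#' @examples
#' radiusFromVolume(4 * pi / 3)   # 1
#' radiusFromVolume(4119.5)       # ~9.944
#' @export
radiusFromVolume <- function(coreVolume) {
  if (any(!is.finite(coreVolume)) || any(coreVolume <= 0))
    stop("core volume must be positive")
  (3 * coreVolume / (4 * pi))^(1 / 3)
}

#' Rasterize a sphere onto a voxel grid
#'
#' A voxel belongs to the mask iff the Euclidean distance from its center (in
#' world mm) to the sphere center is `<= radius` (closed ball; boundary ties
#' included). Voxel centers follow the center-of-voxel convention:
#' `origin + (index - 1) * spacing`.
#'
#' @param roi A [SphereROI-class].
#' @param geometry List with `dim`, `spacing`, `origin` (see [gridGeometry()]).
#' @return Logical 3-D array. Warns (does not error) when the mask is empty —
#'   tiny cores may fall between voxel centers.
#' @export
sphereMask <- function(roi, geometry) {
  dm <- geometry$dim; sp <- geometry$spacing; or <- geometry$origin
  ax <- lapply(1:3, function(a) (or[a] + (seq_len(dm[a]) - 1) * sp[a] - roi@center[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  msk <- d2 <= roi@radius^2
  if (!any(msk))
    warning("sphere mask is empty (radius ", format(roi@radius), " mm)")
  msk
}

#' Normalize contrasts to uninvolved white matter
#'
#' Divides each contrast voxel-wise by the mean of that same contrast inside
#' the patient's white-matter reference sphere, so the normalized mean over
#' the reference region is exactly 1. Idempotent and invariant to rescaling
#' of the raw intensities.
#'
#' @param pvs A [PatientVolumeSet-class].
#' @return The normalized [PatientVolumeSet-class] (`normalized` flag set).
#' @export
normalizeToWM <- function(pvs) {
  geom <- gridGeometry(pvs)
  wm <- sphereMask(pvs@wmROI, geom)
  if (!any(wm)) stop("white-matter ROI rasterizes to an empty mask")
  for (nm in contrastNames()) {
    cv <- pvs@contrasts[[nm]]
    mu <- mean(cv@data[wm])
    if (!is.finite(mu) || mu <= 0)
      stop("white-matter mean is not positive for contrast ", nm)
    cv@data <- cv@data / mu
    pvs@contrasts[[nm]] <- cv
  }
  pvs@normalized <- TRUE
  pvs
}

niftiFileNames <- function() {
  c("T1w" = "t1w.nii.gz", "T1w-post" = "t1wpost.nii.gz", "T2w" = "t2w.nii.gz",
    "T2-FLAIR" = "flair.nii.gz", "ADC" = "adc.nii.gz")
}

writeNiftiVolume <- function(data, path, spacing, origin) {
  img <- RNifti::asNifti(data)
  xf <- diag(4)
  xf[1, 1] <- spacing[1]; xf[2, 2] <- spacing[2]; xf[3, 3] <- spacing[3]
  xf[1:3, 4] <- origin
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  list(data = array(as.numeric(img), dim = dim(img)),
       spacing = abs(c(xf[1, 1], xf[2, 2], xf[3, 3])),
       origin = as.numeric(xf[1:3, 4]))
}

#' Read one patient's co-registered volumes from NIfTI files
#'
#' @param paths Named list/vector of file paths: the five contrasts (names =
#'   [contrastNames()]) plus `brain_mask`.
#' @param meta List with `patient_id`, `wm_center` (mm), `wm_radius` (mm).
#' @return A [PatientVolumeSet-class]. Errors name any missing contrast and
#'   report both shapes on a grid mismatch.
#' @export
readPatient <- function(paths, meta) {
  need <- c(contrastNames(), "brain_mask")
  missing <- setdiff(need, names(paths))
  if (length(missing))
    stop("missing contrast ", paste(missing, collapse = ", "))
  for (nm in need) {
    if (!file.exists(paths[[nm]]))
      stop("missing contrast ", nm, ": file not found: ", paths[[nm]])
  }
  vols <- lapply(need, function(nm) readNiftiVolume(paths[[nm]]))
  names(vols) <- need
  ref <- vols[[contrastNames()[1]]]
  for (nm in need[-1]) {
    if (!identical(dim(vols[[nm]]$data), dim(ref$data)))
      stop(sprintf("grid mismatch: %s is %s but %s is %s", nm,
                   paste(dim(vols[[nm]]$data), collapse = "x"),
                   contrastNames()[1], paste(dim(ref$data), collapse = "x")))
  }
  contrasts <- lapply(contrastNames(), function(nm)
    ContrastVolume(nm, vols[[nm]]$data, vols[[nm]]$spacing, vols[[nm]]$origin))
  names(contrasts) <- contrastNames()
  PatientVolumeSet(patientId = meta$patient_id, contrasts = contrasts,
                   brainMask = vols[["brain_mask"]]$data > 0.5,
                   wmROI = SphereROI(meta$wm_center, meta$wm_radius),
                   normalized = isTRUE(meta$normalized))
}

#' Write one patient's volumes as NIfTI files
#'
#' Inverse of [readPatient()]: writes the five contrasts and the brain mask
#' under `dir` using the package's canonical file names.
#'
#' @param pvs A [PatientVolumeSet-class].
#' @param dir Output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
writePatient <- function(pvs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geom <- gridGeometry(pvs)
  fn <- niftiFileNames()
  paths <- character(0)
  for (nm in contrastNames()) {
    p <- file.path(dir, fn[[nm]])
    writeNiftiVolume(pvs@contrasts[[nm]]@data, p, geom$spacing, geom$origin)
    paths[nm] <- p
  }
  p <- file.path(dir, "brain_mask.nii.gz")
  writeNiftiVolume(pvs@brainMask * 1, p, geom$spacing, geom$origin)
  paths["brain_mask"] <- p
  invisible(paths)
}
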