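# Volume I/O and grid handling: NIfTI read/write (via RNifti), trilinear /
# nearest-neighbor resampling to an isotropic grid, and alignment checks.
#
# Coordinate convention (used everywhere in the package): voxel indices are
# 0-based and world coordinates are origin + index * spacing, per axis.

#' Describe a voxel grid
#'
#' @param shape voxels per axis (length 3).
#' @param spacing mm per axis (length 3).
#' @param origin world position (mm) of voxel (0,0,0); default the zero vector.
#' @return object of class `volume_grid`.
#' @export
volume_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1)) stopf("shape must be 3 positive integers")
  if (length(spacing) != 3 || any(spacing <= 0)) stopf("spacing must be 3 positive values")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels @ %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 6), collapse = "x")))
  invisible(x)
}

#' Read a scalar NIfTI volume
#'
#' @param path path to a 3-D NIfTI file.
#' @return list with `data` (3-D numeric array) and `grid` ([volume_grid()]).
#'   No intensity rescaling is applied beyond the NIfTI scl slope/intercept
#'   handled by RNifti.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3)
    stopf("expected a 3-D volume but '%s' has %d dimensions (extra axis of size %d)",
          path, length(d), d[4])
  sp <- attr(img, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  sp <- abs(as.numeric(sp[seq_len(3)]))
  if (any(!is.finite(sp)) || any(sp <= 0))
    stopf("unreadable or ambiguous voxel spacing in header of %s", path)
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (!inherits(xf, "try-error") && is.matrix(xf)) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  list(data = array(as.numeric(img), d),
       grid = volume_grid(shape = d, spacing = sp, origin = origin))
}

#' Write a scalar volume as NIfTI
#'
#' @param data 3-D numeric array.
#' @param grid a [volume_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, grid, path) {
  if (length(dim(data)) != 3) stopf("data must be a 3-D array")
  if (!all(dim(data) == grid$shape)) stopf("data shape does not match grid")
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Resample a volume to an isotropic grid
#'
#' Continuous mode uses trilinear interpolation; label mode uses nearest
#' neighbor (for masks and label maps). The target grid covers the same
#' physical extent, with `ceiling(extent / target_spacing)` voxels per axis
#' and exactly the requested spacing.
#'
#' @param data 3-D array.
#' @param grid a [volume_grid()].
#' @param target_spacing scalar mm (isotropic target).
#' @param mode `"continuous"` or `"label"`.
#' @return list with resampled `data` and its new `grid`.
#' @export
resample_isotropic <- function(data, grid, target_spacing = 1,
                               mode = c("continuous", "label")) {
  mode <- match.arg(mode)
  if (target_spacing <= 0) stopf("target_spacing must be > 0")
  if (mode == "label") {
    vals <- unique(as.vector(data))
    if (length(vals) > 2 && any(abs(vals - round(vals)) > 1e-8))
      stopf("label mode requires integer-valued labels; found non-integer values")
  }
  d <- grid$shape
  if (all(abs(grid$spacing - target_spacing) < 1e-12))
    return(list(data = data, grid = grid))
  new_shape <- pmax(1L, as.integer(ceiling(d * grid$spacing / target_spacing)))
  # fractional source index of each target voxel center (0-based convention)
  src <- lapply(1:3, function(ax) (seq_len(new_shape[ax]) - 1) * target_spacing / grid$spacing[ax])
  out <- array(0, new_shape)
  if (mode == "label") {
    ii <- lapply(1:3, function(ax) pmin(pmax(round(src[[ax]]) + 1, 1), d[ax]))
    out <- data[ii[[1]], ii[[2]], ii[[3]], drop = FALSE]
    dim(out) <- new_shape
  } else {
    lo <- lapply(1:3, function(ax) pmin(pmax(floor(src[[ax]]), 0), d[ax] - 1))
    fr <- lapply(1:3, function(ax) pmin(pmax(src[[ax]] - lo[[ax]], 0), 1))
    hi <- lapply(1:3, function(ax) pmin(lo[[ax]] + 1, d[ax] - 1))
    # accumulate the 8 trilinear corners with separable weights
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      ix <- (if (cx == 0) lo[[1]] else hi[[1]]) + 1
      iy <- (if (cy == 0) lo[[2]] else hi[[2]]) + 1
      iz <- (if (cz == 0) lo[[3]] else hi[[3]]) + 1
      wx <- if (cx == 0) 1 - fr[[1]] else fr[[1]]
      wy <- if (cy == 0) 1 - fr[[2]] else fr[[2]]
      wz <- if (cz == 0) 1 - fr[[3]] else fr[[3]]
      w <- outer(outer(wx, wy), wz)
      out <- out + w * data[ix, iy, iz, drop = FALSE]
    }
  }
  list(data = out,
       grid = volume_grid(new_shape, rep(target_spacing, 3), grid$origin))
}

#' Check that a case's maps and ROI share one grid
#'
#' Verifies identical shapes and spacings (tolerance 1e-6 mm) across the
#' three NODDI maps and the ROI mask.
#'
#' @param case a `patient_case` (from [generate_case()] or [load_case()]).
#' @param tol spacing tolerance in mm.
#' @return list with `ok` (logical) and `mismatches` (data.frame naming the
#'   offending volume and axis; empty when aligned).
#' @export
check_alignment <- function(case, tol = 1e-6) {
  ref_shape <- dim(case$maps[[1]])
  ref_sp <- case$grid$spacing
  vols <- c(case$maps, list(roi = case$roi))
  grids <- attr(case, "volume_grids")
  mism <- list()
  for (nm in names(vols)) {
    d <- dim(vols[[nm]])
    for (ax in 1:3) {
      if (d[ax] != ref_shape[ax])
        mism[[length(mism) + 1]] <- data.frame(
          volume = nm, axis = ax, what = "shape",
          value = d[ax], reference = ref_shape[ax])
    }
    if (!is.null(grids) && !is.null(grids[[nm]])) {
      for (ax in 1:3) {
        if (abs(grids[[nm]]$spacing[ax] - ref_sp[ax]) > tol)
          mism[[length(mism) + 1]] <- data.frame(
            volume = nm, axis = ax, what = "spacing",
            value = grids[[nm]]$spacing[ax], reference = ref_sp[ax])
      }
    }
  }
  mism <- if (length(mism)) do.call(rbind, mism) else
    data.frame(volume = character(), axis = integer(), what = character(),
               value = numeric(), reference = numeric())
  list(ok = nrow(mism) == 0, mismatches = mism)
}

#' Load a patient case from manifest paths
#'
#' @param row one manifest row with `path_icvf`, `path_isovf`, `path_odi`,
#'   `path_roi` and the clinical columns.
#' @return a `patient_case`.
#' @export
load_case <- function(row) {
  vols <- lapply(c(ICVF = "path_icvf", ISOVF = "path_isovf", ODI = "path_odi"),
                 function(col) read_volume(row[[col]]))
  roi_v <- read_volume(row[["path_roi"]])
  grids <- c(lapply(vols, `[[`, "grid"), list(roi = roi_v$grid))
  case <- structure(list(
    patient_id = row$patient_id, diagnosis = row$diagnosis,
    age = row$age, sex = row$sex, center = row$center,
    maps = lapply(vols, `[[`, "data"),
    roi = roi_v$data > 0.5,
    truth_labels = NULL,
    grid = vols[[1]]$grid
  ), class = "patient_case")
  attr(case, "volume_grids") <- grids
  case
}
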