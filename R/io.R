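# Optional NIfTI export of images and parametric maps (RNifti, Suggests).

.need_rnifti <- function() {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI export requires the RNifti package")
}

#' Write a dynamic image or parametric map as NIfTI
#'
#' Dynamic arrays (`n x n x K`) are written as 4D volumes
#' (x, y, 1 slice, frame); matrices as single 2D slices. Voxel dimensions
#' are recorded in mm.
#'
#' @param image matrix or `n x n x K` array.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param voxel_size_mm in-plane voxel size.
#' @param slice_thickness_mm slice thickness.
#' @return `path`, invisibly.
#' @export
write_dynamic_nifti <- function(image, path, voxel_size_mm = 2.602,
                                slice_thickness_mm = voxel_size_mm) {
  .need_rnifti()
  arr <- if (length(dim(image)) == 3L) {
    array(image, dim = c(dim(image)[1], dim(image)[2], 1L, dim(image)[3]))
  } else {
    array(image, dim = c(dim(image), 1L))
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(voxel_size_mm, voxel_size_mm,
                           slice_thickness_mm,
                           rep(1, length(dim(arr)) - 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_dynamic_nifti
#' @export
read_dynamic_nifti <- function(path) {
  .need_rnifti()
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  if (length(d) == 4L && d[3] == 1L) array(arr, dim = d[c(1, 2, 4)]) else arr
}

#' Export the label map and parameter maps of a phantom example as NIfTI
#'
#' @param kin a `kinetic_param_map`.
#' @param dir output directory (created if missing).
#' @return Vector of written paths, invisibly.
#' @export
write_phantom_nifti <- function(kin, dir) {
  .need_rnifti()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- kin$phantom$voxel_size_mm
  paths <- character(0)
  p <- file.path(dir, "labels.nii.gz")
  write_dynamic_nifti(kin$phantom$labels + 0, p, vs)
  paths <- c(paths, p)
  for (nm in names(kin$maps)) {
    for (par in names(kin$maps[[nm]])) {
      p <- file.path(dir, sprintf("%s_%s.nii.gz", nm, par))
      write_dynamic_nifti(kin$maps[[nm]][[par]], p, vs)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
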