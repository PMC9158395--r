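# NIfTI I/O and ROI time-series extraction. Volumes and masks must share
# the exact voxel lattice; resampling is out of scope (inputs are assumed
# preprocessed and co-registered).

#' Read / write BOLD volumes and ROI masks (NIfTI-1)
#'
#' `readBoldVolume` expects a 4D series; `readRoiMask` expects a 3D mask.
#' Probabilistic masks (values in `[0, 1]`) are binarized at `threshold`
#' (default 0.5); any other non-binary content is a format error unless a
#' threshold is given explicitly.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param expectedDims optional grid dimensions to enforce.
#' @return `readBoldVolume`: a 4D array; `readRoiMask`: a [ROIMask-class].
#' @export
readBoldVolume <- function(path, expectedDims = NULL) {
  vol <- as.array(RNifti::readNifti(path))
  if (length(dim(vol)) != 4L)
    stop("shape error: expected a 4D BOLD series, got ",
         length(dim(vol)), "D in ", path)
  if (!is.null(expectedDims) &&
      !identical(dim(vol)[1:3], as.integer(expectedDims)))
    stop("shape error: volume grid ", paste(dim(vol)[1:3], collapse = "x"),
         " does not match expected ", paste(expectedDims, collapse = "x"))
  vol
}

#' @rdname readBoldVolume
#' @param name ROI name to attach to the mask.
#' @param threshold binarization threshold for probabilistic masks.
#' @export
readRoiMask <- function(path, name = basename(path), expectedDims = NULL,
                        threshold = NULL) {
  m <- as.array(RNifti::readNifti(path))
  if (length(dim(m)) != 3L)
    stop("shape error: expected a 3D mask, got ", length(dim(m)), "D in ",
         path)
  if (!is.null(expectedDims) && !identical(dim(m), as.integer(expectedDims)))
    stop("shape error: mask grid does not match expected dimensions")
  vals <- unique(as.vector(m))
  if (!all(vals %in% c(0, 1))) {
    if (is.null(threshold)) {
      if (any(vals < 0 | vals > 1))
        stop("format error: mask ", path, " is neither binary nor a ",
             "probability map; pass an explicit threshold")
      threshold <- 0.5
    }
    m <- m > threshold
  }
  new("ROIMask", name = name, data = array(as.logical(m), dim(m)))
}

#' @rdname readBoldVolume
#' @param volume 4D array to write.
#' @export
writeBoldVolume <- function(volume, path) {
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}

#' @rdname readBoldVolume
#' @param mask a [ROIMask-class].
#' @export
writeRoiMask <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(mask@data),
                                           dim(mask@data))), path)
  invisible(path)
}

#' Extract an ROI's voxel time-series matrix
#'
#' Rows are the mask's TRUE voxels in fixed lexicographic (array-index)
#' order, so extraction is invariant to how voxels were stored on disk.
#' Voxels with essentially zero temporal variance (sample SD < 1e-12) are
#' dropped with a warning; if every voxel is degenerate the ROI is rejected.
#'
#' @param volume 4D array sharing the mask's grid.
#' @param mask a [ROIMask-class] or logical 3D array.
#' @return V x T matrix.
#' @export
extractRoiTimeseries <- function(volume, mask) {
  arr <- if (is(mask, "ROIMask")) mask@data else mask
  nm <- if (is(mask, "ROIMask")) mask@name else "ROI"
  if (length(dim(volume)) != 4L)
    stop("shape error: volume must be 4D")
  if (!identical(dim(volume)[1:3], dim(arr)))
    stop("shape error: mask grid ", paste(dim(arr), collapse = "x"),
         " does not match volume grid ",
         paste(dim(volume)[1:3], collapse = "x"))
  idx <- which(arr)
  tn <- dim(volume)[4]
  X <- matrix(aperm(volume, c(4, 1, 2, 3)), nrow = tn)[, idx, drop = FALSE]
  X <- t(X)
  sds <- apply(X, 1, sd)
  bad <- sds < 1e-12
  if (all(bad))
    stop("degenerate ROI: all ", nrow(X), " voxels of ", nm,
         " have zero variance")
  if (any(bad)) {
    warning("dropping ", sum(bad), " zero-variance voxel(s) from ", nm)
    X <- X[!bad, , drop = FALSE]
  }
  X
}

#' Unweighted mean time series of an ROI matrix
#'
#' @param x V x T voxel time-series matrix.
#' @return numeric vector of length T.
#' @export
meanTimeseries <- function(x) {
  if (is.null(dim(x)) || nrow(x) < 1L)
    stop("degenerate ROI: empty time-series matrix")
  colMeans(x)
}
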