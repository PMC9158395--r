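#' Construct a voxel grid specification
#'
#' @param dims x/y/z voxel counts (default 24 x 24 x 12).
#' @param voxelMm isotropic voxel size in mm.
#' @param nTimepoints number of BOLD volumes (>= 10).
#' @param tr repetition time in seconds.
#' @export
gridSpec <- function(dims = c(24L, 24L, 12L), voxelMm = 3,
                     nTimepoints = 200L, tr = 2) {
  new("GridSpec", dims = as.integer(dims), voxelMm = voxelMm,
      nTimepoints = as.integer(nTimepoints), tr = tr)
}

#' @rdname gridSpec
#' @export
defaultGridSpec <- function() gridSpec()

boxMask <- function(dims, x, y, z) {
  m <- array(FALSE, dims)
  m[x, y, z] <- TRUE
  m
}

#' Generate the toy geometric ROI mask set
#'
#' Places ten axis-aligned ROIs on the grid as geometric stand-ins for
#' atlas-derived regions: left/right whole hippocampus (72 voxels each),
#' with the posterior (DG) and anterior (CA1/subiculum) segments as disjoint
#' 24-voxel slabs nested inside each hippocampus, plus four 32-voxel
#' resting-state network boxes (CEN, SAL, VIS, SMN) disjoint from the
#' hippocampi and from each other. The layout requires a grid of at least
#' 21 x 19 x 10 voxels.
#'
#' @param grid a [GridSpec-class].
#' @return a [ROIMaskSet-class].
#' @examples
#' masks <- generateMasks(defaultGridSpec())
#' maskSizes(masks)
#' @export
generateMasks <- function(grid) {
  stopifnot(is(grid, "GridSpec"))
  d <- grid@dims
  need <- c(21L, 19L, 10L)
  if (any(d < need))
    stop("grid too small for the ROI layout: need at least ",
         paste(need, collapse = " x "), " voxels, got ",
         paste(d, collapse = " x "))
  geo <- list(
    L_hipp   = list(x = 4:7,   y = 7:12,  z = 5:7),
    R_hipp   = list(x = 18:21, y = 7:12,  z = 5:7),
    L_DG     = list(x = 4:7,   y = 7:8,   z = 5:7),
    R_DG     = list(x = 18:21, y = 7:8,   z = 5:7),
    L_CA1sub = list(x = 4:7,   y = 11:12, z = 5:7),
    R_CA1sub = list(x = 18:21, y = 11:12, z = 5:7),
    CEN      = list(x = 4:7,   y = 16:19, z = 5:6),
    SAL      = list(x = 18:21, y = 16:19, z = 5:6),
    VIS      = list(x = 10:13, y = 3:6,   z = 8:9),
    SMN      = list(x = 10:13, y = 16:19, z = 9:10))
  masks <- lapply(names(geo), function(nm) {
    g <- geo[[nm]]
    new("ROIMask", name = nm, data = boxMask(d, g$x, g$y, g$z))
  })
  names(masks) <- names(geo)
  new("ROIMaskSet", masks = masks, dims = d)
}

# Row indices of a nested segment within its parent hippocampus matrix,
# using the canonical lexicographic voxel order.
segmentRowsIn <- function(segMask, hippMask) {
  seg <- which(segMask@data)
  hip <- which(hippMask@data)
  rows <- match(seg, hip)
  if (anyNA(rows))
    stop("segment ", segMask@name, " is not nested inside ", hippMask@name)
  rows
}
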