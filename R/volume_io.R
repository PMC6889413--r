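#' Read a NIfTI-1 volume
#'
#' Reads a 3D or 4D NIfTI-1 file and returns the data array together with
#' its voxel-to-world affine (sform/qform as resolved by RNifti).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array) and `affine`
#'   (4x4 matrix).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI-1 file: ",
                                           path, " (", conditionMessage(e), ")"))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  list(data = array(as.numeric(img), dim = dim(img)), affine = aff)
}

#' Write a NIfTI-1 volume
#'
#' @param data 3D or 4D numeric array.
#' @param affine 4x4 voxel-to-world transform (stored as sform, code 2).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, affine, path) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("data must be a 3D or 4D array")
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Default scanner affine
#'
#' Diagonal voxel-to-world transform with the acquisition voxel size
#' (4 x 4 x 3.6 mm by default) and a zero origin.
#'
#' @param voxel_size Length-3 numeric, mm per voxel along x, y, z.
#' @return 4x4 matrix.
#' @export
default_affine <- function(voxel_size = c(4, 4, 3.6)) {
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  diag(c(voxel_size, 1))
}

#' Common analysis mask across volumes
#'
#' Intersection of per-volume support masks: for a 4D volume a voxel is
#' kept if its time series has nonzero variance; for a 3D volume if its
#' value is nonzero. All volumes must share one grid.
#'
#' @param volumes A list of 3D/4D arrays (or a single array).
#' @return Logical 3D array.
#' @export
compute_mask <- function(volumes) {
  if (is.array(volumes)) volumes <- list(volumes)
  if (length(volumes) < 1) stop("need at least one volume")
  grid <- dim(volumes[[1]])[1:3]
  mask <- array(TRUE, dim = grid)
  for (v in volumes) {
    dv <- dim(v)
    if (length(dv) < 3 || any(dv[1:3] != grid))
      stop("grid mismatch across volumes: expected ", paste(grid, collapse = "x"),
           ", got ", paste(dv[1:3], collapse = "x"))
    if (length(dv) == 4) {
      m <- apply(v, 1:3, stats::var) > 0
    } else {
      m <- v != 0
    }
    mask <- mask & m
  }
  if (!any(mask)) warning("mask is empty: volumes have disjoint support")
  mask
}

#' Flatten a volume over a mask
#'
#' Converts a 3D or 4D volume to a matrix whose columns are the in-mask
#' voxels in R's native column-major raster order (x fastest). This fixed
#' order is the single voxel-indexing contract shared by every module;
#' [unflatten()] inverts it exactly, writing 0 outside the mask.
#'
#' @param volume 3D array (returns one row) or 4D array (one row per
#'   timepoint/volume).
#' @param mask Logical 3D array on the same grid.
#' @param affine Optional 4x4 affine carried along for reporting.
#' @param row_meaning `"time"` or `"subject"` (metadata only).
#' @return A `masked_matrix`: list with `data`, `mask`, `grid_dims`,
#'   `affine`, `row_meaning`.
#' @export
flatten <- function(volume, mask, affine = default_affine(),
                    row_meaning = c("time", "subject")) {
  row_meaning <- match.arg(row_meaning)
  dv <- dim(volume)
  if (is.null(dv) || !(length(dv) %in% c(3L, 4L)))
    stop("volume must be a 3D or 4D array")
  if (any(dv[1:3] != dim(mask)))
    stop("volume grid ", paste(dv[1:3], collapse = "x"),
         " does not match mask grid ", paste(dim(mask), collapse = "x"))
  idx <- which(as.vector(mask))
  if (length(dv) == 3L) {
    dat <- matrix(as.vector(volume)[idx], nrow = 1)
  } else {
    m <- matrix(volume, nrow = prod(dv[1:3]), ncol = dv[4])
    dat <- t(m[idx, , drop = FALSE])
  }
  structure(list(data = dat, mask = mask, grid_dims = dv[1:3],
                 affine = affine, row_meaning = row_meaning),
            class = "masked_matrix")
}

#' Restore a flat matrix (or vector) to volume form
#'
#' @param x A `masked_matrix`, a plain matrix (rows x in-mask voxels), or a
#'   vector with one value per in-mask voxel.
#' @param mask Logical 3D array (required when `x` is not a `masked_matrix`).
#' @param fill Value written outside the mask (default 0).
#' @return 3D array (single row / vector input) or 4D array.
#' @export
unflatten <- function(x, mask = NULL, fill = 0) {
  if (inherits(x, "masked_matrix")) {
    mask <- x$mask
    x <- x$data
  }
  if (is.null(mask)) stop("mask is required")
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  idx <- which(as.vector(mask))
  if (ncol(x) != length(idx))
    stop("x has ", ncol(x), " columns but mask has ", length(idx), " voxels")
  grid <- dim(mask)
  if (nrow(x) == 1L) {
    out <- array(fill, dim = grid)
    out[idx] <- x[1, ]
    return(out)
  }
  out <- matrix(fill, nrow = prod(grid), ncol = nrow(x))
  out[idx, ] <- t(x)
  array(out, dim = c(grid, nrow(x)))
}

#' @export
print.masked_matrix <- function(x, ...) {
  cat("masked_matrix:", nrow(x$data), "rows (", x$row_meaning, ") x",
      ncol(x$data), "in-mask voxels; grid",
      paste(x$grid_dims, collapse = "x"), "\n")
  invisible(x)
}
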