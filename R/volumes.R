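#' 3D scalar volume with affine and unit tag
#'
#' Container for a single 3D scalar grid (magnetic susceptibility in ppb,
#' mean diffusivity, R2*, fractional anisotropy, fiber-to-field angle in
#' radians, ...) together with a 4x4 voxel-index-to-MNI-mm affine and an
#' optional mask of valid voxels. Voxel indices are 0-based when passed
#' through the affine; NaN is the missing-data sentinel inside `data`, but
#' the mask is authoritative.
#'
#' @param data numeric 3D array.
#' @param affine invertible 4x4 matrix mapping 0-based voxel indices (homogeneous)
#'   to mm coordinates. Defaults to identity (1 mm isotropic).
#' @param mask optional logical array of the same shape; defaults to the
#'   finite voxels of `data`.
#' @param units unit tag carried through arithmetic (e.g. `"ppb"`, `"radians"`).
#' @return An object of class `volume3d` with fields `data`, `affine`,
#'   `mask`, `units`.
#' @export
volume3d <- function(data, affine = diag(4), mask = NULL, units = "unitless") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible")
  if (is.null(mask)) {
    mask <- is.finite(data)
  } else {
    mask <- array(as.logical(mask), dim = dim(data))
    if (!identical(dim(mask), dim(data)))
      stop("data and mask shapes differ")
  }
  structure(list(data = data, affine = affine, mask = mask,
                 units = as.character(units)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d [%s], %d valid voxels\n",
              d[1], d[2], d[3], x$units, sum(x$mask)))
  invisible(x)
}

#' @export
Ops.volume3d <- function(e1, e2) {
  v <- if (inherits(e1, "volume3d")) e1 else e2
  a1 <- if (inherits(e1, "volume3d")) e1$data else e1
  a2 <- if (missing(e2)) NULL else if (inherits(e2, "volume3d")) e2$data else e2
  if (inherits(e1, "volume3d") && inherits(e2, "volume3d"))
    check_aligned(e1, e2)
  out <- if (missing(e2)) get(.Generic)(a1) else get(.Generic)(a1, a2)
  if (is.logical(out)) return(out)
  volume3d(out, v$affine, v$mask, units = v$units)
}

# voxel edge lengths (mm) along the three axes
vol_voxdim <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

# cross-volume operations require equal shape + affine within 1e-4 mm
check_aligned <- function(a, b) {
  da <- if (inherits(a, "volume3d")) dim(a$data) else dim(a$labels)
  db <- if (inherits(b, "volume3d")) dim(b$data) else dim(b$labels)
  if (!identical(da, db)) stop("volumes are not aligned: shapes differ")
  if (max(abs(a$affine - b$affine)) > 1e-4)
    stop("volumes are not aligned: affines differ by more than 1e-4 mm")
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Loads a 3D NIfTI image; the unit tag is taken from `units` or, when
#' present, from a JSON sidecar (`<path minus extensions>.json`) written by
#' [write_volume()]. Non-finite voxels are excluded from the mask.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param units unit tag; overridden by a sidecar `units` entry if present.
#' @return A [volume3d()].
#' @export
read_volume <- function(path, units = "unitless") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected 3D volume")
  side <- sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$units)) units <- meta$units
  }
  volume3d(array(as.numeric(img), dim = dim(img)),
           affine = matrix(RNifti::xform(img), 4, 4), units = units)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Write a volume to NIfTI-1 with a JSON unit sidecar
#'
#' @param v a [volume3d()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume3d"))
  img <- RNifti::asNifti(v$data)
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::qform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(units = v$units), sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Integer label atlas of ROIs and tracts
#'
#' @param labels integer 3D array; 0 is background.
#' @param names named character vector or list mapping label value (as
#'   character) to region name; every nonzero label must be named.
#' @param affine 4x4 voxel-to-mm affine.
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(labels, names, affine = diag(4)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("expected 3D label grid")
  labels <- array(as.integer(labels), dim = dim(labels))
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  names <- unlist(names)
  missing <- setdiff(as.character(present), base::names(names))
  if (length(missing))
    stop("unnamed labels: ", paste(missing, collapse = ", "))
  structure(list(labels = labels, names = names, affine = as.matrix(affine)),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("<label_atlas> %s: %d regions\n",
              paste(dim(x$labels), collapse = " x "), length(x$names)))
  invisible(x)
}

#' Read a label atlas from NIfTI plus a JSON name sidecar
#'
#' @param path NIfTI path; names are read from the sidecar's `names` entry.
#' @return A [label_atlas()].
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected 3D volume")
  side <- sidecar_path(path)
  nm <- character(0)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    nm <- unlist(meta$names)
  }
  label_atlas(array(as.integer(img), dim = dim(img)), nm,
              affine = matrix(RNifti::xform(img), 4, 4))
}

#' Write a label atlas to NIfTI with a JSON name sidecar
#'
#' @param a a [label_atlas()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(a, path) {
  stopifnot(inherits(a, "label_atlas"))
  img <- RNifti::asNifti(a$labels, datatype = "int16")
  RNifti::sform(img) <- structure(a$affine, code = 2L)
  RNifti::qform(img) <- structure(a$affine, code = 2L)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(names = as.list(a$names)), sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

# zero-padded separable 1D Gaussian convolution along each axis
conv_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  L <- d[axis]
  m <- matrix(a, nrow = L)
  r <- (length(kern) - 1L) / 2L
  K <- matrix(0, L, L)
  for (j in seq_len(L)) {
    idx <- (j - r):(j + r)
    keep <- idx >= 1L & idx <= L
    K[idx[keep], j] <- kern[keep]
  }
  out <- array(K %*% m, dim = d[perm])
  aperm(out, order(perm))
}

#' Mask-aware Gaussian smoothing
#'
#' Separable Gaussian filtering with normalized convolution: the data are
#' multiplied by the mask, filtered, and divided by the filtered mask, so
#' masked-out (or NaN) voxels do not bleed into valid ones. Constant fields
#' are preserved exactly up to float tolerance.
#'
#' @param v a [volume3d()].
#' @param sigma_mm Gaussian kernel sigma in mm (scalar); converted per axis
#'   using the voxel size from the affine.
#' @return A smoothed [volume3d()] with the same mask and units.
#' @export
smooth_gaussian <- function(v, sigma_mm) {
  stopifnot(inherits(v, "volume3d"))
  if (!is.numeric(sigma_mm) || length(sigma_mm) != 1L || sigma_mm <= 0)
    stop("sigma must be positive")
  vox <- vol_voxdim(v$affine)
  dat <- v$data
  dat[!v$mask | !is.finite(dat)] <- 0
  msk <- array(as.numeric(v$mask), dim = dim(dat))
  for (axis in 1:3) {
    sig <- sigma_mm / vox[axis]
    r <- max(1L, ceiling(4 * sig))
    kern <- stats::dnorm((-r):r, sd = sig)
    kern <- kern / sum(kern)
    dat <- conv_axis(dat, kern, axis)
    msk <- conv_axis(msk, kern, axis)
  }
  out <- dat / msk
  out[msk <= 0] <- NaN
  volume3d(out, v$affine, v$mask, units = v$units)
}

# integer voxel offsets of a digital ball of given mm radius
ball_offsets <- function(radius_mm, voxdim) {
  r <- floor(radius_mm / voxdim)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d <- sqrt((g$dx * voxdim[1])^2 + (g$dy * voxdim[2])^2 + (g$dz * voxdim[3])^2)
  as.matrix(g[d <= radius_mm + 1e-9, , drop = FALSE])
}

shift_mask <- function(m, off) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    o <- off[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) { src[[k]] <- 1:(d[k] - o);       dst[[k]] <- (1 + o):d[k] }
    else        { src[[k]] <- (1 - o):d[k];       dst[[k]] <- 1:(d[k] + o) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Morphological erosion of a 3D mask
#'
#' `mode = "six_connected"` performs one erosion with the 6-neighbour cross
#' element; `mode = "radius_mm"` erodes with a digital ball of the given
#' physical radius (a voxel survives iff every in-ball neighbour is inside
#' the mask). Voxels beyond the grid border count as background.
#'
#' @param m logical 3D array.
#' @param mode `"six_connected"` or `"radius_mm"`.
#' @param radius_mm ball radius in mm (required for `"radius_mm"`).
#' @param voxdim voxel edge lengths in mm (length 3; default 1 mm isotropic).
#' @return Eroded logical array. Warns (does not error) if the result is empty.
#' @export
erode_mask <- function(m, mode = c("six_connected", "radius_mm"),
                       radius_mm = NULL, voxdim = c(1, 1, 1)) {
  mode <- match.arg(mode)
  if (!is.array(m) || length(dim(m)) != 3L) stop("expected 3D mask")
  m <- array(as.logical(m), dim = dim(m))
  offs <- if (mode == "six_connected") {
    rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
          c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    if (is.null(radius_mm) || radius_mm <= 0)
      stop("radius_mm required for radius_mm mode")
    ball_offsets(radius_mm, voxdim)
  }
  out <- m
  for (i in seq_len(nrow(offs))) {
    off <- offs[i, ]
    if (all(off == 0)) next
    # neighbour at +off must be in-mask: shift by -off aligns it to the voxel
    out <- out & shift_mask(m, -off)
  }
  if (!any(out)) warning("mask is empty after erosion")
  out
}

#' Extract the values of one labelled region
#'
#' Returns the finite, in-mask values of all voxels carrying `label`, in
#' column-major (lexicographic, first index fastest) voxel order.
#'
#' @param v a [volume3d()].
#' @param a a [label_atlas()] aligned with `v`.
#' @param label integer label present in the atlas.
#' @return Numeric vector of voxel values.
#' @export
roi_values <- function(v, a, label) {
  stopifnot(inherits(v, "volume3d"), inherits(a, "label_atlas"))
  check_aligned(v, a)
  if (!any(a$labels == label)) stop("unknown label: ", label)
  sel <- a$labels == label & v$mask & is.finite(v$data)
  as.numeric(v$data[sel])
}

#' Fiber-to-field angle from an orientation field
#'
#' Computes the angle between the predominant white-matter fiber orientation
#' and the main magnetic field axis: theta = arccos(|v . b| / ||v||),
#' folded to \[0, pi/2\] so antipodal orientations are equivalent.
#'
#' @param orientation_field numeric 4D array (X x Y x Z x 3) of per-voxel
#'   direction vectors (need not be unit length).
#' @param b0_axis unit 3-vector of the main field direction (default +z).
#' @param affine 4x4 affine for the output volume.
#' @param mask optional logical 3D array restricting evaluation; a zero
#'   vector inside the mask is an error.
#' @return A [volume3d()] of theta in radians, units `"radians"`.
#' @export
compute_theta <- function(orientation_field, b0_axis = c(0, 0, 1),
                          affine = diag(4), mask = NULL) {
  d <- dim(orientation_field)
  if (length(d) != 4L || d[4] != 3L)
    stop("orientation_field must be X x Y x Z x 3")
  if (abs(sqrt(sum(b0_axis^2)) - 1) > 1e-8)
    stop("b0_axis must be unit length")
  vx <- orientation_field[, , , 1]
  vy <- orientation_field[, , , 2]
  vz <- orientation_field[, , , 3]
  nrm <- sqrt(vx^2 + vy^2 + vz^2)
  if (is.null(mask)) mask <- nrm > 0 & is.finite(nrm)
  if (any(mask & (nrm == 0 | !is.finite(nrm))))
    stop("zero orientation vector inside mask")
  dot <- abs(vx * b0_axis[1] + vy * b0_axis[2] + vz * b0_axis[3])
  theta <- acos(pmin(dot / nrm, 1))
  theta[!mask] <- NaN
  volume3d(theta, affine, mask, units = "radians")
}

#' Nearest-neighbour resampling of a label atlas onto a target grid
#'
#' Resampling is deliberately explicit (labels only, nearest neighbour);
#' scalar volumes are never silently resampled.
#'
#' @param a a [label_atlas()].
#' @param target_affine affine of the target grid.
#' @param target_dim integer length-3 dimensions of the target grid.
#' @return A [label_atlas()] on the target grid.
#' @export
resample_labels <- function(a, target_affine, target_dim) {
  stopifnot(inherits(a, "label_atlas"))
  g <- as.matrix(expand.grid(i = 0:(target_dim[1] - 1),
                             j = 0:(target_dim[2] - 1),
                             k = 0:(target_dim[3] - 1)))
  mm <- cbind(g, 1) %*% t(target_affine)        # target voxel centers in mm
  src <- mm %*% t(solve(a$affine))              # -> source voxel coords
  idx <- round(src[, 1:3])
  d <- dim(a$labels)
  ok <- idx[, 1] >= 0 & idx[, 1] < d[1] &
        idx[, 2] >= 0 & idx[, 2] < d[2] &
        idx[, 3] >= 0 & idx[, 3] < d[3]
  lab <- integer(nrow(idx))
  lab[ok] <- a$labels[idx[ok, , drop = FALSE] + 1L]
  label_atlas(array(lab, dim = target_dim), a$names, affine = target_affine)
}
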