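# HU volume container and world/voxel geometry.
#
# Conventions (used everywhere in the package):
#   * the grid is stored in (x, y, z) axis order;
#   * voxel indices are 0-based and the stored value is the sample at the
#     voxel centre;
#   * world coordinates are millimetres, world = origin + index * spacing.

HU_MIN <- -1024
HU_MAX <- 3071

#' Construct an HU volume
#'
#' A `hu_volume` wraps a 3D numeric array of Hounsfield units together with
#' its voxel spacing (mm) and the world coordinate of the centre of voxel
#' (0,0,0). Values outside the 12-bit CT range \[-1024, 3071\] are clamped and
#' the number of clamped voxels is recorded in the `n_clamped` field (CBCT
#' reconstructions occasionally emit out-of-range values around metal).
#'
#' @param data numeric 3D array of HU values, at least 2 voxels per axis.
#' @param spacing voxel size in mm; scalar or length-3, strictly positive.
#' @param origin world coordinate (mm) of the centre of voxel (0,0,0).
#' @return An object of class `hu_volume` with fields `data`, `spacing`,
#'   `origin` and `n_clamped`.
#' @examples
#' v <- hu_volume(array(0, dim = c(4, 4, 4)), spacing = 0.3)
#' dim(v$data)
#' @export
hu_volume <- function(data, spacing = 0.3, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_input("data must be a 3D array")
  if (any(dim(data) < 2L))
    stop_input("volume must have at least 2 voxels along every axis")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop_input("spacing must be strictly positive (length 1 or 3)")
  origin <- as_point3(origin, "origin")
  storage.mode(data) <- "double"
  if (any(!is.finite(data)))
    stop_input("HU values must all be finite")
  n_clamped <- sum(data < HU_MIN | data > HU_MAX)
  if (n_clamped > 0) {
    data[data < HU_MIN] <- HU_MIN
    data[data > HU_MAX] <- HU_MAX
  }
  structure(list(data = data, spacing = spacing, origin = origin,
                 n_clamped = as.integer(n_clamped)),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("HU volume:", paste(d, collapse = " x "), "voxels\n")
  cat("  spacing (mm):", paste(format(x$spacing), collapse = " x "), "\n")
  cat("  origin  (mm):", paste(format(x$origin), collapse = ", "), "\n")
  cat("  HU range:", format(min(x$data)), "..", format(max(x$data)), "\n")
  if (x$n_clamped > 0)
    cat("  clamped voxels:", x$n_clamped, "\n")
  invisible(x)
}

# World bounding box spanned by voxel centres: 2x3 matrix (min; max).
world_bbox <- function(v) {
  d <- dim(v$data)
  rbind(v$origin, v$origin + (d - 1) * v$spacing)
}

# World points (n x 3) -> continuous 0-based voxel indices (n x 3).
world_to_index <- function(v, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  sweep(sweep(pts, 2L, v$origin, "-"), 2L, v$spacing, "/")
}

index_to_world <- function(v, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx, 2L, v$spacing, "*"), 2L, v$origin, "+")
}

# Trilinear interpolation of the volume at world points (n x 3).
# Out-of-bounds points (beyond the voxel-centre bounding box) get `fill`.
# Returns list(values, oob) with oob a logical vector.
trilinear_sample <- function(v, pts, fill = HU_MIN) {
  idx <- world_to_index(v, pts)
  d <- dim(v$data)
  eps <- 1e-9
  oob <- idx[, 1] < -eps | idx[, 1] > d[1] - 1 + eps |
         idx[, 2] < -eps | idx[, 2] > d[2] - 1 + eps |
         idx[, 3] < -eps | idx[, 3] > d[3] - 1 + eps
  # clamp so arithmetic below stays in range; oob values overwritten at the end
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 0), d[a] - 1)
  i0 <- pmin(floor(idx[, 1]), d[1] - 2); fx <- idx[, 1] - i0
  j0 <- pmin(floor(idx[, 2]), d[2] - 2); fy <- idx[, 2] - j0
  k0 <- pmin(floor(idx[, 3]), d[3] - 2); fz <- idx[, 3] - k0
  n12 <- d[1] * d[2]
  base <- 1 + i0 + d[1] * j0 + n12 * k0
  g <- v$data
  c000 <- g[base];               c100 <- g[base + 1]
  c010 <- g[base + d[1]];        c110 <- g[base + d[1] + 1]
  c001 <- g[base + n12];         c101 <- g[base + n12 + 1]
  c011 <- g[base + d[1] + n12];  c111 <- g[base + d[1] + n12 + 1]
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  val <- c0 * (1 - fz) + c1 * fz
  val[oob] <- fill
  list(values = val, oob = oob)
}

#' Read an HU volume from NIfTI or NRRD
#'
#' Supported containers are NIfTI-1 (`.nii`, `.nii.gz`) and NRRD (`.nrrd`)
#' with axis-aligned geometry. Whatever the on-disk axis convention, the grid
#' is returned in (x, y, z) order with spacing and origin from the file
#' metadata. Values are clamped to \[-1024, 3071\] on load (`n_clamped` in
#' the result counts affected voxels).
#'
#' CBCT gray values only approximate scanner-calibrated HU; when a site
#' calibration is available it can be applied on load as `gain * value +
#' offset`.
#'
#' @param path path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @param gain,offset optional affine recalibration applied to raw values
#'   before clamping.
#' @return An [hu_volume()].
#' @export
read_volume <- function(path, gain = 1, offset = 0) {
  if (!is.character(path) || length(path) != 1L)
    stop_input("path must be a single file path")
  if (!file.exists(path))
    stop_format(sprintf("volume file does not exist: '%s'", path))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    raw <- tryCatch(RNifti::readNifti(path),
                    error = function(e)
                      stop_format(sprintf("cannot read NIfTI file '%s': %s",
                                          path, conditionMessage(e))))
    arr <- as.array(raw)
    arr <- array(as.numeric(arr), dim = dim(arr))  # drop RNifti attributes
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
      arr <- arr[, , , 1, drop = TRUE]
    if (length(dim(arr)) != 3L)
      stop_format(sprintf("'%s' is not a 3D volume", path))
    xf <- RNifti::xform(raw)
    rot <- xf[1:3, 1:3]
    if (max(abs(rot - diag(diag(rot)))) < 1e-4 && all(diag(rot) > 0)) {
      spacing <- diag(rot)
      origin <- xf[1:3, 4]
    } else {
      # oblique or flipped orientation: fall back to pixdim, warn once
      spacing <- RNifti::pixdim(raw)[1:3]
      origin <- c(0, 0, 0)
      warning("non-axis-aligned NIfTI orientation; using pixdim spacing and zero origin")
    }
    if (anyNA(spacing) || any(spacing <= 0))
      stop_metadata(sprintf("missing or invalid voxel spacing in '%s'", path))
    # NIfTI headers store geometry as float32; renormalize to the decimal
    # precision float32 carries so 0.3 mm survives a round trip exactly
    spacing <- signif(spacing, 7)
    origin <- ifelse(origin == 0, 0, signif(origin, 7))
  } else if (grepl("\\.nrrd$", lp)) {
    nr <- read_nrrd(path)
    arr <- nr$data; spacing <- nr$spacing; origin <- nr$origin
  } else {
    stop_format(sprintf("unsupported volume format: '%s' (expect .nii, .nii.gz or .nrrd)",
                        path))
  }
  if (gain != 1 || offset != 0) arr <- arr * gain + offset
  hu_volume(arr, spacing = spacing, origin = origin)
}

#' Write an HU volume to NIfTI or NRRD
#'
#' The format is chosen from the file extension. Data are stored as float64
#' so that `read_volume(write_volume(v))` round-trips the grid exactly.
#'
#' @param v an [hu_volume()].
#' @param path destination `.nii`, `.nii.gz` or `.nrrd` path; the parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (!inherits(v, "hu_volume")) stop_input("v must be an hu_volume")
  if (!dir.exists(dirname(path)))
    stop_io(sprintf("parent directory does not exist: '%s'", dirname(path)))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::asNifti(v$data)
    RNifti::pixdim(img) <- v$spacing
    m <- diag(c(v$spacing, 1))
    m[1:3, 4] <- v$origin
    RNifti::sform(img) <- structure(m, code = 2L)
    RNifti::qform(img) <- structure(m, code = 2L)
    ok <- tryCatch({
      RNifti::writeNifti(img, path, datatype = "double")
      TRUE
    }, error = function(e) FALSE)
    if (!ok || !file.exists(path))
      stop_io(sprintf("cannot write NIfTI file '%s'", path))
  } else if (grepl("\\.nrrd$", lp)) {
    write_nrrd(v$data, v$spacing, v$origin, path)
  } else {
    stop_format(sprintf("unsupported volume format: '%s'", path))
  }
  invisible(path)
}
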