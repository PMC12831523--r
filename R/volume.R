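#' 3-D property volume on a regular grid
#'
#' Container for a voxelized scalar field (Zeff, RED, RSP, or an integer label
#' map) with physical spacing and origin. The origin is the physical position
#' (mm) of the center of voxel `[1, 1, 1]`; x/y are in-plane, z is the slice
#' axis.
#'
#' @param values 3-D numeric array.
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm, all > 0.
#' @param origin Physical position (mm) of the first voxel center; defaults to
#'   centering the grid on (0, 0) in-plane with the first slice at z = 0.
#' @param quantity One of `"zeff"`, `"red"`, `"rsp"`, `"label"`.
#' @return An object of class `property_volume`.
#' @export
property_volume <- function(values, spacing, origin = NULL,
                            quantity = c("zeff", "red", "rsp", "label")) {
  quantity <- match.arg(quantity)
  stopifnot(is.array(values), length(dim(values)) == 3L,
            is.numeric(spacing), length(spacing) == 3L, all(spacing > 0))
  if (quantity != "label" && any(!is.finite(values)))
    stop("property volumes must be finite", call. = FALSE)
  if (is.null(origin)) {
    d <- dim(values)
    origin <- c(-(d[1] - 1) / 2 * spacing[1], -(d[2] - 1) / 2 * spacing[2], 0)
  }
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), quantity = quantity),
            class = "property_volume")
}

#' @export
print.property_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<property_volume> %s  %dx%dx%d voxels @ %.2fx%.2fx%.2f mm\n",
              x$quantity, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
dim.property_volume <- function(x) dim(x$values)

# physical in-plane voxel-center coordinate vectors (mm)
voxel_coords <- function(vol) {
  d <- dim(vol$values)
  list(x = vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
       y = vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
       z = vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3])
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Write a property volume to NIfTI
#'
#' The quantity label and origin are recorded in the header description; the
#' spacing goes into the header geometry (`pixdim`).
#'
#' @param vol A [property_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "property_volume"))
  desc <- sprintf("quantity=%s;origin=%.4f,%.4f,%.4f",
                  vol$quantity, vol$origin[1], vol$origin[2], vol$origin[3])
  im <- RNifti::asNifti(vol$values,
                        reference = list(pixdim = c(-1, vol$spacing, 0, 0, 0, 0),
                                         descrip = desc),
                        datatype = "double")
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a property volume from NIfTI
#'
#' Inverse of [write_volume()]: restores values, spacing, quantity and origin.
#'
#' @param path NIfTI file path.
#' @return A [property_volume()].
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  desc <- RNifti::niftiHeader(im)$descrip
  quantity <- sub(".*quantity=([a-z]+).*", "\\1", desc)
  if (!quantity %in% c("zeff", "red", "rsp", "label"))
    stop("NIfTI description does not identify the stored quantity: ", desc,
         call. = FALSE)
  origin <- NULL
  if (grepl("origin=", desc))
    origin <- as.numeric(strsplit(sub(".*origin=([-0-9.,]+).*", "\\1", desc),
                                  ",")[[1]])
  property_volume(array(as.numeric(im), dim = dim(im)),
                  spacing = RNifti::pixdim(im)[1:3],
                  origin = origin, quantity = quantity)
}
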