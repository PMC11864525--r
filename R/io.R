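# io_formats: reading/writing volumes and intensity normalization.

#' Read a 3D volume from NIfTI or multi-page TIFF
#'
#' NIfTI-1 (.nii / .nii.gz) is the primary container; a 3D multi-page TIFF is
#' accepted for phantoms. Intensities are returned unmodified (as doubles);
#' voxel spacing is taken from the NIfTI header (TIFF has none, so spacing
#' defaults to 1 mm).
#'
#' @param path file path.
#' @return A [Volume3D-class].
#' @seealso [writeVolume()], [normalizeIntensity()]
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lower <- tolower(path)
  if (grepl("\\.tiff?$", lower)) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                      error = function(e)
                        stop("unreadable TIFF file: ", path, " (",
                             conditionMessage(e), ")"))
    if (!is.list(pages)) pages <- list(pages)
    if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
      stop("TIFF pages must be single-channel 2D slices")
    if (length(pages) < 1L) stop("empty TIFF stack: ", path)
    d <- dim(pages[[1L]])
    arr <- array(0, dim = c(length(pages), d[1L], d[2L]))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
    return(Volume3D(arr))
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("unreadable NIfTI file: ", path, " (",
                         conditionMessage(e), ")"))
  arr <- as.array(img)
  # squeeze trailing singleton dims some writers add
  d <- dim(arr)
  while (length(d) > 3L && d[length(d)] == 1L) {
    d <- d[-length(d)]
    dim(arr) <- d
  }
  if (length(arr) == 1L) {
    # a 1x1x1 volume: writers collapse the rank to 1
    d <- c(1L, 1L, 1L)
    dim(arr) <- d
  }
  if (length(d) != 3L)
    stop(sprintf("expected a 3D scalar field, observed rank %d in %s",
                 length(d), path))
  sp <- RNifti::pixdim(img)
  # rank-collapsed degenerate volumes (see above) keep fewer pixdim entries;
  # restore the squeezed axes by recycling the last one
  if (length(sp) >= 1L && length(sp) < 3L)
    sp <- c(sp, rep(sp[length(sp)], 3L - length(sp)))
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    sp <- c(1, 1, 1)
  Volume3D(array(as.numeric(arr), dim = d), spacing = as.numeric(sp[1:3]))
}

#' Write a 3D volume to NIfTI
#'
#' Intensities are written as 64-bit floats so that
#' \code{readVolume(writeVolume(v))} is a lossless, bit-identical round trip;
#' the header spacing equals \code{voxelSpacing(vol)}.
#'
#' @param vol a [Volume3D-class].
#' @param path output path ending in .nii or .nii.gz.
#' @return Invisibly, \code{path}.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "Volume3D"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir)
  arr <- vol@data
  attr(arr, "pixdim") <- vol@spacing
  img <- RNifti::asNifti(arr, datatype = "double")
  ok <- tryCatch({
    RNifti::writeNifti(img, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop("could not write volume to ", path)
  invisible(path)
}

#' Rescale a volume so its maximum intensity is 1
#'
#' Per-volume max normalization: every voxel is divided by the volume maximum,
#' making the Rician noise levels (fractions of peak intensity) well defined.
#' An all-zero volume is returned unchanged. Negative intensities are a domain
#' error: magnitude MR images are nonnegative.
#'
#' @param vol a [Volume3D-class].
#' @return A [Volume3D-class] with max intensity 1 (or all-zero).
#' @examples
#' v <- Volume3D(array(7, c(8, 8, 8)))
#' max(volData(normalizeIntensity(v)))
#' @export
normalizeIntensity <- function(vol) {
  stopifnot(is(vol, "Volume3D"))
  if (any(vol@data < 0))
    stop("negative intensities: magnitude images must be nonnegative")
  mx <- max(vol@data)
  if (mx == 0) return(vol)
  Volume3D(vol@data / mx, spacing = vol@spacing, metadata = vol@metadata)
}
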