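.as_dwi_array <- function(dwi) {
  a <- unclass(as.array(dwi))
  attributes(a) <- list(dim = dim(a))
  if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
  if (length(dim(a)) != 4L)
    stop("expected a 4D diffusion-weighted volume", call. = FALSE)
  storage.mode(a) <- "double"
  a
}

#' NIfTI volume input / output
#'
#' Thin wrappers over [RNifti] for reading DWI volumes and writing
#' parameter maps. `write_volume_nifti()` accepts a plain array, an
#' `xq_param_map` (its `map` field is written) or an `RNifti` image; an
#' optional `template` image supplies the affine/orientation.
#'
#' @param path File path (`.nii` / `.nii.gz`).
#' @return `read_dwi_nifti()`: a 4D `niftiImage`.
#' @export
read_dwi_nifti <- function(path) RNifti::readNifti(path)

#' @param x Array, `xq_param_map` or `niftiImage`.
#' @param template Optional `niftiImage` providing geometry.
#' @rdname read_dwi_nifti
#' @export
write_volume_nifti <- function(x, path, template = NULL) {
  if (inherits(x, "xq_param_map")) x <- x$map
  img <- if (is.null(template)) RNifti::asNifti(x)
         else RNifti::asNifti(x, reference = template)
  RNifti::writeNifti(img, path)
  invisible(path)
}
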