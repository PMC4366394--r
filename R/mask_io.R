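#' Read and write masks and label maps
#'
#' Masks travel as 8-bit PNG (foreground 255, background 0; spacing is not
#' stored in PNG, so it must be supplied on read) or as NIfTI, where pixel
#' spacing comes from the header. Label maps use the same containers with
#' integer labels 0-7 (PNG stores label/7 grey levels).
#'
#' @param mask A `cc_mask`.
#' @param path File path.
#' @param spacing Pixel spacing in mm for PNG input (one or two values).
#' @return `read_mask_*` return a `cc_mask`; writers return `path`
#'   invisibly.
#' @name mask_io
NULL

#' @rdname mask_io
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "cc_mask"))
  png::writePNG(mask$pixels * 1, path)
  invisible(path)
}

#' @rdname mask_io
#' @export
read_mask_png <- function(path, spacing = 1) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  cc_mask(img > 0.5, spacing)
}

#' @rdname mask_io
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "cc_mask"))
  arr <- array(as.integer(mask$pixels),
               dim = c(nrow(mask$pixels), ncol(mask$pixels), 1L))
  attr(arr, "pixdim") <- c(mask$spacing, 1)
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' @rdname mask_io
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] != 1) {
      abort("expected a 2-D or single-slice 3-D NIfTI mask",
            class = "ccmorph_input_error")
    }
    arr <- arr[, , 1]
  }
  sp <- RNifti::pixdim(img)[1:2]
  cc_mask(arr != 0, sp)
}

#' Write a parcellation label map
#'
#' @param result A `cc_parcellation` (see [partition_witelson()]).
#' @param path Output path; `.png` stores labels as grey levels
#'   `label / 7`, `.nii`/`.nii.gz` stores integer labels.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(result, path) {
  stopifnot(inherits(result, "cc_parcellation"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(result$labels / 7, path)
  } else {
    arr <- array(as.integer(result$labels),
                 dim = c(nrow(result$labels), ncol(result$labels), 1L))
    attr(arr, "pixdim") <- c(result$spacing, 1)
    RNifti::writeNifti(RNifti::asNifti(arr), path)
  }
  invisible(path)
}
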