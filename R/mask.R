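#' Binary midsagittal mask
#'
#' A `cc_mask` wraps a logical pixel matrix plus its physical pixel spacing.
#' Rows run superior to inferior, columns anterior to posterior (the mask is
#' assumed to be already midsagittally oriented). The foreground must be
#' nonempty and form a single 8-connected component.
#'
#' @param pixels Logical or 0/1 matrix; `TRUE`/nonzero = corpus callosum.
#' @param spacing Pixel spacing in mm, either one value or `c(row, col)`.
#' @return An object of class `cc_mask` with elements `pixels` (logical
#'   matrix) and `spacing` (named numeric of length 2).
#' @export
#' @examples
#' m <- cc_mask(matrix(1, 20, 90), spacing = 1)
#' mask_area(m)
cc_mask <- function(pixels, spacing = 1) {
  if (!is.matrix(pixels)) {
    abort("pixels must be a matrix", class = "ccmorph_input_error")
  }
  px <- matrix(as.logical(pixels != 0), nrow(pixels), ncol(pixels))
  if (anyNA(px)) {
    abort("mask contains missing values", class = "ccmorph_input_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- c(spacing, spacing)
  if (length(spacing) != 2 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("spacing must be one or two positive values (mm/pixel)",
          class = "ccmorph_input_error")
  }
  if (!any(px)) {
    abort("mask has no foreground pixels", class = "ccmorph_input_error")
  }
  ncomp <- count_components(px)
  if (ncomp != 1) {
    abort(sprintf("mask must have exactly one 8-connected component (found %d)",
                  ncomp),
          class = "ccmorph_input_error")
  }
  structure(
    list(pixels = px, spacing = c(row = spacing[1], col = spacing[2])),
    class = "cc_mask"
  )
}

#' @export
print.cc_mask <- function(x, ...) {
  cat(sprintf("<cc_mask> %d x %d pixels, %.3g x %.3g mm/pixel, %d foreground (%.1f mm^2)\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              sum(x$pixels), mask_area(x)))
  invisible(x)
}

#' Total foreground area of a mask in mm^2
#' @param mask A `cc_mask`.
#' @return Numeric scalar.
#' @export
mask_area <- function(mask) {
  stopifnot(inherits(mask, "cc_mask"))
  sum(mask$pixels) * prod(mask$spacing)
}

# Number of 8-connected foreground components, via an igraph pixel-adjacency
# graph (offsets E, S, SE, SW cover all undirected 8-neighbour pairs).
count_components <- function(px) {
  idx <- which(px)
  if (length(idx) == 0) return(0L)
  if (length(idx) == 1) return(1L)
  nr <- nrow(px)
  nc <- ncol(px)
  id <- integer(length(px))
  id[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cl <- ((idx - 1L) %/% nr) + 1L
  edges <- list()
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (o in offs) {
    rn <- r + o[1]
    cn <- cl + o[2]
    ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    nb <- (cn[ok] - 1L) * nr + rn[ok]
    hit <- px[nb]
    if (any(hit)) {
      edges[[length(edges) + 1L]] <-
        rbind(id[idx[ok][hit]], id[nb[hit]])
    }
  }
  if (length(edges) == 0) return(length(idx))
  g <- igraph::make_graph(edges = as.vector(do.call(cbind, edges)),
                          n = length(idx), directed = FALSE)
  igraph::components(g)$no
}

#' Generate a parametric corpus-callosum-like mask
#'
#' Produces analytic binary fixtures for the parcellation stage:
#' `"rectangle"` (an axis-aligned bar), `"arch"` (a half-annulus with short
#' descending anterior and posterior limbs, the cartoon C-shape of the
#' callosum), and `"arch_rostrum"` (the arch plus a ventral anterior spur
#' below the genu, creating the notch that separates rostrum from genu).
#'
#' @param shape One of `"rectangle"`, `"arch"`, `"arch_rostrum"`.
#' @param length_mm Anterior-posterior extent in mm.
#' @param thickness_mm Body thickness in mm. For arches this is the
#'   difference between outer and inner radius; it must be smaller than the
#'   outer radius `length_mm / 2`.
#' @param spacing Pixel spacing in mm/pixel (isotropic).
#' @param rostrum_mm Length of the rostral spur (arch_rostrum only).
#' @param margin_mm Background margin around the shape.
#' @return A `cc_mask`.
#' @export
#' @examples
#' m <- generate_cc_mask("arch_rostrum", length_mm = 70, thickness_mm = 10,
#'                       spacing = 0.5)
#' print(m)
generate_cc_mask <- function(shape = c("arch_rostrum", "arch", "rectangle"),
                             length_mm = 70, thickness_mm = 10,
                             spacing = 0.5, rostrum_mm = 12,
                             margin_mm = 2) {
  shape <- match.arg(shape)
  if (length_mm <= 0 || thickness_mm <= 0 || spacing <= 0) {
    abort("length, thickness and spacing must be positive",
          class = "ccmorph_shape_error")
  }

  if (shape == "rectangle") {
    w <- max(1L, round(length_mm / spacing))
    h <- max(1L, round(thickness_mm / spacing))
    pad <- ceiling(margin_mm / spacing)
    px <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
    px[pad + seq_len(h), pad + seq_len(w)] <- TRUE
    return(cc_mask(px, spacing))
  }

  r_out <- length_mm / 2
  r_in <- r_out - thickness_mm
  if (r_in <= 0) {
    abort("degenerate arch: thickness must be smaller than the outer radius",
          class = "ccmorph_shape_error")
  }
  drop_ant <- 1.2 * thickness_mm  # genu descends below the arch
  drop_post <- 1.6 * thickness_mm # splenium descends further
  height_mm <- r_out + max(drop_ant, drop_post)
  nc <- ceiling((length_mm + 2 * margin_mm) / spacing)
  nr <- ceiling((height_mm + 2 * margin_mm) / spacing)
  cx <- margin_mm + r_out
  cy <- margin_mm + r_out

  x <- (seq_len(nc) - 0.5) * spacing
  y <- (seq_len(nr) - 0.5) * spacing
  X <- matrix(x, nr, nc, byrow = TRUE)
  Y <- matrix(y, nr, nc)
  D2 <- (X - cx)^2 + (Y - cy)^2
  px <- D2 >= r_in^2 & D2 <= r_out^2 & Y <= cy
  # anterior limb (genu) and posterior limb (splenium)
  px <- px | (X >= cx - r_out & X <= cx - r_in &
                Y > cy & Y <= cy + drop_ant)
  px <- px | (X >= cx + r_in & X <= cx + r_out &
                Y > cy & Y <= cy + drop_post)
  if (shape == "arch_rostrum") {
    t_r <- 0.45 * thickness_mm
    px <- px | (X >= cx - r_in & X <= cx - r_in + rostrum_mm &
                  Y >= cy + drop_ant - t_r & Y <= cy + drop_ant)
  }
  cc_mask(px, spacing)
}
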