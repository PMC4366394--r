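#' Principal anterior-posterior axis of a mask
#'
#' The axis joins the centre of the most anterior foreground pixel (minimal
#' column) to the centre of the most posterior foreground pixel (maximal
#' column). When several pixels tie in a column, the (lower) median row of
#' the tied run is used at both ends, so the axis of an axis-aligned bar is
#' horizontal rather than a corner-to-corner diagonal. Its Euclidean length
#' is the "total length" along which the Witelson fractions are laid out.
#'
#' @param mask A `cc_mask`.
#' @return An object of class `cc_axis`: `anterior` and `posterior` (x, y in
#'   mm; x along columns, y along rows), `direction` (unit vector), `length`
#'   (mm) and the originating pixel coordinates.
#' @export
#' @examples
#' m <- cc_mask(matrix(1, 20, 90), spacing = 1)
#' extract_principal_axis(m)$length  # 89: between extreme pixel centres
extract_principal_axis <- function(mask) {
  stopifnot(inherits(mask, "cc_mask"))
  idx <- which(mask$pixels, arr.ind = TRUE)
  cols <- idx[, 2]
  rows <- idx[, 1]

  med_pick <- function(cand) {
    ord <- cand[order(rows[cand])]
    ord[floor((length(ord) + 1) / 2)]
  }
  a_pick <- med_pick(which(cols == min(cols)))
  p_pick <- med_pick(which(cols == max(cols)))

  sp <- mask$spacing
  to_mm <- function(i) c(x = (cols[i] - 0.5) * sp["col"],
                         y = (rows[i] - 0.5) * sp["row"])
  a <- to_mm(a_pick)
  p <- to_mm(p_pick)
  L <- sqrt(sum((p - a)^2))
  if (L <= 0) {
    abort("degenerate mask: anterior and posterior extremes coincide",
          class = "ccmorph_input_error")
  }
  structure(
    list(
      anterior = unname(a), posterior = unname(p),
      direction = unname((p - a) / L), length = unname(L),
      anterior_pixel = c(row = rows[a_pick], col = cols[a_pick]),
      posterior_pixel = c(row = rows[p_pick], col = cols[p_pick])
    ),
    class = "cc_axis"
  )
}

#' @export
print.cc_axis <- function(x, ...) {
  cat(sprintf("<cc_axis> length %.2f mm, A=(%.1f, %.1f) -> P=(%.1f, %.1f) mm\n",
              x$length, x$anterior[1], x$anterior[2],
              x$posterior[1], x$posterior[2]))
  invisible(x)
}

#' Witelson parcellation of a midsagittal mask
#'
#' Every foreground pixel centre is projected onto the principal axis,
#' giving a position `u` clipped to `[0, L]`. Primary slabs use the
#' classical length fractions, half-open at the upper edge except the
#' splenium: anterior third `[0, L/3)`, anterior midbody `[L/3, L/2)`,
#' posterior midbody `[L/2, 2L/3)`, isthmus `[2L/3, 4L/5)`, splenium
#' `[4L/5, L]`.
#'
#' The anterior third is split into rostrum, genu and rostral body by the
#' ventral notch under the genu: image columns whose anterior-third pixels
#' fall into two or more vertically disjoint runs are notch columns, and
#' pixels in a lower (non-topmost) run of a notch column become rostrum
#' (label 1). The remaining anterior pixels split at `u_Q`, the projection
#' of the most anterior rostrum pixel (the spur's origin): genu (2) when
#' `u < u_Q`, rostral body (3) otherwise. Convex masks have no notch; the
#' fallback then leaves the rostrum empty and splits the anterior third at
#' its midpoint `L/6` into genu and rostral body.
#'
#' @param mask A `cc_mask`.
#' @param axis Optional `cc_axis` computed from the same mask (recomputed
#'   when `NULL`).
#' @param fallback_split Fraction of `L` at which genu and rostral body are
#'   split when no ventral notch exists (default `1/6`).
#' @return An object of class `cc_parcellation`: integer `labels` matrix
#'   (0 background, 1-7 per region), `spacing`, per-region `pixel_counts`
#'   and `areas` (named, mm^2), `total_area`, and the `axis`.
#' @export
#' @examples
#' m <- cc_mask(matrix(1, 20, 90), spacing = 1)
#' partition_witelson(m)$areas
partition_witelson <- function(mask, axis = NULL, fallback_split = 1 / 6) {
  stopifnot(inherits(mask, "cc_mask"))
  if (is.null(axis)) axis <- extract_principal_axis(mask)
  if (!inherits(axis, "cc_axis")) {
    abort("axis must be a cc_axis", class = "ccmorph_input_error")
  }
  if (!isTRUE(mask$pixels[axis$anterior_pixel["row"],
                          axis$anterior_pixel["col"]])) {
    abort("axis does not belong to this mask", class = "ccmorph_input_error")
  }
  if (fallback_split <= 0 || fallback_split >= 1 / 3) {
    abort("fallback_split must lie in (0, 1/3)", class = "ccmorph_config_error")
  }

  idx <- which(mask$pixels, arr.ind = TRUE)
  sp <- mask$spacing
  x <- (idx[, 2] - 0.5) * sp["col"]
  y <- (idx[, 1] - 0.5) * sp["row"]
  u <- (x - axis$anterior[1]) * axis$direction[1] +
    (y - axis$anterior[2]) * axis$direction[2]
  L <- axis$length
  u <- pmin(pmax(u, 0), L)

  lab <- integer(nrow(idx))
  lab[u >= L / 3 & u < L / 2] <- 4L
  lab[u >= L / 2 & u < 2 * L / 3] <- 5L
  lab[u >= 2 * L / 3 & u < 4 * L / 5] <- 6L
  lab[u >= 4 * L / 5] <- 7L

  ant <- which(lab == 0L)  # anterior third, to be split into 1/2/3
  if (length(ant) > 0) {
    acol <- idx[ant, 2]
    arow <- idx[ant, 1]
    rostrum <- logical(length(ant))
    for (cl in sort(unique(acol))) {
      in_col <- which(acol == cl)
      rws <- sort(arow[in_col])
      breaks <- which(diff(rws) > 1L)
      if (length(breaks) == 0) next
      # notch column: pixels below the topmost run are rostral spur
      first_run_end <- rws[breaks[1]]
      rostrum[in_col[arow[in_col] > first_run_end]] <- TRUE
    }
    # the genu/rostral-body boundary sits where the rostral spur begins:
    # u_Q is the projection of the most anterior rostrum pixel
    u_q <- if (any(rostrum)) min(u[ant[rostrum]]) else fallback_split * L
    lab[ant] <- ifelse(rostrum, 1L, ifelse(u[ant] < u_q, 2L, 3L))
  }

  labels <- matrix(0L, nrow(mask$pixels), ncol(mask$pixels))
  labels[cbind(idx[, 1], idx[, 2])] <- lab
  counts <- vapply(1:7, function(k) sum(lab == k), integer(1))
  names(counts) <- CC_REGIONS
  areas <- compute_areas(counts, sp)

  structure(
    list(
      labels = labels, spacing = sp, pixel_counts = counts,
      areas = areas, total_area = sum(areas), axis = axis
    ),
    class = "cc_parcellation"
  )
}

#' @export
print.cc_parcellation <- function(x, ...) {
  cat("<cc_parcellation>\n")
  print(round(x$areas, 2))
  cat(sprintf("total %.2f mm^2 over %d pixels\n",
              x$total_area, sum(x$pixel_counts)))
  invisible(x)
}

#' Convert per-region pixel counts to physical areas
#'
#' @param counts Named integer vector of pixel counts (one per region), or a
#'   `cc_parcellation` from which counts are taken.
#' @param spacing Pixel spacing in mm (one or two values).
#' @return Named numeric vector of areas in mm^2.
#' @export
#' @examples
#' compute_areas(c(rostrum = 100), spacing = 0.5)  # 25 mm^2
compute_areas <- function(counts, spacing) {
  if (inherits(counts, "cc_parcellation")) counts <- counts$pixel_counts
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- c(spacing, spacing)
  stopifnot(length(spacing) == 2, all(spacing > 0), all(counts >= 0))
  counts * spacing[1] * spacing[2]
}

#' Measure one subject's cohort record from a mask
#'
#' Runs axis extraction, Witelson parcellation and area computation, then
#' assembles a one-row cohort record.
#'
#' @param mask A `cc_mask`.
#' @param whole_brain_mL Whole-brain volume in mL (> 0).
#' @param sex `"male"` or `"female"`.
#' @param age_months Age in months (0, 300].
#' @param subject_id Identifier string.
#' @return A one-row tibble with the standard cohort columns.
#' @export
measure_record <- function(mask, whole_brain_mL, sex, age_months,
                           subject_id = "S001") {
  if (!sex %in% c("male", "female")) {
    abort("sex must be 'male' or 'female'", class = "ccmorph_input_error")
  }
  if (!is.finite(age_months) || age_months <= 0 || age_months > 300) {
    abort("age_months must lie in (0, 300]", class = "ccmorph_input_error")
  }
  if (!is.finite(whole_brain_mL) || whole_brain_mL <= 0) {
    abort("whole_brain_mL must be positive", class = "ccmorph_input_error")
  }
  part <- partition_witelson(mask)
  rec <- tibble(
    subject_id = subject_id, sex = sex,
    age_months = as.numeric(age_months),
    whole_brain_mL = as.numeric(whole_brain_mL)
  )
  for (r in CC_REGIONS) rec[[r]] <- unname(part$areas[r])
  rec$total_cc <- sum(part$areas)
  rec
}
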