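# Independent oracles used across the suite. These deliberately share no
# code with the package internals: flood fill instead of graph components,
# per-pixel loops instead of vectorised projection, pair counting instead of
# rank sums, explicit balanced-design sums of squares instead of the
# linear-model decomposition.

# Number of 8-connected components by queue-based flood fill.
flood_fill_components <- function(px) {
  nr <- nrow(px)
  nc <- ncol(px)
  seen <- matrix(FALSE, nr, nc)
  comps <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!px[r0, c0] || seen[r0, c0]) next
    comps <- comps + 1L
    queue <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- cur[1] + dr
        c <- cur[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            px[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  comps
}

# Primary-slab label (4..7, or 0 for the anterior third) for every
# foreground pixel, by scalar per-pixel projection.
brute_primary_labels <- function(mask, axis) {
  px <- mask$pixels
  sp <- mask$spacing
  out <- integer(0)
  L <- axis$length
  # column-major order, matching which(mask$pixels)
  for (c in seq_len(ncol(px))) for (r in seq_len(nrow(px))) {
    if (!px[r, c]) next
    x <- (c - 0.5) * sp[["col"]]
    y <- (r - 0.5) * sp[["row"]]
    u <- (x - axis$anterior[1]) * axis$direction[1] +
      (y - axis$anterior[2]) * axis$direction[2]
    u <- min(max(u, 0), L)
    lab <- if (u < L / 3) 0L else if (u < L / 2) 4L else
      if (u < 2 * L / 3) 5L else if (u < 4 * L / 5) 6L else 7L
    out <- c(out, lab)
  }
  out
}

# Mann-Whitney U for sample x by exhaustive pair counting (ties count 1/2).
brute_u_stat <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# Rasterise a w x h mm rectangle rotated by `angle` degrees, by membership
# test of each pixel centre in the back-rotated rectangle.
rotated_rect_mask <- function(w, h, angle, spacing) {
  th <- angle * pi / 180
  half_diag <- sqrt(w^2 + h^2) / 2 + 2
  n <- ceiling(2 * half_diag / spacing)
  cx <- half_diag
  xs <- (seq_len(n) - 0.5) * spacing - cx
  px <- outer(xs, xs, function(y, x) {
    xr <- cos(th) * x + sin(th) * y
    yr <- -sin(th) * x + cos(th) * y
    abs(xr) <= w / 2 & abs(yr) <= h / 2
  })
  cc_mask(px, spacing)
}

# Univariate mixed-design ANOVA F statistics for a *balanced* sex-by-age
# design with the seven regions as repeated measures, from explicit
# cell-mean sums of squares (balanced => identical across SS types).
brute_mixed_f <- function(cohort) {
  regions <- cc_regions()
  Y <- as.matrix(cohort[, regions])
  n <- nrow(Y)
  p <- ncol(Y)
  sex <- factor(cohort$sex)
  ageg <- assign_age_group(cohort$age_months)
  ageg <- droplevels(ageg)
  cell <- interaction(sex, ageg, drop = TRUE)
  n_cells <- nlevels(cell)

  grand <- mean(Y)
  subj_mean <- rowMeans(Y)
  cell_mean <- tapply(subj_mean, cell, mean)[cell]

  ss_sex <- p * sum((tapply(subj_mean, sex, mean) - grand)^2 *
                      tapply(subj_mean, sex, length))
  ss_age <- p * sum((tapply(subj_mean, ageg, mean) - grand)^2 *
                      tapply(subj_mean, ageg, length))
  ss_cells <- p * sum((tapply(subj_mean, cell, mean) - grand)^2 *
                        tapply(subj_mean, cell, length))
  ss_sexage <- ss_cells - ss_sex - ss_age
  ss_err_between <- p * sum((subj_mean - cell_mean)^2)
  df_between_err <- n - n_cells

  # within part operates on deviations from each subject's mean
  W <- Y - subj_mean
  reg_mean <- colMeans(W)
  ss_region <- n * sum(reg_mean^2)
  cell_reg <- rowsum(W, cell) / as.vector(table(cell))
  ns_cell <- as.vector(table(cell))
  # region x sex / region x age / region x cell interactions via cell means
  sex_reg <- rowsum(W, sex) / as.vector(table(sex))
  age_reg <- rowsum(W, ageg) / as.vector(table(ageg))
  ss_region_sex <- sum(as.vector(table(sex)) *
                         (sex_reg - matrix(reg_mean, nrow(sex_reg), p,
                                           byrow = TRUE))^2)
  ss_region_age <- sum(as.vector(table(ageg)) *
                         (age_reg - matrix(reg_mean, nrow(age_reg), p,
                                           byrow = TRUE))^2)
  ss_region_cell <- sum(ns_cell *
                          (cell_reg - matrix(reg_mean, nrow(cell_reg), p,
                                             byrow = TRUE))^2)
  ss_region_sexage <- ss_region_cell - ss_region_sex - ss_region_age
  # region-by-subject residual around the cell region-profiles
  ss_err_within <- sum((W - cell_reg[cell, ])^2)
  df_within_err <- (p - 1) * (n - n_cells)

  df_sex <- nlevels(sex) - 1
  df_age <- nlevels(ageg) - 1
  df_sexage <- df_sex * df_age
  ms_between_err <- ss_err_between / df_between_err
  ms_within_err <- ss_err_within / df_within_err
  c(
    sex = (ss_sex / df_sex) / ms_between_err,
    age_group = (ss_age / df_age) / ms_between_err,
    sex_age = (ss_sexage / df_sexage) / ms_between_err,
    region = (ss_region / (p - 1)) / ms_within_err,
    region_sex = (ss_region_sex / ((p - 1) * df_sex)) / ms_within_err,
    region_age = (ss_region_age / ((p - 1) * df_age)) / ms_within_err,
    region_sex_age = (ss_region_sexage / ((p - 1) * df_sexage)) /
      ms_within_err
  )
}

# A balanced toy cohort: 2 sexes x 2 age groups x n_per_cell subjects.
balanced_toy_cohort <- function(n_per_cell = 3, seed = 101) {
  set.seed(seed)
  ages <- c(infant = 12, adult = 250)
  rows <- list()
  id <- 0
  for (s in c("male", "female")) for (g in names(ages)) {
    for (k in seq_len(n_per_cell)) {
      id <- id + 1
      areas <- abs(rnorm(7, mean = c(10, 60, 50, 30, 28, 20, 80), sd = 8))
      rec <- tibble::tibble(
        subject_id = sprintf("T%02d", id), sex = s,
        age_months = ages[[g]] + k, whole_brain_mL = 1000 + rnorm(1, 0, 50)
      )
      for (j in seq_along(cc_regions())) rec[[cc_regions()[j]]] <- areas[j]
      rec$total_cc <- sum(areas)
      rows[[id]] <- rec
    }
  }
  dplyr::bind_rows(rows)
}

make_rect_mask <- function(w_mm = 90, h_mm = 20, spacing = 1) {
  cc_mask(matrix(TRUE, round(h_mm / spacing), round(w_mm / spacing)),
          spacing)
}
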