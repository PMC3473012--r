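# Boxel-wise spatial quantification.
#
# Classified per-section nucleus records are binned into a regular 3D grid of
# cubic "boxels". Every quantity assigned to a boxel is measured over a
# larger cubic sampling volume centred on it (default 105^3 um^3 around a
# 21^3 um^3 boxel) so that enough nuclei enter each labelling index; the
# window is slid one boxel at a time, which smooths neighbouring boxels.
# Counts are restricted to one material of the mask; tissue volume within the
# window comes from the mask voxels.

#' Boxel grid specification
#'
#' @param boxel_edge_um Edge of the cubic boxel (um).
#' @param sample_edge_um Edge of the centred cubic sampling volume; must be
#'   an odd multiple of `boxel_edge_um`.
#' @param min_nuclei_per_sample Minimum records per sampling volume for a
#'   boxel to carry labelling indices (default 30 bounds the binomial SE of
#'   an index by about 0.09).
#' @param material Material id(s) of the mask to include.
#' @param max_cycle_h Censoring cap for cycle lengths (hours).
#' @return A `boxel_grid_spec` list.
#' @export
boxel_grid_spec <- function(boxel_edge_um = 21, sample_edge_um = 105,
                            min_nuclei_per_sample = 30, material = 1L,
                            max_cycle_h = 32) {
  ratio <- sample_edge_um / boxel_edge_um
  assert_that(abs(ratio - round(ratio)) < 1e-9 && round(ratio) %% 2 == 1,
              "`sample_edge_um` must be an odd multiple of `boxel_edge_um`")
  assert_that(is_number(min_nuclei_per_sample) && min_nuclei_per_sample >= 1,
              "`min_nuclei_per_sample` must be >= 1")
  structure(list(boxel_edge_um = boxel_edge_um, sample_edge_um = sample_edge_um,
                 half_span = (round(ratio) - 1L) %/% 2L,
                 min_nuclei_per_sample = as.integer(min_nuclei_per_sample),
                 material = as.integer(material), max_cycle_h = max_cycle_h),
            class = "boxel_grid_spec")
}

# sliding-window sum over a 3D array: sum of all array cells within +/- h
# boxels of each cell (window clipped at the array edge)
window_sum <- function(a, h) {
  out <- array(0, dim(a))
  d <- dim(a)
  for (dx in -h:h) for (dy in -h:h) for (dz in -h:h) {
    xs <- seq_len(d[1]) + dx; ys <- seq_len(d[2]) + dy; zs <- seq_len(d[3]) + dz
    okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]; okz <- zs >= 1 & zs <= d[3]
    out[okx, oky, okz] <- out[okx, oky, okz] + a[xs[okx], ys[oky], zs[okz]]
  }
  out
}

#' Build the boxel grid and accumulate counts
#'
#' The grid is anchored at the included material's bounding-box minimum;
#' boxel membership uses half-open intervals, so each record's centroid falls
#' in exactly one boxel (central assignment; the sum of `n_central` over
#' boxels equals the number of included records). Per boxel, `n_total`,
#' `n_long_raw` and `n_short` accumulate the records of all boxels within the
#' centred sampling window, and `tissue_volume_um3` accumulates the included
#' material's voxel volume in the same window.
#'
#' @param records Classified records with `x_um`, `y_um`, `section`,
#'   `material`, `positive_long`, `positive_short`.
#' @param stack The [section_stack()] (for the mask and geometry).
#' @param spec A [boxel_grid_spec()].
#' @return A `boxel_grid` tibble, one row per boxel: `bx`, `by`, `bz`
#'   (0-based indices), centre coordinates in um, `n_central`, `n_total`,
#'   `n_long_raw`, `n_short`, `tissue_volume_um3`. Records outside the grid
#'   or of other materials are counted out (see `attr(, "n_counted_out")`).
#' @export
build_boxel_grid <- function(records, stack, spec = boxel_grid_spec()) {
  stopifnot(inherits(stack, "section_stack"), inherits(spec, "boxel_grid_spec"))
  px <- stack$pixel_size_um; t_um <- stack$section_thickness_um
  be <- spec$boxel_edge_um
  dmask <- dim(stack$mask)

  inc <- array(stack$mask %in% spec$material, dmask)
  idx <- which(inc, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    grid <- tibble(bx = integer(), by = integer(), bz = integer(),
                   x_um = numeric(), y_um = numeric(), z_um = numeric(),
                   n_central = integer(), n_total = numeric(),
                   n_long_raw = numeric(), n_short = numeric(),
                   tissue_volume_um3 = numeric(), valid = logical())
    attr(grid, "spec") <- spec
    class(grid) <- c("boxel_grid", class(grid))
    return(grid)
  }
  # bounding box of the included material, in um
  x_min <- (min(idx[, 1]) - 1) * px; y_min <- (min(idx[, 2]) - 1) * px
  z_min <- (min(idx[, 3]) - 1) * t_um
  x_max <- max(idx[, 1]) * px; y_max <- max(idx[, 2]) * px
  z_max <- max(idx[, 3]) * t_um
  nb <- c(ceiling((x_max - x_min) / be - 1e-9),
          ceiling((y_max - y_min) / be - 1e-9),
          ceiling((z_max - z_min) / be - 1e-9))
  nb <- pmax(nb, 1)

  rec <- records[records$material %in% spec$material & !records$excluded, ]
  z_rec <- (rec$section - 0.5) * t_um
  bi <- floor((rec$x_um - x_min) / be); bj <- floor((rec$y_um - y_min) / be)
  bk <- floor((z_rec - z_min) / be)
  in_grid <- bi >= 0 & bi < nb[1] & bj >= 0 & bj < nb[2] & bk >= 0 & bk < nb[3]
  n_counted_out <- sum(!in_grid) + sum(records$material %in% spec$material &
                                         records$excluded)
  bi <- bi[in_grid]; bj <- bj[in_grid]; bk <- bk[in_grid]
  rec <- rec[in_grid, ]

  acc <- function(w) {
    a <- array(0, nb)
    if (length(w)) {
      flat <- (bk * nb[2] + bj) * nb[1] + bi + 1
      t <- tapply(w, factor(flat, levels = seq_len(prod(nb))), sum)
      a[] <- ifelse(is.na(t), 0, t)
    }
    a
  }
  ones <- rep(1, nrow(rec))
  central <- acc(ones)
  h <- spec$half_span
  n_total <- window_sum(central, h)
  n_long <- window_sum(acc(as.numeric(rec$positive_long)), h)
  n_short <- window_sum(acc(as.numeric(rec$positive_short)), h)

  # tissue volume per boxel from mask voxels, then the same window sum
  vx <- (idx[, 1] - 0.5) * px; vy <- (idx[, 2] - 0.5) * px
  vz <- (idx[, 3] - 0.5) * t_um
  ti <- floor((vx - x_min) / be); tj <- floor((vy - y_min) / be)
  tk <- floor((vz - z_min) / be)
  okv <- ti >= 0 & ti < nb[1] & tj >= 0 & tj < nb[2] & tk >= 0 & tk < nb[3]
  tflat <- (tk[okv] * nb[2] + tj[okv]) * nb[1] + ti[okv] + 1
  tisvox <- array(0, nb)
  tv <- tapply(rep(px * px * t_um, sum(okv)),
               factor(tflat, levels = seq_len(prod(nb))), sum)
  tisvox[] <- ifelse(is.na(tv), 0, tv)
  tissue <- window_sum(tisvox, h)

  co <- expand.grid(bx = 0:(nb[1] - 1), by = 0:(nb[2] - 1), bz = 0:(nb[3] - 1))
  grid <- tibble(bx = co$bx, by = co$by, bz = co$bz,
                 x_um = x_min + (co$bx + 0.5) * be,
                 y_um = y_min + (co$by + 0.5) * be,
                 z_um = z_min + (co$bz + 0.5) * be,
                 n_central = as.integer(central[cbind(co$bx + 1, co$by + 1, co$bz + 1)]),
                 n_total = n_total[cbind(co$bx + 1, co$by + 1, co$bz + 1)],
                 n_long_raw = n_long[cbind(co$bx + 1, co$by + 1, co$bz + 1)],
                 n_short = n_short[cbind(co$bx + 1, co$by + 1, co$bz + 1)],
                 tissue_volume_um3 = tissue[cbind(co$bx + 1, co$by + 1, co$bz + 1)])
  grid$valid <- grid$n_total >= spec$min_nuclei_per_sample &
    grid$tissue_volume_um3 > 0
  attr(grid, "spec") <- spec
  attr(grid, "dims") <- nb
  attr(grid, "n_counted_out") <- n_counted_out
  class(grid) <- c("boxel_grid", class(grid))
  grid
}

#' Labelling-index maps
#'
#' Adds `f_long` (compensated: raw long count divided by the compensation
#' ratio, then by `n_total`), `f_short`, and `delta_f`, all clamped to
#' `[0, 1]`. Boxels below the minimum count stay invalid and carry no
#' indices.
#'
#' @param grid A [build_boxel_grid()] result.
#' @param compensation_ratio Long-analogue detection ratio.
#' @return The grid with index columns.
#' @export
index_maps <- function(grid, compensation_ratio = 0.928) {
  spec <- attr(grid, "spec")
  f_long <- pmin(compensate_long_fraction(grid$n_long_raw, compensation_ratio) /
                   grid$n_total, 1)
  f_short <- pmin(grid$n_short / grid$n_total, 1)
  grid$f_long <- ifelse(grid$valid, f_long, NA_real_)
  grid$f_short <- ifelse(grid$valid, f_short, NA_real_)
  grid$delta_f <- grid$f_long - grid$f_short
  grid
}

#' Cycle-length and S-phase maps
#'
#' Applies the differential exposure time estimator per valid boxel. Boxels
#' where `f_short > f_long` are flagged `inconsistent` and excluded from the
#' maps (they indicate calibration/compensation failure or extreme sampling
#' noise); censored boxels carry `t_c_h = max_cycle_h` with
#' `censored = TRUE`.
#'
#' @param grid Grid with index maps.
#' @param schedule An [exposure_schedule()].
#' @param growth_fraction Scalar growth fraction, or a numeric vector of
#'   per-boxel values. The default 1 makes `t_c_h` the population doubling
#'   time.
#' @param max_cycle_h Censoring cap; default from the grid spec.
#' @return Grid with `t_c_h`, `censored`, `t_s_h`, `inconsistent`.
#' @export
cycle_maps <- function(grid, schedule, growth_fraction = 1, max_cycle_h = NULL) {
  stopifnot(inherits(schedule, "exposure_schedule"))
  spec <- attr(grid, "spec")
  max_cycle_h <- max_cycle_h %||% spec$max_cycle_h
  gf <- rep_len(growth_fraction, nrow(grid))
  ok <- grid$valid & !is.na(grid$f_long)
  incons <- ok & grid$f_short > grid$f_long
  use <- ok & !incons
  t_c <- rep(NA_real_, nrow(grid)); cens <- rep(NA, nrow(grid))
  if (any(use)) {
    est <- estimate_cycle_length(grid$f_long[use], grid$f_short[use],
                                 schedule$delta_t_h, gf[use], max_cycle_h)
    t_c[use] <- est$t_c_h; cens[use] <- est$censored
  }
  ts <- rep(NA_real_, nrow(grid))
  if (any(use)) {
    est_s <- suppressWarnings(
      estimate_s_phase(grid$f_short[use], t_c[use],
                       schedule$short_exposure_h, cens[use]))
    ts[use] <- est_s$t_s_h
  }
  grid$t_c_h <- t_c
  grid$censored <- cens
  grid$t_s_h <- ts
  grid$inconsistent <- incons
  grid
}

#' Cell-density and cell-size maps via Abercrombie's correction
#'
#' Per-section areal counts overcount nuclei that are cut by more than one
#' section; Abercrombie's correction converts the areal density `N_A` to a
#' volumetric density `N_V = N_A / (t + d)` with `t` the section thickness
#' and `d` the mean nucleus diameter. The average cell size is then the
#' reciprocal volume per nucleus, `1 / N_V` um^3.
#'
#' @param grid Grid with counts.
#' @param mean_nucleus_diameter_um Mean nucleus diameter; `NULL` estimates it
#'   from the detected records' median object area
#'   (`d = 2 * sqrt(median_area * pixel_size^2 / pi)`).
#' @param records Records (needed only when estimating the diameter).
#' @param stack The [section_stack()] (for geometry).
#' @return Grid with `n_a_per_um2`, `n_v_per_um3`, `cell_size_um3`.
#' @export
cell_size_maps <- function(grid, stack, mean_nucleus_diameter_um = NULL,
                           records = NULL) {
  t_um <- stack$section_thickness_um
  d_um <- mean_nucleus_diameter_um %||% {
    assert_that(!is.null(records), "supply `records` to estimate the diameter")
    2 * sqrt(median(records$area_px[!records$excluded]) *
               stack$pixel_size_um^2 / pi)
  }
  area <- grid$tissue_volume_um3 / t_um   # summed tissue area over the window's sections
  n_a <- ifelse(area > 0, grid$n_total / area, NA_real_)
  n_v <- n_a / (t_um + d_um)
  grid$n_a_per_um2 <- ifelse(grid$valid, n_a, NA_real_)
  grid$n_v_per_um3 <- ifelse(grid$valid, n_v, NA_real_)
  grid$cell_size_um3 <- ifelse(grid$valid & n_v > 0, 1 / n_v, NA_real_)
  attr(grid, "nucleus_diameter_um") <- d_um
  grid
}

#' Quantify a classified record set into a full boxel map
#'
#' Convenience wrapper: [build_boxel_grid()], [index_maps()], [cycle_maps()]
#' and [cell_size_maps()] in sequence.
#'
#' @inheritParams build_boxel_grid
#' @inheritParams cycle_maps
#' @param compensation_ratio Long-analogue detection ratio.
#' @param mean_nucleus_diameter_um Passed to [cell_size_maps()].
#' @return A fully annotated `boxel_grid` tibble.
#' @export
quantify_boxels <- function(records, stack, schedule,
                            spec = boxel_grid_spec(),
                            compensation_ratio = 0.928,
                            growth_fraction = 1,
                            mean_nucleus_diameter_um = NULL) {
  grid <- build_boxel_grid(records, stack, spec)
  grid <- index_maps(grid, compensation_ratio)
  grid <- cycle_maps(grid, schedule, growth_fraction)
  cell_size_maps(grid, stack, mean_nucleus_diameter_um, records)
}
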