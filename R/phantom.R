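# Synthetic section-image phantom with ground truth.
#
# The phantom emulates what the wet protocol produces: aligned per-section
# grayscale channels (nuclear stain, long analogue, short analogue) plus an
# integer material mask, for a tissue volume whose regions differ in true
# cell-cycle length. Nuclei are hard-core points; each nucleus is a sphere
# that appears in every section slab it intersects, with its in-plane radius
# given by the maximal chord inside the slab -- which is what makes the
# Abercrombie correction genuinely testable downstream.

#' Define one material region of a phantom
#'
#' @param material Positive integer material id (0 is background).
#' @param shape One of `"box"`, `"ellipsoid"`, `"tube"` (a cylinder along z).
#' @param origin Numeric length-3: for a box the minimum corner (um); for an
#'   ellipsoid or tube the centre (tube: centre of its axis).
#' @param size Numeric length-3: box edge lengths; ellipsoid axis diameters;
#'   for a tube `c(diameter, diameter, length)` (um).
#' @param density_per_um3 Nuclear number density (nuclei / um^3).
#' @param nucleus_diameter_um Mean nucleus diameter (um).
#' @param min_separation_um Hard-core minimum separation between nucleus
#'   centres; defaults to the nucleus diameter (non-overlapping nuclei).
#'   Since nuclei are embedded in cells, separations of ~1.2 diameters are
#'   typical at tissue densities and reduce unresolvable in-section
#'   superpositions.
#' @param cycle_length_h,s_phase_h,growth_fraction True population parameters
#'   of the region (see [population_params()]).
#' @return A `phantom_region` list.
#' @export
phantom_region <- function(material, shape = c("box", "ellipsoid", "tube"),
                           origin, size, density_per_um3,
                           nucleus_diameter_um = 5,
                           min_separation_um = nucleus_diameter_um,
                           cycle_length_h = 8, s_phase_h = 3,
                           growth_fraction = 1) {
  shape <- match.arg(shape)
  assert_that(is_number(material) && material >= 1, "`material` must be >= 1")
  assert_that(length(origin) == 3 && length(size) == 3 && all(size > 0),
              "`origin` and `size` must be positive length-3 vectors")
  assert_that(is_number(density_per_um3) && density_per_um3 > 0,
              "`density_per_um3` must be positive")
  assert_that(is_number(nucleus_diameter_um) && nucleus_diameter_um > 0,
              "`nucleus_diameter_um` must be positive")
  assert_that(is_number(min_separation_um) && min_separation_um > 0,
              "`min_separation_um` must be positive")
  structure(list(material = as.integer(material), shape = shape,
                 origin = as.numeric(origin), size = as.numeric(size),
                 density_per_um3 = density_per_um3,
                 nucleus_diameter_um = nucleus_diameter_um,
                 min_separation_um = min_separation_um,
                 cycle_length_h = cycle_length_h, s_phase_h = s_phase_h,
                 growth_fraction = growth_fraction),
            class = "phantom_region")
}

region_volume_um3 <- function(r) {
  switch(r$shape,
         box = prod(r$size),
         ellipsoid = pi / 6 * prod(r$size),
         tube = pi / 4 * r$size[1] * r$size[2] * r$size[3])
}

region_bbox <- function(r) {
  if (r$shape == "box") rbind(r$origin, r$origin + r$size)
  else rbind(r$origin - r$size / 2, r$origin + r$size / 2)
}

# inside test, vectorised over points (n x 3 matrix)
region_inside <- function(r, p) {
  switch(r$shape,
         box = p[, 1] >= r$origin[1] & p[, 1] < r$origin[1] + r$size[1] &
               p[, 2] >= r$origin[2] & p[, 2] < r$origin[2] + r$size[2] &
               p[, 3] >= r$origin[3] & p[, 3] < r$origin[3] + r$size[3],
         ellipsoid = {
           u <- sweep(p, 2, r$origin, "-")
           (u[, 1] / (r$size[1] / 2))^2 + (u[, 2] / (r$size[2] / 2))^2 +
             (u[, 3] / (r$size[3] / 2))^2 <= 1
         },
         tube = {
           u <- sweep(p, 2, r$origin, "-")
           (u[, 1] / (r$size[1] / 2))^2 + (u[, 2] / (r$size[2] / 2))^2 <= 1 &
             abs(u[, 3]) <= r$size[3] / 2
         })
}

#' Specification of a synthetic section-image phantom
#'
#' @param regions List of [phantom_region()] objects; geometries must lie
#'   within `volume_um`.
#' @param volume_um Length-3 volume dimensions in um; `NULL` takes the
#'   bounding box of the regions.
#' @param pixel_size_um In-plane pixel size (um / px).
#' @param section_thickness_um Physical section thickness (um).
#' @param detection_efficiency_long Probability that a truly long-labelled
#'   nucleus is detectable in the long-analogue channel. The default 0.928
#'   reproduces the empirical deficit of long-analogue detections at equal
#'   exposure.
#' @param background,gradient_amplitude Per-channel base background intensity
#'   and planar background-gradient amplitude (16-bit grayscale units).
#' @param noise_sd Additive Gaussian noise sd per channel.
#' @param nuclear_amplitude Peak added intensity of a nucleus in the nuclear
#'   channel.
#' @param speckle_density,speckle_amplitude Bernoulli per-pixel probability
#'   and added intensity of analogue speckle inside labelled nuclei.
#' @param min_chord_um Detection floor: slab intersections whose maximal
#'   chord radius is below this are neither rendered nor listed as
#'   detectable truth (sub-resolution caps).
#' @param merge_factor Projection-occlusion constant: two appearances in the
#'   same section whose centres are closer than
#'   `merge_factor * (r1 + r2)` form a single detectable object.
#' @param seed Integer seed for truth generation and rendering.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(regions, volume_um = NULL, pixel_size_um = 0.5,
                         section_thickness_um = 7,
                         detection_efficiency_long = 0.928,
                         background = c(nuclear = 2000, long = 1500, short = 1500),
                         gradient_amplitude = c(nuclear = 3000, long = 2000, short = 2000),
                         noise_sd = c(nuclear = 600, long = 500, short = 500),
                         nuclear_amplitude = 20000,
                         speckle_density = 0.35, speckle_amplitude = 18000,
                         min_chord_um = 2, merge_factor = 0.65,
                         seed = NULL) {
  if (inherits(regions, "phantom_region")) regions <- list(regions)
  assert_that(length(regions) >= 1 && all(vapply(regions, inherits, TRUE, "phantom_region")),
              "`regions` must be a list of phantom_region objects")
  bb <- Reduce(function(a, b) rbind(pmin(a[1, ], b[1, ]), pmax(a[2, ], b[2, ])),
               lapply(regions, region_bbox))
  if (is.null(volume_um)) volume_um <- bb[2, ]
  assert_that(all(bb[1, ] >= -1e-9) && all(bb[2, ] <= volume_um + 1e-9),
              "region geometries must lie within the phantom volume")
  assert_that(is_number(detection_efficiency_long) &&
                detection_efficiency_long > 0 && detection_efficiency_long <= 1,
              "`detection_efficiency_long` must lie in (0, 1]")
  mats <- vapply(regions, function(r) r$material, 1L)
  assert_that(!anyDuplicated(mats), "region material ids must be unique")
  structure(list(regions = regions, volume_um = as.numeric(volume_um),
                 pixel_size_um = pixel_size_um,
                 section_thickness_um = section_thickness_um,
                 n_sections = ceiling(round(volume_um[3] / section_thickness_um, 6)),
                 detection_efficiency_long = detection_efficiency_long,
                 background = background, gradient_amplitude = gradient_amplitude,
                 noise_sd = noise_sd, nuclear_amplitude = nuclear_amplitude,
                 speckle_density = speckle_density,
                 speckle_amplitude = speckle_amplitude,
                 min_chord_um = min_chord_um, merge_factor = merge_factor,
                 seed = seed),
            class = "phantom_spec")
}

# Hard-core (minimum-separation) dart throwing into one shared occupancy grid;
# fails loudly when the requested density cannot be packed.
place_hardcore <- function(spec, seed_pts) {
  vol <- spec$volume_um
  sep_max <- max(vapply(spec$regions, function(r) r$min_separation_um, 1))
  cs <- sep_max
  nc <- pmax(1L, ceiling(vol / cs))
  occ <- vector("list", prod(nc))
  pts <- list()
  cell_of <- function(p) {
    ci <- pmin(pmax(floor(p / cs) + 1L, 1L), nc)
    ((ci[3] - 1L) * nc[2] + (ci[2] - 1L)) * nc[1] + ci[1]
  }
  all_pts <- matrix(numeric(0), 0, 3)
  for (r in spec$regions) {
    n_target <- round(r$density_per_um3 * region_volume_um3(r))
    bb <- region_bbox(r)
    placed <- 0L; tries <- 0L; max_tries <- n_target * 3000L
    reg_pts <- matrix(NA_real_, n_target, 3)
    while (placed < n_target) {
      tries <- tries + 1L
      if (tries > max_tries)
        abort(sprintf(paste("packing failure in region material %d:",
                            "placed %d of %d nuclei at separation %g um"),
                      r$material, placed, n_target, r$min_separation_um))
      p <- c(runif(1, bb[1, 1], bb[2, 1]), runif(1, bb[1, 2], bb[2, 2]),
             runif(1, bb[1, 3], bb[2, 3]))
      if (!region_inside(r, matrix(p, 1))) next
      ci <- pmin(pmax(floor(p / cs) + 1L, 1L), nc)
      ok <- TRUE
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        ii <- ci + c(di, dj, dk)
        if (any(ii < 1L) || any(ii > nc)) next
        id <- ((ii[3] - 1L) * nc[2] + (ii[2] - 1L)) * nc[1] + ii[1]
        for (q in occ[[id]])
          if (sum((all_pts[q, ] - p)^2) < r$min_separation_um^2) { ok <- FALSE; break }
        if (!ok) break
      }
      if (!ok) next
      placed <- placed + 1L
      reg_pts[placed, ] <- p
      all_pts <- rbind(all_pts, p)
      id <- cell_of(p)
      occ[[id]] <- c(occ[[id]], nrow(all_pts))
    }
    pts[[length(pts) + 1L]] <- list(region = r, pts = reg_pts)
  }
  pts
}

#' Generate the phantom's ground-truth nucleus table
#'
#' Places nuclei by a hard-core point process at each region's density, draws
#' each nucleus's label state from its region's population parameters and the
#' exposure schedule (via [simulate_population()]), then thins long-label
#' detectability by `detection_efficiency_long`.
#'
#' @param spec A [phantom_spec()].
#' @param schedule An [exposure_schedule()].
#' @return A `GroundTruthTable` tibble: `nucleus`, `x_um`, `y_um`, `z_um`,
#'   `section` (slab containing the centre), `diameter_um`, `material`,
#'   `cycling`, `labelled_long_true` (pre-efficiency), `labelled_long`
#'   (detectable, post-efficiency), `labelled_short`.
#' @export
generate_truth <- function(spec, schedule) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(schedule, "exposure_schedule"))
  seed <- spec$seed %||% next_seed()
  with_seed(seed, {
    groups <- place_hardcore(spec)
    tabs <- purrr::map(groups, function(g) {
      r <- g$region
      n <- nrow(g$pts)
      pop <- simulate_population(
        population_params(r$cycle_length_h, r$s_phase_h, r$growth_fraction,
                          n_cells = max(n, 1L), seed = next_seed()),
        schedule)
      tibble(x_um = g$pts[, 1], y_um = g$pts[, 2], z_um = g$pts[, 3],
             diameter_um = r$nucleus_diameter_um, material = r$material,
             cycling = pop$cycling[seq_len(n)],
             labelled_long_true = pop$labelled_long[seq_len(n)],
             labelled_short = pop$labelled_short[seq_len(n)])
    })
    out <- dplyr::bind_rows(tabs)
    out$labelled_long <- out$labelled_long_true &
      (runif(nrow(out)) < spec$detection_efficiency_long)
    out$section <- pmin(pmax(floor(out$z_um / spec$section_thickness_um) + 1L, 1L),
                        spec$n_sections)
    out <- dplyr::mutate(out, nucleus = dplyr::row_number(), .before = 1)
    attr(out, "seed") <- seed
    out
  })
}

#' Per-section appearances of the truth nuclei
#'
#' A nucleus (sphere) appears in every section slab it intersects; the
#' appearance's in-plane radius is the maximal chord of the sphere within the
#' slab. Intersections with chord radius below `spec$min_chord_um` are below
#' the phantom's detection floor and omitted.
#'
#' @param truth A [generate_truth()] table.
#' @param spec The [phantom_spec()] it came from.
#' @return Tibble: `nucleus`, `section`, `x_um`, `y_um`, `chord_um` plus the
#'   nucleus's label columns and material.
#' @export
section_appearances <- function(truth, spec) {
  t_um <- spec$section_thickness_um
  r <- truth$diameter_um / 2
  s_lo <- pmax(1L, floor((truth$z_um - r) / t_um) + 1L)
  s_hi <- pmin(spec$n_sections, floor((truth$z_um + r) / t_um * (1 - 1e-12)) + 1L)
  reps <- pmax(0L, s_hi - s_lo + 1L)
  idx <- rep.int(seq_len(nrow(truth)), reps)
  sec <- unlist(purrr::map2(s_lo, s_hi, function(a, b) if (b >= a) seq.int(a, b) else integer(0)))
  z0 <- (sec - 1) * t_um; z1 <- sec * t_um
  delta <- pmax(0, pmax(z0 - truth$z_um[idx], truth$z_um[idx] - z1))
  chord <- sqrt(pmax(truth$diameter_um[idx]^2 / 4 - delta^2, 0))
  keep <- chord >= spec$min_chord_um
  tibble(nucleus = truth$nucleus[idx][keep], section = sec[keep],
         x_um = truth$x_um[idx][keep], y_um = truth$y_um[idx][keep],
         chord_um = chord[keep], material = truth$material[idx][keep],
         labelled_long = truth$labelled_long[idx][keep],
         labelled_long_true = truth$labelled_long_true[idx][keep],
         labelled_short = truth$labelled_short[idx][keep])
}

#' Detectable per-section truth objects
#'
#' Appearances whose projected cores overlap within a section (centres closer
#' than `merge_factor * (r_i + r_j)`) are physically a single blob in a
#' widefield section image; single-linkage groups of such appearances are
#' reported as one detectable object at their intensity-weighted position,
#' carrying the label state of the dominant (largest-chord) constituent.
#'
#' @inheritParams section_appearances
#' @return Tibble: `section`, `x_um`, `y_um`, `chord_um` (largest
#'   constituent), `n_merged`, label columns, `material`.
#' @export
detectable_truth <- function(truth, spec) {
  app <- section_appearances(truth, spec)
  out <- app |>
    dplyr::group_by(.data$section) |>
    dplyr::group_modify(function(d, key) merge_projections(d, spec$merge_factor)) |>
    dplyr::ungroup()
  out
}

merge_projections <- function(d, merge_factor) {
  n <- nrow(d)
  if (n <= 1) return(dplyr::mutate(d, n_merged = 1L))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  dx <- dist(cbind(d$x_um, d$y_um))
  lim <- outer(d$chord_um, d$chord_um, "+") * merge_factor
  dm <- as.matrix(dx)
  for (i in seq_len(n - 1)) {
    close <- which(dm[i, (i + 1):n] < lim[i, (i + 1):n]) + i
    for (j in close) parent[find(j)] <- find(i)
  }
  root <- vapply(seq_len(n), find, 1L)
  d |>
    dplyr::mutate(.grp = root) |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(
      nucleus = .data$nucleus[which.max(.data$chord_um)],
      x_um = sum(.data$x_um * .data$chord_um^2) / sum(.data$chord_um^2),
      y_um = sum(.data$y_um * .data$chord_um^2) / sum(.data$chord_um^2),
      n_merged = dplyr::n(),
      material = .data$material[which.max(.data$chord_um)],
      labelled_long = .data$labelled_long[which.max(.data$chord_um)],
      labelled_long_true = .data$labelled_long_true[which.max(.data$chord_um)],
      labelled_short = .data$labelled_short[which.max(.data$chord_um)],
      chord_um = max(.data$chord_um), .groups = "drop") |>
    dplyr::select(-".grp")
}

#' Render a phantom into an aligned section-image stack
#'
#' Produces the four aligned stacks the measurement pipeline expects: nuclear
#' stain, long analogue, short analogue (16-bit-range grayscale) and the
#' integer material mask. Nuclei are drawn as centre-weighted discs (squared
#' projected-sphere profile) on a planar background gradient with additive
#' Gaussian noise; labelled nuclei additionally receive Bernoulli per-pixel
#' speckle in the corresponding analogue channel. Deterministic for a fixed
#' `spec$seed`.
#'
#' @param truth A [generate_truth()] table.
#' @param spec The matching [phantom_spec()].
#' @return A `section_stack`: list with 3D arrays `nuclear`, `long`, `short`,
#'   `mask` (dims x, y, section) and geometry metadata.
#' @export
render_sections <- function(truth, spec) {
  px <- spec$pixel_size_um
  W <- round(spec$volume_um[1] / px); H <- round(spec$volume_um[2] / px)
  S <- spec$n_sections
  app <- section_appearances(truth, spec)
  seed <- (spec$seed %||% next_seed()) + 1L
  chans <- c("nuclear", "long", "short")
  stacks <- lapply(setNames(chans, chans), function(ch) array(0, c(W, H, S)))
  mask <- array(0L, c(W, H, S))

  # material mask: rasterise regions at pixel centres, section mid-plane
  xs <- (seq_len(W) - 0.5) * px; ys <- (seq_len(H) - 0.5) * px
  gx <- rep(xs, times = H); gy <- rep(ys, each = W)
  for (s in seq_len(S)) {
    zmid <- (s - 0.5) * spec$section_thickness_um
    m <- integer(W * H)
    for (r in spec$regions) {
      inside <- region_inside(r, cbind(gx, gy, rep(zmid, W * H)))
      m[inside] <- r$material
    }
    mask[, , s] <- m
  }

  grad_x <- matrix(rep((seq_len(W) - 1) / max(W - 1, 1), H), W, H)
  with_seed(seed, {
    for (s in seq_len(S)) {
      a <- app[app$section == s, ]
      base <- lapply(setNames(chans, chans), function(ch)
        spec$background[[ch]] + spec$gradient_amplitude[[ch]] * grad_x)
      for (i in seq_len(nrow(a))) {
        cx <- a$x_um[i] / px + 0.5; cy <- a$y_um[i] / px + 0.5
        cr <- a$chord_um[i] / px
        x0 <- max(1, floor(cx - cr - 1)); x1 <- min(W, ceiling(cx + cr + 1))
        y0 <- max(1, floor(cy - cr - 1)); y1 <- min(H, ceiling(cy + cr + 1))
        if (x1 < x0 || y1 < y0) next
        dd <- outer((x0:x1 - cx)^2, (y0:y1 - cy)^2, "+")
        dome <- pmax(1 - dd / cr^2, 0)
        base$nuclear[x0:x1, y0:y1] <- base$nuclear[x0:x1, y0:y1] +
          spec$nuclear_amplitude * dome^2
        inside <- dd <= cr^2
        for (ch in c("long", "short")) {
          lab <- if (ch == "long") a$labelled_long[i] else a$labelled_short[i]
          if (!lab) next
          spk <- inside & (matrix(runif(length(dd)), nrow(dd)) < spec$speckle_density)
          base[[ch]][x0:x1, y0:y1][spk] <- base[[ch]][x0:x1, y0:y1][spk] +
            spec$speckle_amplitude
        }
      }
      for (ch in chans)
        stacks[[ch]][, , s] <- pmin(pmax(base[[ch]] +
          matrix(rnorm(W * H, 0, spec$noise_sd[[ch]]), W, H), 0), 65535)
    }
  })
  section_stack(nuclear = stacks$nuclear, long = stacks$long,
                short = stacks$short, mask = mask,
                pixel_size_um = px,
                section_thickness_um = spec$section_thickness_um)
}

#' Construct an aligned multi-channel section stack
#'
#' @param nuclear,long,short 3D numeric arrays (x, y, section) of the nuclear
#'   stain and the two analogue channels; `long`/`short` may be `NULL` for
#'   detection-only work.
#' @param mask Integer 3D array of material ids (0 = background).
#' @param pixel_size_um,section_thickness_um Geometry metadata in um.
#' @return A `section_stack` list.
#' @export
section_stack <- function(nuclear, long = NULL, short = NULL, mask,
                          pixel_size_um, section_thickness_um) {
  dn <- dim(nuclear)
  assert_that(length(dn) == 3, "`nuclear` must be a 3D array (x, y, section)")
  assert_that(identical(dim(mask), dn), "`mask` must match the nuclear stack dims")
  for (a in list(long, short))
    if (!is.null(a)) assert_that(identical(dim(a), dn), "channel dims must agree")
  structure(list(nuclear = nuclear, long = long, short = short,
                 mask = mask, pixel_size_um = pixel_size_um,
                 section_thickness_um = section_thickness_um),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$nuclear)
  cat(sprintf("section_stack: %d x %d px, %d sections (%g um/px, %g um thick)\n",
              d[1], d[2], d[3], x$pixel_size_um, x$section_thickness_um))
  cat(sprintf("channels: %s; materials: %s\n",
              paste(c("nuclear", if (!is.null(x$long)) "long",
                      if (!is.null(x$short)) "short", "mask"), collapse = ", "),
              paste(sort(unique(as.integer(x$mask[x$mask > 0]))), collapse = ", ")))
  invisible(x)
}

#' The standard two-region validation phantom
#'
#' A fast-cycling region (true T_C = 8 h, T_S = 3 h) beside a slow-cycling
#' region (true T_C = 40 h, T_S = 8 h), both with growth fraction 1, imaged at
#' 0.5 um/px in 5-um sections with 5-um nuclei. The slow region is dense
#' (2.6e-3 /um^3) because resolving its small labelling difference (dF =
#' 3/40 against the censoring boundary 3/32) needs on the order of a
#' thousand nuclei per 105^3 um^3 sampling window; the whole phantom holds
#' roughly 3,000 nuclei.
#'
#' @param seed Integer seed.
#' @param detection_efficiency_long Long-analogue detectability; default
#'   0.928.
#' @return A [phantom_spec()] with materials 1 (fast) and 2 (slow).
#' @export
two_region_phantom_spec <- function(seed = NULL,
                                    detection_efficiency_long = 0.928) {
  fast <- phantom_region(1, "box", origin = c(0, 0, 0), size = c(84, 126, 60),
                         density_per_um3 = 6e-4, nucleus_diameter_um = 5,
                         min_separation_um = 6,
                         cycle_length_h = 8, s_phase_h = 3)
  slow <- phantom_region(2, "box", origin = c(84, 0, 0), size = c(126, 126, 60),
                         density_per_um3 = 2.6e-3, nucleus_diameter_um = 5,
                         min_separation_um = 6,
                         cycle_length_h = 40, s_phase_h = 8)
  phantom_spec(list(fast, slow), pixel_size_um = 0.5,
               section_thickness_um = 5,
               detection_efficiency_long = detection_efficiency_long,
               seed = seed)
}

#' Idealised measurement records from the ground truth
#'
#' Converts the detectable per-section truth objects into the record format
#' the quantification stage consumes, as if detection and classification were
#' perfect. This isolates the boxel-level estimators from the imaging chain
#' in tests: positivity flags are the truth label states (post-efficiency for
#' the long analogue).
#'
#' @param truth A [generate_truth()] table.
#' @param spec The matching [phantom_spec()].
#' @return A tibble with `record`, `section`, `x_um`, `y_um`, `area_px`,
#'   `material`, `excluded`, `positive_long`, `positive_short`.
#' @export
truth_records <- function(truth, spec) {
  dt <- detectable_truth(truth, spec)
  tibble(record = seq_len(nrow(dt)), id = seq_len(nrow(dt)),
         section = dt$section, x_um = dt$x_um, y_um = dt$y_um,
         area_px = as.integer(round(pi * (dt$chord_um / spec$pixel_size_um)^2)),
         material = dt$material, excluded = FALSE,
         positive_long = dt$labelled_long, positive_short = dt$labelled_short)
}

#' Material-mask-only section stack
#'
#' Rasterises just the material mask of a phantom (all intensity channels
#' zero); cheap scaffolding for quantification tests that start from
#' [truth_records()].
#'
#' @param spec A [phantom_spec()].
#' @return A [section_stack()].
#' @export
mask_stack <- function(spec) {
  px <- spec$pixel_size_um
  W <- round(spec$volume_um[1] / px); H <- round(spec$volume_um[2] / px)
  S <- spec$n_sections
  mask <- array(0L, c(W, H, S))
  xs <- (seq_len(W) - 0.5) * px; ys <- (seq_len(H) - 0.5) * px
  gx <- rep(xs, times = H); gy <- rep(ys, each = W)
  for (s in seq_len(S)) {
    zmid <- (s - 0.5) * spec$section_thickness_um
    m <- integer(W * H)
    for (r in spec$regions) {
      inside <- region_inside(r, cbind(gx, gy, rep(zmid, W * H)))
      m[inside] <- r$material
    }
    mask[, , s] <- m
  }
  section_stack(nuclear = array(0, dim(mask)), mask = mask,
                pixel_size_um = px,
                section_thickness_um = spec$section_thickness_um)
}
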