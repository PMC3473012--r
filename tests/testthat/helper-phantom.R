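# Shared fixtures, built once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

std_schedule <- function() exposure_schedule(4, 1)

# small sparse single-region phantom (fast to render; ~200 nuclei)
small_phantom_spec <- function(seed = 401, density = 4e-4, t_c = 8, t_s = 3,
                               gf = 1, efficiency = 0.928) {
  region <- phantom_region(1, "box", origin = c(0, 0, 0), size = c(120, 120, 35),
                           density_per_um3 = density, nucleus_diameter_um = 5,
                           min_separation_um = 6,
                           cycle_length_h = t_c, s_phase_h = t_s,
                           growth_fraction = gf)
  phantom_spec(list(region), pixel_size_um = 0.5, section_thickness_um = 5,
               detection_efficiency_long = efficiency, seed = seed)
}

small_rendered <- function() {
  fixture("small_rendered", function() {
    spec <- small_phantom_spec()
    truth <- generate_truth(spec, std_schedule())
    list(spec = spec, truth = truth,
         stack = render_sections(truth, spec))
  })
}

# one-to-one greedy matching of detected records to truth objects
match_records <- function(records, truth_objects, radius_um = 2) {
  tp <- 0
  for (s in unique(truth_objects$section)) {
    a <- truth_objects[truth_objects$section == s, ]
    b <- records[records$section == s, ]
    if (!nrow(b) || !nrow(a)) next
    D <- outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2
    repeat {
      j <- which.min(D)
      if (!length(j) || D[j] > radius_um^2) break
      ri <- (j - 1) %% nrow(D) + 1
      ci <- (j - 1) %/% nrow(D) + 1
      tp <- tp + 1
      D[ri, ] <- Inf
      D[, ci] <- Inf
    }
  }
  c(recall = tp / nrow(truth_objects), precision = tp / nrow(records))
}

# draw a filled disc onto a matrix: squared-dome profile, or flat (power 0)
draw_disc <- function(img, cx, cy, r, amp = 1000, power = 2) {
  x0 <- max(1, floor(cx - r - 1)); x1 <- min(nrow(img), ceiling(cx + r + 1))
  y0 <- max(1, floor(cy - r - 1)); y1 <- min(ncol(img), ceiling(cy + r + 1))
  dd <- outer((x0:x1 - cx)^2, (y0:y1 - cy)^2, "+")
  prof <- if (power == 0) (dd <= r^2) * 1 else pmax(1 - dd / r^2, 0)^power
  img[x0:x1, y0:y1] <- img[x0:x1, y0:y1] + amp * prof
  img
}

# synthetic grid with three spatially separated (cell_size, T_C) populations
three_pop_grid <- function(n_side = 6, seed = 701) {
  set.seed(seed)
  blocks <- list(
    list(bx = 0:(n_side - 1), size = 400, t_c = 8, bz0 = 0),     # small, fast
    list(bx = 0:(n_side - 1), size = 1400, t_c = 30, bz0 = 2),   # large, slow
    list(bx = 0:(n_side - 1), size = 1500, t_c = 9, bz0 = 4))    # large, fast
  rows <- purrr::imap(blocks, function(b, i) {
    co <- expand.grid(bx = b$bx, by = 0:(n_side - 1), bz = b$bz0 + 0:1)
    tibble::tibble(bx = co$bx, by = co$by, bz = co$bz,
                   x_um = co$bx * 21, y_um = co$by * 21, z_um = co$bz * 21,
                   valid = TRUE, region = i,
                   cell_size_um3 = rnorm(nrow(co), b$size, 40),
                   t_c_h = rnorm(nrow(co), b$t_c, 0.4),
                   censored = FALSE)
  })
  dplyr::bind_rows(rows)
}

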