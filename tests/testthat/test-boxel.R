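# Boxel grid: counts, indices, cycle maps, Abercrombie cell size.

# homogeneous single-region phantom quantified from idealised truth records
homog_grid <- function(t_c = 8, t_s = 3, density = 1.2e-3, seed = 601,
                       spec_args = list()) {
  region <- phantom_region(1, "box", origin = c(0, 0, 0),
                           size = c(147, 147, 60),
                           density_per_um3 = density, nucleus_diameter_um = 5,
                           min_separation_um = 6,
                           cycle_length_h = t_c, s_phase_h = t_s)
  spec <- phantom_spec(list(region), pixel_size_um = 1,
                       section_thickness_um = 5, seed = seed)
  truth <- generate_truth(spec, std_schedule())
  records <- truth_records(truth, spec)
  stack <- mask_stack(spec)
  list(spec = spec, truth = truth, records = records, stack = stack)
}

test_that("central assignment partitions the included records exactly", {
  fx <- fixture("homog8", function() homog_grid())
  grid <- build_boxel_grid(fx$records, fx$stack, boxel_grid_spec(material = 1))
  expect_equal(sum(grid$n_central), nrow(fx$records))
  # an empty mask yields no valid boxels
  empty <- fx$stack; empty$mask[] <- 0L
  g0 <- build_boxel_grid(fx$records, empty, boxel_grid_spec(material = 1))
  expect_equal(sum(g0$valid), 0)
  # window counts in the interior track density x tissue volume
  interior <- grid$bx >= 2 & grid$bx <= max(grid$bx) - 2 &
    grid$by >= 2 & grid$by <= max(grid$by) - 2
  apps_per_nucleus <- nrow(fx$records) / nrow(fx$truth)
  expected <- 1.2e-3 * apps_per_nucleus * grid$tissue_volume_um3[interior]
  expect_true(all(abs(grid$n_total[interior] - expected) <
                    4 * sqrt(expected) + 10))
})

test_that("labelling-index maps apply compensation and the validity rule", {
  fx <- fixture("homog8", function() homog_grid())
  grid <- build_boxel_grid(fx$records, fx$stack, boxel_grid_spec(material = 1))
  grid <- index_maps(grid, compensation_ratio = 0.928)
  ok <- grid$valid
  expect_true(all(grid$f_long[ok] >= 0 & grid$f_long[ok] <= 1))
  expect_true(all(is.na(grid$f_long[!ok])))
  # arithmetic check on one boxel
  i <- which(ok)[1]
  expect_equal(grid$f_long[i],
               min(grid$n_long_raw[i] / 0.928 / grid$n_total[i], 1))
  # n_total = 100, n_long_raw = 37 at ratio 0.928 gives ~0.3987
  g1 <- tibble::tibble(n_total = 100, n_long_raw = 37, n_short = 10,
                       tissue_volume_um3 = 1, valid = TRUE)
  attr(g1, "spec") <- boxel_grid_spec()
  g1 <- index_maps(g1, 0.928)
  expect_equal(g1$f_long, 37 / 0.928 / 100, tolerance = 1e-12)
  expect_equal(round(g1$f_long, 4), 0.3987)
  # below the minimum count: invalid, no indices
  g2 <- tibble::tibble(n_total = 10, n_long_raw = 3, n_short = 1,
                       tissue_volume_um3 = 1, valid = FALSE)
  attr(g2, "spec") <- boxel_grid_spec()
  expect_true(is.na(index_maps(g2, 0.928)$f_long))
})

test_that("cycle maps recover a homogeneous fast phantom", {
  fx <- fixture("homog8", function() homog_grid())
  grid <- quantify_boxels(fx$records, fx$stack, std_schedule(),
                          boxel_grid_spec(material = 1),
                          mean_nucleus_diameter_um = 5)
  ok <- grid$valid & !is.na(grid$t_c_h)
  expect_gt(sum(ok), 20)
  # true T_C = 8 h: median of valid boxels within 10%
  expect_lt(abs(median(grid$t_c_h[ok]) - 8) / 8, 0.10)
  expect_lt(mean(grid$censored[ok]), 0.05)
  # T_S close to 3 h
  expect_lt(abs(median(grid$t_s_h[ok]) - 3), 0.6)
  # worked example: F 0.875/0.5 at dT 3 gives T_C = 8 h, T_S = 0.5*8 - 1 = 3 h
  g <- tibble::tibble(n_total = 200, n_long_raw = 0.875 * 0.928 * 200,
                      n_short = 100, tissue_volume_um3 = 1, valid = TRUE)
  attr(g, "spec") <- boxel_grid_spec()
  g <- index_maps(g, 0.928)
  g <- cycle_maps(g, std_schedule())
  expect_equal(g$t_c_h, 8)
  expect_equal(g$t_s_h, 3)
})

test_that("slow phantoms censor at the 32 h cap", {
  fx <- fixture("homog40", function() homog_grid(t_c = 40, t_s = 8,
                                                 density = 2.6e-3, seed = 602))
  grid <- quantify_boxels(fx$records, fx$stack, std_schedule(),
                          boxel_grid_spec(material = 1),
                          mean_nucleus_diameter_um = 5)
  ok <- grid$valid & !is.na(grid$t_c_h)
  expect_gte(mean(grid$censored[ok]), 0.9)
  expect_true(all(grid$t_c_h[ok & grid$censored] == 32))
  # delta F = 0 censors
  g <- tibble::tibble(n_total = 100, n_long_raw = 20 * 0.928, n_short = 20,
                      tissue_volume_um3 = 1, valid = TRUE)
  attr(g, "spec") <- boxel_grid_spec()
  g <- cycle_maps(index_maps(g, 0.928), std_schedule())
  expect_true(g$censored)
  # f_short > f_long flags the boxel inconsistent and excludes it
  gi <- tibble::tibble(n_total = 100, n_long_raw = 10 * 0.928, n_short = 30,
                       tissue_volume_um3 = 1, valid = TRUE)
  attr(gi, "spec") <- boxel_grid_spec()
  gi <- cycle_maps(index_maps(gi, 0.928), std_schedule())
  expect_true(gi$inconsistent)
  expect_true(is.na(gi$t_c_h))
})

test_that("overlapping sampling windows smooth the maps", {
  fx <- fixture("homog8", function() homog_grid())
  sm <- quantify_boxels(fx$records, fx$stack, std_schedule(),
                        boxel_grid_spec(material = 1),
                        mean_nucleus_diameter_um = 5)
  rough <- quantify_boxels(fx$records, fx$stack, std_schedule(),
                           boxel_grid_spec(sample_edge_um = 21, material = 1,
                                           min_nuclei_per_sample = 10),
                           mean_nucleus_diameter_um = 5)
  v_sm <- var(sm$delta_f[sm$valid], na.rm = TRUE)
  v_rough <- var(rough$delta_f[rough$valid], na.rm = TRUE)
  expect_gt(v_rough, v_sm)
})

test_that("Abercrombie correction recovers the volumetric density", {
  # sparse phantom with a permissive visibility floor so nearly every
  # sphere-slab intersection is listed
  region <- phantom_region(1, "box", origin = c(0, 0, 0),
                           size = c(147, 147, 60), density_per_um3 = 5e-4,
                           nucleus_diameter_um = 5, min_separation_um = 6)
  spec <- phantom_spec(list(region), pixel_size_um = 1,
                       section_thickness_um = 5, min_chord_um = 1,
                       seed = 603)
  truth <- generate_truth(spec, std_schedule())
  records <- truth_records(truth, spec)
  stack <- mask_stack(spec)
  grid <- quantify_boxels(records, stack, std_schedule(),
                          boxel_grid_spec(material = 1),
                          mean_nucleus_diameter_um = 5)
  ok <- grid$valid & is.finite(grid$n_v_per_um3)
  est <- median(grid$n_v_per_um3[ok])
  expect_lt(abs(est - 5e-4) / 5e-4, 0.10)
  expect_equal(median(grid$cell_size_um3[ok]), 1 / est)
  # arithmetic: N_A = 0.01 /um^2, t = 7, d = 7 -> N_V = 1/1400, size 1400
  g <- tibble::tibble(n_total = 0.01 * 7000, n_long_raw = 0, n_short = 0,
                      tissue_volume_um3 = 7000 * 7, valid = TRUE)
  attr(g, "spec") <- boxel_grid_spec()
  st <- section_stack(nuclear = array(0, c(2, 2, 1)),
                      mask = array(1L, c(2, 2, 1)),
                      pixel_size_um = 1, section_thickness_um = 7)
  g <- cell_size_maps(g, st, mean_nucleus_diameter_um = 7)
  expect_equal(g$n_v_per_um3, 1 / 1400)
  expect_equal(g$cell_size_um3, 1400)
  # d = 0 reduces to the naive slab estimate N_A / t
  g0 <- cell_size_maps(g, st, mean_nucleus_diameter_um = 0)
  expect_equal(g0$n_v_per_um3, 0.01 / 7)
})
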