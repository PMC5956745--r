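side <- sqrt(0.1 * 1e6)  # grid square side, nm

square_terminal <- function(nx, ny) {
  cbind(c(0, nx * side, nx * side, 0), c(0, 0, ny * side, ny * side))
}

test_that("grid density follows its definition on constructed patterns", {
  # 2 x 5 squares = 1 um^2 terminal, 10 valid squares, 10 vesicles
  term <- square_terminal(2, 5)
  set.seed(71)
  ves <- tibble::tibble(x_nm = runif(10, 1, 2 * side - 1),
                        y_nm = runif(10, 1, 5 * side - 1),
                        diameter_nm = 30)
  ann <- terminal_annotation(term, vesicles = ves)
  gd <- grid_density(ann)
  expect_equal(gd$n_valid_squares, 10)
  expect_equal(gd$density_per_um2, 10)
})

test_that("squares touching organelles or the border are excluded", {
  term <- square_terminal(4, 4)
  # organelle covering the left half excludes those 8 squares
  org <- cbind(c(0, 2 * side, 2 * side, 0), c(0, 0, 4 * side, 4 * side))
  set.seed(72)
  ves <- tibble::tibble(x_nm = runif(40, 2 * side + 1, 4 * side - 1),
                        y_nm = runif(40, 1, 4 * side - 1),
                        diameter_nm = 30)
  ann <- terminal_annotation(term, organelles = list(org), vesicles = ves)
  gd <- grid_density(ann)
  expect_equal(gd$n_valid_squares, 8)
  expect_equal(gd$density_per_um2, 40 / (8 * 0.1))

  # a grid origin shifted off-phase makes border-straddling squares invalid
  gd_off <- grid_density(ann, grid_origin = c(side / 2, side / 2))
  expect_lt(gd_off$n_valid_squares, 8)
})

test_that("grid density is origin-insensitive for Poisson patterns", {
  ann <- simulate_terminal(density_per_um2 = 130, seed = 73)
  d <- grid_density_origins(ann)
  expect_equal(nrow(d), 4)
  expect_lt(diff(range(d$density_per_um2)) / mean(d$density_per_um2), 0.15)
})

test_that("grid density recovers the generator truth within 10%", {
  dens <- vapply(1:20, function(s) {
    grid_density(simulate_terminal(density_per_um2 = 131.7,
                                   seed = s))$density_per_um2
  }, numeric(1))
  expect_equal(mean(dens), 131.7, tolerance = 0.1 * 131.7)
})

test_that("active-zone proximity counts and normalization are exact", {
  term <- square_terminal(10, 10)
  az <- cbind(c(1000, 1300), c(0, 0))  # 300 nm along the bottom edge
  ves <- tibble::tibble(x_nm = seq(1010, 1290, length.out = 12),
                        y_nm = 50, diameter_nm = 30)
  ann <- terminal_annotation(term, active_zones = list(az), vesicles = ves)
  prox <- az_proximity_counts(ann)
  expect_equal(prox$n, 12)
  expect_equal(prox$per_unit, 2)  # 12 per 300 nm = 2 per 50 nm

  # everything farther than 100 nm: zero proximal
  far <- terminal_annotation(term, active_zones = list(az),
                             vesicles = dplyr::mutate(ves, y_nm = 200))
  expect_equal(az_proximity_counts(far)$n, 0)

  # the wild-type value 2.70 per 50 nm: 27 vesicles on a 500 nm zone
  az2 <- cbind(c(0, 500), c(0, 0))
  ves2 <- tibble::tibble(x_nm = seq(5, 495, length.out = 27), y_nm = 40,
                         diameter_nm = 30)
  ann2 <- terminal_annotation(term, active_zones = list(az2),
                              vesicles = ves2)
  expect_equal(az_proximity_counts(ann2)$per_unit, 2.70)
})

test_that("membrane adjacency uses one diameter of center distance", {
  term <- square_terminal(10, 10)
  az <- cbind(c(500, 1500), c(0, 0))
  ves <- tibble::tibble(x_nm = c(800, 1000), y_nm = c(25, 35),
                        diameter_nm = c(30, 30))
  ann <- terminal_annotation(term, active_zones = list(az), vesicles = ves)
  adj <- membrane_adjacent_counts(ann)
  expect_equal(adj$n, 1)  # 25 <= 30 adjacent; 35 > 30 not

  # adjacency is always a subset of 100-nm proximity
  sim <- simulate_terminal(density_per_um2 = 120,
                           active_zones = list(az), az_extra_per_az = 15,
                           seed = 74)
  expect_lte(membrane_adjacent_counts(sim)$n, az_proximity_counts(sim)$n)
})

test_that("vesicles are assigned to their nearest active zone only", {
  term <- square_terminal(10, 10)
  az_a <- cbind(c(0, 300), c(0, 0))
  az_b <- cbind(c(2000, 2300), c(0, 0))
  ves <- tibble::tibble(x_nm = c(100, 2100, 2150), y_nm = 30,
                        diameter_nm = 30)
  ann <- terminal_annotation(term, active_zones = list(az_a, az_b),
                             vesicles = ves)
  prox <- az_proximity_counts(ann)
  expect_equal(prox$n, c(1, 2))
  expect_equal(sum(prox$n), 3)
})

test_that("diameter statistics match their definition", {
  term <- square_terminal(4, 4)
  ann <- terminal_annotation(
    term, vesicles = tibble::tibble(x_nm = c(100, 200, 300),
                                    y_nm = 100, diameter_nm = c(30, 30, 36)))
  ds <- diameter_stats(ann)
  expect_equal(ds$mean_nm, 32)
  expect_equal(ds$n, 3)

  single <- terminal_annotation(
    term, vesicles = tibble::tibble(x_nm = 100, y_nm = 100,
                                    diameter_nm = 33))
  expect_true(is.na(diameter_stats(single)$sd_nm))
})

test_that("percent reduction reproduces the printed group comparisons", {
  expect_equal(percent_reduction(2.70, 1.92), 28.9, tolerance = 0.01)
  expect_equal(percent_reduction(1.24, 0.71), 42.7, tolerance = 0.05)
})

test_that("vesicle_stats assembles a consistent one-row summary", {
  az <- cbind(c(500, 1500), c(0, 0))
  ann <- simulate_terminal(density_per_um2 = 130,
                           active_zones = list(az), az_extra_per_az = 20,
                           seed = 75)
  vs <- vesicle_stats(ann)
  expect_s3_class(vs, "vesicle_stats")
  expect_equal(nrow(vs), 1)
  expect_lte(vs$adjacent_per_az, vs$proximal_per_az)
  expect_gte(vs$density_per_um2, 0)
  expect_equal(vs$n_vesicles, nrow(ann$vesicles))
})

test_that("annotations survive a JSON round trip in pixel units", {
  az <- cbind(c(500, 1500), c(0, 0))
  ann <- simulate_terminal(density_per_um2 = 50, active_zones = list(az),
                           seed = 76)
  ann$scale_nm_per_px <- 2.5
  p <- withr::local_tempfile(fileext = ".json")
  write_terminal_annotation(ann, p)
  back <- read_terminal_annotation(p)
  expect_equal(back$vesicles, ann$vesicles, tolerance = 1e-9)
  expect_equal(back$terminal, ann$terminal, tolerance = 1e-9)
  expect_equal(back$active_zones, ann$active_zones, tolerance = 1e-9)
  expect_equal(back$scale_nm_per_px, 2.5)
})
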