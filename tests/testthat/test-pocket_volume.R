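# Grid-based free-volume maps of the substrate-binding cleft.

test_that("single-sphere grid volume approximates the analytic sphere volume", {
  spec <- pocket_spec(sphere_region(c(0, 0, 0), 8), grid_spacing = 1)
  g <- build_grid(spec)
  v_analytic <- 4 / 3 * pi * 8^3
  expect_lt(abs(sum(g$mask) * 1 - v_analytic) / v_analytic, 0.03)
})

test_that("disjoint spheres contribute additively", {
  s1 <- sphere_region(c(0, 0, 0), 5)
  s2 <- sphere_region(c(30, 0, 0), 5)
  n_union <- sum(build_grid(pocket_spec(list(s1, s2)))$mask)
  n1 <- sum(build_grid(pocket_spec(s1))$mask)
  n2 <- sum(build_grid(pocket_spec(s2))$mask)
  expect_equal(n_union, n1 + n2)
})

test_that("three-sphere union volume matches a Monte-Carlo oracle within 2%", {
  spheres <- list(sphere_region(c(0, 0, 0), 8),
                  sphere_region(c(9, 3, 0), 8),
                  sphere_region(c(4, 10, 3), 8))
  g <- build_grid(pocket_spec(spheres, grid_spacing = 0.5))
  v_grid <- sum(g$mask) * 0.5^3
  set.seed(10)
  v_mc <- mc_union_volume(spheres, 1e6)
  expect_lt(abs(v_grid - v_mc) / v_mc, 0.02)
})

test_that("a frame with no occluding atoms leaves the full union open", {
  spec <- pocket_spec(sphere_region(c(0, 0, 0), 8), grid_spacing = 0.5)
  g <- build_grid(spec)
  sc <- make_pocket_scene(spec, "none")
  ffv <- frame_free_volume(coords(sc$structure), sc$structure, spec, g)
  expect_equal(ffv$volume, sum(g$mask) * 0.5^3)
  expect_lt(abs(ffv$volume - sc$expected_volume) / sc$expected_volume,
            0.01)
})

test_that("a single carbon at the sphere centre removes one vdW sphere of volume", {
  spec <- pocket_spec(sphere_region(c(0, 0, 0), 8), grid_spacing = 0.5)
  g <- build_grid(spec)
  sc <- make_pocket_scene(spec, "center_atom")
  ffv <- frame_free_volume(coords(sc$structure), sc$structure, spec, g)
  deficit <- sum(g$mask) * 0.5^3 - ffv$volume
  expect_equal(deficit, 4 / 3 * pi * 1.7^3, tolerance = 0.05)
})

test_that("a half-space slab occludes half of the sphere", {
  spec <- pocket_spec(sphere_region(c(0, 0, 0), 8), grid_spacing = 0.5)
  g <- build_grid(spec)
  sc <- make_pocket_scene(spec, "half_slab")
  ffv <- frame_free_volume(coords(sc$structure), sc$structure, spec, g)
  # half-voxel bias at the planar boundary dominates the grid error
  expect_equal(ffv$volume, sc$expected_volume, tolerance = 0.05)
})

test_that("an element missing from the radii table raises a configuration error", {
  spec <- pocket_spec(sphere_region(c(0, 0, 0), 5),
                      radii_table = c(C = 1.7))
  g <- build_grid(spec)
  sc <- make_pocket_scene(spec, "center_atom")
  sc$structure$atoms$element[1] <- "W"
  expect_error(frame_free_volume(coords(sc$structure), sc$structure,
                                 spec, g), "configuration error.*W")
})

test_that("adding atoms never increases free volume or map values", {
  spec <- pocket_spec(sphere_region(c(0, 0, 0), 6), grid_spacing = 1)
  g <- build_grid(spec)
  set.seed(20)
  pts <- matrix(runif(30, -4, 4), ncol = 3)
  mk <- function(n) new_structure("occl", data.frame(
    serial = 1:n, name = "C", element = "C", res_name = "UNK",
    res_seq = 1:n, chain = "A", altloc = "", occupancy = 1,
    x = pts[1:n, 1], y = pts[1:n, 2], z = pts[1:n, 3],
    stringsAsFactors = FALSE))
  vols <- vapply(1:10, function(n) {
    s <- mk(n)
    frame_free_volume(coords(s), s, spec, g)$volume
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("refining the grid drives the empty-sphere volume toward the analytic value", {
  v_true <- 4 / 3 * pi * 8^3
  err <- vapply(c(1.0, 0.5), function(sp) {
    g <- build_grid(pocket_spec(sphere_region(c(0, 0, 0), 8),
                                grid_spacing = sp))
    abs(sum(g$mask) * sp^3 - v_true) / v_true
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.01)
})

test_that("frequency map is the mean of per-frame open indicators and matches the volume series", {
  spec <- pocket_spec(sphere_region(c(0, 0, 0), 6), grid_spacing = 1)
  g <- build_grid(spec)
  base <- make_pocket_scene(spec, "center_atom")$structure
  # alternate the occluding atom inside / far outside the sphere ("lid")
  xyz_in <- coords(base)
  xyz_out <- xyz_in; xyz_out[1, ] <- c(50, 50, 50)
  frames <- rep(list(xyz_in, xyz_out), 5)
  ens <- new_ensemble(base, frames)
  res <- suppressWarnings(ensemble_frequency_map(ens, spec))
  # exact identity against per-frame recomputation
  opens <- lapply(frames, function(fr)
    frame_free_volume(fr, base, spec, g)$open)
  mean_open <- Reduce(`+`, opens) / length(opens)
  expect_equal(res$map$values[res$map$mask], mean_open[res$map$mask])
  # lid region oscillates at 0.5; the rest of the sphere stays 1
  vals <- res$map$values[res$map$mask]
  expect_true(all(vals %in% c(0.5, 1)))
  expect_gt(sum(vals == 0.5), 0)
  # mean volume equals spacing^3 times the sum of open fractions
  expect_equal(res$volumes$mean,
               sum(res$map$values[res$map$mask]) * spec$grid_spacing^3)
})

test_that("a point open in one of two frames scores 0.5; identical frames give a 0/1 map", {
  spec <- pocket_spec(sphere_region(c(0, 0, 0), 5), grid_spacing = 1)
  base <- make_pocket_scene(spec, "center_atom")$structure
  xyz <- coords(base)
  far <- xyz; far[1, ] <- c(40, 0, 0)
  res2 <- suppressWarnings(
    ensemble_frequency_map(new_ensemble(base, list(xyz, far)), spec))
  centre_val <- res2$map$values[
    which(res2$map$mask & res2$map$values < 1)[1]]
  expect_equal(centre_val, 0.5)
  res1 <- ensemble_frequency_map(new_ensemble(base, list(xyz, xyz)), spec)
  expect_true(all(res1$map$values[res1$map$mask] %in% c(0, 1)))
})

test_that("contouring keeps points at or above the level and is monotone", {
  spec <- pocket_spec(sphere_region(c(0, 0, 0), 5), grid_spacing = 1)
  g <- build_grid(spec)
  set.seed(30)
  g$values[g$mask] <- round(runif(sum(g$mask)), 2)
  ct10 <- contour_map(g, 0.1)
  expect_equal(sum(ct10$mask), sum(g$values[g$mask] >= 0.1))
  ct50 <- contour_map(g, 0.5)
  expect_true(all(which(ct50$mask) %in% which(ct10$mask)))
  # constant maps: all kept or none
  g$values[g$mask] <- 0.5
  expect_equal(sum(contour_map(g, 0.1)$mask), sum(g$mask))
  g$values[g$mask] <- 0.05
  expect_equal(sum(contour_map(g, 0.1)$mask), 0)
  expect_error(contour_map(g, 0), "parameter")
  expect_error(contour_map(g, 1.5), "parameter")
})

test_that("an unsuperposed ensemble triggers a drift warning, not an error", {
  spec <- pocket_spec(sphere_region(c(0, 0, 0), 5), grid_spacing = 1)
  base <- make_pocket_scene(spec, "center_atom")$structure
  xyz <- coords(base)
  expect_warning(ensemble_frequency_map(
    new_ensemble(base, list(xyz, xyz + 5)), spec), "superposed")
})

test_that("time-aware stride helper converts an interval to frames", {
  times <- seq(0, 100, by = 0.5)  # frames every 0.5 ns
  expect_equal(stride_for_interval(times, 2), 4L)
  expect_equal(stride_for_interval(times, 0.25), 1L)
})
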