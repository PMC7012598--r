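# Backbone essential-dynamics PCA.

backbone_base <- function(seed = 1) make_toy_kinase(seed, "up")

test_that("identical frames give an all-zero spectrum", {
  base <- backbone_base()
  ens <- new_ensemble(base, list(coords(base), coords(base), coords(base)))
  model <- fit_pc_model(ens, base)
  expect_true(all(model$eigenvalues < 1e-12))
})

test_that("two frames at -a and +a along one direction give a rank-1 spectrum with eigenvalue a^2", {
  base <- backbone_base()
  xyz <- coords(base)
  # internal direction: orthogonalized against rigid-body motions by the
  # generator machinery via make_mode_trajectory ground truth
  tr <- make_mode_trajectory(base, list(list(vector = rnorm(3 * nrow(xyz)),
                                             variance = 1)),
                             n_frames = 2, noise_sigma = 0, seed = 5)
  v <- attr(tr, "ground_truth")$modes[, 1]
  a <- 2.5
  vm <- matrix(v, ncol = 3, byrow = TRUE)
  ens <- new_ensemble(base, list(xyz - a * vm, xyz + a * vm))
  model <- fit_pc_model(ens, base, backbone_only = FALSE)
  expect_equal(model$eigenvalues[1], a^2, tolerance = 1e-6)
  expect_lt(model$eigenvalues[2], 1e-8)
  expect_gt(abs(sum(model$eigenvectors[, 1] * v)), 1 - 1e-6)
})

test_that("two-mode generator variances and directions are recovered", {
  base <- backbone_base()
  n3 <- 3 * nrow(base$atoms)
  set.seed(6)
  tr <- make_mode_trajectory(base,
                             list(list(vector = rnorm(n3), variance = 9),
                                  list(vector = rnorm(n3), variance = 4)),
                             n_frames = 2000, noise_sigma = 0.1, seed = 7)
  gt <- attr(tr, "ground_truth")
  model <- fit_pc_model(tr, base, backbone_only = FALSE)
  expect_equal(model$eigenvalues[1], 9, tolerance = 0.1)
  expect_equal(model$eigenvalues[2], 4, tolerance = 0.1)
  expect_gt(model$eigenvalues[1], model$eigenvalues[2])
  expect_gt(abs(sum(model$eigenvectors[, 1] * gt$modes[, 1])), 0.99)
})

test_that("eigendecomposition agrees with an SVD oracle on the centred data", {
  base <- backbone_base()
  set.seed(8)
  n3 <- 3 * nrow(reduce_backbone_for_test(base)$atoms)
  tr <- make_mode_trajectory(base,
                             list(list(vector = rnorm(3 * nrow(base$atoms)),
                                       variance = 2)),
                             n_frames = 60, noise_sigma = 0.2, seed = 9)
  model <- fit_pc_model(tr, base)
  # oracle: rebuild the fitted data matrix exactly as the model saw it
  X <- fitted_data_matrix(tr, base)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 0)
  lam <- sv$d^2 / nrow(X)
  k <- length(lam)
  expect_equal(model$eigenvalues[seq_len(k)], lam, tolerance = 1e-8)
  # total variance is conserved: sum of eigenvalues = trace of covariance
  expect_equal(sum(model$eigenvalues), sum(Xc^2) / nrow(X),
               tolerance = 1e-8)
})

test_that("eigenvectors are orthonormal and eigenvalues descend", {
  base <- backbone_base()
  set.seed(10)
  tr <- make_mode_trajectory(base,
                             list(list(vector = rnorm(3 * nrow(base$atoms)),
                                       variance = 5)),
                             n_frames = 40, noise_sigma = 0.3, seed = 11)
  model <- fit_pc_model(tr, base)
  V <- model$eigenvectors[, 1:10]
  G <- t(V) %*% V
  expect_lt(max(abs(G - diag(10))), 1e-8)
  expect_true(all(diff(model$eigenvalues) <= 1e-10))
  expect_true(all(model$eigenvalues >= 0))
})

test_that("a global rotation of all frames leaves the spectrum unchanged", {
  base <- backbone_base()
  set.seed(12)
  tr <- make_mode_trajectory(base,
                             list(list(vector = rnorm(3 * nrow(base$atoms)),
                                       variance = 4)),
                             n_frames = 50, noise_sigma = 0.1, seed = 13)
  model <- fit_pc_model(tr, base)
  R <- random_rotation()
  tr2 <- tr
  tr2$frames <- lapply(tr$frames, function(fr) fr %*% t(R))
  model2 <- fit_pc_model(tr2, base)
  k <- 10
  expect_equal(model2$eigenvalues[1:k], model$eigenvalues[1:k],
               tolerance = 1e-6)
})

test_that("projections behave as an orthonormal coordinate system", {
  base <- backbone_base()
  set.seed(14)
  tr <- make_mode_trajectory(base,
                             list(list(vector = rnorm(3 * nrow(base$atoms)),
                                       variance = 9),
                                  list(vector = rnorm(3 * nrow(base$atoms)),
                                       variance = 4)),
                             n_frames = 300, noise_sigma = 0.05, seed = 15)
  model <- fit_pc_model(tr, base)
  # the mean structure projects to 0
  mean_s <- set_coords(model$topology, model$mean_coords)
  ens_mean <- new_ensemble(model$topology, list(model$mean_coords))
  p0 <- project(ens_mean, model, 1, backbone_only = FALSE)
  expect_equal(p0$values, 0, tolerance = 1e-8)
  # mean + a*PC1 projects to a
  v1 <- matrix(model$eigenvectors[, 1], ncol = 3, byrow = TRUE)
  ens_a <- new_ensemble(model$topology,
                        list(model$mean_coords + 7 * v1))
  expect_equal(project(ens_a, model, 1, backbone_only = FALSE)$values, 7,
               tolerance = 1e-6)
  # projections of the fitting set: variance equals the eigenvalue,
  # distinct components uncorrelated
  p1 <- project(tr, model, 1)$values
  p2 <- project(tr, model, 2)$values
  n <- length(p1)
  expect_equal(mean(p1^2) - mean(p1)^2, model$eigenvalues[1],
               tolerance = 1e-6 * model$eigenvalues[1])
  cov12 <- mean(p1 * p2) - mean(p1) * mean(p2)
  expect_lt(abs(cov12), 1e-6 * model$eigenvalues[1])
  expect_error(project(tr, model, 10^6), "index")
})

test_that("projection histograms sum to the frame count with symmetric binning", {
  h <- histogram_projections(rep(0, 10), bin_width = 1)
  expect_equal(sum(h$counts), 10)
  expect_equal(length(h$centers[h$counts > 0]), 1)
  h2 <- histogram_projections(c(rep(-1, 5), rep(1, 5)), bin_width = 1)
  expect_equal(sum(h2$counts), 10)
  expect_equal(h2$counts[h2$centers == -1], 5)
  expect_equal(h2$counts[h2$centers == 1], 5)
  expect_equal(h2$centers, rev(-h2$centers))  # symmetric axis
  # Gaussian projections: binned s.d. within 10% of sigma at n = 5000
  set.seed(16)
  vals <- rnorm(5000, sd = 12)
  h3 <- histogram_projections(vals, bin_width = 2)
  expect_equal(sum(h3$counts), 5000)
  mu <- sum(h3$centers * h3$counts) / 5000
  sd_binned <- sqrt(sum(h3$counts * (h3$centers - mu)^2) / 5000)
  expect_equal(sd_binned, 12, tolerance = 0.1)
  expect_error(histogram_projections(vals, -1), "parameter")
})

test_that("mode endpoints straddle the mean and re-project correctly", {
  base <- backbone_base()
  set.seed(17)
  tr <- make_mode_trajectory(base,
                             list(list(vector = rnorm(3 * nrow(base$atoms)),
                                       variance = 9),
                                  list(vector = rnorm(3 * nrow(base$atoms)),
                                       variance = 4)),
                             n_frames = 200, noise_sigma = 0.05, seed = 18)
  model <- fit_pc_model(tr, base)
  ep0 <- mode_endpoints(model, 1, amplitude = 0)
  expect_equal(coords(ep0$minus), coords(ep0$plus))
  ep <- mode_endpoints(model, 1, amplitude = 80)
  # midpoint is exactly the mean structure
  expect_equal((coords(ep$minus) + coords(ep$plus)) / 2,
               model$mean_coords, ignore_attr = TRUE)
  prj <- function(s, comp) project(new_ensemble(model$topology,
                                                list(coords(s))),
                                   model, comp, backbone_only = FALSE)$values
  expect_equal(prj(ep$plus, 1), 80, tolerance = 1e-6)
  expect_equal(prj(ep$minus, 1), -80, tolerance = 1e-6)
  # endpoints are orthogonal to the other component
  expect_equal(prj(ep$plus, 2), 0, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  base <- backbone_base()
  expect_error(fit_pc_model(new_ensemble(base, list(coords(base))), base),
               "rank error")
})
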