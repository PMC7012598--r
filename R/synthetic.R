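## Synthetic-data generators with known ground truth.
##
## Every input class the pipeline consumes can be generated here with its
## ground truth attached, so all stages are testable without downloading
## structures or running simulations. All generators are pure functions of
## their parameters and seed, and emit standard formats (PDB, CSV, FASTA)
## through the package's real I/O paths on request.
##
## Noise models: isotropic Gaussian on coordinates; multiplicative Gaussian
## on assay signals (matching mean +/- s.d. replicate reporting).

## fixed probe geometry of the toy kinase (angstrom):
## anchors at (4,0,0) [L152 CD2] and (0,10,0) [Y225 OH]; the mobile L173
## CD2 probe sits at the origin in "up" (d_L152 = 4, d_Y225 = 10) and at
## (4,10,0) in "down" (d_L152 = 10, d_Y225 = 4). The two distance
## gradients are orthogonal, so coordinate noise propagates independently
## into the two distances. Built-in distance separation: 6 A.
TOY_ANCHOR_152 <- c(4, 0, 0)
TOY_ANCHOR_225 <- c(0, 10, 0)
TOY_PROBE_UP <- c(0, 0, 0)
TOY_PROBE_DOWN <- c(4, 10, 0)

#' Built-in distance separation of the toy-kinase switch (angstrom)
#' @export
TOY_SWITCH_SEPARATION <- 6

#' Generate a toy kinase structure in a prescribed loop state
#'
#' A small polypeptide-like coordinate set with full heavy backbone
#' (N, CA, C, O) for residues 140-240 in chain A, carrying the three switch
#' probe atoms: L152 CD2, L173 CD2 and Y225 OH, placed so that state "up"
#' gives d_L152 = 4 and d_Y225 = 10 angstrom, and "down" the reverse.
#' Probe positions are exact; backbone positions get a tiny deterministic
#' jitter from the seed so distinct seeds give distinct structures.
#'
#' @param seed integer RNG seed.
#' @param state "up" or "down".
#' @return a `kin_structure` with attribute `state`.
#' @export
make_toy_kinase <- function(seed = 1, state = c("up", "down")) {
  state <- match.arg(state)
  res <- 140:240
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    expr
  }
  rows <- list()
  serial <- 0L
  add <- function(name, element, res_name, res_seq, xyz) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, element = element, res_name = res_name,
      res_seq = res_seq, chain = "A", altloc = "", occupancy = 1,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  }
  withr_seed({
    jitter <- matrix(stats::rnorm(length(res) * 4 * 3, sd = 0.01), ncol = 3)
    k <- 0L
    for (i in seq_along(res)) {
      r <- res[i]
      res_name <- if (r %in% c(152, 173)) "LEU" else if (r == 225) "TYR" else "ALA"
      base <- c(3.8 * i, -25, 5)  # extended chain, well away from probes
      offs <- list(N = c(-1.2, 0.5, 0), CA = c(0, 0, 0),
                   C = c(1.3, 0.4, 0), O = c(1.4, 1.6, 0))
      for (nm in names(offs)) {
        k <- k + 1L
        add(nm, substr(nm, 1, 1), res_name, r, base + offs[[nm]] + jitter[k, ])
      }
      if (r == 152) add("CD2", "C", res_name, r, TOY_ANCHOR_152)
      if (r == 173) add("CD2", "C", res_name, r,
                        if (state == "up") TOY_PROBE_UP else TOY_PROBE_DOWN)
      if (r == 225) add("OH", "O", res_name, r, TOY_ANCHOR_225)
    }
  })
  s <- new_structure(sprintf("toy_kinase_%s_seed%d", state, seed),
                     do.call(rbind, rows))
  attr(s, "state") <- state
  s
}

#' Generate a two-state switch ensemble with known labels
#'
#' Frames are toy-kinase "up"/"down" coordinate sets (shared topology) with
#' isotropic Gaussian noise of standard deviation `noise_sigma` on every
#' coordinate; labels are recorded as ground truth. Up frames precede down
#' frames.
#'
#' @param n_up,n_down frame counts per state (`n_up + n_down >= 1`).
#' @param noise_sigma coordinate noise s.d. (angstrom).
#' @param seed integer RNG seed.
#' @return list(ensemble: `kin_ensemble`, labels: character vector,
#'   separation: built-in distance separation in angstrom).
#' @export
make_switch_ensemble <- function(n_up, n_down, noise_sigma = 0, seed = 1) {
  if (n_up + n_down < 1) stop("input error: n_up + n_down must be >= 1")
  up <- make_toy_kinase(seed, "up")
  down <- make_toy_kinase(seed, "down")
  labels <- c(rep("up", n_up), rep("down", n_down))
  xyz <- list(up = coords(up), down = coords(down))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  frames <- lapply(labels, function(lb) {
    base <- xyz[[lb]]
    base + matrix(stats::rnorm(length(base), sd = noise_sigma),
                  ncol = 3)
  })
  topo <- up
  topo$id <- sprintf("switch_ensemble_seed%d", seed)
  list(ensemble = new_ensemble(topo, frames), labels = labels,
       separation = TOY_SWITCH_SEPARATION)
}

## basis of the 6-dim rigid-body subspace (3 translations + 3
## infinitesimal rotations about the centroid), orthonormal columns
rigid_body_basis <- function(base_xyz) {
  n <- nrow(base_xyz)
  ctr <- sweep(base_xyz, 2, colMeans(base_xyz))
  B <- matrix(0, nrow = 3 * n, ncol = 6)
  for (k in 1:3) B[seq(k, 3 * n, by = 3), k] <- 1
  # infinitesimal rotations: dr = e_k x r
  ex <- cbind(rep(0, n), -ctr[, 3], ctr[, 2])
  ey <- cbind(ctr[, 3], rep(0, n), -ctr[, 1])
  ez <- cbind(-ctr[, 2], ctr[, 1], rep(0, n))
  B[, 4] <- as.vector(t(ex)); B[, 5] <- as.vector(t(ey))
  B[, 6] <- as.vector(t(ez))
  qr.Q(qr(B))[, 1:6, drop = FALSE]
}

#' Generate a trajectory dominated by prescribed collective modes
#'
#' Frames are `base + sum_i a_i(t) * mode_i + noise` with amplitudes
#' `a_i(t) ~ N(0, variance_i)`. Modes are first projected out of the
#' 6-dimensional rigid-body subspace (global translations and rotations)
#' and then orthonormalized among themselves: principal-component recovery
#' is only well-posed for internal modes, since fitting superposes every
#' frame onto a reference. Any change made to the supplied modes is
#' recorded in the ground truth.
#'
#' @param base a `kin_structure`.
#' @param modes list of `list(vector = 3N-vector, variance = sigma^2)`
#'   entries (variance in angstrom squared).
#' @param n_frames number of frames.
#' @param noise_sigma additional isotropic coordinate noise s.d.
#' @param seed integer RNG seed.
#' @return a `kin_ensemble` with attribute `ground_truth`: list(modes
#'   (3N x k orthonormal matrix actually used), variances, amplitudes
#'   (n_frames x k), modes_adjusted flag, noise_sigma).
#' @export
make_mode_trajectory <- function(base, modes, n_frames, noise_sigma = 0,
                                 seed = 1) {
  stopifnot(inherits(base, "kin_structure"), n_frames >= 1)
  base_xyz <- coords(base)
  n3 <- 3 * nrow(base_xyz)
  V <- do.call(cbind, lapply(modes, function(m) {
    v <- as.numeric(m$vector)
    if (length(v) != n3) stop("mode vector length must be 3N = ", n3)
    v
  }))
  vars <- vapply(modes, function(m) m$variance, numeric(1))
  if (any(vars <= 0)) stop("mode variances must be > 0")
  Rb <- rigid_body_basis(base_xyz)
  Vint <- V - Rb %*% (t(Rb) %*% V)
  Q <- qr.Q(qr(Vint))[, seq_len(ncol(V)), drop = FALSE]
  # keep the sign aligned with the input modes
  for (j in seq_len(ncol(Q)))
    if (sum(Q[, j] * V[, j]) < 0) Q[, j] <- -Q[, j]
  adjusted <- !isTRUE(all.equal(Q, V / rep(sqrt(colSums(V^2)),
                                           each = nrow(V)),
                                tolerance = 1e-8, check.attributes = FALSE))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  A <- sapply(seq_along(vars), function(j)
    stats::rnorm(n_frames, sd = sqrt(vars[j])))
  A <- matrix(A, nrow = n_frames)
  frames <- lapply(seq_len(n_frames), function(i) {
    disp <- Q %*% A[i, ]
    fr <- base_xyz + matrix(disp, ncol = 3, byrow = TRUE)
    if (noise_sigma > 0)
      fr <- fr + matrix(stats::rnorm(length(fr), sd = noise_sigma), ncol = 3)
    fr
  })
  ens <- new_ensemble(base, frames)
  attr(ens, "ground_truth") <- list(modes = Q, variances = vars,
                                    amplitudes = A,
                                    modes_adjusted = adjusted,
                                    noise_sigma = noise_sigma)
  ens
}

#' Generate a pocket scene with analytically known free volume
#'
#' @param spec a [pocket_spec()]; for `occlusion = "half_slab"` and
#'   `"center_atom"` the first sphere is the occluded one.
#' @param occlusion "none" (no occluding atoms), "center_atom" (one carbon
#'   at the centre of sphere 1), or "half_slab" (a dense carbon lattice
#'   occluding the half-space below the centre plane of sphere 1; only
#'   meaningful for a single-sphere spec).
#' @return list(structure: `kin_structure`, expected_volume: closed-form
#'   expected free volume in cubic angstrom).
#' @export
make_pocket_scene <- function(spec,
                              occlusion = c("none", "center_atom",
                                            "half_slab")) {
  occlusion <- match.arg(occlusion)
  stopifnot(inherits(spec, "pocket_spec"))
  vol_union <- union_volume_analytic(spec)
  s1 <- spec$spheres[[1]]
  r_c <- unname(spec$radii_table["C"]) + spec$probe_radius
  mk <- function(xyz) {
    n <- nrow(xyz)
    new_structure(paste0("pocket_scene_", occlusion), data.frame(
      serial = seq_len(n), name = "C", element = "C", res_name = "UNK",
      res_seq = seq_len(n), chain = "A", altloc = "", occupancy = 1,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
  }
  if (occlusion == "none") {
    # one far-away atom so the scene still contains a structure
    far <- s1$center + c(0, 0, s1$radius + 10 * r_c)
    return(list(structure = mk(matrix(far, ncol = 3)),
                expected_volume = vol_union))
  }
  if (occlusion == "center_atom") {
    return(list(structure = mk(matrix(s1$center, ncol = 3)),
                expected_volume = vol_union - 4 / 3 * pi * r_c^3))
  }
  # half_slab: carbon lattice filling z < z_c - r_c so occlusion reaches
  # (just below) the centre plane; lateral spacing 0.5 A keeps the covered
  # boundary within ~0.04 A of the plane
  lat <- 0.5
  xs <- seq(s1$center[1] - s1$radius - r_c, s1$center[1] + s1$radius + r_c,
            by = lat)
  ys <- seq(s1$center[2] - s1$radius - r_c, s1$center[2] + s1$radius + r_c,
            by = lat)
  zs <- seq(s1$center[3] - s1$radius - r_c, s1$center[3] - r_c, by = 1.0)
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  list(structure = mk(g),
       expected_volume = 0.5 * 4 / 3 * pi * s1$radius^3)
}

#' Simulate pseudo-first-order phosphorylation progress curves
#'
#' Product follows `P(t) = S0 * (1 - exp(-(kcat/Km) * E * t))` with
#' multiplicative Gaussian noise per observation. Default conditions mirror
#' a depletion-regime efficiency assay: 10 uM substrate, 0.2 uM kinase,
#' 3 hr incubation.
#'
#' @param kcat_over_Km true efficiency (M^-1 s^-1).
#' @param E_total enzyme concentration (M).
#' @param S0 initial substrate concentration (M).
#' @param timepoints times (s).
#' @param noise_frac multiplicative noise fraction (e.g. 0.02).
#' @param n_replicates replicates (default 4, as in rate-assay legends).
#' @param seed integer RNG seed.
#' @param substrate substrate label.
#' @return list(curves: list of [progress_curve()] (product, M), table:
#'   CSV-ready data.frame(time_s, signal, replicate, substrate),
#'   ground_truth).
#' @export
simulate_progress_curves <- function(kcat_over_Km = 1e3, E_total = 0.2e-6,
                                     S0 = 10e-6,
                                     timepoints = seq(0, 10800, by = 600),
                                     noise_frac = 0.02, n_replicates = 4,
                                     seed = 1, substrate = "FASP") {
  stopifnot(kcat_over_Km > 0, E_total > 0, S0 > 0)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ideal <- S0 * (1 - exp(-kcat_over_Km * E_total * timepoints))
  curves <- lapply(seq_len(n_replicates), function(r) {
    noisy <- ideal * (1 + stats::rnorm(length(ideal), sd = noise_frac))
    noisy[1] <- 0  # no product before the reaction starts
    progress_curve(timepoints, pmax(noisy, 0), time_unit = "s",
                   signal_unit = "M", replicate = r, substrate = substrate)
  })
  table <- do.call(rbind, lapply(curves, function(cv)
    data.frame(time_s = cv$timepoints, signal = cv$signal,
               replicate = cv$replicate, substrate = cv$substrate)))
  list(curves = curves, table = table,
       ground_truth = list(kcat_over_Km = kcat_over_Km, E_total = E_total,
                           S0 = S0, noise_frac = noise_frac))
}

#' Simulate a one-phase luminescence decay (cycloheximide chase)
#'
#' Constant baseline before `t_chx`, then
#' `Y(t) = (Y0 - plateau) * exp(-ln 2 / t_half * (t - t_chx)) + plateau`
#' with multiplicative Gaussian noise.
#'
#' @param t_half true half-life (hr).
#' @param Y0 signal at treatment time.
#' @param plateau minimum signal.
#' @param t_chx treatment time (hr).
#' @param duration total trace length after `t_chx` (hr).
#' @param dt sampling interval (hr).
#' @param noise_frac multiplicative noise fraction.
#' @param n_replicates replicates (default 4).
#' @param seed integer RNG seed.
#' @return list(table: data.frame(time_hr, signal, replicate),
#'   ground_truth).
#' @export
simulate_decay <- function(t_half = 3.5, Y0 = 100, plateau = 10,
                           t_chx = 2, duration = 24, dt = 0.5,
                           noise_frac = 0.02, n_replicates = 4, seed = 1) {
  stopifnot(t_half > 0, Y0 > plateau, plateau >= 0)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  k <- log(2) / t_half
  t_pre <- seq(0, t_chx - dt, by = dt)
  t_post <- seq(t_chx, t_chx + duration, by = dt)
  ideal <- c(rep(Y0, length(t_pre)),
             (Y0 - plateau) * exp(-k * (t_post - t_chx)) + plateau)
  tt <- c(t_pre, t_post)
  table <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    noisy <- ideal * (1 + stats::rnorm(length(ideal), sd = noise_frac))
    data.frame(time_hr = tt, signal = pmax(noisy, .Machine$double.eps),
               replicate = r)
  }))
  list(table = table,
       ground_truth = list(t_half = t_half, k = k, Y0 = Y0,
                           plateau = plateau, t_chx = t_chx,
                           noise_frac = noise_frac))
}

#' Simulate a mutant panel with a linear efficiency-ratio/half-life law
#'
#' Mutant FASP/Degron efficiency ratios are spread evenly over
#' `ratio_range`; half-lives follow `slope * ratio + intercept` plus
#' additive Gaussian noise of s.d. `noise_sd` (hr).
#'
#' @param slope,intercept generating coefficients (hr per unit ratio; hr).
#' @param n_mutants panel size.
#' @param ratio_range range of efficiency ratios.
#' @param noise_sd additive half-life noise s.d. (hr).
#' @param seed integer RNG seed.
#' @return list(table: data.frame(mutant, ratio, half_life_hr),
#'   ground_truth).
#' @export
simulate_phosphoswitch_panel <- function(slope = 1.5, intercept = 1,
                                         n_mutants = 8,
                                         ratio_range = c(0.25, 3),
                                         noise_sd = 0.2, seed = 1) {
  stopifnot(n_mutants >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ratio <- seq(ratio_range[1], ratio_range[2], length.out = n_mutants)
  half_life <- slope * ratio + intercept +
    stats::rnorm(n_mutants, sd = noise_sd)
  list(table = data.frame(mutant = sprintf("mut%02d", seq_len(n_mutants)),
                          ratio = ratio, half_life_hr = half_life),
       ground_truth = list(slope = slope, intercept = intercept,
                           noise_sd = noise_sd))
}

#' Generate a synthetic protein alignment with known substitution rate
#'
#' Starts from a random reference sequence and substitutes each non-
#' reference position independently with probability `p_sub` (gap with
#' probability `p_gap`).
#'
#' @param n_sequences number of sequences (reference included).
#' @param n_positions alignment length.
#' @param p_sub per-position substitution probability.
#' @param p_gap per-position gap probability.
#' @param seed integer RNG seed.
#' @return named character vector of aligned sequences; the reference is
#'   named "REF".
#' @export
make_alignment <- function(n_sequences = 20, n_positions = 30,
                           p_sub = 0.02, p_gap = 0, seed = 1) {
  stopifnot(n_sequences >= 1, n_positions >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref <- sample(aa, n_positions, replace = TRUE)
  seqs <- vapply(seq_len(n_sequences - 1), function(i) {
    s <- ref
    sub <- which(stats::runif(n_positions) < p_sub)
    for (j in sub) s[j] <- sample(setdiff(aa, ref[j]), 1)
    if (p_gap > 0) {
      gp <- stats::runif(n_positions) < p_gap
      s[gp] <- "-"
    }
    paste(s, collapse = "")
  }, character(1))
  out <- c(paste(ref, collapse = ""), seqs)
  names(out) <- c("REF", sprintf("SP%02d", seq_len(n_sequences - 1)))
  out
}

#' Write an alignment as FASTA
#' @param alignment named character vector of sequences.
#' @param path output path.
#' @export
write_alignment <- function(alignment, path) {
  writeLines(as.vector(rbind(paste0(">", names(alignment)), alignment)),
             path)
  invisible(path)
}
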