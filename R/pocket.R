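## Grid-based free-volume analysis of the substrate-binding cleft.
##
## The cleft and the adjacent anion-binding sites are enclosed in a union
## of (by default three overlapping) spheres. A regular grid restricted to
## that union is built once; for each frame a grid point is "closed" iff it
## falls within the van der Waals radius of any protein heavy atom, and the
## free volume is the open-point count times the voxel volume. Averaging
## the per-frame open indicators over an ensemble yields an open-fraction
## map, conventionally contoured at 0.1 to show regions consistently open
## during a simulation.

#' Bondi van der Waals radii (angstrom) for protein heavy atoms
#' @export
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                 P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, SE = 1.90)

#' Define a spherical inclusion region
#' @param center 3-vector (angstrom).
#' @param radius sphere radius (angstrom, > 0).
#' @export
sphere_region <- function(center, radius) {
  stopifnot(length(center) == 3, is.finite(radius))
  if (radius <= 0) stop("sphere radius must be > 0")
  structure(list(center = as.numeric(center), radius = radius),
            class = "sphere_region")
}

#' Pocket analysis specification
#'
#' @param spheres list of [sphere_region()] objects (conventionally three
#'   overlapping spheres covering the substrate cleft and anion sites).
#' @param grid_spacing grid spacing in angstrom (default 1.0).
#' @param radii_table named vector of per-element occlusion radii
#'   (default [BONDI_RADII]; no probe inflation).
#' @param probe_radius optional probe padding added to every occlusion
#'   radius (default 0).
#' @param frame_stride analyse every `frame_stride`-th frame (default 1);
#'   see [stride_for_interval()] to convert a time interval such as
#'   "every two ns" into frames.
#' @export
pocket_spec <- function(spheres, grid_spacing = 1.0,
                        radii_table = BONDI_RADII, probe_radius = 0,
                        frame_stride = 1L) {
  if (inherits(spheres, "sphere_region")) spheres <- list(spheres)
  stopifnot(length(spheres) >= 1, grid_spacing > 0, frame_stride >= 1)
  for (s in spheres) stopifnot(inherits(s, "sphere_region"))
  structure(list(spheres = spheres, grid_spacing = grid_spacing,
                 radii_table = radii_table, probe_radius = probe_radius,
                 frame_stride = as.integer(frame_stride)),
            class = "pocket_spec")
}

#' Convert a sampling time interval to a frame stride
#' @param frame_times frame times (ns) of an ensemble.
#' @param interval_ns desired sampling interval in ns (e.g. 2).
#' @return integer stride (>= 1).
#' @export
stride_for_interval <- function(frame_times, interval_ns) {
  stopifnot(length(frame_times) >= 2, interval_ns > 0)
  dt <- stats::median(diff(frame_times))
  max(1L, as.integer(round(interval_ns / dt)))
}

new_grid_map <- function(origin, spacing, dims, values, mask) {
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = as.integer(dims), values = values, mask = mask),
            class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("<grid_map> %dx%dx%d @ %.2f A, %d points in mask\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, sum(x$mask)))
  invisible(x)
}

grid_axes <- function(map)
  lapply(1:3, function(k) map$origin[k] + (seq_len(map$dims[k]) - 1) * map$spacing)

#' Build the analysis grid inside a union of spheres
#'
#' Grid points lie on a regular lattice (deterministic ordering: x, then y,
#' then z index) covering the bounding box of the spheres; a point belongs
#' to the mask iff it falls inside at least one sphere.
#'
#' @param spec a [pocket_spec()].
#' @return a `grid_map` with all values 0 inside the mask.
#' @export
build_grid <- function(spec) {
  stopifnot(inherits(spec, "pocket_spec"))
  sp <- spec$grid_spacing
  ctr <- t(vapply(spec$spheres, function(s) s$center, numeric(3)))
  rad <- vapply(spec$spheres, function(s) s$radius, numeric(1))
  lo <- apply(ctr - rad, 2, min); hi <- apply(ctr + rad, 2, max)
  origin <- floor(lo / sp) * sp
  dims <- pmax(1L, as.integer(ceiling((hi - origin) / sp)) + 1L)
  axes <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 1) * sp)
  mask <- array(FALSE, dim = dims)
  for (i in seq_along(rad)) {
    d2 <- outer(outer((axes[[1]] - ctr[i, 1])^2,
                      (axes[[2]] - ctr[i, 2])^2, "+"),
                (axes[[3]] - ctr[i, 3])^2, "+")
    mask <- mask | (d2 <= rad[i]^2)
  }
  if (!any(mask)) stop("empty-region error: no grid points inside spheres")
  vals <- array(NA_real_, dim = dims)
  vals[mask] <- 0
  new_grid_map(origin, sp, dims, vals, mask)
}

#' Analytic union-of-spheres volume for a pocket spec
#'
#' Inclusion-exclusion using the closed-form two-sphere lens volume; exact
#' when no three spheres share a common region (an error is raised if a
#' triple overlap is detected by bounding argument, since the triple term
#' has no elementary closed form used here).
#'
#' @param spec a [pocket_spec()].
#' @return volume in cubic angstrom.
#' @export
union_volume_analytic <- function(spec) {
  sph <- spec$spheres
  v <- sum(vapply(sph, function(s) 4 / 3 * pi * s$radius^3, numeric(1)))
  n <- length(sph)
  if (n == 1) return(v)
  pair_overlaps <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((sph[[i]]$center - sph[[j]]$center)^2))
    r1 <- sph[[i]]$radius; r2 <- sph[[j]]$radius
    if (d < r1 + r2) {
      if (d <= abs(r1 - r2)) {
        lens <- 4 / 3 * pi * min(r1, r2)^3
      } else {
        lens <- pi * (r1 + r2 - d)^2 *
          (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
      }
      v <- v - lens
      pair_overlaps[[length(pair_overlaps) + 1L]] <- c(i, j)
    }
  }
  # detect possible triple overlap: three pairwise-overlapping spheres
  if (length(pair_overlaps) >= 3) {
    pairs <- do.call(rbind, pair_overlaps)
    for (i in seq_len(n)) {
      partners <- unique(c(pairs[pairs[, 1] == i, 2],
                           pairs[pairs[, 2] == i, 1]))
      if (length(partners) >= 2) {
        for (a in seq_along(partners)[-1]) for (b in seq_len(a - 1)) {
          pr <- sort(c(partners[a], partners[b]))
          if (any(pairs[, 1] == pr[1] & pairs[, 2] == pr[2]))
            stop("union_volume_analytic: triple sphere overlap; use a Monte-Carlo estimate instead")
        }
      }
    }
  }
  v
}

#' Free volume of one frame inside the grid
#'
#' A grid point is closed iff it lies within `radii_table[element] +
#' probe_radius` of any heavy atom of the frame (hydrogens are excluded,
#' keeping crystal and MD frames comparable). Waters, ions and sulfates
#' must already have been removed via [strip_nonprotein()].
#'
#' @param xyz N x 3 frame coordinates.
#' @param topology `kin_structure` giving atom identities (elements).
#' @param spec a [pocket_spec()].
#' @param grid grid from [build_grid()] (built once and reused).
#' @return list(volume in cubic angstrom, open: logical array over the
#'   grid, TRUE where in-mask and unoccluded).
#' @export
frame_free_volume <- function(xyz, topology, spec, grid) {
  stopifnot(inherits(spec, "pocket_spec"), inherits(grid, "grid_map"))
  xyz <- as.matrix(xyz)
  elements <- toupper(topology$atoms$element)
  heavy <- elements != "H"
  xyz <- xyz[heavy, , drop = FALSE]
  elements <- elements[heavy]
  missing_el <- setdiff(unique(elements), names(spec$radii_table))
  if (length(missing_el))
    stop("configuration error: element(s) missing from radii_table: ",
         paste(missing_el, collapse = ", "))
  radii <- spec$radii_table[elements] + spec$probe_radius
  axes <- grid_axes(grid)
  closed <- array(FALSE, dim = grid$dims)
  for (a in seq_len(nrow(xyz))) {
    r <- radii[a]
    ix <- which(abs(axes[[1]] - xyz[a, 1]) <= r)
    if (!length(ix)) next
    iy <- which(abs(axes[[2]] - xyz[a, 2]) <= r)
    if (!length(iy)) next
    iz <- which(abs(axes[[3]] - xyz[a, 3]) <= r)
    if (!length(iz)) next
    d2 <- outer(outer((axes[[1]][ix] - xyz[a, 1])^2,
                      (axes[[2]][iy] - xyz[a, 2])^2, "+"),
                (axes[[3]][iz] - xyz[a, 3])^2, "+")
    blk <- closed[ix, iy, iz, drop = FALSE]
    closed[ix, iy, iz] <- blk | (d2 <= r^2)
  }
  open <- grid$mask & !closed
  list(volume = sum(open) * spec$grid_spacing^3, open = open)
}

#' Ensemble open-fraction map and free-volume series
#'
#' Frames (at the configured stride) are assumed to be superposed to a
#' common reference beforehand; a centroid drift above `drift_warn`
#' triggers a warning (not an error). Each grid value becomes the fraction
#' of analysed frames in which the point was open; per-frame free volumes
#' are collected alongside.
#'
#' @param ensemble a `kin_ensemble` (protein only; see
#'   [strip_nonprotein()]).
#' @param spec a [pocket_spec()].
#' @param drift_warn centroid-drift threshold in angstrom (default 2).
#' @return list(map: `grid_map` of open fractions, volumes: a
#'   `volume_series` with per-frame volumes (cubic angstrom), mean, sd and
#'   analysed frame indices).
#' @export
ensemble_frequency_map <- function(ensemble, spec, drift_warn = 2.0) {
  stopifnot(inherits(ensemble, "kin_ensemble"))
  grid <- build_grid(spec)
  idx <- seq(1, n_frames(ensemble), by = spec$frame_stride)
  cents <- t(vapply(ensemble$frames[idx], colMeans, numeric(3)))
  drift <- max(sqrt(rowSums(sweep(cents, 2, cents[1, ])^2)))
  if (drift > drift_warn)
    warning(sprintf("ensemble centroid drifts %.2f A; frames may not be superposed to a common reference", drift))
  counts <- array(0, dim = grid$dims)
  volumes <- numeric(length(idx))
  for (k in seq_along(idx)) {
    ffv <- frame_free_volume(ensemble$frames[[idx[k]]], ensemble$topology,
                             spec, grid)
    counts <- counts + ffv$open
    volumes[k] <- ffv$volume
  }
  vals <- array(NA_real_, dim = grid$dims)
  vals[grid$mask] <- counts[grid$mask] / length(idx)
  map <- new_grid_map(grid$origin, grid$spacing, grid$dims, vals, grid$mask)
  vs <- structure(list(volumes = volumes, mean = mean(volumes),
                       sd = stats::sd(volumes), frame_indices = idx),
                  class = "volume_series")
  list(map = map, volumes = vs)
}

#' Contour an open-fraction map
#'
#' Retains grid points whose open fraction is at least `level` (default
#' 0.1, the conventional level for "consistently open" regions); raising
#' the level never adds points.
#'
#' @param map a `grid_map` of open fractions.
#' @param level contour level in (0, 1].
#' @param path optional output path; when given the contoured map is also
#'   written in OpenDX format.
#' @return the contoured `grid_map` (mask reduced to retained points).
#' @export
contour_map <- function(map, level = 0.1, path = NULL) {
  stopifnot(inherits(map, "grid_map"))
  if (!is.numeric(level) || level <= 0 || level > 1)
    stop("parameter error: contour level must be in (0, 1]")
  keep <- map$mask & !is.na(map$values) & map$values >= level
  vals <- array(NA_real_, dim = map$dims)
  vals[keep] <- map$values[keep]
  out <- new_grid_map(map$origin, map$spacing, map$dims, vals, keep)
  if (!is.null(path)) write_grid_map(out, path)
  out
}

#' Default three-sphere pocket specification from a structure
#'
#' Sphere centres are placed at the heavy-atom centroids of anion Site 1
#' residues (R178, K224) and Site 2 residues (R127, K154, K171), with a
#' third sphere at the midpoint covering the substrate cleft; radius 8 A
#' each. All parameters are overridable.
#'
#' @param structure a `kin_structure` (one chain).
#' @param chain chain to use (default first chain present).
#' @param radius sphere radius (angstrom).
#' @param site1_residues,site2_residues residue numbers defining the two
#'   anion sites (author numbering).
#' @param ... further arguments passed to [pocket_spec()].
#' @export
default_pocket_spec <- function(structure, chain = NULL, radius = 8,
                                site1_residues = c(178, 224),
                                site2_residues = c(127, 154, 171), ...) {
  stopifnot(inherits(structure, "kin_structure"))
  if (is.null(chain)) chain <- structure$atoms$chain[1]
  centroid_of <- function(res) {
    at <- structure$atoms
    keep <- at$chain == chain & at$res_seq %in% res &
      toupper(at$element) != "H"
    if (!any(keep)) stop("no heavy atoms for residues ",
                         paste(res, collapse = ","), " in chain ", chain)
    colMeans(as.matrix(at[keep, c("x", "y", "z")]))
  }
  c1 <- centroid_of(site1_residues)
  c2 <- centroid_of(site2_residues)
  pocket_spec(list(sphere_region(c1, radius), sphere_region(c2, radius),
                   sphere_region((c1 + c2) / 2, radius)), ...)
}

#' Write a volume series to CSV (frame, volume_A3)
#' @param vs a `volume_series`.
#' @param path output CSV path.
#' @export
write_volumes_csv <- function(vs, path) {
  stopifnot(inherits(vs, "volume_series"))
  utils::write.csv(data.frame(frame = vs$frame_indices,
                              volume_A3 = vs$volumes),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
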