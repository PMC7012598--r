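## Kabsch least-squares superposition and segment RMSD traces.
##
## Loop stability is assessed as the RMSD of a residue segment (activation
## loop 168-175, or loop L-EF 213-224) along an ensemble, after rigid-body
## superposition of each frame onto a reference. Two fit conventions are
## exposed: fit on the analysed segment itself (default), or fit on a
## stable core and measure the segment without refitting.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation R and translation t minimising the (weighted)
#' RMSD between `R %*% x + t` applied to the mobile coordinates and the
#' reference. Reflections are excluded, so R is always a proper rotation
#' (determinant +1).
#'
#' @param mobile N x 3 coordinate matrix.
#' @param reference N x 3 coordinate matrix (same N, >= 3 atoms).
#' @param weights optional non-negative per-atom weights.
#' @return a `superposition_result`: list(rotation 3x3, translation 3-vector,
#'   rmsd in angstrom).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("shape error: mobile and reference must both be N x 3, got ",
         nrow(mobile), "x", ncol(mobile), " vs ",
         nrow(reference), "x", ncol(reference))
  n <- nrow(mobile)
  if (n < 3) stop("shape error: need at least 3 atoms, got ", n)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative, length N, with positive sum")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  # degeneracy: points effectively collinear or coincident
  if (svd(P, nu = 0, nv = 0)$d[2] < 1e-8 ||
      svd(Q, nu = 0, nv = 0)$d[2] < 1e-8)
    stop("degeneracy error: coordinates are collinear or coincident")
  C <- crossprod(P * w, Q)                       # 3x3 covariance
  s <- svd(C)
  d <- sign(det(s$u) * det(s$v))
  Rrow <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)    # row-vector convention
  rotation <- t(Rrow)
  translation <- as.numeric(cr - rotation %*% cm)
  fitted <- P %*% Rrow
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  structure(list(rotation = rotation, translation = translation,
                 rmsd = rmsd), class = "superposition_result")
}

#' Apply a superposition to coordinates
#' @param sup a `superposition_result`.
#' @param xyz N x 3 coordinate matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(sup, xyz) {
  stopifnot(inherits(sup, "superposition_result"))
  sweep(as.matrix(xyz) %*% t(sup$rotation), 2, sup$translation, "+")
}

#' Plain RMSD between two coordinate sets (no fitting)
#' @param a,b N x 3 matrices.
#' @return RMSD in angstrom.
#' @export
rmsd_plain <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}

## match selection atoms between an ensemble topology and a reference
## structure by (res_seq, name); chains may differ between crystal forms.
match_selection <- function(topology, reference, selection) {
  it <- select_atoms(topology, selection)
  ir <- select_atoms(reference, selection)
  if (length(it) < 3 || length(ir) < 3)
    stop("selection error: selection resolves to fewer than 3 atoms (",
         length(it), " in topology, ", length(ir), " in reference)")
  # match chain-aware first; fall back to (res_seq, name) so that a
  # reference from a different crystal form (other chain ids) still maps
  kt <- paste(topology$atoms$chain[it], topology$atoms$res_seq[it],
              topology$atoms$name[it])
  kr <- paste(reference$atoms$chain[ir], reference$atoms$res_seq[ir],
              reference$atoms$name[ir])
  common <- intersect(kt, kr)
  if (length(common) < 3) {
    kt <- paste(topology$atoms$res_seq[it], topology$atoms$name[it])
    kr <- paste(reference$atoms$res_seq[ir], reference$atoms$name[ir])
    common <- intersect(kt, kr)
  }
  if (length(common) < 3)
    stop("selection error: fewer than 3 atoms shared between topology and reference for this selection")
  list(topo = it[match(common, kt)], ref = ir[match(common, kr)])
}

#' Per-frame segment RMSD trace against a reference
#'
#' For each frame of the ensemble: superpose the frame onto the reference
#' using the atoms of `fit_selection`, then compute the RMSD over
#' `rmsd_selection` without refitting. With `fit_selection ==
#' rmsd_selection` (the default when `rmsd_selection` is NULL) this is the
#' segment-fit convention; passing a stable-core fit selection gives the
#' core-fit convention. Atoms are matched between ensemble topology and
#' reference by residue number and atom name. Unweighted; heavy backbone
#' atoms are the conventional selection.
#'
#' @param ensemble a `kin_ensemble`.
#' @param reference a `kin_structure` (e.g. a crystallographic "up" or
#'   "down" conformation).
#' @param fit_selection an [atom_selection()] used for superposition.
#' @param rmsd_selection selection over which the RMSD is computed
#'   (default: same as `fit_selection`).
#' @param reference_name label for the reference ("up", "down", "initial",
#'   or any custom tag).
#' @param replica_id optional replica identifier.
#' @return an `rmsd_trace`: list(reference_name, segment, series (angstrom),
#'   frame_times, replica_id).
#' @export
segment_rmsd_trace <- function(ensemble, reference, fit_selection,
                               rmsd_selection = NULL,
                               reference_name = "custom",
                               replica_id = NA) {
  stopifnot(inherits(ensemble, "kin_ensemble"),
            inherits(reference, "kin_structure"))
  if (is.null(rmsd_selection)) rmsd_selection <- fit_selection
  fit <- match_selection(ensemble$topology, reference, fit_selection)
  msr <- match_selection(ensemble$topology, reference, rmsd_selection)
  ref_xyz <- coords(reference)
  series <- vapply(ensemble$frames, function(fr) {
    sup <- kabsch_superpose(fr[fit$topo, , drop = FALSE],
                            ref_xyz[fit$ref, , drop = FALSE])
    rmsd_plain(apply_superposition(sup, fr[msr$topo, , drop = FALSE]),
               ref_xyz[msr$ref, , drop = FALSE])
  }, numeric(1))
  structure(list(reference_name = reference_name, segment = rmsd_selection,
                 series = series, frame_times = ensemble$frame_times,
                 replica_id = replica_id),
            class = "rmsd_trace")
}

#' Average RMSD traces across replicas
#'
#' Pointwise arithmetic mean of per-replica traces (the per-replica series
#' are retained alongside the mean, as in per-replica/averaged trace plots).
#'
#' @param traces list of `rmsd_trace` objects of equal length and matching
#'   frame times.
#' @return an `averaged_trace`: list(mean, replicas, n_replicas,
#'   frame_times).
#' @export
replica_average <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 1)
  lens <- vapply(traces, function(tr) length(tr$series), integer(1))
  if (length(unique(lens)) != 1)
    stop("alignment error: traces have differing lengths: ",
         paste(unique(lens), collapse = ", "))
  times <- lapply(traces, function(tr) tr$frame_times)
  for (tm in times[-1])
    if (!identical(tm, times[[1]]))
      stop("alignment error: traces have mismatched frame times")
  mat <- do.call(cbind, lapply(traces, function(tr) tr$series))
  structure(list(mean = rowMeans(mat), replicas = traces,
                 n_replicas = length(traces), frame_times = times[[1]]),
            class = "averaged_trace")
}

#' Write RMSD traces to CSV (time_ns, replica, rmsd_A)
#' @param traces an `rmsd_trace`, list thereof, or `averaged_trace`.
#' @param path output CSV path.
#' @export
write_trace_csv <- function(traces, path) {
  if (inherits(traces, "rmsd_trace")) traces <- list(traces)
  if (inherits(traces, "averaged_trace")) traces <- traces$replicas
  tab <- do.call(rbind, lapply(traces, function(tr) {
    tm <- tr$frame_times
    if (is.null(tm)) tm <- seq_along(tr$series)
    data.frame(time_ns = tm, replica = tr$replica_id, rmsd_A = tr$series)
  }))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
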