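## Essential dynamics: PCA of backbone Cartesian fluctuations.
##
## Trajectories are reduced to backbone atoms, superposed to one reference,
## concatenated, and the covariance matrix of Cartesian fluctuations about
## the concatenated mean is diagonalized. One shared eigenbasis is fitted
## on all systems together, then each system's trajectory is projected into
## it, so that different systems (e.g. wild-type and mutant) are compared
## in the same principal-component space. Covariance uses the population
## divisor n; no mass weighting (projections are reported in angstrom).

reduce_backbone <- function(ensemble, backbone_atoms = BACKBONE_ATOMS) {
  sel <- atom_selection(atom_names = backbone_atoms)
  idx <- select_atoms(ensemble$topology, sel)
  idx <- idx[toupper(ensemble$topology$atoms$element[idx]) != "H"]
  if (length(idx) == 0) stop("no backbone atoms in topology")
  topo <- ensemble$topology
  topo$atoms <- topo$atoms[idx, , drop = FALSE]
  rownames(topo$atoms) <- NULL
  new_ensemble(topo, lapply(ensemble$frames,
                            function(fr) fr[idx, , drop = FALSE]),
               ensemble$frame_times)
}

superpose_frames_to <- function(frames, ref_xyz) {
  lapply(frames, function(fr) {
    sup <- kabsch_superpose(fr, ref_xyz)
    apply_superposition(sup, fr)
  })
}

## deterministic eigenvector sign: largest-|component| entry positive
fix_sign <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Fit a principal-component model of backbone fluctuations
#'
#' Frames of all input ensembles are (optionally) reduced to backbone
#' atoms, superposed onto the reference by Kabsch fitting, and
#' concatenated. The Cartesian covariance (divisor n) about the
#' concatenated mean is diagonalized with a dense symmetric eigensolver;
#' for very large atom counts (3N > 4000) a thin SVD of the centred data
#' matrix provides the top `max_modes` modes instead.
#'
#' @param ensembles a `kin_ensemble` or list of them (shared topology after
#'   backbone reduction).
#' @param reference a `kin_structure` to superpose on (must contain the
#'   same backbone atoms).
#' @param backbone_only reduce to backbone atoms N, CA, C, O (default TRUE).
#' @param backbone_atoms backbone atom-name set.
#' @param max_modes number of modes retained on the large-system SVD path
#'   (default 20).
#' @return a `pc_model`: list(mean_coords N x 3, eigenvectors 3N x k
#'   orthonormal columns, eigenvalues descending (angstrom squared),
#'   topology, reference, n_frames_fit).
#' @export
fit_pc_model <- function(ensembles, reference, backbone_only = TRUE,
                         backbone_atoms = BACKBONE_ATOMS, max_modes = 20) {
  if (inherits(ensembles, "kin_ensemble")) ensembles <- list(ensembles)
  stopifnot(length(ensembles) >= 1, inherits(reference, "kin_structure"))
  if (backbone_only)
    ensembles <- lapply(ensembles, reduce_backbone, backbone_atoms)
  topo <- ensembles[[1]]$topology
  sig0 <- topology_signature(topo$atoms)
  for (e in ensembles[-1]) {
    sig <- topology_signature(e$topology$atoms)
    if (!identical(sig, sig0))
      stop("topology error: ensembles differ after backbone reduction")
  }
  ref <- reference
  if (backbone_only) {
    sel <- atom_selection(atom_names = backbone_atoms)
    ridx <- select_atoms(ref, sel)
    ref$atoms <- ref$atoms[ridx, , drop = FALSE]
  }
  m <- match_selection(topo, ref, atom_selection())
  ref_xyz <- coords(ref)[m$ref, , drop = FALSE]
  frames <- unlist(lapply(ensembles, function(e)
    lapply(e$frames, function(fr) fr[m$topo, , drop = FALSE])),
    recursive = FALSE)
  nfr <- length(frames)
  if (nfr < 2) stop("rank error: need at least 2 frames to fit a PC model")
  fitted <- superpose_frames_to(frames, ref_xyz)
  X <- t(vapply(fitted, function(fr) as.vector(t(fr)), numeric(3 * nrow(ref_xyz))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  p <- ncol(Xc)
  if (p <= 4000) {
    C <- crossprod(Xc) / nfr
    eg <- eigen(C, symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    vecs <- eg$vectors
  } else {
    sv <- svd(Xc, nu = 0, nv = min(max_modes, min(dim(Xc))))
    vals <- (sv$d^2 / nfr)[seq_len(ncol(sv$v))]
    vecs <- sv$v
  }
  vecs <- fix_sign(vecs)
  topo2 <- topo
  topo2$atoms <- topo$atoms[m$topo, , drop = FALSE]
  rownames(topo2$atoms) <- NULL
  structure(list(mean_coords = matrix(mu, ncol = 3, byrow = TRUE),
                 eigenvectors = vecs, eigenvalues = vals,
                 topology = topo2, reference = ref_xyz,
                 n_frames_fit = nfr),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  cat(sprintf("<pc_model> %d atoms, %d modes; leading eigenvalues (A^2): %s\n",
              nrow(x$mean_coords), length(x$eigenvalues),
              paste(sprintf("%.3g", x$eigenvalues[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

align_to_model <- function(ensemble, model, backbone_only = TRUE,
                           backbone_atoms = BACKBONE_ATOMS) {
  if (backbone_only) ensemble <- reduce_backbone(ensemble, backbone_atoms)
  m <- match_selection(ensemble$topology, model$topology, atom_selection())
  if (length(m$topo) != nrow(model$mean_coords))
    stop("topology error: ensemble does not map onto the model atoms")
  ord <- order(m$ref)
  idx <- m$topo[ord]
  lapply(ensemble$frames, function(fr) {
    fr <- fr[idx, , drop = FALSE]
    sup <- kabsch_superpose(fr, model$reference)
    apply_superposition(sup, fr)
  })
}

#' Project an ensemble onto a principal component
#'
#' Frames are superposed to the model's reference exactly as during
#' fitting, then `projection = (frame - mean) . eigenvector` (angstrom).
#'
#' @param ensemble a `kin_ensemble`.
#' @param model a `pc_model`.
#' @param component component index (1-based).
#' @param system label recorded in the result.
#' @param backbone_only,backbone_atoms as in [fit_pc_model()].
#' @return a `projection_series`: list(system, component, values,
#'   frame_times).
#' @export
project <- function(ensemble, model, component = 1, system = "system",
                    backbone_only = TRUE, backbone_atoms = BACKBONE_ATOMS) {
  stopifnot(inherits(model, "pc_model"))
  if (component < 1 || component > ncol(model$eigenvectors))
    stop("index error: component ", component, " out of range 1..",
         ncol(model$eigenvectors))
  fitted <- align_to_model(ensemble, model, backbone_only, backbone_atoms)
  mu <- as.vector(t(model$mean_coords))
  v <- model$eigenvectors[, component]
  vals <- vapply(fitted, function(fr) sum((as.vector(t(fr)) - mu) * v),
                 numeric(1))
  structure(list(system = system, component = component, values = vals,
                 frame_times = ensemble$frame_times),
            class = "projection_series")
}

#' Histogram a projection series
#'
#' Bins are centred on integer multiples of `bin_width`, giving a symmetric
#' axis about 0 that covers all observed values; counts always sum to the
#' frame count.
#'
#' @param series a `projection_series` (or bare numeric vector).
#' @param bin_width bin width in angstrom.
#' @return list(edges, centers, counts).
#' @export
histogram_projections <- function(series, bin_width) {
  if (inherits(series, "projection_series")) series <- series$values
  if (length(series) == 0) stop("empty projection series")
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("parameter error: bin_width must be > 0")
  k <- round(series / bin_width)
  kmax <- max(abs(k))
  centers <- (-kmax:kmax) * bin_width
  counts <- as.integer(table(factor(k, levels = -kmax:kmax)))
  edges <- c(centers - bin_width / 2, centers[length(centers)] + bin_width / 2)
  list(edges = edges, centers = centers, counts = counts)
}

#' Structures at the two endpoints of a mode
#'
#' Returns the mean structure displaced by plus/minus `amplitude` along the
#' chosen eigenvector; the midpoint of the pair is exactly the mean
#' structure.
#'
#' @param model a `pc_model`.
#' @param component component index.
#' @param amplitude displacement in angstrom along the (unit) eigenvector.
#' @return list(minus, plus): two `kin_structure` objects.
#' @export
mode_endpoints <- function(model, component = 1, amplitude = 80) {
  stopifnot(inherits(model, "pc_model"))
  if (component < 1 || component > ncol(model$eigenvectors))
    stop("index error: component out of range")
  v <- matrix(model$eigenvectors[, component], ncol = 3, byrow = TRUE)
  mk <- function(sign_) {
    s <- set_coords(model$topology, model$mean_coords + sign_ * amplitude * v)
    s$id <- sprintf("PC%d=%+g", component, sign_ * amplitude)
    s
  }
  list(minus = mk(-1), plus = mk(1))
}

#' Serialize a PC model to a plain-text file
#'
#' Documented whitespace-separated container: header line with counts, then
#' eigenvalues, mean coordinates, and eigenvector columns.
#' @param model a `pc_model`.
#' @param path output path.
#' @export
write_pc_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  k <- ncol(model$eigenvectors)
  writeLines(sprintf("pc_model %d %d %d", nrow(model$mean_coords), k,
                     model$n_frames_fit), con)
  writeLines(paste(sprintf("%.10g", model$eigenvalues[seq_len(k)]),
                   collapse = " "), con)
  utils::write.table(model$mean_coords, con, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(model$eigenvectors, con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
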