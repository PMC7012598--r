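## Core containers: Structure, Ensemble, AtomSelection.
##
## A Structure holds an atom table in author numbering (CK1delta DeltaC is
## numbered 1-317 by its authors; all residue references such as L152, L173,
## Y225, 168-175 and 213-224 use those numbers and are never renumbered).
## An Ensemble is an ordered list of coordinate frames over one fixed
## topology, e.g. snapshots extracted from an MD trajectory.

ATOM_COLS <- c("serial", "name", "element", "res_name", "res_seq",
               "chain", "altloc", "occupancy", "x", "y", "z")

#' Standard amino-acid residue names
#'
#' The 20 canonical three-letter codes used by [strip_nonprotein()].
#' @export
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Default backbone atom names
#'
#' Four-atom heavy backbone (N, CA, C, O) used throughout for RMSD and PCA;
#' pass `c("N","CA","C")` where the carbonyl oxygen should be excluded.
#' @export
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Create a Structure
#'
#' @param id character identifier (e.g. a PDB accession).
#' @param atoms data.frame with columns serial, name, element, res_name,
#'   res_seq, chain, altloc, occupancy, x, y, z.
#' @param source_format "PDB" or "mmCIF".
#' @return An object of class `kin_structure`.
#' @export
new_structure <- function(id, atoms, source_format = "PDB") {
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(ATOM_COLS, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, ATOM_COLS]
  atoms$res_seq <- as.integer(atoms$res_seq)
  atoms$serial <- as.integer(atoms$serial)
  for (col in c("name", "element", "res_name", "chain", "altloc"))
    atoms[[col]] <- as.character(atoms[[col]])
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atoms table")
  if (any(!is.finite(atoms$occupancy) | atoms$occupancy < 0 |
          atoms$occupancy > 1))
    stop("occupancy values must lie in [0,1]")
  key <- paste(atoms$chain, atoms$res_seq, atoms$name, atoms$altloc)
  if (anyDuplicated(key))
    stop("duplicate (chain, res_seq, name, altloc) atom records: ",
         key[duplicated(key)][1])
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, source_format = source_format),
            class = "kin_structure")
}

#' @export
print.kin_structure <- function(x, ...) {
  cat(sprintf("<kin_structure> id=%s  %d atoms, %d residues, chains: %s\n",
              x$id, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$res_seq))),
              paste(sort(unique(x$atoms$chain)), collapse = ",")))
  invisible(x)
}

#' Coordinates of a Structure as an N x 3 matrix
#' @param x a `kin_structure`.
#' @return numeric matrix with columns x, y, z (angstrom).
#' @export
coords <- function(x) {
  stopifnot(inherits(x, "kin_structure"))
  as.matrix(x$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a Structure
#' @param x a `kin_structure`.
#' @param xyz N x 3 matrix.
#' @return the modified structure.
#' @export
set_coords <- function(x, xyz) {
  stopifnot(inherits(x, "kin_structure"))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(x$atoms) || ncol(xyz) != 3)
    stop("coordinate matrix must be ", nrow(x$atoms), " x 3")
  x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
  x
}

#' Create an Ensemble over a fixed topology
#'
#' @param topology a `kin_structure` giving atom identities.
#' @param frames list of N x 3 coordinate matrices, one per frame.
#' @param frame_times optional numeric vector of times (ns), strictly
#'   increasing.
#' @return An object of class `kin_ensemble`.
#' @export
new_ensemble <- function(topology, frames, frame_times = NULL) {
  stopifnot(inherits(topology, "kin_structure"), is.list(frames))
  n <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    fr <- as.matrix(frames[[i]])
    if (nrow(fr) != n || ncol(fr) != 3)
      stop("frame ", i, " has ", nrow(fr), " coordinates; topology has ",
           n, " atoms")
    frames[[i]] <- fr
  }
  if (!is.null(frame_times)) {
    if (length(frame_times) != length(frames))
      stop("frame_times length must equal frame count")
    if (any(diff(frame_times) <= 0))
      stop("frame_times must be strictly increasing")
  }
  structure(list(topology = topology, frames = frames,
                 frame_times = frame_times),
            class = "kin_ensemble")
}

#' @export
print.kin_ensemble <- function(x, ...) {
  cat(sprintf("<kin_ensemble> %d frames x %d atoms (topology id=%s)\n",
              length(x$frames), nrow(x$topology$atoms), x$topology$id))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `kin_ensemble`.
#' @export
n_frames <- function(ensemble) length(ensemble$frames)

#' Extract one frame of an ensemble as a Structure
#' @param ensemble a `kin_ensemble`.
#' @param i frame index.
#' @export
frame_structure <- function(ensemble, i) {
  stopifnot(i >= 1, i <= n_frames(ensemble))
  s <- set_coords(ensemble$topology, ensemble$frames[[i]])
  s$id <- sprintf("%s/frame%d", ensemble$topology$id, i)
  s
}

#' Define an atom selection
#'
#' Selections are expressed in author residue numbering; all criteria are
#' optional and combined with AND.
#'
#' @param chain chain identifier, or NULL for any chain.
#' @param res_range inclusive `c(start, end)` residue range, or NULL.
#' @param atom_names character vector of atom names, or NULL for any name.
#' @return An object of class `atom_selection`.
#' @export
atom_selection <- function(chain = NULL, res_range = NULL, atom_names = NULL) {
  if (!is.null(res_range)) {
    stopifnot(length(res_range) == 2)
    if (res_range[1] > res_range[2]) stop("res_range start exceeds end")
  }
  structure(list(chain = chain, res_range = res_range,
                 atom_names = atom_names),
            class = "atom_selection")
}

#' Resolve a selection to atom indices
#'
#' @param x a `kin_structure` or `kin_ensemble` (topology is used).
#' @param selection an [atom_selection()].
#' @return integer vector of atom indices in topology order (possibly empty).
#' @export
select_atoms <- function(x, selection) {
  if (inherits(x, "kin_ensemble")) x <- x$topology
  stopifnot(inherits(x, "kin_structure"),
            inherits(selection, "atom_selection"))
  at <- x$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(selection$chain)) keep <- keep & at$chain %in% selection$chain
  if (!is.null(selection$res_range))
    keep <- keep & at$res_seq >= selection$res_range[1] &
      at$res_seq <= selection$res_range[2]
  if (!is.null(selection$atom_names))
    keep <- keep & at$name %in% selection$atom_names
  which(keep)
}

#' Remove non-protein components from a structure or ensemble
#'
#' Drops every atom whose residue name is not one of the 20 standard amino
#' acids: waters, counter-ions, sulfate anions and other heteroatoms are all
#' removed. Idempotent; ensemble frames are reduced consistently with the
#' topology.
#'
#' @param x a `kin_structure` or `kin_ensemble`.
#' @param keep_residues residue names treated as protein (default [AA3]).
#' @return object of the same class containing protein atoms only.
#' @export
strip_nonprotein <- function(x, keep_residues = AA3) {
  if (inherits(x, "kin_structure")) {
    keep <- x$atoms$res_name %in% keep_residues
    x$atoms <- x$atoms[keep, , drop = FALSE]
    rownames(x$atoms) <- NULL
    return(x)
  }
  if (inherits(x, "kin_ensemble")) {
    keep <- x$topology$atoms$res_name %in% keep_residues
    x$topology$atoms <- x$topology$atoms[keep, , drop = FALSE]
    rownames(x$topology$atoms) <- NULL
    x$frames <- lapply(x$frames, function(fr) fr[keep, , drop = FALSE])
    return(x)
  }
  stop("strip_nonprotein expects a kin_structure or kin_ensemble")
}

## element guess from a PDB atom name ("CD2" -> C, "OH" -> O, "1HB" -> H)
guess_element <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[0-9']", "", nm)
    if (nchar(nm) == 0) return("X")
    # two-letter elements that occur in protein work
    two <- toupper(substr(nm, 1, 2))
    if (two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "SE"))
      return(substr(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))), 1, 2))
    toupper(substr(nm, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}
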