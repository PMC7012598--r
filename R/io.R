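## Structure, ensemble and grid-map I/O.
##
## Parsing of PDB v3.3 and mmCIF is delegated to bio3d; writing uses a small
## fixed-format PDB emitter so that multi-model ensembles round-trip exactly.
## Grid maps are serialized as OpenDX scalar fields (readable by PyMOL/VMD).

#' Read a structure from PDB or mmCIF
#'
#' All ATOM and HETATM records are captured (waters/ions are retained;
#' removal is a separate, explicit step via [strip_nonprotein()]).
#' Alternate locations are resolved to a single conformer per atom: the
#' highest-occupancy altloc is kept, ties go to altloc "A" (alphabetically
#' first). mmCIF chains use the author asym id, matching the chain A/B
#' language used for crystal structures such as 1CKJ and 6PXN.
#'
#' @param path file path.
#' @param format "PDB", "mmCIF" or "auto" (by extension: .cif/.mmcif is
#'   mmCIF, anything else PDB).
#' @return a `kin_structure`.
#' @export
read_structure <- function(path, format = c("auto", "PDB", "mmCIF")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmCIF" else "PDB"
  }
  pdb <- tryCatch(
    if (format == "mmCIF") bio3d::read.cif(path, rm.alt = FALSE,
                                           verbose = FALSE)
    else suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                          verbose = FALSE)),
    error = function(e)
      stop("failed to parse ", path, " as ", format, ": ",
           conditionMessage(e)))
  atoms <- bio3d_to_atoms(pdb$atom)
  atoms <- resolve_altlocs(atoms)
  new_structure(id = tools::file_path_sans_ext(basename(path)),
                atoms = atoms, source_format = format)
}

bio3d_to_atoms <- function(at) {
  element <- at$elesy
  if (is.null(element)) element <- NA_character_
  element <- ifelse(is.na(element) | element == "",
                    guess_element(at$elety), toupper(element))
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  occ <- pmin(pmax(occ, 0), 1)
  chain <- at$chain
  chain[is.na(chain)] <- ""
  data.frame(serial = at$eleno, name = at$elety, element = element,
             res_name = at$resid, res_seq = at$resno, chain = chain,
             altloc = alt, occupancy = occ,
             x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
}

## keep one conformer per (chain, res_seq, name): highest occupancy,
## ties broken by alphabetical altloc (so "A" wins a tie)
resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$res_seq, atoms$name, sep = "\r")
  if (!anyDuplicated(key)) {
    atoms$altloc <- ""
    return(atoms)
  }
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  keep_first <- !duplicated(key[ord])
  sel <- sort(ord[keep_first])
  atoms <- atoms[sel, , drop = FALSE]
  atoms$altloc <- ""
  rownames(atoms) <- NULL
  atoms
}

pdb_atom_record <- function(a) {
  # PDB v3.3 fixed columns; atom names of <4 chars start in column 14
  nm <- a$name
  nm <- ifelse(nchar(nm) < 4, paste0(" ", nm), nm)
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$serial %% 100000L, nm, "", a$res_name,
          substr(ifelse(a$chain == "", " ", a$chain), 1, 1),
          a$res_seq, "", a$x, a$y, a$z, a$occupancy, 0,
          substr(a$element, 1, 2))
}

#' Write a structure as a PDB file
#'
#' @param structure a `kin_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "kin_structure"))
  lines <- c(pdb_atom_record(structure$atoms), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble a `kin_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "kin_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  at <- ensemble$topology$atoms
  for (i in seq_len(n_frames(ensemble))) {
    fr <- ensemble$frames[[i]]
    at$x <- fr[, 1]; at$y <- fr[, 2]; at$z <- fr[, 3]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(pdb_atom_record(at), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

topology_signature <- function(atoms)
  paste(atoms$chain, atoms$res_seq, atoms$res_name, atoms$name, sep = "|")

#' Read an ensemble from per-frame files or one multi-model PDB
#'
#' All frames must share one topology (same atom count and identities);
#' the first mismatching atom is reported otherwise.
#'
#' @param paths character vector: either a single multi-model PDB file or
#'   several single-model structure files, one per frame (order preserved).
#' @param frame_times optional strictly increasing times (ns).
#' @return a `kin_ensemble`.
#' @export
read_ensemble <- function(paths, frame_times = NULL) {
  stopifnot(length(paths) >= 1)
  if (length(paths) == 1) {
    pdb <- suppressWarnings(bio3d::read.pdb(paths, multi = TRUE,
                                            rm.alt = FALSE,
                                            verbose = FALSE))
    atoms <- resolve_altlocs(bio3d_to_atoms(pdb$atom))
    topology <- new_structure(tools::file_path_sans_ext(basename(paths)),
                              atoms, "PDB")
    nf <- nrow(pdb$xyz)
    frames <- lapply(seq_len(nf), function(i)
      matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE))
    # altloc resolution may have dropped atoms; keep matching columns
    if (ncol(pdb$xyz) != 3 * nrow(atoms)) {
      keep <- match(atoms$serial, pdb$atom$eleno)
      frames <- lapply(frames, function(fr) fr[keep, , drop = FALSE])
    }
    return(new_ensemble(topology, frames, frame_times))
  }
  structs <- lapply(paths, read_structure)
  sig0 <- topology_signature(structs[[1]]$atoms)
  for (i in seq_along(structs)[-1]) {
    sig <- topology_signature(structs[[i]]$atoms)
    if (length(sig) != length(sig0)) {
      stop("topology mismatch: frame ", i, " has ", length(sig),
           " atoms; frame 1 has ", length(sig0))
    }
    bad <- which(sig != sig0)
    if (length(bad))
      stop("topology mismatch at atom ", bad[1], ": frame 1 has '",
           sig0[bad[1]], "', frame ", i, " has '", sig[bad[1]], "'")
  }
  new_ensemble(structs[[1]], lapply(structs, coords), frame_times)
}

## ---- OpenDX scalar grid I/O -------------------------------------------

#' Write a grid map in OpenDX format
#'
#' Values are written on the full regular grid in the standard DX ordering
#' (z varies fastest); points outside the map's sphere-union mask are
#' written as 0. In-mask values must be open fractions in [0,1].
#'
#' @param map a `grid_map` (see [build_grid()]).
#' @param path output path (conventionally .dx).
#' @return `path`, invisibly.
#' @export
write_grid_map <- function(map, path) {
  stopifnot(inherits(map, "grid_map"))
  vals <- map$values
  vals[!map$mask] <- 0
  inmask <- map$values[map$mask]
  if (length(inmask) && any(inmask < 0 | inmask > 1, na.rm = TRUE))
    stop("grid map values must lie in [0,1]")
  vals[is.na(vals)] <- 0
  d <- map$dims
  flat <- as.vector(aperm(vals, c(3, 2, 1)))  # z fastest
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6g %.6g %.6g", map$origin[1], map$origin[2],
            map$origin[3]),
    sprintf("delta %.6g 0 0", map$spacing),
    sprintf("delta 0 %.6g 0", map$spacing),
    sprintf("delta 0 0 %.6g", map$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(flat))), con)
  # three values per line, 6 significant figures preserved
  n <- length(flat)
  idx <- seq(1, n, by = 3)
  lines <- vapply(idx, function(i)
    paste(sprintf("%.6g", flat[i:min(i + 2, n)]), collapse = " "),
    character(1))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX grid map
#'
#' Returns a `grid_map` whose mask is all-true (the sphere-union mask is not
#' part of the DX format); values are as stored.
#'
#' @param path path to a .dx file written by [write_grid_map()] (or any
#'   axis-aligned scalar DX field with uniform spacing).
#' @return a `grid_map`.
#' @export
read_grid_map <- function(path) {
  lines <- readLines(path)
  g1 <- grep("gridpositions counts", lines, value = TRUE)[1]
  dims <- as.integer(strsplit(sub(".*counts +", "", g1), " +")[[1]])
  og <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(sub("^origin +", "", og), " +")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dmat <- t(vapply(deltas, function(l)
    as.numeric(strsplit(sub("^delta +", "", l), " +")[[1]]),
    numeric(3)))
  spacing <- max(dmat)
  start <- grep("data follows", lines)[1] + 1
  end <- grep('^attribute|^object "', lines)
  end <- min(end[end >= start]) - 1
  flat <- as.numeric(unlist(strsplit(trimws(lines[start:end]), " +")))
  if (length(flat) != prod(dims))
    stop("DX data block has ", length(flat), " values; expected ",
         prod(dims))
  vals <- aperm(array(flat, dim = rev(dims)), c(3, 2, 1))
  new_grid_map(origin = origin, spacing = spacing, dims = dims,
               values = vals, mask = array(TRUE, dim = dims))
}
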