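## Integration helpers for deposited crystal structures.
##
## The deposited accessions relevant to the activation-loop switch are
## 1CKJ (wild type; loop up in chain A, down in chain B) and 6PXN (tau;
## same chain assignment), plus 6PXO/6PXP and 5X17. Coordinate files are
## not bundled with the package: drop PDB/mmCIF files named
## `<accession>.pdb` or `<accession>.cif` into a directory and point
## `options(ck1switch.accession_dir = ...)` at it (the package also looks
## under its own `extdata/accessions`).

#' Locate a local coordinate file for an accession
#' @param accession PDB accession (e.g. "1CKJ").
#' @param dirs directories to search; defaults to
#'   `getOption("ck1switch.accession_dir")` and the package's
#'   `extdata/accessions`.
#' @return path to the file.
#' @export
locate_accession <- function(accession, dirs = NULL) {
  if (is.null(dirs))
    dirs <- c(getOption("ck1switch.accession_dir"),
              system.file("extdata", "accessions", package = "ck1switch"))
  dirs <- dirs[nzchar(dirs)]
  for (d in dirs) for (ext in c("pdb", "cif", "ent")) {
    for (acc in c(accession, tolower(accession), toupper(accession))) {
      p <- file.path(d, paste0(acc, ".", ext))
      if (file.exists(p)) return(p)
    }
  }
  stop("no local coordinate file for accession ", accession,
       "; place <accession>.pdb under options(ck1switch.accession_dir=...)",
       " or inst/extdata/accessions")
}

#' Classify activation-loop conformation per chain of an accession
#' @param accession PDB accession with a locally available file.
#' @param chains chains to classify (default A and B).
#' @param margin classification margin (angstrom).
#' @return named character vector of labels per chain.
#' @export
classify_accession_chains <- function(accession, chains = c("A", "B"),
                                      margin = 1.0) {
  s <- read_structure(locate_accession(accession))
  s$id <- accession
  vapply(chains, function(ch)
    classify_conformation(measure_switch_distances(s, ch),
                          margin = margin)$label,
    character(1))
}

#' Maximum pairwise backbone RMSD of a residue segment across chains
#'
#' Superposes the segment backbone of every chain pair (Kabsch) and
#' reports the largest pairwise RMSD, e.g. over residues 210-230 of the
#' four MD starting chains to check the loop L-EF starting-conformation
#' spread.
#'
#' @param structures list of `kin_structure` objects.
#' @param chains list (parallel to `structures`) of chain vectors.
#' @param res_range inclusive residue range, default `c(210, 230)`.
#' @param backbone_atoms backbone set (default N, CA, C, O).
#' @return list(max_rmsd, pairs: data.frame of all pairwise RMSDs).
#' @export
max_pairwise_segment_rmsd <- function(structures, chains,
                                      res_range = c(210, 230),
                                      backbone_atoms = BACKBONE_ATOMS) {
  stopifnot(length(structures) == length(chains))
  entries <- list()
  for (i in seq_along(structures)) for (ch in chains[[i]]) {
    sel <- atom_selection(chain = ch, res_range = res_range,
                          atom_names = backbone_atoms)
    idx <- select_atoms(structures[[i]], sel)
    at <- structures[[i]]$atoms[idx, , drop = FALSE]
    entries[[length(entries) + 1L]] <- list(
      id = paste0(structures[[i]]$id, ":", ch),
      key = paste(at$res_seq, at$name),
      xyz = as.matrix(at[, c("x", "y", "z")]))
  }
  if (length(entries) < 2) stop("need at least two chains")
  pairs <- list()
  for (a in seq_along(entries)[-1]) for (b in seq_len(a - 1)) {
    common <- intersect(entries[[a]]$key, entries[[b]]$key)
    xa <- entries[[a]]$xyz[match(common, entries[[a]]$key), , drop = FALSE]
    xb <- entries[[b]]$xyz[match(common, entries[[b]]$key), , drop = FALSE]
    sup <- kabsch_superpose(xa, xb)
    pairs[[length(pairs) + 1L]] <-
      data.frame(a = entries[[a]]$id, b = entries[[b]]$id,
                 n_atoms = length(common), rmsd_A = sup$rmsd)
  }
  pairs <- do.call(rbind, pairs)
  list(max_rmsd = max(pairs$rmsd_A), pairs = pairs)
}
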