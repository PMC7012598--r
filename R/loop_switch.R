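## Activation-loop conformational switch metric.
##
## The conformation of the CK1 activation loop is reported by the position
## of the L173 side chain: the distance from L173 CD2 to L152 CD2 is short
## in the "loop up" conformation and long in "loop down", while the distance
## from L173 CD2 to the Y225 hydroxyl behaves the opposite way. Measuring
## the two distances therefore separates the two states without any
## reference structure, and the same probe mapping can be re-targeted to
## equivalent positions in CK1 family homologs.

#' Default switch probe atoms (CK1delta author numbering)
#'
#' `probe` is the mobile reporter atom; `anchor_up` is close to the probe in
#' the "loop up" conformation, `anchor_down` is close in "loop down".
#' @export
DEFAULT_SWITCH_PROBES <- list(
  probe = list(res_seq = 173L, atom_name = "CD2"),
  anchor_up = list(res_seq = 152L, atom_name = "CD2"),
  anchor_down = list(res_seq = 225L, atom_name = "OH"))

find_probe_atom <- function(atoms, chain, res_seq, atom_name) {
  i <- which(atoms$chain == chain & atoms$res_seq == res_seq &
               atoms$name == atom_name)
  if (length(i) == 0)
    stop("switch measurement: atom ", atom_name, " of residue ", res_seq,
         " not found in chain ", chain)
  i[1]
}

#' Measure the two activation-loop switch distances
#'
#' Euclidean distances (angstrom) from the probe atom (default L173 CD2) to
#' the "up" anchor (L152 CD2) and to the "down" anchor (Y225 OH).
#'
#' @param structure a `kin_structure`.
#' @param chain chain identifier.
#' @param probe_residues probe mapping as in [DEFAULT_SWITCH_PROBES]
#'   (override for homologs with equivalent positions).
#' @param frame optional frame index recorded in the result.
#' @return a `switch_measurement`: list with source_id, chain, frame,
#'   d_L152, d_Y225 (angstrom) and label (unset, `NA`).
#' @export
measure_switch_distances <- function(structure, chain,
                                     probe_residues = DEFAULT_SWITCH_PROBES,
                                     frame = NA_integer_) {
  stopifnot(inherits(structure, "kin_structure"))
  at <- structure$atoms
  ip <- find_probe_atom(at, chain, probe_residues$probe$res_seq,
                        probe_residues$probe$atom_name)
  iu <- find_probe_atom(at, chain, probe_residues$anchor_up$res_seq,
                        probe_residues$anchor_up$atom_name)
  id <- find_probe_atom(at, chain, probe_residues$anchor_down$res_seq,
                        probe_residues$anchor_down$atom_name)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d_up <- sqrt(sum((xyz[ip, ] - xyz[iu, ])^2))
  d_down <- sqrt(sum((xyz[ip, ] - xyz[id, ])^2))
  structure(list(source_id = structure$id, chain = chain, frame = frame,
                 d_L152 = d_up, d_Y225 = d_down, label = NA_character_),
            class = "switch_measurement")
}

#' Classify a switch measurement as loop up / loop down
#'
#' Relative rule with an indeterminate margin: "up" if
#' `d_L152 < d_Y225 - margin`, "down" if `d_Y225 < d_L152 - margin`,
#' otherwise "indeterminate". A relative comparison (rather than absolute
#' distance cutoffs) transfers across homologs, where absolute distances
#' shift but the two conformational clusters remain separated.
#'
#' @param m a `switch_measurement`.
#' @param margin indeterminate margin in angstrom (default 1.0).
#' @return the measurement with `label` set.
#' @export
classify_conformation <- function(m, margin = 1.0) {
  stopifnot(inherits(m, "switch_measurement"))
  if (!is.finite(m$d_L152) || !is.finite(m$d_Y225))
    stop("distances must be set before classification")
  m$label <- if (m$d_L152 < m$d_Y225 - margin) "up"
    else if (m$d_Y225 < m$d_L152 - margin) "down"
    else "indeterminate"
  m
}

#' Survey switch conformations across structures or an ensemble
#'
#' One row per chain (crystal-structure input) or per frame (ensemble
#' input). Chains or frames missing any probe atom are skipped with a
#' warning and collected in the survey's skip list rather than silently
#' dropped, since disordered loops are common in crystal structures.
#'
#' @param x either a list of `kin_structure` objects (or a single one), or a
#'   `kin_ensemble`.
#' @param chains optional chain specification: NULL (all chains present),
#'   a character vector applied to every structure, or a list parallel to
#'   the structures.
#' @param margin classification margin (angstrom).
#' @param probe_residues probe mapping (see [DEFAULT_SWITCH_PROBES]).
#' @return a `switch_survey`: list with `rows` (data.frame source_id, chain,
#'   frame, d_L152_A, d_Y225_A, label), `counts` (named up/down/
#'   indeterminate), and `skipped` (data.frame source_id, chain, frame,
#'   reason).
#' @export
survey_ensemble <- function(x, chains = NULL, margin = 1.0,
                            probe_residues = DEFAULT_SWITCH_PROBES) {
  jobs <- list()  # list of (structure, chain, frame)
  if (inherits(x, "kin_ensemble")) {
    ch <- if (is.null(chains)) unique(x$topology$atoms$chain) else chains
    for (i in seq_len(n_frames(x))) {
      s <- frame_structure(x, i)
      s$id <- x$topology$id
      for (c1 in ch) jobs[[length(jobs) + 1L]] <- list(s, c1, i)
    }
  } else {
    if (inherits(x, "kin_structure")) x <- list(x)
    stopifnot(is.list(x), length(x) >= 1)
    for (k in seq_along(x)) {
      s <- x[[k]]
      ch <- if (is.null(chains)) unique(s$atoms$chain)
        else if (is.list(chains)) chains[[k]] else chains
      for (c1 in ch) jobs[[length(jobs) + 1L]] <- list(s, c1, NA_integer_)
    }
  }
  if (length(jobs) == 0) stop("survey_ensemble: no input chains")
  rows <- list(); skipped <- list()
  for (j in jobs) {
    m <- tryCatch(
      classify_conformation(
        measure_switch_distances(j[[1]], j[[2]], probe_residues,
                                 frame = j[[3]]),
        margin = margin),
      error = function(e) e)
    if (inherits(m, "error")) {
      warning("skipping ", j[[1]]$id, " chain ", j[[2]], ": ",
              conditionMessage(m), call. = FALSE)
      skipped[[length(skipped) + 1L]] <-
        data.frame(source_id = j[[1]]$id, chain = j[[2]], frame = j[[3]],
                   reason = conditionMessage(m), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(source_id = m$source_id, chain = m$chain, frame = m$frame,
                   d_L152_A = m$d_L152, d_Y225_A = m$d_Y225, label = m$label,
                   stringsAsFactors = FALSE)
    }
  }
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_id = character(), chain = character(),
               frame = integer(), d_L152_A = numeric(),
               d_Y225_A = numeric(), label = character())
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(source_id = character(), chain = character(),
               frame = integer(), reason = character())
  counts <- c(up = sum(rows$label == "up"),
              down = sum(rows$label == "down"),
              indeterminate = sum(rows$label == "indeterminate"))
  structure(list(rows = rows, counts = counts, skipped = skipped),
            class = "switch_survey")
}

#' @export
print.switch_survey <- function(x, ...) {
  cat(sprintf("<switch_survey> %d measurements (up: %d, down: %d, indeterminate: %d), %d skipped\n",
              nrow(x$rows), x$counts["up"], x$counts["down"],
              x$counts["indeterminate"], nrow(x$skipped)))
  invisible(x)
}

#' Write a switch survey scatter table to CSV
#'
#' Columns: source_id, chain, frame, d_L152_A, d_Y225_A, label.
#' @param survey a `switch_survey`.
#' @param path output CSV path.
#' @export
write_survey_csv <- function(survey, path) {
  stopifnot(inherits(survey, "switch_survey"))
  utils::write.csv(survey$rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
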