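## Reference-anchored conservation of a residue patch across an alignment.
##
## Identity is anchored on the reference sequence (e.g. human CK1delta):
## for each patch position, the percentage of aligned sequences carrying
## the reference residue in that column. Gaps count as mismatches, which
## is the conservative choice for a conservation claim.

#' Read a FASTA multiple sequence alignment
#' @param path FASTA file of aligned, equal-length sequences.
#' @return named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  out <- as.character(aln)
  names(out) <- sub(" .*", "", names(aln))
  out
}

#' Percent identity of an alignment patch, anchored on a reference
#'
#' Patch positions are given in ungapped reference coordinates (author
#' numbering offset by `ref_offset` if the reference sequence does not
#' start at author position 1) and mapped through the reference row's gaps
#' to alignment columns. Per position, identity is
#' `100 * matches / n_sequences` where a match means the aligned residue
#' equals the reference residue; gaps are mismatches. The reference row is
#' included in the count.
#'
#' @param alignment named character vector of aligned sequences (or the
#'   result of [read_alignment()]).
#' @param reference_id name of the reference sequence.
#' @param patch_positions integer vector of reference positions.
#' @param ref_offset author number of the first reference residue minus 1
#'   (default 0: position 1 is residue 1).
#' @return an `alignment_patch`: list(per_position data.frame(position,
#'   column, ref_residue, identity), min_identity, mean_identity,
#'   n_sequences).
#' @export
patch_identity <- function(alignment, reference_id, patch_positions,
                           ref_offset = 0) {
  stopifnot(is.character(alignment), length(alignment) >= 1)
  if (!reference_id %in% names(alignment))
    stop("reference sequence '", reference_id, "' not in alignment")
  lens <- unique(nchar(alignment))
  if (length(lens) != 1)
    stop("sequences are not aligned (unequal lengths)")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(mat) <- names(alignment)
  ref <- mat[reference_id, ]
  is_res <- !(ref %in% c("-", "."))
  ungapped_pos <- cumsum(is_res) + ref_offset
  cols <- vapply(patch_positions, function(p) {
    i <- which(is_res & ungapped_pos == p)
    if (length(i) != 1)
      stop("coordinate error: position ", p,
           " outside the ungapped reference sequence")
    i
  }, integer(1))
  n <- nrow(mat)
  per <- vapply(cols, function(cc)
    100 * sum(mat[, cc] == ref[cc]) / n, numeric(1))
  tab <- data.frame(position = patch_positions, column = cols,
                    ref_residue = ref[cols], identity = per,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(per_position = tab, min_identity = min(per),
                 mean_identity = mean(per), n_sequences = n),
            class = "alignment_patch")
}

#' @export
print.alignment_patch <- function(x, ...) {
  cat(sprintf("<alignment_patch> %d positions over %d sequences; identity min %.1f%%, mean %.1f%%\n",
              nrow(x$per_position), x$n_sequences, x$min_identity,
              x$mean_identity))
  invisible(x)
}

#' Write per-position identity to CSV
#' @param patch an `alignment_patch`.
#' @param path output CSV path.
#' @export
write_identity_csv <- function(patch, path) {
  utils::write.csv(patch$per_position, path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
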