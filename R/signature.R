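# Active-site signature extraction.
#
# A signature is the set of contiguous sequence fragments whose residues'
# centres of geometry lie within a fixed radius (default 10 Angstrom) of the
# centre of geometry of any key catalytic residue.

#' Select the active-site microenvironment of a structure
#'
#' A residue belongs to the microenvironment when the Euclidean distance
#' between its centre of geometry and the centre of geometry of at least one
#' key residue is less than or equal to `radius` (inclusive). Key residues
#' are always included (distance zero to themselves).
#'
#' @param structure A `dasp_structure` from [read_structure()].
#' @param key_refs Character vector of author residue numbers identifying the
#'   key residues (typically three).
#' @param chain Chain identifier (optional for single-chain structures).
#' @param radius Selection radius in Angstrom (default 10).
#' @param heavy_only Use heavy atoms only for centres of geometry.
#' @return Sorted integer vector of 0-based sequence positions.
#' @export
select_microenvironment <- function(structure, key_refs, chain = NULL,
                                    radius = 10, heavy_only = TRUE) {
  if (!is.numeric(radius) || radius <= 0) abort("`radius` must be positive.")
  ch <- pick_chain(structure, chain)
  key_pos <- resolve_residues(structure, key_refs, chain = ch)
  centers <- residue_centers(structure, heavy_only = heavy_only)
  centers <- centers[centers$chain == ch, , drop = FALSE]
  centers <- centers[order(centers$seq_position), , drop = FALSE]
  xyz <- as.matrix(centers[, c("cog_x", "cog_y", "cog_z")])
  key_xyz <- xyz[match(key_pos, centers$seq_position), , drop = FALSE]
  within <- rep(FALSE, nrow(xyz))
  for (k in seq_len(nrow(key_xyz))) {
    d2 <- (xyz[, 1] - key_xyz[k, 1])^2 +
      (xyz[, 2] - key_xyz[k, 2])^2 +
      (xyz[, 3] - key_xyz[k, 3])^2
    within <- within | d2 <= radius^2
  }
  within[match(key_pos, centers$seq_position)] <- TRUE
  sort(centers$seq_position[within])
}

#' Group microenvironment positions into signature fragments
#'
#' Fragments are maximal runs of consecutive sequence positions. Each
#' fragment carrying at least one key residue is flagged as a key-residue
#' fragment.
#'
#' @param structure A `dasp_structure`.
#' @param positions Integer vector of 0-based sequence positions (e.g. from
#'   [select_microenvironment()]).
#' @param key_positions Integer vector of 0-based key-residue positions.
#' @param chain Chain identifier (optional for single-chain structures).
#' @param protein_id Identifier recorded in the fragment table.
#' @return Tibble with one row per fragment: `protein_id`, `chain`, `start`,
#'   `end` (0-based half-open interval), `residues`, `contains_key`.
#' @export
build_signature <- function(structure, positions, key_positions,
                            chain = NULL, protein_id = "protein") {
  if (length(positions) == 0L) abort("Empty position set: no signature.")
  ch <- pick_chain(structure, chain)
  seqstr <- chain_sequence(structure, ch)
  positions <- sort(unique(as.integer(positions)))
  if (any(positions < 0L) || any(positions >= nchar(seqstr))) {
    abort("Positions outside the chain sequence.")
  }
  run_id <- cumsum(c(1L, diff(positions) != 1L))
  frags <- lapply(split(positions, run_id), function(p) {
    tibble(
      protein_id = protein_id, chain = ch,
      start = p[1], end = p[length(p)] + 1L,
      residues = substr(seqstr, p[1] + 1L, p[length(p)] + 1L),
      contains_key = any(key_positions %in% p)
    )
  })
  bind_rows(frags)
}

#' Remove fragments shorter than a minimum length
#'
#' Fragments of three residues or fewer are excluded by default (the
#' DASP3 rule); the legacy behaviour of earlier versions corresponds to
#' `min_len = 3` (ignoring only length-1 and length-2 fragments). A warning
#' is raised when a key-residue fragment is removed.
#'
#' @param signature Fragment tibble from [build_signature()] (may hold
#'   several proteins).
#' @param min_len Minimum fragment length retained (default 4).
#' @return The filtered fragment tibble, order preserved.
#' @export
filter_short_fragments <- function(signature, min_len = 4L) {
  if (min_len < 1L) abort("`min_len` must be >= 1.")
  len <- signature$end - signature$start
  drop <- len < min_len
  if (any(drop & signature$contains_key)) {
    warn(paste0(
      "Removed key-residue fragment(s) shorter than ", min_len, " residues: ",
      paste(unique(signature$protein_id[drop & signature$contains_key]),
            collapse = ", ")
    ))
  }
  out <- signature[!drop, , drop = FALSE]
  if (nrow(out) == 0L) abort("All fragments removed: no usable signature.")
  out
}

#' Extract a filtered active-site signature in one call
#'
#' Convenience wrapper: microenvironment selection, fragment grouping and
#' short-fragment filtering.
#'
#' @inheritParams select_microenvironment
#' @inheritParams build_signature
#' @param min_len Minimum fragment length (4 for DASP3, 3 for legacy);
#'   `NULL` skips filtering.
#' @return Fragment tibble (see [build_signature()]), with the radius stored
#'   in attribute `radius`.
#' @export
extract_signature <- function(structure, key_refs, chain = NULL,
                              protein_id = "protein", radius = 10,
                              min_len = 4L, heavy_only = TRUE) {
  ch <- pick_chain(structure, chain)
  pos <- select_microenvironment(structure, key_refs, chain = ch,
                                 radius = radius, heavy_only = heavy_only)
  key_pos <- resolve_residues(structure, key_refs, chain = ch)
  sig <- build_signature(structure, pos, key_pos, chain = ch,
                         protein_id = protein_id)
  if (!is.null(min_len)) sig <- filter_short_fragments(sig, min_len)
  attr(sig, "radius") <- radius
  sig
}

#' Write signatures to a FASTA-like file plus a TSV fragment index
#'
#' One FASTA-like record per protein, fragments joined with `sep`; the
#' sidecar TSV records `protein_id`, `frag_idx`, `start`, `end`,
#' `contains_key`.
#'
#' @param signatures Fragment tibble covering one or more proteins.
#' @param file Output path for the FASTA-like file.
#' @param index_file Output path for the TSV sidecar (default
#'   `paste0(file, ".idx.tsv")`).
#' @param sep Fragment separator in the FASTA-like records.
#' @return Invisibly, the two paths.
#' @export
write_signatures <- function(signatures, file,
                             index_file = paste0(file, ".idx.tsv"),
                             sep = "/") {
  ids <- unique(signatures$protein_id)
  lines <- unlist(lapply(ids, function(id) {
    fr <- signatures[signatures$protein_id == id, , drop = FALSE]
    fr <- fr[order(fr$start), , drop = FALSE]
    c(paste0(">", id), paste0(fr$residues, collapse = sep))
  }))
  writeLines(lines, file)
  idx <- signatures |>
    group_by(.data$protein_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(frag_idx = row_number()) |>
    ungroup() |>
    select("protein_id", "frag_idx", "start", "end", "contains_key")
  utils::write.table(idx, index_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(file, index_file))
}
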