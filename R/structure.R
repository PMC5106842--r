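# PDB parsing and residue-level geometry.
#
# Parsing itself is delegated to bio3d::read.pdb; this layer enforces the
# conventions the profiling pipeline relies on: first model only, one
# conformer per residue (highest occupancy, ties broken towards altloc 'A'),
# waters and unrecognised HETATM ligands dropped, modified residues mapped
# through a fixed table, and 0-based sequence positions per chain.

#' Parse a protein structure from a PDB file or PDB-format text
#'
#' Returns a residue table: one row per polymer residue, in chain/sequence
#' order, with the residue's atoms nested in a list column. Only the first
#' model of a multi-model file is read. For residues with alternate
#' locations, the conformer with the highest occupancy is kept (ties broken
#' towards altloc `"A"`). Waters and HETATM records other than recognised
#' modified residues are excluded. Non-standard residues get one-letter code
#' `"X"` (see [aa3_to_aa1()]).
#'
#' @param file Path to a PDB file, or a character scalar containing
#'   PDB-format text (detected by embedded newlines).
#' @param map_modified Map common modified residues (MSE etc.) to their
#'   parent one-letter code instead of `"X"`.
#' @return A tibble of class `dasp_structure` with columns `chain`,
#'   `seq_position` (0-based within chain), `author_number` (residue number
#'   plus insertion code, as text), `aa3`, `aa1`, and `atoms` (list of data
#'   frames with `name`, `element`, `x`, `y`, `z` in Angstrom).
#' @export
read_structure <- function(file, map_modified = TRUE) {
  if (length(file) != 1L || !is.character(file)) {
    abort("`file` must be a single path or a PDB text string.")
  }
  if (grepl("\n", file, fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(strsplit(file, "\n", fixed = TRUE)[[1]], path)
  } else {
    if (!file.exists(file)) abort(paste0("PDB file not found: ", file))
    path <- file
  }

  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines)

  # keep only the first model
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl) > 0L) {
    lines <- lines[seq_len(endmdl[1] - 1L)]
    path2 <- tempfile(fileext = ".pdb")
    on.exit(unlink(path2), add = TRUE)
    writeLines(lines, path2)
    path <- path2
  }

  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                          rm.alt = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) abort("PDB model contains no atoms.")

  at$resid <- toupper(at$resid)
  keep <- (at$type == "ATOM" & !(at$resid %in% .water_resnames)) |
    (at$type == "HETATM" & at$resid %in% names(.aa3to1_modified))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) abort("PDB model contains no polymer residues.")

  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  if (is.null(at$elesy)) at$elesy <- NA_character_
  miss <- is.na(at$elesy) | at$elesy == ""
  at$elesy[miss] <- substr(gsub("[^A-Za-z].*$", "", at$elety[miss]), 1, 1)
  at$elesy <- toupper(at$elesy)

  at$res_uid <- paste(at$chain, at$resno, at$insert, sep = "|")
  at <- resolve_altloc(at)

  uid_order <- unique(at$res_uid)
  first_row <- match(uid_order, at$res_uid)
  chain <- at$chain[first_row]
  res <- tibble(
    chain = chain,
    author_number = paste0(at$resno[first_row], at$insert[first_row]),
    aa3 = at$resid[first_row],
    aa1 = aa3_to_aa1(at$resid[first_row], map_modified = map_modified),
    atoms = lapply(uid_order, function(u) {
      a <- at[at$res_uid == u, , drop = FALSE]
      data.frame(name = a$elety, element = a$elesy,
                 x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
    })
  )
  res <- res |>
    group_by(.data$chain) |>
    mutate(seq_position = row_number() - 1L) |>
    ungroup() |>
    select("chain", "seq_position", "author_number", "aa3", "aa1", "atoms")
  class(res) <- c("dasp_structure", class(res))
  res
}

# quick structural validation of coordinate records; errors name the line
validate_pdb_lines <- function(lines) {
  coord <- which(startsWith(lines, "ATOM") | startsWith(lines, "HETATM"))
  if (length(coord) == 0L) abort("No ATOM/HETATM records: empty model.")
  for (i in coord) {
    ln <- lines[i]
    if (nchar(ln) < 54L) {
      abort(sprintf("Malformed PDB record at line %d: too short (%d chars).",
                    i, nchar(ln)))
    }
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (anyNA(xyz)) {
      abort(sprintf("Malformed PDB record at line %d: non-numeric coordinates.", i))
    }
  }
  invisible(TRUE)
}

# one conformer per residue: keep blank-altloc atoms plus, per residue, the
# altloc letter with the highest mean occupancy (tie -> alphabetical)
resolve_altloc <- function(at) {
  has_alt <- at$alt != ""
  if (!any(has_alt)) return(at)
  keep <- !has_alt
  for (u in unique(at$res_uid[has_alt])) {
    rows <- which(at$res_uid == u & has_alt)
    occ <- tapply(at$o[rows], at$alt[rows], mean)
    chosen <- names(occ)[order(-occ, names(occ))][1]
    keep[rows[at$alt[rows] == chosen]] <- TRUE
  }
  at[keep, , drop = FALSE]
}

#' Centre of geometry of one residue's atoms
#'
#' Unweighted mean of the atom coordinates; by default hydrogens (and
#' deuteriums) are excluded so results do not depend on whether a deposition
#' includes hydrogens.
#'
#' @param atoms A data frame with columns `element`, `x`, `y`, `z` (one
#'   residue's `atoms` entry from [read_structure()]).
#' @param heavy_only Exclude hydrogen/deuterium atoms (default `TRUE`).
#' @return Numeric vector `c(x, y, z)` in Angstrom.
#' @export
center_of_geometry <- function(atoms, heavy_only = TRUE) {
  if (heavy_only) atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0L) abort("Residue has no usable atoms for a centre of geometry.")
  c(x = mean(atoms$x), y = mean(atoms$y), z = mean(atoms$z))
}

#' Per-residue centres of geometry for a structure
#'
#' @param structure A `dasp_structure` from [read_structure()].
#' @param heavy_only Passed to [center_of_geometry()].
#' @return The residue table with numeric columns `cog_x`, `cog_y`, `cog_z`
#'   appended (atoms column dropped).
#' @export
residue_centers <- function(structure, heavy_only = TRUE) {
  cog <- vapply(structure$atoms, center_of_geometry,
                numeric(3), heavy_only = heavy_only)
  structure |>
    mutate(cog_x = cog[1, ], cog_y = cog[2, ], cog_z = cog[3, ]) |>
    select(-"atoms")
}

#' One-letter sequence of a chain
#'
#' @param structure A `dasp_structure`.
#' @param chain Chain identifier; may be omitted for single-chain structures.
#' @return One-letter sequence string (empty string for an empty selection).
#' @export
chain_sequence <- function(structure, chain = NULL) {
  ch <- pick_chain(structure, chain)
  rows <- structure[structure$chain == ch, , drop = FALSE]
  paste0(rows$aa1[order(rows$seq_position)], collapse = "")
}

pick_chain <- function(structure, chain) {
  chains <- unique(structure$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L) {
      abort(paste0("Structure has chains ", paste(chains, collapse = ", "),
                   "; specify `chain`."))
    }
    return(chains)
  }
  if (!chain %in% chains) abort(paste0("Chain '", chain, "' not present."))
  chain
}

#' Read a key-residue configuration file
#'
#' One whitespace-separated record per protein:
#' `protein_id structure_file chain res1,res2,res3`, where the residue
#' references are author residue numbers (with optional insertion code).
#' Lines starting with `#` (and blank lines) are ignored.
#'
#' @param file Path to the configuration file.
#' @return Tibble with columns `protein_id`, `structure_file`, `chain`,
#'   and `residue_refs` (list of character vectors).
#' @export
read_key_residues <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort("Key-residue config contains no records.")
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad) > 0L) {
    abort(sprintf("Key-residue config record %d does not have 4 fields.", bad[1]))
  }
  tibble(
    protein_id = map_chr(parts, 1),
    structure_file = map_chr(parts, 2),
    chain = map_chr(parts, 3),
    residue_refs = map(parts, ~ strsplit(.x[4], ",", fixed = TRUE)[[1]])
  )
}

#' Resolve author residue numbers to 0-based sequence positions
#'
#' @param structure A `dasp_structure`.
#' @param refs Character vector of author residue numbers (plus optional
#'   insertion code) to resolve.
#' @param chain Chain identifier (optional for single-chain structures).
#' @return Integer vector of 0-based `seq_position` values, one per ref.
#' @export
resolve_residues <- function(structure, refs, chain = NULL) {
  ch <- pick_chain(structure, chain)
  rows <- structure[structure$chain == ch, , drop = FALSE]
  idx <- match(as.character(refs), rows$author_number)
  if (anyNA(idx)) {
    abort(paste0("Key residue(s) not found in chain ", ch, ": ",
                 paste(refs[is.na(idx)], collapse = ", ")),
          class = "dasp_resolve_error")
  }
  rows$seq_position[idx]
}
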