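# Deterministic synthetic fixtures: toy structures and sequence databases
# with planted active sites, so the full pipeline runs without external
# databases.
#
# Each family member's sequence is background spacers interleaved with
# mutated copies of the motif templates. The matching structure has one
# pseudo-atom per residue (so the atom is the residue's centre of
# geometry): planted motif residues sit on a tight ring (< 10 Angstrom)
# around their key residue's position, and spacer residues sit on a line
# far (>= 15 Angstrom) from every key residue.

#' Specification of a synthetic protein family
#'
#' The defaults define the package's reference study conditions: 20
#' members, three motifs of lengths 8, 6 and 5 with the key residue at the
#' template centre, a per-column substitution rate of 0.1, spacers of 10-30
#' background residues, and the standard background composition.
#'
#' @param n_members Number of family members.
#' @param motif_templates Character vector of motif template strings
#'   (lengths >= 4).
#' @param substitution_rate Per-column probability that a template residue
#'   is replaced by a different background-drawn residue, in \[0, 1).
#' @param spacer_range Integer range (min, max) of spacer lengths.
#' @param key_positions 1-based key-residue position within each template;
#'   default: the template centre.
#' @param background Background composition for spacers and substitutions.
#' @param trim_max Maximum number of residues structurally trimmed from a
#'   motif's C-terminal end per member (sequence keeps the full template, so
#'   trimming creates heterogeneous fragment lengths with conserved flanks).
#' @param seed Integer seed; a fixed seed makes outputs byte-identical.
#' @return A list of class `dasp_family_spec`.
#' @export
family_spec <- function(n_members = 20,
                        motif_templates = c("HDAGWCEF", "GGLGTR", "YKPMN"),
                        substitution_rate = 0.1,
                        spacer_range = c(10, 30),
                        key_positions = NULL,
                        background = dasp_background(),
                        trim_max = 0,
                        seed = 42) {
  if (length(motif_templates) == 0L) abort("Need at least one motif template.")
  if (any(nchar(motif_templates) < 4L)) {
    abort("Motif templates must be at least 4 residues long.")
  }
  if (substitution_rate < 0 || substitution_rate >= 1) {
    abort("`substitution_rate` must lie in [0, 1).")
  }
  if (is.null(key_positions)) {
    key_positions <- ceiling(nchar(motif_templates) / 2)
  }
  stopifnot(length(key_positions) == length(motif_templates),
            all(key_positions >= 1),
            all(key_positions <= nchar(motif_templates)))
  structure(
    list(n_members = n_members, motif_templates = toupper(motif_templates),
         substitution_rate = substitution_rate,
         spacer_range = as.integer(spacer_range),
         key_positions = as.integer(key_positions),
         background = background / sum(background),
         trim_max = as.integer(trim_max), seed = as.integer(seed)),
    class = "dasp_family_spec"
  )
}

# sample() without the scalar-x surprise
sample_from <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

random_residues <- function(n, background) {
  if (n == 0L) return("")
  paste0(sample(names(background), n, replace = TRUE, prob = background),
         collapse = "")
}

mutate_template <- function(template, rate, background) {
  v <- strsplit(template, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(v)) < rate
  for (i in which(hit)) {
    others <- setdiff(names(background), v[i])
    v[i] <- sample(others, 1, prob = background[others])
  }
  paste0(v, collapse = "")
}

# fixed-width PDB ATOM record, one CA pseudo-atom per residue
pdb_atom_line <- function(serial, aa3, chain, resno, x, y, z) {
  sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, aa3, chain, resno, x, y, z)
}

aa1_to_aa3 <- function(aa1) {
  tab <- setNames(names(.aa3to1), unname(.aa3to1))
  out <- unname(tab[aa1])
  out[is.na(out)] <- "UNK"
  out
}

#' Generate a synthetic protein family with planted active sites
#'
#' For each member, emits a full-length sequence (spacers plus mutated motif
#' copies), a toy PDB structure in which the (possibly trimmed) motif
#' residues lie within 10 Angstrom of their key residue and all other
#' residues lie far away, a key-residue configuration, and a manifest of the
#' planted ground truth.
#'
#' @param spec A [family_spec()].
#' @param dir Optional directory: when given, writes `<id>.pdb` files,
#'   `family.fasta`, `keyres.txt` and `manifest.json` there.
#' @return List with `structures` (named PDB text), `sequences` (named
#'   character), `key_residues` (tibble as from [read_key_residues()]), and
#'   `manifest` (tibble: `protein_id`, `motif`, `start`, `end`,
#'   `struct_start`, `struct_end`, `key_position`, all 0-based half-open).
#' @export
generate_family <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "dasp_family_spec"))
  K <- length(spec$motif_templates)
  with_fixed_seed(spec$seed, {
    members <- lapply(seq_len(spec$n_members), function(m) {
      id <- sprintf("fam%02d", m)
      spacers <- vapply(
        sample_from(spec$spacer_range[1]:spec$spacer_range[2], K + 1,
                    replace = TRUE),
        random_residues, character(1), background = spec$background
      )
      motifs <- vapply(spec$motif_templates, mutate_template, character(1),
                       rate = spec$substitution_rate,
                       background = spec$background, USE.NAMES = FALSE)
      trims <- vapply(seq_len(K), function(k) {
        len <- nchar(motifs[k])
        max_trim <- min(spec$trim_max, len - max(4L, spec$key_positions[k]))
        if (max_trim <= 0L) 0L else sample_from(0:max_trim, 1)
      }, integer(1))

      seq_parts <- character(0)
      manifest <- vector("list", K)
      pos <- 0L
      for (k in seq_len(K)) {
        seq_parts <- c(seq_parts, spacers[k])
        pos <- pos + nchar(spacers[k])
        len <- nchar(motifs[k])
        manifest[[k]] <- tibble(
          protein_id = id, motif = k,
          start = pos, end = pos + len,
          struct_start = pos, struct_end = pos + len - trims[k],
          key_position = pos + spec$key_positions[k] - 1L
        )
        seq_parts <- c(seq_parts, motifs[k])
        pos <- pos + len
      }
      seq_parts <- c(seq_parts, spacers[K + 1])
      sequence <- paste0(seq_parts, collapse = "")
      manifest <- bind_rows(manifest)

      # structure: key residue at each motif's cluster centre, other planted
      # residues on a radius-3 ring around it; everything else on a distant line
      n <- nchar(sequence)
      coords <- cbind(20 * seq_len(n), 0, 500)
      for (k in seq_len(K)) {
        centre <- c(200 * k, 0, 0)
        res0 <- manifest$struct_start[k]:(manifest$struct_end[k] - 1L)
        keyp <- manifest$key_position[k]
        ring <- setdiff(res0, keyp)
        ang <- 2 * pi * seq_along(ring) / max(1L, length(ring))
        coords[keyp + 1L, ] <- centre
        if (length(ring) > 0L) {
          coords[ring + 1L, ] <- cbind(centre[1] + 3 * cos(ang),
                                       centre[2] + 3 * sin(ang),
                                       centre[3])
        }
      }
      aa1 <- strsplit(sequence, "", fixed = TRUE)[[1]]
      pdb <- c(
        vapply(seq_len(n), function(i) {
          pdb_atom_line(i, aa1_to_aa3(aa1[i]), "A", i,
                        coords[i, 1], coords[i, 2], coords[i, 3])
        }, character(1)),
        "TER", "END"
      )
      list(id = id, sequence = sequence, pdb = paste0(pdb, collapse = "\n"),
           manifest = manifest,
           key_refs = as.character(manifest$key_position + 1L))
    })
  })

  structures <- setNames(lapply(members, `[[`, "pdb"),
                         vapply(members, `[[`, "", "id"))
  sequences <- setNames(vapply(members, `[[`, "", "sequence"),
                        names(structures))
  key_residues <- tibble(
    protein_id = names(structures),
    structure_file = paste0(names(structures), ".pdb"),
    chain = "A",
    residue_refs = lapply(members, `[[`, "key_refs")
  )
  manifest <- bind_rows(lapply(members, `[[`, "manifest"))

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(structures)) {
      writeLines(structures[[id]], file.path(dir, paste0(id, ".pdb")))
    }
    Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences),
                                file.path(dir, "family.fasta"))
    writeLines(
      c("# protein_id  structure_file  chain  key_residues",
        sprintf("%s\t%s\t%s\t%s", key_residues$protein_id,
                key_residues$structure_file, key_residues$chain,
                vapply(key_residues$residue_refs, paste, "", collapse = ","))),
      file.path(dir, "keyres.txt")
    )
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                           dataframe = "rows")
    }
  }
  list(structures = structures, sequences = sequences,
       key_residues = key_residues, manifest = manifest)
}

#' Generate a decoy database of background sequences
#'
#' Independent sequences drawn i.i.d. from the background composition, with
#' no planted motifs.
#'
#' @param n Number of sequences (>= 1).
#' @param length_range Integer range (min, max) of sequence lengths.
#' @param composition Residue composition (default [dasp_background()]).
#' @param seed Integer seed.
#' @return Named character vector (`decoy0001`, ...).
#' @export
generate_decoys <- function(n, length_range = c(100, 200),
                            composition = dasp_background(), seed = 1) {
  if (n < 1L) abort("`n` must be >= 1.")
  composition <- composition / sum(composition)
  with_fixed_seed(seed, {
    lens <- sample_from(length_range[1]:length_range[2], n, replace = TRUE)
    setNames(
      vapply(lens, random_residues, character(1), background = composition),
      sprintf("decoy%04d", seq_len(n))
    )
  })
}
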