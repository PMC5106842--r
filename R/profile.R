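# Active-site profile (ASP) construction.
#
# Fragments are aligned individually rather than as whole concatenated
# signatures: the k-th key-residue fragment of every protein forms key block
# k, and non-key fragments are paired by N->C rank within the intervals
# between key fragments. Within a block, each fragment is placed against the
# block's longest fragment at the offset maximising the summed BLOSUM62
# score (terminal gaps only; ties towards the smallest offset, i.e. gaps at
# the C-terminal side). Motif length is then set by the longest fragment
# (DASP3) or the shortest (legacy), with shorter rows extended from — or all
# rows truncated to — the complete protein sequence.

#' Check that every protein has the same number of key-residue fragments
#'
#' Profile construction is only meaningful when the k-th key fragment is
#' comparable across proteins; a mismatch in key-fragment counts terminates
#' construction with an error listing the per-protein counts.
#'
#' @param signatures Fragment tibble covering at least two proteins (see
#'   [build_signature()]).
#' @return The common key-fragment count, invisibly usable downstream.
#' @export
check_key_fragment_consistency <- function(signatures) {
  ids <- unique(signatures$protein_id)
  if (length(ids) < 2L) {
    abort("At least two proteins are required to build a profile.",
          class = "dasp_profile_error")
  }
  counts <- vapply(ids, function(id) {
    sum(signatures$contains_key[signatures$protein_id == id])
  }, integer(1))
  if (length(unique(counts)) != 1L) {
    tab <- paste0(ids, "=", counts, collapse = ", ")
    maj <- as.integer(names(sort(table(counts), decreasing = TRUE))[1])
    outliers <- ids[counts != maj]
    abort(
      paste0("Inconsistent key-fragment counts across proteins (", tab,
             "); outlier(s): ", paste(outliers, collapse = ", "),
             ". Choose different key residues."),
      class = c("dasp_keycount_error", "dasp_profile_error")
    )
  }
  if (counts[1] == 0L) {
    abort("No key-residue fragments present in any signature.",
          class = "dasp_profile_error")
  }
  counts[[1]]
}

# best placement offset of `short` inside `anchor` (terminal gaps only):
# maximises summed BLOSUM62 over the overlap; ties -> smallest offset
best_offset <- function(short, anchor) {
  ls <- nchar(short)
  la <- nchar(anchor)
  offs <- 0:(la - ls)
  sc <- vapply(offs, function(o) {
    blosum_string_score(short, substr(anchor, o + 1L, o + ls))
  }, numeric(1))
  offs[which.max(sc)]
}

#' Group signature fragments into raw aligned motif blocks
#'
#' Key fragments are paired by N->C rank across proteins; non-key fragments
#' are assigned to the interval between key fragments in which they fall and
#' paired by rank within that interval. Blocks reaching fewer than
#' `min_occupancy` of the proteins are dropped with a warning. Within each
#' block every fragment is given a placement offset against the block's
#' longest fragment.
#'
#' @param signatures Fragment tibble (key-fragment consistency already
#'   satisfied; see [check_key_fragment_consistency()]).
#' @param min_occupancy Minimum fraction of proteins a non-key block must
#'   cover to be retained (default 1: all proteins).
#' @return List of raw blocks, each a list with `is_key`, `width`, and a
#'   `members` tibble (`protein_id`, `chain`, `start`, `end`, `residues`,
#'   `contains_key`, `offset`), ordered N->C by median fragment start.
#' @export
align_fragment_sets <- function(signatures, min_occupancy = 1) {
  ids <- unique(signatures$protein_id)
  labelled <- lapply(ids, function(id) {
    fr <- signatures[signatures$protein_id == id, , drop = FALSE]
    fr <- fr[order(fr$start), , drop = FALSE]
    keycum <- cumsum(fr$contains_key)
    lab <- character(nrow(fr))
    lab[fr$contains_key] <- paste0("K", keycum[fr$contains_key])
    if (any(!fr$contains_key)) {
      iv <- keycum[!fr$contains_key]
      rk <- stats::ave(iv, iv, FUN = seq_along)
      lab[!fr$contains_key] <- sprintf("I%d.%d", iv, rk)
    }
    fr$block_label <- lab
    fr
  })
  all_fr <- bind_rows(labelled)

  labels <- unique(all_fr$block_label)
  blocks <- lapply(labels, function(lb) {
    members <- all_fr[all_fr$block_label == lb, , drop = FALSE]
    lens <- nchar(members$residues)
    anchor_i <- order(-lens, members$residues, members$protein_id)[1]
    anchor <- members$residues[anchor_i]
    members$offset <- vapply(seq_len(nrow(members)), function(i) {
      if (i == anchor_i) 0L else as.integer(best_offset(members$residues[i], anchor))
    }, integer(1))
    list(
      is_key = startsWith(lb, "K"),
      width = nchar(anchor),
      members = as_tibble(members[, c("protein_id", "chain", "start", "end",
                                      "residues", "contains_key", "offset")])
    )
  })

  occ <- vapply(blocks, function(b) nrow(b$members) / length(ids), numeric(1))
  if (any(occ < min_occupancy)) {
    warn(paste0("Dropping ", sum(occ < min_occupancy),
                " partially occupied non-key block(s)."))
    blocks <- blocks[occ >= min_occupancy]
  }
  med <- vapply(blocks, function(b) median(b$members$start), numeric(1))
  blocks[order(med)]
}

#' Fix a motif block's length and make its rows gap-free
#'
#' In DASP3 mode the motif spans the longest fragment in the block and every
#' shorter fragment is extended with the adjacent residues of its complete
#' protein sequence (terminal gaps of the placement decide the direction).
#' In legacy mode the motif spans the shortest fragment and all rows are
#' truncated to the columns it covers. Where an extension would run past a
#' sequence terminus the row is padded with `X` and a warning is recorded.
#'
#' @param block A raw block from [align_fragment_sets()].
#' @param full_sequences Named character vector of complete protein
#'   sequences (names = protein ids).
#' @param mode `"dasp3"` (extend to longest) or `"legacy"` (truncate to
#'   shortest).
#' @return A list with `is_key`, `width`, and a `rows` tibble
#'   (`protein_id`, `start`, `end`, `row`): gap-free rows of equal length,
#'   with 0-based half-open source intervals (clamped to the sequence).
#' @export
extend_to_longest <- function(block, full_sequences, mode = "dasp3") {
  mode <- match.arg(mode, c("dasp3", "legacy"))
  m <- block$members
  if (mode == "dasp3") {
    c0 <- 0L
    c1 <- block$width
  } else {
    lens <- nchar(m$residues)
    si <- order(lens, m$residues, m$protein_id)[1]
    c0 <- m$offset[si]
    c1 <- c0 + lens[si]
  }
  target_len <- c1 - c0
  padded <- character(0)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    id <- m$protein_id[i]
    if (!id %in% names(full_sequences)) {
      abort(paste0("No full sequence supplied for protein ", id, "."))
    }
    seqstr <- full_sequences[[id]]
    L <- nchar(seqstr)
    new_start <- m$start[i] + (c0 - m$offset[i])
    new_end <- new_start + target_len
    left_pad <- max(0L, -new_start)
    right_pad <- max(0L, new_end - L)
    if (left_pad + right_pad > 0L) padded <<- c(padded, id)
    core <- substr(seqstr, new_start + left_pad + 1L, new_end - right_pad)
    row <- paste0(strrep("X", left_pad), core, strrep("X", right_pad))
    # the original fragment's residues are authoritative within its interval
    frag_cols <- (m$offset[i] - c0) + seq_len(nchar(m$residues[i]))
    keep <- frag_cols >= 1L & frag_cols <= target_len
    if (any(keep)) {
      rv <- strsplit(row, "", fixed = TRUE)[[1]]
      fv <- strsplit(m$residues[i], "", fixed = TRUE)[[1]]
      rv[frag_cols[keep]] <- fv[keep]
      row <- paste0(rv, collapse = "")
    }
    tibble(protein_id = id,
           start = new_start + left_pad,
           end = new_end - right_pad,
           row = row)
  })
  if (length(padded) > 0L) {
    warn(paste0("Motif extension ran past a sequence terminus for: ",
                paste(unique(padded), collapse = ", "), "; padded with 'X'."))
  }
  list(is_key = block$is_key, width = target_len, rows = bind_rows(rows))
}

#' Check that no protein's extended motif intervals overlap
#'
#' Fragment overlap created by motif extension is detected at profile
#' construction time; the remedy is to choose different key residues.
#'
#' @param blocks List of extended blocks ([extend_to_longest()]).
#' @return `TRUE` invisibly, or an error naming the protein and the two
#'   clashing blocks.
#' @export
detect_overlaps <- function(blocks) {
  per_protein <- bind_rows(lapply(seq_along(blocks), function(b) {
    mutate(blocks[[b]]$rows, block = b)
  }))
  for (id in unique(per_protein$protein_id)) {
    iv <- per_protein[per_protein$protein_id == id, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    if (nrow(iv) > 1L) {
      clash <- which(iv$end[-nrow(iv)] > iv$start[-1])
      if (length(clash) > 0L) {
        i <- clash[1]
        abort(
          sprintf(paste0("Motif overlap for protein %s: blocks %d and %d ",
                         "share residues after extension. ",
                         "Choose different key residues."),
                  id, iv$block[i], iv$block[i + 1]),
          class = c("dasp_overlap_error", "dasp_profile_error")
        )
      }
    }
  }
  invisible(TRUE)
}

#' Build an active-site profile from signatures
#'
#' Runs the full construction: short-fragment filtering, key-fragment
#' consistency check, fragment-wise block alignment, motif-length fixing
#' (extension in DASP3 mode, truncation in legacy mode) and the overlap
#' check.
#'
#' @param signatures Fragment tibble covering all proteins (see
#'   [extract_signature()]).
#' @param full_sequences Named character vector of complete sequences.
#' @param mode `"dasp3"` or `"legacy"`.
#' @param min_len Minimum fragment length; defaults to 4 in DASP3 mode and
#'   3 in legacy mode.
#' @param min_occupancy See [align_fragment_sets()].
#' @param radius Radius (Angstrom) recorded as profile metadata.
#' @return An object of class `dasp_profile`: a list with `protein_ids`,
#'   `mode`, `radius`, `min_len`, and `blocks` (each with `index`, `is_key`,
#'   `width`, `rows`).
#' @export
build_profile <- function(signatures, full_sequences,
                          mode = c("dasp3", "legacy"), min_len = NULL,
                          min_occupancy = 1, radius = 10) {
  mode <- match.arg(mode)
  if (is.null(min_len)) min_len <- if (mode == "dasp3") 4L else 3L
  signatures <- filter_short_fragments(signatures, min_len)
  check_key_fragment_consistency(signatures)
  raw <- align_fragment_sets(signatures, min_occupancy = min_occupancy)
  blocks <- lapply(raw, extend_to_longest, full_sequences = full_sequences,
                   mode = mode)
  detect_overlaps(blocks)
  blocks <- lapply(seq_along(blocks), function(i) {
    c(list(index = i), blocks[[i]])
  })
  structure(
    list(protein_ids = unique(signatures$protein_id), mode = mode,
         radius = radius, min_len = min_len, blocks = blocks),
    class = "dasp_profile"
  )
}

#' @export
print.dasp_profile <- function(x, ...) {
  cat(sprintf("Active-site profile (%s): %d proteins, %d motif blocks\n",
              x$mode, length(x$protein_ids), length(x$blocks)))
  for (b in x$blocks) {
    cat(sprintf("  motif %d: len %d%s, %d rows\n",
                b$index, b$width, if (b$is_key) " [key]" else "",
                nrow(b$rows)))
  }
  invisible(x)
}

#' Tidy an active-site profile into a long tibble
#'
#' @param x A `dasp_profile`.
#' @param ... Unused.
#' @return Tibble with one row per (block, protein): `block`, `is_key`,
#'   `width`, `protein_id`, `start`, `end`, `row`.
#' @export
tidy.dasp_profile <- function(x, ...) {
  bind_rows(lapply(x$blocks, function(b) {
    mutate(b$rows, block = b$index, is_key = b$is_key, width = b$width)
  })) |>
    select("block", "is_key", "width", "protein_id", "start", "end", "row")
}

#' One-row summary of an active-site profile
#'
#' @param x A `dasp_profile`.
#' @param ... Unused.
#' @return Tibble with `mode`, `n_proteins`, `n_blocks`, `n_key_blocks`,
#'   `min_width`, `max_width`, `radius`.
#' @export
glance.dasp_profile <- function(x, ...) {
  w <- vapply(x$blocks, function(b) b$width, integer(1))
  tibble(
    mode = x$mode,
    n_proteins = length(x$protein_ids),
    n_blocks = length(x$blocks),
    n_key_blocks = sum(vapply(x$blocks, function(b) b$is_key, logical(1))),
    min_width = min(w), max_width = max(w),
    radius = x$radius
  )
}

#' Write a profile to its plain-text file format
#'
#' Header lines (`mode`, `radius`, `min_len`, `proteins`), then per block a
#' `>motif` record followed by one row per protein. Round-trips through
#' [read_profile()].
#'
#' @param profile A `dasp_profile`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_profile <- function(profile, file) {
  lines <- c(
    "# active-site profile",
    paste0("mode\t", profile$mode),
    paste0("radius\t", profile$radius),
    paste0("min_len\t", profile$min_len),
    paste0("proteins\t", paste(profile$protein_ids, collapse = ","))
  )
  for (b in profile$blocks) {
    lines <- c(lines, sprintf(">motif %d key=%s len=%d",
                              b$index, b$is_key, b$width))
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", b$rows$protein_id,
                              b$rows$start, b$rows$end, b$rows$row))
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read a profile written by [write_profile()]
#'
#' @param file Path to a profile file.
#' @return A `dasp_profile`.
#' @export
read_profile <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  hdr <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, "\t"))]
    if (length(ln) != 1L) abort(paste0("Profile file missing header '", key, "'."))
    sub(paste0("^", key, "\t"), "", ln)
  }
  mode <- hdr("mode")
  radius <- as.numeric(hdr("radius"))
  min_len <- as.integer(hdr("min_len"))
  protein_ids <- strsplit(hdr("proteins"), ",", fixed = TRUE)[[1]]
  starts <- which(startsWith(lines, ">motif"))
  if (length(starts) == 0L) abort("Profile file contains no motif blocks.")
  bounds <- c(starts, length(lines) + 1L)
  blocks <- lapply(seq_along(starts), function(i) {
    hd <- lines[starts[i]]
    m <- regmatches(hd, regexec("^>motif (\\d+) key=(\\S+) len=(\\d+)$", hd))[[1]]
    if (length(m) != 4L) abort(paste0("Malformed motif header: ", hd))
    body <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    rows <- tibble(
      protein_id = map_chr(parts, 1),
      start = as.integer(map_chr(parts, 2)),
      end = as.integer(map_chr(parts, 3)),
      row = map_chr(parts, 4)
    )
    list(index = as.integer(m[2]), is_key = as.logical(m[3]),
         width = as.integer(m[4]), rows = rows)
  })
  structure(
    list(protein_ids = protein_ids, mode = mode, radius = radius,
         min_len = min_len, blocks = blocks),
    class = "dasp_profile"
  )
}
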