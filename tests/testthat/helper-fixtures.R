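# Test fixtures built in code: point-atom PDB texts, toy alphabets, and a
# small planted family shared across tests.

# PDB text with one atom per residue at given coordinates
point_pdb <- function(aa3, coords, chain = "A", resno = seq_along(aa3)) {
  stopifnot(nrow(coords) == length(aa3))
  lines <- vapply(seq_along(aa3), function(i) {
    sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, aa3[i], chain, resno[i],
            coords[i, 1], coords[i, 2], coords[i, 3])
  }, character(1))
  paste0(c(lines, "TER", "END"), collapse = "\n")
}

# PDB text with explicit full atom control (for altloc/water/hydrogen cases)
atom_record <- function(serial, name, altloc, resname, chain, resno,
                        x, y, z, occ = 1, element = "C",
                        record = "ATOM") {
  sprintf("%-6s%5d %s%1s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f  0.00          %2s",
          record, serial, formatC(name, width = -4), altloc, resname, chain,
          resno, x, y, z, occ, element)
}

# fragment tibble shorthand for profile tests (structures not needed)
frag <- function(protein_id, start, residues, contains_key = FALSE,
                 chain = "A") {
  tibble::tibble(protein_id = protein_id, chain = chain, start = start,
                 end = start + nchar(residues), residues = residues,
                 contains_key = contains_key)
}

# signatures for a generated family, via the real structure pipeline
family_signatures <- function(fam, min_len = 4L) {
  dplyr::bind_rows(lapply(seq_len(nrow(fam$key_residues)), function(i) {
    id <- fam$key_residues$protein_id[i]
    st <- read_structure(fam$structures[[id]])
    extract_signature(st, fam$key_residues$residue_refs[[i]],
                      chain = fam$key_residues$chain[i],
                      protein_id = id, min_len = min_len)
  }))
}

# random PSSM over a small alphabet, built from random motif rows
toy_pssm <- function(alphabet = c("A", "B", "C", "D"), len = 3, n_rows = 5,
                     background = NULL) {
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / length(alphabet), length(alphabet)),
                                  alphabet)
  }
  rows <- vapply(seq_len(n_rows), function(i) {
    paste0(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
  build_pssm(rows, background = background)
}

# exhaustive window-score distribution oracle: enumerate all |alphabet|^L
# windows, weight by background probability
enumerate_distribution <- function(pssm) {
  A <- length(pssm$alphabet)
  L <- pssm$length
  grid <- as.matrix(expand.grid(rep(list(seq_len(A)), L)))
  sc <- numeric(nrow(grid))
  pr <- rep(1, nrow(grid))
  for (j in seq_len(L)) {
    sc <- sc + pssm$scores[cbind(grid[, j], j)]
    pr <- pr * pssm$background[grid[, j]]
  }
  tapply(pr, sc, sum)
}

# the package's reference study conditions, shared by the acceptance tests:
# 20 members, motifs 8/6/5, substitution rate 0.1, 500 decoys; computed once
.acc_cache <- new.env(parent = emptyenv())
acceptance_fixture <- function() {
  if (is.null(.acc_cache$fix)) {
    spec <- family_spec(seed = 4242)
    fam <- generate_family(spec)
    prof <- build_profile(family_signatures(fam), fam$sequences,
                          mode = "dasp3")
    decoys <- generate_decoys(500, seed = 4243)
    res <- search_database(c(fam$sequences, decoys), prof)
    .acc_cache$fix <- list(spec = spec, fam = fam, prof = prof,
                           decoys = decoys, res = res)
  }
  .acc_cache$fix
}
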