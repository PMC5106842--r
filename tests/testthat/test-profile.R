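test_that("key-fragment-count consistency is enforced across proteins", {
  ok <- dplyr::bind_rows(
    frag("p1", 0, "AAAA", TRUE), frag("p1", 10, "CCCC", TRUE),
    frag("p2", 0, "AAAA", TRUE), frag("p2", 10, "CCCC", TRUE)
  )
  expect_equal(check_key_fragment_consistency(ok), 2L)

  bad <- dplyr::bind_rows(ok, frag("p3", 0, "AAAA", TRUE))
  err <- expect_error(check_key_fragment_consistency(bad),
                      class = "dasp_keycount_error")
  expect_match(conditionMessage(err), "p3")

  single <- dplyr::bind_rows(frag("p1", 0, "AAAA", TRUE))
  expect_error(check_key_fragment_consistency(single),
               class = "dasp_profile_error")
})

test_that("non-key fragments pair by rank between key fragments", {
  sig <- dplyr::bind_rows(
    frag("p1", 0, "AAAA", TRUE), frag("p1", 10, "DEFG"),
    frag("p1", 20, "CCCC", TRUE),
    frag("p2", 5, "AAAA", TRUE), frag("p2", 15, "DDFG"),
    frag("p2", 25, "CCCC", TRUE)
  )
  blocks <- align_fragment_sets(sig)
  expect_length(blocks, 3L)
  expect_equal(vapply(blocks, `[[`, logical(1), "is_key"),
               c(TRUE, FALSE, TRUE))
  expect_equal(sort(blocks[[2]]$members$residues), c("DDFG", "DEFG"))
})

test_that("identical fragment strings align gap-free at offset zero", {
  sig <- dplyr::bind_rows(
    frag("p1", 0, "AAAA", TRUE), frag("p2", 7, "AAAA", TRUE)
  )
  b <- align_fragment_sets(sig)[[1]]
  expect_equal(b$members$offset, c(0L, 0L))
  expect_equal(b$width, 4L)
})

test_that("terminal-gap placement matches a global alignment oracle", {
  # GGLG vs GGLGA: the oracle (Needleman-Wunsch, BLOSUM62, open 10/extend
  # 0.5) leaves a single terminal gap; our offset placement must agree
  pa <- Biostrings::pairwiseAlignment(
    "GGLG", "GGLGA", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5, type = "global"
  )
  oracle_pattern <- as.character(Biostrings::alignedPattern(pa))
  expect_equal(unname(oracle_pattern), "GGLG-")

  sig <- dplyr::bind_rows(
    frag("p1", 3, "GGLGA", TRUE), frag("p2", 3, "GGLG", TRUE)
  )
  b <- align_fragment_sets(sig)[[1]]
  short <- b$members[b$members$residues == "GGLG", ]
  expect_equal(short$offset, 0L)  # gap at the C-terminus, as in the oracle
})

test_that("motif extension widens short rows from the full sequence", {
  # p2's fragment TSKY sits inside ..MM[TSKY]QQ..; extension to length 6
  # must pull the flanking residues the terminal gaps point at
  sig <- dplyr::bind_rows(
    frag("p1", 2, "WTSKYD", TRUE),
    frag("p2", 4, "TSKY", TRUE)
  )
  seqs <- c(p1 = "AAWTSKYDAA", p2 = "AAMMTSKYQQ")
  raw <- align_fragment_sets(sig)[[1]]
  ext <- extend_to_longest(raw, seqs, mode = "dasp3")
  expect_equal(ext$width, 6L)
  rows <- setNames(ext$rows$row, ext$rows$protein_id)
  expect_equal(unname(rows["p1"]), "WTSKYD")
  expect_equal(unname(nchar(rows["p2"])), 6L)
  expect_match(rows["p2"], "TSKY")
  # the original residues are untouched inside the original interval
  p2row <- ext$rows[ext$rows$protein_id == "p2", ]
  off <- 4 - p2row$start
  expect_equal(substr(p2row$row, off + 1, off + 4), "TSKY")

  # legacy mode truncates to the shortest fragment's columns instead
  leg <- extend_to_longest(raw, seqs, mode = "legacy")
  expect_equal(leg$width, 4L)
  expect_equal(setNames(leg$rows$row, leg$rows$protein_id)[["p2"]], "TSKY")

  # equal lengths: extension is the identity
  sig2 <- dplyr::bind_rows(frag("p1", 2, "WTSKYD", TRUE),
                           frag("p2", 2, "WTSKYE", TRUE))
  ext2 <- extend_to_longest(align_fragment_sets(sig2)[[1]],
                            c(p1 = "AAWTSKYDAA", p2 = "AAWTSKYEAA"),
                            mode = "dasp3")
  expect_equal(sort(ext2$rows$row), c("WTSKYD", "WTSKYE"))
})

test_that("extension past a sequence terminus pads with X and warns", {
  sig <- dplyr::bind_rows(
    frag("p1", 2, "WTSKYD", TRUE),
    frag("p2", 0, "TSKY", TRUE)   # at the very N-terminus
  )
  seqs <- c(p1 = "AAWTSKYDAA", p2 = "TSKYQQ")
  raw <- align_fragment_sets(sig)[[1]]
  expect_warning(ext <- extend_to_longest(raw, seqs, mode = "dasp3"),
                 "terminus")
  p2row <- ext$rows$row[ext$rows$protein_id == "p2"]
  expect_equal(nchar(p2row), 6L)
  expect_match(p2row, "X")
})

test_that("post-extension overlap is detected and names the offender", {
  ok <- list(
    list(is_key = TRUE, width = 4,
         rows = tibble::tibble(protein_id = "p", start = 0, end = 4, row = "AAAA")),
    list(is_key = TRUE, width = 4,
         rows = tibble::tibble(protein_id = "p", start = 4, end = 8, row = "CCCC"))
  )
  expect_true(detect_overlaps(ok))  # shared boundary is fine (half-open)

  clash <- ok
  clash[[2]]$rows$start <- 3
  err <- expect_error(detect_overlaps(clash), class = "dasp_overlap_error")
  expect_match(conditionMessage(err), "p")
  expect_match(conditionMessage(err), "1 and 2")
})

test_that("profiles from an unmutated family reproduce the planted motifs", {
  spec <- family_spec(n_members = 4, substitution_rate = 0, seed = 9)
  fam <- generate_family(spec)
  prof <- build_profile(family_signatures(fam), fam$sequences, mode = "dasp3")
  expect_length(prof$blocks, length(spec$motif_templates))
  for (k in seq_along(prof$blocks)) {
    expect_true(all(prof$blocks[[k]]$rows$row == spec$motif_templates[k]))
    expect_true(prof$blocks[[k]]$is_key)
  }
})

test_that("profile construction is invariant to protein input order", {
  fam <- generate_family(family_spec(n_members = 5, seed = 13))
  sigs <- family_signatures(fam)
  prof1 <- build_profile(sigs, fam$sequences)
  shuffled <- dplyr::bind_rows(
    lapply(rev(unique(sigs$protein_id)),
           function(id) sigs[sigs$protein_id == id, ])
  )
  prof2 <- build_profile(shuffled, fam$sequences)
  t1 <- dplyr::arrange(tidy(prof1), block, protein_id)
  t2 <- dplyr::arrange(tidy(prof2), block, protein_id)
  expect_equal(t1, t2)
})

test_that("block widths follow the longest (dasp3) / shortest (legacy) rule", {
  fam <- generate_family(family_spec(n_members = 6, trim_max = 2, seed = 17))
  sigs <- family_signatures(fam)
  raw <- align_fragment_sets(filter_short_fragments(sigs, 4))
  p3 <- build_profile(sigs, fam$sequences, mode = "dasp3")
  pl <- build_profile(sigs, fam$sequences, mode = "legacy")
  for (k in seq_along(raw)) {
    lens <- nchar(raw[[k]]$members$residues)
    expect_equal(p3$blocks[[k]]$width, max(lens))
    expect_equal(pl$blocks[[k]]$width, min(lens))
    expect_lte(pl$blocks[[k]]$width, p3$blocks[[k]]$width)
    # extension never rewrites residues inside the original fragments
    for (i in seq_len(nrow(raw[[k]]$members))) {
      m <- raw[[k]]$members[i, ]
      r3 <- p3$blocks[[k]]$rows
      row <- r3$row[r3$protein_id == m$protein_id]
      st <- r3$start[r3$protein_id == m$protein_id]
      expect_equal(substr(row, m$start - st + 1, m$end - st), m$residues)
    }
  }
})

test_that("rebuilding a profile from its own search hits keeps block lengths", {
  fam <- generate_family(family_spec(n_members = 6, trim_max = 2, seed = 19))
  sigs <- family_signatures(fam)
  prof <- build_profile(sigs, fam$sequences)
  res <- search_database(fam$sequences, prof)
  hits <- tidy(res)$seq_id
  prof2 <- build_profile(sigs[sigs$protein_id %in% hits, ],
                         fam$sequences[hits])
  w1 <- vapply(prof$blocks, `[[`, integer(1), "width")
  w2 <- vapply(prof2$blocks, `[[`, integer(1), "width")
  expect_length(w2, length(w1))
  expect_true(all(w2 >= w1))
})

test_that("profiles round-trip through the text format", {
  fam <- generate_family(family_spec(n_members = 4, seed = 23))
  prof <- build_profile(family_signatures(fam), fam$sequences)
  f <- tempfile()
  write_profile(prof, f)
  back <- read_profile(f)
  expect_equal(back$mode, prof$mode)
  expect_equal(back$protein_ids, prof$protein_ids)
  expect_equal(length(back$blocks), length(prof$blocks))
  for (k in seq_along(prof$blocks)) {
    expect_equal(back$blocks[[k]]$rows, prof$blocks[[k]]$rows)
    expect_equal(back$blocks[[k]]$width, prof$blocks[[k]]$width)
    expect_equal(back$blocks[[k]]$is_key, prof$blocks[[k]]$is_key)
  }
})

test_that("profile construction surfaces the documented errors end to end", {
  fam <- generate_family(family_spec(n_members = 3, seed = 29))
  sigs <- family_signatures(fam)
  # drop one protein's key fragment -> inconsistent counts
  idx <- which(sigs$protein_id == "fam01" & sigs$contains_key)[1]
  expect_error(build_profile(sigs[-idx, ], fam$sequences),
               class = "dasp_profile_error")
})
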