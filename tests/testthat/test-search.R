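test_that("a planted exact motif is placed at its planted position", {
  withr::with_seed(51, {
    bg <- dasp_background()
    motif <- "HDAGWCEF"
    p <- build_pssm(rep(motif, 6), background = bg)
    backbone <- paste0(sample(names(bg), 200, replace = TRUE, prob = bg),
                       collapse = "")
    planted_at <- 120L  # 0-based
    seqstr <- paste0(substr(backbone, 1, planted_at), motif,
                     substr(backbone, planted_at + 1, 200))
    pm <- place_motif(seqstr, p)
    expect_true(pm$placed)
    expect_equal(pm$position, planted_at)
    expect_lt(pm$sequence_pvalue, 1e-6)
  })
})

test_that("placement equals a brute-force best-window oracle", {
  withr::with_seed(53, {
    bg <- dasp_background()
    p <- build_pssm(c("GGLGTR", "GGLGSR", "GGMGTR"), background = bg)
    for (rep in 1:5) {
      seqstr <- paste0(sample(names(bg), 80, replace = TRUE, prob = bg),
                       collapse = "")
      excl <- rbind(c(10L, 25L), c(50L, 58L))
      pm <- place_motif(seqstr, p, excluded = excl)
      # oracle: score every start, drop overlapping ones, take the best
      idx <- encode_sequence(seqstr)
      L <- p$length
      starts0 <- 0:(nchar(seqstr) - L)
      ok <- vapply(starts0, function(s) {
        all(s + L <= excl[, 1] | s >= excl[, 2])
      }, logical(1))
      sc <- vapply(starts0, function(s) {
        sum(ifelse(is.na(idx[s + 1:L]), 0, p$scores[cbind(idx[s + 1:L], 1:L)]))
      }, numeric(1))
      best <- starts0[ok][which.max(sc[ok])]
      expect_equal(pm$position, best)
      expect_equal(pm$n_windows, sum(ok))
      expect_equal(pm$window_pvalue, window_pvalue(max(sc[ok]), p$dist))
    }
  })
})

test_that("unplaceable motifs return the sentinel and tied scores go N-terminal", {
  bg <- dasp_background()
  p <- build_pssm(rep("HDAGWCEF", 3), background = bg)
  expect_warning(pm <- place_motif("ACD", p, quiet = FALSE), "no allowed")
  expect_false(pm$placed)
  expect_equal(pm$sequence_pvalue, 1)

  pa <- build_pssm(rep("AAAA", 3), background = bg)
  tie <- place_motif("AAAAAAAA", pa)
  expect_equal(tie$position, 0L)
})

test_that("greedy longest-first placement never overlaps and stays colinear on members", {
  spec <- family_spec(n_members = 5, substitution_rate = 0, seed = 57)
  fam <- generate_family(spec)
  prof <- build_profile(family_signatures(fam), fam$sequences)
  pssms <- profile_pssms(prof)
  man <- fam$manifest
  for (id in names(fam$sequences)) {
    r <- search_sequence(fam$sequences[[id]], pssms)
    pl <- r$placements[r$placements$placed, ]
    iv <- pl[order(pl$position), c("position", "length")]
    expect_true(all(diff(iv$position) >= iv$length[-nrow(iv)]))
    # every motif is recovered at its planted source interval
    mm <- man[man$protein_id == id, ]
    expect_equal(pl$position[order(pl$block)], mm$start[order(mm$motif)])
    expect_true(r$colinear)
    expect_lt(r$combined_pvalue, 1e-8)
  }
})

test_that("a sequence of concatenated motifs places every motif", {
  spec <- family_spec(n_members = 4, substitution_rate = 0, seed = 59)
  fam <- generate_family(spec)
  prof <- build_profile(family_signatures(fam), fam$sequences)
  pssms <- profile_pssms(prof)
  concat <- paste0(spec$motif_templates, collapse = "")
  r <- search_sequence(concat, pssms)
  expect_true(all(r$placements$placed))
  expect_lt(r$combined_pvalue, 1e-10)
})

test_that("database search reports members, handles degenerate databases", {
  fam <- generate_family(family_spec(n_members = 4, seed = 61))
  prof <- build_profile(family_signatures(fam), fam$sequences)
  res <- search_database(fam$sequences, prof)
  expect_equal(sort(tidy(res)$seq_id), sort(names(fam$sequences)))
  expect_equal(sum(res$histogram$count), 4L)

  short <- c(tiny = "ACDE")
  res2 <- search_database(short, prof)
  expect_equal(nrow(res2$reported), 0L)
  expect_equal(res2$histogram,
               tibble::tibble(log10_bin = 0L, count = 1L))
  expect_equal(res2$scores$combined_pvalue, 1)

  expect_error(search_database(character(0), prof), "Empty")

  dup <- setNames(fam$sequences[c(1, 1)], c("a", "a"))
  expect_warning(res3 <- search_database(dup, prof), "Duplicate")
  expect_equal(length(unique(res3$scores$seq_id)), 2L)
})

test_that("adding sequences never changes existing scores", {
  fam <- generate_family(family_spec(n_members = 4, seed = 67))
  prof <- build_profile(family_signatures(fam), fam$sequences)
  decoys <- generate_decoys(30, seed = 68)
  r1 <- search_database(fam$sequences, prof)
  r2 <- search_database(c(fam$sequences, decoys), prof)
  merged <- dplyr::left_join(r1$scores[, c("seq_id", "combined_pvalue")],
                             r2$scores[, c("seq_id", "combined_pvalue")],
                             by = "seq_id")
  expect_equal(merged$combined_pvalue.x, merged$combined_pvalue.y)
})

test_that("fragment order fraction counts colinear placements", {
  mk <- function(positions, lens = rep(5L, length(positions))) {
    tibble::tibble(block = seq_along(positions), length = lens,
                   position = positions, placed = !is.na(positions))
  }
  res <- tibble::tibble(
    seq_id = c("s1", "s2"),
    placements = list(mk(c(0L, 10L, 20L)), mk(c(10L, 0L, 20L)))
  )
  expect_equal(fragment_order_fraction(res), 0.5)
  res_ok <- tibble::tibble(seq_id = "s1", placements = list(mk(c(0L, 10L))))
  expect_equal(fragment_order_fraction(res_ok), 1)
  # restricting to long motifs can rescue colinearity
  res_mix <- tibble::tibble(
    seq_id = "s1",
    placements = list(mk(c(30L, 0L, 40L), lens = c(3L, 8L, 8L)))
  )
  expect_equal(fragment_order_fraction(res_mix), 0)
  expect_equal(fragment_order_fraction(res_mix, min_motif_len = 4), 1)
})

test_that("separation magnitude follows its definition, floor and flags", {
  fake <- function(scores, reported_ids) {
    structure(list(
      scores = scores,
      reported = scores[scores$seq_id %in% reported_ids, ]
    ), class = "dasp_search")
  }
  sc <- tibble::tibble(seq_id = c("m1", "m2", "d1"),
                       combined_pvalue = c(1e-12, 1e-10, 1e-6))
  s <- fake(sc, c("m1", "m2", "d1"))
  expect_equal(as.numeric(separation_magnitude(s, c("m1", "m2"))), 4)
  expect_equal(as.numeric(separation_magnitude(fake(sc[1:2, ], c("m1", "m2")),
                                               c("m1", "m2"))),
               log10(1.01e-5) - log10(1e-10))
  expect_warning(out <- separation_magnitude(s, c("m1", "missing")),
                 "missing")
  expect_lt(out, 0)
  expect_equal(attr(out, "missing_members"), "missing")
  expect_error(separation_magnitude(s, character(0)), "non-empty")
})

test_that("search outputs write deterministic TSV", {
  fam <- generate_family(family_spec(n_members = 4, seed = 71))
  prof <- build_profile(family_signatures(fam), fam$sequences)
  res <- search_database(c(fam$sequences, generate_decoys(5, seed = 72)), prof)
  f1 <- tempfile(); f2 <- tempfile()
  write_search_results(res, f1)
  write_histogram(res, f2)
  lines <- readLines(f1)
  expect_equal(lines[1], "rank\tseq_id\tcombined_pvalue\tmotifs\tcolinear")
  expect_equal(length(lines), nrow(res$reported) + 1L)
  expect_match(lines[2], "^1\tfam[0-9]+\t[0-9.]+e-[0-9]+\t1:[0-9]+:")
  h <- utils::read.delim(f2)
  expect_equal(sum(h$count), nrow(res$scores))
})
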