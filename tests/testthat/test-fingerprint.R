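test_that("fp_run evaluates detectors per residue pair and frame", {
  sides <- split_sides(make_hbond_pair(2.9, 180))
  res <- fp_run(sides$lig, sides$prot)
  expect_s3_class(res, "fingerprint_result")
  expect_equal(nrow(res$entries), 1L)
  expect_equal(res$entries$interaction, "HBDonor")
  expect_equal(res$entries$lig_res, "HOH1.A")
  expect_equal(res$entries$prot_res, "ACE2.B")
  # atom indices are retained, 0-based, parent-referenced
  expect_equal(res$entries$lig_atoms[[1]], c(0L, 1L))   # O and H1
  expect_equal(res$entries$prot_atoms[[1]], 0L)         # acceptor O

  # 0 frames: empty result with the interaction key intact
  empty <- fp_run(list(), list())
  expect_equal(length(empty$frames), 0L)
  expect_equal(empty$interaction_names, default_interactions())
  expect_equal(nrow(empty$entries), 0L)

  # identical frames give identical per-frame entry sets
  res3 <- fp_run(rep(list(sides$lig), 3), rep(list(sides$prot), 3))
  expect_equal(nrow(res3$entries), 3L)
  expect_equal(unique(res3$entries$interaction), "HBDonor")
  expect_equal(res3$entries$frame, 0:2)

  expect_error(fp_run(rep(list(sides$lig), 2), list(sides$prot)),
               "frame counts differ")
  expect_error(fp_run(sides$lig, sides$prot, interactions = "UnknownName"),
               "UnknownName")
})

test_that("intramolecular runs skip self-pairs", {
  s <- make_hbond_pair(2.9, 180)
  res <- fp_run(s, s)
  expect_false(any(res$entries$lig_res == res$entries$prot_res))
  # both directions of the donor/acceptor pair appear, as twins
  expect_setequal(res$entries$interaction, c("HBDonor", "HBAcceptor"))
})

test_that("the distance prefilter never changes results", {
  frames <- list(make_hbond_pair(2.9, 180), make_ion_pair(4.4),
                 make_ring_dimer(3.4, 0, 0), make_hbond_pair(3.4, 135),
                 make_ion_pair(15))
  for (s in frames) {
    sides <- split_sides(s)
    a <- fp_run(sides$lig, sides$prot, prefilter = TRUE)
    b <- fp_run(sides$lig, sides$prot, prefilter = FALSE)
    expect_equal(a$entries[, c("frame", "lig_res", "prot_res", "interaction")],
                 b$entries[, c("frame", "lig_res", "prot_res", "interaction")])
  }
})

test_that("to_bitvector exposes a fixed full-Cartesian layout", {
  sides <- split_sides(make_hbond_pair(2.9, 180))
  far <- split_sides(make_hbond_pair(4.9, 180))
  res <- fp_run(list(sides$lig, far$lig), list(sides$prot, far$prot))
  b0 <- to_bitvector(res, 0)
  b1 <- to_bitvector(res, 1)
  key <- attr(b0, "key")
  expect_equal(length(b0), length(default_interactions()))  # 1 lig x 1 prot
  expect_identical(key, attr(b1, "key"))                    # layout invariant
  expect_equal(sum(b0), 1L)
  expect_true(b0[key$interaction == "HBDonor"])
  expect_equal(sum(b1), 0L)                                 # all-false frame
  expect_error(to_bitvector(res, 99), "unknown frame")
})

test_that("to_table is consistent with bitvectors and entries", {
  sides <- split_sides(make_hbond_pair(2.9, 180))
  far <- split_sides(make_hbond_pair(4.9, 180))
  res <- fp_run(list(sides$lig, far$lig, sides$lig),
                list(sides$prot, far$prot, sides$prot))
  tab <- to_table(res)
  expect_equal(nrow(tab), 3L)
  expect_equal(names(tab), c("frame", "HOH1.A|ACE2.B|HBDonor"))
  expect_equal(tab[[2]], c(TRUE, FALSE, TRUE))
  # round trip against the bitvector view
  for (f in res$frames) {
    bits <- to_bitvector(res, f)
    key <- attr(bits, "key")
    for (col in names(tab)[-1]) {
      parts <- strsplit(col, "|", fixed = TRUE)[[1]]
      at <- which(key$lig_res == parts[1] & key$prot_res == parts[2] &
                    key$interaction == parts[3])
      expect_identical(unname(bits[at]), tab[tab$frame == f, col])
    }
  }
  # empty result: 0 interaction columns
  e <- fp_run(list(), list())
  expect_equal(dim(to_table(e)), c(0L, 1L))
})

test_that("frequencies count presence fractions exactly", {
  # 10-frame synthetic trajectory with known truth: H-bond in frames where
  # the geometry is within criteria
  ds <- c(2.8, 2.9, 3.0, 3.6, 3.2, 4.0, 3.4, 2.7, 3.9, 3.1)  # 7 within 3.5
  lig <- list(); prot <- list()
  for (d in ds) {
    sides <- split_sides(make_hbond_pair(d, 180))
    lig[[length(lig) + 1]] <- sides$lig
    prot[[length(prot) + 1]] <- sides$prot
  }
  res <- fp_run(lig, prot)
  fr <- frequencies(res)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$freq, 0.7)
  # aggregate per residue: any interaction
  fr_res <- frequencies(res, by = "residue")
  expect_equal(fr_res$freq, 0.7)
  # 2-of-4 and 4-of-4 cases
  near <- split_sides(make_hbond_pair(2.9, 180))
  farr <- split_sides(make_hbond_pair(4.9, 180))
  res2 <- fp_run(list(near$lig, farr$lig, near$lig, farr$lig),
                 list(near$prot, farr$prot, near$prot, farr$prot))
  expect_equal(frequencies(res2)$freq, 0.5)
  res3 <- fp_run(rep(list(near$lig), 4), rep(list(near$prot), 4))
  expect_equal(frequencies(res3)$freq, 1.0)
  expect_error(frequencies(fp_run(list(), list())), "0-frame")
})

test_that("frequencies are invariant under frame permutation", {
  rows <- data.frame(
    frame = c(0L, 2L, 3L, 0L, 1L),
    lig_res = "LIG1.L",
    prot_res = c("ALA1.A", "ALA1.A", "ALA1.A", "GLY2.A", "GLY2.A"),
    interaction = c("HBDonor", "HBDonor", "HBDonor", "Hydrophobic",
                    "Hydrophobic"), stringsAsFactors = FALSE)
  res <- mk_result(4L, rows)
  perm <- rows
  perm$frame <- 3L - rows$frame        # reverse the frame order
  res_p <- mk_result(4L, perm)
  expect_equal(frequencies(res)$freq, frequencies(res_p)$freq)
})

test_that("tanimoto_matrix follows set arithmetic", {
  near <- split_sides(make_hbond_pair(2.9, 180))
  farr <- split_sides(make_hbond_pair(4.9, 180))
  res <- fp_run(list(near$lig, near$lig, farr$lig),
                list(near$prot, near$prot, farr$prot))
  tm <- tanimoto_matrix(res)
  expect_equal(dim(tm), c(3L, 3L))
  expect_equal(diag(tm), c(`0` = 1, `1` = 1, `2` = 1))
  expect_equal(tm[1, 2], 1)          # identical frames
  expect_equal(tm[1, 3], 0)          # bits {HBDonor} vs {} -> 0/1
  expect_true(isSymmetric(unname(tm)))
  # empty-vs-empty convention is configurable
  tm0 <- tanimoto_matrix(fp_run(list(farr$lig, farr$lig),
                                list(farr$prot, farr$prot)), empty_value = 0)
  expect_equal(tm0[1, 2], 0)

  # closed-form {a,b} vs {b,c} = 1/3 on a constructed store
  rows <- data.frame(frame = c(0L, 0L, 1L, 1L), lig_res = "LIG1.L",
                     prot_res = c("ALA1.A", "GLY2.A", "GLY2.A", "SER3.A"),
                     interaction = "HBDonor", stringsAsFactors = FALSE)
  res_ab <- mk_result(2L, rows, prot_residues = c("ALA1.A", "GLY2.A", "SER3.A"))
  expect_equal(tanimoto_matrix(res_ab)[1, 2], 1 / 3)
})

test_that("tanimoto_matrix agrees with brute-force set arithmetic", {
  set.seed(99)
  n_bits <- 12L
  residues <- sprintf("RES%d.A", seq_len(n_bits))
  for (rep in 1:25) {
    n_frames <- 4L
    rows <- do.call(rbind, lapply(seq_len(n_frames) - 1L, function(f) {
      on <- residues[runif(n_bits) < 0.4]
      if (!length(on)) return(NULL)
      data.frame(frame = f, lig_res = "LIG1.L", prot_res = on,
                 interaction = "Hydrophobic", stringsAsFactors = FALSE)
    }))
    if (is.null(rows)) next
    res <- mk_result(n_frames, rows, prot_residues = residues)
    tm <- tanimoto_matrix(res)
    for (i in seq_len(n_frames)) for (j in seq_len(n_frames)) {
      bi <- to_bitvector(res, i - 1L); bj <- to_bitvector(res, j - 1L)
      expect_equal(unname(tm[i, j]), o_tanimoto(bi, bj), info = paste(rep, i, j))
    }
    expect_true(all(tm >= 0 & tm <= 1))
  }
})

test_that("CSV export is deterministic and complete", {
  sides <- split_sides(make_hbond_pair(2.9, 180))
  res <- fp_run(list(sides$lig, sides$lig), list(sides$prot, sides$prot))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  fp_to_csv(res, p1)
  fp_to_csv(res, p2)
  expect_identical(readLines(p1), readLines(p2))
  tab <- utils::read.csv(p1)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$interaction, rep("HBDonor", 2))
  expect_equal(tab$lig_atoms, rep("0;1", 2))
})
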