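defs <- builtin_interactions()

present <- function(name, s, swap = FALSE) {
  fr <- fragment_by_residue(s)
  if (swap) detect(defs[[name]], fr[[2]], fr[[1]])$present
  else detect(defs[[name]], fr[[1]], fr[[2]])$present
}

test_that("distance-only detectors honour their inclusive cutoffs", {
  expect_true(present("Anionic", make_ion_pair(4.4)))
  expect_true(present("Anionic", make_ion_pair(4.5)))    # boundary inclusive
  expect_false(present("Anionic", make_ion_pair(4.6)))
  expect_true(present("Cationic", make_ion_pair(4.4), swap = TRUE))

  ms <- make_metal_site(2.7)
  fr <- fragment_by_residue(ms)
  r <- detect(defs$MetalDonor, fr[[1]], fr[[2]])
  expect_true(r$present)
  expect_equal(r$ligand_atoms, 0L)       # the Mg
  expect_equal(r$protein_atoms, 1L)      # the carbonyl O (parent index 1)
  expect_false(present("MetalDonor", make_metal_site(2.9)))

  expect_true(present("Hydrophobic", make_hydrophobic_pair(4.5)))
  expect_false(present("Hydrophobic", make_hydrophobic_pair(4.6)))

  bad <- interaction_definition("X", "distance", "NoSuchPattern",
                                "Cation", 4.5)
  fr <- fragment_by_residue(make_ion_pair(4.0))
  expect_error(detect(bad, fr[[1]], fr[[2]]), "NoSuchPattern")
})

test_that("hydrogen bonds need both the D-A distance and the DHA angle", {
  expect_true(present("HBDonor", make_hbond_pair(2.9, 180)))
  expect_false(present("HBDonor", make_hbond_pair(2.9, 120)))
  expect_false(present("HBDonor", make_hbond_pair(3.6, 180)))
  expect_true(present("HBDonor", make_hbond_pair(3.5, 180)))   # boundary
  expect_true(present("HBDonor", make_hbond_pair(3.0, 130)))   # boundary
  # role-swapped twin sees the same geometry from the acceptor side
  expect_true(present("HBAcceptor", make_hbond_pair(2.9, 180), swap = TRUE))
  # donor heavy atoms without any bonded H are skipped, not an error
  s <- make_hbond_pair(2.9, 180)
  fr <- fragment_by_residue(s)
  expect_false(detect(defs$HBDonor, fr[[2]], fr[[1]])$present)
})

test_that("halogen bonds apply both angular windows", {
  expect_true(present("XBDonor", make_xbond_pair(3.2, 175, 110)))
  expect_false(present("XBDonor", make_xbond_pair(3.2, 175, 70)))
  expect_false(present("XBDonor", make_xbond_pair(3.2, 175, 150)))
  expect_false(present("XBDonor", make_xbond_pair(3.2, 120, 110)))
  expect_false(present("XBDonor", make_xbond_pair(3.6, 175, 110)))
  expect_true(present("XBDonor", make_xbond_pair(3.5, 175, 110)))  # boundary
  expect_true(present("XBDonor", make_xbond_pair(3.2, 175, 80)))   # boundary
  expect_true(present("XBAcceptor", make_xbond_pair(3.2, 175, 110),
                      swap = TRUE))
})

test_that("stacking variants split by centroid distance and plane angle", {
  # parallel-displaced: gap 2.5, ctd-ctd 5.9
  off <- sqrt(5.9^2 - 2.5^2)
  s <- make_ring_dimer(2.5, off, 0)
  expect_true(present("PiStacking", s))
  expect_false(present("EdgeToFace", s))   # angle 0 outside [50, 90]
  expect_false(present("FaceToFace", s))   # ctd 5.9 > 4.5

  # T-shaped: normal angle 90, ctd 4.7 -> the rims approach within 3.8
  t_shape <- make_ring_dimer(4.7, 0, 90)
  fr <- fragment_by_residue(t_shape)
  mind <- min_pairwise_distance(o_coords(fr[[1]])[1:6, ],
                                o_coords(fr[[2]])[1:6, ])
  expect_lte(mind, 3.8)
  expect_true(present("EdgeToFace", t_shape))
  expect_true(present("PiStacking", t_shape))
  expect_false(present("FaceToFace", t_shape))

  # cofacial sandwich: min distance equals the gap for aligned atoms
  expect_false(present("FaceToFace", make_ring_dimer(4.0, 0, 0)))  # min 4.0
  expect_true(present("FaceToFace", make_ring_dimer(3.7, 0, 0)))
  # FaceToFace implies PiStacking (strictly tighter constraints)
  for (gap in c(3.2, 3.5, 3.8)) for (off in c(0, 1, 2)) {
    s <- make_ring_dimer(gap, off, 0)
    if (present("FaceToFace", s)) expect_true(present("PiStacking", s))
  }
})

test_that("pi-cation requires distance and the folded normal angle", {
  expect_true(present("CationPi", make_pication(4.0, 0), swap = TRUE))
  expect_false(present("CationPi", make_pication(4.0, 90), swap = TRUE))
  expect_false(present("CationPi", make_pication(4.6, 0), swap = TRUE))
  expect_true(present("CationPi", make_pication(4.5, 0), swap = TRUE))
  expect_true(present("CationPi", make_pication(4.0, 30), swap = TRUE))
  expect_false(present("CationPi", make_pication(4.0, 30.5), swap = TRUE))
  # PiCation is the role-swapped twin
  expect_true(present("PiCation", make_pication(4.0, 0)))
})

test_that("vdW contact uses radii sums with an additive tolerance", {
  tab <- load_vdw_table()
  pair_at <- function(d) fragment_by_residue(make_hydrophobic_pair(d))
  fr <- pair_at(3.9)
  expect_true(detect_vdw_contact(fr[[1]], fr[[2]], tab)$present)   # 3.9 <= 4.0
  fr <- pair_at(4.1)
  expect_false(detect_vdw_contact(fr[[1]], fr[[2]], tab)$present)  # 4.1 > 4.0
  # tolerance 0, distance exactly r1 + r2: inclusive boundary
  fr <- pair_at(3.4)
  expect_true(detect_vdw_contact(fr[[1]], fr[[2]], tab, tolerance = 0)$present)
})

test_that("configure returns a modified copy and validates inputs", {
  hb <- defs$HBDonor
  wide <- configure(hb, list(distance_max = 4.1))
  fr <- fragment_by_residue(make_hbond_pair(3.8, 180))
  expect_true(detect(wide, fr[[1]], fr[[2]])$present)
  expect_false(detect(hb, fr[[1]], fr[[2]])$present)    # original untouched
  same <- configure(hb, list())
  for (s in list(make_hbond_pair(2.9, 180), make_hbond_pair(3.4, 140),
                 make_hbond_pair(3.6, 180))) {
    fr <- fragment_by_residue(s)
    expect_equal(detect(same, fr[[1]], fr[[2]])$present,
                 detect(hb, fr[[1]], fr[[2]])$present)
  }
  expect_error(configure(hb, list(distance_max = -1)), "> 0")
  expect_error(configure(hb, list(nonsense = 1)), "unknown override")
})

test_that("custom interactions plug into the registry and fingerprint", {
  close_contact <- function(lig, prot) {
    cl <- as.matrix(lig$atoms[, c("x", "y", "z")])
    cp <- as.matrix(prot$atoms[, c("x", "y", "z")])
    for (i in seq_len(nrow(cl))) for (j in seq_len(nrow(cp))) {
      if (sqrt(sum((cl[i, ] - cp[j, ])^2)) <= 3.0) {
        return(detection_result(TRUE, lig$parent_indices[i],
                                prot$parent_indices[j]))
      }
    }
    detection_result(FALSE)
  }
  reg <- register_interaction(builtin_interactions(), close_contact,
                              name = "CloseContact")
  sides <- split_sides(make_hbond_pair(2.9, 180))
  res <- fp_run(sides$lig, sides$prot, interactions = c("HBDonor", "CloseContact"),
                interaction_registry = reg)
  expect_true("CloseContact" %in% res$entries$interaction)

  # contract violation: present with empty atom lists
  broken <- function(lig, prot) {
    r <- detection_result(FALSE)
    r$present <- TRUE
    r
  }
  reg2 <- register_interaction(builtin_interactions(), broken, name = "Broken")
  fr <- fragment_by_residue(make_ion_pair(3.0))
  expect_error(detect(reg2$Broken, fr[[1]], fr[[2]]), "contract")

  expect_error(register_interaction(reg, close_contact, name = "CloseContact"),
               "already registered")
  # overwrite replaces behaviour
  never <- function(lig, prot) detection_result(FALSE)
  reg3 <- register_interaction(reg, never, name = "CloseContact",
                               overwrite = TRUE)
  expect_false(detect(reg3$CloseContact, fr[[1]], fr[[2]])$present)
})

test_that("role-swap twins agree under argument exchange", {
  twins <- list(c("HBDonor", "HBAcceptor"), c("XBDonor", "XBAcceptor"),
                c("Anionic", "Cationic"), c("CationPi", "PiCation"),
                c("MetalDonor", "MetalAcceptor"))
  battery <- list(
    make_hbond_pair(2.9, 180), make_hbond_pair(3.3, 150),
    make_xbond_pair(3.2, 175, 110), make_xbond_pair(3.0, 160, 95),
    make_ion_pair(4.0), make_ion_pair(5.0),
    make_metal_site(2.5), make_metal_site(3.0),
    make_pication(4.0, 10), make_pication(4.3, 45))
  seed <- 100L
  for (s in battery) {
    for (jit in list(NULL, 0.05, 0.15)) {
      sj <- if (is.null(jit)) s else jitter_structure(s, jit, seed <- seed + 1L)
      fr <- fragment_by_residue(sj)
      for (tw in twins) {
        a <- detect(defs[[tw[1]]], fr[[1]], fr[[2]])$present
        b <- detect(defs[[tw[2]]], fr[[2]], fr[[1]])$present
        expect_identical(a, b, info = paste(tw[1], "vs", tw[2]))
      }
    }
  }
})

test_that("scanning a single parameter flips presence exactly once", {
  flips <- function(vals) sum(diff(vals) != 0)
  # ionic distance scan
  pres <- vapply(seq(3.0, 6.0, by = 0.1),
                 function(d) present("Anionic", make_ion_pair(d)), TRUE)
  expect_equal(flips(pres), 1L)
  expect_true(pres[1]); expect_false(pres[length(pres)])
  # H-bond angle scan
  pres <- vapply(seq(100, 180, by = 1),
                 function(t) present("HBDonor", make_hbond_pair(3.0, t)), TRUE)
  expect_equal(flips(pres), 1L)
  expect_false(pres[1]); expect_true(pres[length(pres)])
  # stacking centroid scan at fixed gap
  pres <- vapply(seq(3.0, 7.0, by = 0.1), function(ctd) {
    off <- sqrt(max(0, ctd^2 - 2.5^2))
    present("PiStacking", make_ring_dimer(2.5, off, 0))
  }, TRUE)
  expect_equal(flips(pres), 1L)
})

test_that("detectors agree with the brute-force oracle on random fixtures", {
  tab <- load_vdw_table()
  set.seed(2024)
  n_cases <- 60L   # the full >= 200-case battery runs in test-acceptance.R
  for (i in seq_len(n_cases)) {
    kind <- sample(c("hbond", "xbond", "ion", "metal", "ring", "phobic"), 1)
    s <- switch(kind,
      hbond = make_hbond_pair(runif(1, 2.0, 4.5), runif(1, 95, 180)),
      xbond = make_xbond_pair(runif(1, 2.0, 4.5), runif(1, 90, 180),
                              runif(1, 40, 170)),
      ion = make_ion_pair(runif(1, 2.5, 6.0)),
      metal = make_metal_site(runif(1, 1.8, 3.5)),
      ring = make_ring_dimer(runif(1, 2.5, 5.0), runif(1, 0, 4),
                             runif(1, 0, 90)),
      phobic = make_hydrophobic_pair(runif(1, 3.0, 6.0)))
    s <- jitter_structure(s, sd = 0.08, seed = 3000L + i)
    fr <- fragment_by_residue(s)
    lf <- fr[[1]]; pf <- fr[[2]]
    expect_identical(detect(defs$HBDonor, lf, pf)$present,
                     o_detect_hbond(lf, pf), info = paste(kind, i))
    expect_identical(detect(defs$XBDonor, lf, pf)$present,
                     o_detect_xbond(lf, pf), info = paste(kind, i))
    expect_identical(detect(defs$Anionic, lf, pf)$present,
                     o_detect_distance(o_anions(lf), o_cations(pf), lf, pf, 4.5),
                     info = paste(kind, i))
    expect_identical(detect(defs$MetalDonor, lf, pf)$present,
                     o_detect_distance(o_metals(lf), o_metal_ligands(pf),
                                       lf, pf, 2.8), info = paste(kind, i))
    expect_identical(detect(defs$Hydrophobic, lf, pf)$present,
                     o_detect_distance(o_hydrophobics(lf), o_hydrophobics(pf),
                                       lf, pf, 4.5), info = paste(kind, i))
    expect_identical(detect(defs$PiStacking, lf, pf)$present,
                     o_detect_stacking(lf, pf, 6.0, c(0, 90)),
                     info = paste(kind, i))
    expect_identical(detect(defs$FaceToFace, lf, pf)$present,
                     o_detect_stacking(lf, pf, 4.5, c(0, 40)),
                     info = paste(kind, i))
    expect_identical(detect_vdw_contact(lf, pf, tab)$present,
                     o_detect_vdw(lf, pf, tab), info = paste(kind, i))
  }
})

test_that("fragments without a matching moiety yield absent, not errors", {
  fr <- fragment_by_residue(make_hydrophobic_pair(4.0))
  for (nm in c("Anionic", "HBDonor", "XBDonor", "PiStacking", "CationPi",
               "MetalDonor")) {
    expect_false(detect(defs[[nm]], fr[[1]], fr[[2]])$present, info = nm)
  }
})
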