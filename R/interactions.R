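# Geometric interaction detectors.  Each detector implements the "detect"
# contract: two residue fragments in, a detection result out (Boolean
# presence plus the 0-based parent atom indices responsible on each side).
#
# Conventions that matter:
#  * every distance/angle threshold is INCLUSIVE (<=, and closed angle
#    windows), with a 1e-9 numerical slack so a geometry constructed exactly
#    at a printed cutoff is detected;
#  * the H-bond angle is measured AT the hydrogen, between the H->D and
#    H->A vectors, so a linear D-H...A arrangement scores ~180 degrees;
#  * normal-vs-normal and normal-vs-direction angles are always folded to
#    [0, 90] before testing windows (ring normals have arbitrary sign);
#  * detectors stop at the first match pair satisfying all constraints under
#    the deterministic moiety match order; `all_pairs = TRUE` enumerates
#    every satisfying pair (used for atom-frequency statistics).

.in_window <- function(theta, lo, hi) {
  theta >= lo - .geom_eps & theta <= hi + .geom_eps
}

.le_cut <- function(d, cut) d <= cut + .geom_eps

#' Detection result constructor
#'
#' @param present logical scalar.
#' @param ligand_atoms,protein_atoms 0-based parent atom indices responsible
#'   for the interaction (empty when absent).
#' @return object of class `detection_result`.
#' @export
detection_result <- function(present = FALSE, ligand_atoms = integer(),
                             protein_atoms = integer()) {
  if (present && (!length(ligand_atoms) || !length(protein_atoms))) {
    stop("a present detection must name atoms on both sides")
  }
  if (!present) {
    ligand_atoms <- integer()
    protein_atoms <- integer()
  }
  structure(list(present = present,
                 ligand_atoms = as.integer(ligand_atoms),
                 protein_atoms = as.integer(protein_atoms)),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  if (x$present) {
    cat(sprintf("<detection> present  lig[%s]  prot[%s]\n",
                paste(x$ligand_atoms, collapse = ","),
                paste(x$protein_atoms, collapse = ",")))
  } else cat("<detection> absent\n")
  invisible(x)
}

.absent <- function() detection_result(FALSE)

# collect all satisfying (lig_atoms, prot_atoms) pairs or stop at the first
.collector <- function(all_pairs) {
  hits <- list()
  list(
    add = function(lig, prot) {
      hits[[length(hits) + 1L]] <<- list(lig = as.integer(lig),
                                         prot = as.integer(prot))
      !all_pairs          # TRUE -> caller may stop
    },
    result = function() {
      if (!length(hits)) return(.absent())
      r <- detection_result(TRUE, hits[[1L]]$lig, hits[[1L]]$prot)
      r$pairs <- hits
      r
    }
  )
}

#' Interaction definition
#'
#' Pairs two moiety roles with distance / angle constraints.  The bundled
#' default thresholds follow the standard geometric criteria (ionic and
#' hydrophobic 4.5 A; H-bond D-A 3.5 A with the D-H...A angle in
#' \[130, 180\]; halogen bond X-A 3.5 A with \[130, 180\] at X and
#' \[80, 140\] at A; metal coordination 2.8 A; stacking centroid cutoffs
#' 6.0 / 6.0 / 4.5 A with angle windows \[0,90\] / \[50,90\] / \[0,40\] and
#' a minimum ring-atom distance of 3.8 A).
#'
#' @param name interaction name.
#' @param kind detector kernel: one of "distance", "hbond", "xbond",
#'   "pi_stacking", "pi_cation", "vdw", "custom".
#' @param ligand_moiety,protein_moiety moiety pattern names.
#' @param distance_max distance cutoff in Angstrom (> 0).
#' @param angle_ranges named list of `c(lo, hi)` degree windows; which names
#'   are honoured depends on `kind` (see the detector functions).
#' @param symmetric_inverse name of the role-swapped twin, or NA.
#' @param swap_roles evaluate with ligand/protein roles exchanged (twins).
#' @param detect optional custom detector `function(lig, prot, ...)` for
#'   `kind = "custom"`.
#' @return object of class `interaction_definition`.
#' @export
interaction_definition <- function(name, kind, ligand_moiety = NA,
                                   protein_moiety = NA, distance_max = NULL,
                                   angle_ranges = list(),
                                   symmetric_inverse = NA,
                                   swap_roles = FALSE, detect = NULL) {
  if (!is.null(distance_max) && distance_max <= 0) {
    stop("distance_max must be > 0")
  }
  for (w in angle_ranges) {
    if (length(w) != 2L || w[1L] > w[2L] || w[1L] < 0 || w[2L] > 180) {
      stop("angle ranges must be [lo, hi] with 0 <= lo <= hi <= 180")
    }
  }
  structure(list(name = name, kind = kind,
                 ligand_moiety = ligand_moiety,
                 protein_moiety = protein_moiety,
                 distance_max = distance_max,
                 angle_ranges = angle_ranges,
                 symmetric_inverse = symmetric_inverse,
                 swap_roles = swap_roles,
                 detect = detect),
            class = "interaction_definition")
}

#' @export
print.interaction_definition <- function(x, ...) {
  cat(sprintf("<interaction> %s (%s): %s ~ %s, d <= %s\n", x$name, x$kind,
              x$ligand_moiety, x$protein_moiety,
              ifelse(is.null(x$distance_max), "vdW", x$distance_max)))
  invisible(x)
}

# ---- detector kernels -------------------------------------------------------

#' Distance-only detection (ionic, metal, hydrophobic)
#'
#' Present iff some (ligand-match atom, protein-match atom) pair lies within
#' `distance_max` (inclusive).
#'
#' @param defn an `interaction_definition` with `kind = "distance"`.
#' @param lig,prot `residue_fragment`s (ligand side first).
#' @param registry moiety pattern registry.
#' @param all_pairs report every satisfying pair (in `$pairs`), not just the
#'   first.
#' @return a `detection_result`.
#' @export
detect_distance_only <- function(defn, lig, prot,
                                 registry = builtin_patterns(),
                                 all_pairs = FALSE) {
  lm <- match_moiety(lig, defn$ligand_moiety, registry)
  pm <- match_moiety(prot, defn$protein_moiety, registry)
  if (!length(lm) || !length(pm)) return(.absent())
  cl <- .frag_coords(lig); cp <- .frag_coords(prot)
  coll <- .collector(all_pairs)
  for (a in lm) for (b in pm) {
    d <- .dist3(cl[a[1L] + 1L, ], cp[b[1L] + 1L, ])
    if (.le_cut(d, defn$distance_max)) {
      if (coll$add(lig$parent_indices[a[1L] + 1L],
                   prot$parent_indices[b[1L] + 1L])) {
        return(coll$result())
      }
    }
  }
  coll$result()
}

#' Hydrogen-bond detection
#'
#' Present iff the donor-heavy-atom to acceptor distance is within the D-A
#' cutoff (default 3.5 A) AND the angle at the hydrogen between H->D and
#' H->A lies in the `DHA` window (default \[130, 180\] degrees).  The donor
#' side is whichever fragment carries the donor moiety: the ligand for the
#' HBDonor interaction, the protein for its HBAcceptor twin
#' (`swap_roles = TRUE`).
#'
#' @inheritParams detect_distance_only
#' @export
detect_hbond <- function(defn, lig, prot, registry = builtin_patterns(),
                         all_pairs = FALSE) {
  swapped <- isTRUE(defn$swap_roles)
  don_frag <- if (swapped) prot else lig
  acc_frag <- if (swapped) lig else prot
  dm <- match_moiety(don_frag, "HBDonor", registry)
  am <- match_moiety(acc_frag, "HBAcceptor", registry)
  if (!length(dm) || !length(am)) return(.absent())
  cd <- .frag_coords(don_frag); ca <- .frag_coords(acc_frag)
  win <- defn$angle_ranges$DHA %||% c(130, 180)
  coll <- .collector(all_pairs)
  for (dh in dm) {
    D <- cd[dh[1L] + 1L, ]; H <- cd[dh[2L] + 1L, ]
    for (aa in am) {
      A <- ca[aa[1L] + 1L, ]
      if (!.le_cut(.dist3(D, A), defn$distance_max)) next
      theta <- angle_between(D - H, A - H)
      if (.in_window(theta, win[1L], win[2L])) {
        don_atoms <- don_frag$parent_indices[dh + 1L]
        acc_atoms <- acc_frag$parent_indices[aa[1L] + 1L]
        stop_now <- if (swapped) coll$add(acc_atoms, don_atoms)
                    else coll$add(don_atoms, acc_atoms)
        if (stop_now) return(coll$result())
      }
    }
  }
  coll$result()
}

#' Halogen-bond detection
#'
#' Present iff the halogen to acceptor distance is within the X-A cutoff
#' (default 3.5 A) AND the angle at X between X->D and X->A lies in the
#' `XDA` window (default \[130, 180\]) AND the angle at the acceptor between
#' A->X and A->R lies in the `AXR` window (default \[80, 140\]).  Both angle
#' windows constrain one geometry and are always applied together.
#'
#' @inheritParams detect_distance_only
#' @export
detect_xbond <- function(defn, lig, prot, registry = builtin_patterns(),
                         all_pairs = FALSE) {
  swapped <- isTRUE(defn$swap_roles)
  don_frag <- if (swapped) prot else lig
  acc_frag <- if (swapped) lig else prot
  dm <- match_moiety(don_frag, "XBDonor", registry)    # (D, X)
  am <- match_moiety(acc_frag, "XBAcceptor", registry) # (A, R)
  if (!length(dm) || !length(am)) return(.absent())
  cd <- .frag_coords(don_frag); ca <- .frag_coords(acc_frag)
  win_x <- defn$angle_ranges$XDA %||% c(130, 180)
  win_a <- defn$angle_ranges$AXR %||% c(80, 140)
  coll <- .collector(all_pairs)
  for (dx in dm) {
    D <- cd[dx[1L] + 1L, ]; X <- cd[dx[2L] + 1L, ]
    for (ar in am) {
      A <- ca[ar[1L] + 1L, ]; R <- ca[ar[2L] + 1L, ]
      if (!.le_cut(.dist3(X, A), defn$distance_max)) next
      ang_x <- angle_between(D - X, A - X)
      if (!.in_window(ang_x, win_x[1L], win_x[2L])) next
      ang_a <- angle_between(X - A, R - A)
      if (!.in_window(ang_a, win_a[1L], win_a[2L])) next
      don_atoms <- don_frag$parent_indices[dx + 1L]
      acc_atoms <- acc_frag$parent_indices[ar + 1L]
      stop_now <- if (swapped) coll$add(acc_atoms, don_atoms)
                  else coll$add(don_atoms, acc_atoms)
      if (stop_now) return(coll$result())
    }
  }
  coll$result()
}

#' Aromatic stacking detection
#'
#' Three independent variants sharing one kernel, distinguished by the
#' centroid-centroid cutoff and the folded inter-normal angle window:
#' PiStacking (ctd <= 6.0 A, angle \[0, 90\]), EdgeToFace (ctd <= 6.0 A,
#' angle \[50, 90\]) and FaceToFace (ctd <= 4.5 A, angle \[0, 40\]).  All
#' additionally require the minimum interatomic distance between the two
#' rings to be <= 3.8 A (the `min_distance` entry of `angle_ranges` is not
#' an angle; it is carried in the definition as `min_distance_max`).
#' Reported atoms are the full ring atom sets on each side.
#'
#' @inheritParams detect_distance_only
#' @export
detect_pi_stacking <- function(defn, lig, prot,
                               registry = builtin_patterns(),
                               all_pairs = FALSE) {
  lr <- match_moiety(lig, "Aromatic", registry)
  pr <- match_moiety(prot, "Aromatic", registry)
  if (!length(lr) || !length(pr)) return(.absent())
  win <- defn$angle_ranges$planes %||% c(0, 90)
  min_max <- defn$min_distance_max %||% 3.8
  coll <- .collector(all_pairs)
  for (r1 in lr) {
    p1 <- .frag_coords(lig, r1)
    c1 <- centroid(p1); n1 <- ring_normal(p1)
    for (r2 in pr) {
      p2 <- .frag_coords(prot, r2)
      c2 <- centroid(p2); n2 <- ring_normal(p2)
      if (!.le_cut(.dist3(c1, c2), defn$distance_max)) next
      theta <- angle_between(n1, n2, fold_to_90 = TRUE)
      if (!.in_window(theta, win[1L], win[2L])) next
      if (!.le_cut(min_pairwise_distance(p1, p2), min_max)) next
      if (coll$add(lig$parent_indices[r1 + 1L],
                   prot$parent_indices[r2 + 1L])) {
        return(coll$result())
      }
    }
  }
  coll$result()
}

#' Cation-pi / pi-cation detection
#'
#' Present iff the cation atom lies within `distance_max` (default 4.5 A) of
#' an aromatic ring centroid AND the folded angle between the ring normal
#' and the centroid->cation vector lies in the `normal_ctd` window (default
#' \[0, 30\] degrees).  When a fragment holds several rings, any ring may
#' satisfy the criterion.  The cation side is the ligand for CationPi and
#' the protein for the PiCation twin.
#'
#' @inheritParams detect_distance_only
#' @export
detect_pi_cation <- function(defn, lig, prot, registry = builtin_patterns(),
                             all_pairs = FALSE) {
  swapped <- isTRUE(defn$swap_roles)   # TRUE: ligand is the aromatic side
  cat_frag <- if (swapped) prot else lig
  aro_frag <- if (swapped) lig else prot
  cm <- match_moiety(cat_frag, "Cation", registry)
  rm_ <- match_moiety(aro_frag, "Aromatic", registry)
  if (!length(cm) || !length(rm_)) return(.absent())
  cc <- .frag_coords(cat_frag)
  win <- defn$angle_ranges$normal_ctd %||% c(0, 30)
  coll <- .collector(all_pairs)
  for (cidx in cm) {
    P <- cc[cidx[1L] + 1L, ]
    for (ring in rm_) {
      pts <- .frag_coords(aro_frag, ring)
      ctd <- centroid(pts)
      if (!.le_cut(.dist3(P, ctd), defn$distance_max)) next
      n <- ring_normal(pts)
      theta <- angle_between(n, P - ctd, fold_to_90 = TRUE)
      if (!.in_window(theta, win[1L], win[2L])) next
      cat_atoms <- cat_frag$parent_indices[cidx[1L] + 1L]
      aro_atoms <- aro_frag$parent_indices[ring + 1L]
      stop_now <- if (swapped) coll$add(aro_atoms, cat_atoms)
                  else coll$add(cat_atoms, aro_atoms)
      if (stop_now) return(coll$result())
    }
  }
  coll$result()
}

#' van der Waals contact detection
#'
#' Two residues are in contact if any interatomic distance is below or equal
#' to the sum of the two atoms' van der Waals radii plus a tolerance factor
#' (0.6 A by default).
#'
#' @param lig,prot `residue_fragment`s.
#' @param table a `vdw_table` (see [load_vdw_table()]).
#' @param tolerance additive tolerance in Angstrom.
#' @param all_pairs report every contacting pair.
#' @return a `detection_result`.
#' @export
detect_vdw_contact <- function(lig, prot, table = load_vdw_table(),
                               tolerance = 0.6, all_pairs = FALSE) {
  cl <- .frag_coords(lig); cp <- .frag_coords(prot)
  rl <- .vdw_lookup(lig$atoms$element, table)
  rp <- .vdw_lookup(prot$atoms$element, table)
  coll <- .collector(all_pairs)
  for (i in seq_len(nrow(cl))) for (j in seq_len(nrow(cp))) {
    if (.le_cut(.dist3(cl[i, ], cp[j, ]), rl[i] + rp[j] + tolerance)) {
      if (coll$add(lig$parent_indices[i], prot$parent_indices[j])) {
        return(coll$result())
      }
    }
  }
  coll$result()
}

# ---- registry and configuration ---------------------------------------------

#' Built-in interaction registry
#'
#' All available interaction definitions.  The default fingerprint set (see
#' [default_interactions()]) is Hydrophobic, PiStacking, PiCation, CationPi,
#' Anionic, Cationic, HBDonor and HBAcceptor; EdgeToFace, FaceToFace, the
#' halogen-bond and metal interactions and VdWContact are available but off
#' by default.
#'
#' @return named list of `interaction_definition` objects.
#' @export
builtin_interactions <- function() {
  defs <- list(
    interaction_definition("Anionic", "distance", "Anion", "Cation", 4.5,
                           symmetric_inverse = "Cationic"),
    interaction_definition("Cationic", "distance", "Cation", "Anion", 4.5,
                           symmetric_inverse = "Anionic"),
    interaction_definition("CationPi", "pi_cation", "Cation", "Aromatic", 4.5,
                           angle_ranges = list(normal_ctd = c(0, 30)),
                           symmetric_inverse = "PiCation"),
    interaction_definition("PiCation", "pi_cation", "Aromatic", "Cation", 4.5,
                           angle_ranges = list(normal_ctd = c(0, 30)),
                           symmetric_inverse = "CationPi", swap_roles = TRUE),
    interaction_definition("PiStacking", "pi_stacking", "Aromatic", "Aromatic",
                           6.0, angle_ranges = list(planes = c(0, 90))),
    interaction_definition("EdgeToFace", "pi_stacking", "Aromatic", "Aromatic",
                           6.0, angle_ranges = list(planes = c(50, 90))),
    interaction_definition("FaceToFace", "pi_stacking", "Aromatic", "Aromatic",
                           4.5, angle_ranges = list(planes = c(0, 40))),
    interaction_definition("HBDonor", "hbond", "HBDonor", "HBAcceptor", 3.5,
                           angle_ranges = list(DHA = c(130, 180)),
                           symmetric_inverse = "HBAcceptor"),
    interaction_definition("HBAcceptor", "hbond", "HBAcceptor", "HBDonor", 3.5,
                           angle_ranges = list(DHA = c(130, 180)),
                           symmetric_inverse = "HBDonor", swap_roles = TRUE),
    interaction_definition("XBDonor", "xbond", "XBDonor", "XBAcceptor", 3.5,
                           angle_ranges = list(XDA = c(130, 180),
                                               AXR = c(80, 140)),
                           symmetric_inverse = "XBAcceptor"),
    interaction_definition("XBAcceptor", "xbond", "XBAcceptor", "XBDonor", 3.5,
                           angle_ranges = list(XDA = c(130, 180),
                                               AXR = c(80, 140)),
                           symmetric_inverse = "XBDonor", swap_roles = TRUE),
    interaction_definition("MetalDonor", "distance", "Metal", "MetalLigand",
                           2.8, symmetric_inverse = "MetalAcceptor"),
    interaction_definition("MetalAcceptor", "distance", "MetalLigand", "Metal",
                           2.8, symmetric_inverse = "MetalDonor"),
    interaction_definition("Hydrophobic", "distance", "Hydrophobic",
                           "Hydrophobic", 4.5),
    interaction_definition("VdWContact", "vdw")
  )
  defs <- lapply(defs, function(d) {
    if (d$kind == "pi_stacking") d$min_distance_max <- 3.8
    d
  })
  stats::setNames(defs, vapply(defs, `[[`, "", "name"))
}

#' Default interaction set for the fingerprint engine
#' @return character vector of interaction names.
#' @export
default_interactions <- function() {
  c("Hydrophobic", "PiStacking", "PiCation", "CationPi",
    "Anionic", "Cationic", "HBDonor", "HBAcceptor")
}

#' Reconfigure an interaction definition
#'
#' Returns a modified copy; the original is untouched.  There is no firm
#' consensus on empirical interaction thresholds, so every cutoff and window
#' is overridable (e.g. redefining the H-bond D-A cutoff to 4.1 A).
#'
#' @param defn an `interaction_definition`.
#' @param overrides named list; keys among `distance_max`, `angle_ranges`,
#'   `min_distance_max`, `ligand_moiety`, `protein_moiety`.
#' @return new `interaction_definition`.
#' @export
configure <- function(defn, overrides = list()) {
  stopifnot(inherits(defn, "interaction_definition"))
  allowed <- c("distance_max", "angle_ranges", "min_distance_max",
               "ligand_moiety", "protein_moiety")
  bad <- setdiff(names(overrides), allowed)
  if (length(bad)) stop("unknown override key(s): ", paste(bad, collapse = ", "))
  out <- defn
  for (k in names(overrides)) out[[k]] <- overrides[[k]]
  if (!is.null(out$distance_max) && out$distance_max <= 0) {
    stop("distance_max must be > 0")
  }
  for (w in out$angle_ranges) {
    if (length(w) != 2L || w[1L] > w[2L] || w[1L] < 0 || w[2L] > 180) {
      stop("angle ranges must be [lo, hi] with 0 <= lo <= hi <= 180")
    }
  }
  class(out) <- "interaction_definition"
  out
}

#' Register an interaction
#'
#' Adds a built-in-style definition or a fully custom detector to an
#' interaction registry; the fingerprint engine then evaluates it under its
#' name.  A custom detector is a `function(lig, prot, ...)` returning a
#' `detection_result` (wrapped via `kind = "custom"`).
#'
#' @param registry named list of definitions.
#' @param defn an `interaction_definition`, or a detect function.
#' @param name required when `defn` is a bare function.
#' @param overwrite allow replacing an existing name?
#' @return the updated registry.
#' @export
register_interaction <- function(registry, defn, name = NULL,
                                 overwrite = FALSE) {
  if (is.function(defn)) {
    if (is.null(name)) stop("a custom detector function needs a name")
    defn <- interaction_definition(name, "custom", detect = defn)
  }
  stopifnot(inherits(defn, "interaction_definition"))
  if (defn$name %in% names(registry) && !overwrite) {
    stop("interaction '", defn$name,
         "' already registered (use overwrite = TRUE)")
  }
  registry[[defn$name]] <- defn
  registry
}

#' Run one interaction detector on a fragment pair
#'
#' Dispatches on the definition's kernel kind and validates the detect
#' contract (a present result must name atoms on both sides).
#'
#' @inheritParams detect_distance_only
#' @param vdw_table,vdw_tolerance forwarded to [detect_vdw_contact()].
#' @return a `detection_result`.
#' @export
detect <- function(defn, lig, prot, registry = builtin_patterns(),
                   all_pairs = FALSE, vdw_table = NULL, vdw_tolerance = 0.6) {
  res <- switch(defn$kind,
    distance    = detect_distance_only(defn, lig, prot, registry, all_pairs),
    hbond       = detect_hbond(defn, lig, prot, registry, all_pairs),
    xbond       = detect_xbond(defn, lig, prot, registry, all_pairs),
    pi_stacking = detect_pi_stacking(defn, lig, prot, registry, all_pairs),
    pi_cation   = detect_pi_cation(defn, lig, prot, registry, all_pairs),
    vdw         = detect_vdw_contact(lig, prot,
                                     table = vdw_table %||% load_vdw_table(),
                                     tolerance = vdw_tolerance,
                                     all_pairs = all_pairs),
    custom      = defn$detect(lig, prot),
    stop("unknown interaction kind: ", defn$kind)
  )
  if (!inherits(res, "detection_result")) {
    stop("detector '", defn$name, "' violated the detect contract: ",
         "must return a detection_result")
  }
  if (res$present && (!length(res$ligand_atoms) || !length(res$protein_atoms))) {
    stop("detector '", defn$name, "' violated the detect contract: ",
         "present result with empty atom list")
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
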