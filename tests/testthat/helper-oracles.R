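# Independent brute-force oracles.  These re-derive moiety matches and
# geometry from the atom tables with naive loops and direct formulas; they
# share no code with the package detectors beyond the data structures.

o_dist <- function(p, q) sqrt(sum((p - q)^2))

o_angle_at <- function(vertex, a, b) {
  u <- a - vertex; v <- b - vertex
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, ct))) * 180 / pi
}

o_fold90 <- function(theta) if (theta > 90) 180 - theta else theta

o_coords <- function(frag) as.matrix(frag$atoms[, c("x", "y", "z")])

o_neighbours <- function(frag, i0) {
  b <- frag$bonds
  if (!nrow(b)) return(integer())
  unique(c(b[b[, 1] == i0, 2], b[b[, 2] == i0, 1]))
}

# least-squares plane normal via eigen-decomposition of the covariance
o_plane_normal <- function(pts) {
  centred <- sweep(pts, 2, colMeans(pts))
  ev <- eigen(crossprod(centred), symmetric = TRUE)
  ev$vectors[, 3]
}

# all rings of the given size among aromatic atoms, by exhaustive subset
# enumeration: a subset is a ring iff every member has exactly 2 bonded
# neighbours inside the subset and the subset is connected
o_aromatic_rings <- function(frag, size) {
  arom <- which(frag$atoms$is_aromatic) - 1L
  if (length(arom) < size) return(list())
  combos <- utils::combn(arom, size, simplify = FALSE)
  Filter(function(sub) {
    degs <- vapply(sub, function(i) length(intersect(o_neighbours(frag, i), sub)), 0L)
    if (!all(degs == 2L)) return(FALSE)
    # connectivity walk
    seen <- sub[1]; frontier <- sub[1]
    while (length(frontier)) {
      nxt <- setdiff(intersect(unlist(lapply(frontier, o_neighbours, frag = frag)), sub), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    length(seen) == size
  }, combos)
}

o_rings <- function(frag) {
  rings <- c(o_aromatic_rings(frag, 6L), o_aromatic_rings(frag, 5L))
  keys <- vapply(rings, function(r) paste(sort(r), collapse = ","), "")
  rings[!duplicated(keys)]
}

o_anions  <- function(frag) which(frag$atoms$formal_charge <= -1L) - 1L
o_cations <- function(frag) which(frag$atoms$formal_charge >= 1L) - 1L
o_metals  <- function(frag) which(frag$atoms$element %in%
  c("Ca", "Cd", "Co", "Cu", "Fe", "Mg", "Mn", "Ni", "Zn")) - 1L
o_metal_ligands <- function(frag) which(
  (frag$atoms$element %in% c("O", "N") | frag$atoms$formal_charge <= -1L) &
    frag$atoms$formal_charge < 1L) - 1L
o_hydrophobics <- function(frag) which(
  (frag$atoms$element %in% c("C", "S", "F", "Cl", "Br", "I", "At")) &
    frag$atoms$formal_charge == 0L) - 1L
o_hb_acceptors <- function(frag) which(
  (frag$atoms$element %in% c("N", "O", "F") | frag$atoms$formal_charge <= -1L) &
    frag$atoms$formal_charge < 1L) - 1L

o_hb_donors <- function(frag) {
  out <- list()
  for (d in which(frag$atoms$element %in% c("N", "O", "S")) - 1L) {
    for (h in o_neighbours(frag, d)) {
      if (frag$atoms$element[h + 1] == "H") out[[length(out) + 1]] <- c(d, h)
    }
  }
  out
}

o_xb_donors <- function(frag) {
  out <- list()
  for (d in which(frag$atoms$element %in% c("C", "N", "Si", "F", "Cl", "Br", "I")) - 1L) {
    for (x in o_neighbours(frag, d)) {
      if (frag$atoms$element[x + 1] %in% c("Cl", "Br", "I", "At")) {
        out[[length(out) + 1]] <- c(d, x)
      }
    }
  }
  out
}

o_xb_acceptors <- function(frag) {
  out <- list()
  acc <- which((frag$atoms$element %in% c("N", "O", "P", "S", "Se", "Te") |
                  frag$atoms$is_aromatic) & frag$atoms$formal_charge < 1L) - 1L
  for (a in acc) for (r in o_neighbours(frag, a)) {
    out[[length(out) + 1]] <- c(a, r)
  }
  out
}

# naive presence-only detectors -----------------------------------------------

o_detect_distance <- function(lig_idx, prot_idx, lig, prot, cutoff) {
  cl <- o_coords(lig); cp <- o_coords(prot)
  for (i in lig_idx) for (j in prot_idx) {
    if (o_dist(cl[i + 1, ], cp[j + 1, ]) <= cutoff) return(TRUE)
  }
  FALSE
}

o_detect_hbond <- function(don, acc, cutoff = 3.5, window = c(130, 180)) {
  cd <- o_coords(don); ca <- o_coords(acc)
  for (dh in o_hb_donors(don)) for (a in o_hb_acceptors(acc)) {
    D <- cd[dh[1] + 1, ]; H <- cd[dh[2] + 1, ]; A <- ca[a + 1, ]
    if (o_dist(D, A) <= cutoff &&
        o_angle_at(H, D, A) >= window[1] && o_angle_at(H, D, A) <= window[2]) {
      return(TRUE)
    }
  }
  FALSE
}

o_detect_xbond <- function(don, acc, cutoff = 3.5,
                           win_x = c(130, 180), win_a = c(80, 140)) {
  cd <- o_coords(don); ca <- o_coords(acc)
  for (dx in o_xb_donors(don)) for (ar in o_xb_acceptors(acc)) {
    D <- cd[dx[1] + 1, ]; X <- cd[dx[2] + 1, ]
    A <- ca[ar[1] + 1, ]; R <- ca[ar[2] + 1, ]
    ax <- o_angle_at(X, D, A); aa <- o_angle_at(A, X, R)
    if (o_dist(X, A) <= cutoff &&
        ax >= win_x[1] && ax <= win_x[2] &&
        aa >= win_a[1] && aa <= win_a[2]) return(TRUE)
  }
  FALSE
}

o_detect_stacking <- function(lig, prot, ctd_cut, win, min_cut = 3.8) {
  for (r1 in o_rings(lig)) for (r2 in o_rings(prot)) {
    p1 <- o_coords(lig)[r1 + 1, , drop = FALSE]
    p2 <- o_coords(prot)[r2 + 1, , drop = FALSE]
    c1 <- colMeans(p1); c2 <- colMeans(p2)
    if (o_dist(c1, c2) > ctd_cut) next
    th <- o_fold90(o_angle_at(c(0, 0, 0), o_plane_normal(p1), o_plane_normal(p2)))
    if (th < win[1] || th > win[2]) next
    mind <- Inf
    for (i in seq_len(nrow(p1))) for (j in seq_len(nrow(p2))) {
      mind <- min(mind, o_dist(p1[i, ], p2[j, ]))
    }
    if (mind <= min_cut) return(TRUE)
  }
  FALSE
}

o_detect_pication <- function(cat_frag, aro_frag, cutoff = 4.5,
                              win = c(0, 30)) {
  cc <- o_coords(cat_frag)
  for (cidx in o_cations(cat_frag)) for (ring in o_rings(aro_frag)) {
    pts <- o_coords(aro_frag)[ring + 1, , drop = FALSE]
    ctd <- colMeans(pts)
    P <- cc[cidx + 1, ]
    if (o_dist(P, ctd) > cutoff) next
    th <- o_fold90(o_angle_at(c(0, 0, 0), o_plane_normal(pts), P - ctd))
    if (th >= win[1] && th <= win[2]) return(TRUE)
  }
  FALSE
}

o_detect_vdw <- function(lig, prot, radii, tolerance = 0.6) {
  cl <- o_coords(lig); cp <- o_coords(prot)
  for (i in seq_len(nrow(cl))) for (j in seq_len(nrow(cp))) {
    lim <- radii[[lig$atoms$element[i]]] + radii[[prot$atoms$element[j]]] +
      tolerance
    if (o_dist(cl[i, ], cp[j, ]) <= lim) return(TRUE)
  }
  FALSE
}

# set-arithmetic Tanimoto on two logical vectors
o_tanimoto <- function(a, b, empty = 1) {
  u <- sum(a | b)
  if (u == 0) empty else sum(a & b) / u
}
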