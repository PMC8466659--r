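# Parametric synthetic complexes at EXACT geometries.  These are geometric
# probes for the interaction criteria, not physically relaxed conformers:
# the one guarantee is that the requested parameter (a distance, an angle),
# re-measured from the emitted coordinates, matches to better than 1e-6.
# All builders are deterministic; jitter_structure() adds seeded noise for
# the property-test suites.

# assemble a structure from per-residue pieces
# each piece: list(atoms = data.frame(element,x,y,z,formal_charge,is_aromatic,
#                                     name), bonds = 0-based local matrix,
#              resname, resnum, chain)
.assemble <- function(pieces, inter_bonds = NULL, frame_id = 0L) {
  offset <- 0L
  atom_rows <- list()
  bond_rows <- list()
  for (p in pieces) {
    a <- p$atoms
    n <- nrow(a)
    if (is.null(a$formal_charge)) a$formal_charge <- 0L
    if (is.null(a$is_aromatic))   a$is_aromatic <- FALSE
    if (is.null(a$name))          a$name <- make.unique(a$element, sep = "")
    a$resname <- p$resname; a$resnum <- p$resnum; a$chain <- p$chain
    atom_rows[[length(atom_rows) + 1L]] <- a
    if (!is.null(p$bonds) && nrow(p$bonds)) {
      bond_rows[[length(bond_rows) + 1L]] <- p$bonds + offset
    }
    offset <- offset + n
  }
  atoms <- do.call(rbind, atom_rows)
  rownames(atoms) <- NULL
  bonds <- if (length(bond_rows)) do.call(rbind, bond_rows)
           else matrix(integer(), ncol = 2L)
  if (!is.null(inter_bonds)) bonds <- rbind(bonds, inter_bonds)
  new_structure(atoms, bonds, frame_id = frame_id)
}

.adf <- function(element, x, y, z, formal_charge = 0L, is_aromatic = FALSE,
                 name = NULL) {
  d <- data.frame(element = element, x = x, y = y, z = z,
                  formal_charge = as.integer(formal_charge),
                  is_aromatic = is_aromatic, stringsAsFactors = FALSE)
  d$name <- if (is.null(name)) make.unique(element, sep = "") else name
  d
}

.OH_BOND <- 0.96   # A, donor O-H
.CO_BOND <- 1.23   # A, carbonyl C=O
.CX_BOND <- 1.90   # A, C-Br
.RING_R  <- 1.39   # A, benzene C radius
.CH_RING <- 2.47   # A, benzene H radius

#' Hydrogen-bond pair fixture
#'
#' A water-like donor residue (`HOH 1 A`) and a carbonyl-like acceptor
#' residue (`ACE 2 B`) with the donor oxygen at the origin, the acceptor
#' oxygen at distance `d_DA` along x, and the donor hydrogen placed so that
#' the D-H...A angle at the hydrogen equals `theta_DHA` exactly.  The second
#' water hydrogen points away from the acceptor and cannot satisfy the
#' angular window.
#'
#' @param d_DA donor-acceptor heavy atom distance, Angstrom (> 1).
#' @param theta_DHA angle at the hydrogen, degrees, in \[0, 180\].
#' @return a `structure3d` with two residues.
#' @export
make_hbond_pair <- function(d_DA, theta_DHA = 180) {
  stopifnot(d_DA > 1.0, theta_DHA >= 0, theta_DHA <= 180)
  b <- .OH_BOND
  th <- theta_DHA * pi / 180
  disc <- d_DA^2 - (b * sin(th))^2
  if (disc < 0) stop("infeasible H-bond geometry: H placement impossible")
  t <- b * cos(th) + sqrt(disc)       # |H...A|
  if (t <= 0) stop("infeasible H-bond geometry: H placement impossible")
  hx <- (b^2 + d_DA^2 - t^2) / (2 * d_DA)
  hy2 <- b^2 - hx^2
  hy <- sqrt(max(0, hy2))
  donor <- list(
    atoms = .adf(c("O", "H", "H"),
                 x = c(0, hx, -b),
                 y = c(0, hy, 0),
                 z = c(0, 0, 0),
                 name = c("O", "H1", "H2")),
    bonds = rbind(c(0L, 1L), c(0L, 2L)),
    resname = "HOH", resnum = 1L, chain = "A")
  acceptor <- list(
    atoms = .adf(c("O", "C"),
                 x = c(d_DA, d_DA + .CO_BOND), y = c(0, 0), z = c(0, 0),
                 name = c("O", "C")),
    bonds = rbind(c(0L, 1L)),
    resname = "ACE", resnum = 2L, chain = "B")
  .assemble(list(donor, acceptor))
}

# benzene template: 6 aromatic C + 6 H in the z = 0 plane, centred at origin,
# first carbon on +x
.benzene_piece <- function(resname, resnum, chain, rot = diag(3),
                           shift = c(0, 0, 0)) {
  ang <- (0:5) * pi / 3
  cx <- .RING_R * cos(ang); cy <- .RING_R * sin(ang)
  hx <- .CH_RING * cos(ang); hy <- .CH_RING * sin(ang)
  m <- cbind(c(cx, hx), c(cy, hy), rep(0, 12))
  m <- m %*% t(rot)
  m <- sweep(m, 2L, shift, "+")
  atoms <- .adf(c(rep("C", 6), rep("H", 6)), m[, 1], m[, 2], m[, 3],
                is_aromatic = c(rep(TRUE, 6), rep(FALSE, 6)),
                name = c(paste0("C", 1:6), paste0("H", 1:6)))
  ring <- cbind(0:5, c(1:5, 0L))
  ch <- cbind(0:5, 6:11)
  list(atoms = atoms, bonds = rbind(ring, ch),
       resname = resname, resnum = resnum, chain = chain)
}

.rot_y <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
         3L, 3L, byrow = TRUE)
}

#' Benzene dimer fixture
#'
#' Two benzene residues: ring 1 in the z = 0 plane centred at the origin,
#' ring 2 centred at `(lateral_offset, 0, gap)` and rotated by `tilt`
#' degrees about an in-plane (y) axis through its own centroid.  The
#' centroid separation is therefore `sqrt(gap^2 + lateral_offset^2)` and the
#' inter-plane (normal-normal) angle equals `tilt` exactly.
#'
#' @param gap plane separation along z, Angstrom (> 0).
#' @param lateral_offset centroid displacement along x, Angstrom.
#' @param tilt inter-plane angle, degrees.
#' @return a `structure3d` with two `BNZ` residues.
#' @export
make_ring_dimer <- function(gap, lateral_offset = 0, tilt = 0) {
  stopifnot(gap > 0)
  r1 <- .benzene_piece("BNZ", 1L, "A")
  r2 <- .benzene_piece("BNZ", 2L, "B", rot = .rot_y(tilt),
                       shift = c(lateral_offset, 0, gap))
  .assemble(list(r1, r2))
}

#' Ion-pair fixture
#'
#' An acetate-like anion (`ACT 1 A`, one carboxylate oxygen carrying formal
#' charge -1 at the origin) and an ammonium cation (`AMM 2 B`, nitrogen with
#' formal charge +1 at distance `d` along x).  The charged-atom separation
#' is exactly `d`.
#'
#' @param d anion-cation distance, Angstrom (> 0).
#' @return a `structure3d`.
#' @export
make_ion_pair <- function(d) {
  stopifnot(d > 0)
  anion <- list(
    atoms = .adf(c("O", "C", "O"),
                 x = c(0, -1.25, -1.90), y = c(0, 0.0, 1.05), z = c(0, 0, 0),
                 formal_charge = c(-1L, 0L, 0L),
                 name = c("O1", "C", "O2")),
    bonds = rbind(c(0L, 1L), c(1L, 2L)),
    resname = "ACT", resnum = 1L, chain = "A")
  hdir <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  hpos <- sweep(1.01 * hdir, 2L, c(d, 0, 0), "+")
  cation <- list(
    atoms = .adf(c("N", rep("H", 4)),
                 x = c(d, hpos[, 1]), y = c(0, hpos[, 2]), z = c(0, hpos[, 3]),
                 formal_charge = c(1L, rep(0L, 4)),
                 name = c("N", paste0("H", 1:4))),
    bonds = cbind(0L, 1:4),
    resname = "AMM", resnum = 2L, chain = "B")
  .assemble(list(anion, cation))
}

#' Metal-site fixture
#'
#' A bare Mg(2+) residue (`MG 1 A`) at the origin and a carbonyl-like
#' acceptor residue with its oxygen at distance `d` along x.
#'
#' @param d metal-oxygen distance, Angstrom (> 0).
#' @return a `structure3d`.
#' @export
make_metal_site <- function(d) {
  stopifnot(d > 0)
  metal <- list(
    atoms = .adf("Mg", 0, 0, 0, formal_charge = 2L, name = "MG"),
    bonds = NULL, resname = "MG", resnum = 1L, chain = "A")
  acceptor <- list(
    atoms = .adf(c("O", "C"),
                 x = c(d, d + .CO_BOND), y = c(0, 0), z = c(0, 0),
                 name = c("O", "C")),
    bonds = rbind(c(0L, 1L)),
    resname = "ACE", resnum = 2L, chain = "B")
  .assemble(list(metal, acceptor))
}

#' Halogen-bond pair fixture
#'
#' A bromomethane-like donor (`XBD 1 A`: carbon D bonded to bromine X, the
#' halogen at the origin) and a carbonyl-like acceptor (`ACE 2 B`: oxygen A
#' at distance `d_XA` along x, substituent carbon R).  The angle at the
#' halogen between X->D and X->A equals `theta_X`; the angle at the acceptor
#' between A->X and A->R equals `theta_A`; both exactly.
#'
#' @param d_XA halogen-acceptor distance, Angstrom (> 0).
#' @param theta_X angle at the halogen, degrees, in \[0, 180\].
#' @param theta_A angle at the acceptor, degrees, in \[0, 180\].
#' @return a `structure3d`.
#' @export
make_xbond_pair <- function(d_XA, theta_X = 180, theta_A = 120) {
  stopifnot(d_XA > 0, theta_X >= 0, theta_X <= 180,
            theta_A >= 0, theta_A <= 180)
  tx <- theta_X * pi / 180
  ta <- theta_A * pi / 180
  D <- .CX_BOND * c(cos(tx), sin(tx), 0)
  A <- c(d_XA, 0, 0)
  R <- A + .CO_BOND * c(-cos(ta), sin(ta), 0)
  donor <- list(
    atoms = .adf(c("Br", "C"),
                 x = c(0, D[1]), y = c(0, D[2]), z = c(0, D[3]),
                 name = c("BR", "C")),
    bonds = rbind(c(0L, 1L)),
    resname = "XBD", resnum = 1L, chain = "A")
  acceptor <- list(
    atoms = .adf(c("O", "C"),
                 x = c(A[1], R[1]), y = c(A[2], R[2]), z = c(A[3], R[3]),
                 name = c("O", "C")),
    bonds = rbind(c(0L, 1L)),
    resname = "ACE", resnum = 2L, chain = "B")
  .assemble(list(donor, acceptor))
}

#' Hydrophobic pair fixture
#'
#' Two methane residues with their carbons separated by exactly `d`.
#'
#' @param d carbon-carbon distance, Angstrom (> 0).
#' @return a `structure3d`.
#' @export
make_hydrophobic_pair <- function(d) {
  stopifnot(d > 0)
  methane <- function(resnum, chain, shift) {
    hdir <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    hpos <- sweep(1.09 * hdir, 2L, shift, "+")
    list(atoms = .adf(c("C", rep("H", 4)),
                      x = c(shift[1], hpos[, 1]),
                      y = c(shift[2], hpos[, 2]),
                      z = c(shift[3], hpos[, 3]),
                      name = c("C", paste0("H", 1:4))),
         bonds = cbind(0L, 1:4),
         resname = "MTH", resnum = resnum, chain = chain)
  }
  .assemble(list(methane(1L, "A", c(0, 0, 0)), methane(2L, "B", c(d, 0, 0))))
}

#' Minimal tripeptide fixture
#'
#' Three backbone-only residues (ALA 1, GLY 2, SER 3 on chain A; atoms N,
#' H, CA, C, O each) joined by peptide bonds, used to exercise residue
#' fragmentation, bond-cut accounting and round-trips.  Geometry is a
#' schematic extended chain, not a relaxed conformation.
#'
#' @return a `structure3d` with 15 atoms and 2 inter-residue bonds.
#' @export
make_tripeptide <- function() {
  res_piece <- function(resname, resnum, xoff) {
    list(atoms = .adf(c("N", "H", "C", "C", "O"),
                      x = xoff + c(0, -0.4, 1.45, 2.40, 2.40),
                      y = c(0, 0.9, 0, 1.0, 2.23),
                      z = c(0, 0, 0, 0, 0),
                      name = c("N", "H", "CA", "C", "O")),
         bonds = rbind(c(0L, 1L), c(0L, 2L), c(2L, 3L), c(3L, 4L)),
         resname = resname, resnum = resnum, chain = "A")
  }
  pieces <- list(res_piece("ALA", 1L, 0), res_piece("GLY", 2L, 3.8),
                 res_piece("SER", 3L, 7.6))
  # peptide bonds C(i) - N(i+1); 5 atoms per residue, C is local atom 3
  inter <- rbind(c(3L, 5L), c(8L, 10L))
  .assemble(pieces, inter_bonds = inter)
}

#' Small reference molecules
#'
#' Single-residue molecules used by the moiety-matching truth table tests:
#' benzene, methane, methanol, methylammonium, acetate, chlorobenzene,
#' water, tetrafluoromethane, and a bare magnesium ion.
#'
#' @param name one of `"benzene"`, `"methane"`, `"methanol"`,
#'   `"methylammonium"`, `"acetate"`, `"chlorobenzene"`, `"water"`,
#'   `"tetrafluoromethane"`, `"magnesium"`.
#' @return a single-residue `structure3d` labelled `UNL 1`.
#' @export
make_small_molecule <- function(name) {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  piece <- switch(name,
    benzene = {
      p <- .benzene_piece("UNL", 1L, "")
      p
    },
    methane = list(
      atoms = .adf(c("C", rep("H", 4)),
                   x = c(0, 1.09 * tet[, 1]), y = c(0, 1.09 * tet[, 2]),
                   z = c(0, 1.09 * tet[, 3])),
      bonds = cbind(0L, 1:4), resname = "UNL", resnum = 1L, chain = ""),
    tetrafluoromethane = list(
      atoms = .adf(c("C", rep("F", 4)),
                   x = c(0, 1.32 * tet[, 1]), y = c(0, 1.32 * tet[, 2]),
                   z = c(0, 1.32 * tet[, 3])),
      bonds = cbind(0L, 1:4), resname = "UNL", resnum = 1L, chain = ""),
    methanol = list(
      atoms = .adf(c("C", "O", "H", "H", "H", "H"),
                   x = c(0, 1.43, 1.75, -0.5, -0.5, -0.5),
                   y = c(0, 0, 0.9, 0.9, -0.9, 0),
                   z = c(0, 0, 0, 0.3, 0.3, -1.0)),
      bonds = rbind(c(0L, 1L), c(1L, 2L), c(0L, 3L), c(0L, 4L), c(0L, 5L)),
      resname = "UNL", resnum = 1L, chain = ""),
    methylammonium = list(
      atoms = .adf(c("C", "N", "H", "H", "H", "H", "H", "H"),
                   x = c(0, 1.50, 1.9, 1.9, 1.9, -0.5, -0.5, -0.5),
                   y = c(0, 0, 0.9, -0.9, 0, 0.9, -0.9, 0),
                   z = c(0, 0, 0, 0, 1.0, 0.3, 0.3, -1.0),
                   formal_charge = c(0L, 1L, rep(0L, 6))),
      bonds = rbind(c(0L, 1L), c(1L, 2L), c(1L, 3L), c(1L, 4L),
                    c(0L, 5L), c(0L, 6L), c(0L, 7L)),
      resname = "UNL", resnum = 1L, chain = ""),
    acetate = list(
      atoms = .adf(c("C", "C", "O", "O", "H", "H", "H"),
                   x = c(0, 1.50, 2.15, 2.05, -0.5, -0.5, -0.5),
                   y = c(0, 0, 1.05, -1.05, 0.9, -0.9, 0),
                   z = c(0, 0, 0, 0, 0.3, 0.3, -1.0),
                   formal_charge = c(0L, 0L, -1L, 0L, 0L, 0L, 0L)),
      bonds = rbind(c(0L, 1L), c(1L, 2L), c(1L, 3L),
                    c(0L, 4L), c(0L, 5L), c(0L, 6L)),
      resname = "UNL", resnum = 1L, chain = ""),
    chlorobenzene = {
      p <- .benzene_piece("UNL", 1L, "")
      # replace H on C1 by Cl at 1.74 A
      p$atoms$element[7L] <- "Cl"
      p$atoms$name[7L] <- "CL"
      p$atoms$x[7L] <- .RING_R + 1.74
      p
    },
    water = list(
      atoms = .adf(c("O", "H", "H"),
                   x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = c(0, 0, 0)),
      bonds = rbind(c(0L, 1L), c(0L, 2L)),
      resname = "UNL", resnum = 1L, chain = ""),
    magnesium = list(
      atoms = .adf("Mg", 0, 0, 0, formal_charge = 2L),
      bonds = NULL, resname = "UNL", resnum = 1L, chain = ""),
    stop("unknown molecule: ", name)
  )
  .assemble(list(piece))
}

#' Add seeded Gaussian coordinate noise
#'
#' @param structure a `structure3d`.
#' @param sd noise standard deviation per coordinate, Angstrom.
#' @param seed integer seed (noise is deterministic given the seed).
#' @return a perturbed copy.
#' @export
jitter_structure <- function(structure, sd = 0.05, seed = 1L) {
  stopifnot(inherits(structure, "structure3d"))
  n <- nrow(structure$atoms)
  noise <- withr_seed_rnorm(3L * n, sd, seed)
  structure$atoms$x <- structure$atoms$x + noise[seq_len(n)]
  structure$atoms$y <- structure$atoms$y + noise[n + seq_len(n)]
  structure$atoms$z <- structure$atoms$z + noise[2L * n + seq_len(n)]
  structure
}

# rnorm under a local RNG state (does not disturb the caller's stream)
withr_seed_rnorm <- function(n, sd, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n, 0, sd)
}
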