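# Molecular data model: structures, per-residue fragmentation, and moiety
# matching against the built-in pattern registry.
#
# Input contract: structures must arrive with explicit hydrogens, formal
# charges and aromaticity already perceived (file readers and fixtures both
# satisfy it).  Bond/charge inference from raw topologies is deliberately
# not performed here.
#
# Atom index conventions: every user-facing atom index (detection results,
# tables, CSV export) is 0-based and refers to the parent structure.
# Fragment-local matching also uses 0-based indices; the mapping back to the
# parent is the fragment's `parent_indices` vector.

#' Build a molecular structure
#'
#' A `structure3d` holds one frame of a molecular system: an atom table with
#' coordinates, elements, formal charges, aromatic flags and residue
#' metadata, plus an explicit bond list.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `formal_charge` (integer, default 0), `is_aromatic` (logical,
#'   default FALSE), `resname`, `resnum`, `chain`, `name` (atom name),
#'   `serial` (1-based file serial).
#' @param bonds two-column integer matrix of 0-based atom indices (may have
#'   zero rows).
#' @param frame_id integer frame identifier (>= 0).
#' @return object of class `structure3d`.
#' @export
new_structure <- function(atoms, bonds = matrix(integer(), ncol = 2L),
                          frame_id = 0L) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  required <- c("element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(atoms)
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  if (is.null(atoms$is_aromatic))   atoms$is_aromatic <- FALSE
  if (is.null(atoms$resname))       atoms$resname <- "UNL"
  if (is.null(atoms$resnum))        atoms$resnum <- 1L
  if (is.null(atoms$chain))         atoms$chain <- ""
  if (is.null(atoms$name))          atoms$name <- make.unique(atoms$element)
  if (is.null(atoms$serial))        atoms$serial <- seq_len(n)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("atom coordinates must be finite")
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (nrow(bonds) && (min(bonds) < 0L || max(bonds) >= n)) {
    stop("bond indices out of range (must be 0-based atom indices)")
  }
  structure(
    list(atoms = atoms, bonds = bonds, frame_id = as.integer(frame_id)),
    class = "structure3d"
  )
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %d atoms, %d bonds, %d residue(s), frame %d\n",
              nrow(x$atoms), nrow(x$bonds),
              nrow(unique(x$atoms[, c("resname", "resnum", "chain")])),
              x$frame_id))
  invisible(x)
}

#' Subset a structure by chain or residue
#'
#' Extracts the atoms of the selected chains/residues into a standalone
#' `structure3d` (bond indices remapped, coordinates untouched).  Handy for
#' splitting a complex into its "ligand" and "protein" sides before
#' [fp_run()].
#'
#' @param structure a `structure3d`.
#' @param chains character vector of chain ids to keep, or NULL.
#' @param residues character vector of residue keys (see [residue_key()])
#'   to keep, or NULL.
#' @return a `structure3d`.
#' @export
subset_structure <- function(structure, chains = NULL, residues = NULL) {
  stopifnot(inherits(structure, "structure3d"))
  at <- structure$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chains)) keep <- keep & at$chain %in% chains
  if (!is.null(residues)) {
    keys <- sprintf("%s%d.%s", at$resname, at$resnum, at$chain)
    keep <- keep & keys %in% residues
  }
  if (!any(keep)) stop("subset_structure: empty selection")
  rows <- which(keep)
  b <- structure$bonds
  bkeep <- (b[, 1L] + 1L) %in% rows & (b[, 2L] + 1L) %in% rows
  b <- b[bkeep, , drop = FALSE]
  if (nrow(b)) b[] <- match(b + 1L, rows) - 1L
  atoms <- at[rows, , drop = FALSE]
  rownames(atoms) <- NULL
  new_structure(atoms, b, frame_id = structure$frame_id)
}

#' Residue identity
#'
#' @param name residue name (e.g. "ALA").
#' @param number residue number.
#' @param chain chain identifier, possibly "".
#' @return object of class `residue_id`.
#' @export
residue_id <- function(name, number, chain = "") {
  structure(list(name = as.character(name), number = as.integer(number),
                 chain = as.character(chain)),
            class = "residue_id")
}

#' Canonical string key for a residue
#'
#' Formats a residue as `NAME<number>.<chain>` (e.g. `"ALA1.A"`), the key
#' used in fingerprint tables and graphs.
#'
#' @param rid a `residue_id` (or a fragment, whose id is used).
#' @return character scalar.
#' @export
residue_key <- function(rid) {
  if (inherits(rid, "residue_fragment")) rid <- rid$residue_id
  sprintf("%s%d.%s", rid$name, rid$number, rid$chain)
}

#' @export
format.residue_id <- function(x, ...) residue_key(x)

#' @export
print.residue_id <- function(x, ...) {
  cat("<residue_id>", residue_key(x), "\n"); invisible(x)
}

# Total order on residues: (chain, number, name).
.residue_order_keys <- function(atoms) {
  order(atoms$chain, atoms$resnum, atoms$resname)
}

#' Fragment a structure into residues
#'
#' Carves the parent structure into child residue fragments keyed on residue
#' name, number and chain, preserving coordinates, intra-residue bonds and
#' the local-to-parent atom index mapping.  Fragments are returned in the
#' residue total order (chain, number, name).
#'
#' @param structure a `structure3d`.
#' @return list of `residue_fragment` objects partitioning the atom set.
#' @export
fragment_by_residue <- function(structure) {
  stopifnot(inherits(structure, "structure3d"))
  at <- structure$atoms
  bad <- which(is.na(at$resname) | is.na(at$resnum))
  if (length(bad)) {
    stop("atom(s) lacking residue metadata at 0-based index ",
         paste(bad - 1L, collapse = ", "))
  }
  key <- paste(at$chain, at$resnum, at$resname, sep = "\r")
  # unique keys in (chain, number, name) order
  ord <- order(at$chain, at$resnum, at$resname)
  ukeys <- unique(key[ord])
  lapply(ukeys, function(k) {
    rows <- which(key == k)             # preserves parent atom order
    fragment_atoms <- at[rows, , drop = FALSE]
    rownames(fragment_atoms) <- NULL
    parent0 <- rows - 1L
    keep <- structure$bonds[, 1L] %in% parent0 & structure$bonds[, 2L] %in% parent0
    local_bonds <- structure$bonds[keep, , drop = FALSE]
    if (nrow(local_bonds)) {
      local_bonds[] <- match(local_bonds, parent0) - 1L
    }
    structure(
      list(
        residue_id = residue_id(fragment_atoms$resname[1L],
                                fragment_atoms$resnum[1L],
                                fragment_atoms$chain[1L]),
        atoms = fragment_atoms,
        bonds = local_bonds,            # 0-based local indices
        parent_indices = parent0        # local i (0-based) -> parent 0-based
      ),
      class = "residue_fragment"
    )
  })
}

#' @export
print.residue_fragment <- function(x, ...) {
  cat(sprintf("<residue_fragment> %s: %d atoms\n",
              residue_key(x$residue_id), nrow(x$atoms)))
  invisible(x)
}

.frag_coords <- function(frag, local0 = NULL) {
  m <- as.matrix(frag$atoms[, c("x", "y", "z")])
  if (!is.null(local0)) m <- m[local0 + 1L, , drop = FALSE]
  m
}

# 0-based neighbours of a 0-based local atom index
.frag_neighbours <- function(frag, i0) {
  b <- frag$bonds
  if (!nrow(b)) return(integer())
  sort(unique(c(b[b[, 1L] == i0, 2L], b[b[, 2L] == i0, 1L])))
}

# ---- aromatic ring perception ----------------------------------------------

# Enumerate simple cycles of length `size` restricted to the 0-based
# candidate atoms, given a 0-based bond matrix.  Residues are small, so a
# pruned DFS is adequate.  Cycles are deduplicated as atom SETS.
.find_rings <- function(bonds0, candidates0, size) {
  if (length(candidates0) < size || !nrow(bonds0)) return(list())
  nbrs <- function(i0) {
    sort(unique(c(bonds0[bonds0[, 1L] == i0, 2L],
                  bonds0[bonds0[, 2L] == i0, 1L])))
  }
  adj <- lapply(candidates0, function(i) intersect(nbrs(i), candidates0))
  names(adj) <- as.character(candidates0)
  found <- new.env(parent = emptyenv())
  res <- list()
  dfs <- function(path) {
    last <- path[length(path)]
    for (nb in adj[[as.character(last)]]) {
      if (length(path) == size && nb == path[1L]) {
        key <- paste(sort(path), collapse = ",")
        if (is.null(found[[key]])) {
          assign(key, TRUE, envir = found)
          res[[length(res) + 1L]] <<- sort(path)
        }
      } else if (length(path) < size && !(nb %in% path) && nb > path[1L]) {
        # nb > path[1] canonicalizes the start atom to the ring's minimum
        dfs(c(path, nb))
      }
    }
  }
  for (start in candidates0) dfs(start)
  res
}

# aromatic rings of a fragment: cycles among flagged-aromatic atoms; a ring
# matched by both the 5- and 6-membered patterns counts once at the caller
.aromatic_rings <- function(frag, size) {
  .find_rings(frag$bonds, which(frag$atoms$is_aromatic) - 1L, size)
}

# ---- moiety patterns --------------------------------------------------------

#' Create a moiety pattern
#'
#' A moiety pattern is a named substructure query: a predicate over a
#' residue fragment that returns the 0-based local atom tuples matching a
#' chemical group (anion, aromatic ring, donor-H pair, ...).  The built-in
#' registry expresses the standard SMARTS queries as graph predicates over
#' elements, formal charges, aromatic flags and bonds.
#'
#' @param name unique pattern name.
#' @param arity number of atoms captured per match (`NA` for variable arity,
#'   e.g. aromatic rings).
#' @param match function(fragment) returning a list of 0-based local integer
#'   vectors.
#' @param smarts optional SMARTS-style text, for documentation only.
#' @return object of class `moiety_pattern`.
#' @export
moiety_pattern <- function(name, arity, match, smarts = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.function(match))
  if (!is.na(arity) && arity < 1L) stop("pattern arity must be >= 1")
  structure(list(name = name, arity = arity, match = match, smarts = smarts),
            class = "moiety_pattern")
}

#' @export
print.moiety_pattern <- function(x, ...) {
  cat(sprintf("<moiety_pattern> %s (arity %s)%s\n", x$name,
              ifelse(is.na(x$arity), "ring", x$arity),
              if (!is.null(x$smarts)) paste0("  ", x$smarts) else ""))
  invisible(x)
}

# helper: single-atom matches from a logical predicate over the atom table
.atom_matches <- function(frag, predicate) {
  hits <- which(predicate(frag$atoms)) - 1L
  lapply(hits, function(i) i)
}

.is_halogen <- function(el) el %in% c("F", "Cl", "Br", "I", "At")

#' Built-in moiety pattern registry
#'
#' Returns the default pattern set used by the interaction detectors:
#' \describe{
#'   \item{Anion / Cation}{formal charge <= -1 / >= +1.}
#'   \item{Aromatic}{flagged-aromatic rings of size 6 or 5, deduplicated as
#'     atom sets; fused systems report each ring.}
#'   \item{HBAcceptor}{N, O, F or any anion, excluding cations.}
#'   \item{HBDonor}{N/O/S heavy atom plus one bonded hydrogen (arity 2).}
#'   \item{XBAcceptor}{N, O, P, S, Se, Te or aromatic atom (not cationic)
#'     plus one bonded substituent R (arity 2).}
#'   \item{XBDonor}{C/N/Si/F/Cl/Br/I heavy atom bonded to a Cl/Br/I/At
#'     halogen (arity 2: donor, halogen).}
#'   \item{Metal}{Ca, Cd, Co, Cu, Fe, Mg, Mn, Ni or Zn.}
#'   \item{MetalLigand}{O, N or any anion, excluding cations.}
#'   \item{Hydrophobic}{C, S or halogen with zero formal charge.}
#' }
#'
#' @return named list of `moiety_pattern` objects (a pattern registry).
#' @export
builtin_patterns <- function() {
  pats <- list(
    moiety_pattern("Anion", 1L, smarts = "[-{1-}]",
      match = function(frag) .atom_matches(frag, function(a) a$formal_charge <= -1L)),
    moiety_pattern("Cation", 1L, smarts = "[+{1-}]",
      match = function(frag) .atom_matches(frag, function(a) a$formal_charge >= 1L)),
    moiety_pattern("Aromatic", NA_integer_,
      smarts = "a1:a:a:a:a:a:1 | a1:a:a:a:a:1",
      match = function(frag) {
        rings <- c(.aromatic_rings(frag, 6L), .aromatic_rings(frag, 5L))
        if (!length(rings)) return(list())
        keys <- vapply(rings, paste, "", collapse = ",")
        rings <- rings[!duplicated(keys)]
        rings[order(vapply(rings, `[`, 0L, 1L))]
      }),
    moiety_pattern("HBAcceptor", 1L, smarts = "[N,O,F,-{1-};!+{1-}]",
      match = function(frag) .atom_matches(frag, function(a)
        (a$element %in% c("N", "O", "F") | a$formal_charge <= -1L) &
          a$formal_charge < 1L)),
    moiety_pattern("HBDonor", 2L, smarts = "[#7,#8,#16][H]",
      match = function(frag) {
        donors <- which(frag$atoms$element %in% c("N", "O", "S")) - 1L
        out <- list()
        for (d in donors) {
          hs <- .frag_neighbours(frag, d)
          hs <- hs[frag$atoms$element[hs + 1L] == "H"]
          for (h in hs) out[[length(out) + 1L]] <- c(d, h)
        }
        out
      }),
    moiety_pattern("XBAcceptor", 2L, smarts = "[#7,#8,P,S,Se,Te,a;!+{1-}][*]",
      match = function(frag) {
        acc <- which((frag$atoms$element %in% c("N", "O", "P", "S", "Se", "Te") |
                        frag$atoms$is_aromatic) &
                       frag$atoms$formal_charge < 1L) - 1L
        out <- list()
        for (a in acc) {
          for (r in .frag_neighbours(frag, a)) {
            out[[length(out) + 1L]] <- c(a, r)
          }
        }
        out
      }),
    moiety_pattern("XBDonor", 2L, smarts = "[#6,#7,Si,F,Cl,Br,I]-[Cl,Br,I,At]",
      match = function(frag) {
        don <- which(frag$atoms$element %in%
                       c("C", "N", "Si", "F", "Cl", "Br", "I")) - 1L
        out <- list()
        for (d in don) {
          xs <- .frag_neighbours(frag, d)
          xs <- xs[frag$atoms$element[xs + 1L] %in% c("Cl", "Br", "I", "At")]
          for (x in xs) out[[length(out) + 1L]] <- c(d, x)
        }
        out
      }),
    moiety_pattern("Metal", 1L, smarts = "[Ca,Cd,Co,Cu,Fe,Mg,Mn,Ni,Zn]",
      match = function(frag) .atom_matches(frag, function(a)
        a$element %in% c("Ca", "Cd", "Co", "Cu", "Fe", "Mg", "Mn", "Ni", "Zn"))),
    moiety_pattern("MetalLigand", 1L, smarts = "[O,N,-{1-};!+{1-}]",
      match = function(frag) .atom_matches(frag, function(a)
        (a$element %in% c("O", "N") | a$formal_charge <= -1L) &
          a$formal_charge < 1L)),
    moiety_pattern("Hydrophobic", 1L, smarts = "[#6,#16,F,Cl,Br,I,At;+0]",
      match = function(frag) .atom_matches(frag, function(a)
        (a$element %in% c("C", "S") | .is_halogen(a$element)) &
          a$formal_charge == 0L))
  )
  stats::setNames(pats, vapply(pats, `[[`, "", "name"))
}

#' Match a moiety pattern against a residue fragment
#'
#' @param fragment a `residue_fragment`.
#' @param pattern a `moiety_pattern`, or a pattern name resolved in
#'   `registry`.
#' @param registry pattern registry (default [builtin_patterns()]).
#' @return list of 0-based fragment-local integer vectors, one per match,
#'   unique and sorted ascending by first (then second) captured atom index.
#' @export
match_moiety <- function(fragment, pattern, registry = builtin_patterns()) {
  stopifnot(inherits(fragment, "residue_fragment"))
  if (is.character(pattern)) {
    if (!pattern %in% names(registry)) {
      stop("unknown moiety pattern: ", pattern)
    }
    pattern <- registry[[pattern]]
  }
  stopifnot(inherits(pattern, "moiety_pattern"))
  matches <- pattern$match(fragment)
  if (!length(matches)) return(list())
  matches <- lapply(matches, as.integer)
  keys <- vapply(matches, paste, "", collapse = ",")
  matches <- matches[!duplicated(keys)]
  first <- vapply(matches, `[`, 0L, 1L)
  second <- vapply(matches, function(m) if (length(m) > 1L) m[2L] else -1L, 0L)
  matches[order(first, second)]
}

#' Register a moiety pattern
#'
#' @param registry named list of patterns (e.g. from [builtin_patterns()]).
#' @param pattern a `moiety_pattern`.
#' @param overwrite allow replacing an existing name?
#' @return the updated registry.
#' @export
register_pattern <- function(registry, pattern, overwrite = FALSE) {
  stopifnot(inherits(pattern, "moiety_pattern"))
  if (pattern$name %in% names(registry) && !overwrite) {
    stop("pattern '", pattern$name,
         "' already registered (use overwrite = TRUE)")
  }
  registry[[pattern$name]] <- pattern
  registry
}
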