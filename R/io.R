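# Readers and writers for standard structure formats.
#
# Contract: structures must reach the detectors with explicit hydrogens,
# formal charges and aromaticity.  PDB carries charges (columns 79-80) and
# connectivity (CONECT) but not aromaticity, which is therefore perceived on
# read from the bonded ring systems (planar 5/6-rings of C/N/O/S); SDF
# carries charges (M  CHG) and aromatic bonds (type 4); MOL2 carries
# aromaticity via .ar atom/bond types but only partial charges, which are
# ignored (only formal charges drive moiety matching).
#
# Coordinates are Angstrom everywhere.  Atom indices in all outputs are
# 0-based; 1-based PDB serials are preserved in the atom table's `serial`
# column.

.normalize_element <- function(el) {
  el <- trimws(el)
  el <- ifelse(nchar(el) >= 1L,
               paste0(toupper(substr(el, 1L, 1L)),
                      tolower(substr(el, 2L, nchar(el)))), el)
  el
}

# mark atoms aromatic when they sit in a planar 5/6-ring of C/N/O/S atoms
.perceive_aromaticity <- function(atoms, bonds, planarity_tol = 0.1) {
  cand <- which(atoms$element %in% c("C", "N", "O", "S")) - 1L
  flags <- rep(FALSE, nrow(atoms))
  rings <- c(.find_rings(bonds, cand, 6L), .find_rings(bonds, cand, 5L))
  for (ring in rings) {
    pts <- as.matrix(atoms[ring + 1L, c("x", "y", "z")])
    centred <- sweep(pts, 2L, colMeans(pts))
    sv <- svd(centred)
    if (sv$d[2L] < 1e-8) next
    dev <- abs(centred %*% sv$v[, 3L])
    if (max(dev) <= planarity_tol) flags[ring + 1L] <- TRUE
  }
  flags
}

# ---- PDB --------------------------------------------------------------------

.parse_pdb_charge <- function(txt) {
  txt <- trimws(txt)
  if (txt == "") return(0L)
  if (grepl("^[0-9]+[+-]$", txt)) {
    v <- as.integer(substr(txt, 1L, nchar(txt) - 1L))
    if (substr(txt, nchar(txt), nchar(txt)) == "-") v <- -v
    return(v)
  }
  if (grepl("^[+-][0-9]+$", txt)) return(as.integer(txt))
  0L
}

.read_pdb <- function(path, perceive_aromaticity = TRUE) {
  lines <- readLines(path, warn = FALSE)
  models <- list()
  cur <- list()
  serial_bonds <- list()
  ln <- 0L
  for (line in lines) {
    ln <- ln + 1L
    rec <- substr(line, 1L, 6L)
    if (rec %in% c("ATOM  ", "HETATM")) {
      line <- formatC(line, width = 80L, flag = "-")
      serial <- suppressWarnings(as.integer(substr(line, 7L, 11L)))
      x <- suppressWarnings(as.numeric(substr(line, 31L, 38L)))
      y <- suppressWarnings(as.numeric(substr(line, 39L, 46L)))
      z <- suppressWarnings(as.numeric(substr(line, 47L, 54L)))
      if (anyNA(c(serial, x, y, z))) {
        stop("unparseable ", trimws(rec), " record at line ", ln,
             " of ", path)
      }
      el <- .normalize_element(substr(line, 77L, 78L))
      name <- trimws(substr(line, 13L, 16L))
      if (el == "") el <- .normalize_element(gsub("[0-9']", "", name))
      cur[[length(cur) + 1L]] <- data.frame(
        element = el, x = x, y = y, z = z,
        formal_charge = .parse_pdb_charge(substr(line, 79L, 80L)),
        is_aromatic = FALSE,
        resname = trimws(substr(line, 18L, 20L)),
        resnum = suppressWarnings(as.integer(substr(line, 23L, 26L))),
        chain = trimws(substr(line, 22L, 22L)),
        name = name, serial = serial, stringsAsFactors = FALSE)
    } else if (rec == "CONECT") {
      fields <- as.integer(substring(line,
                                     seq(7L, 27L, by = 5L),
                                     seq(11L, 31L, by = 5L)))
      fields <- fields[!is.na(fields)]
      if (length(fields) >= 2L) {
        for (k in fields[-1L]) {
          serial_bonds[[length(serial_bonds) + 1L]] <- c(fields[1L], k)
        }
      }
    } else if (rec == "ENDMDL") {
      models[[length(models) + 1L]] <- cur
      cur <- list()
    }
  }
  if (length(cur)) models[[length(models) + 1L]] <- cur
  if (!length(models)) stop("no ATOM/HETATM records found in ", path)

  frames <- lapply(seq_along(models), function(mi) {
    atoms <- do.call(rbind, models[[mi]])
    rownames(atoms) <- NULL
    bonds <- matrix(integer(), ncol = 2L)
    if (length(serial_bonds)) {
      b <- do.call(rbind, serial_bonds)
      b[] <- match(b, atoms$serial) - 1L     # serial -> 0-based index
      b <- b[stats::complete.cases(b) & b[, 1L] != b[, 2L], , drop = FALSE]
      # dedupe undirected pairs
      key <- paste(pmin(b[, 1L], b[, 2L]), pmax(b[, 1L], b[, 2L]))
      bonds <- matrix(as.integer(b[!duplicated(key), , drop = FALSE]),
                      ncol = 2L)
    }
    if (perceive_aromaticity) {
      atoms$is_aromatic <- .perceive_aromaticity(atoms, bonds)
    }
    new_structure(atoms, bonds, frame_id = mi - 1L)
  })
  if (length(frames) == 1L) frames[[1L]] else frames
}

#' Write a structure (or frame list) to a PDB file
#'
#' Standard fixed columns with the element symbol in columns 77-78 and the
#' formal charge in columns 79-80; bonds are written as CONECT records and
#' multiple frames as MODEL/ENDMDL blocks.
#'
#' @param structure a `structure3d` or list of frames with identical
#'   topology.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  frames <- .as_frame_list(structure)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (fi in seq_along(frames)) {
    s <- frames[[fi]]
    if (multi) writeLines(sprintf("MODEL     %4d", fi), con)
    a <- s$atoms
    for (i in seq_len(nrow(a))) {
      q <- a$formal_charge[i]
      qtxt <- if (q == 0L) "  " else sprintf("%d%s", abs(q),
                                             ifelse(q > 0, "+", "-"))
      nm <- a$name[i]
      nmtxt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else substr(nm, 1, 4)
      chain <- substr(a$chain[i], 1L, 1L)
      if (chain == "") chain <- " "
      writeLines(sprintf(
        "HETATM%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%2s",
        a$serial[i], nmtxt, substr(a$resname[i], 1L, 3L),
        chain, a$resnum[i],
        a$x[i], a$y[i], a$z[i], 1.0, 0.0,
        formatC(toupper(a$element[i]), width = 2L), qtxt), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  s1 <- frames[[1L]]
  if (nrow(s1$bonds)) {
    serials <- s1$atoms$serial
    for (i in seq_len(nrow(s1$bonds))) {
      writeLines(sprintf("CONECT%5d%5d",
                         serials[s1$bonds[i, 1L] + 1L],
                         serials[s1$bonds[i, 2L] + 1L]), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

# ---- SDF (V2000) ------------------------------------------------------------

.read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # split records on $$$$
  recs <- split(lines, cumsum(c(0L, utils::head(grepl("^\\${4}", lines), -1L))))
  structures <- list()
  for (rec in recs) {
    rec <- rec[!grepl("^\\${4}", rec)]
    if (length(rec) < 4L || !any(nzchar(trimws(rec)))) next
    counts <- rec[4L]
    natoms <- as.integer(substr(counts, 1L, 3L))
    nbonds <- as.integer(substr(counts, 4L, 6L))
    if (is.na(natoms)) stop("unparseable SDF counts line in ", path)
    atom_lines <- rec[5L:(4L + natoms)]
    atoms <- do.call(rbind, lapply(atom_lines, function(l) {
      data.frame(
        element = .normalize_element(substr(l, 32L, 34L)),
        x = as.numeric(substr(l, 1L, 10L)),
        y = as.numeric(substr(l, 11L, 20L)),
        z = as.numeric(substr(l, 21L, 30L)),
        stringsAsFactors = FALSE)
    }))
    atoms$formal_charge <- 0L
    atoms$is_aromatic <- FALSE
    bonds <- matrix(integer(), ncol = 2L)
    if (nbonds > 0L) {
      bond_lines <- rec[(5L + natoms):(4L + natoms + nbonds)]
      bt <- do.call(rbind, lapply(bond_lines, function(l) {
        c(as.integer(substr(l, 1L, 3L)), as.integer(substr(l, 4L, 6L)),
          as.integer(substr(l, 7L, 9L)))
      }))
      bonds <- bt[, 1:2, drop = FALSE] - 1L
      aromatic_rows <- which(bt[, 3L] == 4L)
      for (r in aromatic_rows) {
        atoms$is_aromatic[bt[r, 1L]] <- TRUE
        atoms$is_aromatic[bt[r, 2L]] <- TRUE
      }
    }
    for (l in rec[grepl("^M  CHG", rec)]) {
      fields <- as.integer(strsplit(trimws(substr(l, 7L, nchar(l))),
                                    "[[:space:]]+")[[1L]])
      npairs <- fields[1L]
      for (k in seq_len(npairs)) {
        atoms$formal_charge[fields[2L * k]] <- fields[2L * k + 1L]
      }
    }
    atoms$resname <- "UNL"; atoms$resnum <- 1L; atoms$chain <- ""
    structures[[length(structures) + 1L]] <-
      new_structure(atoms, bonds, frame_id = length(structures))
  }
  if (!length(structures)) stop("no records found in ", path)
  if (length(structures) == 1L) structures[[1L]] else structures
}

# ---- MOL2 -------------------------------------------------------------------

.read_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- ""
  atoms <- list(); bonds <- list()
  for (line in lines) {
    if (startsWith(line, "@<TRIPOS>")) {
      sec <- sub("@<TRIPOS>", "", line)
      next
    }
    if (!nzchar(trimws(line))) next
    f <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
    if (sec == "ATOM") {
      type <- f[6L]
      el <- .normalize_element(strsplit(type, ".", fixed = TRUE)[[1L]][1L])
      atoms[[length(atoms) + 1L]] <- data.frame(
        element = el,
        x = as.numeric(f[3L]), y = as.numeric(f[4L]), z = as.numeric(f[5L]),
        formal_charge = 0L,
        is_aromatic = grepl("\\.ar$", type),
        resname = if (length(f) >= 8L) gsub("[0-9]+$", "", f[8L]) else "UNL",
        resnum = if (length(f) >= 7L) as.integer(f[7L]) else 1L,
        chain = "",
        name = f[2L], serial = as.integer(f[1L]),
        stringsAsFactors = FALSE)
    } else if (sec == "BOND") {
      a1 <- as.integer(f[2L]); a2 <- as.integer(f[3L])
      bonds[[length(bonds) + 1L]] <- c(a1, a2, f[4L])
      if (identical(f[4L], "ar")) {
        atoms[[a1]]$is_aromatic <- TRUE
        atoms[[a2]]$is_aromatic <- TRUE
      }
    }
  }
  if (!length(atoms)) stop("no @<TRIPOS>ATOM section found in ", path)
  at <- do.call(rbind, atoms)
  rownames(at) <- NULL
  b <- if (length(bonds)) {
    m <- do.call(rbind, lapply(bonds, function(x) as.integer(x[1:2]))) - 1L
    matrix(as.integer(m), ncol = 2L)
  } else matrix(integer(), ncol = 2L)
  new_structure(at, b, frame_id = 0L)
}

#' Read a molecular structure file
#'
#' Dispatches on `format` (or the file extension): PDB (multi-MODEL files
#' return a list of frames), SDF V2000 (multi-record files return a list)
#' or MOL2.  See the format notes in the package documentation for what
#' each dialect can and cannot carry.
#'
#' @param path input file.
#' @param format `"pdb"`, `"sdf"`, `"mol2"`, or `NULL` to use the
#'   extension.
#' @param perceive_aromaticity for PDB only: flag planar 5/6-rings of
#'   C/N/O/S as aromatic (PDB cannot encode aromaticity explicitly).
#' @return a `structure3d`, or a list of them for multi-frame input.
#' @export
read_structure <- function(path, format = NULL, perceive_aromaticity = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- tolower(sub(".*\\.", "", basename(path)))
  }
  switch(tolower(format),
         pdb = .read_pdb(path, perceive_aromaticity),
         sdf = .read_sdf(path),
         mol2 = .read_mol2(path),
         stop("unsupported format: ", format))
}

# ---- interaction threshold config ------------------------------------------

#' Write interaction definitions to a JSON config file
#'
#' Serializes name, moiety roles, distance cutoff and angle windows so
#' threshold overrides are reproducible and shareable.
#'
#' @param registry named list of `interaction_definition`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interaction_config <- function(registry, path) {
  payload <- lapply(registry, function(d) {
    out <- list(kind = d$kind,
                ligand_moiety = d$ligand_moiety,
                protein_moiety = d$protein_moiety)
    if (!is.null(d$distance_max)) out$distance_max <- d$distance_max
    if (length(d$angle_ranges)) out$angle_ranges <- d$angle_ranges
    if (!is.null(d$min_distance_max)) out$min_distance_max <- d$min_distance_max
    out
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read interaction threshold overrides from a JSON config file
#'
#' Each top-level key names an interaction; its object may override
#' `distance_max`, `angle_ranges` (named \[lo, hi\] windows),
#' `min_distance_max` and the moiety names.  Unknown interaction names are
#' an error.
#'
#' @param path config file.
#' @param registry base registry to modify (default
#'   [builtin_interactions()]).
#' @return the updated registry.
#' @export
read_interaction_config <- function(path, registry = builtin_interactions()) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  for (nm in names(cfg)) {
    if (!nm %in% names(registry)) {
      stop("config references unknown interaction: ", nm)
    }
    keys <- intersect(names(cfg[[nm]]),
                      c("distance_max", "angle_ranges", "min_distance_max",
                        "ligand_moiety", "protein_moiety"))
    registry[[nm]] <- configure(registry[[nm]], cfg[[nm]][keys])
  }
  registry
}
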