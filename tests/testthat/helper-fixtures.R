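# Shared test fixtures and small builders.

# split a two-residue fixture into ligand (chain A) / protein (chain B) sides
split_sides <- function(s) {
  list(lig = subset_structure(s, chains = "A"),
       prot = subset_structure(s, chains = "B"))
}

# the two fragments of a two-residue fixture, in residue order
frags2 <- function(s) fragment_by_residue(s)

# cation placed relative to a benzene ring: at distance `d` from the ring
# centroid, with the centroid->cation direction making `angle` degrees with
# the ring normal (ring in z = 0 plane centred at origin, normal = z)
make_pication <- function(d, angle = 0) {
  benz <- make_small_molecule("benzene")
  ba <- benz$atoms
  ba$resname <- "BNZ"; ba$resnum <- 1L; ba$chain <- "A"
  th <- angle * pi / 180
  pos <- c(d * sin(th), 0, d * cos(th))
  hoff <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  cat_at <- data.frame(
    element = c("N", rep("H", 4)),
    x = c(pos[1], pos[1] + 1.01 * hoff[, 1]),
    y = c(pos[2], pos[2] + 1.01 * hoff[, 2]),
    z = c(pos[3], pos[3] + 1.01 * hoff[, 3]),
    formal_charge = c(1L, rep(0L, 4)), is_aromatic = FALSE,
    resname = "AMM", resnum = 2L, chain = "B",
    name = c("N", paste0("H", 1:4)), stringsAsFactors = FALSE)
  ba$serial <- seq_len(nrow(ba))
  cat_at$serial <- nrow(ba) + seq_len(nrow(cat_at))
  atoms <- rbind(ba[, names(cat_at)], cat_at)
  nb <- nrow(ba)
  bonds <- rbind(benz$bonds, cbind(nb, nb + 1:4))
  new_structure(atoms, bonds)
}

# concatenate two structures into one (atoms appended, bonds re-offset)
merge2 <- function(s1, s2) {
  cols <- c("element", "x", "y", "z", "formal_charge", "is_aromatic",
            "resname", "resnum", "chain", "name")
  atoms <- rbind(s1$atoms[, cols], s2$atoms[, cols])
  atoms$serial <- seq_len(nrow(atoms))
  bonds <- rbind(s1$bonds, s2$bonds + nrow(s1$atoms))
  new_structure(atoms, bonds, frame_id = s1$frame_id)
}

# build a fingerprint_result directly (same layout fp_run produces), for
# network/similarity tests where per-frame truth is stated by hand.
# rows: data.frame(frame, lig_res, prot_res, interaction) plus optional
# list-columns lig_atoms / prot_atoms
mk_result <- function(n_frames, rows,
                      interactions = unique(rows$interaction),
                      lig_residues = unique(rows$lig_res),
                      prot_residues = unique(rows$prot_res)) {
  entries <- data.frame(frame = as.integer(rows$frame),
                        lig_res = rows$lig_res, prot_res = rows$prot_res,
                        interaction = rows$interaction,
                        stringsAsFactors = FALSE)
  la <- if (!is.null(rows$lig_atoms)) rows$lig_atoms
        else replicate(nrow(rows), 0L, simplify = FALSE)
  pa <- if (!is.null(rows$prot_atoms)) rows$prot_atoms
        else replicate(nrow(rows), 0L, simplify = FALSE)
  entries$lig_atoms <- la
  entries$prot_atoms <- pa
  entries$pairs <- lapply(seq_len(nrow(entries)), function(i) {
    list(list(lig = la[[i]], prot = pa[[i]]))
  })
  structure(list(interaction_names = interactions,
                 frames = seq_len(n_frames) - 1L,
                 lig_residues = lig_residues,
                 prot_residues = prot_residues,
                 entries = entries),
            class = "fingerprint_result")
}
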