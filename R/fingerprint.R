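# Fingerprint engine: run interaction detectors over frame/pose sequences
# per residue pair, store results, and expose bitvector / tabular /
# frequency / similarity views of the one store.

.as_frame_list <- function(x) {
  if (inherits(x, "structure3d")) list(x)
  else if (is.list(x) && all(vapply(x, inherits, TRUE, "structure3d"))) x
  else stop("expected a structure3d or a list of structure3d frames")
}

.select_residues <- function(frags, selection) {
  if (is.null(selection)) return(frags)
  keys <- vapply(frags, residue_key, "")
  keep <- if (is.function(selection)) {
    vapply(frags, function(f) isTRUE(selection(f$residue_id)), TRUE)
  } else keys %in% as.character(selection)
  frags[keep]
}

#' Run an interaction fingerprint over frames
#'
#' For every frame and every (ligand residue, protein residue) pair passing
#' the selection filter, evaluates each requested interaction detector and
#' stores presence plus the responsible atom indices.  Passing the same
#' structure sequence on both sides performs an intramolecular analysis;
#' pairs of a residue with itself are always skipped.
#'
#' A residue-pair distance prefilter (minimum any-atom distance greater than
#' 6 Angstrom plus the largest distance cutoff in play) skips hopeless pairs
#' for speed; it is a pure optimization and cannot change results.
#'
#' @param lig_frames,prot_frames a `structure3d` or list of them; equal
#'   length, index-aligned.
#' @param interactions character vector of interaction names (default
#'   [default_interactions()]).
#' @param interaction_registry named list from [builtin_interactions()]
#'   possibly extended via [register_interaction()].
#' @param pattern_registry moiety registry (see [builtin_patterns()]).
#' @param selection optional protein residue filter: character vector of
#'   residue keys, or `function(residue_id) -> logical`.
#' @param all_pairs record every satisfying atom pair (needed for
#'   atom-frequency statistics in [lig_network()]).
#' @param prefilter logical; apply the distance prefilter.
#' @param vdw_table,vdw_tolerance forwarded to the VdWContact detector.
#' @return object of class `fingerprint_result`.
#' @export
fp_run <- function(lig_frames, prot_frames,
                   interactions = default_interactions(),
                   interaction_registry = builtin_interactions(),
                   pattern_registry = builtin_patterns(),
                   selection = NULL, all_pairs = FALSE, prefilter = TRUE,
                   vdw_table = NULL, vdw_tolerance = 0.6) {
  lig_frames <- .as_frame_list(lig_frames)
  prot_frames <- .as_frame_list(prot_frames)
  if (length(lig_frames) != length(prot_frames)) {
    stop("ligand and protein frame counts differ (",
         length(lig_frames), " vs ", length(prot_frames), ")")
  }
  unknown <- setdiff(interactions, names(interaction_registry))
  if (length(unknown)) {
    stop("unknown interaction(s): ", paste(unknown, collapse = ", "))
  }
  defs <- interaction_registry[interactions]
  n_frames <- length(lig_frames)

  cutoffs <- unlist(lapply(defs, function(d) d$distance_max))
  pre_cut <- 6.0 + max(c(cutoffs, 6.0))

  lig_res_keys <- prot_res_keys <- character()
  rows <- list()
  for (fi in seq_len(n_frames)) {
    lfr <- fragment_by_residue(lig_frames[[fi]])
    pfr <- .select_residues(fragment_by_residue(prot_frames[[fi]]), selection)
    if (fi == 1L) {
      lig_res_keys <- vapply(lfr, residue_key, "")
      prot_res_keys <- vapply(pfr, residue_key, "")
    }
    for (lf in lfr) {
      lkey <- residue_key(lf)
      lcoords <- .frag_coords(lf)
      for (pf in pfr) {
        pkey <- residue_key(pf)
        if (identical(lkey, pkey)) next      # self-pair (intramolecular runs)
        if (prefilter &&
            min_pairwise_distance(lcoords, .frag_coords(pf)) > pre_cut) next
        for (defn in defs) {
          res <- detect(defn, lf, pf, registry = pattern_registry,
                        all_pairs = all_pairs, vdw_table = vdw_table,
                        vdw_tolerance = vdw_tolerance)
          if (res$present) {
            rows[[length(rows) + 1L]] <- list(
              frame = fi - 1L, lig_res = lkey, prot_res = pkey,
              interaction = defn$name,
              lig_atoms = res$ligand_atoms, prot_atoms = res$protein_atoms,
              pairs = res$pairs %||% list(list(lig = res$ligand_atoms,
                                               prot = res$protein_atoms)))
          }
        }
      }
    }
  }
  entries <- if (length(rows)) {
    data.frame(
      frame = vapply(rows, `[[`, 0L, "frame"),
      lig_res = vapply(rows, `[[`, "", "lig_res"),
      prot_res = vapply(rows, `[[`, "", "prot_res"),
      interaction = vapply(rows, `[[`, "", "interaction"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(frame = integer(), lig_res = character(),
               prot_res = character(), interaction = character(),
               stringsAsFactors = FALSE)
  }
  entries$lig_atoms <- lapply(rows, `[[`, "lig_atoms")
  entries$prot_atoms <- lapply(rows, `[[`, "prot_atoms")
  entries$pairs <- lapply(rows, `[[`, "pairs")

  structure(list(
    interaction_names = interactions,
    frames = seq_len(n_frames) - 1L,
    lig_residues = lig_res_keys,
    prot_residues = prot_res_keys,
    entries = entries
  ), class = "fingerprint_result")
}

#' @export
print.fingerprint_result <- function(x, ...) {
  cat(sprintf(paste0("<fingerprint_result> %d frame(s), %d ligand x %d ",
                     "protein residue(s), %d interaction(s), %d hits\n"),
              length(x$frames), length(x$lig_residues),
              length(x$prot_residues), length(x$interaction_names),
              nrow(x$entries)))
  invisible(x)
}

# full Cartesian bit key: (lig_res x prot_res x interaction), self-pairs
# excluded; residues in total order as recorded, interactions in
# registration order
.bit_key <- function(result) {
  grid <- expand.grid(interaction = result$interaction_names,
                      prot_res = result$prot_residues,
                      lig_res = result$lig_residues,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$lig_res != grid$prot_res, c("lig_res", "prot_res",
                                                "interaction")]
  rownames(grid) <- NULL
  grid
}

.key_id <- function(lig_res, prot_res, interaction) {
  paste(lig_res, prot_res, interaction, sep = "\r")
}

#' Bitvector view of one frame
#'
#' Deterministic bit layout over the full Cartesian key (ligand residue x
#' protein residue x interaction; the ligand collapses to one unit when it
#' is a single residue), identical for every frame of a result so vectors
#' are comparable across frames and runs.
#'
#' @param result a `fingerprint_result`.
#' @param frame a frame id present in `result$frames`.
#' @return logical vector with a `key` attribute (data.frame lig_res,
#'   prot_res, interaction describing each bit).
#' @export
to_bitvector <- function(result, frame) {
  stopifnot(inherits(result, "fingerprint_result"))
  if (!frame %in% result$frames) stop("unknown frame: ", frame)
  key <- .bit_key(result)
  ids <- .key_id(key$lig_res, key$prot_res, key$interaction)
  e <- result$entries[result$entries$frame == frame, , drop = FALSE]
  bits <- ids %in% .key_id(e$lig_res, e$prot_res, e$interaction)
  attr(bits, "key") <- key
  bits
}

#' Tabular view of a fingerprint result
#'
#' Wide logical data.frame: one row per frame, one column per observed
#' (ligand residue, protein residue, interaction) group; missing entries
#' are `FALSE`.
#'
#' @param result a `fingerprint_result`.
#' @return data.frame with a `frame` column followed by logical columns
#'   named `lig_res|prot_res|interaction`.
#' @export
to_table <- function(result) {
  stopifnot(inherits(result, "fingerprint_result"))
  e <- result$entries
  groups <- unique(e[, c("lig_res", "prot_res", "interaction")])
  out <- data.frame(frame = result$frames)
  if (nrow(groups) == 0L) return(out)
  groups <- groups[order(groups$lig_res, groups$prot_res,
                         groups$interaction), , drop = FALSE]
  eid <- .key_id(e$lig_res, e$prot_res, e$interaction)
  for (gi in seq_len(nrow(groups))) {
    gid <- .key_id(groups$lig_res[gi], groups$prot_res[gi],
                   groups$interaction[gi])
    frames_present <- e$frame[eid == gid]
    out[[paste(groups$lig_res[gi], groups$prot_res[gi],
               groups$interaction[gi], sep = "|")]] <-
      result$frames %in% frames_present
  }
  out
}

#' Interaction frequencies across frames
#'
#' Fraction of frames in which each group is present.  `by = "interaction"`
#' returns one row per (ligand residue, protein residue, interaction);
#' `by = "pair"` aggregates to any-interaction contact per residue pair;
#' `by = "residue"` aggregates to any-interaction contact per protein
#' residue (the statistic behind "in contact with the ligand in at least
#' 97% of frames"-style queries).
#'
#' @param result a `fingerprint_result` with >= 1 frame.
#' @param by aggregation level.
#' @return data.frame with a `freq` column in \[0, 1\].
#' @export
frequencies <- function(result, by = c("interaction", "pair", "residue")) {
  stopifnot(inherits(result, "fingerprint_result"))
  by <- match.arg(by)
  n <- length(result$frames)
  if (n == 0L) stop("frequencies undefined for a 0-frame result")
  e <- result$entries
  cols <- switch(by,
                 interaction = c("lig_res", "prot_res", "interaction"),
                 pair = c("lig_res", "prot_res"),
                 residue = "prot_res")
  if (!nrow(e)) {
    out <- stats::setNames(
      as.data.frame(matrix(character(), ncol = length(cols))), cols)
    out$freq <- numeric()
    return(out)
  }
  id <- do.call(paste, c(e[cols], sep = "\r"))
  # count distinct frames per group (a group may have one row per frame only,
  # but "pair"/"residue" levels merge several interactions in one frame)
  tab <- tapply(e$frame, id, function(f) length(unique(f)))
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- cols
  out$freq <- as.numeric(tab) / n
  out <- out[do.call(order, out[cols]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tanimoto similarity matrix between frames
#'
#' `T(i, j) = |bits_i AND bits_j| / |bits_i OR bits_j|` over the per-frame
#' bitvectors.  Two all-false frames compare as `empty_value` (1 by default:
#' identical absence of interactions).
#'
#' @param result a `fingerprint_result` with >= 1 frame.
#' @param empty_value similarity assigned when both frames have no bit set.
#' @return symmetric `n_frames x n_frames` matrix with unit diagonal,
#'   values in \[0, 1\].
#' @export
tanimoto_matrix <- function(result, empty_value = 1) {
  stopifnot(inherits(result, "fingerprint_result"))
  n <- length(result$frames)
  if (n == 0L) stop("tanimoto_matrix undefined for a 0-frame result")
  bits <- vapply(result$frames, function(f) to_bitvector(result, f),
                 logical(length(to_bitvector(result, result$frames[1L]))))
  bits <- matrix(bits, ncol = n)       # bits x frames
  m <- crossprod(bits * 1)             # intersections
  counts <- diag(m)
  unions <- outer(counts, counts, "+") - m
  tm <- ifelse(unions == 0, empty_value, m / ifelse(unions == 0, 1, unions))
  diag(tm) <- 1
  dimnames(tm) <- list(result$frames, result$frames)
  tm
}

#' Export a fingerprint result to CSV (long format)
#'
#' One row per present detection: frame, ligand residue, protein residue,
#' interaction, present flag, and the 0-based parent atom indices on each
#' side (`;`-separated).  Ordering is fully deterministic (frame, ligand
#' residue, protein residue, interaction).
#'
#' @param result a `fingerprint_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
fp_to_csv <- function(result, path) {
  stopifnot(inherits(result, "fingerprint_result"))
  e <- result$entries
  flat <- data.frame(
    frame = e$frame, lig_res = e$lig_res, prot_res = e$prot_res,
    interaction = e$interaction, present = rep(TRUE, nrow(e)),
    lig_atoms = vapply(e$lig_atoms, paste, "", collapse = ";"),
    prot_atoms = vapply(e$prot_atoms, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  flat <- flat[order(flat$frame, flat$lig_res, flat$prot_res,
                     flat$interaction), , drop = FALSE]
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}
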