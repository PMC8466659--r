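# Aggregation of fingerprint results into interaction-network graph data:
# ligand interaction networks (frequency-thresholded, most-frequent-atom
# endpoints), residue interaction networks with display filters and
# state comparison, and GraphML / JSON node-link export.

.graph <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph> %d node(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

.empty_edges <- function(extra = NULL) {
  e <- data.frame(from = character(), to = character(),
                  interaction = character(), weight = numeric(),
                  intra = logical(), stringsAsFactors = FALSE)
  for (nm in extra) e[[nm]] <- character()
  e
}

# parse "ALA135.A" -> list(name, number, chain)
.parse_key <- function(key) {
  m <- regmatches(key, regexec("^([A-Za-z]+)(-?[0-9]+)\\.(.*)$", key))[[1]]
  if (length(m) != 4L) stop("unparseable residue key: ", key)
  list(name = m[2L], number = as.integer(m[3L]), chain = m[4L])
}

.recount_degrees <- function(g) {
  inc <- c(g$edges$from, g$edges$to)
  g$nodes$degree <- vapply(g$nodes$id, function(id) sum(inc == id), 0L)
  g
}

.drop_isolated <- function(g) {
  g <- .recount_degrees(g)
  g$nodes <- g$nodes[g$nodes$degree > 0L, , drop = FALSE]
  rownames(g$nodes) <- NULL
  g
}

#' Ligand interaction network
#'
#' Aggregates a ligand-protein fingerprint run into one edge per (protein
#' residue, interaction) group whose frequency across frames is at least
#' `threshold`.  The ligand endpoint of each edge is the MOST FREQUENT
#' ligand atom for that group across frames (ties broken by lowest atom
#' index); edge weight is the group frequency.  Run the fingerprint with
#' `all_pairs = TRUE` for complete atom statistics.
#'
#' @param result a `fingerprint_result`.
#' @param threshold minimum frequency in \[0, 1\] (default 0.3).
#' @return an `interaction_graph` whose ligand nodes are named
#'   `<lig_res>:atom<idx>`.
#' @export
lig_network <- function(result, threshold = 0.3) {
  stopifnot(inherits(result, "fingerprint_result"))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  n <- length(result$frames)
  if (n == 0L) stop("lig_network needs >= 1 frame")
  e <- result$entries
  gid <- .key_id(e$lig_res, e$prot_res, e$interaction)
  edges <- .empty_edges()
  node_ids <- character(); node_types <- character(); node_labels <- character()
  for (g in unique(gid)) {
    rows <- which(gid == g)
    freq <- length(unique(e$frame[rows])) / n
    if (freq < threshold) next
    # per-frame ligand atom participation: an atom counts once per frame
    atom_frames <- list()
    for (r in rows) {
      atoms <- unique(unlist(lapply(e$pairs[[r]], `[[`, "lig")))
      for (a in atoms) {
        k <- as.character(a)
        atom_frames[[k]] <- union(atom_frames[[k]], e$frame[r])
      }
    }
    counts <- vapply(atom_frames, length, 0L)
    idx <- as.integer(names(atom_frames))
    best <- idx[order(-counts, idx)][1L]
    lig_node <- sprintf("%s:atom%d", e$lig_res[rows[1L]], best)
    prot_node <- e$prot_res[rows[1L]]
    edges <- rbind(edges, data.frame(
      from = lig_node, to = prot_node,
      interaction = e$interaction[rows[1L]], weight = freq, intra = FALSE,
      stringsAsFactors = FALSE))
    node_ids <- c(node_ids, lig_node, prot_node)
    node_types <- c(node_types, "ligand_atom", "residue")
    node_labels <- c(node_labels, lig_node, prot_node)
  }
  keep <- !duplicated(node_ids)
  nodes <- data.frame(id = node_ids[keep], type = node_types[keep],
                      label = node_labels[keep],
                      segment = rep(NA_character_, sum(keep)),
                      degree = integer(sum(keep)), stringsAsFactors = FALSE)
  .recount_degrees(.graph(nodes, edges))
}

#' Residue interaction network
#'
#' One edge per detected (residue, residue, interaction) triple, weighted by
#' frequency, with the display filters used for residue-network figures:
#' drop edges within one segment (helix/domain label), drop edges between
#' sequence neighbours, drop named interaction types (e.g. Hydrophobic),
#' drop edges between covalently linked residues, and prune residues left
#' without any interaction.  All filters commute.
#'
#' @param result a `fingerprint_result` (typically an intramolecular or
#'   two-chain run).
#' @param segments optional named character vector mapping residue keys to
#'   segment labels (e.g. `c("ARG135.A" = "TM3")`); see
#'   [read_segment_labels()].
#' @param drop_same_segment drop edges whose endpoints share a segment
#'   label.
#' @param min_separation drop edges between same-chain residues whose
#'   number difference is below this (e.g. 3 drops |i - j| < 3); `NULL`
#'   disables.
#' @param drop_interactions character vector of interaction names to hide.
#' @param drop_covalent `"none"`, `"sequence_adjacent"` (same-chain
#'   neighbours, |i - j| <= 1) or `"bonded"` (alias of sequence_adjacent for
#'   chain neighbours; disulfide-style links cannot be recovered from a
#'   fingerprint result and must be filtered by segment instead).
#' @param drop_isolated prune nodes with no remaining edge.
#' @return an `interaction_graph`.
#' @export
residue_network <- function(result, segments = NULL,
                            drop_same_segment = FALSE,
                            min_separation = NULL,
                            drop_interactions = character(),
                            drop_covalent = c("none", "sequence_adjacent",
                                              "bonded"),
                            drop_isolated = TRUE) {
  stopifnot(inherits(result, "fingerprint_result"))
  drop_covalent <- match.arg(drop_covalent)
  n <- length(result$frames)
  if (n == 0L) stop("residue_network needs >= 1 frame")
  fr <- frequencies(result, by = "interaction")
  all_keys <- unique(c(fr$lig_res, fr$prot_res,
                       result$lig_residues, result$prot_residues))
  seg_of <- function(key) {
    if (is.null(segments)) return(NA_character_)
    if (!is.null(segments[key]) && !is.na(segments[key])) unname(segments[key])
    else NA_character_
  }
  if (drop_same_segment && !is.null(segments)) {
    unknown <- setdiff(names(segments), all_keys)
    if (length(unknown)) {
      stop("segment label(s) reference unknown residues: ",
           paste(unknown, collapse = ", "))
    }
  }
  edges <- .empty_edges()
  if (nrow(fr)) {
    pa <- lapply(fr$lig_res, .parse_key)
    pb <- lapply(fr$prot_res, .parse_key)
    keep <- rep(TRUE, nrow(fr))
    for (i in seq_len(nrow(fr))) {
      a <- pa[[i]]; b <- pb[[i]]
      same_chain <- identical(a$chain, b$chain)
      dn <- abs(a$number - b$number)
      if (fr$interaction[i] %in% drop_interactions) keep[i] <- FALSE
      if (!is.null(min_separation) && same_chain && dn < min_separation) {
        keep[i] <- FALSE
      }
      if (drop_covalent != "none" && same_chain && dn <= 1L) keep[i] <- FALSE
      if (drop_same_segment) {
        sa <- seg_of(fr$lig_res[i]); sb <- seg_of(fr$prot_res[i])
        if (!is.na(sa) && !is.na(sb) && identical(sa, sb)) keep[i] <- FALSE
      }
    }
    fr <- fr[keep, , drop = FALSE]
    if (nrow(fr)) {
      edges <- data.frame(
        from = fr$lig_res, to = fr$prot_res, interaction = fr$interaction,
        weight = fr$freq,
        intra = vapply(seq_len(nrow(fr)), function(i) {
          identical(.parse_key(fr$lig_res[i])$chain,
                    .parse_key(fr$prot_res[i])$chain)
        }, TRUE),
        stringsAsFactors = FALSE)
    }
  }
  nodes <- data.frame(
    id = all_keys, type = "residue", label = all_keys,
    segment = vapply(all_keys, seg_of, ""),
    degree = 0L, stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  g <- .graph(nodes, edges)
  if (drop_isolated) .drop_isolated(g) else .recount_degrees(g)
}

#' Compare two interaction networks
#'
#' Labels each edge of the union graph `"only_a"`, `"only_b"` or `"both"`,
#' the comparison used to contrast e.g. active and inactive receptor
#' states (an ionic-lock salt bridge present only in the inactive state
#' shows up as an `only_b` edge).  Edge identity is (unordered endpoint
#' pair, interaction).
#'
#' @param graph_a,graph_b `interaction_graph`s over a comparable residue
#'   id scheme.
#' @return an `interaction_graph` whose edges carry a `state` column.
#' @export
compare_states <- function(graph_a, graph_b) {
  stopifnot(inherits(graph_a, "interaction_graph"),
            inherits(graph_b, "interaction_graph"))
  eid <- function(e) {
    if (!nrow(e)) return(character())
    vapply(seq_len(nrow(e)), function(i) {
      ends <- sort(c(e$from[i], e$to[i]))
      paste(ends[1L], ends[2L], e$interaction[i], sep = "\r")
    }, "")
  }
  ia <- eid(graph_a$edges); ib <- eid(graph_b$edges)
  ea <- graph_a$edges; ea$state <- ifelse(ia %in% ib, "both", "only_a")
  eb <- graph_b$edges[!(ib %in% ia), , drop = FALSE]
  if (nrow(eb)) eb$state <- "only_b"
  edges <- rbind(ea, eb)
  rownames(edges) <- NULL
  nodes <- rbind(graph_a$nodes, graph_b$nodes)
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  .recount_degrees(.graph(nodes, edges))
}

#' Convert an interaction graph to an igraph object
#'
#' @param graph an `interaction_graph`.
#' @return an `igraph` graph with all node/edge attributes carried over.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  nodes <- graph$nodes
  nodes$segment[is.na(nodes$segment)] <- ""
  edges <- graph$edges
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Write an interaction graph to GraphML
#'
#' @param graph an `interaction_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Write an interaction graph as JSON node-link data
#'
#' Layout: `{"nodes": [...], "links": [...]}` with one object per node and
#' edge, the standard node-link interchange consumed by d3-style viewers.
#'
#' @param graph an `interaction_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_json_nodelink <- function(graph, path) {
  stopifnot(inherits(graph, "interaction_graph"))
  payload <- list(nodes = graph$nodes, links = graph$edges)
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read residue-to-segment labels from a two-column text file
#'
#' Whitespace-separated lines `"<residue key> <label>"`, e.g.
#' `"ARG135.A TM3"`; `#` comments allowed.
#'
#' @param path file path.
#' @return named character vector (names are residue keys).
#' @export
read_segment_labels <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("residue", "segment"),
                           stringsAsFactors = FALSE)
  stats::setNames(tab$segment, tab$residue)
}
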