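# Charge-redistribution analysis: directed fragment-level charge-flow graph
# from apo->holo charge changes plus FMO2 dimer charge transfer, and hub
# detection (fragments mediating indirect coupling between fragments that
# share no direct edge).

new_flow_graph <- function(nodes, edges, threshold, metadata = list()) {
  out <- list(nodes = tibble::as_tibble(nodes),
              edges = tibble::as_tibble(edges),
              threshold = threshold,
              metadata = metadata)
  class(out) <- "flow_graph"
  out
}

#' Build the directed charge-flow graph between apo and holo states
#'
#' Nodes are fragments annotated with their binding-induced charge shift
#' `delta_q = q_holo - q_apo` (for the guest, relative to its formal charge).
#' Edges come from the FMO2 dimer charge shifts: for a dimer pair (I, J) the
#' dimer-minus-monomer Mulliken charge change `dq_I` estimates the electron
#' flow, giving a directed edge I -> J with weight `|dq_I|` when `dq_I > 0`
#' (I loses electrons), J -> I otherwise. Edges below `threshold` are
#' dropped. Without dimer data a guest-centred `delta_q` heuristic is used
#' and recorded in the graph metadata.
#'
#' @param fmo1_apo All-QM [fmo1()] result of the host alone.
#' @param fmo1_holo All-QM [fmo1()] result of the complex (host fragment ids
#'   matching `fmo1_apo`).
#' @param pairs [fmo2()] pair table of the holo run (may be `NULL`).
#' @param rmin Distance map tibble (`fragment_id`, `rmin`) for node
#'   annotation.
#' @param threshold Minimum edge weight in e (default 0.005).
#' @param pairs_apo Optional [fmo2()] pair table of the apo run, used to
#'   dimer-correct the apo fragment charges symmetrically.
#' @return A `flow_graph` object with `$nodes`, `$edges`, `$threshold`.
#' @export
charge_flow_graph <- function(fmo1_apo, fmo1_holo, pairs = NULL, rmin = NULL,
                              threshold = 0.005, pairs_apo = NULL) {
  if (threshold <= 0) rlang::abort("threshold must be positive")
  fr_apo <- if (inherits(fmo1_apo, "fmo1_result")) {
    fr <- fmo1_apo$fragments
    if (!is.null(pairs_apo)) {
      corr <- fmo2_fragment_charges(fmo1_apo, pairs_apo)
      fr$q <- corr$q[match(fr$fragment_id, corr$fragment_id)]
    }
    fr
  } else tibble::as_tibble(fmo1_apo)
  fr_holo <- if (inherits(fmo1_holo, "fmo1_result")) {
    fr <- fmo1_holo$fragments
    if (!is.null(pairs)) {
      corr <- fmo2_fragment_charges(fmo1_holo, pairs)
      fr$q <- corr$q[match(fr$fragment_id, corr$fragment_id)]
    }
    fr
  } else tibble::as_tibble(fmo1_holo)

  host_holo <- fr_holo[fr_holo$role != "guest", ]
  host_apo <- fr_apo[fr_apo$role != "guest", ]
  if (!setequal(host_holo$fragment_id, host_apo$fragment_id)) {
    rlang::abort("apo and holo runs do not share host fragment ids")
  }
  m <- match(host_holo$fragment_id, host_apo$fragment_id)
  nodes <- tibble::tibble(
    fragment_id = host_holo$fragment_id,
    name = host_holo$name,
    delta_q = host_holo$q - host_apo$q[m]
  )
  guest <- fr_holo[fr_holo$role == "guest", ]
  if (nrow(guest) > 0) {
    nodes <- dplyr::bind_rows(nodes, tibble::tibble(
      fragment_id = guest$fragment_id, name = guest$name,
      delta_q = guest$q - guest$formal_charge
    ))
  }
  nodes <- dplyr::arrange(nodes, .data$fragment_id)
  if (!is.null(rmin)) {
    nodes <- dplyr::left_join(nodes,
                              tibble::as_tibble(rmin)[, c("fragment_id", "rmin")],
                              by = "fragment_id")
  } else {
    nodes$rmin <- NA_real_
  }

  metadata <- list(total_delta_q = sum(nodes$delta_q))
  dimers <- if (!is.null(pairs)) pairs[pairs$method == "dimer", ] else NULL
  if (!is.null(dimers) && nrow(dimers) > 0) {
    src <- ifelse(dimers$delta_q_i > 0, dimers$i, dimers$j)
    dst <- ifelse(dimers$delta_q_i > 0, dimers$j, dimers$i)
    w <- abs(dimers$delta_q_i)
    edges <- tibble::tibble(source = src, target = dst, weight = w,
                            derived_from = "dimer")
  } else {
    rlang::warn("no dimer charge data; falling back to delta_q heuristic")
    metadata$fallback <- "delta_q heuristic (no dimer data)"
    if (nrow(guest) == 1) {
      host_nodes <- nodes[nodes$fragment_id != guest$fragment_id, ]
      src <- ifelse(host_nodes$delta_q > 0, host_nodes$fragment_id,
                    guest$fragment_id)
      dst <- ifelse(host_nodes$delta_q > 0, guest$fragment_id,
                    host_nodes$fragment_id)
      edges <- tibble::tibble(source = src, target = dst,
                              weight = abs(host_nodes$delta_q),
                              derived_from = "delta_q")
    } else {
      edges <- tibble::tibble(source = integer(), target = integer(),
                              weight = numeric(), derived_from = character())
    }
  }
  edges <- edges[edges$weight >= threshold & edges$source != edges$target, ]
  edges <- dplyr::arrange(edges, .data$source, .data$target)
  new_flow_graph(nodes, edges, threshold, metadata)
}

#' @export
print.flow_graph <- function(x, ...) {
  cat(sprintf("<flow_graph> %d nodes, %d edges (threshold %g e)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  if (!is.null(x$metadata$fallback)) {
    cat(sprintf("  note: %s\n", x$metadata$fallback))
  }
  invisible(x)
}

#' @export
tidy.flow_graph <- function(x, ...) x$edges

flow_graph_igraph <- function(graph) {
  verts <- data.frame(name = as.character(graph$nodes$fragment_id))
  if (nrow(graph$edges) > 0) {
    ed <- data.frame(from = as.character(graph$edges$source),
                     to = as.character(graph$edges$target),
                     weight = graph$edges$weight)
  } else {
    ed <- data.frame(from = character(), to = character(), weight = numeric())
  }
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
}

#' Detect hub fragments mediating indirect coupling
#'
#' A mediation triplet (i, k, j) has charge-flow edges i-k and k-j but no
#' direct i-j edge; the mediator k is a hub candidate. Nodes are ranked by
#' (triplet participation count, betweenness centrality on the undirected
#' thresholded graph) lexicographically, ties broken by fragment id; only
#' nodes mediating at least one triplet are reported.
#'
#' @param graph A [charge_flow_graph()] result.
#' @param top_k Number of hubs to report (default 5).
#' @return A `hub_report` with `$hubs` (ranked fragment ids), `$scores`
#'   (per-node triplet counts and betweenness in `[0, 1]`) and `$triplets`
#'   (i, k, j with supporting edge weights).
#' @export
detect_hubs <- function(graph, top_k = 5) {
  stopifnot(inherits(graph, "flow_graph"))
  ids <- graph$nodes$fragment_id
  out_empty <- function() {
    out <- list(hubs = integer(),
                scores = tibble::tibble(fragment_id = integer(),
                                        triplets = integer(),
                                        betweenness = numeric()),
                triplets = tibble::tibble(i = integer(), k = integer(),
                                          j = integer(), w_ik = numeric(),
                                          w_kj = numeric()),
                top_k = top_k)
    class(out) <- "hub_report"
    out
  }
  if (nrow(graph$edges) == 0) return(out_empty())

  # Undirected adjacency with edge weights (max over directions).
  ed <- graph$edges
  a <- pmin(ed$source, ed$target); b <- pmax(ed$source, ed$target)
  und <- dplyr::summarise(dplyr::group_by(tibble::tibble(a = a, b = b,
                                                         w = ed$weight),
                                          .data$a, .data$b),
                          w = max(.data$w), .groups = "drop")
  nbr <- list()
  wmap <- new.env(parent = emptyenv())
  ekey <- function(i, j) paste(min(i, j), max(i, j))
  for (r in seq_len(nrow(und))) {
    i <- und$a[r]; j <- und$b[r]
    nbr[[as.character(i)]] <- c(nbr[[as.character(i)]], j)
    nbr[[as.character(j)]] <- c(nbr[[as.character(j)]], i)
    assign(ekey(i, j), und$w[r], envir = wmap)
  }
  has_edge <- function(i, j) exists(ekey(i, j), envir = wmap)

  trip <- list()
  for (k in sort(as.integer(names(nbr)))) {
    nb <- sort(unique(nbr[[as.character(k)]]))
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    for (c_i in seq_len(ncol(cmb))) {
      i <- cmb[1, c_i]; j <- cmb[2, c_i]
      if (!has_edge(i, j)) {
        trip[[length(trip) + 1]] <- tibble::tibble(
          i = i, k = k, j = j,
          w_ik = get(ekey(i, k), envir = wmap),
          w_kj = get(ekey(k, j), envir = wmap)
        )
      }
    }
  }
  triplets <- if (length(trip) > 0) dplyr::bind_rows(trip) else
    tibble::tibble(i = integer(), k = integer(), j = integer(),
                   w_ik = numeric(), w_kj = numeric())

  g <- flow_graph_igraph(graph)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  btw <- btw[as.character(ids)]
  counts <- table(factor(triplets$k, levels = ids))
  scores <- tibble::tibble(
    fragment_id = ids,
    triplets = as.integer(counts),
    betweenness = as.numeric(btw)
  )
  scores <- dplyr::arrange(scores, dplyr::desc(.data$triplets),
                           dplyr::desc(.data$betweenness), .data$fragment_id)
  hubs <- scores$fragment_id[scores$triplets > 0]
  hubs <- utils::head(hubs, top_k)
  out <- list(hubs = hubs, scores = scores, triplets = triplets,
              top_k = top_k)
  class(out) <- "hub_report"
  out
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("<hub_report> %d hub(s) of top_k = %d; %d mediation triplet(s)\n",
              length(x$hubs), x$top_k, nrow(x$triplets)))
  if (length(x$hubs) > 0) {
    cat("  hubs:", paste(x$hubs, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.hub_report <- function(x, ...) x$scores

#' Export a flow graph as edge/node TSV files
#'
#' @param graph A `flow_graph`.
#' @param dir Output directory (created if missing).
#' @return Paths of the two files, invisibly.
#' @export
write_flow_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- graph$nodes
  node_path <- file.path(dir, "nodes.tsv")
  edge_path <- file.path(dir, "edges.tsv")
  utils::write.table(
    data.frame(fragment_id = nodes$fragment_id, name = nodes$name,
               rmin_A = nodes$rmin, delta_q_e = nodes$delta_q),
    node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(source = graph$edges$source, target = graph$edges$target,
               weight_e = graph$edges$weight,
               derived_from = graph$edges$derived_from),
    edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(node_path, edge_path))
}
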