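#' Build a coupling graph gated by spatial contacts
#'
#' Nodes are fragments; an undirected edge joins fragments `i` and `j` iff
#' (a) the minimum inter-Calpha distance between the two 4-residue windows
#' in a reference structure is at most `cutoff` (so paths are physically
#' contiguous) and (b) their coupling `nMI(i, j) >= min_nmi`. Edge cost is
#' `-ln(nMI)`: multiplicative coupling along a path becomes additive cost,
#' so stronger coupling means a shorter path.
#'
#' @param network An [ensemble_average()] network or [mi_matrix()].
#' @param reference A [trajectory()] (its frame `ref_frame` supplies Calpha
#'   positions) covering the fragment space.
#' @param cutoff Contact cutoff in nm (default 0.75).
#' @param min_nmi Minimum coupling for an edge (default 0.01).
#' @param ref_frame Reference frame index (default 1).
#' @return An object of class `coupling_graph`: `edges` tibble (`i, j,
#'   nmi, dist, cost`), `nodes` fragment tibble, parameters.
#' @export
build_graph <- function(network, reference, cutoff = 0.75, min_nmi = 0.01,
                        ref_frame = 1L) {
  if (inherits(network, "ensemble_network")) {
    vals <- network$matrix; frags <- network$fragments
  } else if (inherits(network, "mi_matrix")) {
    vals <- network$values; frags <- network$fragments
  } else {
    abort("`network` must be an ensemble_network or mi_matrix.")
  }
  stopifnot(inherits(reference, "Trajectory"))
  sel <- select_calpha(reference)
  xyz <- frame_coords(reference, ref_frame)
  # per-fragment 4-Calpha coordinate block
  frag_xyz <- lapply(seq_len(nrow(frags)), function(f) {
    ch <- sel[sel$chain == frags$chain[f], ]
    if (nrow(ch) == 0L) {
      abort(paste0("Reference lacks chain ", frags$chain[f]))
    }
    pos <- match(frags$first_resid[f] + 0:3, ch$resid[[1]])
    if (anyNA(pos)) {
      abort(sprintf("Reference lacks residues %d-%d of chain %s.",
                    frags$first_resid[f], frags$first_resid[f] + 3L,
                    frags$chain[f]))
    }
    xyz[ch$atom_idx[[1]][pos], , drop = FALSE]
  })
  P <- nrow(frags)
  edges <- list()
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      if (vals[i, j] < min_nmi) next
      dd <- min(sqrt(outer(rowSums(frag_xyz[[i]]^2),
                           rowSums(frag_xyz[[j]]^2), `+`) -
                       2 * tcrossprod(frag_xyz[[i]], frag_xyz[[j]])))
      if (!is.finite(dd) || dd > cutoff) next
      edges[[length(edges) + 1L]] <- tibble(
        i = i, j = j, nmi = vals[i, j], dist = dd,
        cost = -log(vals[i, j]))
    }
  }
  edges <- dplyr::bind_rows(edges)
  if (nrow(edges) == 0L) {
    abort("Empty coupling graph: relax `cutoff` or `min_nmi`.")
  }
  structure(list(edges = edges, nodes = frags, cutoff = cutoff,
                 min_nmi = min_nmi),
            class = "coupling_graph")
}

#' @export
print.coupling_graph <- function(x, ...) {
  cat(sprintf(
    "<coupling_graph> %d fragments, %d contact-gated edges (cutoff %.2f nm, nMI >= %g)\n",
    nrow(x$nodes), nrow(x$edges), x$cutoff, x$min_nmi))
  invisible(x)
}

#' Convert a coupling graph to an igraph object
#' @param graph A [build_graph()] result.
#' @return An undirected [igraph::graph] with `weight = cost` edges.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "coupling_graph"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$edges$i, to = graph$edges$j,
               weight = graph$edges$cost),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(graph$nodes))))
  g
}

## Dijkstra with deterministic lexicographic tie-breaks: among equal-cost
## relaxations the predecessor with the lower node index wins, and the
## frontier pops the lowest-index node among equal distances.
.dijkstra <- function(n, adj, sources) {
  dist <- rep(Inf, n); prev <- rep(NA_integer_, n)
  dist[sources] <- 0
  visited <- rep(FALSE, n)
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]  # which.min: lowest index on ties
    visited[u] <- TRUE
    for (e in adj[[u]]) {
      v <- e[1]; w <- e[2]
      nd <- dist[u] + w
      if (nd < dist[v] - 1e-15 ||
          (abs(nd - dist[v]) <= 1e-15 && !is.na(prev[v]) && u < prev[v])) {
        dist[v] <- min(nd, dist[v]); prev[v] <- u
      }
    }
  }
  list(dist = dist, prev = prev)
}

#' Minimal-cost communication pathways between fragment sets
#'
#' Runs Dijkstra's algorithm from a virtual super-source (zero-cost links to
#' every source fragment) and traces the minimal `-ln(nMI)` path to each
#' sink, returning up to `k` sink paths sorted by total cost (ties broken
#' lexicographically). Unreachable sinks are reported explicitly.
#'
#' @param graph A [build_graph()] result.
#' @param sources,sinks Fragment indices (or residue lists mapped via
#'   [fragments_for_residues()]).
#' @param k Maximum number of sink paths returned (default 1).
#' @return A tibble of class `path_result` with columns `sink`, `path`
#'   (list of fragment indices), `cost`, `edge_costs` (list), `reachable`.
#' @export
shortest_path <- function(graph, sources, sinks, k = 1L) {
  stopifnot(inherits(graph, "coupling_graph"))
  n <- nrow(graph$nodes)
  sources <- unique(as.integer(sources)); sinks <- unique(as.integer(sinks))
  if (!length(sources) || !length(sinks)) {
    abort("`sources` and `sinks` must be non-empty.")
  }
  if (any(c(sources, sinks) < 1L) || any(c(sources, sinks) > n)) {
    abort("Source/sink fragment index out of range.")
  }
  adj <- vector("list", n)
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[r]; j <- graph$edges$j[r]; w <- graph$edges$cost[r]
    adj[[i]] <- c(adj[[i]], list(c(j, w)))
    adj[[j]] <- c(adj[[j]], list(c(i, w)))
  }
  dj <- .dijkstra(n, adj, sources)
  res <- lapply(sort(sinks), function(s) {
    if (!is.finite(dj$dist[s])) {
      return(tibble(sink = s, path = list(integer(0)), cost = Inf,
                    edge_costs = list(numeric(0)), reachable = FALSE))
    }
    path <- s
    while (!is.na(dj$prev[path[1]])) path <- c(dj$prev[path[1]], path)
    ec <- vapply(seq_len(length(path) - 1L), function(t) {
      e <- graph$edges
      hit <- (e$i == path[t] & e$j == path[t + 1]) |
             (e$j == path[t] & e$i == path[t + 1])
      e$cost[hit][1]
    }, numeric(1))
    tibble(sink = s, path = list(path), cost = dj$dist[s],
           edge_costs = list(ec), reachable = TRUE)
  })
  out <- dplyr::bind_rows(res)
  out <- out[order(out$cost, out$sink), ]
  out <- head(out, k)
  class(out) <- c("path_result", class(out))
  out
}

#' Map residue lists to fragment indices
#'
#' A fragment belongs to a set if any of its 4 residues is listed.
#'
#' @param graph A [build_graph()] result (or any object with a `nodes` /
#'   `fragments` tibble).
#' @param residues Integer residue indices.
#' @param chain Optional chain filter.
#' @return Integer fragment indices.
#' @export
fragments_for_residues <- function(graph, residues, chain = NULL) {
  nodes <- graph$nodes %||% graph$fragments
  hit <- vapply(seq_len(nrow(nodes)), function(f) {
    any((nodes$first_resid[f] + 0:3) %in% residues) &&
      (is.null(chain) || nodes$chain[f] %in% chain)
  }, logical(1))
  which(hit)
}

#' Fraction of hub fragments lying on at least one pathway
#'
#' @param paths A [shortest_path()] result (or list of them).
#' @param hubs A [call_hubs()] `hub_table` (or integer fragment indices).
#' @return List with `fraction` and `per_hub` tibble (`fragment, on_path`).
#' @export
hub_path_overlap <- function(paths, hubs) {
  if (inherits(paths, "path_result")) paths <- list(paths)
  nodes <- unique(unlist(lapply(paths, function(p) unlist(p$path))))
  hub_ids <- if (inherits(hubs, "hub_table")) hubs$hubs$fragment
             else as.integer(hubs)
  if (!length(hub_ids)) {
    return(list(fraction = NA_real_,
                per_hub = tibble(fragment = integer(), on_path = logical())))
  }
  on_path <- hub_ids %in% nodes
  list(fraction = mean(on_path),
       per_hub = tibble(fragment = hub_ids, on_path = on_path))
}
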