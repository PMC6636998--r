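## a straight-chain reference whose fragments are 4-residue slots
chain_reference <- function(n_res = 20, spacing = 0.38) {
  coords <- array(0, dim = c(1, n_res, 3))
  coords[1, , 1] <- spacing * seq_len(n_res)
  trajectory(coords, tibble::tibble(
    chain = "A", resid = seq_len(n_res), resname = "ALA", name = "CA",
    mass = 12.011))
}

net_from_matrix <- function(v, n_res = 20) {
  p <- nrow(v)
  frag <- tibble::tibble(column = seq_len(p), chain = "A",
                         first_resid = 4 * (seq_len(p) - 1) + 1)
  structure(list(state = "s", matrix = v, weights = NULL, samples = list(v),
                 fragments = frag, mask = NULL),
            class = "ensemble_network")
}

test_that("build_graph gates edges by contact distance and coupling", {
  v <- matrix(0, 5, 5)
  v[1, 2] <- v[2, 1] <- 0.5     # adjacent slots: contact at ~0.38 nm
  v[1, 5] <- v[5, 1] <- 0.9     # slots 1 and 5 are ~ 4.9 nm apart: no edge
  v[2, 3] <- v[3, 2] <- 0.005   # below min_nmi: no edge
  g <- build_graph(net_from_matrix(v), chain_reference(), cutoff = 0.75,
                   min_nmi = 0.01)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$i, 1L); expect_equal(g$edges$j, 2L)
  expect_equal(g$edges$cost, log(2), tolerance = 1e-12)  # -ln(0.5)

  v0 <- matrix(0, 5, 5)
  expect_error(build_graph(net_from_matrix(v0), chain_reference()),
               "cutoff")
})

test_that("3-node chain: hand-computed shortest path", {
  # A-B cost 1, B-C cost 1, direct A-C cost 3  =>  A-B-C, cost 2
  v <- matrix(0, 3, 3)
  v[1, 2] <- v[2, 1] <- exp(-1)
  v[2, 3] <- v[3, 2] <- exp(-1)
  v[1, 3] <- v[3, 1] <- exp(-3)
  ref <- chain_reference(12)
  g <- build_graph(net_from_matrix(v, 12), ref, cutoff = 10, min_nmi = 1e-6)
  p <- shortest_path(g, sources = 1, sinks = 3)
  expect_equal(p$path[[1]], c(1L, 2L, 3L))
  expect_equal(p$cost, 2, tolerance = 1e-12)
  expect_equal(sum(p$edge_costs[[1]]), p$cost)
})

test_that("Dijkstra equals exhaustive enumeration on random graphs <= 8 nodes", {
  set.seed(61)
  for (trial in 1:40) {
    n <- sample(4:8, 1)
    v <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.5) v[i, j] <- v[j, i] <- runif(1, 0.05, 0.95)
    }
    if (all(v == 0)) next
    ref <- chain_reference(4 * n + 4)
    g <- tryCatch(build_graph(net_from_matrix(v, 4 * n + 4), ref,
                              cutoff = 100, min_nmi = 1e-6),
                  error = function(e) NULL)
    if (is.null(g)) next
    from <- sample(n, 1); to <- sample(setdiff(1:n, from), 1)
    got <- shortest_path(g, from, to)
    oracle <- enum_shortest(g$edges, n, from, to)
    if (!got$reachable) {
      expect_equal(oracle$cost, Inf)
    } else {
      expect_equal(got$cost, oracle$cost, tolerance = 1e-10)
      # cross-check against igraph's Dijkstra as a second, independent route
      ig <- igraph::graph_from_data_frame(
        data.frame(from = g$edges$i, to = g$edges$j, weight = g$edges$cost),
        directed = FALSE, vertices = data.frame(name = 1:n))
      expect_equal(got$cost,
                   igraph::distances(ig, v = as.character(from),
                                     to = as.character(to))[1, 1],
                   tolerance = 1e-10)
    }
  }
})

test_that("planted high-coupling conduit is traversed end to end", {
  n <- 10
  v <- matrix(0, n, n)
  conduit <- c(1, 3, 5, 7, 9)
  for (k in seq_len(length(conduit) - 1)) {
    v[conduit[k], conduit[k + 1]] <- v[conduit[k + 1], conduit[k]] <- 0.9
  }
  set.seed(71)  # weak background couplings
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (v[i, j] == 0) v[i, j] <- v[j, i] <- runif(1, 0.01, 0.05)
  }
  ref <- chain_reference(4 * n + 4)
  g <- build_graph(net_from_matrix(v, 4 * n + 4), ref, cutoff = 100,
                   min_nmi = 1e-3)
  p <- shortest_path(g, sources = 1, sinks = 9)
  expect_true(all(conduit %in% p$path[[1]]))
})

test_that("unreachable sinks are reported explicitly, not dropped", {
  v <- matrix(0, 6, 6)
  v[1, 2] <- v[2, 1] <- 0.5
  v[4, 5] <- v[5, 4] <- 0.5   # separate component
  ref <- chain_reference(28)
  g <- build_graph(net_from_matrix(v, 28), ref, cutoff = 100, min_nmi = 1e-6)
  p <- shortest_path(g, sources = 1, sinks = c(2, 5), k = 2)
  expect_equal(nrow(p), 2L)
  expect_true(p$reachable[p$sink == 2])
  expect_false(p$reachable[p$sink == 5])
  expect_equal(p$cost[p$sink == 5], Inf)
})

test_that("path cost is monotone in edge coupling; off-path edges are inert", {
  v <- matrix(0, 6, 6)
  v[1, 2] <- v[2, 1] <- 0.5; v[2, 3] <- v[3, 2] <- 0.5
  v[4, 5] <- v[5, 4] <- 0.2  # off the optimal 1-2-3 path
  ref <- chain_reference(28)
  mk <- function(vv) build_graph(net_from_matrix(vv, 28), ref, cutoff = 100,
                                 min_nmi = 1e-6)
  base <- shortest_path(mk(v), 1, 3)
  # raise an on-path coupling -> cost cannot increase
  v_up <- v; v_up[1, 2] <- v_up[2, 1] <- 0.8
  expect_lte(shortest_path(mk(v_up), 1, 3)$cost, base$cost + 1e-12)
  # remove an off-path edge -> identical optimal path
  v_rm <- v; v_rm[4, 5] <- v_rm[5, 4] <- 0
  p_rm <- shortest_path(mk(v_rm), 1, 3)
  expect_identical(p_rm$path[[1]], base$path[[1]])
  expect_equal(p_rm$cost, base$cost)
})

test_that("super-source equals the minimum over per-source runs", {
  set.seed(81)
  n <- 8
  v <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < 0.6) v[i, j] <- v[j, i] <- runif(1, 0.05, 0.9)
  }
  ref <- chain_reference(4 * n + 4)
  g <- build_graph(net_from_matrix(v, 4 * n + 4), ref, cutoff = 100,
                   min_nmi = 1e-6)
  srcs <- c(1, 4); sink <- 7
  joint <- shortest_path(g, srcs, sink)
  per_source <- min(shortest_path(g, 1, sink)$cost,
                    shortest_path(g, 4, sink)$cost)
  expect_equal(joint$cost, per_source, tolerance = 1e-12)
})

test_that("hub/path overlap fractions and residue-to-fragment mapping", {
  paths <- tibble::tibble(sink = 5L, path = list(c(1L, 3L, 5L)), cost = 1,
                          edge_costs = list(c(0.5, 0.5)), reachable = TRUE)
  class(paths) <- c("path_result", class(paths))
  expect_equal(hub_path_overlap(paths, c(1L, 3L))$fraction, 1)
  expect_equal(hub_path_overlap(paths, c(2L, 4L))$fraction, 0)
  ov <- hub_path_overlap(paths, c(1L, 3L, 5L, 2L, 4L))
  expect_equal(ov$fraction, 0.6)
  expect_equal(sum(ov$per_hub$on_path), 3L)

  v <- matrix(0, 5, 5); v[1, 2] <- v[2, 1] <- 0.5
  g <- build_graph(net_from_matrix(v), chain_reference(), cutoff = 0.75,
                   min_nmi = 0.01)
  # fragment f covers residues 4(f-1)+1 .. 4(f-1)+4
  expect_equal(fragments_for_residues(g, 1:4), 1L)
  expect_equal(fragments_for_residues(g, 6), 2L)
  expect_equal(fragments_for_residues(g, c(2, 10)), c(1L, 3L))
})
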