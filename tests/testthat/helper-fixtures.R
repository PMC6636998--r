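## Fixtures and independent oracles, all built in code at test time.

## --- tiny PDB writer (independent of the package's writer) ----------------

write_toy_pdb <- function(path, n_models = 2, n_res = 6, chains = "A",
                          jitter = 0, seed = 1) {
  set.seed(seed)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n_models)) {
    if (n_models > 1) writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0
    for (ch in chains) {
      for (r in seq_len(n_res)) {
        serial <- serial + 1
        xyz <- c(3.8 * r, 10 * match(ch, chains), 0) +
          if (jitter > 0) rnorm(3, sd = jitter) else 0
        writeLines(sprintf(
          "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, ch, r, xyz[1], xyz[2], xyz[3]), con)
      }
    }
    if (n_models > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## a small in-code trajectory (no file round trip)
toy_traj <- function(n_frames = 3, n_res = 8, chains = "A", jitter = 0.01,
                     seed = 1) {
  set.seed(seed)
  n_atoms <- n_res * length(chains)
  coords <- array(0, dim = c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames)) {
    a <- 0
    for (ci in seq_along(chains)) {
      for (r in seq_len(n_res)) {
        a <- a + 1
        coords[f, a, ] <- c(0.38 * r, 1.5 * ci, 0) + rnorm(3, sd = jitter)
      }
    }
  }
  trajectory(coords, tibble::tibble(
    chain = rep(chains, each = n_res),
    resid = rep(seq_len(n_res), times = length(chains)),
    resname = "ALA", name = "CA", mass = 12.011))
}

## random proper rotation
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

## --- independent oracles ---------------------------------------------------

## minimum RMSD by explicit minimisation over Euler angles (coarse grid +
## Nelder-Mead refinement); independent of the SVD route.
rmsd_min_oracle <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz1 <- matrix(c(ca[1], -sa[1], 0, sa[1], ca[1], 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, byrow = TRUE)
    Rz2 <- matrix(c(ca[3], -sa[3], 0, sa[3], ca[3], 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  f <- function(ang) sqrt(sum((P %*% t(rot(ang)) - Q)^2) / nrow(P))
  grid <- as.matrix(expand.grid(a = seq(0, 2 * pi, length.out = 13)[-13],
                                b = seq(0, pi, length.out = 7),
                                c = seq(0, 2 * pi, length.out = 13)[-13]))
  v <- apply(grid, 1, f)
  best <- grid[which.min(v), ]
  for (rep in 1:3) {
    o <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
    best <- o$par
  }
  o$value
}

## contingency-table MI / joint entropy by explicit enumeration loops
brute_mi <- function(ci, cj) {
  n <- length(ci)
  ui <- unique(ci); uj <- unique(cj)
  I <- 0; H <- 0; Bij <- 0
  for (a in ui) for (b in uj) {
    pab <- sum(ci == a & cj == b) / n
    if (pab > 0) {
      pa <- sum(ci == a) / n; pb <- sum(cj == b) / n
      I <- I + pab * log(pab / (pa * pb))
      H <- H - pab * log(pab)
      Bij <- Bij + 1
    }
  }
  list(I = I, H = H, Bij = Bij, Bi = length(ui), Bj = length(uj),
       eps = (Bij - length(ui) - length(uj) + 1) / (2 * n))
}

## matrix square root via eigendecomposition, then the trace formula directly
overlap_sqrtm_oracle <- function(A, B) {
  msqrt <- function(M) {
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(M)) %*% t(e$vectors)
  }
  sa <- msqrt(A); sb <- msqrt(B)
  trA <- sum(pmax(eigen(A, symmetric = TRUE, only.values = TRUE)$values, 0))
  trB <- sum(pmax(eigen(B, symmetric = TRUE, only.values = TRUE)$values, 0))
  d <- sqrt(max(trA + trB - 2 * sum(diag(sa %*% sb)), 0))
  1 - d / sqrt(trA + trB)
}

## exact two-sided rank-sum p by enumeration of all group assignments
exact_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U of x
  combs <- utils::combn(n1 + n2, n1)
  Ws <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12)
}

## all simple paths between two nodes; returns min cost (and a path)
enum_shortest <- function(edges, n, from, to) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]; w <- edges$cost[r]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  best <- list(cost = Inf, path = integer(0))
  dfs <- function(node, visited, cost, path) {
    if (cost >= best$cost) return()
    if (node == to) {
      best <<- list(cost = cost, path = path)
      return()
    }
    if (is.null(adj[[node]])) return()
    for (k in seq_len(nrow(adj[[node]]))) {
      nxt <- adj[[node]][k, 1]
      if (!visited[nxt]) {
        visited[nxt] <- TRUE
        dfs(nxt, visited, cost + adj[[node]][k, 2], c(path, nxt))
        visited[nxt] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n); visited[from] <- TRUE
  dfs(from, visited, 0, from)
  best
}

## naive complete-linkage agglomeration: returns merge heights
complete_linkage_heights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        h <- max(D[clusters[[a]], clusters[[b]]])
        if (h < best[1]) best <- c(h, a, b)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

## block matrices with a planted regime switch: two near-orthogonal
## rank-structured bases plus small noise (omega within >= .95, across < .5
## asserted where used)
make_regime_blocks <- function(n_blocks = 20, switch_at = 11, p = 12,
                               noise = 5e-4, seed = 1) {
  set.seed(seed)
  baseA <- matrix(0, p, p); baseA[2, 8] <- baseA[8, 2] <- 0.8
  baseA[3, 9] <- baseA[9, 3] <- 0.6
  baseB <- matrix(0, p, p); baseB[4, 10] <- baseB[10, 4] <- 0.8
  baseB[5, 11] <- baseB[11, 5] <- 0.6
  lapply(seq_len(n_blocks), function(b) {
    base <- if (b < switch_at) baseA else baseB
    E <- matrix(rnorm(p * p, sd = noise), p, p)
    E <- (E + t(E)) / 2
    diag(E) <- 0
    pmax(pmin(base + E, 1), 0)
  })
}

## substate-sample matrix stacks with one planted differing pair
make_hub_stacks <- function(n_samples = 5, p = 10, pair = c(2, 7),
                            nmi_apo = 0.05, fold = 8, cv = 0.1,
                            base = 0.3, seed = 1) {
  set.seed(seed)
  mk <- function(level) {
    lapply(seq_len(n_samples), function(s) {
      M <- matrix(base, p, p)
      M[pair[1], pair[2]] <- M[pair[2], pair[1]] <- level
      noise <- matrix(rnorm(p * p, sd = cv * base), p, p)
      noise <- (noise + t(noise)) / 2
      M <- M + noise  # additive background noise, sd = cv * base
      M[pair[1], pair[2]] <- M[pair[2], pair[1]] <-
        level * (1 + rnorm(1, sd = cv))
      diag(M) <- 0
      pmax(pmin(M, 1), 0)
    })
  }
  list(apo = mk(nmi_apo), holo = mk(nmi_apo * fold))
}

## wrap plain matrices as a substate_set with given probabilities
as_substate_set <- function(mats, probs = NULL) {
  n <- length(mats)
  if (is.null(probs)) probs <- rep(1 / n, n)
  structure(list(
    substates = tibble::tibble(
      substate = seq_len(n), blocks = as.list(seq_len(n)),
      n_blocks = rep(1L, n), probability = probs, representative = mats),
    n_blocks = n, omega_threshold = NA_real_, min_run = 1L,
    fragments = NULL), class = "substate_set")
}
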