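test_that("split_blocks: balanced contiguous cover with remainder rule", {
  b <- split_blocks(400, 20)
  expect_equal(nrow(b), 20L)
  expect_true(all(b$n == 20))
  expect_equal(b$start[1], 1L)
  expect_equal(b$end[20], 400L)
  expect_true(all(b$start[-1] == b$end[-20] + 1L))

  b2 <- split_blocks(10, 3)
  expect_equal(b2$n, c(4L, 3L, 3L))
  expect_error(split_blocks(5, 6), "n_blocks")
  expect_error(split_blocks(5, 0), "n_blocks")
})

test_that("covariance overlap limits: identity, orthogonality, scalar multiple", {
  set.seed(3)
  A <- crossprod(matrix(rnorm(25), 5, 5))  # random PSD
  expect_equal(covariance_overlap(A, A)$omega, 1)
  o <- covariance_overlap(diag(c(1, 0)), diag(c(0, 1)))
  expect_equal(o$omega, 0)
  expect_equal(o$d, sqrt(2), tolerance = 1e-12)
  # closed form for B = 2A: omega = 1 - sqrt((3 - 2 sqrt(2)) / 3)
  o2 <- covariance_overlap(A, 2 * A)
  expect_equal(o2$omega, 1 - sqrt((3 - 2 * sqrt(2)) / 3), tolerance = 1e-10)
  # all-zero matrices are defined as identical
  expect_equal(covariance_overlap(matrix(0, 3, 3), matrix(0, 3, 3))$omega, 1)
  expect_error(covariance_overlap(diag(2), diag(3)), "dimension")
})

test_that("overlap matches a matrix-square-root oracle and is symmetric", {
  set.seed(12)
  for (case in 1:8) {
    p <- sample(3:8, 1)
    A <- crossprod(matrix(rnorm(p * p), p, p)) / p
    B <- crossprod(matrix(rnorm(p * p), p, p)) / p
    ab <- covariance_overlap(A, B)$omega
    ba <- covariance_overlap(B, A)$omega
    expect_lt(abs(ab - ba), 1e-10)
    expect_lt(abs(ab - overlap_sqrtm_oracle(A, B)), 1e-9)
    expect_gte(ab, 0); expect_lte(ab, 1)
  }
})

test_that("negative eigenvalues are clipped with a warning above 1% of trace", {
  M <- diag(c(1, 1, 1)); M[1, 3] <- M[3, 1] <- 2  # indefinite
  expect_warning(covariance_overlap(M, M), "clipped")
})

test_that("segmentation: identical blocks collapse to one substate", {
  A <- crossprod(matrix(rnorm(16), 4, 4))
  ss <- segment_substates(replicate(6, A, simplify = FALSE))
  expect_equal(nrow(ss$substates), 1L)
  expect_equal(ss$substates$probability, 1)
  expect_equal(ss$substates$representative[[1]], A)
})

test_that("a planted regime switch is recovered with correct probabilities", {
  blocks <- make_regime_blocks(n_blocks = 20, switch_at = 11, seed = 4)
  # construction check: high within-regime, low across-regime overlap
  expect_gt(covariance_overlap(blocks[[1]], blocks[[5]], warn = FALSE)$omega,
            0.95)
  expect_lt(covariance_overlap(blocks[[1]], blocks[[15]], warn = FALSE)$omega,
            0.5)
  ss <- segment_substates(blocks, omega_threshold = 0.85, min_run = 2)
  expect_equal(nrow(ss$substates), 2L)
  expect_equal(ss$substates$blocks[[1]], 1:10)
  expect_equal(ss$substates$blocks[[2]], 11:20)
  expect_equal(ss$substates$probability, c(0.5, 0.5))
})

test_that("threshold 1 on distinct blocks isolates every block (min_run 1)", {
  set.seed(6)
  blocks <- lapply(1:5, function(i) crossprod(matrix(rnorm(9), 3, 3)))
  ss <- segment_substates(blocks, omega_threshold = 1, min_run = 1)
  expect_equal(nrow(ss$substates), 5L)
  expect_equal(ss$substates$probability, rep(0.2, 5))
  expect_error(segment_substates(list(), 0.85), ">= 1")
  expect_error(segment_substates(blocks, 0), "omega_threshold")
})

test_that("substates partition the block sequence contiguously (property)", {
  for (seed in 1:6) {
    blocks <- make_regime_blocks(n_blocks = 12, switch_at = sample(3:10, 1),
                                 noise = 0.03, seed = seed)
    ss <- segment_substates(blocks, 0.8, min_run = 2)
    all_blocks <- sort(unlist(ss$substates$blocks))
    expect_equal(all_blocks, 1:12)
    expect_true(all(vapply(ss$substates$blocks,
                           function(b) all(diff(b) == 1), logical(1))))
    expect_equal(sum(ss$substates$probability), 1, tolerance = 1e-12)
    # deterministic given inputs
    ss2 <- segment_substates(blocks, 0.8, min_run = 2)
    expect_identical(tidy(ss), tidy(ss2))
  }
})

test_that("complete-linkage clustering separates planted groups", {
  set.seed(19)
  A <- crossprod(matrix(rnorm(16), 4, 4))
  B <- crossprod(matrix(rnorm(16), 4, 4) + 3 * diag(4))
  mats <- c(replicate(3, A, simplify = FALSE),
            replicate(3, B, simplify = FALSE))
  cl <- cluster_substates(mats, k = 2)
  expect_equal(length(unique(cl$clusters[1:3])), 1L)
  expect_equal(length(unique(cl$clusters[4:6])), 1L)
  expect_false(cl$clusters[1] == cl$clusters[4])
})

test_that("linkage heights match the brute-force complete-linkage oracle (<= 6 mats)", {
  set.seed(23)
  mats <- lapply(1:6, function(i) {
    M <- crossprod(matrix(rnorm(16, sd = i), 4, 4)) / 4
    M
  })
  cl <- cluster_substates(mats)
  oracle_h <- complete_linkage_heights(cl$dist)
  expect_equal(sort(cl$hclust$height), sort(oracle_h), tolerance = 1e-12)
  expect_error(cluster_substates(mats[1]), ">= 2")
})

test_that("apo-like / holo-like / shared ensembles yield the 3-cluster structure", {
  set.seed(29)
  mk <- function(base, n, noise = 0.01) {
    lapply(seq_len(n), function(i) {
      E <- matrix(rnorm(144, sd = noise), 12, 12); E <- (E + t(E)) / 2
      pmax(base + E, 0)
    })
  }
  baseA <- matrix(0, 12, 12); baseA[2, 8] <- baseA[8, 2] <- 0.8
  baseB <- matrix(0, 12, 12); baseB[4, 10] <- baseB[10, 4] <- 0.8
  baseC <- matrix(0, 12, 12); baseC[6, 12] <- baseC[12, 6] <- 0.8
  mats <- c(mk(baseA, 4), mk(baseB, 4), mk(baseC, 4))
  labels <- c(rep("apo", 4), rep("holo", 4),
              rep(c("apo", "holo"), 2))  # shared regime from both states
  cl <- cluster_substates(mats, labels = paste0(labels, seq_along(mats)),
                          k = 3)
  grp <- split(cl$clusters, rep(c("A", "B", "C"), each = 4))
  expect_true(all(vapply(grp, function(g) length(unique(g)) == 1, logical(1))))
  expect_equal(length(unique(vapply(grp, `[`, integer(1) , 1))), 3L)
})
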