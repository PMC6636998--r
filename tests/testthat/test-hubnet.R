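frag10 <- tibble::tibble(column = 1:20, chain = "A",
                         first_resid = 4 * (0:19) + 1)

ens_from <- function(mats, state = "s", probs = NULL) {
  ss <- as_substate_set(mats, probs)
  ss$fragments <- frag10[seq_len(nrow(mats[[1]])), ]
  ensemble_average(ss, state = state)
}

test_that("ensemble averaging: identity, arithmetic and weighted means", {
  A <- matrix(0.2, 4, 4); diag(A) <- 0
  e1 <- ens_from(list(A))
  expect_equal(e1$matrix, A)

  B <- matrix(0.4, 4, 4); diag(B) <- 0
  e2 <- ens_from(list(A, B))  # equal probabilities
  expect_equal(e2$matrix[1, 2], 0.3)
  expect_equal(sum(e2$weights$weight), 1)

  C <- matrix(0, 4, 4)
  A2 <- matrix(0.4, 4, 4); diag(A2) <- 0
  e3 <- ens_from(list(A2, C), probs = c(0.75, 0.25))
  expect_equal(e3$matrix[1, 2], 0.3)

  # averaging commutes with fragment relabeling (permutation)
  set.seed(2)
  P <- diag(4)[sample(4), ]
  e_perm <- ens_from(list(P %*% A %*% t(P), P %*% B %*% t(P)))
  expect_equal(e_perm$matrix, P %*% e2$matrix %*% t(P))

  expect_error(ensemble_average(list()), ">= 1")
})

test_that("difference network: zero on identical ensembles, exact arithmetic", {
  A <- matrix(0.1, 5, 5); diag(A) <- 0
  ea <- ens_from(list(A, A))
  d0 <- difference_network(ea, ea)
  expect_true(all(d0$pairs$log2fc == 0))
  expect_true(all(d0$pairs$delta == 0))

  H <- matrix(0.4, 5, 5); diag(H) <- 0
  eh <- ens_from(list(H, H), state = "holo")
  d <- difference_network(ea, eh, pseudocount = 0)
  expect_equal(unique(d$pairs$log2fc[!d$pairs$masked]), 2)  # log2(0.4/0.1)

  # pseudocount regularises 0/0 to log2fc = 0
  Z <- matrix(0, 5, 5)
  ez <- ens_from(list(Z, Z))
  dz <- difference_network(ez, ez, pseudocount = 1e-3)
  expect_true(all(dz$pairs$log2fc == 0))

  # antisymmetry at c = 0
  d_rev <- difference_network(eh, ea, pseudocount = 0)
  expect_equal(d_rev$pairs$log2fc, -d$pairs$log2fc)
})

test_that("rank-sum p-values match exact enumeration to 1e-10", {
  set.seed(33)
  for (case in 1:12) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, 0, 2))
    got <- suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
    expect_lt(abs(got - exact_ranksum_p(x, y)), 1e-10)
  }
})

test_that("call_hubs: identical stacks give zero hubs; planted pair is found", {
  st <- make_hub_stacks(n_samples = 5, pair = c(2, 7), fold = 1, cv = 0,
                        seed = 40)
  ea <- ens_from(st$apo, "apo"); eh <- ens_from(st$apo, "holo")
  d_id <- difference_network(ea, eh)
  h0 <- call_hubs(d_id, p_max = 0.01)
  expect_equal(nrow(h0$hubs), 0L)

  st2 <- make_hub_stacks(n_samples = 5, pair = c(2, 7), fold = 8, cv = 0.05,
                         nmi_apo = 0.05, seed = 41)
  d <- difference_network(ens_from(st2$apo, "apo"),
                          ens_from(st2$holo, "holo"))
  h <- call_hubs(d, lfc_min = 2, p_max = 0.01)
  sig <- h$pairs[h$pairs$significant, ]
  expect_true(any(sig$i == 2 & sig$j == 7))
  expect_setequal(h$hubs$fragment[h$hubs$rank <= 2], c(2L, 7L))
  # BH q is monotone non-decreasing in raw p
  ord <- order(h$pairs$p[!h$pairs$masked])
  q_sorted <- h$pairs$q[!h$pairs$masked][ord]
  expect_true(all(diff(q_sorted) >= -1e-12))
})

test_that("call_hubs guards and top-k export", {
  st <- make_hub_stacks(n_samples = 1, seed = 1)
  d <- difference_network(ens_from(st$apo, "apo"), ens_from(st$holo, "holo"))
  expect_error(call_hubs(d), ">= 2 substate samples")

  # 6 shifted pairs over 12 distinct fragments; top_k trims to exactly 10
  set.seed(50)
  p <- 14
  mk <- function(level, jit) lapply(1:5, function(s) {
    M <- matrix(0.02, p, p)
    for (i in 1:6) M[i, i + 7] <- M[i + 7, i] <- level
    M <- M + (function(E) (E + t(E)) / 2)(matrix(rnorm(p * p, sd = jit), p, p))
    diag(M) <- 0
    pmax(M, 0.001)
  })
  ea <- ens_from(mk(0.05, 0.001), "apo")
  eh <- ens_from(mk(0.40, 0.001), "holo")
  h <- call_hubs(difference_network(ea, eh), lfc_min = 2, p_max = 0.01,
                 top_k = 10)
  expect_equal(nrow(h$hubs), 10L)
  expect_equal(h$hubs$rank, 1:10)
})

test_that("hub recovery: planted fragments rank top-2 in >= 95% of 20 seeds", {
  hits <- vapply(1:20, function(seed) {
    st <- make_hub_stacks(n_samples = 5, pair = c(3, 8), fold = 8,
                          cv = 0.1, nmi_apo = 0.05, seed = seed)
    d <- difference_network(ens_from(st$apo, "apo"),
                            ens_from(st$holo, "holo"))
    h <- call_hubs(d, lfc_min = 2, p_max = 0.01)
    nrow(h$hubs) >= 2 && setequal(h$hubs$fragment[h$hubs$rank <= 2], c(3L, 8L))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("MSA substitution suggestions: frequencies, thresholds, gap mapping", {
  msa <- c(s1 = "MAKV", s2 = "MAKV", s3 = "MAKV", s4 = "MSKV")
  out <- suggest_substitutions(msa, "s1", positions = 2, min_freq = 0.2)
  expect_equal(out$residue, "S")
  expect_equal(out$freq, 0.25)
  expect_equal(out$wt, "A")
  out2 <- suggest_substitutions(msa, "s1", positions = 2, min_freq = 0.5)
  expect_equal(nrow(out2[!is.na(out2$residue) & out2$freq > 0, ]), 0L)

  # leading gap in the target: ungapped position 1 maps to column 2
  msa_g <- c(t1 = "-AKV", t2 = "MSKV", t3 = "MSKV", t4 = "MSKV")
  out3 <- suggest_substitutions(msa_g, "t1", positions = 1, min_freq = 0.1)
  expect_equal(unique(out3$column), 2L)
  expect_equal(out3$residue, "S")
  expect_equal(out3$freq, 0.75)

  msa_all_gap <- c(t1 = "A-KV", t2 = "A-KV")
  expect_error(suggest_substitutions(msa_all_gap, "zz", 1), "not found")

  # FASTA file input path
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "MAKV", ">s2", "MAKV", ">s3", "MAKV", ">s4", "MSKV"), f)
  expect_equal(suggest_substitutions(f, "s1", 2, 0.2)$residue, "S")
})

test_that("coupling coefficient Q: sign convention and reference kinetics", {
  expect_equal(coupling_q(1, 1)$Q, 1)
  expect_equal(coupling_q(1, 1)$log10Q, 0)
  q <- coupling_q(1.22, c(FBP = 0.23, Phe = 7.08))
  expect_equal(q$Q[1], 1.22 / 0.23, tolerance = 1e-12)   # ~5.30, activation
  expect_equal(q$Q[2], 1.22 / 7.08, tolerance = 1e-12)   # ~0.172, inhibition
  expect_gt(q$Q[1], 1); expect_gt(q$log10Q[1], 0)
  expect_lt(q$Q[2], 1); expect_lt(q$log10Q[2], 0)
  expect_equal(q$coupling, c("activation", "inhibition"))
  expect_error(coupling_q(-1, 2), "positive")
  expect_error(coupling_q(1, 0), "positive")
})
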