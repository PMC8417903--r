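test_that("posterior similarity matrices are co-clustering proportions", {
  alloc <- rbind(c(1, 1, 2), c(1, 2, 2), c(1, 1, 1), c(2, 2, 1))
  S <- compute_psm(alloc)
  expect_equal(diag(S), rep(1, 3))
  expect_equal(S, t(S))
  expect_equal(S[1, 2], 3 / 4)
  expect_equal(S[1, 3], 1 / 4)
  expect_true(all(S >= 0 & S <= 1))
  expect_equal(compute_psm(rbind(c(1, 1), c(2, 2)))[1, 2], 1)
  expect_equal(compute_psm(rbind(c(1, 2), c(1, 2)))[1, 2], 0)
})

test_that("consensus averaging is element-wise and order-checked", {
  A <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  B <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(consensus_psm(list(A, A)), A)
  expect_equal(consensus_psm(list(A, B))[1, 2], 0.5)
  expect_equal(consensus_psm(list(A, B)), consensus_psm(list(B, A)))
  C <- matrix(1, 2, 2, dimnames = list(c("b", "a"), c("b", "a")))
  expect_error(consensus_psm(list(A, C)), "order")
  expect_error(consensus_psm(list(A, matrix(1, 3, 3))), "shape")
})

test_that("representative clustering recovers block structure", {
  for (k in 2:6) {
    sizes <- rep(c(5, 6), length.out = k)
    lab <- rep(seq_len(k), sizes[seq_len(k)])
    S <- outer(lab, lab, "==") * 1
    rownames(S) <- colnames(S) <- paste0("s", seq_along(lab))
    rc <- representative_clustering(S, k_range = 2:6)
    expect_identical(rc$k, k)
    expect_equal(adjusted_rand(rc$labels, lab), 1)
  }
  # degenerate: everything co-clustered
  S1 <- matrix(1, 4, 4)
  expect_warning(rc1 <- representative_clustering(S1), "degenerate")
  expect_identical(rc1$k, 1L)
  expect_identical(rc1$labels, rep(1L, 4))
})

test_that("silhouette-selected k maximises the brute-force average width", {
  set.seed(61)
  lab <- rep(1:3, c(6, 5, 7))
  S <- outer(lab, lab, "==") * 0.9 + 0.05
  diag(S) <- 1
  S <- S + matrix(runif(length(lab)^2, -0.03, 0.03), length(lab))
  S <- (S + t(S)) / 2
  diag(S) <- 1
  rc <- representative_clustering(S, 2:6)
  d <- 1 - S
  for (i in seq_len(nrow(rc$silhouette))) {
    k <- rc$silhouette$k[i]
    pam_k <- cluster::pam(stats::as.dist(d), k)
    expect_equal(rc$silhouette$avg_width[i],
                 silhouette_bruteforce(d, pam_k$clustering), tolerance = 1e-10)
  }
  expect_identical(rc$k, 3L)
})

test_that("PAM reaches the exhaustive k-medoids optimum on all partition-induced problems", {
  # every set partition of up to 6 items induces a 0/1 block dissimilarity;
  # PAM at the true block count must recover the partition at the globally
  # optimal cost (verified by enumerating every medoid set)
  for (n in 4:6) {
    for (lab in all_partitions(n)) {
      k <- max(lab)
      if (k < 2 || k >= n) next
      d <- 1 - outer(lab, lab, "==")
      fit <- cluster::pam(stats::as.dist(d), k)
      cost <- sum(vapply(seq_len(n), function(i) min(d[i, fit$id.med]), numeric(1)))
      expect_equal(cost, pam_bruteforce_cost(d, k), tolerance = 1e-12)
      expect_equal(adjusted_rand(fit$clustering, lab), 1)
    }
  }
})

test_that("adjusted Rand agrees with pair counting on all small partitions", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(adjusted_rand(1:4, 1:4), 1)
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  parts <- all_partitions(5)
  set.seed(63)
  idx <- cbind(sample(length(parts), 250, TRUE), sample(length(parts), 250, TRUE))
  for (r in seq_len(nrow(idx))) {
    la <- parts[[idx[r, 1]]]
    lb <- parts[[idx[r, 2]]]
    expect_equal(adjusted_rand(la, lb), ari_bruteforce(la, lb), tolerance = 1e-12)
  }
  # independent library cross-check
  expect_equal(adjusted_rand(parts[[10]], parts[[48]]),
               mclust::adjustedRandIndex(parts[[10]], parts[[48]]))
})

test_that("Cohen's kappa agrees with its definition and matches labels", {
  a <- rep(c(1, 2), c(50, 50))
  b <- c(rep(1, 40), rep(2, 10), rep(1, 10), rep(2, 40))
  expect_equal(cohens_kappa(a, b), 0.6)
  expect_equal(cohens_kappa(a, a), 1)
  parts <- all_partitions(6)
  set.seed(64)
  idx <- cbind(sample(length(parts), 150, TRUE), sample(length(parts), 150, TRUE))
  for (r in seq_len(nrow(idx))) {
    la <- parts[[idx[r, 1]]]
    lb <- parts[[idx[r, 2]]]
    expect_equal(cohens_kappa(la, lb), kappa_bruteforce(la, lb), tolerance = 1e-12)
  }
  # swapped labels recover full agreement after Hungarian matching
  expect_equal(cohens_kappa(c(1, 1, 2, 2), c(2, 2, 1, 1), match = TRUE), 1)
  expect_identical(match_labels(c(1, 1, 2, 2), c(2, 2, 1, 1)), c(1L, 1L, 2L, 2L))
  expect_warning(k <- cohens_kappa(c(1, 1), c(1, 1)), "undefined")
  expect_true(is.na(k) || k == 1)
})

test_that("lower-triangle correlation behaves as a pairwise comparison", {
  set.seed(65)
  S <- matrix(runif(64), 8)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  expect_equal(lower_triangle_correlation(S, S), 1)
  expect_equal(lower_triangle_correlation(S, 1 - S), -1)
  perm <- sample(8)
  expect_equal(lower_triangle_correlation(S[perm, perm], (1 - S)[perm, perm]), -1)
  expect_warning(r <- lower_triangle_correlation(S, matrix(1, 8, 8)), "constant")
  expect_true(is.na(r))
  expect_error(lower_triangle_correlation(S, matrix(1, 3, 3)), "shape")
})

test_that("cluster-parameter posteriors average allocated components", {
  # hand-built two-iteration chain over 2 subjects and known parameters
  chain <- structure(list(
    alloc = rbind(c(1L, 2L), c(1L, 1L)),
    theta_o = array(rep(c(0.9, 0.1), each = 4), c(2, 2, 2)),
    theta_d = array(c(0.2, 0.2, 0.4, 0.4), c(2, 2, 1)),
    mu = array(c(-1, -1, 1, 1), c(2, 2, 1)),
    Sigma = array(1, c(2, 2, 1, 1)),
    logw = matrix(log(0.5), 2, 2),
    alpha = c(1, 1), n_occupied = c(2L, 1L), logdens = c(-1, -1),
    ids = c("u", "v"),
    priors = profreg_priors(2, 1, H = 2),
    control = profreg_control(20, 10, 5, 1),
    binary = "flag", continuous = "z"
  ), class = "profreg_chain")
  clus <- structure(list(labels = c(1L, 1L), medoids = 1L, k = 1L,
                         silhouette = NULL, ids = c("u", "v")),
                    class = "representative_clustering")
  out <- cluster_param_posteriors(chain, clus)
  # iteration 1 averages components (1, 2) -> 0.3; iteration 2 -> 0.2
  flag <- out[out$parameter == "flag", ]
  expect_equal(flag$mean, mean(c(0.3, 0.2)))
  z <- out[out$parameter == "mean_z", ]
  expect_equal(z$mean, mean(c(0, -1)))
  # empty representative cluster is an error
  clus_bad <- clus
  clus_bad$k <- 2L
  expect_error(cluster_param_posteriors(chain, clus_bad), "empty")
})

test_that("agreement reports cover every chain pair", {
  sim <- generate_cohort(synth_scenario("crisp_clusters", n_subjects = 60L), seed = 9)
  pd <- profreg_data(sim$profiles)
  ch <- suppressWarnings(
    run_chain(pd, control = profreg_control(n_iter = 500, burn_in = 250,
                                            thin = 5, seed = 2))
  )
  rep3 <- list(ch, ch, ch)
  agr <- chain_agreement(rep3, k_range = 2:5)
  expect_identical(nrow(agr$pairs), 3L)
  expect_equal(agr$mean_pearson, 1)
  expect_equal(agr$mean_ari, 1)
})
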