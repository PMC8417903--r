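toy_profiles <- function(n = 40, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("p%03d", seq_len(n)),
    class = sample(1:2, n, TRUE),
    ad_positive = rbinom(n, 1, 0.3), mta_positive = rbinom(n, 1, 0.4),
    fsd_positive = rbinom(n, 1, 0.2), fspv_positive = rbinom(n, 1, 0.4),
    arwmc_positive = rbinom(n, 1, 0.25),
    hv = rnorm(n), vv = rnorm(n), hv_rate = rnorm(n), vv_rate = rnorm(n)
  )
}

test_that("profile datasets validate their covariates", {
  pd <- profreg_data(toy_profiles())
  expect_identical(pd$n, 40L)
  expect_identical(pd$G, 2L)
  bad <- toy_profiles()
  bad$ad_positive[1] <- 2
  expect_error(profreg_data(bad), "0/1")
  allmiss <- toy_profiles()
  allmiss[1, c("ad_positive", "mta_positive", "fsd_positive", "fspv_positive",
               "arwmc_positive", "hv", "vv", "hv_rate", "vv_rate")] <- NA
  expect_error(profreg_data(allmiss), "every covariate missing")
  expect_error(profreg_priors(2, nu0 = 3), "nu0")
})

test_that("chain initialisation and runs are reproducible and sized right", {
  pd <- profreg_data(toy_profiles())
  pr <- profreg_priors(pd$G, H = 12)
  ctl <- profreg_control(n_iter = 100, burn_in = 50, thin = 5, seed = 9)
  s1 <- latentcog:::profreg_init(pd, pr, ctl)
  s2 <- latentcog:::profreg_init(pd, pr, ctl)
  expect_identical(s1, s2)
  expect_true(all(s1$alloc <= 10))
  # stick construction: first weight is V1
  expect_equal(latentcog:::stick_logweights(s1$V)[1], log(s1$V[1]))
  ch1 <- suppressWarnings(run_chain(pd, pr, ctl))
  ch2 <- suppressWarnings(run_chain(pd, pr, ctl))
  expect_identical(nrow(ch1$alloc), 10L) # (100 - 50) / 5
  expect_identical(ch1$alloc, ch2$alloc)
  expect_identical(ch1$alpha, ch2$alpha)
  # stick weights form a subprobability vector with the tail remainder
  expect_true(all(rowSums(exp(ch1$logw)) <= 1 + 1e-8))
  # the log joint density trace is finite at every kept iteration
  expect_true(all(is.finite(ch1$logdens)))
})

test_that("single forced component reproduces the Beta conjugate posterior", {
  # all subjects in one component: each sweep draws the Bernoulli parameter
  # fresh from Beta(a0 + s, b0 + n - s)
  n <- 24
  set.seed(5)
  dat <- tibble::tibble(
    subject_id = seq_len(n), class = 1L,
    w = rbinom(n, 1, 0.6),
    z = rnorm(n)
  )
  pd <- profreg_data(dat, outcome = "class", binary = "w", continuous = "z",
                     n_outcome_levels = 1)
  pr <- profreg_priors(1, n_continuous = 1, H = 1)
  ch <- run_chain(pd, pr, profreg_control(n_iter = 5500, burn_in = 500,
                                          thin = 1, seed = 2))
  draws <- ch$theta_d[, 1, 1]
  s <- sum(dat$w)
  ks <- suppressWarnings(stats::ks.test(draws, stats::pbeta, 1 + s, 1 + n - s))
  expect_gt(ks$p.value, 0.01)
  # small worked case from the conjugate closed form: data (1,1,1,0)
  pd2 <- profreg_data(
    tibble::tibble(subject_id = 1:4, class = 1L, w = c(1, 1, 1, 0), z = rnorm(4)),
    binary = "w", continuous = "z", n_outcome_levels = 1
  )
  ch2 <- run_chain(pd2, profreg_priors(1, 1, H = 1),
                   profreg_control(n_iter = 4000, burn_in = 500, thin = 1, seed = 3))
  d2 <- ch2$theta_d[, 1, 1]
  expect_equal(mean(d2), 4 / 6, tolerance = 0.02)
  expect_lt(abs(var(d2) - 4 * 2 / (36 * 7)), 0.005)
})

test_that("well-separated Gaussian blobs are recovered by the sampler", {
  set.seed(77)
  n <- 60
  centre <- rep(c(-5, 5), each = n / 2)
  dat <- tibble::tibble(
    subject_id = seq_len(n), class = 1L,
    flag = rbinom(n, 1, 0.5),
    z1 = rnorm(n, centre, 0.1), z2 = rnorm(n, -centre, 0.1)
  )
  pd <- profreg_data(dat, binary = "flag", continuous = c("z1", "z2"),
                     n_outcome_levels = 1)
  pr <- profreg_priors(1, 2, H = 20)
  ch <- suppressWarnings(
    run_chain(pd, pr, profreg_control(n_iter = 400, burn_in = 200, thin = 2, seed = 8))
  )
  last <- ch$alloc[nrow(ch$alloc), ]
  expect_identical(length(unique(last[1:30])), 1L)
  expect_identical(length(unique(last[31:60])), 1L)
  expect_false(last[1] == last[31])
})

test_that("occupied-cluster count grows with the concentration parameter", {
  # prior simulation through the package's stick construction
  set.seed(12)
  occupied <- vapply(c(0.5, 2, 10), function(alpha) {
    mean(vapply(1:200, function(r) {
      V <- c(rbeta(29, 1, alpha), 1)
      w <- exp(latentcog:::stick_logweights(V))
      length(unique(sample.int(30, 50, TRUE, prob = w)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(occupied) > 0))
})

test_that("held-out allocation uses covariates only and flags bad profiles", {
  set.seed(31)
  sim <- generate_cohort(synth_scenario("crisp_clusters", n_subjects = 90L), seed = 4)
  pd <- profreg_data(sim$profiles)
  ch <- suppressWarnings(
    run_chain(pd, control = profreg_control(n_iter = 600, burn_in = 300,
                                            thin = 3, seed = 6))
  )
  # a new profile at a tight cluster's centre lands in that cluster's
  # component in most iterations: compare against a training member
  member <- which(sim$truth$cluster == 1)[1]
  centroid <- sim$profiles[member, ]
  centroid$subject_id <- "new"
  new_pd <- profreg_data(centroid, n_outcome_levels = pd$G)
  al <- predict_allocation(ch, new_pd, seed = 2)
  agree <- mean(al[, 1] == ch$alloc[, member])
  expect_gt(agree, 0.9)
  # two identical new subjects have near-identical allocation distributions
  two <- dplyr::bind_rows(centroid, centroid)
  two$subject_id <- c("n1", "n2")
  al2 <- predict_allocation(ch, profreg_data(two, n_outcome_levels = pd$G), seed = 2)
  f1 <- tabulate(al2[, 1], 50) / nrow(al2)
  f2 <- tabulate(al2[, 2], 50) / nrow(al2)
  expect_lt(max(abs(f1 - f2)), 0.1)
})

test_that("chain summaries are stable under subject reordering", {
  sim <- generate_cohort(synth_scenario("crisp_clusters", n_subjects = 60L), seed = 14)
  prof <- sim$profiles
  ctl <- profreg_control(n_iter = 800, burn_in = 400, thin = 2, seed = 21)
  S1 <- compute_psm(suppressWarnings(run_chain(profreg_data(prof), control = ctl)))
  perm <- sample(nrow(prof))
  S2 <- compute_psm(suppressWarnings(run_chain(profreg_data(prof[perm, ]), control = ctl)))
  back <- match(rownames(S1), rownames(S2))
  expect_lt(mean(abs(S1 - S2[back, back])), 0.05)
})
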