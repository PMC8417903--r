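#' Stratified split-half plans for stability assessment
#'
#' Repeatedly splits the cohort into two subsets by stratifying on the
#' number of usable visits and randomly allocating, with equal probability,
#' within each stratum (balanced to within one subject per stratum; a
#' stratum of size one is assigned at random and logged).
#'
#' @param cohort A [cohort_table()] (visit counts are taken from visits with
#'   at least one observed outcome) or a data frame with `subject_id` and
#'   `n_visits`.
#' @param n_splits Number of repeated splits (default 10).
#' @param seed Integer seed; the plan is exactly reproducible from
#'   (`seed`, `n_splits`, strata).
#' @return Object of class `split_plan`: tibble `assignments` (`split`,
#'   `subject_id`, `subset`), plus `n_splits`, `seed`, `singleton_strata`.
#' @export
make_splits <- function(cohort, n_splits = 10L, seed = 1L) {
  if (inherits(cohort, "cohort_table")) {
    v <- cohort$visits
    if (all(c("cdrsb", "mmse") %in% names(v))) {
      v <- dplyr::filter(v, !is.na(.data$cdrsb) | !is.na(.data$mmse))
    }
    strata <- v |> dplyr::count(.data$subject_id, name = "n_visits")
  } else {
    strata <- tibble::as_tibble(cohort)[, c("subject_id", "n_visits")]
  }
  singletons <- strata |>
    dplyr::count(.data$n_visits) |>
    dplyr::filter(.data$n == 1L)
  if (nrow(singletons) > 0L) {
    inform(sprintf("%d stratum(s) of size one assigned at random", nrow(singletons)))
  }
  set.seed(seed)
  assignments <- purrr::map_dfr(seq_len(n_splits), function(s) {
    purrr::map_dfr(split(strata$subject_id, strata$n_visits), function(ids) {
      m <- length(ids)
      perm <- sample(ids)
      n1 <- floor(m / 2) + (m %% 2 == 1L) * rbinom(1L, 1L, 0.5)
      tibble::tibble(
        split = s, subject_id = perm,
        subset = rep(c(1L, 2L), c(n1, m - n1))
      )
    })
  })
  structure(list(
    assignments = assignments, n_splits = as.integer(n_splits),
    seed = as.integer(seed),
    singleton_strata = singletons$n_visits
  ), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d splits over %d subjects\n",
              x$n_splits, length(unique(x$assignments$subject_id))))
  invisible(x)
}

split_ids <- function(plan, s, j) {
  a <- plan$assignments
  a$subject_id[a$split == s & a$subset == j]
}

#' Class-structure stability under repeated sub-setting
#'
#' For each split, fits the latent-class model on each subset, predicts
#' class membership out of sample for the other subset, and compares the
#' out-of-sample predictions with the in-sample assignments (Cohen's kappa
#' after label matching, and the adjusted Rand index). Each split also
#' contributes one comparison of the stitched in-sample subset assignments
#' against the full-data model's assignments.
#'
#' @param outcomes,covariates Model inputs as for [fit_mlcmm()].
#' @param spec An [mlcmm_spec()] or class count.
#' @param plan A [make_splits()] plan.
#' @param control An [mlcmm_control()] used for every fit.
#' @param full_fit Optional pre-computed full-data fit (fitted here
#'   otherwise).
#' @return Object of class `stability_report`: `subset_comparisons` (tibble:
#'   `split`, `subset`, `kappa`, `ari`), `full_comparisons` (tibble:
#'   `split`, `kappa`, `ari`), `summary` (means and SDs), `failures`.
#' @export
class_stability <- function(outcomes, covariates, spec, plan,
                            control = mlcmm_control(), full_fit = NULL) {
  if (is.numeric(spec)) spec <- mlcmm_spec(spec)
  if (is.null(full_fit)) {
    full_fit <- fit_mlcmm(outcomes, covariates, spec, control)
  }
  full_labels <- setNames(full_fit$labels, full_fit$subject_ids)
  subset_rows <- list(); full_rows <- list(); failures <- character(0)
  for (s in seq_len(plan$n_splits)) {
    fits <- vector("list", 2L)
    for (j in 1:2) {
      ids <- split_ids(plan, s, j)
      ctl <- control
      ctl$seed <- derive_seed(control$seed, 100L * s + j)
      fits[[j]] <- tryCatch(
        fit_mlcmm(
          dplyr::filter(outcomes, .data$subject_id %in% ids),
          dplyr::filter(covariates, .data$subject_id %in% ids),
          spec, ctl
        ),
        error = function(e) NULL
      )
    }
    if (any(vapply(fits, is.null, logical(1)))) {
      failures <- c(failures, sprintf("split %d: subset fit failed", s))
      next
    }
    stitched <- list()
    for (j in 1:2) {
      other <- 3L - j
      ids_j <- fits[[j]]$subject_ids
      insample <- fits[[j]]$labels
      pred <- predict_class_newdata(
        fits[[other]],
        dplyr::filter(outcomes, .data$subject_id %in% ids_j),
        dplyr::filter(covariates, .data$subject_id %in% ids_j)
      )
      oos <- pred$class[match(ids_j, pred$subject_id)]
      subset_rows[[length(subset_rows) + 1L]] <- tibble::tibble(
        split = s, subset = j,
        kappa = cohens_kappa(insample, oos, match = TRUE),
        ari = adjusted_rand(insample, oos)
      )
      matched <- match_labels(full_labels[ids_j], insample)
      stitched[[j]] <- setNames(matched, ids_j)
    }
    stitched <- unlist(stitched)
    common <- intersect(names(full_labels), names(stitched))
    full_rows[[length(full_rows) + 1L]] <- tibble::tibble(
      split = s,
      kappa = cohens_kappa(full_labels[common], stitched[common]),
      ari = adjusted_rand(full_labels[common], stitched[common])
    )
  }
  subset_comparisons <- dplyr::bind_rows(subset_rows)
  full_comparisons <- dplyr::bind_rows(full_rows)
  structure(list(
    subset_comparisons = subset_comparisons,
    full_comparisons = full_comparisons,
    summary = tibble::tibble(
      comparison = c("subset", "full"),
      mean_kappa = c(mean(subset_comparisons$kappa), mean(full_comparisons$kappa)),
      sd_kappa = c(sd(subset_comparisons$kappa), sd(full_comparisons$kappa)),
      mean_ari = c(mean(subset_comparisons$ari), mean(full_comparisons$ari)),
      sd_ari = c(sd(subset_comparisons$ari), sd(full_comparisons$ari))
    ),
    failures = failures
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  print(x$summary)
  if (length(x$failures)) cat("failures:", paste(x$failures, collapse = "; "), "\n")
  invisible(x)
}

# Predicted dissimilarity block between held-out and training subjects:
# 1 - co-allocation frequency over kept iterations, averaged over chains.
predicted_dissimilarity <- function(chains, new_data, seed = 1L) {
  blocks <- purrr::imap(chains, function(chain, idx) {
    alloc_new <- predict_allocation(chain, new_data, seed = derive_seed(seed, idx))
    R <- nrow(alloc_new)
    agree <- matrix(0, new_data$n, ncol(chain$alloc))
    for (r in seq_len(R)) {
      a_new <- alloc_new[r, ]; a_tr <- chain$alloc[r, ]
      lev <- union(unique(a_new), unique(a_tr))
      In <- matrix(0, length(a_new), length(lev))
      In[cbind(seq_along(a_new), match(a_new, lev))] <- 1
      It <- matrix(0, length(a_tr), length(lev))
      It[cbind(seq_along(a_tr), match(a_tr, lev))] <- 1
      agree <- agree + In %*% t(It)
    }
    1 - agree / R
  })
  D <- Reduce(`+`, blocks) / length(blocks)
  dimnames(D) <- list(new_data$ids, chains[[1]]$ids)
  D
}

#' Cluster-structure stability under repeated sub-setting
#'
#' For each subset of each split: runs profile regression, forms the
#' consensus similarity matrix and representative clustering, and compares
#' them with the full-data results restricted to the subset (lower-triangle
#' Pearson correlation; adjusted Rand index). For each direction of each
#' split it additionally predicts allocations for the held-out subset,
#' compares the predicted dissimilarity block against the corresponding
#' off-diagonal block of the full-data consensus matrix, and assigns each
#' held-out subject to the training representative cluster with the
#' smallest mean predicted dissimilarity (ties toward the larger cluster),
#' scoring that predicted clustering against the held-out subset's own
#' representative clustering.
#'
#' @param profiles Profile table (see [profreg_data()]) including the
#'   outcome class column.
#' @param plan A [make_splits()] plan.
#' @param priors Optional [profreg_priors()].
#' @param control A [profreg_control()] for the subset chains.
#' @param n_chains Chains per subset.
#' @param k_range Candidate cluster counts for the representative
#'   clusterings.
#' @param full_psm,full_clustering Full-data consensus similarity matrix
#'   (with subject ids as dimnames) and its representative clustering;
#'   computed here if omitted.
#' @param seed Seed for the held-out allocation draws.
#' @return Object of class `cluster_stability_report` with
#'   `subset_comparisons`, `heldout_comparisons`, and `summary` tibbles.
#' @export
cluster_stability <- function(profiles, plan, priors = NULL,
                              control = profreg_control(n_iter = 10000L,
                                                        burn_in = 2000L,
                                                        thin = 10L),
                              n_chains = 6L, k_range = 2:8,
                              full_psm = NULL, full_clustering = NULL,
                              seed = 1L) {
  profiles <- tibble::as_tibble(profiles)
  if (is.null(full_psm)) {
    full_data <- profreg_data(profiles)
    ctl <- control; ctl$seed <- derive_seed(seed, 0L)
    full_chains <- run_chains(full_data, priors, n_chains, ctl)
    full_psm <- consensus_psm(purrr::map(full_chains, compute_psm))
    full_clustering <- representative_clustering(full_psm, k_range)
  }
  full_ids <- rownames(full_psm)
  subset_rows <- list(); heldout_rows <- list()
  subset_results <- list()
  for (s in seq_len(plan$n_splits)) {
    for (j in 1:2) {
      ids <- intersect(full_ids, split_ids(plan, s, j))
      dat <- profreg_data(dplyr::filter(profiles, .data$subject_id %in% ids))
      ctl <- control
      ctl$seed <- derive_seed(seed, 1000L * s + j)
      chains <- run_chains(dat, priors, n_chains, ctl)
      S <- consensus_psm(purrr::map(chains, compute_psm))
      clus <- representative_clustering(S, k_range)
      pos <- match(dat$ids, full_ids)
      subset_rows[[length(subset_rows) + 1L]] <- tibble::tibble(
        split = s, subset = j,
        pearson = lower_triangle_correlation(S, full_psm[pos, pos]),
        ari = adjusted_rand(clus$labels, full_clustering$labels[pos])
      )
      subset_results[[paste(s, j)]] <- list(data = dat, chains = chains,
                                            clustering = clus)
    }
    for (j in 1:2) {
      other <- 3L - j
      train <- subset_results[[paste(s, j)]]
      held <- subset_results[[paste(s, other)]]
      D <- predicted_dissimilarity(train$chains, held$data,
                                   seed = derive_seed(seed, 2000L * s + j))
      pos_new <- match(held$data$ids, full_ids)
      pos_tr <- match(train$data$ids, full_ids)
      block <- 1 - full_psm[pos_new, pos_tr]
      r <- if (sd(D) == 0 || sd(block) == 0) NA_real_ else cor(c(D), c(block))
      sizes <- tabulate(train$clustering$labels, train$clustering$k)
      mean_d <- sapply(seq_len(train$clustering$k), function(h) {
        rowMeans(D[, train$clustering$labels == h, drop = FALSE])
      })
      pred_lab <- apply(mean_d, 1L, function(row) {
        cand <- which(row == min(row))
        cand[which.max(sizes[cand])]
      })
      heldout_rows[[length(heldout_rows) + 1L]] <- tibble::tibble(
        split = s, trained_on = j,
        pearson_block = r,
        ari_predicted = adjusted_rand(pred_lab, held$clustering$labels)
      )
    }
  }
  subset_comparisons <- dplyr::bind_rows(subset_rows)
  heldout_comparisons <- dplyr::bind_rows(heldout_rows)
  structure(list(
    subset_comparisons = subset_comparisons,
    heldout_comparisons = heldout_comparisons,
    full_clustering = full_clustering,
    summary = tibble::tibble(
      comparison = c("subset_vs_full", "heldout_prediction"),
      mean_pearson = c(mean(subset_comparisons$pearson),
                       mean(heldout_comparisons$pearson_block)),
      mean_ari = c(mean(subset_comparisons$ari),
                   mean(heldout_comparisons$ari_predicted))
    )
  ), class = "cluster_stability_report")
}

#' @export
print.cluster_stability_report <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
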