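#' Posterior similarity matrix from kept allocations
#'
#' `S[i, j]` is the proportion of kept MCMC iterations in which subjects i
#' and j are allocated to the same mixture component. Symmetric, unit
#' diagonal, entries in \[0, 1\].
#'
#' @param allocations Either a `profreg_chain` or an integer matrix (kept
#'   iterations x subjects).
#' @return N x N numeric matrix; subject ids (if known) as dimnames.
#' @export
compute_psm <- function(allocations) {
  ids <- NULL
  if (inherits(allocations, "profreg_chain")) {
    ids <- allocations$ids
    allocations <- allocations$alloc
  }
  allocations <- as.matrix(allocations)
  R <- nrow(allocations); n <- ncol(allocations)
  if (R < 1L) abort("need at least one kept iteration")
  S <- matrix(0, n, n)
  for (r in seq_len(R)) {
    a <- allocations[r, ]
    lev <- unique(a)
    I <- matrix(0, n, length(lev))
    I[cbind(seq_len(n), match(a, lev))] <- 1
    S <- S + tcrossprod(I)
  }
  S <- S / R
  if (!is.null(ids)) dimnames(S) <- list(ids, ids)
  S
}

#' Element-wise consensus of several similarity matrices
#'
#' @param S_list List of posterior similarity matrices over the same
#'   subjects in the same order.
#' @return Their element-wise mean.
#' @export
consensus_psm <- function(S_list) {
  stopifnot(length(S_list) >= 1L)
  d <- dim(S_list[[1]])
  nm <- dimnames(S_list[[1]])
  for (S in S_list) {
    if (!identical(dim(S), d)) abort("similarity matrices differ in shape")
    if (!is.null(nm) && !identical(dimnames(S), nm)) {
      abort("similarity matrices differ in subject order")
    }
  }
  Reduce(`+`, S_list) / length(S_list)
}

#' Representative clustering of a posterior similarity matrix
#'
#' Partitioning around medoids on the dissimilarity `1 - S` for each
#' candidate number of clusters, selecting the k with the largest average
#' silhouette width (ties toward the smaller k). A degenerate matrix whose
#' off-diagonal entries are all 1 yields a single cluster with a warning.
#'
#' @param S Posterior similarity matrix.
#' @param k_range Candidate cluster counts (subset of 2..N-1).
#' @return Object of class `representative_clustering`: `labels`, `medoids`,
#'   `k`, `silhouette` (tibble of average widths per k), `ids`.
#' @export
representative_clustering <- function(S, k_range = 2:15) {
  n <- nrow(S)
  diss <- 1 - S
  if (all(diss[upper.tri(diss)] < 1e-12)) {
    warn("degenerate similarity matrix (all pairs co-clustered); one cluster")
    return(structure(list(
      labels = rep(1L, n), medoids = 1L, k = 1L,
      silhouette = tibble::tibble(k = integer(0), avg_width = numeric(0)),
      ids = rownames(S) %||% seq_len(n)
    ), class = "representative_clustering"))
  }
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (!length(k_range)) abort("`k_range` must contain values in 2..N-1")
  d <- stats::as.dist(diss)
  fits <- purrr::map(k_range, function(k) cluster::pam(d, k, cluster.only = FALSE))
  widths <- vapply(fits, function(f) f$silinfo$avg.width, numeric(1))
  best <- which(widths == max(widths))[1L]
  structure(list(
    labels = as.integer(fits[[best]]$clustering),
    medoids = as.integer(fits[[best]]$id.med),
    k = k_range[best],
    silhouette = tibble::tibble(k = k_range, avg_width = widths),
    ids = rownames(S) %||% seq_len(n)
  ), class = "representative_clustering")
}

#' @export
print.representative_clustering <- function(x, ...) {
  cat(sprintf("<representative_clustering> k = %d; sizes: %s\n",
              x$k, paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Posterior summaries of cluster-averaged component parameters
#'
#' For each representative cluster and each mixture-component parameter, the
#' per-iteration average of the parameter of the component each member is
#' allocated to, summarised over pooled kept iterations by the posterior
#' mean and a credible interval. A narrow interval indicates that the
#' representative cluster tracks a consistent mixture component.
#'
#' @param chains A `profreg_chain` or list of them (pooled).
#' @param clustering A [representative_clustering()] over the same subjects.
#' @param level Credible level (default 0.90).
#' @return Tibble with `cluster`, `parameter`, `mean`, `ci_lower`,
#'   `ci_upper`.
#' @export
cluster_param_posteriors <- function(chains, clustering, level = 0.90) {
  if (inherits(chains, "profreg_chain")) chains <- list(chains)
  if (any(tabulate(clustering$labels, clustering$k) == 0L)) {
    abort("empty representative cluster")
  }
  lab <- clustering$labels
  a <- (1 - level) / 2
  ch1 <- chains[[1]]
  G <- dim(ch1$theta_o)[3]; Q <- dim(ch1$theta_d)[3]; C <- dim(ch1$mu)[3]
  pnames <- c(
    paste0("outcome_class", seq_len(G)),
    ch1$binary %||% paste0("binary_", seq_len(Q)),
    paste0("mean_", ch1$continuous %||% paste0("continuous_", seq_len(C)))
  )
  pieces <- list()
  for (chain in chains) {
    R <- nrow(chain$alloc)
    draws <- array(NA_real_, c(R, clustering$k, G + Q + C))
    for (r in seq_len(R)) {
      comp <- chain$alloc[r, ]
      vals <- cbind(
        matrix(chain$theta_o[r, , ], nrow = chain$priors$H)[comp, , drop = FALSE],
        matrix(chain$theta_d[r, , ], nrow = chain$priors$H)[comp, , drop = FALSE],
        matrix(chain$mu[r, , ], nrow = chain$priors$H)[comp, , drop = FALSE]
      )
      draws[r, , ] <- rowsum(vals, lab) / tabulate(lab, clustering$k)
    }
    pieces <- c(pieces, list(draws))
  }
  draws <- do.call(function(...) abind_first(list(...)), pieces)
  G_Q_C <- dim(draws)[3]
  out <- purrr::map_dfr(seq_len(clustering$k), function(h) {
    purrr::map_dfr(seq_len(G_Q_C), function(j) {
      v <- draws[, h, j]
      tibble::tibble(
        cluster = h, parameter = pnames[j], mean = mean(v),
        ci_lower = unname(quantile(v, a)), ci_upper = unname(quantile(v, 1 - a))
      )
    })
  })
  out
}

# rbind 3-d arrays along the first dimension.
abind_first <- function(arrays) {
  if (length(arrays) == 1L) return(arrays[[1]])
  d <- dim(arrays[[1]])
  total <- sum(vapply(arrays, function(a) dim(a)[1], integer(1)))
  out <- array(NA_real_, c(total, d[2], d[3]))
  at <- 0L
  for (a in arrays) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Adjusted Rand index of two partitions
#'
#' Hubert--Arabie chance-corrected agreement: 1 for identical partitions (up
#' to relabelling), around 0 for independent ones.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Scalar.
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) abort("label vectors differ in length")
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}

#' Match cluster labels between two partitions
#'
#' Finds the relabelling of `labels_b` that maximises the confusion-table
#' trace against `labels_a` (exact search over label permutations; at most 8
#' distinct labels).
#'
#' @param labels_a,labels_b Equal-length label vectors with integer-coercible
#'   labels.
#' @return `labels_b` relabelled onto `labels_a`'s label set.
#' @export
match_labels <- function(labels_a, labels_b) {
  la <- as.integer(factor(labels_a))
  lb <- as.integer(factor(labels_b))
  ka <- max(la); kb <- max(lb)
  k <- max(ka, kb)
  if (k > 8L) abort("label matching supports at most 8 distinct labels")
  tab <- matrix(0L, k, k)
  tt <- table(factor(lb, seq_len(k)), factor(la, seq_len(k)))
  tab[, ] <- tt
  perms <- all_permutations(k)
  scores <- vapply(seq_len(nrow(perms)), function(i) {
    sum(tab[cbind(seq_len(k), perms[i, ])])
  }, numeric(1))
  best <- perms[which.max(scores), ]
  unname(best[lb])
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, 0L, k)
  for (pos in seq_len(k)) {
    block <- cbind(
      sub[, seq_len(pos - 1L), drop = FALSE], k,
      sub[, seq(pos, k - 1L)[seq_len(k - pos)], drop = FALSE]
    )
    out <- rbind(out, block)
  }
  out
}

#' Cohen's kappa between two label vectors
#'
#' `(p_o - p_e) / (1 - p_e)` over the shared label space. For clusterings
#' with arbitrary label names, set `match = TRUE` to first relabel `labels_b`
#' by [match_labels()].
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @param match Relabel `labels_b` to maximise agreement first?
#' @return Scalar; `NA` with a warning when chance agreement is 1.
#' @export
cohens_kappa <- function(labels_a, labels_b, match = FALSE) {
  if (length(labels_a) != length(labels_b)) abort("label vectors differ in length")
  if (match) labels_b <- match_labels(labels_a, labels_b)
  lev <- union(unique(labels_a), unique(labels_b))
  tab <- table(factor(labels_a, lev), factor(labels_b, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warn("chance agreement is 1; kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Pearson correlation of strictly-lower-triangle entries
#'
#' Compares two (dis)similarity matrices over the same subjects by the
#' correlation of their pairwise entries.
#'
#' @param S_a,S_b Square matrices of identical shape and subject order.
#' @return Scalar; `NA` with a warning if either triangle is constant.
#' @export
lower_triangle_correlation <- function(S_a, S_b) {
  if (!identical(dim(S_a), dim(S_b))) abort("matrices differ in shape")
  a <- S_a[lower.tri(S_a)]
  b <- S_b[lower.tri(S_b)]
  if (sd(a) == 0 || sd(b) == 0) {
    warn("constant lower triangle; correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Agreement report across independent chains
#'
#' Pairwise lower-triangle Pearson correlations of the chain posterior
#' similarity matrices and pairwise adjusted Rand indices of the chain
#' representative clusterings, with their means and standard deviations.
#'
#' @param chains List of `profreg_chain` objects (>= 2).
#' @param k_range Passed to [representative_clustering()].
#' @return List with `pairs` (tibble: `chain_a`, `chain_b`, `pearson`,
#'   `ari`), `mean_pearson`, `sd_pearson`, `mean_ari`, `sd_ari`,
#'   `psm_list`, `clusterings`.
#' @export
chain_agreement <- function(chains, k_range = 2:15) {
  stopifnot(length(chains) >= 2L)
  psm_list <- purrr::map(chains, compute_psm)
  clusterings <- purrr::map(psm_list, representative_clustering, k_range = k_range)
  idx <- utils::combn(length(chains), 2L)
  pairs <- purrr::map_dfr(seq_len(ncol(idx)), function(j) {
    a <- idx[1L, j]; b <- idx[2L, j]
    tibble::tibble(
      chain_a = a, chain_b = b,
      pearson = lower_triangle_correlation(psm_list[[a]], psm_list[[b]]),
      ari = adjusted_rand(clusterings[[a]]$labels, clusterings[[b]]$labels)
    )
  })
  list(
    pairs = pairs,
    mean_pearson = mean(pairs$pearson), sd_pearson = sd(pairs$pearson),
    mean_ari = mean(pairs$ari), sd_ari = sd(pairs$ari),
    psm_list = psm_list, clusterings = clusterings
  )
}

#' Heatmap of a posterior similarity matrix
#'
#' Subjects are ordered by representative cluster (if supplied), showing the
#' block structure of the co-clustering probabilities.
#'
#' @param S Posterior similarity matrix.
#' @param clustering Optional [representative_clustering()] for ordering.
#' @return A ggplot object.
#' @export
plot_psm <- function(S, clustering = NULL) {
  ord <- if (!is.null(clustering)) order(clustering$labels) else seq_len(nrow(S))
  So <- S[ord, ord]
  df <- tidyr::expand_grid(i = seq_len(nrow(So)), j = seq_len(ncol(So)))
  df$s <- So[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i, fill = .data$s)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "P(same cluster)", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
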