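# Patient phenotyping: t-SNE + K-means, SOM + Ward clustering, random-forest
# feature importance, the median-dominance table, and the UPDRS-based
# tremor-dominant / akinetic-rigid / mixed subtype ratio.

#' t-SNE embedding followed by K-means
#'
#' Embeds the standardized metric table in 2D with t-SNE and clusters the
#' embedding with K-means (10 restarts, best inertia kept). When the cohort
#' is too small for the requested perplexity (t-SNE requires
#' `perplexity <= (n - 1) / 3`), the perplexity is clamped with a warning.
#'
#' @param x Standardized subjects-by-features table or matrix.
#' @param k Number of clusters (default 3).
#' @param perplexity t-SNE perplexity (default 30).
#' @param lr t-SNE learning rate (default 200).
#' @param iters Maximum t-SNE iterations (default 1000).
#' @param seed Integer seed.
#' @return Tibble with `subject` (row index), `cluster`, and the embedding
#'   coordinates `tsne_1`, `tsne_2`.
#' @export
tsne_kmeans <- function(x, k = 3L, perplexity = 30, lr = 200,
                        iters = 1000L, seed = 1L) {
  x <- as.matrix(numeric_part(tibble::as_tibble(x)))
  n <- nrow(x)
  if (k > n) {
    rlang::abort("more clusters than subjects",
                 class = "pdmotor_validation_error")
  }
  if (all(apply(x, 2L, function(v) max(v) - min(v)) == 0)) {
    rlang::warn("all subjects identical; returning a single cluster")
    return(tibble::tibble(subject = seq_len(n), cluster = 1L,
                          tsne_1 = 0, tsne_2 = 0))
  }
  max_perp <- floor((n - 1) / 3)
  if (perplexity > max_perp) {
    rlang::warn(paste0("perplexity ", perplexity, " too large for n = ", n,
                       "; clamped to ", max_perp))
    perplexity <- max_perp
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  emb <- Rtsne::Rtsne(x, dims = 2L, perplexity = perplexity, eta = lr,
                      max_iter = iters, theta = 0,
                      check_duplicates = FALSE, pca = FALSE, verbose = FALSE)$Y
  km <- stats::kmeans(emb, centers = k, nstart = 10L)
  tibble::tibble(subject = seq_len(n), cluster = as.integer(km$cluster),
                 tsne_1 = emb[, 1L], tsne_2 = emb[, 2L])
}

grid_coords <- function(grid) {
  as.matrix(expand.grid(row = seq_len(grid[1L]), col = seq_len(grid[2L])))
}

bmu_indices <- function(x, weights) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(weights))) +
    outer(rep(1, nrow(x)), rowSums(weights^2)) -
    2 * x %*% t(weights)
  max.col(-d2, ties.method = "first")
}

train_som_once <- function(x, grid, epochs, radius0, lr0 = 0.5, lr1 = 0.01,
                           init_weights = NULL) {
  n <- nrow(x)
  coords <- grid_coords(grid)
  m <- nrow(coords)
  # squared grid distances between all node pairs
  gd2 <- as.matrix(stats::dist(coords))^2
  w <- if (is.null(init_weights)) {
    apply(x, 2L, function(col) stats::runif(m, min(col), max(col)))
  } else {
    init_weights
  }
  if (is.null(dim(w))) w <- matrix(w, nrow = m)
  total <- max(1L, epochs * n)
  u <- 0L
  if (epochs > 0L) {
    for (e in seq_len(epochs)) {
      for (i in sample.int(n)) {
        frac <- u / total
        lr <- lr0 + (lr1 - lr0) * frac
        radius <- radius0 + (1 - radius0) * frac
        xi <- x[i, ]
        d2 <- rowSums(sweep(w, 2L, xi)^2)
        b <- which.min(d2)
        h <- exp(-gd2[, b] / (2 * radius^2))
        w <- w + lr * h * (matrix(xi, m, ncol(x), byrow = TRUE) - w)
        u <- u + 1L
      }
    }
  }
  bmu <- bmu_indices(x, w)
  qe <- mean(sqrt(rowSums((x - w[bmu, , drop = FALSE])^2)))
  list(weights = w, qe = qe, bmu = bmu)
}

#' Train a self-organizing map
#'
#' Online SOM with rectangular topology, Gaussian neighborhood, and linear
#' decay of both the learning rate (0.5 to 0.01) and the neighborhood
#' radius (initial value to 1). Every combination of grid size, epoch count
#' and initial radius is trained `restarts` times from seeded random
#' initializations; the model with the lowest quantization error (mean
#' Euclidean distance of samples to their best-matching unit) is returned.
#'
#' @param x Standardized subjects-by-features matrix or table.
#' @param grid Grid size `c(rows, cols)` or a list of candidate sizes.
#' @param epochs Epoch count or list of candidates.
#' @param radius Initial neighborhood radius or list of candidates
#'   (default: half the larger grid dimension).
#' @param restarts Seeded restarts per configuration (default 10).
#' @param seed Integer seed.
#' @param init_weights Optional explicit initial weight matrix (nodes x
#'   features); used with `epochs = 0` this makes the quantization error of
#'   a known codebook directly checkable.
#' @return Object of class `pd_som`: `weights` (nodes x features), `grid`,
#'   `qe`, `bmu` (per-sample best-matching unit), `data`, `config`.
#' @export
train_som <- function(x, grid = c(6L, 6L), epochs = 200L, radius = NULL,
                      restarts = 10L, seed = 1L, init_weights = NULL) {
  x <- as.matrix(numeric_part(tibble::as_tibble(x)))
  grids <- if (is.list(grid)) grid else list(grid)
  if (any(vapply(grids, function(g) any(g < 1L) || prod(g) < 1L, logical(1L)))) {
    rlang::abort("empty SOM grid", class = "pdmotor_validation_error")
  }
  epoch_list <- if (is.list(epochs)) epochs else list(epochs)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  best <- NULL
  for (g in grids) {
    radius_list <- if (is.null(radius)) {
      list(max(g) / 2)
    } else if (is.list(radius)) radius else list(radius)
    for (ep in epoch_list) {
      for (r0 in radius_list) {
        for (rs in seq_len(restarts)) {
          fit <- train_som_once(x, g, ep, r0, init_weights = init_weights)
          if (is.null(best) || fit$qe < best$qe) {
            best <- fit
            best$grid <- g
            best$config <- list(epochs = ep, radius = r0, restart = rs,
                                seed = seed)
          }
        }
      }
    }
  }
  structure(c(best, list(data = x)), class = "pd_som")
}

#' @export
print.pd_som <- function(x, ...) {
  cat("<pd_som>", paste(x$grid, collapse = "x"), "grid, QE",
      signif(x$qe, 4L), "\n")
  invisible(x)
}

#' @export
glance.pd_som <- function(x, ...) {
  tibble::tibble(rows = x$grid[1L], cols = x$grid[2L], qe = x$qe,
                 epochs = x$config$epochs, radius = x$config$radius)
}

#' Ward clustering of SOM neuron weights
#'
#' Agglomerative clustering (Ward criterion on Euclidean distances) of the
#' trained neuron weights; the dendrogram is cut at each requested k and
#' every subject inherits the cluster of its best-matching unit. Cuts of
#' the same tree are nested across k.
#'
#' @param som A `pd_som` from [train_som()].
#' @param k Cluster counts to cut at (default `c(2, 3, 4)`).
#' @return List with `assignments` (tibble: `k`, `subject`, `cluster`),
#'   `node_clusters` (named list of per-node labels), and `tree` (the
#'   `hclust` object).
#' @export
ward_cut <- function(som, k = c(2L, 3L, 4L)) {
  m <- nrow(som$weights)
  if (any(k > m)) {
    rlang::abort("k exceeds the SOM node count",
                 class = "pdmotor_validation_error")
  }
  tree <- stats::hclust(stats::dist(som$weights), method = "ward.D2")
  node_clusters <- lapply(stats::setNames(k, as.character(k)), function(kk) {
    stats::cutree(tree, k = kk)
  })
  assignments <- dplyr::bind_rows(lapply(as.character(k), function(kk) {
    tibble::tibble(
      k = as.integer(kk),
      subject = seq_along(som$bmu),
      cluster = as.integer(node_clusters[[kk]][som$bmu])
    )
  }))
  list(assignments = assignments, node_clusters = node_clusters, tree = tree)
}

#' Random-forest feature importance for a clustering
#'
#' Trains one 500-tree classification forest per seed on the features with
#' the cluster labels as classes, collects out-of-bag permutation
#' importance, and averages across seeds.
#'
#' @param x Subjects-by-features table or matrix.
#' @param labels Cluster labels (>= 2 distinct).
#' @param n_seeds Number of independently seeded forests (default 10).
#' @param n_trees Trees per forest (default 500).
#' @param seed Base seed.
#' @param top Number of top features flagged (default 10).
#' @return Tibble ranked by mean importance: `feature`, `importance`
#'   (mean OOB permutation importance), `importance_sd`, `rank`, `top`.
#' @export
rf_importance <- function(x, labels, n_seeds = 10L, n_trees = 500L,
                          seed = 1L, top = 10L) {
  x <- as.matrix(numeric_part(tibble::as_tibble(x)))
  if (length(unique(labels)) < 2L) {
    rlang::abort("feature importance needs at least 2 clusters",
                 class = "pdmotor_validation_error")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  imp <- vapply(seq_len(n_seeds), function(s) {
    set.seed(seed + s - 1L)
    rf <- randomForest::randomForest(x, y = factor(labels), ntree = n_trees,
                                     importance = TRUE)
    randomForest::importance(rf, type = 1L, scale = FALSE)[, 1L]
  }, numeric(ncol(x)))
  out <- tibble::tibble(
    feature = colnames(x),
    importance = rowMeans(imp),
    importance_sd = apply(imp, 1L, stats::sd)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$importance))
  out$rank <- seq_len(nrow(out))
  out$top <- out$rank <= top
  out
}

#' Median-dominance table across clusters
#'
#' For each feature, a one-way ANOVA tests for mean differences among
#' clusters; features passing `p < alpha` move to pairwise two-sample
#' t-tests, Bonferroni-corrected over the number of cluster pairs. In every
#' significant pair the cluster with the higher feature median scores one
#' "win"; the table aggregates wins per feature and cluster.
#'
#' @param x Subjects-by-features table or matrix.
#' @param labels Cluster labels (>= 2 clusters, each with >= 2 members).
#' @param alpha Significance level (default 0.05), used for both the ANOVA
#'   screen and the corrected pairwise tests.
#' @return Object of class `pd_dominance`: `counts` (tibble `feature`,
#'   `cluster`, `wins`, zero rows omitted), `anova` (tibble `feature`,
#'   `p_value`, `skipped`).
#' @export
dominance <- function(x, labels, alpha = 0.05) {
  x <- as.matrix(numeric_part(tibble::as_tibble(x)))
  labels <- as.integer(factor(labels))
  cl <- sort(unique(labels))
  if (length(cl) < 2L || any(table(labels) < 2L)) {
    rlang::abort("dominance needs >= 2 clusters with >= 2 members each",
                 class = "pdmotor_validation_error")
  }
  pairs <- utils::combn(cl, 2L)
  n_pairs <- ncol(pairs)
  anova_rows <- list()
  count_rows <- list()
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    feature <- colnames(x)[j]
    if (stats::var(v) == 0 ||
        all(vapply(cl, function(c) stats::var(v[labels == c]) == 0,
                   logical(1L)))) {
      anova_rows[[length(anova_rows) + 1L]] <-
        tibble::tibble(feature = feature, p_value = NA_real_, skipped = TRUE)
      next
    }
    p <- stats::anova(stats::lm(v ~ factor(labels)))[["Pr(>F)"]][1L]
    anova_rows[[length(anova_rows) + 1L]] <-
      tibble::tibble(feature = feature, p_value = p, skipped = FALSE)
    if (is.na(p) || p >= alpha) next
    for (q in seq_len(n_pairs)) {
      a <- pairs[1L, q]
      b <- pairs[2L, q]
      va <- v[labels == a]
      vb <- v[labels == b]
      if (stats::var(va) == 0 && stats::var(vb) == 0) next
      p_pair <- stats::t.test(va, vb)$p.value
      if (min(1, p_pair * n_pairs) < alpha) {
        winner <- if (stats::median(va) >= stats::median(vb)) a else b
        count_rows[[length(count_rows) + 1L]] <-
          tibble::tibble(feature = feature, cluster = winner)
      }
    }
  }
  counts <- if (length(count_rows)) {
    dplyr::count(dplyr::bind_rows(count_rows), .data$feature, .data$cluster,
                 name = "wins")
  } else {
    tibble::tibble(feature = character(0L), cluster = integer(0L),
                   wins = integer(0L))
  }
  structure(
    list(counts = counts, anova = dplyr::bind_rows(anova_rows),
         alpha = alpha),
    class = "pd_dominance"
  )
}

#' @export
print.pd_dominance <- function(x, ...) {
  cat("<pd_dominance>", sum(!x$anova$skipped & x$anova$p_value < x$alpha,
                            na.rm = TRUE),
      "significant features,", sum(x$counts$wins), "wins\n")
  invisible(x)
}

#' @export
tidy.pd_dominance <- function(x, ...) x$counts

#' Tremor-dominant / akinetic-rigid / mixed subtype from UPDRS-III
#'
#' The subtype ratio compares mean tremor item scores (Q20, Q21) with mean
#' akinetic-rigid item scores (Q22-Q26, Q31): tremor-dominant when the
#' ratio is at least `thresholds[1]`, akinetic-rigid when at most
#' `thresholds[2]`, mixed otherwise. A zero denominator yields
#' tremor-dominant when the numerator is positive and mixed when both are
#' zero.
#'
#' @param updrs Tibble of exams (columns `Q18`..`Q31`; one row per subject).
#' @param thresholds Upper and lower ratio thresholds, default
#'   `c(1.5, 1/1.5)`.
#' @return Tibble with `ratio` and `phenotype`
#'   (`"tremor_dominant"`, `"akinetic_rigid"`, `"mixed"`), one row per exam.
#' @export
eggers_classify <- function(updrs, thresholds = c(1.5, 1 / 1.5)) {
  need <- c(updrs_tremor_items(), updrs_akinetic_items())
  if (!all(need %in% names(updrs))) {
    rlang::abort("exam is missing tremor or akinetic-rigid items",
                 class = "pdmotor_validation_error")
  }
  num <- rowMeans(as.matrix(updrs[updrs_tremor_items()]))
  den <- rowMeans(as.matrix(updrs[updrs_akinetic_items()]))
  ratio <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, NaN))
  phenotype <- dplyr::case_when(
    den == 0 & num > 0 ~ "tremor_dominant",
    den == 0 & num == 0 ~ "mixed",
    ratio >= thresholds[1L] ~ "tremor_dominant",
    ratio <= thresholds[2L] ~ "akinetic_rigid",
    TRUE ~ "mixed"
  )
  tibble::tibble(ratio = ratio, phenotype = phenotype)
}

#' Compare two partitions of the same subjects
#'
#' Adjusted Rand index, cross-tabulation, and (when the feature table is
#' supplied) the mean silhouette width of each partition in the
#' standardized metric space.
#'
#' @param a,b Integer/character label vectors over the same subjects.
#' @param x Optional subjects-by-features table for silhouettes.
#' @return List with `ari`, `contingency`, `silhouette_a`, `silhouette_b`
#'   (NA without `x` or for single-cluster partitions).
#' @export
compare_partitions <- function(a, b, x = NULL) {
  if (length(a) != length(b)) {
    rlang::abort("partitions cover different subjects",
                 class = "pdmotor_validation_error")
  }
  sil <- function(lab) {
    if (is.null(x) || length(unique(lab)) < 2L) return(NA_real_)
    d <- stats::dist(as.matrix(numeric_part(tibble::as_tibble(x))))
    mean(cluster::silhouette(as.integer(factor(lab)), d)[, "sil_width"])
  }
  list(
    ari = mclust::adjustedRandIndex(a, b),
    contingency = table(a, b),
    silhouette_a = sil(a),
    silhouette_b = sil(b)
  )
}
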