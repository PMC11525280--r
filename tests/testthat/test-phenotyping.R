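blobs <- function(n_per = 20L, d = 3L, centers = c(0, 8, -8), sd = 0.5,
                  seed = 1L) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(centers, function(c0) {
      matrix(rnorm(n_per * d, c0, sd), n_per, d)
    }))
    colnames(x) <- paste0("f", seq_len(d))
    list(x = x, labels = rep(seq_along(centers), each = n_per))
  })
}

test_that("t-SNE + K-means recovers well-separated blobs", {
  b <- blobs()
  for (s in 1:5) {
    res <- suppressWarnings(tsne_kmeans(b$x, k = 3, seed = s))
    expect_equal(mclust::adjustedRandIndex(res$cluster, b$labels), 1.0)
  }
  # k = 1 labels everyone identically
  res1 <- suppressWarnings(tsne_kmeans(b$x, k = 1, seed = 1))
  expect_true(all(res1$cluster == 1L))
  # degenerate input: warning plus a single effective cluster
  same <- matrix(1, 20, 3, dimnames = list(NULL, paste0("f", 1:3)))
  expect_warning(r0 <- tsne_kmeans(same, k = 3, seed = 1), "identical")
  expect_true(all(r0$cluster == 1L))
  expect_error(tsne_kmeans(b$x[1:3, ], k = 10, seed = 1),
               class = "pdmotor_validation_error")
})

test_that("a small cohort clamps the t-SNE perplexity with a warning", {
  b <- blobs(n_per = 10L)  # n = 30 < 3 * 30
  expect_warning(tsne_kmeans(b$x, k = 3, perplexity = 30, seed = 2),
                 "clamped")
})

test_that("SOM quantization error honours its contracts", {
  b <- blobs(seed = 3)
  z <- scale(b$x)
  # data equal to the initial codebook: QE = 0 with no training
  init <- z[sample(nrow(z), 36, replace = TRUE), ]
  som0 <- train_som(z[1:36, ], grid = c(6, 6), epochs = 0, restarts = 1,
                    seed = 1, init_weights = z[1:36, ])
  expect_lt(som0$qe, 1e-12)
  # a 1x1 grid converges to the data mean
  som1 <- train_som(z, grid = c(1, 1), epochs = 50, restarts = 2, seed = 2)
  qe_mean <- mean(sqrt(rowSums(sweep(z, 2, colMeans(z))^2)))
  expect_equal(som1$qe, qe_mean, tolerance = 0.05)
  # the returned model is the QE argmin across trained configurations
  som_a <- train_som(z, grid = list(c(2, 2), c(4, 4)), epochs = 30,
                     restarts = 2, seed = 3)
  som_b <- train_som(z, grid = c(2, 2), epochs = 30, restarts = 2, seed = 3)
  expect_lte(som_a$qe, som_b$qe)
  expect_error(train_som(z, grid = c(0, 3)), class = "pdmotor_validation_error")
})

test_that("SOM quantization error decreases with training in expectation", {
  b <- blobs(seed = 4)
  z <- scale(b$x)
  qes <- vapply(1:10, function(s) {
    short <- train_som(z, grid = c(4, 4), epochs = 2, restarts = 1, seed = s)
    long <- train_som(z, grid = c(4, 4), epochs = 40, restarts = 1, seed = s)
    c(short$qe, long$qe)
  }, numeric(2L))
  expect_lt(mean(qes[2L, ]), mean(qes[1L, ]))
})

test_that("Ward cuts recover blob structure and are nested across k", {
  b <- blobs(seed = 5)
  z <- scale(b$x)
  som <- train_som(z, grid = c(6, 6), epochs = 60, restarts = 3, seed = 6)
  wc <- ward_cut(som, k = c(2, 3, 4))
  lab3 <- wc$assignments$cluster[wc$assignments$k == 3]
  expect_equal(mclust::adjustedRandIndex(lab3, b$labels), 1.0)
  # nestedness: each k = 3 cluster maps into exactly one k = 2 cluster
  lab2 <- wc$assignments$cluster[wc$assignments$k == 2]
  expect_true(all(tapply(lab2, lab3, function(v) length(unique(v))) == 1))
  lab4 <- wc$assignments$cluster[wc$assignments$k == 4]
  expect_true(all(tapply(lab3, lab4, function(v) length(unique(v))) == 1))
  # linkage heights are non-decreasing
  expect_true(all(diff(wc$tree$height) >= -1e-9))
  expect_error(ward_cut(som, k = 99), class = "pdmotor_validation_error")
})

test_that("random-forest importance finds a planted discriminative feature", {
  withr::local_seed(20)
  n <- 60
  labels <- rep(1:3, each = 20)
  x <- cbind(signal = labels + rnorm(n, 0, 0.05),
             matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("noise", 1:5))))
  imp <- rf_importance(x, labels, n_seeds = 5, n_trees = 300, seed = 2)
  expect_identical(imp$feature[1L], "signal")
  expect_true(imp$top[imp$feature == "signal"])
  # uninformative features have importance near zero
  x0 <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("n", 1:4)))
  imp0 <- rf_importance(x0, labels, n_seeds = 5, n_trees = 300, seed = 3)
  se <- imp0$importance_sd / sqrt(5)
  expect_true(all(abs(imp0$importance) < pmax(2 * se, 0.02)))
  expect_error(rf_importance(x, rep(1, n)), class = "pdmotor_validation_error")
})

test_that("duplicated features keep their joint importance and ranking", {
  withr::local_seed(21)
  n <- 60
  labels <- rep(1:2, each = 30)
  base <- cbind(sig = labels + rnorm(n, 0, 0.2),
                matrix(rnorm(n * 3), n, 3,
                       dimnames = list(NULL, paste0("z", 1:3))))
  dup <- cbind(base, sig_copy = base[, "sig"])
  imp <- rf_importance(dup, labels, n_seeds = 5, n_trees = 300, seed = 4)
  expect_true(all(c("sig", "sig_copy") %in% imp$feature[1:2]))
})

test_that("dominance counts match an independent brute-force recomputation", {
  brute_dominance <- function(x, labels, alpha = 0.05) {
    cl <- sort(unique(labels))
    pairs <- utils::combn(cl, 2)
    wins <- list()
    for (j in seq_len(ncol(x))) {
      v <- x[, j]
      p <- stats::anova(stats::lm(v ~ factor(labels)))[["Pr(>F)"]][1]
      if (is.na(p) || p >= alpha) next
      for (q in seq_len(ncol(pairs))) {
        va <- v[labels == pairs[1, q]]
        vb <- v[labels == pairs[2, q]]
        if (stats::t.test(va, vb)$p.value * ncol(pairs) < alpha) {
          w <- if (median(va) >= median(vb)) pairs[1, q] else pairs[2, q]
          key <- paste(colnames(x)[j], w)
          wins[[key]] <- (wins[[key]] %||% 0L) + 1L
        }
      }
    }
    wins
  }
  withr::local_seed(30)
  n <- 60
  labels <- rep(1:3, each = 20)
  x <- cbind(
    high_in_3 = ifelse(labels == 3, 10, 0) + rnorm(n),
    high_in_1 = ifelse(labels == 1, 5, 0) + rnorm(n),
    flat = rnorm(n)
  )
  d <- dominance(x, labels)
  brute <- brute_dominance(x, labels)
  got <- stats::setNames(d$counts$wins,
                         paste(d$counts$feature, d$counts$cluster))
  expect_mapequal(as.list(got), brute)
  # a feature elevated only in cluster 3 wins both of its significant pairs
  expect_equal(unname(got["high_in_3 3"]), 2L)
  expect_false("flat" %in% d$counts$feature)
})

test_that("two clear clusters give a single dominance win", {
  withr::local_seed(31)
  labels <- rep(1:2, each = 20)
  x <- cbind(A = c(rnorm(20, 10), rnorm(20, 0)), B = rnorm(40))
  d <- dominance(x, labels)
  expect_equal(d$counts$feature, "A")
  expect_equal(d$counts$cluster, 1L)
  expect_equal(d$counts$wins, 1L)
})

test_that("null features trigger dominance wins at roughly the alpha rate", {
  withr::local_seed(32)
  hits <- replicate(200, {
    v <- rnorm(40)
    labels <- rep(1:2, each = 20)
    p <- stats::anova(stats::lm(v ~ factor(labels)))[["Pr(>F)"]][1]
    p < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.04)
})

test_that("UPDRS subtype classification follows the tremor/akinetic ratio", {
  mk <- function(scores) tibble::as_tibble(
    as.list(stats::setNames(scores, updrs_items()))
  )
  all_tremor <- mk(c(0, 0, 4, 4, rep(0, 10)))
  expect_equal(eggers_classify(all_tremor)$phenotype, "tremor_dominant")
  all_equal <- mk(rep(2, 14))
  expect_equal(eggers_classify(all_equal)$phenotype, "mixed")
  all_zero <- mk(rep(0, 14))
  expect_equal(eggers_classify(all_zero)$phenotype, "mixed")
  ar <- mk(c(0, 0, 0, 0, 4, 4, 4, 4, 4, 0, 0, 0, 0, 4))
  expect_equal(eggers_classify(ar)$phenotype, "akinetic_rigid")
  expect_error(eggers_classify(all_zero[, 1:5]),
               class = "pdmotor_validation_error")
})

test_that("partition comparison returns ARI 1 for identical labelings", {
  a <- rep(1:3, each = 10)
  comp <- compare_partitions(a, a)
  expect_equal(comp$ari, 1.0)
  # one cluster against many: ARI 0
  expect_equal(compare_partitions(rep(1, 30), a)$ari, 0)
  # permutation null: mean ARI about 0
  withr::local_seed(33)
  aris <- replicate(100, mclust::adjustedRandIndex(sample(a), a))
  expect_lt(abs(mean(aris)), 0.05)
  expect_error(compare_partitions(a, a[1:10]),
               class = "pdmotor_validation_error")
})
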