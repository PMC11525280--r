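# Elastic-net prediction of the total UPDRS-III score.
#
# The solver is an in-package coordinate descent on the objective
#   (1/2n) ||y - b0 - X b||^2 + lambda (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)
# with features standardized internally and df = number of nonzero
# coefficients. Hyperparameters come from a grid search that discards every
# (alpha, lambda) pair whose full-data df exceeds a cap of 50% of the cohort
# size, then maximizes leave-one-out R^2.

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- as.matrix(x[vapply(x, is.numeric, logical(1L))])
  }
  storage.mode(x) <- "double"
  x
}

standardize_train <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  s_safe <- ifelse(s > 0, s, 1)
  xs <- sweep(sweep(x, 2L, m), 2L, s_safe, "/")
  xs[, s == 0] <- 0
  list(xs = xs, mean = m, sd = s, sd_safe = s_safe)
}

apply_standardization <- function(x, st) {
  xs <- sweep(sweep(x, 2L, st$mean), 2L, st$sd_safe, "/")
  xs[, st$sd == 0] <- 0
  xs
}

#' Fit an elastic net at fixed hyperparameters
#'
#' Coordinate-descent fit of the penalized least-squares objective.
#' Features are standardized internally (SD denominator n - 1) and the
#' response centered; reported coefficients are on the original feature
#' scale. `df` counts nonzero coefficients.
#'
#' @param x Subjects-by-features table (numeric matrix or data frame;
#'   non-numeric columns are dropped).
#' @param y Numeric response (total UPDRS-III).
#' @param alpha L1 mixing parameter in `(0, 1]`.
#' @param lambda Penalty strength (>= 0).
#' @param tol Coordinate-descent convergence tolerance: a sweep's largest
#'   coefficient change, relative to the coefficient scale (absolute while
#'   all coefficients are below 1), must fall below it.
#' @param max_iter Sweep cap.
#' @return An object of class `pd_enet` with elements `intercept`,
#'   `coefficients` (named, original scale), `alpha`, `lambda`, `df`,
#'   `standardization` (per-feature mean/SD), and `objective` (penalized
#'   objective after each sweep, non-increasing).
#' @export
fit_enet <- function(x, y, alpha, lambda, tol = 1e-7, max_iter = 2000L) {
  x <- as_feature_matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    rlang::abort("fit_enet requires finite inputs",
                 class = "pdmotor_validation_error")
  }
  if (nrow(x) < 3L) {
    rlang::abort("fit_enet needs at least 3 subjects",
                 class = "pdmotor_validation_error")
  }
  st <- standardize_train(x)
  yc <- y - mean(y)
  fit <- enet_fit_cpp(st$xs, yc, alpha, lambda, tol, max_iter)
  beta_std <- fit$beta
  beta <- beta_std / st$sd_safe
  beta[st$sd == 0] <- 0
  names(beta) <- colnames(x)
  structure(
    list(
      intercept = mean(y) - sum(beta * st$mean),
      coefficients = beta,
      beta_std = stats::setNames(beta_std, colnames(x)),
      alpha = alpha, lambda = lambda,
      df = sum(beta_std != 0),
      standardization = st[c("mean", "sd")],
      objective = fit$objective,
      y_mean = mean(y)
    ),
    class = "pd_enet"
  )
}

#' @export
print.pd_enet <- function(x, ...) {
  cat("<pd_enet> alpha", x$alpha, "lambda", signif(x$lambda, 4L),
      "df", x$df, "\n")
  invisible(x)
}

#' @export
predict.pd_enet <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  if (!identical(colnames(x), names(object$coefficients))) {
    if (!all(names(object$coefficients) %in% colnames(x))) {
      rlang::abort("newdata lacks the model's features",
                   class = "pdmotor_validation_error")
    }
    x <- x[, names(object$coefficients), drop = FALSE]
  }
  drop(object$intercept + x %*% object$coefficients)
}

#' @export
tidy.pd_enet <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @export
glance.pd_enet <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, lambda = x$lambda, df = x$df,
                 sweeps = length(x$objective))
}

#' Largest useful penalty
#'
#' The smallest `lambda` at which every coefficient is zero,
#' `max |x_j' y| / (n alpha)` on standardized features and centered
#' response.
#'
#' @inheritParams fit_enet
#' @return Scalar `lambda_max`.
#' @export
lambda_max <- function(x, y, alpha) {
  x <- as_feature_matrix(x)
  st <- standardize_train(x)
  yc <- y - mean(y)
  max(abs(crossprod(st$xs, yc))) / (nrow(x) * max(alpha, 1e-3))
}

default_lambda_grid <- function(x, y, alpha, n_lambda = 50L, ratio = 1e-3) {
  lmax <- lambda_max(x, y, alpha)
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

cv_report <- function(truth, pred, scheme = "loo") {
  ss_res <- sum((truth - pred)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  structure(
    list(
      predictions = tibble::tibble(truth = truth, predicted = pred),
      mae = mean(abs(truth - pred)),
      r2 = 1 - ss_res / ss_tot,
      scheme = scheme
    ),
    class = "pd_cv"
  )
}

#' @export
print.pd_cv <- function(x, ...) {
  cat("<pd_cv>", x$scheme, " MAE", signif(x$mae, 4L),
      " R2", signif(x$r2, 4L), "\n")
  invisible(x)
}

#' @export
glance.pd_cv <- function(x, ...) {
  tibble::tibble(mae = x$mae, r2 = x$r2, scheme = x$scheme,
                 n = nrow(x$predictions))
}

#' @export
tidy.pd_cv <- function(x, ...) x$predictions

# LOOCV predictions for a whole lambda path at one alpha. Each fold
# re-standardizes on its training rows. `test_rows` optionally overrides the
# held-out design row (used by the cluster-augmented model, where the
# held-out subject's cluster indicator must come from a leakage-free
# assignment).
path_loocv_predictions <- function(x, y, alpha, lambdas, test_rows = NULL,
                                   tol = 1e-7) {
  n <- nrow(x)
  preds <- matrix(NA_real_, n, length(lambdas))
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]
    yt <- y[-i]
    st <- standardize_train(xt)
    betas <- enet_path_cpp(st$xs, yt - mean(yt), alpha, lambdas, tol)
    row <- if (is.null(test_rows)) x[i, ] else test_rows[i, ]
    xs <- (row - st$mean) / ifelse(st$sd > 0, st$sd, 1)
    xs[st$sd == 0] <- 0
    preds[i, ] <- mean(yt) + drop(xs %*% betas)
  }
  preds
}

#' Leave-one-out cross-validation at fixed hyperparameters
#'
#' Each subject is predicted by a model refit on the remaining n - 1
#' subjects, re-standardizing features within every fold. No shortcut
#' formula is used: every fold is a genuine refit.
#'
#' @inheritParams fit_enet
#' @return A `pd_cv` object with per-subject predictions, `mae`, and `r2`
#'   (`1 - SS_res / SS_tot`).
#' @export
loocv <- function(x, y, alpha, lambda, tol = 1e-7) {
  x <- as_feature_matrix(x)
  stopifnot(nrow(x) >= 3L)
  preds <- path_loocv_predictions(x, y, alpha, lambda, tol = tol)
  cv_report(y, preds[, 1L])
}

#' Grid search with a degrees-of-freedom cap
#'
#' For every (alpha, lambda) pair the full-data df is computed; pairs whose
#' df exceeds `floor(df_cap_frac * n)` are discarded outright (their LOOCV
#' score is never needed, so it is not computed), the remaining pairs are
#' scored by LOOCV R^2, and the highest R^2 wins (ties: smallest df, then
#' largest lambda). The winning model is refit on the full data.
#'
#' @inheritParams fit_enet
#' @param alpha_grid Mixing parameters to try.
#' @param n_lambda,lambda_ratio Per-alpha log-spaced penalty grid from
#'   `lambda_max` down to `lambda_ratio * lambda_max`.
#' @param df_cap_frac Df cap as a fraction of the cohort size (default 0.5).
#' @return List with `fit` (the selected `pd_enet`), `cv` (its `pd_cv`
#'   LOOCV report) and `grid` (tibble of every evaluated pair with `df`,
#'   `r2`, `mae`, `accepted`).
#' @export
enet_grid_search <- function(x, y, alpha_grid = seq(0.1, 1, by = 0.1),
                             n_lambda = 50L, lambda_ratio = 1e-3,
                             df_cap_frac = 0.5, tol = 1e-7) {
  x <- as_feature_matrix(x)
  n <- nrow(x)
  cap <- floor(df_cap_frac * n)
  st <- standardize_train(x)
  yc <- y - mean(y)
  rows <- list()
  pred_store <- list()
  for (alpha in alpha_grid) {
    lambdas <- default_lambda_grid(x, y, alpha, n_lambda, lambda_ratio)
    full_betas <- enet_path_cpp(st$xs, yc, alpha, lambdas, tol)
    dfs <- colSums(full_betas != 0)
    # pairs over the df cap are discarded whatever their cross-validated
    # score, so LOOCV is only spent on the cap-eligible head of the path
    # (the over-cap tail is also where p > n makes fits degenerate and slow)
    eligible <- dfs <= cap
    n_eval <- if (any(eligible)) max(which(eligible)) else 0L
    r2 <- rep(NA_real_, length(lambdas))
    mae <- rep(NA_real_, length(lambdas))
    if (n_eval > 0L) {
      preds <- path_loocv_predictions(x, y, alpha, lambdas[seq_len(n_eval)],
                                      tol = tol)
      pred_store[[as.character(alpha)]] <- preds
      r2[seq_len(n_eval)] <- apply(preds, 2L, function(p) {
        1 - sum((y - p)^2) / sum((y - mean(y))^2)
      })
      mae[seq_len(n_eval)] <- apply(preds, 2L, function(p) mean(abs(y - p)))
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      alpha = alpha, lambda = lambdas, df = as.integer(dfs),
      r2 = r2, mae = mae, accepted = eligible,
      lambda_index = seq_along(lambdas)
    )
  }
  grid <- dplyr::bind_rows(rows)
  ok <- grid[grid$accepted, , drop = FALSE]
  if (nrow(ok) == 0L) {
    rlang::abort(
      paste0("every grid point exceeds the df cap (", cap,
             "); extend the lambda grid upward"),
      class = "pdmotor_validation_error"
    )
  }
  ok <- dplyr::arrange(ok, dplyr::desc(.data$r2), .data$df,
                       dplyr::desc(.data$lambda))
  best <- ok[1L, ]
  fit <- fit_enet(x, y, best$alpha, best$lambda, tol = tol)
  stopifnot(fit$df <= cap)
  # the per-subject LOOCV predictions for the winning pair were already
  # computed (warm-started) during the search
  cv <- cv_report(y, pred_store[[as.character(best$alpha)]][, best$lambda_index])
  grid$lambda_index <- NULL
  list(fit = fit, cv = cv, grid = grid)
}

#' Apply a frozen model to a second visit
#'
#' Applies a day-1 fit (coefficients and standardization untouched) to
#' day-2 features and scores the predictions.
#'
#' @param fit A `pd_enet` from [fit_enet()] or [enet_grid_search()].
#' @param x_new,y_new Day-2 features and observed totals.
#' @return A `pd_cv` report (scheme `"transfer"`).
#' @export
transfer_predict <- function(fit, x_new, y_new) {
  pred <- predict(fit, x_new)
  out <- cv_report(y_new, pred, scheme = "transfer")
  out
}

one_hot <- function(labels, levels_all = sort(unique(labels))) {
  m <- vapply(levels_all, function(l) as.numeric(labels == l),
              numeric(length(labels)))
  colnames(m) <- paste0("cluster_", levels_all)
  m
}

# Leakage-free held-out cluster labels: for each LOOCV fold either retrain a
# SOM on the training subjects (nodes vote with the supplied labels; the
# held-out subject inherits its BMU's majority label) or fall back to the
# nearest training-cluster centroid.
heldout_cluster_labels <- function(x, labels, som_args = NULL) {
  n <- nrow(x)
  out <- labels
  for (i in seq_len(n)) {
    xt <- scale(x[-i, , drop = FALSE])
    ctr <- attr(xt, "scaled:center")
    scl <- attr(xt, "scaled:scale")
    scl[!is.finite(scl) | scl == 0] <- 1
    xi <- (x[i, ] - ctr) / scl
    lt <- labels[-i]
    if (!is.null(som_args)) {
      som <- do.call(train_som, c(list(x = xt), som_args))
      bmu_train <- bmu_indices(xt, som$weights)
      node_lab <- vapply(seq_len(nrow(som$weights)), function(k) {
        members <- lt[bmu_train == k]
        if (length(members) == 0L) NA_integer_ else
          as.integer(names(sort(table(members), decreasing = TRUE))[1L])
      }, integer(1L))
      k_i <- bmu_indices(matrix(xi, 1L), som$weights)
      lab <- node_lab[k_i]
      if (is.na(lab)) {
        d <- colSums((t(som$weights) - xi)^2)
        lab <- node_lab[order(d)][which(!is.na(node_lab[order(d)]))[1L]]
      }
      out[i] <- lab
    } else {
      cents <- vapply(sort(unique(lt)), function(l) {
        colMeans(xt[lt == l, , drop = FALSE])
      }, numeric(ncol(xt)))
      out[i] <- sort(unique(lt))[which.min(colSums((cents - xi)^2))]
    }
  }
  out
}

#' Cluster-augmented elastic net
#'
#' Appends one-hot cluster indicators to the feature table (penalized like
#' any other feature) and reruns the df-capped grid search with LOOCV. The
#' held-out subject's indicator in each fold comes from a leakage-free
#' assignment: a SOM retrained on the fold's training subjects (held-out
#' subject inherits its best-matching unit's majority label) when
#' `som_args` is supplied, otherwise the nearest training-cluster centroid.
#'
#' @inheritParams enet_grid_search
#' @param clusters Integer cluster labels aligned with the rows of `x`.
#' @param som_args Optional list of [train_som()] arguments for the per-fold
#'   assignment (e.g. `list(grid = c(6, 6), epochs = 50, restarts = 1,
#'   seed = 1)`).
#' @return As [enet_grid_search()].
#' @export
cluster_augmented_fit <- function(x, y, clusters,
                                  alpha_grid = seq(0.1, 1, by = 0.1),
                                  n_lambda = 50L, lambda_ratio = 1e-3,
                                  df_cap_frac = 0.5, som_args = NULL,
                                  tol = 1e-7) {
  x <- as_feature_matrix(x)
  if (length(unique(clusters)) < 2L) {
    return(enet_grid_search(x, y, alpha_grid, n_lambda, lambda_ratio,
                            df_cap_frac, tol))
  }
  levels_all <- sort(unique(clusters))
  held <- heldout_cluster_labels(x, clusters, som_args)
  x_aug <- cbind(x, one_hot(clusters, levels_all))
  x_test <- cbind(x, one_hot(held, levels_all))
  n <- nrow(x_aug)
  cap <- floor(df_cap_frac * n)
  st <- standardize_train(x_aug)
  yc <- y - mean(y)
  rows <- list()
  pred_store <- list()
  for (alpha in alpha_grid) {
    lambdas <- default_lambda_grid(x_aug, y, alpha, n_lambda, lambda_ratio)
    full_betas <- enet_path_cpp(st$xs, yc, alpha, lambdas, tol)
    dfs <- colSums(full_betas != 0)
    eligible <- dfs <= cap
    n_eval <- if (any(eligible)) max(which(eligible)) else 0L
    r2 <- rep(NA_real_, length(lambdas))
    mae <- rep(NA_real_, length(lambdas))
    if (n_eval > 0L) {
      preds <- path_loocv_predictions(x_aug, y, alpha,
                                      lambdas[seq_len(n_eval)],
                                      test_rows = x_test, tol = tol)
      pred_store[[as.character(alpha)]] <- preds
      r2[seq_len(n_eval)] <- apply(preds, 2L, function(p) {
        1 - sum((y - p)^2) / sum((y - mean(y))^2)
      })
      mae[seq_len(n_eval)] <- apply(preds, 2L, function(p) mean(abs(y - p)))
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      alpha = alpha, lambda = lambdas, df = as.integer(dfs),
      r2 = r2, mae = mae, accepted = eligible,
      lambda_index = seq_along(lambdas)
    )
  }
  grid <- dplyr::bind_rows(rows)
  ok <- grid[grid$accepted, , drop = FALSE]
  if (nrow(ok) == 0L) {
    rlang::abort("every grid point exceeds the df cap",
                 class = "pdmotor_validation_error")
  }
  ok <- dplyr::arrange(ok, dplyr::desc(.data$r2), .data$df,
                       dplyr::desc(.data$lambda))
  best <- ok[1L, ]
  fit <- fit_enet(x_aug, y, best$alpha, best$lambda, tol = tol)
  cv <- cv_report(y, pred_store[[as.character(best$alpha)]][, best$lambda_index])
  grid$lambda_index <- NULL
  list(fit = fit, cv = cv, grid = grid)
}
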