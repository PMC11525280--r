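# Standardization and PCA variance-explained curves for UPDRS items, motor
# metrics, and their union.

numeric_part <- function(df) {
  if (is.matrix(df)) return(as.data.frame(df))
  df[vapply(df, is.numeric, logical(1L))]
}

#' Median imputation of missing metrics
#'
#' Replaces `NA` entries of each numeric column by the column (cohort)
#' median. Identifier columns pass through untouched.
#'
#' @param df Data frame or tibble.
#' @return Tibble of the same shape.
#' @export
impute_median <- function(df) {
  df <- tibble::as_tibble(df)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) {
    v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    v
  })
  df
}

#' Standardize a subjects-by-variables table
#'
#' Each numeric column has its mean removed and is divided by its standard
#' deviation (denominator n - 1). Constant columns carry no information for
#' a correlation-structure analysis and are dropped with a warning.
#'
#' @param df Data frame, tibble or matrix (rows = subjects).
#' @return Tibble of standardized columns (mean 0, SD 1).
#' @export
#' @examples
#' standardize_table(data.frame(a = c(1, 2, 3)))
standardize_table <- function(df) {
  x <- numeric_part(df)
  if (nrow(x) < 2L) {
    rlang::abort("standardization needs at least 2 subjects",
                 class = "pdmotor_validation_error")
  }
  sds <- vapply(x, stats::sd, numeric(1L))
  constant <- !is.na(sds) & sds == 0
  if (all(constant)) {
    rlang::abort("all columns are constant", class = "pdmotor_validation_error")
  }
  if (any(constant)) {
    rlang::warn(paste0("dropping constant columns: ",
                       paste(names(x)[constant], collapse = ", ")))
    x <- x[!constant]
    sds <- sds[!constant]
  }
  tibble::as_tibble(lapply(stats::setNames(names(x), names(x)), function(cn) {
    (x[[cn]] - mean(x[[cn]])) / sds[[cn]]
  }))
}

#' PCA variance-explained curve
#'
#' Principal component analysis of a standardized table (i.e. of the
#' correlation structure), with components ordered by explained variance.
#'
#' @param df Standardized subjects-by-variables table (see
#'   [standardize_table()]; missing values must be imputed upstream, see
#'   [impute_median()]).
#' @return Object of class `pd_pca`: `loadings` (variables x components),
#'   `explained` (per-component variance fractions, summing to 1),
#'   `cum_explained`, `variable_names`.
#' @export
pca_curve <- function(df) {
  x <- as.matrix(numeric_part(df))
  if (nrow(x) < 2L) {
    rlang::abort("PCA needs at least 2 subjects",
                 class = "pdmotor_validation_error")
  }
  if (anyNA(x)) {
    rlang::abort("PCA input contains missing values; impute first",
                 class = "pdmotor_validation_error")
  }
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  v <- pc$sdev^2
  explained <- v / sum(v)
  structure(
    list(
      loadings = pc$rotation,
      explained = explained,
      cum_explained = cumsum(explained),
      variable_names = colnames(x),
      scores = pc$x
    ),
    class = "pd_pca"
  )
}

#' @export
print.pd_pca <- function(x, ...) {
  cat("<pd_pca>", length(x$variable_names), "variables,",
      length(x$explained), "components; PC1 explains",
      sprintf("%.1f%%", 100 * x$explained[1L]), "\n")
  invisible(x)
}

#' @export
tidy.pd_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$explained),
    explained = x$explained,
    cum_explained = x$cum_explained
  )
}

#' @export
glance.pd_pca <- function(x, ...) {
  tibble::tibble(
    n_variables = length(x$variable_names),
    n_components = length(x$explained),
    pc1_explained = x$explained[1L],
    n_for_80pct = which(x$cum_explained >= 0.8)[1L]
  )
}

#' PCA of UPDRS items and motor metrics combined
#'
#' Column-concatenates the two standardized tables (subjects aligned by row
#' order, or by `subject_id` when both carry one) and runs [pca_curve()] on
#' the union.
#'
#' @param updrs_df,metrics_df Standardized tables with aligned subjects;
#'   either may be empty (zero columns), in which case the result equals
#'   the PCA of the other.
#' @return A `pd_pca` object.
#' @export
combined_pca <- function(updrs_df, metrics_df) {
  a <- numeric_part(tibble::as_tibble(updrs_df))
  b <- numeric_part(tibble::as_tibble(metrics_df))
  if (ncol(a) == 0L) return(pca_curve(b))
  if (ncol(b) == 0L) return(pca_curve(a))
  if (nrow(a) != nrow(b)) {
    rlang::abort("subject mismatch between the two tables",
                 class = "pdmotor_validation_error")
  }
  names(b) <- make.unique(c(names(a), names(b)))[-seq_along(a)]
  pca_curve(dplyr::bind_cols(a, b))
}

#' Plot a variance-explained curve
#'
#' @param object A `pd_pca` object (or a named list of them, plotted as one
#'   curve per set).
#' @param ... Unused.
#' @return A ggplot showing cumulative percentage of variance explained
#'   against the number of components retained.
#' @export
autoplot.pd_pca <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = 100 * .data$cum_explained)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "number of principal components retained",
                  y = "% of variability explained") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Variance-explained curves for several variable sets
#'
#' @param pcas Named list of `pd_pca` objects (e.g. UPDRS-only, metrics-only,
#'   combined).
#' @return A ggplot with one cumulative curve per set.
#' @export
plot_pca_curves <- function(pcas) {
  df <- dplyr::bind_rows(lapply(names(pcas), function(nm) {
    dplyr::mutate(tidy(pcas[[nm]]), set = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = 100 * .data$cum_explained,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "number of principal components retained",
                  y = "% of variability explained", colour = NULL) +
    ggplot2::theme_minimal()
}
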