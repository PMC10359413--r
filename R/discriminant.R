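#' Supervised linear discriminant analysis of FA profiles
#'
#' Canonical discriminant analysis with equal prior probabilities and the
#' pooled within-groups covariance matrix: discriminant functions are the
#' eigenvectors of `W^-1 B` (W pooled within-groups, B between-groups
#' scatter), samples are scored on each function, and classification
#' assigns each sample to the class with the nearest centroid in the
#' discriminant space (equivalent to minimal Mahalanobis distance under
#' the within-groups metric, with equal priors).
#'
#' When the variable count approaches or exceeds the sample count (as with
#' 40+ FA variables on 16 samples) the pooled covariance is singular; a
#' small ridge `lambda = ridge * trace(W) / p` is added to the diagonal by
#' default to make the analysis well defined and reportable. Each function
#' is oriented so that the alphabetically first class has a negative mean
#' score, making plots deterministic.
#'
#' @param data Profile tibble.
#' @param label Grouping metadata column (default `"diagnosis"`).
#' @param label2 Optional second grouping column (e.g. `"tissue"`); classes
#'   are then the crossed levels, as when synovium and fat-pad samples of
#'   both diagnoses enter one analysis.
#' @param variables Feature columns to use. Default `NULL` selects the raw
#'   (individual) FA columns when any label parses as a chain name,
#'   otherwise all variable columns.
#' @param ridge Ridge scale for the within-groups covariance (default
#'   `1e-6`); set to 0 to disable, in which case a singular covariance is
#'   an error naming the collinear variables.
#' @return An object of class `fa_lda` with eigenvalues, percent of
#'   between-group variance per function, per-sample scores, standardized
#'   and structure coefficients, and the resubstitution classification
#'   table. Methods: [tidy.fa_lda()], [glance.fa_lda()],
#'   [augment.fa_lda()], [autoplot.fa_lda()].
#' @export
fit_lda <- function(data, label = "diagnosis", label2 = NULL,
                    variables = NULL, ridge = 1e-6) {
  data <- tibble::as_tibble(data)
  if (is.null(variables)) {
    vars <- profile_variables(data)
    raw <- vars[variable_kind(vars) == "raw_fa"]
    variables <- if (length(raw)) raw else vars
  }
  X <- as.matrix(data[variables])
  cls <- as.character(data[[label]])
  if (!is.null(label2)) cls <- paste(cls, data[[label2]], sep = ".")
  cls <- factor(cls)
  g <- nlevels(cls)
  if (g < 2L) stop("need at least 2 classes", call. = FALSE)
  counts <- table(cls)
  if (any(counts < 2L)) {
    stop("every class needs at least 2 samples", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)

  means <- rowsum(X, cls) / as.vector(counts)
  grand <- colMeans(X)
  # pooled within-groups covariance
  Xc <- X - means[cls, , drop = FALSE]
  W <- crossprod(Xc) / (n - g)
  if (ridge > 0) {
    W <- W + diag(ridge * sum(diag(W)) / p, p)
  }
  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch)) {
    dg <- diag(W)
    stop("singular pooled within-groups covariance; near-constant or ",
         "collinear variable(s): ",
         paste(sQuote(variables[dg <= sort(dg)[min(3, p)]]), collapse = ", "),
         " (enable ridge regularization)", call. = FALSE)
  }
  # between-groups scatter
  Md <- sweep(means, 2, grand)
  B <- crossprod(Md * sqrt(as.vector(counts)))
  # generalized eigenproblem via whitening: W = R'R
  Rinv <- backsolve(ch, diag(p))
  A <- t(Rinv) %*% B %*% Rinv
  A <- (A + t(A)) / 2
  eig <- eigen(A, symmetric = TRUE)
  m <- min(g - 1L, p)
  evals <- pmax(eig$values[seq_len(m)], 0)
  Wdir <- Rinv %*% eig$vectors[, seq_len(m), drop = FALSE]  # w' W w = 1
  # sign convention: first class (alphabetical) scores negative on average
  centroids <- sweep(means, 2, grand) %*% Wdir
  flip <- ifelse(centroids[1L, ] > 0, -1, 1)
  Wdir <- sweep(Wdir, 2, flip, "*")
  centroids <- sweep(centroids, 2, flip, "*")
  scores <- sweep(X, 2, grand) %*% Wdir
  colnames(scores) <- colnames(Wdir) <- colnames(centroids) <-
    paste0("LD", seq_len(m))

  pct <- if (sum(evals) > 0) 100 * evals / sum(evals) else rep(0, m)
  predicted <- .lda_classify(scores, centroids)
  sds <- sqrt(diag(crossprod(Xc) / (n - g)))
  standardized <- Wdir * sds
  structure_coef <- stats::cor(X, scores)

  structure(
    list(
      eigenvalues = evals,
      pct_variance = pct,
      n_functions = m,
      directions = Wdir,
      centroids = centroids,
      grand_mean = grand,
      scores = scores,
      classes = levels(cls),
      class_of = cls,
      predicted = predicted,
      resubstitution = mean(predicted == cls),
      confusion = table(observed = cls, predicted = predicted),
      standardized = standardized,
      structure = structure_coef,
      variables = variables, label = label, label2 = label2,
      ridge = ridge, priors = rep(1 / g, g)
    ),
    class = "fa_lda"
  )
}

# nearest-centroid rule in the discriminant space (equal priors)
.lda_classify <- function(scores, centroids) {
  d2 <- outer(rowSums(scores^2), rowSums(centroids^2), "+") -
    2 * scores %*% t(centroids)
  factor(rownames(centroids)[max.col(-d2, ties.method = "first")],
         levels = rownames(centroids))
}

#' @export
print.fa_lda <- function(x, ...) {
  cat("Linear discriminant analysis (equal priors, within-groups covariance)\n")
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  %d discriminant function(s); %% of between-group variance: %s\n",
              x$n_functions,
              paste(sprintf("%.1f", x$pct_variance), collapse = ", ")))
  cat(sprintf("  resubstitution accuracy: %.3f\n", x$resubstitution))
  invisible(x)
}

#' @rdname fit_lda
#' @param x,object An `fa_lda` object.
#' @param ... Unused.
#' @method tidy fa_lda
#' @export
tidy.fa_lda <- function(x, ...) {
  purrr::map_dfr(seq_len(x$n_functions), function(j) {
    tibble::tibble(
      function_ = paste0("LD", j),
      variable = x$variables,
      coefficient = unname(x$directions[, j]),
      standardized = unname(x$standardized[, j]),
      structure = unname(x$structure[, j])
    )
  })
}

#' @rdname fit_lda
#' @method glance fa_lda
#' @export
glance.fa_lda <- function(x, ...) {
  tibble::tibble(
    n_functions = x$n_functions,
    pct_variance_1 = x$pct_variance[1L],
    pct_variance_12 = sum(x$pct_variance[seq_len(min(2L, x$n_functions))]),
    resubstitution_accuracy = x$resubstitution,
    n_classes = length(x$classes),
    n_variables = length(x$variables)
  )
}

#' @rdname fit_lda
#' @param data_ Unused (for generic compatibility).
#' @method augment fa_lda
#' @export
augment.fa_lda <- function(x, data_ = NULL, ...) {
  out <- tibble::as_tibble(x$scores)
  out$class <- x$class_of
  out$predicted <- x$predicted
  dplyr::relocate(out, "class", "predicted")
}

#' Leave-one-out classification accuracy of the discriminant analysis
#'
#' Refits the analysis without each sample in turn and classifies the
#' held-out sample with the refitted functions; returns the fraction of
#' correct diagnoses. This is the honest predictive counterpart of the
#' (optimistic) resubstitution accuracy.
#'
#' @inheritParams fit_lda
#' @return Fraction of correctly classified held-out samples.
#' @export
loo_accuracy <- function(data, label = "diagnosis", label2 = NULL,
                         variables = NULL, ridge = 1e-6) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  cls <- as.character(data[[label]])
  if (!is.null(label2)) cls <- paste(cls, data[[label2]], sep = ".")
  correct <- logical(n)
  for (i in seq_len(n)) {
    fit <- fit_lda(data[-i, , drop = FALSE], label = label, label2 = label2,
                   variables = variables, ridge = ridge)
    x <- as.matrix(data[i, fit$variables, drop = FALSE])
    sc <- sweep(x, 2, fit$grand_mean) %*% fit$directions
    pred <- .lda_classify(sc, fit$centroids)
    correct[i] <- as.character(pred) == cls[i]
  }
  mean(correct)
}

#' Scatter plot of discriminant scores
#'
#' Plots samples on discriminant functions 1-2 (or function 1 against a
#' jittered axis when only one function exists), colored by class.
#'
#' @param object An `fa_lda` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fa_lda
#' @export
autoplot.fa_lda <- function(object, ...) {
  df <- augment.fa_lda(object)
  if (object$n_functions >= 2L) {
    ggplot2::ggplot(df, ggplot2::aes(.data$LD1, .data$LD2,
                                     color = .data$class)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(
        x = sprintf("Function 1 (%.1f%%)", object$pct_variance[1L]),
        y = sprintf("Function 2 (%.1f%%)", object$pct_variance[2L]),
        color = NULL
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$LD1, .data$class,
                                     color = .data$class)) +
      ggplot2::geom_jitter(height = 0.1, width = 0, size = 2) +
      ggplot2::labs(x = "Function 1 (100%)", y = NULL, color = NULL) +
      ggplot2::theme_minimal()
  }
}
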