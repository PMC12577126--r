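# Elastic-net models of expression from the factor matrix. glmnet does
# the path fitting; the cross-validation loop lives here so that missing
# cells can be mean-imputed inside each training fold (no leakage), the
# alpha mixing parameter can be grid-searched, and fold assignment can be
# derived from gene identifiers (permuting row order never changes the
# fit).

# correlation that treats a constant prediction (null model) as 0
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

impute_train_means <- function(X, means = NULL) {
  if (is.null(means)) means <- colMeans(X, na.rm = TRUE)
  means[is.nan(means)] <- 0
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) X[na, j] <- means[j]
  }
  list(X = X, means = means)
}

fold_ids <- function(ids, nfolds, seed) {
  o <- order(ids)
  set.seed(derive_seed(seed, "folds"))
  f <- sample(rep_len(seq_len(nfolds), length(ids)))
  out <- integer(length(ids))
  out[o] <- f
  out
}

#' Fit an elastic net with cross-validated parameter selection
#'
#' Grid-searches the L1/L2 mixing parameter over \code{alpha_grid} and a
#' 100-point lambda path with \code{nfolds}-fold cross-validation.
#' Predictors are standardized; missing cells are mean-imputed using
#' training-fold means only. Fold membership derives from the row
#' identifiers, not row order.
#'
#' @param x Numeric matrix or the data.frame from
#'   \code{\link{build_factor_matrix}} (a \code{gene_id} column is used
#'   for fold derivation and dropped from the predictors).
#' @param y Response vector (e.g. log2 TPM, or allelic log2FC).
#' @param nfolds Cross-validation folds.
#' @param seed Seed for fold assignment.
#' @param alpha_grid Candidate mixing parameters.
#' @param nlambda Lambda path length.
#' @return Object of class \code{enet_fit}: selected \code{alpha},
#'   \code{lambda_min}, \code{lambda_1se}, coefficient vectors on the
#'   original and standardized scales, the CV curve at the selected
#'   alpha, \code{r_insample}, \code{r_cv}, and \code{n_obs}.
#' @export
fit_enet_cv <- function(x, y, nfolds = 5, seed = 1L,
                        alpha_grid = seq(0.1, 1, by = 0.1),
                        nlambda = 100) {
  if (is.data.frame(x)) {
    ids <- x$gene_id %||% rownames(x) %||% seq_len(nrow(x))
    x <- as.matrix(x[, setdiff(names(x), "gene_id"), drop = FALSE])
  } else {
    ids <- rownames(x) %||% seq_len(nrow(x))
    x <- as.matrix(x)
  }
  ok <- !is.na(y)
  x <- x[ok, , drop = FALSE]; y <- y[ok]; ids <- ids[ok]
  if (stats::sd(y) == 0) stop("constant response", call. = FALSE)
  all_na <- colSums(!is.na(x)) == 0
  if (any(all_na)) {
    warning("dropping all-NA column(s): ",
            paste(colnames(x)[all_na], collapse = ", "))
    x <- x[, !all_na, drop = FALSE]
  }
  if (nrow(x) < 10 * nfolds)
    stop("need at least ", 10 * nfolds, " rows for ", nfolds,
         "-fold cross-validation", call. = FALSE)
  foldid <- fold_ids(ids, nfolds, seed)

  full <- impute_train_means(x)
  best <- NULL
  for (alpha in alpha_grid) {
    path <- glmnet::glmnet(full$X, y, alpha = alpha, nlambda = nlambda,
                           standardize = TRUE)
    lambda <- path$lambda
    mse_fold <- matrix(NA_real_, nrow = nfolds, ncol = length(lambda))
    cv_pred <- rep(NA_real_, length(y))
    for (k in seq_len(nfolds)) {
      tr <- foldid != k
      imp <- impute_train_means(x[tr, , drop = FALSE])
      Xte <- impute_train_means(x[!tr, , drop = FALSE], imp$means)$X
      fit_k <- glmnet::glmnet(imp$X, y[tr], alpha = alpha,
                              lambda = lambda, standardize = TRUE)
      pred <- stats::predict(fit_k, Xte)
      mse_fold[k, seq_len(ncol(pred))] <-
        colMeans((pred - y[!tr])^2)
    }
    cvm <- colMeans(mse_fold, na.rm = TRUE)
    cvsd <- apply(mse_fold, 2, stats::sd, na.rm = TRUE) / sqrt(nfolds)
    i_min <- which.min(cvm)
    if (is.null(best) || cvm[i_min] < best$cvm[best$i_min]) {
      best <- list(alpha = alpha, lambda = lambda, cvm = cvm, cvsd = cvsd,
                   i_min = i_min, path = path)
    }
  }
  lambda <- best$lambda
  i_min <- best$i_min
  lambda_min <- lambda[i_min]
  in_band <- which(best$cvm <= best$cvm[i_min] + best$cvsd[i_min])
  lambda_1se <- max(lambda[in_band])

  # CV predictions at (alpha*, lambda_min) for r_cv
  cv_pred <- rep(NA_real_, length(y))
  for (k in seq_len(nfolds)) {
    tr <- foldid != k
    imp <- impute_train_means(x[tr, , drop = FALSE])
    Xte <- impute_train_means(x[!tr, , drop = FALSE], imp$means)$X
    fit_k <- glmnet::glmnet(imp$X, y[tr], alpha = best$alpha,
                            lambda = lambda, standardize = TRUE)
    cv_pred[!tr] <- stats::predict(fit_k, Xte, s = lambda_min)
  }

  coef_at <- function(s) {
    b <- as.matrix(stats::coef(best$path, s = s))
    stats::setNames(b[, 1], rownames(b))
  }
  beta_min <- coef_at(lambda_min)
  sds <- apply(full$X, 2, stats::sd)
  beta_std <- beta_min[-1] * sds
  pred_in <- as.vector(stats::predict(best$path, full$X, s = lambda_min))

  structure(list(
    alpha = best$alpha, lambda = lambda,
    lambda_min = lambda_min, lambda_1se = lambda_1se,
    cvm = best$cvm, cvsd = best$cvsd,
    coef = beta_min[-1], intercept = beta_min[1],
    coef_std = beta_std,
    r_insample = safe_cor(pred_in, y),
    r_cv = safe_cor(cv_pred, y),
    n_obs = length(y), nfolds = nfolds, seed = seed,
    x_means = full$means, x_sds = sds, y = y, glmnet_path = best$path,
    at_lambda = "lambda_min"),
    class = "enet_fit")
}

#' @export
print.enet_fit <- function(x, ...) {
  nz <- sum(x$coef != 0)
  cat(sprintf(
    "Elastic-net fit (%s): alpha = %.1f, lambda = %.4g\n",
    x$at_lambda, x$alpha,
    if (x$at_lambda == "lambda_min") x$lambda_min else x$lambda_1se))
  cat(sprintf("  %d of %d coefficients nonzero; R(in-sample) = %.3f, R(CV) = %.3f\n",
              nz, length(x$coef), x$r_insample, x$r_cv))
  invisible(x)
}

#' Reduce an elastic-net fit by the lambda-1SE rule
#'
#' Re-extracts coefficients at the largest lambda whose CV mean-squared
#' error is within one standard error of the minimum; the support can
#' only shrink.
#'
#' @param fit An \code{\link{fit_enet_cv}} object.
#' @return A new \code{enet_fit} at \code{lambda_1se}.
#' @export
reduce_1se <- function(fit) {
  stopifnot(inherits(fit, "enet_fit"))
  b <- as.matrix(stats::coef(fit$glmnet_path, s = fit$lambda_1se))
  beta <- stats::setNames(b[-1, 1], rownames(b)[-1])
  out <- fit
  out$coef <- beta
  out$intercept <- b[1, 1]
  out$coef_std <- beta * fit$x_sds[names(beta)]
  out$at_lambda <- "lambda_1se"
  out
}

#' Ranked coefficient report for an elastic-net fit
#'
#' Factors ordered by coefficient magnitude, annotated with the registry
#' grouping (data type, region, overall/allelic) for plotting, plus the
#' variance-explained summary.
#'
#' @param fit An \code{enet_fit}.
#' @param registry Optional \code{\link{factor_registry}} table for
#'   grouping columns.
#' @return Data.frame of nonzero coefficients sorted by |coefficient|;
#'   attributes \code{r_insample}, \code{r_cv}.
#' @export
enet_report <- function(fit, registry = factor_registry()) {
  stopifnot(inherits(fit, "enet_fit"))
  nz <- fit$coef[fit$coef != 0]
  out <- data.frame(factor = names(nz), coefficient = unname(nz),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$coefficient)), , drop = FALSE]
  i <- match(out$factor, registry$name)
  out$factor_type <- registry$factor_type[i]
  out$region <- registry$region[i]
  out$kind <- registry$kind[i]
  rownames(out) <- NULL
  attr(out, "r_insample") <- fit$r_insample
  attr(out, "r_cv") <- fit$r_cv
  out
}
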