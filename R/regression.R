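# Standardized linear models linking void descriptors to solvation targets:
# intercept-free fits on standardized data, exhaustive subset search,
# leave-one-out validation and leave-k-out error scaling.

#' Standardize feature columns
#'
#' Shifts each used column to zero mean and scales to unit standard
#' deviation.  The population convention (divide by n) is the default; the
#' transform parameters are returned for inverse mapping.
#'
#' @param table Data frame or matrix of numeric columns.
#' @param columns Columns to standardize (default all).
#' @param sd_type \code{"population"} (divide by n) or \code{"sample"}.
#' @return List with \code{data}, \code{center}, \code{scale},
#'   \code{sd_type}.
#' @export
standardize <- function(table, columns = NULL, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  tab <- as.data.frame(table)
  columns <- columns %||% names(tab)
  ctr <- scl <- stats::setNames(numeric(length(columns)), columns)
  for (cn in columns) {
    x <- tab[[cn]]
    if (!is.numeric(x)) stop("column ", cn, " is not numeric")
    m <- mean(x)
    s <- pop_sd(x, sd_type)
    if (s < 1e-12 * (1 + abs(m)))
      stop("degenerate (constant) column: ", cn)
    tab[[cn]] <- (x - m) / s
    ctr[cn] <- m
    scl[cn] <- s
  }
  list(data = tab, center = ctr, scale = scl, sd_type = sd_type)
}

pop_sd <- function(x, sd_type = "population") {
  n <- length(x)
  if (sd_type == "population") sqrt(sum((x - mean(x))^2) / n) else stats::sd(x)
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2}
#' with \eqn{\bar y} the mean of the actual values; negative values signal a
#' predictor worse than the mean.
#'
#' @param y Actual values (length >= 2, non-constant).
#' @param y_hat Predicted values.
#' @return Numeric scalar.
#' @export
r_squared <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("y and y_hat differ in length")
  if (length(y) < 2) stop("need at least two observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot < 1e-300) stop("constant y: R-squared undefined")
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Intercept-free least squares on standardized data
#'
#' Fits \eqn{y = \sum_j w_j X_j} by least squares (no intercept: both sides
#' are assumed centered by standardization).
#'
#' @param X Numeric matrix or data frame of standardized features.
#' @param y Standardized response.
#' @return List with \code{weights} (named), \code{r2}, \code{fitted}.
#' @export
fit_linear <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) stop("need n > p observations")
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    drop_ <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_, collapse = ", "))
  }
  w <- qr.coef(qr_, y)
  fitted <- drop(X %*% w)
  list(weights = stats::setNames(as.numeric(w), colnames(X)),
       r2 = r_squared(y, fitted), fitted = fitted)
}

# standardize-train / fit / predict-test on the original scale
fit_predict_fold <- function(X, y, train, test, sd_type = "population") {
  Xtr <- X[train, , drop = FALSE]
  mu <- colMeans(Xtr)
  sg <- apply(Xtr, 2, pop_sd, sd_type = sd_type)
  if (any(sg < 1e-12)) stop("constant feature inside a training fold")
  my <- mean(y[train]); sy <- pop_sd(y[train], sd_type)
  if (sy < 1e-300) stop("constant response inside a training fold")
  Ztr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
  ztr_y <- (y[train] - my) / sy
  qr_ <- qr(Ztr)
  if (qr_$rank < ncol(Ztr))
    stop("rank-deficient training fold (rows ",
         paste(utils::head(test, 3), collapse = ","), " held out)")
  w <- qr.coef(qr_, ztr_y)
  Zte <- sweep(sweep(X[test, , drop = FALSE], 2, mu), 2, sg, "/")
  drop(Zte %*% w) * sy + my
}

#' Leave-one-out cross-validation
#'
#' For each point: re-standardize within the training fold, fit the
#' intercept-free model, and predict the held-out point on the original
#' scale.  \code{mse_loo} is the mean of the per-point squared errors;
#' \code{r2_loo} applies the coefficient of determination to the LOO
#' predictions.
#'
#' @param X Feature matrix / data frame on the original scale.
#' @param y Response on the original scale.
#' @param sd_type Standardization convention (see \code{\link{standardize}}).
#' @param refit_standardization Re-estimate means and scales inside every
#'   fold (default TRUE); FALSE standardizes once globally.
#' @return List with \code{mse_loo}, \code{r2_loo}, \code{predictions}.
#' @export
loo_cv <- function(X, y, sd_type = "population", refit_standardization = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < ncol(X) + 3) stop("need n >= p + 3 for leave-one-out")
  pred <- numeric(n)
  if (refit_standardization) {
    for (k in seq_len(n))
      pred[k] <- fit_predict_fold(X, y, setdiff(seq_len(n), k), k, sd_type)
  } else {
    sx <- standardize(as.data.frame(X), sd_type = sd_type)
    my <- mean(y); sy <- pop_sd(y, sd_type)
    Z <- as.matrix(sx$data)
    zy <- (y - my) / sy
    for (k in seq_len(n)) {
      tr <- setdiff(seq_len(n), k)
      w <- qr.coef(qr(Z[tr, , drop = FALSE]), zy[tr])
      pred[k] <- drop(Z[k, , drop = FALSE] %*% w) * sy + my
    }
  }
  list(mse_loo = mean((y - pred)^2),
       r2_loo = r_squared(y, pred),
       predictions = pred)
}

#' Exhaustive best-subset linear model
#'
#' Evaluates every non-empty subset of the candidate features (at most 12)
#' and selects the winner by minimum leave-one-out mean squared error
#' (default) or maximum in-sample R-squared.  Ties break to fewer features,
#' then to lexicographic feature-name order.
#'
#' @param table Data frame holding features and target on the original scale.
#' @param target Name of the target column.
#' @param features Character vector of candidate feature columns.
#' @param criterion \code{"loo_mse"} or \code{"r2"}.
#' @param sd_type Standardization convention.
#' @return A \code{regression_result}: selected features, standardized
#'   weights, \code{r2}, \code{r2_loo}, \code{mse_loo}, LOO predictions.
#' @export
best_subset <- function(table, target, features,
                        criterion = c("loo_mse", "r2"),
                        sd_type = "population") {
  criterion <- match.arg(criterion)
  tab <- as.data.frame(table)
  stopifnot(target %in% names(tab), all(features %in% names(tab)))
  if (length(features) > 12)
    stop("exhaustive search is limited to 12 candidate features")
  if (anyNA(tab[, c(target, features)]))
    stop("missing values in used columns")
  if (criterion == "r2")
    warning("in-sample R-squared is monotone in feature count; ",
            "the full feature set always wins")
  y <- tab[[target]]
  n <- length(y)

  subsets <- unlist(lapply(seq_along(features), function(k)
    utils::combn(sort(features), k, simplify = FALSE)), recursive = FALSE)
  max_p <- if (criterion == "loo_mse") n - 3 else n - 1
  subsets <- Filter(function(s) length(s) <= max_p, subsets)
  if (length(subsets) == 0) stop("no admissible subset (n too small)")

  score <- vapply(subsets, function(s) {
    X <- as.matrix(tab[, s, drop = FALSE])
    out <- tryCatch({
      if (criterion == "loo_mse") loo_cv(X, y, sd_type)$mse_loo
      else -global_fit(tab, target, s, sd_type)$r2
    }, error = function(e) Inf)
    out
  }, numeric(1))

  sizes <- lengths(subsets)
  keys <- vapply(subsets, paste, "", collapse = ",")
  ord <- order(score, sizes, keys)
  best <- subsets[[ord[1]]]
  result_for_subset(tab, target, best, sd_type, criterion)
}

global_fit <- function(tab, target, features, sd_type) {
  sx <- standardize(tab[, c(features, target), drop = FALSE], sd_type = sd_type)
  fit_linear(as.matrix(sx$data[, features, drop = FALSE]), sx$data[[target]])
}

result_for_subset <- function(tab, target, features, sd_type, criterion) {
  fit <- global_fit(tab, target, features, sd_type)
  X <- as.matrix(tab[, features, drop = FALSE])
  y <- tab[[target]]
  loo <- if (nrow(X) >= ncol(X) + 3) loo_cv(X, y, sd_type) else
    list(mse_loo = NA_real_, r2_loo = NA_real_, predictions = rep(NA_real_, nrow(X)))
  structure(list(features = features,
                 weights = fit$weights,
                 intercept = 0,
                 r2 = fit$r2,
                 r2_loo = loo$r2_loo,
                 mse_loo = loo$mse_loo,
                 loo_predictions = loo$predictions,
                 criterion = criterion,
                 sd_type = sd_type,
                 target = target),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Best-subset linear model for '%s' (criterion %s)\n",
              x$target, x$criterion))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat("  standardized weights:\n")
  print(round(x$weights, 4))
  cat(sprintf("  R2 = %.4f   R2_LOO = %.4f   MSE_LOO = %.4g\n",
              x$r2, x$r2_loo, x$mse_loo))
  invisible(x)
}

#' Leave-k-out error-scaling diagnostic
#'
#' Root-mean prediction error over leave-\eqn{i}-out folds, for
#' \eqn{i = 1 \ldots k}, and the ratio
#' \eqn{(\mathrm{Error}_i \sqrt{N-i}) / (\mathrm{Error}_1 \sqrt{N-1})};
#' proximity to 1 validates the expected \eqn{1/\sqrt{N}} error scaling.
#' All folds are enumerated when there are at most \code{max_folds} of
#' them, otherwise \code{n_repeats} folds are sampled under \code{seed}.
#'
#' @param table Data frame with target and features (original scale).
#' @param target,features Column names.
#' @param k Largest number of points left out (1 to 3 typical).
#' @param n_repeats Folds sampled when enumeration is too large.
#' @param seed Integer seed for fold sampling.
#' @param max_folds Enumeration limit (default 2000).
#' @param sd_type Standardization convention.
#' @return Data frame with columns \code{k}, \code{error}, \code{ratio};
#'   attribute \code{"degenerate"} is TRUE when the baseline error is
#'   numerically zero (all ratios then 1 by convention).
#' @export
leave_k_out_ratio <- function(table, target, features, k = 3,
                              n_repeats = 200, seed = 1L, max_folds = 2000,
                              sd_type = "population") {
  tab <- as.data.frame(table)
  X <- as.matrix(tab[, features, drop = FALSE])
  y <- tab[[target]]
  n <- length(y)
  if (n <= ncol(X) + k + 1) stop("insufficient n for leave-", k, "-out")
  errs <- numeric(k)
  with_seed(seed, {
    for (i in seq_len(k)) {
      folds <- if (choose(n, i) <= max_folds) {
        utils::combn(n, i, simplify = FALSE)
      } else {
        lapply(seq_len(n_repeats), function(...) sort(sample.int(n, i)))
      }
      se <- vapply(folds, function(te) {
        pr <- fit_predict_fold(X, y, setdiff(seq_len(n), te), te, sd_type)
        mean((y[te] - pr)^2)
      }, numeric(1))
      errs[i] <- sqrt(mean(se))
    }
  })
  degenerate <- errs[1] < 1e-10
  ratio <- if (degenerate) rep(1, k)
           else errs * sqrt(n - seq_len(k)) / (errs[1] * sqrt(n - 1))
  out <- data.frame(k = seq_len(k), error = errs, ratio = ratio)
  attr(out, "degenerate") <- degenerate
  out
}

#' Predict void variables from chemical properties
#'
#' Runs the exhaustive best-subset search independently for each void
#' variable as target, with the chemical properties as candidate features;
#' reports the standardized coefficients per target.
#'
#' @param chem Data frame of chemical properties, rows keyed by entity name
#'   (rownames).
#' @param void_vars Data frame of void variables, same row entities.
#' @param criterion,sd_type Passed to \code{\link{best_subset}}.
#' @return List with \code{results} (one \code{regression_result} per void
#'   variable) and \code{coefficients} (targets x features matrix of
#'   standardized weights, 0 where a feature was not selected).
#' @export
fit_chemistry_to_void <- function(chem, void_vars,
                                  criterion = "loo_mse",
                                  sd_type = "population") {
  chem <- as.data.frame(chem)
  void_vars <- as.data.frame(void_vars)
  if (!identical(nrow(chem), nrow(void_vars)))
    stop("row mismatch between tables")
  if (!is.null(rownames(chem)) && !is.null(rownames(void_vars))) {
    if (!setequal(rownames(chem), rownames(void_vars)))
      stop("unmatched entities: ",
           paste(union(setdiff(rownames(chem), rownames(void_vars)),
                       setdiff(rownames(void_vars), rownames(chem))),
                 collapse = ", "))
    void_vars <- void_vars[rownames(chem), , drop = FALSE]
  }
  targets <- names(void_vars)
  features <- names(chem)
  results <- lapply(targets, function(tg) {
    tab <- cbind(chem, void_vars[, tg, drop = FALSE])
    best_subset(tab, tg, features, criterion = criterion, sd_type = sd_type)
  })
  names(results) <- targets
  coefs <- matrix(0, length(targets), length(features),
                  dimnames = list(targets, features))
  for (tg in targets)
    coefs[tg, results[[tg]]$features] <- results[[tg]]$weights
  list(results = results, coefficients = coefs)
}
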