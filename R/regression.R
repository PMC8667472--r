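#' The eight model feature columns, in canonical order
#' @export
lai_feature_names <- c("lpi", "h_mean", "h_std", "h_skew", "h_q3", "vci",
                       "hull_volume", "cap")

#' Join features with ground-reference effective LAI into a model dataset
#'
#' Drops records flagged missing or with any `NA` among the eight feature
#' columns or the target, keeping the dataset contract: no missing values,
#' fixed feature order, `lai_eff` target, `genotype` and `replicate` keys.
#'
#' @param features Feature table from [extract_study_features()].
#' @param reference A data frame with `region_id` and `lai_eff` columns
#'   (ground-reference effective LAI per plot).
#' @return A tibble with metadata, the eight features and `lai_eff`.
#' @export
assemble_dataset <- function(features, reference) {
  ds <- dplyr::inner_join(features, reference[c("region_id", "lai_eff")],
                          by = "region_id")
  keep <- stats::complete.cases(ds[c(lai_feature_names, "lai_eff")])
  if ("missing" %in% names(ds)) keep <- keep & !ds$missing
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " region(s) excluded for missing features")
  }
  tibble::as_tibble(ds[keep, , drop = FALSE])
}

#' Variety-level 75/25 train/test split
#'
#' Varieties (genotypes), not records, are randomly partitioned so that
#' both replicates of a variety always land on the same side of the split —
#' otherwise near-duplicate plots would leak between train and test.
#' `round(train_fraction * V)` varieties go to training (at least 1 on each
#' side). Deterministic given `seed`.
#'
#' @param ds Dataset from [assemble_dataset()] with a `genotype` column.
#' @param train_fraction Fraction of varieties assigned to training.
#' @param seed Integer seed controlling the assignment.
#' @return A list with tibbles `train` and `test` and the `train_varieties`.
#' @export
split_by_variety <- function(ds, train_fraction = 0.75, seed = 1) {
  varieties <- unique(ds$genotype)
  v <- length(varieties)
  if (v < 4) stop("need >= 4 distinct varieties to split", call. = FALSE)
  n_train <- min(v - 1L, max(1L, round(train_fraction * v)))
  train_v <- withr::with_seed(seed, sample(varieties, n_train))
  list(train = ds[ds$genotype %in% train_v, , drop = FALSE],
       test = ds[!ds$genotype %in% train_v, , drop = FALSE],
       train_varieties = train_v)
}

r_squared <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    warning("zero-variance target: R^2 reported as 0 by convention",
            call. = FALSE)
    return(0)
  }
  1 - sum((obs - pred)^2) / ss_tot
}

cv_fold_ids <- function(n, folds, seed) {
  folds <- min(folds, n)
  withr::with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
}

# pooled out-of-fold R^2: single R^2 over all held-out predictions, which is
# far more stable than averaging per-fold R^2 on ~n/10-record folds
cv_r2_pooled <- function(y, oof_pred) r_squared(y, oof_pred)

#' Stepwise multiple linear regression (SMLR)
#'
#' Bidirectional stepwise ordinary least squares on the raw feature scale:
#' forward steps add the candidate with the smallest partial-F p-value below
#' `alpha`; backward steps drop any retained predictor whose partial-F
#' p-value has risen to `alpha` or above; iteration stops at a fixed point.
#' If nothing is significant the intercept-only model is returned with a
#' warning.
#'
#' @param train Training dataset (features + `lai_eff`).
#' @param alpha Significance level for entry and removal (default 0.05).
#' @param features Candidate feature columns.
#' @return An object of class `lai_smlr` with the `lm` fit and the selected
#'   features.
#' @export
fit_smlr <- function(train, alpha = 0.05, features = lai_feature_names) {
  df <- as.data.frame(train[c(features, "lai_eff")])
  current <- character(0)
  fit <- stats::lm(lai_eff ~ 1, data = df)
  ss_tot <- sum((df$lai_eff - mean(df$lai_eff))^2)
  for (iter in seq_len(50)) {
    # partial-F tests are meaningless once the fit is numerically exact
    if (sum(stats::residuals(fit)^2) <= 1e-12 * ss_tot) break
    changed <- FALSE
    remaining <- setdiff(features, current)
    if (length(remaining) > 0) {
      # upper scope must contain the current terms as well as candidates
      scope <- stats::reformulate(c(current, remaining))
      a1 <- stats::add1(fit, scope = scope, test = "F")
      cand <- rownames(a1)[-1]
      pv <- a1[["Pr(>F)"]][-1]
      if (length(pv) > 0 && any(is.finite(pv)) &&
          min(pv, na.rm = TRUE) < alpha) {
        current <- c(current, cand[which.min(pv)])
        fit <- stats::lm(stats::reformulate(current, "lai_eff"), data = df)
        changed <- TRUE
      }
    }
    if (length(current) > 0 &&
        sum(stats::residuals(fit)^2) > 1e-12 * ss_tot) {
      d1 <- stats::drop1(fit, test = "F")
      pv <- d1[["Pr(>F)"]][-1]
      if (length(pv) > 0 && max(pv, na.rm = TRUE) >= alpha) {
        current <- setdiff(current, rownames(d1)[-1][which.max(pv)])
        fit <- if (length(current) == 0) {
          stats::lm(lai_eff ~ 1, data = df)
        } else {
          stats::lm(stats::reformulate(current, "lai_eff"), data = df)
        }
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(current) == 0) {
    warning("no feature significant at alpha = ", alpha,
            "; returning intercept-only model", call. = FALSE)
  }
  structure(list(family = "SMLR", fit = fit, selected = current,
                 features = features, alpha = alpha,
                 train_r2 = r_squared(df$lai_eff, stats::fitted(fit))),
            class = "lai_smlr")
}

#' @export
predict.lai_smlr <- function(object, newdata, ...) {
  unname(stats::predict(object$fit, newdata = as.data.frame(newdata)))
}

#' Partial least squares regression (PLSR)
#'
#' Standardized (z-scored on train) PLS regression; the number of latent
#' components is chosen to maximize the pooled 10-fold cross-validated R^2
#' on the training set, then the model is refit on the full training data.
#' At full rank (as many components as features) PLSR reproduces ordinary
#' least squares.
#'
#' @param train Training dataset.
#' @param max_components Largest component count searched (default 8).
#' @param folds CV folds (default 10).
#' @param seed Seed for the CV fold assignment.
#' @param features Feature columns used.
#' @param ncomp Optional fixed component count; skips the CV search.
#' @return An object of class `lai_plsr`.
#' @export
fit_plsr <- function(train, max_components = 8, folds = 10, seed = 1,
                     features = lai_feature_names, ncomp = NULL) {
  x <- as.matrix(train[features])
  y <- train$lai_eff
  n <- nrow(x)
  ncomp_max <- min(max_components, ncol(x), n - 2L)
  stopifnot(n >= ncomp_max + 1)
  if (is.null(ncomp)) {
    fold_id <- cv_fold_ids(n, folds, seed)
    oof <- matrix(NA_real_, n, ncomp_max)
    for (f in unique(fold_id)) {
      tr <- fold_id != f
      m <- mixOmics::pls(x[tr, , drop = FALSE], y[tr], ncomp = ncomp_max,
                         mode = "regression", scale = TRUE)
      pr <- stats::predict(m, x[!tr, , drop = FALSE])$predict
      oof[!tr, ] <- pr[, 1, seq_len(ncomp_max)]
    }
    cv_r2 <- vapply(seq_len(ncomp_max), function(k) {
      cv_r2_pooled(y, oof[, k])
    }, numeric(1))
    ncomp <- which.max(cv_r2)
  } else {
    stopifnot(ncomp >= 1, ncomp <= ncomp_max)
    cv_r2 <- rep(NA_real_, ncomp_max)
    cv_r2[ncomp] <- NA_real_
  }
  fit <- mixOmics::pls(x, y, ncomp = ncomp_max, mode = "regression",
                       scale = TRUE)
  structure(list(family = "PLSR", fit = fit, ncomp = ncomp,
                 cv_r2 = cv_r2[ncomp], cv_r2_by_ncomp = cv_r2,
                 features = features, seed = seed,
                 train_r2 = r_squared(
                   y, stats::predict(fit, x)$predict[, 1, ncomp])),
            class = "lai_plsr")
}

#' @export
predict.lai_plsr <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[object$features])
  unname(stats::predict(object$fit, x)$predict[, 1, object$ncomp])
}

#' Hyperparameter grid for support vector regression
#'
#' The documented search grid: cost `C` in \{0.1, 1, 10, 100\}, kernel
#' coefficient `gamma` in \{scale, 0.01, 0.1, 1\} (where `scale` = 1/p on
#' standardized inputs), `epsilon` in \{0.01, 0.1, 0.5\}, polynomial degree
#' in \{2, 3\}. Parameters irrelevant to a kernel are dropped from its grid.
#'
#' @param kernel One of `"rbf"`, `"linear"`, `"poly"`, `"sigmoid"`.
#' @param n_features Feature count, used for `gamma = "scale"`.
#' @return A data frame of hyperparameter combinations.
#' @export
svr_grid <- function(kernel = c("rbf", "linear", "poly", "sigmoid"),
                     n_features = length(lai_feature_names)) {
  kernel <- match.arg(kernel)
  cost <- c(0.1, 1, 10, 100)
  gamma <- c(1 / n_features, 0.01, 0.1, 1)
  epsilon <- c(0.01, 0.1, 0.5)
  if (kernel == "linear") {
    expand.grid(cost = cost, epsilon = epsilon,
                gamma = 1 / n_features, degree = 3)
  } else if (kernel == "poly") {
    expand.grid(cost = cost, gamma = gamma, epsilon = epsilon,
                degree = c(2, 3))
  } else {
    expand.grid(cost = cost, gamma = gamma, epsilon = epsilon, degree = 3)
  }
}

#' Support vector regression (SVR)
#'
#' Grid-searched epsilon-SVR with standardized inputs (z-scored on train,
#' the same scaling applied at prediction). Each grid point is scored by
#' pooled 10-fold CV R^2 on the training set; the best combination is refit
#' on the full training data.
#'
#' @param train Training dataset.
#' @param kernel `"rbf"` (default), `"linear"`, `"poly"` or `"sigmoid"`.
#' @param grid Hyperparameter grid; defaults to [svr_grid()] for the kernel.
#' @param folds CV folds (default 10).
#' @param seed Seed for the CV fold assignment.
#' @param features Feature columns used.
#' @return An object of class `lai_svr`.
#' @export
fit_svr <- function(train, kernel = c("rbf", "linear", "poly", "sigmoid"),
                    grid = NULL, folds = 10, seed = 1,
                    features = lai_feature_names) {
  kernel <- match.arg(kernel)
  if (is.null(grid)) grid <- svr_grid(kernel, n_features = length(features))
  e_kernel <- c(rbf = "radial", linear = "linear", poly = "polynomial",
                sigmoid = "sigmoid")[[kernel]]
  x <- as.matrix(train[features])
  y <- train$lai_eff
  n <- nrow(x)
  fold_id <- cv_fold_ids(n, folds, seed)
  if (min(table(fold_id)) < 2) stop("CV fold with < 2 records", call. = FALSE)
  if (stats::sd(y) == 0) {
    # degenerate training target: constant predictor, R^2 = 0 convention
    warning("zero-variance training target: fitting a constant predictor",
            call. = FALSE)
    return(structure(list(family = paste0("SVR-", kernel), kernel = kernel,
                          fit = NULL, constant = mean(y),
                          hyperparameters = grid[1, , drop = FALSE],
                          cv_r2 = 0, features = features, seed = seed,
                          train_r2 = 0),
                     class = "lai_svr"))
  }
  score <- suppressWarnings(vapply(seq_len(nrow(grid)), function(g) {
    oof <- rep(NA_real_, n)
    for (f in unique(fold_id)) {
      tr <- fold_id != f
      m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = e_kernel,
                      cost = grid$cost[g], gamma = grid$gamma[g],
                      epsilon = grid$epsilon[g], degree = grid$degree[g],
                      scale = TRUE)
      oof[!tr] <- stats::predict(m, x[!tr, , drop = FALSE])
    }
    cv_r2_pooled(y, oof)
  }, numeric(1)))
  best <- which.max(score)
  fit <- e1071::svm(x, y, kernel = e_kernel, cost = grid$cost[best],
                    gamma = grid$gamma[best], epsilon = grid$epsilon[best],
                    degree = grid$degree[best], scale = TRUE)
  structure(list(family = paste0("SVR-", kernel), kernel = kernel, fit = fit,
                 hyperparameters = grid[best, , drop = FALSE],
                 cv_r2 = score[best], features = features, seed = seed,
                 train_r2 = r_squared(y, stats::predict(fit, x))),
            class = "lai_svr")
}

#' @export
predict.lai_svr <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[object$features])
  if (is.null(object$fit)) return(rep(object$constant, nrow(x)))
  unname(stats::predict(object$fit, x))
}

#' Evaluate a fitted LAI model on held-out data
#'
#' Reports the coefficient of determination `R^2 = 1 - SS_res / SS_tot` and
#' the root mean squared error of the residuals on the test set. A
#' zero-variance test target makes R^2 undefined; it is reported as 0 with a
#' warning.
#'
#' @param model A fitted `lai_smlr`, `lai_plsr` or `lai_svr` object.
#' @param test Held-out dataset with the feature columns and `lai_eff`.
#' @return A one-row tibble: `family, r2, rmse, n_test`.
#' @export
evaluate_model <- function(model, test) {
  pred <- stats::predict(model, test)
  obs <- test$lai_eff
  tibble::tibble(family = model$family,
                 r2 = r_squared(obs, pred),
                 rmse = sqrt(mean((obs - pred)^2)),
                 n_test = length(obs))
}

#' Prediction table for a fitted model
#'
#' @param model Fitted model object.
#' @param data Dataset to predict.
#' @return Tibble `region_id, y_true, y_pred`.
#' @export
predictions_table <- function(model, data) {
  tibble::tibble(region_id = data$region_id, y_true = data$lai_eff,
                 y_pred = stats::predict(model, data))
}

# --- broom-style methods --------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy lai_smlr
#' @export
tidy.lai_smlr <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std.error = sm[, 2], statistic = sm[, 3],
                 p.value = sm[, 4])
}

#' @method glance lai_smlr
#' @export
glance.lai_smlr <- function(x, ...) {
  tibble::tibble(family = x$family,
                 n_selected = length(x$selected),
                 selected = paste(x$selected, collapse = "+"),
                 train_r2 = x$train_r2)
}

#' @method tidy lai_plsr
#' @export
tidy.lai_plsr <- function(x, ...) {
  w <- x$fit$loadings$X[, seq_len(x$ncomp), drop = FALSE]
  tibble::as_tibble(as.data.frame(w), rownames = "feature")
}

#' @method glance lai_plsr
#' @export
glance.lai_plsr <- function(x, ...) {
  tibble::tibble(family = x$family, ncomp = x$ncomp, cv_r2 = x$cv_r2,
                 train_r2 = x$train_r2)
}

#' @method tidy lai_svr
#' @export
tidy.lai_svr <- function(x, ...) {
  tibble::as_tibble(x$hyperparameters)
}

#' @method glance lai_svr
#' @export
glance.lai_svr <- function(x, ...) {
  tibble::tibble(family = x$family, cost = x$hyperparameters$cost,
                 gamma = x$hyperparameters$gamma,
                 epsilon = x$hyperparameters$epsilon,
                 degree = x$hyperparameters$degree,
                 cv_r2 = x$cv_r2, train_r2 = x$train_r2)
}

#' @export
print.lai_smlr <- function(x, ...) {
  cat("<SMLR> selected:", if (length(x$selected)) paste(x$selected,
                                                        collapse = ", ")
      else "(intercept only)",
      sprintf("| train R2 = %.3f\n", x$train_r2))
  invisible(x)
}

#' @export
print.lai_plsr <- function(x, ...) {
  cat(sprintf("<PLSR> %d component(s) | CV R2 = %.3f | train R2 = %.3f\n",
              x$ncomp, x$cv_r2, x$train_r2))
  invisible(x)
}

#' @export
print.lai_svr <- function(x, ...) {
  cat(sprintf("<%s> C=%g gamma=%g eps=%g | CV R2 = %.3f | train R2 = %.3f\n",
              x$family, x$hyperparameters$cost, x$hyperparameters$gamma,
              x$hyperparameters$epsilon, x$cv_r2, x$train_r2))
  invisible(x)
}
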