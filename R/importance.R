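#' Absolute Pearson correlation matrix of the model features
#'
#' Pairwise absolute Pearson correlations among the eight features
#' (optionally including the `lai_eff` target), displayed on a 0-1 scale.
#' Zero-variance columns have undefined correlations; these are reported as
#' 0 with a warning.
#'
#' @param ds Dataset from [assemble_dataset()] (>= 3 records).
#' @param include_target Also correlate the `lai_eff` column.
#' @param features Feature columns used.
#' @return A symmetric matrix with unit diagonal.
#' @export
correlation_matrix <- function(ds, include_target = FALSE,
                               features = lai_feature_names) {
  cols <- c(features, if (include_target) "lai_eff")
  x <- as.matrix(ds[cols])
  stopifnot(nrow(x) >= 3)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance column(s): ",
            paste(cols[sds == 0], collapse = ", "),
            "; correlations with them reported as 0", call. = FALSE)
  }
  r <- suppressWarnings(abs(stats::cor(x)))
  r[is.na(r)] <- 0
  diag(r) <- 1
  r
}

#' Leave-one-out weight of a feature
#'
#' The weight assigned to a removed feature given the reference model's
#' test R^2 with (`r2_original`) and without (`r2_new`) it:
#' `1 - r2_new / r2_original`. Positive when removal hurts the fit, 0 when
#' it changes nothing, negative when removal helps.
#'
#' @param r2_original Test R^2 of the full-feature model (> 0).
#' @param r2_new Test R^2 of the model refit without the feature.
#' @return The dimensionless weight (always <= 1).
#' @export
feature_weight <- function(r2_original, r2_new) {
  stopifnot(r2_original > 0)
  1 - r2_new / r2_original
}

# one fitted model of the requested family, used by the LOO refits
fit_lai_model <- function(train, family = c("svr", "smlr", "plsr"),
                          kernel = "rbf", grid = NULL, folds = 10, seed = 1,
                          features = lai_feature_names) {
  family <- match.arg(family)
  switch(family,
         svr = fit_svr(train, kernel = kernel, grid = grid, folds = folds,
                       seed = seed, features = features),
         smlr = fit_smlr(train, features = features),
         plsr = fit_plsr(train, max_components = length(features),
                         folds = folds, seed = seed, features = features))
}

#' Leave-one-out feature weights
#'
#' Quantifies each feature's contribution to a reference model (by default
#' SVR with the RBF kernel, the strongest family on these data) by refitting
#' the full protocol without the feature and comparing test R^2:
#' `weight = 1 - R2_new / R2_original`. The same variety-level split, CV
#' folds and hyperparameter grid are reused for every refit (seed-pinned)
#' so the weights reflect the removal of the feature and nothing else.
#' Weights never exceed 1; a weight of 0 means removal left the fit
#' unchanged, and negative weights (removal improved the fit) are possible
#' and reported as-is.
#'
#' @param ds Dataset from [assemble_dataset()].
#' @param family,kernel Reference model family (see [fit_svr()] etc.).
#' @param seed Seed pinning the split and CV folds.
#' @param train_fraction Variety fraction assigned to training.
#' @param grid Optional SVR hyperparameter grid passed to every fit.
#' @param folds CV folds for model selection.
#' @param features Feature columns considered.
#' @return A `lai_feature_weights` tibble (`feature, r2_new, weight`,
#'   sorted by decreasing weight) with attributes `r2_original` and
#'   `family`.
#' @export
loo_feature_weights <- function(ds, family = "svr", kernel = "rbf", seed = 1,
                                train_fraction = 0.75, grid = NULL,
                                folds = 10, features = lai_feature_names) {
  split <- split_by_variety(ds, train_fraction = train_fraction, seed = seed)
  base <- fit_lai_model(split$train, family = family, kernel = kernel,
                        grid = grid, folds = folds, seed = seed,
                        features = features)
  r2_original <- evaluate_model(base, split$test)$r2
  if (r2_original <= 0) {
    stop("baseline uninformative: R^2_original <= 0", call. = FALSE)
  }
  out <- purrr::map_dfr(features, function(f) {
    kept <- setdiff(features, f)
    m <- fit_lai_model(split$train, family = family, kernel = kernel,
                       grid = grid, folds = folds, seed = seed,
                       features = kept)
    r2_new <- evaluate_model(m, split$test)$r2
    tibble::tibble(feature = f, r2_new = r2_new,
                   weight = feature_weight(r2_original, r2_new))
  })
  out <- out[order(-out$weight), ]
  attr(out, "r2_original") <- r2_original
  attr(out, "family") <- base$family
  class(out) <- c("lai_feature_weights", class(out))
  out
}
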