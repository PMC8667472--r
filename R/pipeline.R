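#' Run the full LAI estimation pipeline on a study bundle
#'
#' Convenience wrapper chaining every stage: DTM from the bare-earth epoch,
#' height normalization and region clipping, the eight-feature extraction,
#' dataset assembly against the ground-reference table, the variety-level
#' 75/25 split, model fitting for the requested families, and held-out
#' evaluation.
#'
#' @param bundle A study bundle as returned by [generate_study()], or any
#'   list with `bare_earth`, `canopy`, `regions` and a `truth`/`reference`
#'   table carrying `region_id` and `lai_eff`.
#' @param config Feature settings from [feature_config()].
#' @param families Character vector among `"smlr"`, `"plsr"`, `"svr"`.
#' @param kernel SVR kernel.
#' @param cell_size DTM cell size (m).
#' @param seed Seed pinning the split and CV folds.
#' @param train_fraction Variety fraction assigned to training.
#' @param svr_grid Optional SVR grid override.
#' @return A list: `features`, `dataset`, `split`, `models` (named list of
#'   fitted objects), and `metrics` (tibble of per-family test R^2/RMSE).
#' @export
run_lai_pipeline <- function(bundle, config = feature_config(),
                             families = c("smlr", "plsr", "svr"),
                             kernel = "rbf", cell_size = 0.25, seed = 1,
                             train_fraction = 0.75, svr_grid = NULL) {
  reference <- bundle$truth %||% bundle$reference
  dtm <- build_dtm(bundle$bare_earth, cell_size = cell_size)
  features <- extract_study_features(bundle$canopy, dtm, bundle$regions,
                                     config)
  dataset <- assemble_dataset(features, reference)
  split <- split_by_variety(dataset, train_fraction = train_fraction,
                            seed = seed)
  models <- list()
  for (fam in families) {
    models[[fam]] <- fit_lai_model(split$train, family = fam,
                                   kernel = kernel, grid = svr_grid,
                                   seed = seed)
  }
  metrics <- purrr::map_dfr(models, evaluate_model, test = split$test)
  list(features = features, dataset = dataset, split = split,
       models = models, metrics = metrics)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
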