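#' Bundle feature vectors with concentrations and replicate groups
#'
#' @param features `n x 51` matrix or data.frame with the
#'   [feature_names()] columns.
#' @param concentrations concentrations in mM (> 0), length `n`.
#' @param groups replicate identifiers (length `n`); images of the same
#'   physical replicate share a group and are never split across
#'   train/test.
#' @param split optional factor/character of `"train"`/`"test"`
#'   assignments overriding the seeded grouped split.
#' @return Object of class `assay_dataset`.
#' @export
assay_dataset <- function(features, concentrations, groups = NULL, split = NULL) {
  x <- as.matrix(features)
  if (!all(feature_names() %in% colnames(x))) {
    missing <- setdiff(feature_names(), colnames(x))
    stop(sprintf("feature schema mismatch; missing: %s",
                 paste(utils::head(missing, 3), collapse = ", ")), call. = FALSE)
  }
  x <- x[, feature_names(), drop = FALSE]
  if (nrow(x) != length(concentrations)) stop("row counts disagree", call. = FALSE)
  if (any(concentrations <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (any(!is.finite(x))) stop("features must be finite", call. = FALSE)
  if (is.null(groups)) groups <- seq_len(nrow(x))
  if (length(groups) != nrow(x)) stop("groups length mismatch", call. = FALSE)
  structure(list(features = x, concentrations = as.numeric(concentrations),
                 groups = as.character(groups), split = split),
            class = "assay_dataset")
}

default_svr_grid <- function() {
  list(cost = c(0.1, 1, 10, 100), epsilon = c(0.01, 0.1),
       gamma_mult = c(0.5, 1, 2))
}

# grouped assignment of groups to folds, seeded and deterministic
make_group_folds <- function(groups, k, seed) {
  ug <- unique(groups)
  if (k > length(ug)) {
    stop(sprintf("cv_folds (%d) exceeds the number of groups (%d)",
                 k, length(ug)), call. = FALSE)
  }
  withr::with_seed(seed, {
    perm <- sample(ug)
  })
  fold_of <- stats::setNames(rep_len(seq_len(k), length(ug)), perm)
  unname(fold_of[groups])
}

#' Train the SVM concentration predictor
#'
#' Epsilon support vector regression of `log10(concentration)` on the
#' standardized 51-feature vectors; the log target lets one model span
#' both the millimolar and the molar assay range.  Features are
#' standardized with training-split statistics only; hyperparameters are
#' chosen by grouped cross-validated grid search; performance is reported
#' on the held-out split, which never shares a replicate group with
#' training.
#'
#' @param data an [assay_dataset()].
#' @param kernel `"rbf"` (default), `"linear"` or `"polynomial"`.
#' @param cv_folds folds of the grouped grid-search cross-validation
#'   (must not exceed the number of training groups).
#' @param seed seed controlling the split and fold assignment.
#' @param train_fraction fraction of replicate groups assigned to
#'   training when `data$split` is not given.
#' @param grid hyperparameter grid; see `default_svr_grid()` for the
#'   shape.  `gamma_mult` scales the `1/p` heuristic and is ignored by
#'   the linear kernel.
#' @return Object of class `glucose_svr` holding the fitted model,
#'   standardization parameters, the feature schema and a `report` with
#'   held-out `r_squared`, per-sample `(actual, predicted)` mM pairs and
#'   the selected hyperparameters.
#' @export
train_predictor <- function(data, kernel = c("rbf", "linear", "polynomial"),
                            cv_folds = 2L, seed = 1L, train_fraction = 0.7,
                            grid = default_svr_grid()) {
  stopifnot(inherits(data, "assay_dataset"))
  kernel <- match.arg(kernel)
  x <- data$features
  y <- log10(data$concentrations)
  if (length(unique(data$concentrations)) < 2L) {
    stop("need at least 2 distinct concentrations", call. = FALSE)
  }

  if (!is.null(data$split)) {
    in_train <- data$split == "train"
  } else {
    ug <- unique(data$groups)
    n_train <- max(1L, round(train_fraction * length(ug)))
    if (n_train == length(ug)) n_train <- length(ug) - 1L
    withr::with_seed(seed, {
      train_groups <- sample(ug, n_train)
    })
    in_train <- data$groups %in% train_groups
  }
  if (!any(in_train) || all(in_train)) stop("degenerate train/test split", call. = FALSE)

  # standardization from the training split only (no leakage)
  centers <- colMeans(x[in_train, , drop = FALSE])
  scales <- apply(x[in_train, , drop = FALSE], 2, stats::sd)
  scales[!is.finite(scales) | scales < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, centers), 2, scales, "/")

  xtr <- xs[in_train, , drop = FALSE]; ytr <- y[in_train]
  gamma_base <- 1 / ncol(x)
  gammas <- if (kernel == "linear") gamma_base else gamma_base * grid$gamma_mult
  combos <- expand.grid(cost = grid$cost, epsilon = grid$epsilon,
                        gamma = unique(gammas), KEEP.OUT.ATTRS = FALSE)

  folds <- make_group_folds(data$groups[in_train], cv_folds, derive_seed(seed, 97L))
  cv_mse <- vapply(seq_len(nrow(combos)), function(ci) {
    errs <- vapply(seq_len(cv_folds), function(k) {
      tr <- folds != k
      if (!any(tr) || all(tr)) return(NA_real_)
      m <- e1071::svm(xtr[tr, , drop = FALSE], ytr[tr], type = "eps-regression",
                      kernel = if (kernel == "rbf") "radial" else kernel,
                      cost = combos$cost[ci], epsilon = combos$epsilon[ci],
                      gamma = combos$gamma[ci], scale = FALSE)
      mean((stats::predict(m, xtr[!tr, , drop = FALSE]) - ytr[!tr])^2)
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  best <- combos[which.min(cv_mse), ]

  model <- e1071::svm(xtr, ytr, type = "eps-regression",
                      kernel = if (kernel == "rbf") "radial" else kernel,
                      cost = best$cost, epsilon = best$epsilon,
                      gamma = best$gamma, scale = FALSE)

  xte <- xs[!in_train, , drop = FALSE]; yte <- y[!in_train]
  pred_te <- stats::predict(model, xte)
  ss_res <- sum((yte - pred_te)^2)
  ss_tot <- sum((yte - mean(yte))^2)
  r2 <- if (ss_tot < 1e-12) 0 else 1 - ss_res / ss_tot

  obj <- structure(list(
    model = model, kernel = kernel, centers = centers, scales = scales,
    feature_names = feature_names(), train_index = which(in_train),
    train_conc_range = range(data$concentrations[in_train]),
    train_residual_sd = stats::sd(stats::predict(model, xtr) - ytr),
    report = list(
      r_squared = r2,
      pairs = data.frame(actual_mM = 10^yte, predicted_mM = 10^as.numeric(pred_te)),
      hyperparameters = as.list(best),
      n_train = sum(in_train), n_test = sum(!in_train))),
    class = "glucose_svr")
  obj
}

#' @export
print.glucose_svr <- function(x, ...) {
  hp <- x$report$hyperparameters
  cat(sprintf("SVR (%s kernel): cost %g, epsilon %g, gamma %g\n",
              x$kernel, hp$cost, hp$epsilon, hp$gamma))
  cat(sprintf("Held-out R^2 = %.3f  (train n = %d, test n = %d)\n",
              x$report$r_squared, x$report$n_train, x$report$n_test))
  invisible(x)
}

#' Predict concentrations for new feature vectors
#'
#' @param model a [train_predictor()] result.
#' @param features one feature vector (named, length 51), or an
#'   `n x 51` matrix/data.frame with the schema columns in any order.
#' @return Concentrations in mM, with attribute `"extrapolated"` marking
#'   predictions outside the training concentration range.
#' @export
predict_concentration <- function(model, features) {
  stopifnot(inherits(model, "glucose_svr"))
  x <- if (is.null(dim(features))) matrix(features, nrow = 1,
                                          dimnames = list(NULL, names(features)))
       else as.matrix(features)
  if (is.null(colnames(x)) || !all(model$feature_names %in% colnames(x)) ||
      ncol(x) != length(model$feature_names)) {
    stop(sprintf("feature schema mismatch: expected the %d named features of this model",
                 length(model$feature_names)), call. = FALSE)
  }
  x <- x[, model$feature_names, drop = FALSE]  # order-invariant by name
  xs <- sweep(sweep(x, 2, model$centers), 2, model$scales, "/")
  conc <- 10^as.numeric(stats::predict(model$model, xs))
  attr(conc, "extrapolated") <- conc < model$train_conc_range[1] |
    conc > model$train_conc_range[2]
  conc
}
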