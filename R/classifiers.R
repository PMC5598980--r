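#' Classifier specifications
#'
#' The six benchmarked classifiers with their fixed parameters and default
#' tuning grids. Tuned parameters are selected per outer fold by an inner
#' stratified 10-fold CV; the random forest needs no tuning (500 trees,
#' `floor(sqrt(p))` candidate variables per split) and the boosted model
#' always subsamples 50% of the observations per tree.
#'
#' @param name one of `"svm_lin"`, `"svm_rbf"`, `"knn"`, `"ct"`, `"gbm"`,
#'   `"rf"`.
#' @param tuning_grid optional named list of candidate values overriding the
#'   default grid (empty list disables tuning).
#' @return An object of class `ims_classifier`.
#' @export
classifier_spec <- function(name = c("rf", "svm_lin", "svm_rbf", "knn", "ct", "gbm"),
                            tuning_grid = NULL) {
  name <- match.arg(name)
  default_grid <- switch(name,
    svm_lin = list(cost = c(0.1, 1, 10, 100)),
    svm_rbf = list(cost = c(0.1, 1, 10, 100), gamma_scale = c(0.1, 1, 10)),
    knn = list(k = c(1, 3, 5, 7, 9, 15)),
    ct = list(cp = c(0.001, 0.01, 0.1)),
    gbm = list(nrounds = c(50, 100, 500), max_depth = 1:3, eta = c(0.01, 0.1)),
    rf = list())
  structure(list(name = name,
                 tuning_grid = if (is.null(tuning_grid)) default_grid
                               else tuning_grid),
            class = "ims_classifier")
}

grid_rows <- function(grid) {
  if (!length(grid)) return(list(list()))
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

# center/scale columns by training statistics (zero-variance columns pass
# through); distance-based classifiers need this
standardize_pair <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sd <- apply(Xtr, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(tr = sweep(sweep(Xtr, 2, mu), 2, sd, `/`),
       te = sweep(sweep(Xte, 2, mu), 2, sd, `/`))
}

# fit one classifier on (Xtr, ytr) and return case-class scores for Xte;
# y is a factor with levels c("control", "case")
fit_score <- function(name, params, Xtr, ytr, Xte) {
  p <- ncol(Xtr)
  switch(name,
    svm_lin = ,
    svm_rbf = {
      s <- standardize_pair(Xtr, Xte)
      gamma <- if (name == "svm_rbf") (params$gamma_scale %||% 1) / p else 1 / p
      fit <- e1071::svm(s$tr, ytr, kernel = if (name == "svm_lin") "linear" else "radial",
                        cost = params$cost %||% 1, gamma = gamma, scale = FALSE)
      pred <- stats::predict(fit, s$te, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      # orient the decision value toward the case class
      pair <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
      if (pair[1] == "case") as.numeric(dv[, 1]) else -as.numeric(dv[, 1])
    },
    knn = {
      s <- standardize_pair(Xtr, Xte)
      k <- min(params$k %||% 5, nrow(s$tr))
      pred <- class::knn(s$tr, s$te, ytr, k = k, prob = TRUE)
      pr <- attr(pred, "prob")
      ifelse(pred == "case", pr, 1 - pr)
    },
    ct = {
      df <- data.frame(.y = ytr, Xtr, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., df, method = "class",
                          control = rpart::rpart.control(cp = params$cp %||% 0.01))
      stats::predict(fit, data.frame(Xte, check.names = FALSE),
                     type = "prob")[, "case"]
    },
    gbm = {
      fit <- xgboost::xgboost(
        Xtr, ytr, objective = "binary:logistic",
        nrounds = params$nrounds %||% 100,
        max_depth = params$max_depth %||% 2,
        learning_rate = params$eta %||% 0.1,
        subsample = 0.5, nthreads = 1, verbosity = 0)
      # probability of the second factor level, i.e. the case class
      stats::predict(fit, Xte, type = "response")
    },
    rf = {
      fit <- randomForest::randomForest(Xtr, ytr, ntree = 500,
                                        mtry = max(1, floor(sqrt(p))))
      stats::predict(fit, Xte, type = "prob")[, "case"]
    },
    stop(sprintf("unknown classifier '%s'", name), call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
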