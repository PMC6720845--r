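# The domain-domain interaction classifier: an RBF-kernel C-SVC over the
# 20-dimensional normalized pair vectors, with libsvm-style grid search and
# repeated stratified 5-fold cross-validation.

#' SVM configuration for the DDI classifier
#'
#' Defaults are the published optimum `c = 9.1896`, `g = 3.0314` (the RBF
#' `g` is the gamma of `exp(-g * ||u - v||^2)`, the libsvm convention).
#'
#' @param c cost parameter, > 0
#' @param g RBF kernel width, > 0
#' @param seed integer seed controlling fold shuffles
#' @param n_folds folds per cross-validation repeat (>= 2)
#' @param n_repeats minimum number of CV repeats (>= 1); repeats continue up
#'   to `max_repeats` until the standard deviation of the repeat accuracies
#'   drops below `stability_sd` percentage points
#' @param max_repeats upper bound on repeats
#' @param stability_sd stability criterion in accuracy percentage points
#' @return object of class `svm_config`
#' @export
svm_config <- function(c = 9.1896, g = 3.0314, seed = 42L, n_folds = 5L,
                       n_repeats = 5L, max_repeats = 20L, stability_sd = 0.5) {
  stopifnot(c > 0, g > 0, n_folds >= 2L, n_repeats >= 1L,
            max_repeats >= n_repeats)
  structure(list(c = c, g = g, seed = as.integer(seed),
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 max_repeats = as.integer(max_repeats),
                 stability_sd = stability_sd),
            class = "svm_config")
}

.check_vectors <- function(vectors, labels = NULL) {
  vectors <- as.matrix(vectors)
  if (!all(is.finite(vectors))) stop("feature matrix contains NaN/Inf")
  if (!is.null(labels)) {
    if (length(labels) != nrow(vectors)) stop("label length mismatch")
    if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
    if (length(unique(labels)) < 2L)
      stop("both classes must be present")
  }
  vectors
}

#' Train the DDI SVM
#'
#' External labels use the {1, 0} convention; they are mapped to {+1, -1}
#' internally for the solver. Training is deterministic (SMO has no random
#' component; `seed` only matters for cross-validation).
#'
#' @param vectors n x 20 matrix of normalized pair vectors
#' @param labels integer vector in {0, 1}
#' @param config an [svm_config()]
#' @return object of class `ddi_model` supporting [predict_pairs()] and
#'   [decision_values()]
#' @export
ddi_train <- function(vectors, labels, config = svm_config()) {
  vectors <- .check_vectors(vectors, labels)
  y <- ifelse(labels == 1L, 1L, -1L)
  fit <- svc_train_cpp(vectors, as.integer(y), config$c, config$g)
  structure(list(sv = fit$sv, coef = as.numeric(fit$coef), rho = fit$rho,
                 c = config$c, g = config$g, seed = config$seed,
                 n_sv = fit$n_sv,
                 iterations = fit$iterations, dim = ncol(vectors),
                 feature_names = colnames(vectors)),
            class = "ddi_model")
}

#' @export
print.ddi_model <- function(x, ...) {
  cat(sprintf("<ddi_model: RBF C-SVC, c=%.4f g=%.4f, %d SVs, dim %d>\n",
              x$c, x$g, x$n_sv, x$dim))
  invisible(x)
}

#' SVM decision values for a set of pair vectors
#' @param model a `ddi_model`
#' @param vectors matrix with the model's feature dimension
#' @return numeric decision values (positive = interacting side)
#' @export
decision_values <- function(model, vectors) {
  stopifnot(inherits(model, "ddi_model"))
  vectors <- .check_vectors(vectors)
  if (nrow(vectors) == 0L) return(numeric(0L))
  if (ncol(vectors) != model$dim)
    stop("expected ", model$dim, " features, got ", ncol(vectors))
  rbf_decision_cpp(model$sv, model$coef, model$rho, model$g, vectors)
}

#' Hard labels for a set of pair vectors
#' @inheritParams decision_values
#' @return integer labels in {0, 1}, order-preserving
#' @export
predict_pairs <- function(model, vectors) {
  as.integer(decision_values(model, vectors) > 0)
}

# stratified fold assignment: within each class, a shuffled round-robin, so
# each fold's class ratio is within one sample of the global ratio
.stratified_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < n_folds)
      stop("class ", cl, " has fewer samples (", length(idx),
           ") than folds (", n_folds, ")")
    folds[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

# one CV repeat: pooled out-of-fold hard labels and decision values; with
# refit_normalizer the min-max normalizer is fitted on each training fold
# only (no leakage of evaluation ranges)
.cv_once <- function(vectors, labels, config, refit_normalizer = FALSE) {
  folds <- .stratified_folds(labels, config$n_folds)
  pred <- integer(length(labels))
  dec <- numeric(length(labels))
  for (f in seq_len(config$n_folds)) {
    test <- folds == f
    xtr <- vectors[!test, , drop = FALSE]
    xte <- vectors[test, , drop = FALSE]
    if (refit_normalizer) {
      nz <- suppressWarnings(fit_normalizer(xtr))
      xtr <- apply_normalizer(nz, xtr)
      xte <- apply_normalizer(nz, xte)
    }
    model <- ddi_train(xtr, labels[!test], config)
    dv <- decision_values(model, xte)
    dec[test] <- dv
    pred[test] <- as.integer(dv > 0)
  }
  list(pred = pred, dec = dec)
}

#' Repeated stratified cross-validation of the DDI SVM
#'
#' Each repeat reshuffles the stratified fold assignment, pools the
#' out-of-fold predictions into one confusion matrix, and derives the full
#' metric set. At least `n_repeats` repeats are run; repeats continue (up to
#' `max_repeats`) until the standard deviation of the repeat accuracies is
#' below `stability_sd` percentage points.
#'
#' @inheritParams ddi_train
#' @param refit_normalizer if `TRUE`, `vectors` are raw (unnormalized) pair
#'   vectors and a min-max normalizer is refitted on each training fold — the
#'   leakage-free protocol
#' @return object of class `cv_report`: list with `repeats` (data frame, one
#'   row per repeat: TP/TN/FP/FN and all metrics), `mean`, `max`, `auc`
#'   (pooled out-of-fold decision-value AUC of the first repeat), `config`
#' @export
cross_validate <- function(vectors, labels, config = svm_config(),
                           refit_normalizer = FALSE) {
  vectors <- .check_vectors(vectors, labels)
  labels <- as.integer(labels)
  set.seed(config$seed)
  rows <- list()
  auc <- NA_real_
  repeat {
    r <- length(rows) + 1L
    cv <- .cv_once(vectors, labels, config, refit_normalizer)
    cc <- confusion_counts(truth = labels, predicted = cv$pred)
    met <- compute_metrics(cc)
    if (r == 1L) auc <- roc_auc(cv$dec, labels)$auc
    rows[[r]] <- data.frame(repeat_id = r, tp = cc$tp, tn = cc$tn,
                            fp = cc$fp, fn = cc$fn,
                            acc = met$acc, sn = met$sn, spe = met$spe,
                            pre = met$pre, f1 = met$f1, mcc = met$mcc)
    if (r >= config$n_repeats &&
        (r >= config$max_repeats ||
         stats::sd(vapply(rows, function(x) x$acc, numeric(1))) <
           config$stability_sd)) break
  }
  rep_df <- do.call(rbind, rows)
  metric_cols <- c("acc", "sn", "spe", "pre", "f1", "mcc")
  structure(list(repeats = rep_df,
                 mean = colMeans(rep_df[metric_cols]),
                 max = apply(rep_df[metric_cols], 2L, max),
                 auc = auc, config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d repeats of %d-fold CV>\n",
              nrow(x$repeats), x$config$n_folds))
  print(round(x$repeats[, -1], 2))
  cat("mean:", paste(sprintf("%s=%.2f", names(x$mean), x$mean),
                     collapse = " "), "\n")
  invisible(x)
}

#' Grid search for the SVM hyperparameters
#'
#' Evaluates every `(c, g)` grid point by `n_folds`-fold cross-validated
#' accuracy (single repeat per point, shared fold assignment so points are
#' comparable) and returns the maximizer; ties go to smaller `c`, then
#' smaller `g`. The default grids are the customary libsvm lattice
#' `c = 2^(-5..15)`, `g = 2^(-15..3)`.
#'
#' @inheritParams ddi_train
#' @param c_grid,g_grid candidate values (duplicates are ignored)
#' @return list with `c`, `g`, and the per-point `table` (c, g, accuracy)
#' @export
grid_search <- function(vectors, labels,
                        c_grid = 2^seq(-5, 15, by = 2),
                        g_grid = 2^seq(-15, 3, by = 2),
                        config = svm_config()) {
  vectors <- .check_vectors(vectors, labels)
  labels <- as.integer(labels)
  if (!length(c_grid) || !length(g_grid)) stop("empty grid")
  c_grid <- sort(unique(c_grid)); g_grid <- sort(unique(g_grid))
  set.seed(config$seed)
  folds <- .stratified_folds(labels, config$n_folds)
  grid <- expand.grid(c = c_grid, g = g_grid)
  acc <- vapply(seq_len(nrow(grid)), function(k) {
    cfg <- svm_config(c = grid$c[k], g = grid$g[k], seed = config$seed,
                      n_folds = config$n_folds, n_repeats = 1L,
                      max_repeats = 1L)
    pred <- integer(length(labels))
    for (f in seq_len(cfg$n_folds)) {
      test <- folds == f
      m <- ddi_train(vectors[!test, , drop = FALSE], labels[!test], cfg)
      pred[test] <- predict_pairs(m, vectors[test, , drop = FALSE])
    }
    100 * mean(pred == labels)
  }, numeric(1))
  # maximize accuracy; ties -> smaller c, then smaller g
  ord <- order(-acc, grid$c, grid$g)
  best <- ord[1L]
  list(c = grid$c[best], g = grid$g[best],
       table = cbind(grid, accuracy = acc))
}

#' Save a DDI model (with its normalizer) as a self-describing text file
#'
#' @param model a `ddi_model`
#' @param params the `minmax_normalizer` used for its inputs (optional)
#' @param path output file
#' @export
write_ddi_model <- function(model, path, params = NULL) {
  stopifnot(inherits(model, "ddi_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# domppi ddi_model v1",
               sprintf("c\t%.17g", model$c),
               sprintf("g\t%.17g", model$g),
               sprintf("seed\t%d", model$seed %||% 42L),
               sprintf("rho\t%.17g", model$rho),
               sprintf("dim\t%d", model$dim),
               sprintf("n_sv\t%d", model$n_sv),
               sprintf("features\t%s",
                       paste(model$feature_names, collapse = ","))), con)
  if (!is.null(params)) {
    stopifnot(inherits(params, "minmax_normalizer"))
    writeLines(sprintf("normalizer\t%.17g\t%.17g\t%s\t%s", params$y_min,
                       params$y_max,
                       paste(sprintf("%.17g", params$x_min), collapse = ","),
                       paste(sprintf("%.17g", params$x_max), collapse = ",")),
               con)
  }
  writeLines("sv_block", con)
  sv <- cbind(model$coef, model$sv)
  utils::write.table(format(sv, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Load a DDI model written by [write_ddi_model()]
#' @param path file path
#' @return list with `model` (a `ddi_model`) and `params` (normalizer or NULL)
#' @export
read_ddi_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "# domppi ddi_model"))
    stop("not a ddi_model file: ", path)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  key <- vapply(kv, `[`, character(1L), 1L)
  get1 <- function(k) kv[[match(k, key)]][2L]
  params <- NULL
  if ("normalizer" %in% key) {
    nf <- kv[[match("normalizer", key)]]
    feats <- strsplit(get1("features"), ",", fixed = TRUE)[[1L]][1:10]
    params <- structure(list(
      x_min = stats::setNames(as.numeric(strsplit(nf[4L], ",")[[1L]]),
                              sub("^a_", "", feats)),
      x_max = stats::setNames(as.numeric(strsplit(nf[5L], ",")[[1L]]),
                              sub("^a_", "", feats)),
      y_min = as.numeric(nf[2L]), y_max = as.numeric(nf[3L])),
      class = "minmax_normalizer")
  }
  svstart <- match("sv_block", key) + 1L
  sv <- do.call(rbind, lapply(kv[seq(svstart, length(kv))], as.numeric))
  dim <- as.integer(get1("dim"))
  structure_model <- structure(list(
    sv = sv[, -1L, drop = FALSE], coef = sv[, 1L],
    rho = as.numeric(get1("rho")), c = as.numeric(get1("c")),
    g = as.numeric(get1("g")),
    seed = if ("seed" %in% key) as.integer(get1("seed")) else NA_integer_,
    n_sv = as.integer(get1("n_sv")),
    dim = dim,
    feature_names = strsplit(get1("features"), ",", fixed = TRUE)[[1L]]),
    class = "ddi_model")
  list(model = structure_model, params = params)
}
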