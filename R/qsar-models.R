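# Ridge-regression and Tanimoto-kernel SVR potency models with a double
# (internal + external) cross-validation protocol.
#
# Compounds are represented as 1024-bit folded circular fingerprints
# (bond diameter 4).  Per trial the series is split 80/20; hyperparameters
# are selected by internal 5-fold cross-validation on the 80% and the
# refit model predicts the held-out 20%.  External predictions are
# averaged per compound over all trials in which it was external.

#' Fingerprint featurization of an analog set
#'
#' @param analogs an [analog_set()] (or character vector of SMILES)
#' @param nbits folded fingerprint length (default 1024)
#' @return binary matrix with compound ids as row names
#' @export
featurize <- function(analogs, nbits = 1024L) {
  if (is.character(analogs)) {
    smiles <- analogs
    ids <- names(analogs)
    if (is.null(ids)) ids <- as.character(seq_along(smiles))
  } else {
    smiles <- analogs$key
    ids <- analogs$id
  }
  x <- morgan_fingerprint(smiles, nbits = nbits, radius = 2L)
  rownames(x) <- ids
  x
}

#' Fit a ridge regression model
#'
#' Minimizes ||Xw - y||^2 + alpha ||w||^2 with an unpenalized intercept
#' (data are centered before the penalized solve).  Uses the kernel
#' (dual) identity when there are more features than instances.
#'
#' @param x feature matrix
#' @param y numeric response
#' @param alpha ridge penalty (>= 0)
#' @return object of class `rr_model`
#' @export
fit_rr <- function(x, y, alpha) {
  stopifnot(nrow(x) == length(y), alpha >= 0, nrow(x) >= 2L)
  xbar <- colMeans(x)
  ybar <- mean(y)
  xc <- sweep(x, 2, xbar)
  yc <- y - ybar
  n <- nrow(xc); p <- ncol(xc)
  if (all(abs(xc) < 1e-12)) {
    warning("all feature rows identical; intercept-only model")
    w <- rep(0, p)
  } else if (alpha == 0) {
    w <- qr.coef(qr(xc), yc)
    w[is.na(w)] <- 0
  } else if (n < p) {
    # w = X' (XX' + alpha I)^-1 y
    kk <- tcrossprod(xc)
    diag(kk) <- diag(kk) + alpha
    w <- crossprod(xc, solve(kk, yc))
  } else {
    xtx <- crossprod(xc)
    diag(xtx) <- diag(xtx) + alpha
    w <- solve(xtx, crossprod(xc, yc))
  }
  structure(list(w = as.numeric(w), intercept = ybar - sum(xbar * w),
                 alpha = alpha), class = "rr_model")
}

#' @export
predict.rr_model <- function(object, newdata, ...) {
  as.numeric(newdata %*% object$w) + object$intercept
}

#' Fit an epsilon-insensitive SVR with the Tanimoto kernel
#'
#' Solves the SVR dual with a sequential-minimal-optimization solver on
#' the precomputed Tanimoto kernel over binary fingerprints; predictions
#' are f(x) = sum_i beta_i K(x_i, x) + b.
#'
#' @param x binary fingerprint matrix
#' @param y numeric response
#' @param C regularization parameter (> 0)
#' @param eps epsilon-tube half width (>= 0)
#' @param tol SMO KKT tolerance
#' @return object of class `svr_model`
#' @export
fit_svr <- function(x, y, C, eps, tol = 1e-8) {
  stopifnot(nrow(x) == length(y), C > 0, eps >= 0)
  k <- tanimoto_kernel(x)
  fit <- .svr_smo_cpp(k, as.numeric(y), C, eps, tol)
  if (!fit$converged)
    warning("SVR solver hit the iteration cap before reaching tolerance")
  structure(list(beta = as.numeric(fit$beta), b = fit$b, x_train = x,
                 C = C, eps = eps, iterations = fit$iterations),
            class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  k <- tanimoto_kernel(newdata, object$x_train)
  as.numeric(k %*% object$beta) + object$b
}

#' Coefficient of determination
#'
#' R2 = 1 - sum((y - f)^2) / sum((y - mean(y))^2); may be negative for
#' models worse than predicting the mean.
#'
#' @param true observed values
#' @param predicted predicted values
#' @return R-squared
#' @export
r_squared <- function(true, predicted) {
  stopifnot(length(true) == length(predicted), length(true) >= 2L)
  tss <- sum((true - mean(true))^2)
  if (tss <= 0) stop("zero variance in true values; R2 undefined")
  1 - sum((true - predicted)^2) / tss
}

#' Double cross-validation protocol parameters
#'
#' @param n_trials number of random external splits (default 35)
#' @param external_fraction held-out fraction per trial (default 0.2)
#' @param internal_folds folds of the internal grid-search CV (default 5)
#' @param seed master seed; per-trial seeds are drawn from it and
#'   recorded
#' @param rr_alpha_grid 7 ridge penalties (log-spaced 1e-3..1e3)
#' @param svr_c_grid 18 SVR C values (log-spaced 1e-4..1e5)
#' @param svr_eps_grid 5 epsilon values
#' @param coverage_retries extra reshuffles to ensure every flagged
#'   compound is externally predicted at least once
#' @return object of class `cv_protocol`
#' @export
cv_protocol <- function(n_trials = 35L, external_fraction = 0.2,
                        internal_folds = 5L, seed = 1L,
                        rr_alpha_grid = 10^seq(-3, 3, length.out = 7),
                        svr_c_grid = 10^seq(-4, 5, length.out = 18),
                        svr_eps_grid = c(0.01, 0.05, 0.1, 0.2, 0.5),
                        coverage_retries = 25L) {
  structure(list(n_trials = as.integer(n_trials),
                 external_fraction = external_fraction,
                 internal_folds = as.integer(internal_folds),
                 seed = as.integer(seed),
                 rr_alpha_grid = rr_alpha_grid,
                 svr_c_grid = svr_c_grid, svr_eps_grid = svr_eps_grid,
                 coverage_retries = as.integer(coverage_retries)),
            class = "cv_protocol")
}

.fit_model <- function(kind, x, y, pars, tol = 1e-8) {
  if (kind == "rr") fit_rr(x, y, pars$alpha)
  else fit_svr(x, y, pars$C, pars$eps, tol = tol)
}

.param_grid <- function(kind, protocol) {
  if (kind == "rr") {
    data.frame(alpha = protocol$rr_alpha_grid)
  } else {
    expand.grid(C = protocol$svr_c_grid, eps = protocol$svr_eps_grid)
  }
}

# internal k-fold grid search; returns the selected row of the grid.
# Selection: highest mean fold R2, ties toward stronger regularization
# (larger alpha / smaller C, then larger eps).
.grid_search <- function(kind, x, y, folds, grid) {
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    r2s <- numeric(length(unique(folds)))
    for (f in sort(unique(folds))) {
      tr <- folds != f
      fit <- .fit_model(kind, x[tr, , drop = FALSE], y[tr], grid[g, , drop = FALSE])
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      r2s[f] <- if (stats::var(y[!tr]) > 0) r_squared(y[!tr], pred)
      else -sum((y[!tr] - pred)^2)
    }
    scores[g] <- mean(r2s)
  }
  ord <- if (kind == "rr") order(-scores, -grid$alpha)
  else order(-scores, grid$C, -grid$eps)
  grid[ord[1], , drop = FALSE]
}

#' Run the double cross-validation protocol on one series
#'
#' @param series an `analog_series` with member potencies, or a list
#'   with elements `x` (fingerprints), `y` (potencies), `ids`
#' @param protocol a [cv_protocol()]
#' @param model_kind `"rr"` or `"svr"`
#' @param must_cover optional compound ids (e.g. FW EAs) that must each
#'   appear in at least one external set; splits are redrawn within the
#'   retry budget to satisfy this
#' @return list of class `double_cv`: `predictions` (per-compound means
#'   over external appearances), `per_trial` (trial, R2, selected
#'   hyperparameters), `mean_r2`, `trial_seeds`
#' @export
run_double_cv <- function(series, protocol, model_kind = c("rr", "svr"),
                          must_cover = NULL) {
  model_kind <- match.arg(model_kind)
  if (inherits(series, "analog_series")) {
    x <- featurize(analog_set(series$members$id, series$members$key,
                              series$members$potency))
    y <- stats::setNames(series$members$potency, series$members$id)
  } else {
    x <- series$x; y <- stats::setNames(series$y, series$ids)
  }
  ids <- rownames(x)
  n <- length(ids)
  if (n < 25L) stop("need at least 25 compounds for the 80/20 + 5-fold protocol")
  n_ext <- max(1L, round(protocol$external_fraction * n))
  grid <- .param_grid(model_kind, protocol)
  # draw per-trial external sets under the coverage constraint
  splits <- with_seed(protocol$seed, {
    trial_seeds <- sample.int(.Machine$integer.max, protocol$n_trials)
    ext_sets <- lapply(trial_seeds, function(s)
      with_seed(s, sample.int(n, n_ext)))
    if (!is.null(must_cover)) {
      retries <- 0L
      repeat {
        covered <- unique(ids[unlist(ext_sets)])
        missing <- setdiff(must_cover, covered)
        if (!length(missing) || retries >= protocol$coverage_retries) break
        retries <- retries + 1L
        # replace compounds in the least-recently-drawn trial with the
        # uncovered ids
        tgt <- ((retries - 1L) %% protocol$n_trials) + 1L
        take <- match(utils::head(missing, n_ext), ids)
        keep <- setdiff(ext_sets[[tgt]], take)
        ext_sets[[tgt]] <- utils::head(c(take, keep), n_ext)
      }
      covered <- unique(ids[unlist(ext_sets)])
      missing <- setdiff(must_cover, covered)
      if (length(missing))
        warning("compounds never externally predicted: ",
                paste(missing, collapse = ", "))
    }
    list(trial_seeds = trial_seeds, ext_sets = ext_sets)
  })
  pred_sum <- stats::setNames(numeric(n), ids)
  pred_cnt <- stats::setNames(integer(n), ids)
  per_trial <- vector("list", protocol$n_trials)
  for (t in seq_len(protocol$n_trials)) {
    ext <- splits$ext_sets[[t]]
    tr <- setdiff(seq_len(n), ext)
    folds <- with_seed(splits$trial_seeds[t] %% .Machine$integer.max,
                       sample(rep_len(seq_len(protocol$internal_folds),
                                      length(tr))))
    best <- .grid_search(model_kind, x[tr, , drop = FALSE], y[tr], folds, grid)
    fit <- .fit_model(model_kind, x[tr, , drop = FALSE], y[tr], best)
    pred <- stats::predict(fit, x[ext, , drop = FALSE])
    r2 <- if (stats::var(y[ext]) > 0) r_squared(y[ext], pred) else NA_real_
    pred_sum[ext] <- pred_sum[ext] + pred
    pred_cnt[ext] <- pred_cnt[ext] + 1L
    per_trial[[t]] <- cbind(data.frame(trial = t, r2 = r2), best)
  }
  per_trial <- do.call(rbind, per_trial)
  predictions <- data.frame(
    id = ids, true_potency = unname(y[ids]),
    predicted = ifelse(pred_cnt > 0, pred_sum / pmax(pred_cnt, 1L), NA_real_),
    n_external_trials = unname(pred_cnt), stringsAsFactors = FALSE)
  rownames(predictions) <- NULL
  structure(list(model_kind = model_kind, predictions = predictions,
                 per_trial = per_trial,
                 mean_r2 = mean(per_trial$r2, na.rm = TRUE),
                 trial_seeds = splits$trial_seeds),
            class = "double_cv")
}

#' @export
print.double_cv <- function(x, ...) {
  cat(sprintf("<double_cv %s> %d trials, mean external R2 = %.3f\n",
              x$model_kind, nrow(x$per_trial), x$mean_r2))
  invisible(x)
}
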