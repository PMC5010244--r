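#' Mean centering and Pareto scaling
#'
#' Column-wise preprocessing for spectral/metabolite matrices: subtract the
#' column mean and, under Pareto scaling, divide by the square root of the
#' column standard deviation (damping high-intensity dominance while keeping
#' some magnitude information). Constant columns are centered but never
#' divided; they are reported in `zero_sd`.
#'
#' @param X numeric matrix (samples x variables), finite entries.
#' @param mean_center logical, subtract column means.
#' @param pareto logical, divide by sqrt(column sd).
#' @return list with `X` (the preprocessed matrix) and `params` (class
#'   `preproc_params`: `center`, `scale`, `zero_sd`), reusable on new data
#'   via [apply_preprocess()].
#' @export
preprocess <- function(X, mean_center = TRUE, pareto = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 2)
    stop("input error: at least 2 rows are required", call. = FALSE)
  if (any(!is.finite(X)))
    stop("input error: X contains non-finite entries", call. = FALSE)
  ctr <- if (mean_center) colMeans(X) else rep(0, ncol(X))
  sds <- apply(X, 2, sd)
  zero_sd <- sds == 0
  scl <- if (pareto) ifelse(zero_sd, 1, sqrt(sds)) else rep(1, ncol(X))
  params <- structure(list(center = ctr, scale = scl, zero_sd = zero_sd),
                      class = "preproc_params")
  list(X = apply_preprocess(params, X), params = params)
}

#' @rdname preprocess
#' @param params a `preproc_params` object fitted on training data.
#' @export
apply_preprocess <- function(params, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, params$center, "-"), 2, params$scale, "/")
}

#' Principal component analysis of a preprocessed matrix
#'
#' Successive variance-maximizing orthonormal directions of an
#' already-preprocessed (e.g. mean-centered, Pareto-scaled) matrix, via
#' singular value decomposition.
#'
#' @param X preprocessed numeric matrix.
#' @param n_components number of components (must not exceed the rank).
#' @return list with `scores` (n x a), `loadings` (p x a, orthonormal
#'   columns), `explained_variance` (per-component variance) and
#'   `explained_variance_ratio`.
#' @export
fit_pca <- function(X, n_components = 2) {
  X <- as.matrix(X)
  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (n_components > rank)
    stop(sprintf("input error: n_components (%d) exceeds the matrix rank (%d)",
                 n_components, rank), call. = FALSE)
  a <- seq_len(n_components)
  list(scores = sv$u[, a, drop = FALSE] %*% diag(sv$d[a], n_components),
       loadings = sv$v[, a, drop = FALSE],
       explained_variance = sv$d[a]^2 / (nrow(X) - 1),
       explained_variance_ratio = sv$d[a]^2 / sum(sv$d^2))
}

#' Fit a PLS1 discriminant model (NIPALS)
#'
#' Partial least squares regression of a binary class code y in {0, 1} on a
#' preprocessed matrix X, by the NIPALS algorithm with deflation of X and y.
#' Predictions are continuous; class membership is called at the 0.5
#' threshold. Score vectors are mutually orthogonal.
#'
#' @param X preprocessed numeric matrix (samples x variables).
#' @param y binary vector coded 0/1 with both classes present.
#' @param n_components number of latent variables (<= rank of X).
#' @param reduce logical; when `TRUE`, silently cap `n_components` at the
#'   number of extractable components instead of erroring (used inside
#'   cross-validation folds).
#' @return object of class `plsda_model`: weights `W` (unit columns),
#'   loadings `P`, y-loadings `q`, scores `T`, regression coefficients
#'   `coefficients`, intercept `y_mean`, and `fitted` (continuous training
#'   predictions).
#' @export
fit_plsda <- function(X, y, n_components = 2, reduce = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2)
    stop("input error: y must be binary 0/1 with both classes present",
         call. = FALSE)
  if (nrow(X) != length(y))
    stop("input error: X and y dimensions disagree", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  ybar <- mean(y)
  E <- X; f <- y - ybar
  A <- n_components
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  tol <- 1e-12 * (sum(X^2) + 1)
  a_done <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw^2 < tol) break
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    if (tt < tol) break
    p_ <- crossprod(E, t_) / tt
    q_a <- sum(t_ * f) / tt
    E <- E - t_ %*% t(p_)
    f <- f - t_ * q_a
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; q[a] <- q_a
    a_done <- a
  }
  if (a_done < A) {
    if (!reduce)
      stop(sprintf("input error: only %d PLS components are extractable (requested %d)",
                   a_done, A), call. = FALSE)
    A <- a_done
    if (A == 0L)
      stop("input error: X carries no usable variance", call. = FALSE)
    W <- W[, 1:A, drop = FALSE]; P <- P[, 1:A, drop = FALSE]
    Tm <- Tm[, 1:A, drop = FALSE]; q <- q[1:A]
  }
  rownames(W) <- rownames(P) <- colnames(X)
  B <- W %*% solve(crossprod(P, W), q)
  fitted <- drop(ybar + X %*% B)
  structure(list(W = W, P = P, q = q, T = Tm, coefficients = drop(B),
                 y_mean = ybar, n_components = A, fitted = fitted),
            class = "plsda_model")
}

#' @rdname fit_plsda
#' @param object a fitted `plsda_model`.
#' @param newdata matrix in the same (preprocessed) variable space.
#' @param ... unused.
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  drop(object$y_mean + as.matrix(newdata) %*% object$coefficients)
}

#' Variable importance in projection (VIP)
#'
#' Standard VIP scores of a PLS model:
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a (w_{ja}/\|w_a\|)^2 / \sum_a SS_a}}
#' with \eqn{SS_a = q_a^2 t_a' t_a} the y-variance explained by component
#' a. The mean of the squared VIPs equals 1 for any model; variables with
#' VIP > 1 contribute more than average to the discrimination.
#'
#' @param model a fitted [fit_plsda()] model.
#' @return numeric vector of VIP scores, one per variable.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  ss <- model$q^2 * colSums(model$T^2)
  if (sum(ss) <= 0)
    stop("input error: the model explains no y-variance", call. = FALSE)
  p <- nrow(model$W)
  w2 <- sweep(model$W^2, 2, colSums(model$W^2), "/")
  setNames(sqrt(p * drop(w2 %*% ss) / sum(ss)), rownames(model$W))
}

# Mann-Whitney AUROC with ties counted 1/2
.auroc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("input error: both classes are required for ROC analysis",
         call. = FALSE)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated ROC curve and AUROC
#'
#' Receiver operating characteristic of continuous (cross-validated) class
#' predictions against the true labels. The area under the curve equals the
#' Mann-Whitney U statistic divided by \eqn{n_1 n_0}, with ties counted
#' one-half.
#'
#' @param scores continuous predictions (higher = more class-1-like).
#' @param y binary labels (0/1).
#' @return list with `auroc` and `curve` (data.frame of `threshold`, `fpr`,
#'   `tpr`).
#' @export
cv_roc <- function(scores, y) {
  y <- as.numeric(y)
  auc <- .auroc(scores, y)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[y == 0] >= t), numeric(1))
  list(auroc = auc, curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr))
}

#' Venetian-blind cross-validation of a PLS-DA model
#'
#' Ten-fold Venetian-blind cross-validation, repeated: within each repeat
#' the sample order is shuffled (seeded) and fold k collects the samples
#' whose shuffled index is congruent to k modulo `folds` (the interleaved
#' "Venetian blind" pattern), so each run holds out 1/folds of the data.
#' Preprocessing is re-fitted inside every training fold. Reported are
#'
#' * `q2`: the correlation-based predictive statistic — the average over
#'   folds and repeats of the correlation between the held-out class code
#'   and its prediction;
#' * `q2_press`: the conventional \eqn{1 - PRESS/TSS};
#' * `rmsecv`: root mean square error of all held-out predictions;
#' * `accuracy`: pooled held-out accuracy at the 0.5 threshold;
#' * `auroc`: Mann-Whitney AUROC of the per-subject mean held-out
#'   prediction.
#'
#' Folds containing a single class (or degenerate predictions) are skipped
#' with a warning and counted in `skipped_folds`.
#'
#' @param X numeric matrix (samples x variables), raw scale.
#' @param y binary class code 0/1.
#' @param folds number of folds (default 10).
#' @param repeats number of repeated shuffles of the whole process.
#' @param n_components latent variables per fold model.
#' @param mean_center,pareto preprocessing flags, see [preprocess()].
#' @param seed integer seed; the report is reproducible given the seed.
#' @return list of class `cv_report`; `predictions` is the n x repeats
#'   matrix of held-out predictions, `mean_prediction` its row mean.
#' @export
venetian_cv <- function(X, y, folds = 10, repeats = 10, n_components = 2,
                        mean_center = TRUE, pareto = TRUE, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < folds)
    stop("input error: need at least as many samples as folds",
         call. = FALSE)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2)
    stop("input error: y must be binary 0/1 with both classes present",
         call. = FALSE)
  set.seed(as.integer(seed))
  preds <- matrix(NA_real_, n, repeats)
  fold_cors <- c()
  skipped <- 0L
  for (r in seq_len(repeats)) {
    ord <- sample.int(n)
    fold_of <- integer(n)
    fold_of[ord] <- (seq_len(n) - 1L) %% folds + 1L
    for (k in seq_len(folds)) {
      te <- which(fold_of == k); tr <- which(fold_of != k)
      if (length(unique(y[tr])) < 2) { skipped <- skipped + 1L; next }
      pp <- preprocess(X[tr, , drop = FALSE], mean_center, pareto)
      fit <- fit_plsda(pp$X, y[tr], n_components, reduce = TRUE)
      yhat <- predict(fit, apply_preprocess(pp$params, X[te, , drop = FALSE]))
      preds[te, r] <- yhat
      if (length(unique(y[te])) >= 2 && sd(yhat) > 0)
        fold_cors <- c(fold_cors, cor(y[te], yhat))
      else skipped <- skipped + 1L
    }
  }
  if (skipped > 0)
    warning(sprintf("%d fold(s) skipped (single class or degenerate predictions)",
                    skipped))
  held <- !is.na(preds)
  yrep <- matrix(y, n, repeats)
  press <- sum((yrep[held] - preds[held])^2)
  tss <- sum((yrep[held] - mean(y))^2)
  mean_pred <- rowMeans(preds, na.rm = TRUE)
  structure(list(
    q2 = mean(fold_cors),
    q2_press = 1 - press / tss,
    rmsecv = sqrt(mean((yrep[held] - preds[held])^2)),
    accuracy = mean((preds[held] >= 0.5) == yrep[held]),
    auroc = .auroc(mean_pred, y),
    predictions = preds,
    mean_prediction = mean_pred,
    fold_cors = fold_cors,
    skipped_folds = skipped,
    folds = folds, repeats = repeats, n_components = n_components,
    seed = seed),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(paste0("<cv_report> %d-fold x %d repeats, %d components\n",
                     "  Q2 (correlation) = %.3f | Q2 (1-PRESS/TSS) = %.3f\n",
                     "  RMSECV = %.3f | accuracy = %.3f | AUROC = %.3f\n"),
              x$folds, x$repeats, x$n_components, x$q2, x$q2_press,
              x$rmsecv, x$accuracy, x$auroc))
  invisible(x)
}

#' Choose the number of latent variables by cross-validated error
#'
#' Runs [venetian_cv()] for 1..`max_components` latent variables and returns
#' the count minimizing the pooled RMSECV.
#'
#' @inheritParams venetian_cv
#' @param max_components largest model size considered (default 10).
#' @return list with `n_components` (the minimizer) and `rmsecv` (vector).
#' @export
select_ncomp <- function(X, y, max_components = 10, folds = 10, repeats = 3,
                         mean_center = TRUE, pareto = TRUE, seed = 1L) {
  max_components <- min(max_components, ncol(X), nrow(X) - 1)
  rmse <- vapply(seq_len(max_components), function(a)
    suppressWarnings(
      venetian_cv(X, y, folds, repeats, a, mean_center, pareto, seed)$rmsecv),
    numeric(1))
  list(n_components = which.min(rmse), rmsecv = rmse)
}

#' Permutation validation of a PLS-DA model
#'
#' Re-estimates the cross-validated predictive statistic (the
#' correlation-based Q2 of [venetian_cv()]) under random permutations of
#' the class labels, giving an empirical p-value
#' \eqn{p = (1 + \#\{Q2_{perm} \ge Q2_{obs}\}) / (1 + n_{perm})} for the
#' hypothesis that the observed model predicts no better than chance.
#'
#' @inheritParams venetian_cv
#' @param n_permutations number of label permutations (>= 1).
#' @return list of class `permutation_report`: `observed`, `permuted`
#'   (length `n_permutations`), `p`, `n_permutations`.
#' @export
permutation_test <- function(X, y, n_permutations = 50, folds = 10,
                             repeats = 3, n_components = 2,
                             mean_center = TRUE, pareto = TRUE, seed = 1L) {
  if (n_permutations < 1)
    stop("input error: n_permutations must be >= 1", call. = FALSE)
  obs <- suppressWarnings(
    venetian_cv(X, y, folds, repeats, n_components, mean_center, pareto,
                seed))$q2
  set.seed(as.integer(seed) + 1L)
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_permutations)
  permuted <- vapply(seq_len(n_permutations), function(i) {
    set.seed(perm_seeds[i])
    yp <- sample(y)
    suppressWarnings(
      venetian_cv(X, yp, folds, repeats, n_components, mean_center, pareto,
                  perm_seeds[i]))$q2
  }, numeric(1))
  structure(list(observed = obs, permuted = permuted,
                 p = (1 + sum(permuted >= obs)) / (1 + n_permutations),
                 n_permutations = n_permutations),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("<permutation_report> observed Q2 = %.3f, %d permutations, p = %.4f\n",
              x$observed, x$n_permutations, x$p))
  invisible(x)
}
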