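#' Log-transform and autoscale a predictor block and response
#'
#' Log10-transform followed by column-wise zero-mean unit-variance scaling,
#' the standard preprocessing for PLSR on concentration data. Zeros are made
#' positive by an offset (default: half the smallest positive value per
#' column). The preprocessing record (offsets, means, SDs) is returned so a
#' fold's training-set parameters can be applied to held-out samples.
#'
#' @param X Numeric matrix (samples x variables), nonnegative.
#' @param Y Numeric response vector, nonnegative.
#' @param log_offset Scalar or per-column offsets; `NULL` picks half the
#'   smallest positive value in each column.
#' @param record Optional record from a previous call; when supplied its
#'   offsets/means/SDs are applied instead of being re-estimated.
#' @return List with `X`, `Y` (standardized) and `record`.
#' @export
preprocess_plsr <- function(X, Y, log_offset = NULL, record = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop("X and Y must be finite", call. = FALSE)
  if (is.null(record)) {
    floor_x <- apply(X, 2, function(col) {
      pos <- col[col > 0]
      if (!length(pos)) stop("all-zero column", call. = FALSE)
      min(pos) / 2
    })
    off <- if (!is.null(log_offset)) rep_len(log_offset, ncol(X)) else
      ifelse(apply(X == 0, 2, any), floor_x, 0)
    yoff <- if (any(Y == 0)) min(Y[Y > 0]) / 2 else 0
    lX <- log10(sweep(X, 2, off, "+"))
    lY <- log10(Y + yoff)
    mu <- colMeans(lX); sd <- apply(lX, 2, stats::sd)
    zero <- which(sd == 0 | !is.finite(sd))
    if (length(zero))
      stop("zero-variance column(s): ",
           paste(colnames(X)[zero] %||% zero, collapse = ", "), call. = FALSE)
    ymu <- mean(lY); ysd <- stats::sd(lY)
    if (ysd == 0) stop("zero-variance response", call. = FALSE)
    record <- list(x_offset = off, x_floor = floor_x, x_mean = mu, x_sd = sd,
                   y_offset = yoff, y_floor = min(Y[Y > 0]) / 2,
                   y_mean = ymu, y_sd = ysd)
  }
  # held-out zeros in columns whose training data had none are floored at
  # half the smallest positive training value before the log
  lX <- log10(pmax(sweep(X, 2, record$x_offset, "+"),
                   rep(record$x_floor, each = nrow(X))))
  Xs <- sweep(sweep(lX, 2, record$x_mean, "-"), 2, record$x_sd, "/")
  Ys <- (log10(pmax(Y + record$y_offset, record$y_floor)) -
           record$y_mean) / record$y_sd
  list(X = Xs, Y = as.numeric(Ys), record = record)
}

#' Fit a PLS1 regression by NIPALS
#'
#' Iterative latent-variable decomposition for a single response: per
#' component a unit-norm X-weight maximizing covariance with the Y residual,
#' scores, X- and Y-loadings, then deflation of X and Y. Cumulative R2Y is
#' `1 - SS_res/SS_tot`. Inputs are expected centered/scaled (see
#' [preprocess_plsr()]).
#'
#' @param X Standardized predictor matrix (n x p).
#' @param Y Standardized response vector (length n).
#' @param A Number of components, `A <= rank(X)` and `A < n`.
#' @return A `plsr_fit`: weights `W` (p x A), loadings `P` (p x A), Y-loadings
#'   `q` (A), scores `T` (n x A), coefficients `B`, cumulative `r2y`, `ssy`
#'   per component, and `vip` scores.
#' @export
fit_plsr <- function(X, Y, A) {
  X <- as.matrix(X); Y <- as.numeric(Y)
  n <- nrow(X); p <- ncol(X)
  if (A < 1 || A > min(n - 1, p)) stop("invalid number of components", call. = FALSE)
  W <- P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- ssy <- r2y <- numeric(A)
  ss_tot <- sum(Y^2)
  if (ss_tot == 0) stop("response has no variance", call. = FALSE)
  Xr <- X; yr <- Y
  for (a in seq_len(A)) {
    w <- crossprod(Xr, yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("NIPALS failed to extract component ", a,
           ": residual covariance is zero", call. = FALSE)
    w <- w / nw
    t <- as.numeric(Xr %*% w)
    tt <- sum(t^2)
    pl <- as.numeric(crossprod(Xr, t)) / tt
    qa <- sum(yr * t) / tt
    Xr <- Xr - tcrossprod(t, pl)
    yr <- yr - qa * t
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; q[a] <- qa
    ssy[a] <- qa^2 * tt
    r2y[a] <- 1 - sum(yr^2) / ss_tot
  }
  # regression coefficients in the standardized space
  B <- W %*% solve(crossprod(P, W), q)
  fit <- structure(list(W = W, P = P, q = q, T = Tm, B = as.numeric(B),
                        A = A, ssy = ssy, r2y = r2y,
                        var_names = colnames(X)),
                   class = "plsr_fit")
  fit$vip <- vip_scores(fit)
  fit
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat("<plsr_fit>", x$A, "component(s); cumulative R2Y:",
      paste(sprintf("%.3f", x$r2y), collapse = ", "), "\n")
  invisible(x)
}

#' Predict from a PLS fit
#'
#' @param object A `plsr_fit`.
#' @param newdata Standardized predictor matrix.
#' @param ... Unused.
#' @return Predicted standardized response.
#' @export
predict.plsr_fit <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$B)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a SSY_a w_aj^2 / sum_a SSY_a)` where `SSY_a` is the
#' Y-variance explained by component `a` and `w_aj` the unit-norm weight;
#' the mean of squared VIP scores is 1 by construction.
#'
#' @param fit A `plsr_fit`.
#' @return Named numeric vector of VIP scores.
#' @export
vip_scores <- function(fit) {
  p <- nrow(fit$W)
  num <- as.numeric(fit$W^2 %*% fit$ssy)
  v <- sqrt(p * num / sum(fit$ssy))
  stats::setNames(v, fit$var_names)
}

#' Cross-validated Q2
#'
#' `Q2 = 1 - PRESS/SS_tot` per cumulative component count, with folds formed
#' as contiguous blocks after a seeded shuffle and preprocessing refit inside
#' each training fold. Predictions are de-standardized with the training
#' fold's record before PRESS is accumulated on the raw log scale.
#'
#' @param X Raw (untransformed) predictor matrix.
#' @param Y Raw response vector.
#' @param A Maximum number of components.
#' @param folds Number of folds (default 7).
#' @param seed Integer seed for the shuffle.
#' @param log_offset Passed to [preprocess_plsr()] (training folds).
#' @return Numeric vector `q2[1..A]`.
#' @export
q2_crossval <- function(X, Y, A, folds = 7, seed = 1L, log_offset = NULL) {
  X <- as.matrix(X); Y <- as.numeric(Y)
  n <- nrow(X)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (n < folds) stop("more folds than samples", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  # contiguous blocks over the shuffled order
  fold_id <- integer(n)
  fold_id[ord] <- cut(seq_len(n), folds, labels = FALSE)

  press <- numeric(A); sstot <- 0
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    prep <- preprocess_plsr(X[tr, , drop = FALSE], Y[tr], log_offset)
    amax <- min(A, sum(tr) - 1, ncol(X))
    fit <- fit_plsr(prep$X, prep$Y, amax)
    test <- preprocess_plsr(X[te, , drop = FALSE], Y[te], record = prep$record)
    y_true <- log10(pmax(Y[te] + prep$record$y_offset, prep$record$y_floor))
    for (a in seq_len(A)) {
      aa <- min(a, amax)
      Ba <- fit$W[, 1:aa, drop = FALSE] %*%
        solve(crossprod(fit$P[, 1:aa, drop = FALSE],
                        fit$W[, 1:aa, drop = FALSE]), fit$q[1:aa])
      pred_s <- as.numeric(test$X %*% Ba)
      y_hat <- pred_s * prep$record$y_sd + prep$record$y_mean
      press[a] <- press[a] + sum((y_true - y_hat)^2)
    }
    mu_y <- mean(log10(Y[tr] + prep$record$y_offset))
    sstot <- sstot + sum((y_true - mu_y)^2)
  }
  1 - press / sstot
}

#' Select the number of components by cross-validation
#'
#' Smallest A whose incremental Q2 gain falls below `min_gain` (0.01); at
#' least one component.
#'
#' @param q2 Vector of cumulative Q2 values.
#' @param min_gain Minimum incremental gain to accept another component.
#' @return Integer component count.
#' @export
select_components <- function(q2, min_gain = 0.01) {
  if (length(q2) == 1) return(1L)
  gains <- diff(c(0, q2))
  a <- 1L
  for (i in 2:length(q2)) {
    if (gains[i] >= min_gain) a <- i else break
  }
  a
}

#' PLSR of an endpoint on protein concentrations, per cell class
#'
#' Runs the preprocessing, component selection (unless `A` is given),
#' NIPALS fit, Q2 cross-validation, and VIP scoring separately for malignant
#' and non-malignant cells.
#'
#' @param proteins Cells x variables matrix of molar protein concentrations
#'   (rownames are cell IDs).
#' @param endpoints Endpoint table from [run_cohort()].
#' @param response Endpoint column used as Y (NADPH:NADP+ ratio by default).
#' @param A Component count; `NULL` selects by cross-validated Q2 gain.
#' @param max_A Maximum components considered during selection.
#' @param folds,seed Cross-validation controls.
#' @return Named list (`malignant`, `non_malignant`) of lists with `fit`,
#'   `A`, `r2y`, `q2`, `vip`, `n`.
#' @export
plsr_by_class <- function(proteins, endpoints, response = "nadph_ratio",
                          A = NULL, max_A = 6, folds = 7, seed = 1L) {
  ep <- endpoints[endpoints$status == "stable" &
                    is.finite(endpoints[[response]]), ]
  out <- list()
  for (cls in c(1, 0)) {
    ids <- ep$cell_id[ep$malignant == cls]
    X <- proteins[ids, , drop = FALSE]
    Y <- ep[[response]][match(ids, ep$cell_id)]
    amax <- min(max_A, ncol(X), length(Y) - 1)
    q2 <- q2_crossval(X, Y, amax, folds = folds, seed = seed)
    a_use <- if (is.null(A)) select_components(q2) else min(A, amax)
    prep <- preprocess_plsr(X, Y)
    fit <- fit_plsr(prep$X, prep$Y, a_use)
    out[[if (cls == 1) "malignant" else "non_malignant"]] <-
      list(fit = fit, A = a_use, r2y = fit$r2y[a_use], q2 = q2,
           vip = fit$vip, n = length(Y))
  }
  out
}
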