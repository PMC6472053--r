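#' NorCont normalization of a bucket matrix
#'
#' Expresses each bucket as percent-of-lipid content: every bucket of row
#' \eqn{i} is multiplied by \eqn{3 / I_{TL}(i)}, where \eqn{I_{TL}(i)} is
#' the sum of that row's terminal-methyl buckets (the 0.88 and 0.95 ppm
#' regions, three protons per chain). Under the one-proton-per-bucket
#' convention a normalized bucket is then the analyte's content per acyl
#' chain, which removes per-sample differences in total lipid (fat
#' content) exactly.
#'
#' @param bm a `bucket_matrix` (UNor).
#' @param methyl_idx bucket indices of the methyl regions; default derived
#'   from the bucket centers and [integration_windows()].
#' @return a `bucket_matrix` with `normalization = "NorCont"`.
#' @export
normalize_norcont <- function(bm, methyl_idx = NULL) {
  stopifnot(inherits(bm, "bucket_matrix"))
  if (is.null(methyl_idx)) methyl_idx <- methyl_bucket_indices(bm$centers)
  if (!length(methyl_idx)) stop("no methyl buckets identified", call. = FALSE)
  tl <- rowSums(bm$values[, methyl_idx, drop = FALSE])
  if (any(tl <= 0)) {
    bad <- bm$sample_ids[tl <= 0]
    stop("non-positive methyl bucket sum for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- bm
  out$values <- bm$values * (3 / tl)
  out$normalization <- "NorCont"
  out
}

#' Pareto scaling
#'
#' Mean-centers each column and divides by the square root of its sample
#' standard deviation — a compromise between no scaling and unit-variance
#' scaling that damps the dominance of intense buckets while keeping the
#' data near their original magnitudes. Constant columns are mapped to
#' zero.
#'
#' @param x numeric matrix (samples x variables) or a `bucket_matrix`.
#' @return matrix of the same shape with attributes `scaled:center` and
#'   `scaled:scale`; for a `bucket_matrix` input, the object is returned
#'   with its `values` replaced.
#' @export
pareto_scale <- function(x) {
  if (inherits(x, "bucket_matrix")) {
    out <- x
    out$values <- pareto_scale(x$values)
    return(out)
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sc <- sqrt(sdv)
  sc[sc == 0] <- 1          # constant columns -> centered zeros
  out <- sweep(sweep(x, 2, mu), 2, sc, "/")
  attr(out, "scaled:center") <- mu
  attr(out, "scaled:scale") <- sc
  out
}

as_values <- function(x) {
  if (inherits(x, "bucket_matrix")) x$values else as.matrix(x)
}

#' Principal component analysis of a (scaled) data matrix
#'
#' Singular value decomposition of the column-centered matrix (via
#' `stats::prcomp`, no additional scaling — apply [pareto_scale()] first).
#'
#' @param x numeric matrix or `bucket_matrix` (typically Pareto-scaled).
#' @param n_components number of components to keep.
#' @return list of class `pca_model`: `scores` (n x a), `loadings` (p x a),
#'   `explained_variance_pct` (length a) and `center`.
#' @export
pca_fit <- function(x, n_components = 2) {
  x <- as_values(x)
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  n_components <- min(n_components, nrow(x) - 1L, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- seq_len(n_components)
  structure(list(scores = pc$x[, keep, drop = FALSE],
                 loadings = pc$rotation[, keep, drop = FALSE],
                 explained_variance_pct = 100 * ev[keep] / sum(ev),
                 center = pc$center),
            class = "pca_model")
}

one_hot <- function(classes) {
  classes <- as.factor(classes)
  if (nlevels(classes) != 2L) stop("exactly two classes required", call. = FALSE)
  if (any(table(classes) < 2L)) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  y <- stats::model.matrix(~ classes - 1)
  colnames(y) <- levels(classes)
  y
}

#' Fit a two-class PLS-DA model by NIPALS
#'
#' Iterative NIPALS extraction of latent variables from the (optionally
#' Pareto-scaled, internally mean-centered) bucket matrix against the
#' one-hot class membership matrix, with deflation of both blocks after
#' each component. Weights are unit-norm; scores are mutually orthogonal.
#' Cumulative \eqn{R^2Y = 1 - RSS(Y)/TSS(Y)} is reported per component.
#'
#' @param x numeric matrix or `bucket_matrix` (samples x variables).
#' @param classes two-level factor (or coercible), >= 2 samples per class.
#' @param n_components number of latent variables (default 2).
#' @param tol NIPALS convergence tolerance on the score vector.
#' @param max_iter maximum NIPALS iterations per component.
#' @return list of class `plsda_model` with `weights`, `loadings`
#'   (X-loadings), `y_loadings`, `scores`, `ssy` (Y variance captured per
#'   component), `R2Y` (cumulative per component), `x_center`, `y_center`,
#'   `class_levels`, `n_components`.
#' @export
plsda_fit <- function(x, classes, n_components = 2, tol = 1e-12,
                      max_iter = 500L) {
  x <- as_values(x)
  y <- one_hot(classes)
  if (nrow(x) != nrow(y)) stop("x and classes length mismatch", call. = FALSE)
  n <- nrow(x); p <- ncol(x)
  n_components <- min(n_components, n - 1L, p)
  x_center <- colMeans(x); y_center <- colMeans(y)
  E <- sweep(x, 2, x_center)
  F <- sweep(y, 2, y_center)
  tss <- sum(F^2)
  W <- matrix(0, p, n_components); P <- matrix(0, p, n_components)
  Q <- matrix(0, ncol(y), n_components); Tm <- matrix(0, n, n_components)
  ssy <- numeric(n_components); r2y <- numeric(n_components)
  for (a in seq_len(n_components)) {
    u <- F[, which.max(apply(F, 2, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(E, u)
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps) {
        stop("NIPALS breakdown at component ", a, call. = FALSE)
      }
      w <- w / nw
      tt <- drop(E %*% w)
      q <- crossprod(F, tt) / sum(tt^2)
      u <- drop(F %*% q) / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * max(sqrt(sum(tt^2)), 1)) break
      t_old <- tt
      if (it == max_iter) {
        stop("NIPALS failed to converge for component ", a, call. = FALSE)
      }
    }
    pp <- crossprod(E, tt) / sum(tt^2)
    E <- E - tcrossprod(tt, pp)
    F <- F - tcrossprod(tt, q)
    W[, a] <- w; P[, a] <- pp; Q[, a] <- q; Tm[, a] <- tt
    ssy[a] <- sum(tt^2) * sum(q^2)
    r2y[a] <- 1 - sum(F^2) / tss
  }
  dimnames(W) <- list(colnames(x), paste0("LV", seq_len(n_components)))
  dimnames(P) <- dimnames(W)
  dimnames(Tm) <- list(rownames(x), colnames(W))
  structure(list(weights = W, loadings = P, y_loadings = Q, scores = Tm,
                 ssy = ssy, R2Y = r2y, x_center = x_center,
                 y_center = y_center,
                 class_levels = levels(as.factor(classes)),
                 n_components = n_components),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d component(s), classes %s vs %s, R2Y(cum) = %.3f\n",
              x$n_components, x$class_levels[1], x$class_levels[2],
              x$R2Y[x$n_components]))
  invisible(x)
}

#' Predict class membership from a fitted PLS-DA model
#'
#' @param object a `plsda_model`.
#' @param newdata matrix (samples x variables) on the same scale as the
#'   training data.
#' @param ... unused.
#' @return list with `y_hat` (predicted membership matrix) and `class`
#'   (factor, argmax rule).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  newdata <- as_values(newdata)
  B <- object$weights %*%
    solve(crossprod(object$loadings, object$weights)) %*% t(object$y_loadings)
  y_hat <- sweep(newdata, 2, object$x_center) %*% B
  y_hat <- sweep(y_hat, 2, object$y_center, "+")
  cls <- factor(object$class_levels[max.col(y_hat)],
                levels = object$class_levels)
  list(y_hat = y_hat, class = cls)
}

# stratified segment assignment: within each class, shuffled round-robin
make_segments <- function(classes, n_segments) {
  n <- length(classes)
  seg <- integer(n)
  for (cl in levels(classes)) {
    idx <- sample(which(classes == cl))
    seg[idx] <- rep_len(seq_len(n_segments), length(idx))
  }
  seg
}

#' Segmented cross-validation of a PLS-DA model
#'
#' Splits the samples into `n_segments` (stratified at random, or given
#' explicitly, e.g. grouping technical replicates into one segment),
#' refits the model with each segment held out, and pools the out-of-fold
#' predictions into \eqn{Q^2 = 1 - PRESS/TSS}, the percentage of correctly
#' predicted samples and the two-sided Fisher's exact p-value of the
#' pooled confusion matrix.
#'
#' @param x matrix or `bucket_matrix`.
#' @param classes two-level factor.
#' @param n_segments number of cross-validation segments (default 7).
#' @param n_components latent variables per fit.
#' @param segments optional explicit integer segment assignment (overrides
#'   the random split).
#' @param seed optional RNG seed for the split.
#' @return list of class `validation_report`: `Q2`, `pct_correct`,
#'   `fisher_p`, `confusion`, `predicted`, `segments`, `n_segments`.
#' @export
plsda_cv <- function(x, classes, n_segments = 7, n_components = 2,
                     segments = NULL, seed = NULL) {
  x <- as_values(x)
  classes <- as.factor(classes)
  y <- one_hot(classes)
  n <- nrow(x)
  if (is.null(segments)) {
    if (n_segments < 2L) stop("n_segments must be >= 2", call. = FALSE)
    if (!is.null(seed)) set.seed(as.integer(seed))
    segments <- make_segments(classes, n_segments)
  } else {
    segments <- as.integer(factor(segments))
    n_segments <- max(segments)
  }
  for (s in unique(segments)) {
    held <- classes[segments == s]
    for (cl in levels(classes)) {
      if (sum(held == cl) == sum(classes == cl)) {
        stop("segment ", s, " contains the entire class '", cl, "'",
             call. = FALSE)
      }
    }
  }
  y_hat <- matrix(NA_real_, n, ncol(y))
  for (s in unique(segments)) {
    in_tr <- segments != s
    fit <- plsda_fit(x[in_tr, , drop = FALSE], classes[in_tr],
                     n_components = n_components)
    y_hat[!in_tr, ] <- predict(fit, x[!in_tr, , drop = FALSE])$y_hat
  }
  tss <- sum(sweep(y, 2, colMeans(y))^2)
  press <- sum((y - y_hat)^2)
  predicted <- factor(levels(classes)[max.col(y_hat)], levels = levels(classes))
  confusion <- table(truth = classes, predicted = predicted)
  pct_correct <- 100 * mean(predicted == classes)
  fisher_p <- fisher_exact_2x2(matrix(as.integer(confusion), 2, 2))
  structure(list(Q2 = 1 - press / tss, pct_correct = pct_correct,
                 fisher_p = fisher_p, confusion = confusion,
                 predicted = predicted, segments = segments,
                 n_segments = n_segments),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> Q2 = %.3f, %.1f%% correct, Fisher p = %.3g\n",
              x$Q2, x$pct_correct, x$fisher_p))
  invisible(x)
}

#' Variable Importance in the Projection (VIP)
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a w_{ja}^2 / \sum_a SSY_a}}
#' with unit-norm weight vectors \eqn{w_a} and \eqn{SSY_a} the Y variance
#' captured by component \eqn{a}; the mean squared VIP equals 1.
#'
#' @param model a `plsda_model`.
#' @return numeric vector of VIP scores, one per variable.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  W <- model$weights
  p <- nrow(W)
  num <- (W^2) %*% model$ssy
  sqrt(p * drop(num) / sum(model$ssy))
}

#' Permutation validation of a PLS-DA model
#'
#' Refits the model and its cross-validation under `n_permutations` random
#' permutations of the class labels. Both \eqn{R^2Y} and \eqn{Q^2} are
#' regressed on the absolute correlation between the permuted and original
#' label vectors (the original model enters at correlation 1); the model
#' is flagged valid when every permuted \eqn{R^2Y} and \eqn{Q^2} falls
#' below the original values and the \eqn{Q^2} regression intercept is
#' negative.
#'
#' @param x matrix or `bucket_matrix`.
#' @param classes two-level factor.
#' @param n_permutations number of permutations (default 100).
#' @param n_segments,n_components passed to [plsda_cv()] / [plsda_fit()].
#' @param seed RNG seed.
#' @return list of class `permutation_report`: `R2Y`, `Q2` (originals),
#'   `perm_R2Y`, `perm_Q2`, `perm_cor`, `r2_intercept`, `q2_intercept`,
#'   `valid`, `n_permutations`.
#' @export
permutation_test <- function(x, classes, n_permutations = 100,
                             n_segments = 7, n_components = 2, seed = NULL) {
  if (n_permutations < 20L) stop("n_permutations must be >= 20", call. = FALSE)
  x <- as_values(x)
  classes <- as.factor(classes)
  if (!is.null(seed)) set.seed(as.integer(seed))
  fit0 <- plsda_fit(x, classes, n_components = n_components)
  cv0 <- plsda_cv(x, classes, n_segments = n_segments,
                  n_components = n_components)
  y_num <- as.numeric(classes == levels(classes)[2])
  perm_r2 <- numeric(n_permutations); perm_q2 <- numeric(n_permutations)
  perm_cor <- numeric(n_permutations)
  for (i in seq_len(n_permutations)) {
    repeat {
      perm <- sample(classes)
      if (stats::sd(as.numeric(perm == levels(classes)[2])) > 0) break
    }
    perm_cor[i] <- abs(stats::cor(as.numeric(perm == levels(classes)[2]), y_num))
    fit_i <- plsda_fit(x, perm, n_components = n_components)
    cv_i <- plsda_cv(x, perm, n_segments = n_segments,
                     n_components = n_components)
    perm_r2[i] <- fit_i$R2Y[fit_i$n_components]
    perm_q2[i] <- cv_i$Q2
  }
  r2_orig <- fit0$R2Y[fit0$n_components]
  xs <- c(perm_cor, 1)
  r2_line <- stats::lm(c(perm_r2, r2_orig) ~ xs)
  q2_line <- stats::lm(c(perm_q2, cv0$Q2) ~ xs)
  r2_int <- unname(stats::coef(r2_line)[1])
  q2_int <- unname(stats::coef(q2_line)[1])
  structure(list(R2Y = r2_orig, Q2 = cv0$Q2, perm_R2Y = perm_r2,
                 perm_Q2 = perm_q2, perm_cor = perm_cor,
                 r2_intercept = r2_int, q2_intercept = q2_int,
                 valid = all(perm_r2 < r2_orig) && all(perm_q2 < cv0$Q2) &&
                   q2_int < 0,
                 n_permutations = n_permutations),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf(
    "<permutation_report> %d permutations; R2Y = %.3f, Q2 = %.3f; intercepts R2 = %.3f, Q2 = %.3f; %s\n",
    x$n_permutations, x$R2Y, x$Q2, x$r2_intercept, x$q2_intercept,
    if (x$valid) "model valid" else "model NOT validated"))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities, over
#' all tables with the observed margins, that do not exceed the
#' probability of the observed table. Perfect separation of 14 vs 16
#' samples gives \eqn{p = 1/\binom{30}{14} \approx 6.9\times 10^{-9}}.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return the p-value.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(14, 0, 0, 16), 2, 2))
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (anyNA(table) || any(table < 0) || any(table != round(table))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("table margins must be positive", call. = FALSE)
  }
  stats::fisher.test(table)$p.value
}

#' Hotelling T-squared outlier screening of score vectors
#'
#' Flags samples whose Hotelling \eqn{T^2} over the selected components
#' exceeds the F-distribution based \eqn{100(1-\alpha)\%} limit
#' \deqn{T^2_{crit} = \frac{a (n-1)(n+1)}{n (n-a)} F_{1-\alpha; a, n-a},}
#' the limit that draws the confidence ellipse on a score plot.
#' Degenerate (zero-variance) components carry no information and are
#' dropped; if all components are degenerate no sample is flagged.
#'
#' @param scores n x a matrix of component scores (e.g. from [pca_fit()]
#'   or [plsda_fit()]).
#' @param alpha significance level; default 0.05 (95\% ellipse).
#' @return logical vector of outlier flags with attributes `t2` and
#'   `limit`.
#' @export
hotelling_outliers <- function(scores, alpha = 0.05) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  ctr <- sweep(scores, 2, colMeans(scores))
  v <- apply(ctr, 2, stats::var)
  keep <- v > 1e-12 * max(v, 1e-300)
  a <- sum(keep)
  if (a == 0L) {
    return(structure(rep(FALSE, n), t2 = rep(0, n), limit = Inf))
  }
  if (n <= a) stop("more components than samples", call. = FALSE)
  t2 <- rowSums(sweep(ctr[, keep, drop = FALSE]^2, 2, v[keep], "/"))
  limit <- a * (n - 1) * (n + 1) / (n * (n - a)) *
    stats::qf(1 - alpha, a, n - a)
  structure(t2 > limit, t2 = t2, limit = limit)
}

#' Two-sample t-test for a candidate marker
#'
#' Welch's t-test by default (pooled-variance optional). Two identical
#' zero-variance groups are handled as "no evidence of difference"
#' (t = 0, p = 1) instead of an error.
#'
#' @param values_group1,values_group2 numeric vectors (>= 2 values each).
#' @param pooled use the pooled-variance (classic) t-test.
#' @return named numeric `c(t, p)`.
#' @export
marker_ttest <- function(values_group1, values_group2, pooled = FALSE) {
  g1 <- as.numeric(values_group1); g2 <- as.numeric(values_group2)
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (stats::sd(g1) == 0 && stats::sd(g2) == 0) {
    if (mean(g1) == mean(g2)) return(c(t = 0, p = 1))
    return(c(t = if (mean(g1) > mean(g2)) Inf else -Inf, p = 0))
  }
  ht <- stats::t.test(g1, g2, var.equal = pooled)
  c(t = unname(ht$statistic), p = ht$p.value)
}
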