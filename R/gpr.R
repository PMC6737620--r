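# Gaussian-process regression for HBA/HBD strengths.
#
# Covariance: K = C * M + W, where C is a constant factor optimized on
# a log scale in [1e-3, 1e3], M is a Matern kernel (nu fixed at 0.5,
# 1.5 or 2.5; length scale optimized in [1e-2, 1e2]; gamma a fixed
# non-negative distance scale defaulting to 1, under which nu = 1.5
# reduces to the textbook (1 + sqrt(3) d/l) exp(-sqrt(3) d/l) form),
# and W is a white kernel with fixed noise 0.05 on the diagonal.
# Targets are standardized before fitting, so the fixed noise lives on
# the standardized scale; predictions are transformed back to kJ/mol.
#
# The reported "variance estimate" is the 95% interval half-width,
# 1.96 * posterior sd, in kJ/mol; it gates the applicability domain
# (default thresholds: HBA 4.2, HBD 3.2 kJ/mol).

#' Kernel configuration
#'
#' @param kernel_form "Matern" (default), "RBF" or
#'   "RationalQuadratic" (alpha fixed at 1).
#' @param nu Matern smoothness, one of 0.5, 1.5, 2.5.
#' @param C constant factor (initial value when optimized).
#' @param length_scale l (initial value when optimized).
#' @param C_bounds,l_bounds optimization ranges.
#' @param white_noise fixed diagonal noise (standardized-target scale).
#' @param gamma fixed non-negative scale inside the Matern form.
#' @export
kernel_config <- function(kernel_form = c("Matern", "RBF",
                                          "RationalQuadratic"),
                          nu = 1.5, C = 1, length_scale = 1,
                          C_bounds = c(1e-3, 1e3),
                          l_bounds = c(1e-2, 1e2), white_noise = 0.05,
                          gamma = 1) {
  kernel_form <- match.arg(kernel_form)
  stopifnot(nu %in% c(0.5, 1.5, 2.5), white_noise >= 0, gamma >= 0,
            C_bounds[1] > 0, C_bounds[1] < C_bounds[2],
            l_bounds[1] > 0, l_bounds[1] < l_bounds[2])
  structure(list(kernel_form = kernel_form, nu = nu, C = C,
                 length_scale = length_scale, C_bounds = C_bounds,
                 l_bounds = l_bounds, white_noise = white_noise,
                 gamma = gamma),
            class = "kernel_config")
}

# base kernel value at scaled distances (matrix ok), without C or noise
.base_kernel <- function(d, cfg) {
  s <- cfg$gamma * d / cfg$length_scale
  switch(cfg$kernel_form,
         RBF = exp(-0.5 * s^2),
         RationalQuadratic = (1 + s^2 / 2)^(-1),
         Matern = switch(as.character(cfg$nu),
                         "0.5" = exp(-s),
                         "1.5" = (1 + sqrt(3) * s) * exp(-sqrt(3) * s),
                         "2.5" = (1 + sqrt(5) * s + 5 * s^2 / 3) *
                           exp(-sqrt(5) * s)))
}

#' Evaluate the combined kernel on two descriptor vectors
#'
#' C * M(x_i, x_j) plus the white-noise term when the two points are the
#' same data point (identical vectors).
#'
#' @param x_i,x_j descriptor vectors of equal dimension.
#' @param cfg a [kernel_config()].
#' @export
kernel_eval <- function(x_i, x_j, cfg = kernel_config()) {
  if (length(x_i) != length(x_j))
    stop("descriptor dimension mismatch: ", length(x_i), " vs ",
         length(x_j))
  d <- sqrt(sum((x_i - x_j)^2))
  v <- cfg$C * .base_kernel(d, cfg)
  if (isTRUE(all.equal(x_i, x_j, tolerance = 0))) v <- v + cfg$white_noise
  v
}

.dist_matrix <- function(X, Y = NULL) {
  if (is.null(Y)) as.matrix(stats::dist(X))
  else {
    xx <- rowSums(X^2); yy <- rowSums(Y^2)
    d2 <- outer(xx, yy, "+") - 2 * X %*% t(Y)
    sqrt(pmax(d2, 0))
  }
}

#' Full kernel matrix on a descriptor matrix (noise on the diagonal)
#' @param X descriptor matrix (rows = points).
#' @param cfg a [kernel_config()].
#' @export
kernel_matrix <- function(X, cfg = kernel_config()) {
  K <- cfg$C * .base_kernel(.dist_matrix(X), cfg)
  diag(K) <- diag(K) + cfg$white_noise
  K
}

# negative log marginal likelihood at (log C, log l)
.neg_lml <- function(par, D, ys, cfg) {
  cfg$C <- exp(par[1]); cfg$length_scale <- exp(par[2])
  K <- cfg$C * .base_kernel(D, cfg)
  diag(K) <- diag(K) + cfg$white_noise + 1e-10
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  0.5 * sum(ys * alpha) + sum(log(diag(L))) +
    0.5 * length(ys) * log(2 * pi)
}

#' Fit a Gaussian-process strength model
#'
#' Standardizes the targets, then maximizes the log marginal likelihood
#' over (C, l) on the log scale within the configured bounds, by
#' L-BFGS-B from `n_restarts` log-uniform starting points drawn under
#' `seed` (plus the configured start).  nu stays fixed.
#'
#' @param X descriptor matrix (rows = sites).
#' @param y target free energies, kJ/mol.
#' @param cfg a [kernel_config()].
#' @param role "HBA" or "HBD" (controls the applicability-domain
#'   threshold at prediction time).
#' @param seed RNG seed for the restarts.
#' @param n_restarts random restarts (default 5).
#' @param optimize set FALSE to keep the configured C and l.
#' @return object of class `hbgpr`.
#' @export
hbgpr <- function(X, y, cfg = kernel_config(), role = c("HBA", "HBD"),
                  seed = 1, n_restarts = 5, optimize = TRUE) {
  role <- match.arg(role)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (any(!is.finite(X))) stop("X contains non-finite values")
  ymean <- mean(y)
  yscale <- stats::sd(y)
  if (!is.finite(yscale) || yscale < 1e-12) yscale <- 1
  ys <- (y - ymean) / yscale
  D <- .dist_matrix(X)
  if (optimize) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    lb <- log(c(cfg$C_bounds[1], cfg$l_bounds[1]))
    ub <- log(c(cfg$C_bounds[2], cfg$l_bounds[2]))
    starts <- rbind(c(log(cfg$C), log(cfg$length_scale)),
                    matrix(stats::runif(2 * n_restarts, lb, ub),
                           ncol = 2, byrow = TRUE))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      opt <- tryCatch(
        stats::optim(starts[s, ], .neg_lml, D = D, ys = ys, cfg = cfg,
                     method = "L-BFGS-B", lower = lb, upper = ub),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value))
        best <- opt
    }
    if (is.null(best)) stop("hyperparameter optimization failed")
    cfg$C <- exp(best$par[1])
    cfg$length_scale <- exp(best$par[2])
    lml <- -best$value
  } else {
    lml <- -.neg_lml(c(log(cfg$C), log(cfg$length_scale)), D, ys, cfg)
  }
  K <- cfg$C * .base_kernel(D, cfg)
  diag(K) <- diag(K) + cfg$white_noise + 1e-10
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) {
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    stop(sprintf(
      "kernel matrix not positive definite despite noise (min eigenvalue %.3e, condition %.3e)",
      min(ev), max(ev) / max(min(ev), 1e-300)))
  }
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  structure(list(cfg = cfg, X = X, y = y, ymean = ymean,
                 yscale = yscale, L = L, alpha = alpha, role = role,
                 log_marginal_likelihood = lml),
            class = "hbgpr")
}

#' @export
print.hbgpr <- function(x, ...) {
  cat(sprintf(
    "<hbgpr> %s model: n = %d, p = %d; %s kernel (nu = %g), C = %.4g, l = %.4g, noise = %g\n",
    x$role, nrow(x$X), ncol(x$X), x$cfg$kernel_form, x$cfg$nu, x$cfg$C,
    x$cfg$length_scale, x$cfg$white_noise))
  cat(sprintf("  log marginal likelihood (standardized targets): %.3f\n",
              x$log_marginal_likelihood))
  invisible(x)
}

#' @export
summary.hbgpr <- function(object, ...) {
  print(object)
  pr <- predict(object, object$X)
  cat(sprintf(
    "  training-set RMSE %.3f kJ/mol, mean variance estimate %.3f kJ/mol\n",
    sqrt(mean((pr$mean - object$y)^2)), mean(pr$variance_estimate)))
  invisible(object)
}

#' @export
coef.hbgpr <- function(object, ...) {
  c(C = object$cfg$C, length_scale = object$cfg$length_scale,
    nu = object$cfg$nu, white_noise = object$cfg$white_noise,
    gamma = object$cfg$gamma)
}

#' Predict strengths with predictive-variance estimates
#'
#' @param object an [hbgpr()] model.
#' @param newdata query descriptor matrix.
#' @param ... unused.
#' @return data.frame: `mean` (kJ/mol), `sd` (posterior sd, kJ/mol),
#'   `variance_estimate` (1.96 * sd: the 95% interval half-width the
#'   applicability domain is gated on), `in_domain`.
#' @export
predict.hbgpr <- function(object, newdata, ...) {
  Xq <- as.matrix(newdata)
  if (ncol(Xq) != ncol(object$X))
    stop("query dimension ", ncol(Xq), " does not match training ",
         ncol(object$X))
  cfg <- object$cfg
  Ks <- cfg$C * .base_kernel(.dist_matrix(Xq, object$X), cfg)
  mu <- as.numeric(Ks %*% object$alpha)
  v <- backsolve(object$L, t(Ks), transpose = TRUE)
  kss <- cfg$C + cfg$white_noise
  var_s <- pmax(kss - colSums(v^2), 0)
  sd_kj <- sqrt(var_s) * object$yscale
  ve <- 1.96 * sd_kj
  data.frame(mean = mu * object$yscale + object$ymean, sd = sd_kj,
             variance_estimate = ve,
             in_domain = vapply(ve, function(x)
               ad_check(x, object$role) == "inside", logical(1)))
}

#' @export
residuals.hbgpr <- function(object, ...) {
  object$y - predict(object, object$X)$mean
}

#' Applicability-domain check on a variance estimate
#'
#' A prediction is outside the domain when its variance estimate
#' exceeds the role threshold: 4.2 kJ/mol for acceptors, 3.2 for donors
#' (the floors the training-set variance estimates fall to with full
#' data).  Boundary values are inside.
#'
#' @param variance_estimate 1.96 * posterior sd, kJ/mol.
#' @param role "HBA" or "HBD".
#' @param threshold optional override.
#' @return "inside" or "outside" (vectorized).
#' @export
ad_check <- function(variance_estimate, role = c("HBA", "HBD"),
                     threshold = NULL) {
  role <- match.arg(role)
  stopifnot(all(variance_estimate >= 0))
  if (is.null(threshold))
    threshold <- if (role == "HBA") 4.2 else 3.2
  ifelse(variance_estimate > threshold, "outside", "inside")
}

.metrics <- function(y, pred) {
  rmse <- sqrt(mean((y - pred$mean)^2))
  r2 <- 1 - sum((y - pred$mean)^2) / sum((y - mean(y))^2)
  sp <- suppressWarnings(stats::cor(y, pred$mean, method = "spearman"))
  data.frame(rmse = rmse, r2 = r2, spearman = sp,
             mean_variance_estimate = mean(pred$variance_estimate))
}

#' k-fold cross-validation of a GPR configuration
#'
#' Deterministic shuffled split under `seed`; per-fold fit/predict;
#' pooled metrics over the concatenated held-out predictions.
#'
#' @param X descriptor matrix.
#' @param y targets, kJ/mol.
#' @param cfg a [kernel_config()].
#' @param k folds (default 10).
#' @param seed RNG seed (fold shuffle and restarts).
#' @param role "HBA" or "HBD".
#' @param n_restarts restarts per fold fit.
#' @return list: `per_fold` (data.frame of metrics), `pooled`
#'   (one-row data.frame), `fold` (assignment vector).
#' @export
kfold_cv <- function(X, y, cfg = kernel_config(), k = 10, seed = 1,
                     role = "HBA", n_restarts = 2) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- length(y)
  if (n < k) stop("need at least k observations")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  preds <- data.frame(mean = numeric(n), sd = numeric(n),
                      variance_estimate = numeric(n),
                      in_domain = logical(n))
  per <- list()
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- hbgpr(X[tr, , drop = FALSE], y[tr], cfg, role = role,
                 seed = seed + f, n_restarts = n_restarts)
    pr <- predict(fit, X[!tr, , drop = FALSE])
    preds[!tr, ] <- pr
    per[[f]] <- .metrics(y[!tr], pr)
  }
  list(per_fold = do.call(rbind, per), pooled = .metrics(y, preds),
       fold = fold)
}

#' Learning curve over nested training fractions
#'
#' Fractions of the (seed-shuffled) data are nested: each fraction's
#' training set contains the previous one.  Metrics (including the mean
#' variance estimate) are evaluated on the training fraction itself,
#' tracking how the model's self-confidence evolves with data volume.
#'
#' @param X descriptor matrix.
#' @param y targets, kJ/mol.
#' @param cfg a [kernel_config()].
#' @param fractions training fractions (default 0.1 to 1.0 in 10%
#'   steps).
#' @param seed RNG seed.
#' @param role "HBA" or "HBD".
#' @param n_restarts restarts per fit.
#' @return data.frame: fraction, n, rmse, r2, spearman,
#'   mean_variance_estimate.
#' @export
learning_curve <- function(X, y, cfg = kernel_config(),
                           fractions = seq(0.1, 1.0, by = 0.1),
                           seed = 1, role = "HBA", n_restarts = 2) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- length(y)
  if (ceiling(min(fractions) * n) < 5)
    stop("smallest fraction yields fewer than 5 points")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- sample.int(n)
  rows <- list()
  for (f in fractions) {
    take <- perm[seq_len(ceiling(f * n))]
    fit <- hbgpr(X[take, , drop = FALSE], y[take], cfg, role = role,
                 seed = seed, n_restarts = n_restarts)
    pr <- predict(fit, X[take, , drop = FALSE])
    m <- .metrics(y[take], pr)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(fraction = f, n = length(take)), m)
  }
  do.call(rbind, rows)
}

#' Serialize a fitted GPR model
#'
#' Kernel configuration and hyperparameters go to `<path>.json`;
#' training data to `<path>_X.csv` / `<path>_y.csv` sidecars.
#'
#' @param model an [hbgpr()].
#' @param path basename (no extension).
#' @export
save_hbgpr <- function(model, path) {
  jsonlite::write_json(list(
    cfg = unclass(model$cfg), role = model$role, ymean = model$ymean,
    yscale = model$yscale,
    log_marginal_likelihood = model$log_marginal_likelihood),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(model$X, paste0(path, "_X.csv"), row.names = FALSE)
  utils::write.csv(data.frame(y = model$y), paste0(path, "_y.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Load a serialized GPR model
#' @param path basename used in [save_hbgpr()].
#' @export
load_hbgpr <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  cfg <- do.call(kernel_config, meta$cfg[c("kernel_form", "nu", "C",
                                           "length_scale", "C_bounds",
                                           "l_bounds", "white_noise",
                                           "gamma")])
  X <- as.matrix(utils::read.csv(paste0(path, "_X.csv")))
  y <- utils::read.csv(paste0(path, "_y.csv"))$y
  hbgpr(X, y, cfg, role = meta$role, optimize = FALSE)
}
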