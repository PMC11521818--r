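#' Huber loss
#'
#' \deqn{L_\delta(r) = r^2/2 \textrm{ for } |r| \le \delta;\quad
#'       \delta(|r| - \delta/2) \textrm{ otherwise.}}
#' Quadratic for small residuals, linear for large ones; continuous and
#' once-differentiable at the knot.
#'
#' @param residual numeric vector of residuals y - f(x).
#' @param delta transition point (> 0).
#' @return Loss values, same length as \code{residual}.
#' @export
#' @examples
#' huber_loss(3, 1)  # 2.5
huber_loss <- function(residual, delta) {
  if (!is.numeric(delta) || delta <= 0)
    chl_stop("chlorospec_domain_error", "delta must be > 0")
  ifelse(abs(residual) <= delta,
         0.5 * residual^2,
         delta * (abs(residual) - 0.5 * delta))
}

std_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv < 1e-12] <- 1
  list(mean = mu, sd = sdv)
}
std_apply <- function(X, s) sweep(sweep(X, 2, s$mean), 2, s$sd, "/")

as_X <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X)))
    chl_stop("chlorospec_input_error", "X must be a finite numeric matrix")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

check_newdata <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$feature_names))
    chl_stop("chlorospec_input_error",
             sprintf("expected %d feature columns, got %d",
                     length(model$feature_names), ncol(X)))
  colnames(X) <- model$feature_names
  X
}

new_chl_model <- function(preset, state, feature_names, training_summary,
                          scaling = NULL) {
  structure(list(preset = preset, state = state,
                 feature_names = feature_names, scaling = scaling,
                 training_summary = training_summary),
            class = c(paste0("chl_", preset), "chl_model"))
}

#' @export
print.chl_model <- function(x, ...) {
  cat(sprintf("chlorospec model '%s' on %d feature(s)\n", x$preset,
              length(x$feature_names)))
  ts <- x$training_summary
  if (!is.null(ts$iterations))
    cat(sprintf("  iterations: %s, converged: %s\n", ts$iterations,
                isTRUE(ts$converged)))
  invisible(x)
}

#' Huber robust linear regression by IRLS
#'
#' Fits a linear model minimizing the summed Huber loss via iteratively
#' reweighted least squares (weights 1 for |r| <= delta, delta/|r| beyond).
#' When \code{delta} is NULL the transition point is re-estimated each
#' iteration as 1.345 times a median-absolute-deviation residual scale,
#' giving ~95% efficiency under Gaussian noise.
#'
#' @param X samples x features matrix (n > p).
#' @param y response vector.
#' @param delta fixed Huber transition point, or NULL for the adaptive
#'   MAD-based choice.
#' @param max_iterations,tolerance IRLS stopping controls (maximum
#'   coefficient change below \code{tolerance} counts as converged).
#' @return A \code{chl_model} with coefficients in
#'   \code{state$coefficients} (intercept first).
#' @export
fit_robust_linear <- function(X, y, delta = NULL, max_iterations = 100,
                              tolerance = 1e-8) {
  X <- as_X(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1)
    chl_stop("chlorospec_input_error", "need n > p + 1 samples")
  Xd <- cbind(`(Intercept)` = 1, X)
  if (qr(Xd)$rank < ncol(Xd))
    chl_stop("chlorospec_decomposition_error", "singular design matrix")
  beta <- qr.solve(Xd, y)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iterations)) {
    iter <- it
    r <- y - drop(Xd %*% beta)
    d <- if (is.null(delta)) {
      s <- stats::mad(r, center = 0)
      if (s < 1e-12) s <- max(1e-12, stats::sd(r))
      1.345 * s
    } else delta
    w <- ifelse(abs(r) <= d, 1, d / pmax(abs(r), 1e-300))
    fit <- stats::lm.wfit(Xd, y, w)
    new_beta <- fit$coefficients
    if (max(abs(new_beta - beta)) < tolerance) {
      beta <- new_beta; converged <- TRUE; break
    }
    beta <- new_beta
  }
  new_chl_model("robust_linear",
                state = list(coefficients = beta, delta = delta),
                feature_names = colnames(X),
                training_summary = list(iterations = iter,
                                        converged = converged))
}

#' @export
predict.chl_robust_linear <- function(object, newdata, ...) {
  X <- check_newdata(object, newdata)
  drop(cbind(1, X) %*% object$state$coefficients)
}

#' Stepwise linear regression with interaction terms
#'
#' Builds a term set over main effects and pairwise interactions by
#' partial-F p-value stepping: terms enter when p < \code{p_enter} and
#' leave when p > \code{p_remove}. The bidirectional strategy (default)
#' starts from all linear terms, as does backward; forward starts from the
#' intercept-only model. Interactions are only eligible while both parents
#' are in the model, and main effects marginal to a retained interaction
#' are never dropped.
#'
#' @param X samples x features matrix.
#' @param y response vector.
#' @param direction \code{"bidirectional"} (default), \code{"forward"} or
#'   \code{"backward"}.
#' @param p_enter,p_remove entry/removal p-value thresholds; must satisfy
#'   \code{p_enter < p_remove}.
#' @param max_steps maximum number of add/remove steps; 0 returns the
#'   starting model untouched.
#' @return A \code{chl_model}; selected terms in
#'   \code{training_summary$selected_terms}.
#' @export
fit_stepwise <- function(X, y, direction = c("bidirectional", "forward",
                                             "backward"),
                         p_enter = 0.05, p_remove = 0.10, max_steps = 1000) {
  direction <- match.arg(direction)
  if (p_enter >= p_remove)
    chl_stop("chlorospec_config_error", "p_enter must be < p_remove")
  X <- as_X(X)
  nms <- make.names(colnames(X), unique = TRUE)
  df <- as.data.frame(X); names(df) <- nms
  df$.y <- y
  mains <- nms
  inters <- if (length(nms) >= 2)
    utils::combn(nms, 2, FUN = function(v) paste(v, collapse = ":")) else character(0)
  start_formula <- if (direction == "forward") ".y ~ 1"
    else paste(".y ~", paste(mains, collapse = " + "))
  fit <- stats::lm(stats::as.formula(start_formula), data = df)
  steps <- 0L
  trace <- character(0)
  term_parents <- function(tm) strsplit(tm, ":", fixed = TRUE)[[1]]
  repeat {
    if (steps >= max_steps) break
    current <- attr(stats::terms(fit), "term.labels")
    changed <- FALSE
    if (direction %in% c("bidirectional", "backward") && length(current)) {
      # droppable: not marginal to a retained interaction
      kept_inters <- current[grepl(":", current)]
      protected <- unique(unlist(lapply(kept_inters, term_parents)))
      droppable <- setdiff(current, protected)
      if (length(droppable)) {
        dr <- stats::drop1(fit, scope = stats::as.formula(
          paste("~", paste(droppable, collapse = " + "))), test = "F")
        pv <- dr[["Pr(>F)"]][-1]
        if (length(pv) && any(!is.na(pv)) && max(pv, na.rm = TRUE) > p_remove) {
          worst <- droppable[which.max(pv)]
          fit <- stats::update(fit, stats::as.formula(paste(". ~ . -", worst)))
          steps <- steps + 1L
          trace <- c(trace, paste("-", worst))
          changed <- TRUE
        }
      }
    }
    if (!changed && direction %in% c("bidirectional", "forward")) {
      current <- attr(stats::terms(fit), "term.labels")
      cand_main <- setdiff(mains, current)
      cand_int <- inters[!inters %in% current &
                           vapply(inters, function(tm)
                             all(term_parents(tm) %in% current), logical(1))]
      candidates <- c(cand_main, cand_int)
      if (length(candidates)) {
        ad <- stats::add1(fit, scope = stats::as.formula(
          paste("~ . +", paste(candidates, collapse = " + "))), test = "F")
        pv <- ad[["Pr(>F)"]][-1]
        if (length(pv) && any(!is.na(pv)) && min(pv, na.rm = TRUE) < p_enter) {
          best <- candidates[which.min(pv)]
          fit <- stats::update(fit, stats::as.formula(paste(". ~ . +", best)))
          steps <- steps + 1L
          trace <- c(trace, paste("+", best))
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  new_chl_model("stepwise_linear",
                state = list(fit = fit, term_names = nms),
                feature_names = colnames(X),
                training_summary = list(
                  iterations = steps, converged = steps < max_steps,
                  selected_terms = attr(stats::terms(fit), "term.labels"),
                  trace = trace))
}

#' @export
predict.chl_stepwise_linear <- function(object, newdata, ...) {
  X <- check_newdata(object, newdata)
  nd <- as.data.frame(X)
  names(nd) <- object$state$term_names
  unname(stats::predict(object$state$fit, newdata = nd))
}

#' Gaussian (RBF) kernel
#'
#' \deqn{K(x, y) = \exp(-\|x-y\|^2 / (2\sigma^2))}
#' 1 at x = y, strictly decreasing in distance, symmetric.
#'
#' @param x,y feature vectors of equal dimension.
#' @param sigma bandwidth (> 0).
#' @return Similarity in (0, 1\].
#' @export
kernel_gaussian <- function(x, y, sigma) {
  if (length(x) != length(y))
    chl_stop("chlorospec_input_error", "x and y must have equal dimension")
  if (sigma <= 0) chl_stop("chlorospec_domain_error", "sigma must be > 0")
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

#' Matern 5/2 covariance
#'
#' \deqn{k(r) = \sigma (1 + \sqrt5 r/l + 5r^2/(3l^2)) \exp(-\sqrt5 r/l)}
#' where \eqn{\sigma} is the kernel value at r = 0 (variance scale), l the
#' length scale and r the distance. Positive, monotone decreasing, -> 0 as
#' r -> Inf; sample paths of the corresponding GP are twice differentiable.
#'
#' @param r distance(s), >= 0.
#' @param sigma variance scale (> 0).
#' @param length_scale length scale l (> 0).
#' @return Covariance values.
#' @export
#' @examples
#' kernel_matern52(1, 1, 1)  # ~0.524
kernel_matern52 <- function(r, sigma = 1, length_scale = 1) {
  if (any(r < 0)) chl_stop("chlorospec_domain_error", "r must be >= 0")
  if (sigma <= 0 || length_scale <= 0)
    chl_stop("chlorospec_domain_error", "sigma and length_scale must be > 0")
  u <- sqrt(5) * r / length_scale
  sigma * (1 + u + u^2 / 3) * exp(-u)
}

# "Auto" SVR settings: box constraint from the response spread
# (IQR/1.349, a robust sigma estimate), epsilon a tenth of that.
svr_auto <- function(y) {
  s <- stats::IQR(y) / 1.349
  if (s <= 0) s <- max(stats::sd(y), 1e-6)
  list(cost = s, epsilon = s / 10)
}

#' Epsilon-insensitive support vector regression
#'
#' Quadratic-polynomial or Gaussian-kernel eps-SVR with automatic box
#' constraint and tube width derived from the response spread (box =
#' IQR(y)/1.349, epsilon = box/10), features standardized before fitting.
#' The Gaussian preset stores its fixed kernel scale (default 0.83),
#' plugged into the kernel form exp(-d^2/(2 s^2)). Backed by
#' \code{e1071::svm}.
#'
#' @param X samples x features matrix.
#' @param y response vector.
#' @param kernel \code{"quadratic"} or \code{"fine_gaussian"}.
#' @param kernel_scale Gaussian kernel scale s (fine_gaussian only).
#' @param cost,epsilon override the automatic box constraint / tube width.
#' @param standardize z-score the features (default TRUE).
#' @return A \code{chl_model}.
#' @export
fit_svr <- function(X, y, kernel = c("quadratic", "fine_gaussian"),
                    kernel_scale = 0.83, cost = NULL, epsilon = NULL,
                    standardize = TRUE) {
  kernel <- match.arg(kernel)
  X <- as_X(X)
  if (any(!is.finite(y)))
    chl_stop("chlorospec_input_error", "non-finite response")
  scaling <- if (standardize) std_fit(X) else NULL
  Xs <- if (standardize) std_apply(X, scaling) else X
  auto <- svr_auto(y)
  if (is.null(cost)) cost <- auto$cost
  if (is.null(epsilon)) epsilon <- auto$epsilon
  fit <- tryCatch({
    if (kernel == "quadratic") {
      e1071::svm(Xs, y, type = "eps-regression", kernel = "polynomial",
                 degree = 2, gamma = 1, coef0 = 1, cost = cost,
                 epsilon = epsilon, scale = FALSE)
    } else {
      e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                 gamma = 1 / (2 * kernel_scale^2), cost = cost,
                 epsilon = epsilon, scale = FALSE)
    }
  }, error = function(e) {
    if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) NULL
    else stop(e)
  })
  preset <- if (kernel == "quadratic") "svm_quadratic" else "svm_fine_gaussian"
  # a tube wider than the response spread leaves no support vectors; the
  # flat (mean) predictor is then the eps-SVR solution
  constant <- if (is.null(fit)) mean(y) else NULL
  new_chl_model(preset,
                state = list(svm = fit, constant = constant,
                             kernel_scale = if (kernel == "fine_gaussian")
                               kernel_scale else NA_real_,
                             cost = cost, epsilon = epsilon),
                feature_names = colnames(X), scaling = scaling,
                training_summary = list(
                  n_support_vectors = if (is.null(fit)) 0L else fit$tot.nSV,
                  converged = TRUE))
}

#' @export
predict.chl_svm_quadratic <- function(object, newdata, ...) {
  X <- check_newdata(object, newdata)
  if (!is.null(object$state$constant))
    return(rep(object$state$constant, nrow(X)))
  if (!is.null(object$scaling)) X <- std_apply(X, object$scaling)
  unname(stats::predict(object$state$svm, X))
}

#' @export
predict.chl_svm_fine_gaussian <- predict.chl_svm_quadratic

matern_K <- function(D, s, l) {
  u <- sqrt(5) * D / l
  s * (1 + u + u^2 / 3) * exp(-u)
}

gpr_nll <- function(theta, D, y, fixed_noise, jitter) {
  s <- exp(theta[1]); l <- exp(theta[2])
  vn <- if (is.null(fixed_noise)) exp(theta[3]) else fixed_noise
  n <- length(y)
  K <- matern_K(D, s, l) + diag(vn + jitter, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  ones <- rep(1, n)
  Kinv_y <- backsolve(L, forwardsolve(t(L), y))
  Kinv_1 <- backsolve(L, forwardsolve(t(L), ones))
  cmean <- sum(ones * Kinv_y) / sum(ones * Kinv_1)
  r <- y - cmean
  alpha <- backsolve(L, forwardsolve(t(L), r))
  nll <- 0.5 * sum(r * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  if (!is.finite(nll)) 1e10 else nll
}

#' Exact Gaussian process regression with a Matern 5/2 kernel
#'
#' Constant mean basis (estimated by generalized least squares under the
#' kernel), isotropic Matern 5/2 covariance, Gaussian observation noise.
#' Kernel variance, length scale and noise variance are optimized by
#' maximizing the log marginal likelihood (quasi-Newton on log parameters,
#' multiple seeded restarts from data-driven initializations, escalating
#' diagonal jitter on Cholesky failure). Features and response are
#' standardized internally.
#'
#' @param X samples x features matrix.
#' @param y response vector.
#' @param noise fixed observation-noise variance (on the standardized
#'   response scale), or NULL to optimize it; 0 gives jitter-only
#'   interpolation.
#' @param n_restarts optimizer restarts (default 3).
#' @param jitter initial diagonal stabilizer; escalated up to 1e-6.
#' @param seed RNG seed for the restart draws.
#' @return A \code{chl_model}; \code{predict()} returns the posterior mean,
#'   and \code{predict(..., se = TRUE)} a list with mean and predictive SD.
#' @export
fit_gpr <- function(X, y, noise = NULL, n_restarts = 3, jitter = 1e-12,
                    seed = 1) {
  X <- as_X(X)
  n <- nrow(X)
  if (n < 2) chl_stop("chlorospec_input_error", "need at least 2 samples")
  scaling <- std_fit(X)
  Xs <- std_apply(X, scaling)
  y_mu <- mean(y); y_sd <- max(sd(y), 1e-12)
  ys <- (y - y_mu) / y_sd
  D <- as.matrix(stats::dist(Xs))
  med_d <- stats::median(D[upper.tri(D)])
  if (!is.finite(med_d) || med_d <= 0) med_d <- 1
  fixed_noise <- noise
  base_init <- c(log(1), log(med_d),
                 if (is.null(fixed_noise)) log(0.1) else NULL)
  inits <- with_seed(seed, {
    c(list(base_init),
      lapply(seq_len(max(0, n_restarts - 1)), function(i)
        base_init + rnorm(length(base_init), sd = 1)))
  })
  best <- NULL
  for (jit in c(jitter, 1e-10, 1e-8, 1e-6)) {
    for (init in inits) {
      opt <- tryCatch(
        stats::optim(init, gpr_nll, D = D, y = ys, fixed_noise = fixed_noise,
                     jitter = jit, method = "L-BFGS-B",
                     lower = rep(-15, length(init)),
                     upper = rep(10, length(init)),
                     control = list(maxit = 200)),
        error = function(e) NULL)
      if (!is.null(opt) && opt$value < 1e9 &&
          (is.null(best) || opt$value < best$value)) {
        best <- opt; best$jitter <- jit
        best$init_nll <- gpr_nll(init, D, ys, fixed_noise, jit)
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best))
    chl_stop("chlorospec_conditioning_error",
             "GPR covariance not positive definite after jitter escalation")
  s <- exp(best$par[1]); l <- exp(best$par[2])
  vn <- if (is.null(fixed_noise)) exp(best$par[3]) else fixed_noise
  K <- matern_K(D, s, l) + diag(vn + best$jitter, n)
  L <- chol(K)
  ones <- rep(1, n)
  Kinv_y <- backsolve(L, forwardsolve(t(L), ys))
  Kinv_1 <- backsolve(L, forwardsolve(t(L), ones))
  cmean <- sum(ones * Kinv_y) / sum(ones * Kinv_1)
  alpha <- backsolve(L, forwardsolve(t(L), ys - cmean))
  new_chl_model("gpr_matern52",
                state = list(Xs = Xs, L = L, alpha = alpha, cmean = cmean,
                             sigma = s, length_scale = l, noise = vn,
                             jitter = best$jitter,
                             y_mu = y_mu, y_sd = y_sd),
                feature_names = colnames(X), scaling = scaling,
                training_summary = list(
                  nll = best$value, init_nll = best$init_nll,
                  iterations = best$counts[["function"]],
                  converged = best$convergence == 0))
}

#' @export
predict.chl_gpr_matern52 <- function(object, newdata, se = FALSE, ...) {
  X <- check_newdata(object, newdata)
  st <- object$state
  Xs <- std_apply(X, object$scaling)
  # cross-distances to training inputs
  Dx <- sqrt(pmax(outer(rowSums(Xs^2), rowSums(st$Xs^2), "+") -
                    2 * Xs %*% t(st$Xs), 0))
  Ks <- matern_K(Dx, st$sigma, st$length_scale)
  mu_s <- st$cmean + drop(Ks %*% st$alpha)
  mu <- st$y_mu + st$y_sd * mu_s
  if (!se) return(mu)
  v <- backsolve(st$L, forwardsolve(t(st$L), t(Ks)))
  var_lat <- pmax(0, st$sigma - colSums(v^2))
  list(mean = mu, sd = st$y_sd * sqrt(var_lat + st$noise))
}

nn_unpack <- function(theta, sizes) {
  out <- list(); pos <- 0L
  for (i in seq_len(length(sizes) - 1)) {
    nin <- sizes[i]; nout <- sizes[i + 1]
    W <- matrix(theta[pos + seq_len(nin * nout)], nin, nout); pos <- pos + nin * nout
    b <- theta[pos + seq_len(nout)]; pos <- pos + nout
    out[[i]] <- list(W = W, b = b)
  }
  out
}

nn_forward <- function(layers, X) {
  A <- X
  acts <- list(A)
  nl <- length(layers)
  for (i in seq_len(nl)) {
    Z <- sweep(A %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    A <- if (i < nl) pmax(Z, 0) else Z   # ReLU hidden, linear output
    acts[[i + 1]] <- A
  }
  list(pred = drop(A), acts = acts)
}

nn_obj_grad <- function(theta, sizes, X, y, lambda) {
  layers <- nn_unpack(theta, sizes)
  fw <- nn_forward(layers, X)
  n <- nrow(X)
  r <- fw$pred - y
  loss <- 0.5 * mean(r^2) +
    0.5 * lambda * sum(vapply(layers, function(l) sum(l$W^2), numeric(1)))
  delta <- matrix(r / n, ncol = 1)
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    A_prev <- fw$acts[[i]]
    gW <- t(A_prev) %*% delta + lambda * layers[[i]]$W
    gb <- colSums(delta)
    grads[[i]] <- list(W = gW, b = gb)
    if (i > 1) {
      delta <- (delta %*% t(layers[[i]]$W)) * (fw$acts[[i]] > 0)
    }
  }
  g <- unlist(lapply(grads, function(gr) c(as.vector(gr$W), gr$b)))
  list(value = loss, gradient = g)
}

#' Three-hidden-layer ReLU regression network
#'
#' Fully connected network with three hidden layers (default 20-20-20 ReLU
#' units) and a linear output, trained full-batch with a quasi-Newton
#' optimizer (L-BFGS-B) on the mean squared error plus an optional L2
#' penalty (default lambda = 0). Seeded He-style initialization makes
#' training deterministic; optimization stops at \code{iteration_limit} or
#' on convergence. Inputs and response are standardized internally.
#'
#' @param X samples x features matrix (n >= 10).
#' @param y response vector.
#' @param layer_sizes hidden layer widths (default \code{c(20, 20, 20)}).
#' @param iteration_limit optimizer iteration cap (default 1000).
#' @param lambda L2 regularization strength (default 0).
#' @param seed initialization seed.
#' @return A \code{chl_model}.
#' @export
fit_trilayer_nn <- function(X, y, layer_sizes = c(20, 20, 20),
                            iteration_limit = 1000, lambda = 0, seed = 1) {
  X <- as_X(X)
  if (any(!is.finite(y)))
    chl_stop("chlorospec_input_error", "non-finite response")
  if (nrow(X) < 10)
    chl_stop("chlorospec_input_error", "need at least 10 samples")
  scaling <- std_fit(X)
  Xs <- std_apply(X, scaling)
  y_mu <- mean(y); y_sd <- max(sd(y), 1e-12)
  ys <- (y - y_mu) / y_sd
  sizes <- c(ncol(X), layer_sizes, 1L)
  n_par <- sum((sizes[-length(sizes)] + 1) * sizes[-1])
  theta0 <- with_seed(seed, {
    th <- numeric(0)
    for (i in seq_len(length(sizes) - 1)) {
      nin <- sizes[i]; nout <- sizes[i + 1]
      th <- c(th, rnorm(nin * nout, sd = sqrt(2 / nin)), rep(0, nout))
    }
    th
  })
  stopifnot(length(theta0) == n_par)
  fn <- function(th) nn_obj_grad(th, sizes, Xs, ys, lambda)$value
  gr <- function(th) nn_obj_grad(th, sizes, Xs, ys, lambda)$gradient
  opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = iteration_limit,
                                     factr = 1e4))
  new_chl_model("trilayer_nn",
                state = list(theta = opt$par, sizes = sizes,
                             y_mu = y_mu, y_sd = y_sd, lambda = lambda),
                feature_names = colnames(X), scaling = scaling,
                training_summary = list(
                  iterations = min(opt$counts[["gradient"]], iteration_limit),
                  converged = opt$convergence == 0,
                  final_loss = opt$value))
}

#' @export
predict.chl_trilayer_nn <- function(object, newdata, ...) {
  X <- check_newdata(object, newdata)
  Xs <- std_apply(X, object$scaling)
  layers <- nn_unpack(object$state$theta, object$state$sizes)
  object$state$y_mu + object$state$y_sd * nn_forward(layers, Xs)$pred
}

#' Fit one of the six model presets
#'
#' Dispatcher over the model families with their default hyper-parameters:
#' \code{robust_linear} (Huber IRLS), \code{stepwise_linear} (partial-F,
#' interactions allowed, up to 1000 steps), \code{svm_quadratic} and
#' \code{svm_fine_gaussian} (eps-SVR, automatic box/epsilon, Gaussian
#' kernel scale 0.83), \code{gpr_matern52} (constant mean, isotropic
#' Matern 5/2, marginal-likelihood optimization) and \code{trilayer_nn}
#' (3 x 20 ReLU units, iteration limit 1000, lambda 0).
#'
#' @param preset model family name (see above).
#' @param X samples x features matrix.
#' @param y response vector.
#' @param seed seed for the stochastic initializers (GPR restarts, network
#'   init).
#' @param ... passed on to the specific \code{fit_*} function.
#' @return A \code{chl_model}.
#' @export
fit_model <- function(preset, X, y, seed = 1, ...) {
  switch(preset,
         robust_linear = fit_robust_linear(X, y, ...),
         stepwise_linear = fit_stepwise(X, y, ...),
         svm_quadratic = fit_svr(X, y, kernel = "quadratic", ...),
         svm_fine_gaussian = fit_svr(X, y, kernel = "fine_gaussian", ...),
         gpr_matern52 = fit_gpr(X, y, seed = seed, ...),
         trilayer_nn = fit_trilayer_nn(X, y, seed = seed, ...),
         chl_stop("chlorospec_config_error", paste("unknown preset:", preset)))
}

#' The six model preset names
#' @return Character vector of preset identifiers.
#' @export
model_presets <- function() {
  c("robust_linear", "stepwise_linear", "svm_quadratic",
    "svm_fine_gaussian", "gpr_matern52", "trilayer_nn")
}
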