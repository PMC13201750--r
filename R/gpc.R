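## Expectation-propagation Gaussian process classification with a probit
## likelihood and an anisotropic squared-exponential kernel. Parallel EP
## with damping: all site approximations are updated from the current
## marginals, then the Gaussian posterior is recomputed by one Cholesky
## factorization per sweep. Numerically this follows the standard
## B = I + sW K sW parameterization, which stays stable as site precisions
## tend to zero.

## anisotropic squared-exponential kernel matrix
se_kernel <- function(X1, X2, loglen, logsf) {
  s1 <- sweep(X1, 2L, exp(loglen), `/`)
  s2 <- sweep(X2, 2L, exp(loglen), `/`)
  d2 <- outer(rowSums(s1^2), rowSums(s2^2), `+`) - 2 * tcrossprod(s1, s2)
  exp(2 * logsf) * exp(-0.5 * pmax(d2, 0))
}

## log of the standard normal hazard-like ratio phi(z)/Phi(z), stable for
## very negative z
erf_ratio <- function(z) exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))

## core EP loop; K must include jitter. Returns site parameters, posterior
## factors and the EP log marginal likelihood.
ep_fit <- function(K, y, maxit = 80, tol = 1e-6, damping = 0.7, warm = NULL) {
  n <- length(y)
  ttau <- warm$ttau %||% rep(0, n)
  tnu <- warm$tnu %||% rep(0, n)
  Kdiag <- diag(K)
  post <- function(ttau, tnu) {
    sW <- sqrt(pmax(ttau, 0))
    B <- diag(n) + (sW %o% sW) * K
    U <- chol(B)
    V <- backsolve(U, sW * K, transpose = TRUE)   # solves t(U) V = sW*K
    sdiag <- pmax(Kdiag - colSums(V^2), 1e-10)
    mu <- drop(K %*% tnu - crossprod(V, V %*% tnu))
    list(sW = sW, U = U, sdiag = sdiag, mu = mu)
  }
  p <- post(ttau, tnu)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    tau_n <- pmax(1 / p$sdiag - ttau, 1e-12)     # cavity precisions
    nu_n <- p$mu / p$sdiag - tnu
    s2 <- 1 / tau_n
    m <- nu_n * s2
    z <- y * m / sqrt(1 + s2)
    r <- erf_ratio(z)
    mhat <- m + y * s2 * r / sqrt(1 + s2)
    vhat <- pmax(s2 - s2^2 * r * (z + r) / (1 + s2), 1e-10)
    ttau_new <- pmax(1 / vhat - tau_n, 0)
    tnu_new <- mhat / vhat - nu_n
    dmax <- max(abs(ttau_new - ttau), abs(tnu_new - tnu))
    ttau <- (1 - damping) * ttau + damping * ttau_new
    tnu <- (1 - damping) * tnu + damping * tnu_new
    p <- post(ttau, tnu)
    if (dmax < tol) { converged <- TRUE; break }
  }
  ## EP log marginal likelihood from the converged sites
  tau_n <- pmax(1 / p$sdiag - ttau, 1e-12)
  nu_n <- p$mu / p$sdiag - tnu
  s2 <- 1 / tau_n
  m <- nu_n * s2
  z <- y * m / sqrt(1 + s2)
  lZhat <- stats::pnorm(z, log.p = TRUE)
  stau <- pmax(ttau, 1e-10)
  mu_s <- tnu / stau
  sig2_s <- 1 / stau
  term_site <- lZhat -
    (-0.5 * log(2 * pi * (s2 + sig2_s)) - (mu_s - m)^2 / (2 * (s2 + sig2_s)))
  b <- p$sW * mu_s
  quad <- sum(backsolve(p$U, b, transpose = TRUE)^2)
  logdet <- 2 * sum(log(diag(p$U))) - sum(log(stau))
  term_gauss <- -0.5 * (n * log(2 * pi) + logdet + quad)
  logZ <- sum(term_site) + term_gauss
  list(ttau = ttau, tnu = tnu, sW = p$sW, U = p$U, mu = p$mu,
       sdiag = p$sdiag, logZ = logZ, converged = converged, iters = it)
}

## prediction factors reusable across query batches
ep_predict_factors <- function(K, fit) {
  w <- fit$sW * drop(K %*% fit$tnu)
  v <- backsolve(fit$U, backsolve(fit$U, w, transpose = TRUE))
  list(alpha = fit$tnu - fit$sW * v, sW = fit$sW, U = fit$U)
}

#' GPC fitting configuration
#'
#' @param optimize optimize kernel hyperparameters by maximizing the EP
#'   approximation to the log marginal likelihood (Nelder-Mead on log
#'   lengthscales and log signal sd).
#' @param restarts number of optimizer starts (first from the default
#'   initial values, the rest from seeded perturbations).
#' @param maxit Nelder-Mead iteration budget per restart.
#' @param epMaxit,epTol,damping EP sweep budget, convergence tolerance on
#'   site natural parameters, and damping factor.
#' @param jitter relative diagonal jitter added to the kernel matrix.
#' @param loglen,logsf initial (or fixed, when `optimize = FALSE`) log
#'   lengthscales per standardized feature and log signal sd.
#' @param seed integer seed controlling restart perturbations.
#' @return List of class `gpcConfig`.
#' @export
gpcConfig <- function(optimize = TRUE, restarts = 2L, maxit = 40L,
                      epMaxit = 80L, epTol = 1e-6, damping = 0.7,
                      jitter = 1e-6, loglen = 0, logsf = log(1.5),
                      seed = 1L) {
  structure(list(optimize = optimize, restarts = as.integer(restarts),
                 maxit = as.integer(maxit), epMaxit = as.integer(epMaxit),
                 epTol = epTol, damping = damping, jitter = jitter,
                 loglen = loglen, logsf = logsf, seed = as.integer(seed)),
            class = "gpcConfig")
}

feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    cols <- intersect(c("x_mm", "y_mm", "ms_angle", "acpc_angle"),
                      names(features))
    if (length(cols) < 2L) cols <- names(features)[vapply(features, is.numeric, TRUE)]
    features <- as.matrix(features[, cols, drop = FALSE])
  }
  storage.mode(features) <- "double"
  features
}

#' Train a Gaussian process engagement classifier
#'
#' Fits a binary GP classifier with probit likelihood by expectation
#' propagation on the (standardized) trajectory features. One model is
#' trained per target region; SNr-engagement and SNc-engagement classifiers
#' are independent. Hyperparameters (per-feature lengthscales and signal
#' sd) are chosen by maximizing the EP log marginal likelihood unless
#' `config$optimize` is `FALSE`. Deterministic given the config seed.
#'
#' @param features `data.frame` (columns `x_mm`, `y_mm`, `ms_angle`,
#'   `acpc_angle`) or numeric matrix.
#' @param labels logical (or 0/1) engagement labels for the target region.
#' @param target region name the labels refer to ("SNr" or "SNc").
#' @param config a [gpcConfig()].
#' @return A [GpcModel-class].
#' @export
trainGpc <- function(features, labels, target = "SNr", config = gpcConfig()) {
  X <- feature_matrix(features)
  y <- ifelse(as.logical(labels), 1, -1)
  if (any(!is.finite(X))) stop("features contain non-finite values")
  if (length(unique(y)) < 2L)
    stop("labels contain a single class; need both engaged and non-engaged examples")
  if (min(table(y)) < 2L) stop("need at least 2 examples per class")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  d <- ncol(Xs)
  loglen0 <- rep(config$loglen, length.out = d)

  warm <- new.env(parent = emptyenv())
  objective <- function(theta) {
    if (any(theta[1:d] < log(0.05)) || any(theta[1:d] > log(50)) ||
        theta[d + 1L] < log(0.1) || theta[d + 1L] > log(20)) return(1e8)
    K <- se_kernel(Xs, Xs, theta[1:d], theta[d + 1L])
    diag(K) <- diag(K) * (1 + config$jitter) + 1e-8
    fit <- ep_fit(K, y, maxit = config$epMaxit, tol = config$epTol,
                  damping = config$damping, warm = warm$site)
    warm$site <- fit[c("ttau", "tnu")]
    -fit$logZ
  }

  theta0 <- c(loglen0, config$logsf)
  if (config$optimize) {
    set.seed(config$seed)
    starts <- list(theta0)
    if (config$restarts > 1L)
      for (r in seq_len(config$restarts - 1L))
        starts[[r + 1L]] <- theta0 + stats::rnorm(d + 1L, 0, 0.5)
    best <- NULL
    for (s in starts) {
      warm$site <- NULL
      o <- stats::optim(s, objective, method = "Nelder-Mead",
                        control = list(maxit = config$maxit, reltol = 1e-4))
      if (is.null(best) || o$value < best$value) best <- o
    }
    theta <- best$par
  } else {
    theta <- theta0
  }

  K <- se_kernel(Xs, Xs, theta[1:d], theta[d + 1L])
  diag(K) <- diag(K) * (1 + config$jitter) + 1e-8
  fit <- ep_fit(K, y, maxit = config$epMaxit, tol = config$epTol,
                damping = config$damping)
  pf <- ep_predict_factors(K, fit)
  new("GpcModel", X = Xs, y = y, center = ctr, scaleSd = scl,
      hyper = list(loglen = theta[1:d], logsf = theta[d + 1L]),
      site = fit[c("ttau", "tnu")],
      post = list(alpha = pf$alpha, sW = pf$sW, U = pf$U),
      target = target, logZ = fit$logZ, config = unclass(config))
}

#' Predicted engagement probabilities
#'
#' Evaluates the EP predictive distribution at new feature vectors and
#' returns the probability of engagement (the positive class). Far from all
#' training data the prediction reverts to the GP prior, probability 0.5.
#'
#' @param model a [GpcModel-class].
#' @param newdata `data.frame` or matrix of features on the original scale.
#' @param chunk number of query points per prediction block.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predictGpc <- function(model, newdata, chunk = 4000L) {
  Xq <- feature_matrix(newdata)
  Xq <- sweep(sweep(Xq, 2L, model@center), 2L, model@scaleSd, `/`)
  n <- nrow(Xq)
  out <- numeric(n)
  sf2 <- exp(2 * model@hyper$logsf)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    Ks <- se_kernel(Xq[s:e, , drop = FALSE], model@X,
                    model@hyper$loglen, model@hyper$logsf)
    fmean <- drop(Ks %*% model@post$alpha)
    Vs <- backsolve(model@post$U, model@post$sW * t(Ks), transpose = TRUE)
    fvar <- pmax(sf2 - colSums(Vs^2), 1e-12)
    out[s:e] <- stats::pnorm(fmean / sqrt(1 + fvar))
  }
  out
}

#' @describeIn predictGpc `predict` method; `type` is ignored (probabilities
#'   are always returned).
#' @param object a [GpcModel-class].
#' @param ... passed to `predictGpc`.
#' @export
setMethod("predict", "GpcModel", function(object, newdata, ...)
  predictGpc(object, newdata, ...))
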