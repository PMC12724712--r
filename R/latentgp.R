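## Latent Gaussian-process model of ongoing binned counts: periodic kernel,
## scaled SoftPlus link, generalized Poisson observations with a small
## uniform contamination. Hyperparameters are fitted by maximizing a
## Laplace-approximate marginal likelihood (type-II) with Gaussian log-prior
## penalties on the periodic lengthscale and the dispersion.

#' Periodic covariance kernel
#'
#' \deqn{k(t, t') = \sigma^2 \exp\{-2 \sin^2(\pi (t - t') / p) / \ell^2\}}
#' where \code{p} is the oscillation period and \code{lengthscale} the
#' (dimensionless) periodic lengthscale. Exactly periodic:
#' \code{k(t, t + p) = sigma^2}.
#'
#' @param t,tPrime numeric time vectors (s).
#' @param variance kernel variance \eqn{\sigma^2} (> 0).
#' @param period oscillation period \code{p} (s, > 0).
#' @param lengthscale periodic lengthscale \eqn{\ell} (> 0).
#' @return Covariance matrix of dimension \code{length(t) x length(tPrime)}.
#' @examples
#' periodicKernel(0, 75, variance = 5, period = 300, lengthscale = 1)
#' # 5 * exp(-1)
#' @export
periodicKernel <- function(t, tPrime, variance = 1, period = 300,
                           lengthscale = 1) {
  stopifnot(variance > 0, period > 0, lengthscale > 0)
  d <- outer(t, tPrime, "-")
  variance * exp(-2 * sin(pi * d / period)^2 / lengthscale^2)
}

#' Scaled SoftPlus link
#'
#' \code{mu = A * log(1 + exp(x))}: maps a latent value to a positive rate,
#' linear for large \code{x} and exponentially small (but never zero) for
#' very negative \code{x}. Numerically stable at both extremes.
#'
#' @param x latent value(s).
#' @param A rate scale (spikes/s); default 10.
#' @return Rate(s), > 0.
#' @examples
#' softplusLink(0)    # 10 * log(2)
#' softplusLink(50)   # ~500, no overflow
#' @export
softplusLink <- function(x, A = 10) {
  A * (pmax(x, 0) + log1p(exp(-abs(x))))
}

softplus_deriv <- function(x) 1 / (1 + exp(-x))  # d softplus / dx

#' @rdname dgenpois
#' @details \code{genpoisLogPmf} is an alias for
#'   \code{dgenpois(..., log = TRUE)}.
#' @export
genpoisLogPmf <- function(y, theta, alpha) dgenpois(y, theta, alpha,
                                                    log = TRUE)

## per-bin contaminated log-likelihood as a function of the latent value
latent_loglik <- function(f, y, alpha, A, bin, pNoise, yMax) {
  mu <- pmax(softplusLink(f, A) * bin, 1e-9)
  contaminatedLogLik(y, mu, alpha, pNoise = pNoise, yMax = yMax)
}

## diagonal gradient/curvature of the log-likelihood in f (finite differences;
## each bin depends on its own latent value only)
latent_grad_W <- function(f, y, alpha, A, bin, pNoise, yMax, h = 1e-4) {
  lp <- latent_loglik(f + h, y, alpha, A, bin, pNoise, yMax)
  lm <- latent_loglik(f - h, y, alpha, A, bin, pNoise, yMax)
  l0 <- latent_loglik(f, y, alpha, A, bin, pNoise, yMax)
  g <- (lp - lm) / (2 * h)
  w <- -(lp - 2 * l0 + lm) / h^2
  list(grad = g, W = pmax(w, 1e-6), loglik = sum(l0))
}

## Laplace approximation to log p(y | hyperparameters); Rasmussen & Williams
## Alg 3.1 with a damped Newton inner loop. Returns the mode and the
## approximate log marginal likelihood.
laplace_marginal <- function(y, K, cmean, alpha, A, bin, pNoise, yMax,
                             f0 = NULL, maxNewton = 60) {
  n <- length(y)
  Kc <- K + diag(1e-6 * mean(diag(K)) + 1e-10, n)
  f <- if (is.null(f0)) rep(cmean, n) else f0
  obj_old <- -Inf
  L <- NULL; gw <- NULL
  for (it in seq_len(maxNewton)) {
    gw <- latent_grad_W(f, y, alpha, A, bin, pNoise, yMax)
    sW <- sqrt(gw$W)
    B <- diag(n) + (sW %o% sW) * Kc
    L <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(L)) return(list(ok = FALSE))
    ft <- f - cmean
    b <- gw$W * ft + gw$grad
    a <- b - sW * backsolve(L, forwardsolve(t(L), sW * (Kc %*% b)))
    f_new <- cmean + drop(Kc %*% a)
    # damped step with backtracking on the penalized objective
    step <- 1
    q_of <- function(fv) {
      ftv <- fv - cmean
      av <- solve(Kc, ftv)
      sum(latent_loglik(fv, y, alpha, A, bin, pNoise, yMax)) -
        0.5 * sum(ftv * av)
    }
    obj_new <- q_of(f_new)
    while (!is.finite(obj_new) || obj_new < obj_old - 1e-8) {
      step <- step / 2
      if (step < 1e-4) break
      f_new <- f + step * (f_new - f)
      obj_new <- q_of(f_new)
    }
    if (!is.finite(obj_new)) return(list(ok = FALSE))
    f <- f_new
    if (abs(obj_new - obj_old) < 1e-6 * (abs(obj_old) + 1)) { obj_old <- obj_new; break }
    obj_old <- obj_new
  }
  gw <- latent_grad_W(f, y, alpha, A, bin, pNoise, yMax)
  sW <- sqrt(gw$W)
  B <- diag(n) + (sW %o% sW) * Kc
  L <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(L)) return(list(ok = FALSE))
  ft <- f - cmean
  av <- solve(Kc, ft)
  lml <- gw$loglik - 0.5 * sum(ft * av) - sum(log(diag(L)))
  list(ok = TRUE, f = f, lml = lml, K = Kc, W = gw$W, grad = gw$grad)
}

#' GPFit: fitted latent Gaussian-process model
#'
#' @slot hyper named numeric: \code{variance}, \code{period},
#'   \code{lengthscale}, \code{alpha}, \code{cmean}.
#' @slot A,bin,pNoise model constants.
#' @slot trainTimes,trainCounts,testTimes,testCounts the data split.
#' @slot latentTrain posterior-mode latent on the training grid.
#' @slot predTrain,predTest predicted mean counts per bin.
#' @slot pseudoR2Train,pseudoR2Test squared-error pseudo-R².
#' @slot objective final penalized negative log marginal likelihood.
#' @slot convergence optimizer convergence code (0 = success).
#' @export
setClass("GPFit",
  representation(hyper = "numeric", A = "numeric", bin = "numeric",
    pNoise = "numeric", trainTimes = "numeric", trainCounts = "integer",
    testTimes = "numeric", testCounts = "integer", latentTrain = "numeric",
    predTrain = "numeric", predTest = "numeric", pseudoR2Train = "numeric",
    pseudoR2Test = "numeric", objective = "numeric",
    convergence = "integer"))

setMethod("show", "GPFit", function(object) {
  h <- object@hyper
  cat(sprintf(
    "GPFit: period %.1f s, alpha %.3f, variance %.3f, lengthscale %.3f\n",
    h["period"], h["alpha"], h["variance"], h["lengthscale"]))
  cat(sprintf("  train %d bins, test %d bins; pseudo-R2 %.3f / %.3f\n",
    length(object@trainCounts), length(object@testCounts),
    object@pseudoR2Train, object@pseudoR2Test))
})

#' Fit the latent periodic GP to binned ongoing counts
#'
#' Models binned spike counts as generalized Poisson observations of a
#' latent periodic Gaussian process passed through the scaled SoftPlus link,
#' with a small uniform contamination for outlier bins. The final
#' \code{holdout} seconds are held out: hyperparameters (kernel variance,
#' period, lengthscale, dispersion \code{alpha}, constant mean) maximize a
#' Laplace-approximate marginal likelihood on the training bins only, with
#' Gaussian log-prior penalties \code{lengthscale ~ N(0.1, 0.1)} and
#' \code{alpha ~ N(0, 0.5)}. The period is initialized at 300 s. Held-out
#' predictions come from the trained model only.
#'
#' @param countsObj a \code{BinnedCounts} of ongoing activity (5 s bins
#'   typically).
#' @param holdout held-out tail duration (s); default 300.
#' @param A SoftPlus scale (spikes/s); default 10.
#' @param pNoise contamination weight; default 0.001.
#' @param init optional named list overriding initial values
#'   (\code{variance}, \code{period}, \code{lengthscale}, \code{alpha},
#'   \code{cmean}).
#' @param periodInit initial period (s); default 300.
#' @param maxit optimizer iteration budget; default 400.
#' @return A \code{GPFit}.
#' @export
fitLatentGP <- function(countsObj, holdout = 300, A = 10, pNoise = 0.001,
                        init = list(), periodInit = 300, maxit = 400) {
  stopifnot(is(countsObj, "BinnedCounts"))
  y <- counts(countsObj); tc <- binTimes(countsObj)
  bin <- countsObj@binWidth
  t_end <- countsObj@t0 + length(y) * bin
  train <- tc < (t_end - holdout)
  if (sum(train) < 10) stop("too few training bins after holdout")
  if (!any(!train)) warning("holdout window is empty; no test predictions")
  ytr <- y[train]; ttr <- tc[train]
  yte <- y[!train]; tte <- tc[!train]
  yMax <- max(ytr)  # training window only: held-out counts must not leak
  # crude latent-scale init from the count mean
  mu0 <- max(mean(ytr) / bin, 1e-3)
  c0 <- log(expm1(mu0 / A))  # softplus inverse
  th0 <- list(variance = 1, period = periodInit, lengthscale = 0.7,
              alpha = 0, cmean = c0)
  th0[names(init)] <- init
  # unconstrained parameterization
  pack <- function(th) c(log(th$variance), log(th$period),
                         log(th$lengthscale), atanh(th$alpha * 0.999),
                         th$cmean)
  unpack <- function(p) list(variance = exp(p[1]), period = exp(p[2]),
    lengthscale = exp(p[3]), alpha = tanh(p[4]), cmean = p[5])
  f_warm <- NULL
  objfun <- function(p) {
    th <- unpack(p)
    if (th$variance > 1e4 || th$period > 1e5 || th$lengthscale > 1e3)
      return(1e8)
    K <- periodicKernel(ttr, ttr, th$variance, th$period, th$lengthscale)
    lap <- laplace_marginal(ytr, K, th$cmean, th$alpha, A, bin, pNoise,
                            yMax, f0 = f_warm)
    if (!lap$ok) return(1e8)
    f_warm <<- lap$f
    # Gaussian log-prior penalties on lengthscale and alpha
    lpen <- dnorm(th$lengthscale, 0.1, 0.1, log = TRUE) +
      dnorm(th$alpha, 0, 0.5, log = TRUE)
    -(lap$lml + lpen)
  }
  opt <- optim(pack(th0), objfun, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-7))
  th <- unpack(opt$par)
  K <- periodicKernel(ttr, ttr, th$variance, th$period, th$lengthscale)
  lap <- laplace_marginal(ytr, K, th$cmean, th$alpha, A, bin, pNoise, yMax)
  if (!lap$ok) stop("Laplace approximation failed at the optimum")
  ft <- lap$f - th$cmean
  avec <- solve(lap$K, ft)
  pred_latent <- function(tnew) {
    Ks <- periodicKernel(tnew, ttr, th$variance, th$period, th$lengthscale)
    th$cmean + drop(Ks %*% avec)
  }
  mu_tr <- softplusLink(lap$f, A) * bin
  mu_te <- if (length(tte)) softplusLink(pred_latent(tte), A) * bin
           else numeric(0)
  r2tr <- pseudoR2(ytr, mu_tr, mean(ytr))
  r2te <- if (length(tte)) pseudoR2(yte, mu_te, mean(ytr)) else NA_real_
  new("GPFit",
    hyper = c(variance = th$variance, period = th$period,
              lengthscale = th$lengthscale, alpha = th$alpha,
              cmean = th$cmean),
    A = A, bin = bin, pNoise = pNoise,
    trainTimes = ttr, trainCounts = as.integer(ytr),
    testTimes = as.numeric(tte), testCounts = as.integer(yte),
    latentTrain = lap$f, predTrain = mu_tr, predTest = as.numeric(mu_te),
    pseudoR2Train = r2tr, pseudoR2Test = r2te,
    objective = opt$value, convergence = as.integer(opt$convergence))
}

#' Squared-error pseudo-R²
#'
#' \code{1 - sum((obs - pred)^2) / sum((obs - trainMean)^2)}: 1 for perfect
#' prediction, 0 for predicting the training mean, negative when predictions
#' are worse than the training mean (as for aperiodic cells at test time).
#'
#' @param observed observed counts.
#' @param predicted predicted mean counts (same length).
#' @param trainMean scalar baseline computed from the training window only.
#' @return Numeric scalar (NA with a warning when the observed series equals
#'   the baseline exactly).
#' @export
pseudoR2 <- function(observed, predicted, trainMean) {
  stopifnot(length(observed) == length(predicted), length(trainMean) == 1)
  denom <- sum((observed - trainMean)^2)
  if (denom == 0) {
    warning("observed series equals the baseline; pseudo-R2 undefined")
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / denom
}

#' Phase-folded reconstruction of the fitted rate
#'
#' Evaluates the fitted rate over the training span and folds it modulo the
#' fitted period into a fixed number of phase bins, averaging per bin. Phase
#' 0 is the training-window start; profiles are defined up to cyclic shift.
#'
#' @param fit a \code{GPFit}.
#' @param nPhase number of phase bins; default 50.
#' @param period folding period (s); defaults to the fitted period.
#' @return List with \code{phase} (bin centers in [0, 1)) and \code{rate}
#'   (mean predicted rate per phase bin, spikes/s).
#' @export
phaseFold <- function(fit, nPhase = 50, period = NULL) {
  stopifnot(is(fit, "GPFit"))
  p <- if (is.null(period)) unname(fit@hyper["period"]) else period
  if (!is.finite(p)) stop("fitted period is not finite")
  span <- diff(range(fit@trainTimes))
  if (p > span) warning("folding period exceeds the training span")
  ph <- ((fit@trainTimes - fit@trainTimes[1]) %% p) / p
  idx <- pmin(floor(ph * nPhase) + 1, nPhase)
  rate <- fit@predTrain / fit@bin  # back to spikes/s
  prof <- vapply(seq_len(nPhase), function(i) {
    if (any(idx == i)) mean(rate[idx == i]) else NA_real_
  }, 0)
  list(phase = (seq_len(nPhase) - 0.5) / nPhase, rate = prof)
}
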