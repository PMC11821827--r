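#' Zero-one-inflated beta log-density
#'
#' The ZOIB distribution on \[0, 1\] mixes a point mass at \{0, 1\} with a
#' beta density on (0, 1). `p01` is the total probability of the point
#' masses and `coi` the conditional probability of 1 given a point mass, so
#' P(Y = 0) = p01 (1 - coi), P(Y = 1) = p01 coi, and on (0, 1) the density
#' is (1 - p01) Beta(y; mu phi, (1 - mu) phi) in the mean-precision
#' parameterization. In the excess-zeros/ones notation used for inflated
#' beta models, omega = p01 and zeta = p01 * coi.
#'
#' @param y Values in \[0, 1\].
#' @param mu Beta mean in (0, 1).
#' @param phi Beta precision, > 0.
#' @param p01 Probability of the \{0, 1\} point masses, in \[0, 1\].
#' @param coi Conditional probability of 1 given a point mass, in \[0, 1\].
#' @return Log-density, vectorized over `y` (and `mu`).
#' @export
zoib_logdensity <- function(y, mu, phi, p01, coi) {
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]", call. = FALSE)
  if (any(mu <= 0 | mu >= 1)) stop("mu must lie in (0, 1)", call. = FALSE)
  if (any(phi <= 0)) stop("phi must be positive", call. = FALSE)
  if (any(p01 < 0 | p01 > 1) || any(coi < 0 | coi > 1)) {
    stop("p01 and coi must lie in [0, 1]", call. = FALSE)
  }
  n <- max(length(y), length(mu))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  out <- numeric(n)
  is0 <- y == 0; is1 <- y == 1; mid <- !is0 & !is1
  out[is0] <- log(p01) + log1p(-coi)
  out[is1] <- log(p01) + log(coi)
  out[mid] <- log1p(-p01) +
    stats::dbeta(y[mid], mu[mid] * phi, (1 - mu[mid]) * phi, log = TRUE)
  out
}

#' Draw from the zero-one-inflated beta distribution
#'
#' @inheritParams zoib_logdensity
#' @param n Number of draws.
#' @return Numeric vector of draws in \[0, 1\].
#' @export
rzoib <- function(n, mu, phi, p01, coi) {
  mu <- rep_len(mu, n)
  inflated <- stats::runif(n) < p01
  y <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  y[inflated] <- as.numeric(stats::runif(sum(inflated)) < coi)
  y
}

# ---- multivariate-t proposal helpers -------------------------------------

rmvt_prop <- function(nd, mode, cholS, df) {
  d <- length(mode)
  z <- matrix(stats::rnorm(nd * d), nd, d) %*% cholS
  w <- sqrt(df / stats::rchisq(nd, df))
  sweep(z * w, 2, mode, "+")
}

dmvt_log <- function(x, mode, cholS, df) {
  d <- length(mode)
  z <- backsolve(cholS, t(x) - mode, transpose = TRUE)
  q <- colSums(z^2)
  lgamma((df + d) / 2) - lgamma(df / 2) - (d / 2) * log(df * pi) -
    sum(log(diag(cholS))) - ((df + d) / 2) * log1p(q / df)
}

# Student-t prior density (location-scale) used for the intercept.
dt_ls <- function(x, df, location, scale) {
  stats::dt((x - location) / scale, df, log = TRUE) - log(scale)
}

# ---- sampler --------------------------------------------------------------

#' MCMC for the zero-one-inflated beta regression
#'
#' Samples the posterior of a ZOIB regression with logit link for the beta
#' mean. Priors follow the standard weakly-informative setup for inflated
#' beta models: Student-t(3, 0, 2.5) on the intercept, flat on the remaining
#' coefficients (optionally normal(0, `coef_prior_sd`)), Gamma(0.01, 0.01)
#' on the precision phi, flat (Beta(1, 1)) on the mixture weight `p01`, and
#' Beta(1, 1) on the conditional-one probability `coi`.
#'
#' Because the \{0, 1\} point-mass block factorizes out of the likelihood,
#' `p01` and `coi` are drawn exactly from their conjugate Beta posteriors.
#' The beta-regression block (coefficients, log phi) is sampled by one of
#' two kernels chosen by problem size: for large models, independence
#' Metropolis-Hastings on a Laplace-calibrated multivariate-t mixture
#' proposal (refreshed during warmup, interleaved with coordinate sweeps);
#' for small models with cheap likelihoods, univariate slice sampling along
#' the eigen-directions of the refreshed posterior covariance.
#'
#' @param y Response in \[0, 1\] (0 and 1 allowed).
#' @param X Design matrix (first column the intercept), rows matching `y`.
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param iter Total iterations per chain.
#' @param warmup Iterations discarded per chain.
#' @param seed Integer seed; identical seeds and chain plan give identical
#'   draws.
#' @param coef_prior_sd Normal prior sd for non-intercept coefficients;
#'   `Inf` (default) means flat.
#' @param sampler `"auto"` (default: kernel chosen by problem size),
#'   `"imh"` (independence Metropolis-Hastings) or `"slice"`
#'   (eigen-direction slice sampling; slower per iteration but robust to
#'   skewed, weakly identified posteriors).
#' @return A list with `draws` (array retained-iterations x chains x
#'   parameters; parameters are the coefficients named after `X` columns,
#'   then `phi`, `p01`, `coi`), `rhat` (named), `accept_rate`, and the model
#'   frame pieces needed by summaries.
#' @export
zoib_mcmc <- function(y, X, chains = 2, iter = 2000, warmup = 1000,
                      seed = 1L, coef_prior_sd = Inf,
                      sampler = c("auto", "imh", "slice")) {
  sampler <- match.arg(sampler)
  stopifnot(is.matrix(X), nrow(X) == length(y), chains >= 1,
            iter > warmup, warmup >= 1)
  if (any(y < 0 | y > 1)) stop("response outside [0, 1]", call. = FALSE)
  is0 <- y == 0; is1 <- y == 1; mid <- !is0 & !is1
  n0 <- sum(is0); n1 <- sum(is1); nc <- sum(mid)
  if (nc == 0L) {
    stop("no responses strictly inside (0, 1); beta block is unidentified",
         call. = FALSE)
  }
  yc <- y[mid]
  Xc <- X[mid, , drop = FALSE]
  p <- ncol(X)
  d <- p + 1L                                # coefficients + log phi
  parnames <- c(colnames(X), "phi", "p01", "coi")

  logpost <- function(theta) {
    b <- theta[seq_len(p)]
    phi <- exp(theta[d])
    eta <- drop(Xc %*% b)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    ll <- sum(stats::dbeta(yc, mu * phi, (1 - mu) * phi, log = TRUE))
    if (!is.finite(ll)) return(-Inf)
    lp <- dt_ls(b[1], 3, 0, 2.5)
    if (is.finite(coef_prior_sd) && p > 1) {
      lp <- lp + sum(stats::dnorm(b[-1], 0, coef_prior_sd, log = TRUE))
    }
    lp <- lp + stats::dgamma(phi, 0.01, rate = 0.01, log = TRUE) + theta[d]
    ll + lp
  }

  # Laplace approximation at the posterior mode seeds the proposal
  mom_mu <- mean(yc)
  mom_phi <- max(mom_mu * (1 - mom_mu) / max(stats::var(yc), 1e-6) - 1, 1)
  init <- c(stats::qlogis(mom_mu), rep(0, p - 1), log(mom_phi))
  opt <- stats::optim(init, function(th) -logpost(th), method = "BFGS",
                      control = list(maxit = 1000), hessian = TRUE)
  mode <- opt$par
  Sigma <- tryCatch(solve(opt$hessian + diag(1e-10, d)),
                    error = function(e) NULL)
  ok <- !is.null(Sigma) && all(is.finite(Sigma)) &&
    all(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values > 0)
  if (!ok) Sigma <- diag(1e-2, d)

  prop_df <- 7
  safe_chol <- function(S0) {
    S0 <- (S0 + t(S0)) / 2
    ev <- eigen(S0, symmetric = TRUE)
    lam <- pmax(ev$values, 1e-12 * max(ev$values))
    chol(ev$vectors %*% (lam * t(ev$vectors)) * 1.1)
  }

  # Kernel choice. Large models (many continuous observations) have
  # near-Gaussian posteriors and expensive likelihoods: independence MH on
  # the Laplace approximation is efficient there. Small models (e.g. annual
  # volume regressions) have cheap likelihoods but skewed, diffuse
  # posteriors: univariate slice sampling along the eigen-directions of the
  # (refreshed) posterior covariance needs no tuning and mixes where a
  # Metropolis proposal cannot.
  use_slice <- switch(sampler, slice = TRUE, imh = FALSE,
                      auto = nc * d <= 1000)
  sweep_every <- 5L
  # defensive mixture proposal: a 3x-wider second component bounds the
  # importance weights that make a pure independence kernel sticky
  wide <- 3
  rprop <- function(nd, loc, cholS) {
    comp <- stats::runif(nd) < 0.9
    x1 <- rmvt_prop(nd, loc, cholS, prop_df)
    x2 <- rmvt_prop(nd, loc, wide * cholS, prop_df)
    x1[!comp, ] <- x2[!comp, ]
    x1
  }
  dprop <- function(x, loc, cholS) {
    l1 <- dmvt_log(x, loc, cholS, prop_df)
    l2 <- dmvt_log(x, loc, wide * cholS, prop_df)
    mx <- pmax(l1, l2)
    mx + log(0.9 * exp(l1 - mx) + 0.1 * exp(l2 - mx))
  }
  run_imh <- function(nsteps, cur, loc, cholS) {
    prop <- rprop(nsteps, loc, cholS)
    lq <- dprop(prop, loc, cholS)
    lp_prop <- apply(prop, 1, logpost)
    logu <- log(stats::runif(nsteps))
    step_sd <- 2.4 * sqrt(diag(crossprod(cholS)))
    zmat <- matrix(stats::rnorm(nsteps * d), nsteps, d)
    lumat <- matrix(log(stats::runif(nsteps * d)), nsteps, d)
    lp_cur <- logpost(cur)
    lq_cur <- dprop(matrix(cur, 1), loc, cholS)
    kept <- matrix(NA_real_, nsteps, d)
    acc <- 0L
    for (i in seq_len(nsteps)) {
      if (i %% sweep_every == 0L) {
        moved <- FALSE
        for (j in seq_len(d)) {
          cand <- cur
          cand[j] <- cur[j] + step_sd[j] * zmat[i, j]
          lp_cand <- logpost(cand)
          if (lumat[i, j] < lp_cand - lp_cur) {
            cur <- cand; lp_cur <- lp_cand; moved <- TRUE
          }
        }
        if (moved) {
          lq_cur <- dprop(matrix(cur, 1), loc, cholS)
          acc <- acc + 1L
        }
      } else if (logu[i] < (lp_prop[i] - lq[i]) - (lp_cur - lq_cur)) {
        cur <- prop[i, ]; lp_cur <- lp_prop[i]; lq_cur <- lq[i]
        acc <- acc + 1L
      }
      kept[i, ] <- cur
    }
    list(kept = kept, cur = cur, acc = acc)
  }

  # slice sampler along the columns of a direction matrix U (each column
  # scaled to about one posterior sd); standard stepping-out and shrinkage
  run_slice <- function(nsteps, cur, U) {
    kept <- matrix(NA_real_, nsteps, d)
    lp_cur <- logpost(cur)
    for (i in seq_len(nsteps)) {
      for (k in seq_len(d)) {
        u <- U[, k]
        logy <- lp_cur - stats::rexp(1)
        L <- -stats::runif(1)
        R <- L + 1
        steps <- 0L
        while (logpost(cur + L * u) > logy && steps < 30L) {
          L <- L - 1; steps <- steps + 1L
        }
        steps <- 0L
        while (logpost(cur + R * u) > logy && steps < 30L) {
          R <- R + 1; steps <- steps + 1L
        }
        repeat {
          tt <- stats::runif(1, L, R)
          lp_new <- logpost(cur + tt * u)
          if (lp_new >= logy) {
            cur <- cur + tt * u; lp_cur <- lp_new; break
          }
          if (tt < 0) L <- tt else R <- tt
        }
      }
      kept[i, ] <- cur
    }
    list(kept = kept, cur = cur)
  }
  eigen_directions <- function(S0) {
    S0 <- (S0 + t(S0)) / 2
    ev <- eigen(S0, symmetric = TRUE)
    lam <- pmax(ev$values, 1e-12 * max(ev$values))
    sweep(ev$vectors, 2, sqrt(lam), "*")
  }

  S <- iter - warmup
  draws <- array(NA_real_, dim = c(S, chains, length(parnames)),
                 dimnames = list(NULL, NULL, parnames))
  accept <- 0L
  round_acc <- rep(list(numeric(3)), chains)
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    cur <- mode
    if (use_slice) {
      # half the warmup with Laplace directions, then refresh the rotation
      # from the warmup sample covariance
      U <- eigen_directions(Sigma)
      half <- c(floor(warmup / 2), warmup - floor(warmup / 2))
      for (r in 1:2) {
        wu <- run_slice(half[r], cur, U)
        cur <- wu$cur
        S2 <- stats::cov(wu$kept)
        if (all(is.finite(S2)) && all(diag(S2) > 0)) {
          U <- eigen_directions(S2 + 0.05 * Sigma)
        }
      }
      sm <- run_slice(S, cur, U)
      accept <- accept + S                    # slice updates always move
      kept <- sm$kept
    } else {
      loc <- mode
      cholS <- safe_chol(Sigma)
      # staged warmup; after each round, refit the proposal moments from the
      # round's draws (handles posteriors wider or skewer than the Laplace
      # fit)
      rounds <- c(floor(warmup / 3), floor(warmup / 3),
                  warmup - 2 * floor(warmup / 3))
      for (r in seq_along(rounds)) {
        wu <- run_imh(rounds[r], cur, loc, cholS)
        cur <- wu$cur
        round_acc[[ch]][r] <- wu$acc / rounds[r]
        if (wu$acc >= max(10, 0.02 * rounds[r])) {
          loc2 <- colMeans(wu$kept)
          S2 <- stats::cov(wu$kept)
          if (all(is.finite(S2)) && all(diag(S2) > 0)) {
            loc <- loc2
            cholS <- safe_chol(S2 + 0.1 * Sigma)
          }
        }
      }
      sm <- run_imh(S, cur, loc, cholS)
      accept <- accept + sm$acc
      kept <- sm$kept
    }
    draws[, ch, seq_len(p)] <- kept[, seq_len(p)]
    draws[, ch, "phi"] <- exp(kept[, d])
    # conjugate exact draws for the inflation block
    draws[, ch, "p01"] <- stats::rbeta(S, 1 + n0 + n1, 1 + nc)
    draws[, ch, "coi"] <- stats::rbeta(S, 1 + n1, 1 + n0)
  }
  rhat <- apply(draws, 3, split_rhat)
  list(draws = draws, rhat = rhat,
       accept_rate = accept / (chains * S), round_accept = round_acc,
       parnames = parnames, n0 = n0, n1 = n1, nc = nc, X = X, y = y,
       chain_plan = c(chains = chains, iter = iter, warmup = warmup),
       seed = seed)
}

#' Rank-normalized split R-hat
#'
#' The potential scale-reduction diagnostic computed on rank-normalized
#' draws after splitting each chain in half. Values near 1 indicate that
#' chains mix over the same distribution; above about 1.01 indicates
#' non-convergence.
#'
#' @param x A matrix of draws (iterations x chains), or an iterations x
#'   chains slice of a draws array.
#' @return The R-hat value. Chains that are exactly constant return 1 (with
#'   attribute `constant = TRUE`).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  niter <- nrow(x)
  if (ncol(x) < 2L) stop("need at least 2 chains", call. = FALSE)
  if (niter < 4L) stop("need at least 4 draws per chain", call. = FALSE)
  if (stats::var(as.vector(x)) == 0) {
    return(structure(1, constant = TRUE))
  }
  half <- floor(niter / 2)
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(niter - half + 1):niter, , drop = FALSE])
  r <- matrix(rank(splits, ties.method = "average"), nrow(splits))
  z <- stats::qnorm((r - 0.375) / (length(r) + 0.25))
  m <- ncol(z); nn <- nrow(z)
  means <- colMeans(z)
  vars <- apply(z, 2, stats::var)
  B <- nn * stats::var(means)
  W <- mean(vars)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Bayesian R-squared
#'
#' Per posterior draw, R2 = var(fitted) / (var(fitted) + var(residual)),
#' where fitted values are the model-implied expectations E\[y|x\] and
#' residuals are observed minus fitted.
#'
#' @param fitted_draws Matrix of fitted values, draws x observations.
#' @param y Observed response.
#' @return A list with `draws` (per-draw R2), `median`, `q2.5`, `q97.5`.
#' @export
bayes_r2 <- function(fitted_draws, y) {
  stopifnot(is.matrix(fitted_draws), ncol(fitted_draws) == length(y))
  vfit <- apply(fitted_draws, 1, stats::var)
  if (all(vfit == 0)) stop("fitted values have zero variance", call. = FALSE)
  vres <- apply(sweep(fitted_draws, 2, y, function(f, y) y - f), 1,
                stats::var)
  r2 <- vfit / (vfit + vres)
  q <- stats::quantile(r2, c(0.5, 0.025, 0.975), names = FALSE)
  list(draws = r2, median = q[1], q2.5 = q[2], q97.5 = q[3])
}

# Flatten a draws array to draws x parameter matrix (chains stacked).
flatten_draws <- function(draws) {
  d <- dim(draws)
  out <- matrix(aperm(draws, c(1, 2, 3)), d[1] * d[2], d[3])
  colnames(out) <- dimnames(draws)[[3]]
  out
}

posterior_summary <- function(fit) {
  fl <- flatten_draws(fit$draws)
  data.frame(
    parameter = colnames(fl),
    mean = colMeans(fl),
    sd = apply(fl, 2, stats::sd),
    q2.5 = apply(fl, 2, stats::quantile, 0.025),
    q97.5 = apply(fl, 2, stats::quantile, 0.975),
    rhat = fit$rhat[colnames(fl)],
    row.names = NULL
  )
}
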