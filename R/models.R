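#' Condition signalling a trait with a single observed category
#' @noRd
single_category_error <- function(trait, category) {
  structure(
    class = c("benthovuln_single_category", "error", "condition"),
    list(message = sprintf(
      "trait %s has a single observed category (%s); model skipped",
      trait, category), call = NULL)
  )
}

#' Fit the mortality-severity ZOIB model for one trait
#'
#' Regresses per-record percent mortality (rescaled to \[0, 1\]; records at
#' 100% form the one-inflated mass) on the record species' category of one
#' trait, with a logit link on the beta mean and the priors described in
#' [zoib_mcmc()]. One such model per trait quantifies which categories are
#' hit hardest.
#'
#' @param records A `mortality_records` data.frame.
#' @param trait A trait code (e.g. `"I"`).
#' @param table The `trait_table` giving each species its categories.
#' @param chains,iter,warmup Chain plan (default 2 chains x 2000 iterations,
#'   warmup 1000: 2000 retained draws).
#' @param seed Integer seed.
#' @param rhat_tol Convergence threshold on split R-hat (default 1.01).
#' @param attempts Chains marginally over the threshold are resampled from
#'   scratch with a fresh derived seed, up to this many times (default 3);
#'   the fit errors with diagnostics if the last attempt still fails.
#' @return A `zoib_fit` list: `fit` (the [zoib_mcmc()] result), `summary`
#'   (parameter table with R-hat), `severity_by_category` (data.frame
#'   `trait`, `category`, `n_records`, `mean_percent`, `q2.5_percent`,
#'   `q97.5_percent`), `r2` (Bayesian R-squared summary), `trait`.
#' @export
fit_severity_model <- function(records, trait, table, chains = 2,
                               iter = 2000, warmup = 1000, seed = 1L,
                               rhat_tol = 1.01, attempts = 3L) {
  schema <- attr(table, "schema")
  tr <- schema_trait(schema, trait)
  cat_of_species <- stats::setNames(as.data.frame(table)[[trait]],
                                    table$species)
  cats <- unname(cat_of_species[records$species])
  if (anyNA(cats)) {
    stop("record species absent from trait table: ",
         paste(unique(records$species[is.na(cats)]), collapse = ", "),
         call. = FALSE)
  }
  observed <- intersect(tr$categories, unique(cats))   # vocabulary order
  if (length(observed) < 2L) {
    stop(single_category_error(trait, observed))
  }
  f <- factor(cats, levels = observed)
  X <- stats::model.matrix(~f)
  colnames(X) <- c("(Intercept)", paste0("cat_", observed[-1]))
  y <- records$percent_mortality / 100
  for (att in seq_len(attempts)) {
    # final attempt switches to the slice kernel, which is robust to the
    # skewed posteriors of sparsely observed categories
    fit <- zoib_mcmc(y, X, chains = chains, iter = iter, warmup = warmup,
                     seed = seed + (att - 1L) * 1000L,
                     sampler = if (att == attempts) "slice" else "auto")
    if (all(fit$rhat <= rhat_tol)) break
  }
  check_convergence(fit, rhat_tol, paste("severity model, trait", trait))
  fl <- flatten_draws(fit$draws)
  # expected mortality per category: E[y] = p01*coi + (1-p01)*mu_cat
  eta <- matrix(fl[, "(Intercept)"], nrow(fl), length(observed))
  for (j in seq_along(observed)[-1]) {
    eta[, j] <- eta[, j] + fl[, paste0("cat_", observed[j])]
  }
  ey <- fl[, "p01"] * fl[, "coi"] + (1 - fl[, "p01"]) * stats::plogis(eta)
  sev <- data.frame(
    trait = trait,
    category = observed,
    n_records = as.integer(table(f)[observed]),
    mean_percent = 100 * colMeans(ey),
    q2.5_percent = 100 * apply(ey, 2, stats::quantile, 0.025),
    q97.5_percent = 100 * apply(ey, 2, stats::quantile, 0.975),
    row.names = NULL
  )
  fitted <- ey[, as.integer(f), drop = FALSE]
  r2 <- bayes_r2(fitted, y)
  structure(list(fit = fit, summary = posterior_summary(fit),
                 severity_by_category = sev, r2 = r2, trait = trait),
            class = "zoib_fit")
}

#' Fit the trait-volume ZOIB model on annual impacted fractions
#'
#' Regresses the annual impacted trait-volume fraction on the number of FEs
#' impacted by each driver class that year (numeric predictors), with the
#' same ZOIB family and priors as the severity models. Years with no impact
#' contribute zeros through the zero-inflation mass.
#'
#' @param fractions Annual impacted volume fractions in \[0, 1\] (>= 10
#'   values).
#' @param driver_counts Numeric matrix, one row per year, one column per
#'   driver class: FEs impacted by that class that year.
#' @param min_informative Predictors with fewer nonzero years than this are
#'   dropped (default 3): a flat-prior coefficient informed by one or two
#'   observations is unidentified and only destabilizes the fit. Dropped
#'   columns are reported in `dropped_predictors`.
#' @param chains,iter,warmup Chain plan (default 2 chains x 3000 iterations,
#'   warmup 1000: 4000 retained draws).
#' @inheritParams fit_severity_model
#' @return A `zoib_fit` list (`fit`, `summary`, `r2`).
#' @export
fit_volume_model <- function(fractions, driver_counts, chains = 2,
                             iter = 3000, warmup = 1000, seed = 1L,
                             rhat_tol = 1.01, min_informative = 3L,
                             attempts = 3L) {
  stopifnot(is.matrix(driver_counts), nrow(driver_counts) == length(fractions))
  if (length(fractions) < 10L) {
    stop("need at least 10 annual observations", call. = FALSE)
  }
  if (all(fractions == 0)) {
    stop("all-zero response: no impacted volume to model", call. = FALSE)
  }
  keep <- apply(driver_counts, 2, function(col) {
    stats::var(col) > 0 && sum(col != 0) >= min_informative
  })
  Xd <- driver_counts[, keep, drop = FALSE]
  # sample on centered/scaled predictors for conditioning, report raw-scale
  ctr <- colMeans(Xd)
  scl <- apply(Xd, 2, stats::sd)
  Xs <- sweep(sweep(Xd, 2, ctr), 2, scl, "/")
  X <- cbind("(Intercept)" = 1, Xs)
  pn <- colnames(Xd)
  for (att in seq_len(attempts)) {
    fit <- zoib_mcmc(fractions, X, chains = chains, iter = iter,
                     warmup = warmup, seed = seed + (att - 1L) * 1000L,
                     sampler = if (att == attempts) "slice" else "auto")
    # back-transform coefficient draws to the raw count scale
    if (length(pn)) {
      for (ch in seq_len(dim(fit$draws)[2])) {
        bsc <- matrix(fit$draws[, ch, pn], ncol = length(pn))
        fit$draws[, ch, pn] <- sweep(bsc, 2, scl, "/")
        fit$draws[, ch, "(Intercept)"] <- fit$draws[, ch, "(Intercept)"] -
          drop(bsc %*% (ctr / scl))
      }
    }
    fit$rhat <- apply(fit$draws, 3, split_rhat)
    if (all(fit$rhat <= rhat_tol)) break
  }
  check_convergence(fit, rhat_tol, "volume model")
  fl <- flatten_draws(fit$draws)
  b <- fl[, c("(Intercept)", pn), drop = FALSE]
  mu <- stats::plogis(b %*% t(cbind(1, Xd)))
  ey <- fl[, "p01"] * fl[, "coi"] + (1 - fl[, "p01"]) * mu
  r2 <- bayes_r2(ey, fractions)
  structure(list(fit = fit, summary = posterior_summary(fit), r2 = r2,
                 dropped_predictors = colnames(driver_counts)[!keep]),
            class = "zoib_fit")
}

check_convergence <- function(fit, rhat_tol, label) {
  bad <- fit$rhat[fit$rhat > rhat_tol]
  if (length(bad)) {
    stop(sprintf(
      "%s did not converge: R-hat > %.3g for %s (acceptance rate %.2f)",
      label, rhat_tol,
      paste(sprintf("%s=%.3f", names(bad), bad), collapse = ", "),
      fit$accept_rate), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.zoib_fit <- function(x, ...) {
  cat("zoib_fit")
  if (!is.null(x$trait)) cat(" (severity model, trait ", x$trait, ")", sep = "")
  cat(sprintf(": %d retained draws, max R-hat %.3f, R2 %.2f [%.2f, %.2f]\n",
              nrow(flatten_draws(x$fit$draws)), max(x$fit$rhat),
              x$r2$median, x$r2$q2.5, x$r2$q97.5))
  if (!is.null(x$severity_by_category)) {
    print(x$severity_by_category, digits = 3)
  }
  invisible(x)
}
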