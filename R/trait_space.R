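#' Gower dissimilarity over mixed nominal/ordinal traits
#'
#' Computes d(i,j) = (1/10) * sum over traits of a per-trait dissimilarity:
#' 0/1 mismatch for nominal traits; for an ordinal trait with K ordered
#' categories at ranks 1..K, |rank_i - rank_j| / (K - 1) (range-scaled
#' ranks). All traits receive equal weight, so distances lie in \[0, 1\].
#'
#' The `"podani"` variant replaces vocabulary ranks by tie-adjusted ranks of
#' the observed values (Podani's extension of Gower to ordinal variables);
#' with every category observed exactly equally it coincides with the
#' classic range-scaled form only in the untied case, so the default remains
#' `"rank"`.
#'
#' @param x A `trait_table` (species level) or `functional_entities`
#'   (FE level: one row per unique signature, labelled by fe_id).
#' @param level `"FE"` (default when `x` is a `functional_entities`) or
#'   `"species"`.
#' @param ordinal `"rank"` (vocabulary ranks scaled by K-1) or `"podani"`
#'   (tie-adjusted observed ranks).
#' @return A symmetric matrix of class `trait_dist` with zero diagonal and
#'   labels as dimnames.
#' @export
gower_distance <- function(x, level = c("FE", "species"),
                           ordinal = c("rank", "podani")) {
  ordinal <- match.arg(ordinal)
  if (inherits(x, "functional_entities")) {
    schema <- x$schema
    df <- x$fe
    labels <- df$fe_id
  } else if (inherits(x, "trait_table")) {
    level <- match.arg(level)
    schema <- attr(x, "schema")
    if (level == "FE") {
      fes <- build_functional_entities(x)
      df <- fes$fe
      labels <- df$fe_id
    } else {
      df <- as.data.frame(x)
      labels <- df$species
    }
  } else {
    stop("x must be a trait_table or functional_entities", call. = FALSE)
  }
  n <- nrow(df)
  if (n < 2L) stop("need at least two rows to form pairs", call. = FALSE)
  acc <- matrix(0, n, n)
  for (tr in schema$traits) {
    v <- df[[tr$code]]
    if (tr$kind == "nominal") {
      delta <- outer(v, v, FUN = "!=") * 1
    } else {
      K <- length(tr$categories)
      r <- match(v, tr$categories)
      if (ordinal == "rank") {
        delta <- abs(outer(r, r, "-")) / (K - 1)
      } else {
        delta <- podani_delta(r)
      }
    }
    acc <- acc + delta
  }
  d <- acc / length(schema$traits)
  dimnames(d) <- list(labels, labels)
  structure(d, class = c("trait_dist", "matrix"))
}

# Podani (1999) tie-adjusted ordinal dissimilarity on observed ranks.
podani_delta <- function(r) {
  rk <- rank(r)                       # tied average ranks of observed values
  tcount <- table(r)
  Ti <- as.numeric(tcount[as.character(r)])
  r_min <- rk[which.min(r)]; T_min <- Ti[which.min(r)]
  r_max <- rk[which.max(r)]; T_max <- Ti[which.max(r)]
  denom <- r_max - r_min - (T_max - 1) / 2 - (T_min - 1) / 2
  if (denom <= 0) return(matrix(0, length(r), length(r)))
  num <- abs(outer(rk, rk, "-")) - outer(Ti - 1, Ti - 1, "+") / 2
  delta <- pmax(num, 0) / denom
  delta[outer(r, r, "==")] <- 0
  delta
}

#' Principal coordinates embedding of a dissimilarity matrix
#'
#' Classical scaling: square and double-centre the dissimilarities,
#' eigendecompose, and scale eigenvectors by the square roots of positive
#' eigenvalues. All eigenvalues are retained (signed) for reporting, but
#' axes with non-positive eigenvalues are dropped from the coordinates; no
#' Cailliez or Lingoes correction is applied. Eigenvalues below
#' `1e-9 * max(eigenvalue)` in magnitude are treated as zero.
#'
#' @param D A symmetric dissimilarity matrix (e.g. from [gower_distance()]).
#' @return A `trait_space`: list with `labels`, `coordinates` (n x m, columns
#'   ordered by decreasing eigenvalue), `eigenvalues` (length n, signed),
#'   `mad_profile` and `m_selected` (NULL until [select_dimension()]).
#' @export
pcoa_embedding <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 points for an embedding", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-12) stop("D must be symmetric", call. = FALSE)
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (max(D) == 0) {
    return(structure(list(labels = labels,
                          coordinates = matrix(0, n, 1,
                                               dimnames = list(labels, "PC1")),
                          eigenvalues = rep(0, n),
                          mad_profile = NULL, m_selected = NULL),
                     class = "trait_space"))
  }
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  lambda <- e$values
  tol <- 1e-9 * max(abs(lambda))
  lambda[abs(lambda) < tol] <- 0
  pos <- which(lambda > 0)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda[pos]),
                                                    length(pos))
  dimnames(coords) <- list(labels, paste0("PC", seq_along(pos)))
  structure(list(labels = labels, coordinates = coords,
                 eigenvalues = lambda, mad_profile = NULL, m_selected = NULL),
            class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat(sprintf("trait_space: %d points, %d positive axes", length(x$labels),
              ncol(x$coordinates)))
  if (!is.null(x$m_selected)) {
    cat(sprintf("; m_selected = %d (mAD = %.4g)", x$m_selected,
                x$mad_profile[as.character(x$m_selected)]))
  }
  cat("\n")
  invisible(x)
}

euclid_m <- function(space, m) {
  as.matrix(stats::dist(space$coordinates[, seq_len(m), drop = FALSE]))
}

#' Trait-space quality: mean absolute deviation (mAD)
#'
#' mAD is the mean over all unordered pairs of the absolute difference
#' between the input dissimilarity and the Euclidean distance computed from
#' the first `m` coordinates. Lower is better; at full dimension of a
#' Euclidean-representable input it is numerically zero.
#'
#' @param D The dissimilarity matrix the space was built from.
#' @param space A `trait_space` from [pcoa_embedding()].
#' @param m Number of leading axes to use.
#' @param scale_euclid If TRUE, the m-dimensional Euclidean distances are
#'   rescaled by `max(D)/max(euclid)` before comparison. Default FALSE (raw
#'   distances).
#' @return The mAD value (single number).
#' @export
mad_quality <- function(D, space, m, scale_euclid = FALSE) {
  D <- as.matrix(D)
  navail <- ncol(space$coordinates)
  if (m < 1 || m > navail) {
    stop(sprintf("m = %d exceeds the %d available positive axes", m, navail),
         call. = FALSE)
  }
  E <- euclid_m(space, m)
  if (scale_euclid && max(E) > 0) E <- E * max(D) / max(E)
  ut <- upper.tri(D)
  mean(abs(D[ut] - E[ut]))
}

#' Select embedding dimensionality by minimizing mAD
#'
#' Computes the mAD profile over candidate dimensions and picks the
#' dimension with the lowest mAD, breaking ties toward the smaller
#' dimension.
#'
#' @inheritParams mad_quality
#' @param candidates Candidate dimensions (default 2..10); candidates beyond
#'   the available positive axes are dropped.
#' @return The `trait_space` with `mad_profile` (named numeric) and
#'   `m_selected` filled in.
#' @export
select_dimension <- function(D, candidates = 2:10, scale_euclid = FALSE) {
  space <- pcoa_embedding(D)
  navail <- ncol(space$coordinates)
  cand <- sort(unique(candidates[candidates >= 1 & candidates <= navail]))
  if (length(cand) == 0L) {
    stop("no candidate dimension within the available positive axes",
         call. = FALSE)
  }
  prof <- vapply(cand, function(m) mad_quality(D, space, m, scale_euclid),
                 numeric(1))
  names(prof) <- as.character(cand)
  space$mad_profile <- prof
  space$m_selected <- cand[which.min(prof)]   # which.min takes the first = smallest m
  space
}
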