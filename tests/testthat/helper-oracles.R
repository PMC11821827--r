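# Independent geometry oracle, sharing no code with hull_volumes().
#
# Points are translated so their centroid sits at the origin (strictly
# inside the hull); every facet hyperplane then has the form a.x = 1 with
# the interior on the a.x < 1 side, so an m-subset is a facet iff
# a = solve(P_subset, 1) satisfies a.x_i <= 1 for all points. Assumes
# general position (random continuous coordinates), where each facet is a
# simplex found exactly once.

brute_hull_facets <- function(points, tol = 1e-9) {
  n <- nrow(points)
  m <- ncol(points)
  stopifnot(n >= m + 1)
  ctr <- colMeans(points)
  P <- sweep(points, 2, ctr)
  combs <- utils::combn(n, m)
  A <- vector("list", ncol(combs))
  idx_list <- vector("list", ncol(combs))
  nf <- 0L
  ones <- rep(1, m)
  for (j in seq_len(ncol(combs))) {
    idx <- combs[, j]
    a <- tryCatch(solve(P[idx, , drop = FALSE], ones),
                  error = function(e) NULL)
    if (is.null(a) || !all(is.finite(a))) next
    if (all(P %*% a <= 1 + tol)) {
      nf <- nf + 1L
      A[[nf]] <- a
      idx_list[[nf]] <- idx
    }
  }
  list(A = do.call(rbind, A[seq_len(nf)]), centroid = ctr,
       facets = idx_list[seq_len(nf)], P = P)
}

# Exact hull volume: sum of cone volumes from the centroid to each facet
# simplex, |det(facet vertices)| / m!.
brute_hull_volume <- function(points, oracle = NULL) {
  if (is.null(oracle)) oracle <- brute_hull_facets(points)
  m <- ncol(points)
  vols <- vapply(oracle$facets, function(idx) {
    abs(det(oracle$P[idx, , drop = FALSE]))
  }, numeric(1))
  sum(vols) / factorial(m)
}

# Rejection-sampling Monte-Carlo hull volume: uniform draws in the bounding
# box; membership tested against the brute-force facet inequalities with
# early rejection (points outside any facet block are dropped immediately).
mc_hull_volume <- function(points, oracle = NULL, ndraw = 1e6, seed = 1,
                           tol = 1e-9) {
  if (is.null(oracle)) oracle <- brute_hull_facets(points)
  m <- ncol(points)
  lo <- apply(oracle$P, 2, min)
  hi <- apply(oracle$P, 2, max)
  box <- prod(hi - lo)
  At <- t(oracle$A)
  fb <- split(seq_len(nrow(oracle$A)),
              ceiling(seq_len(nrow(oracle$A)) / 32))
  set.seed(seed)
  inside <- 0
  done <- 0
  block <- 2e5
  while (done < ndraw) {
    k <- min(block, ndraw - done)
    U <- matrix(stats::runif(k * m, rep(lo, each = k), rep(hi, each = k)),
                k, m)
    alive <- seq_len(k)
    for (fi in fb) {
      S <- U[alive, , drop = FALSE] %*% At[, fi, drop = FALSE]
      alive <- alive[rowSums(S > 1 + tol) == 0]
      if (length(alive) == 0L) break
    }
    inside <- inside + length(alive)
    done <- done + k
  }
  box * inside / ndraw
}

# Classical-scaling oracle via stats::cmdscale, for PCoA cross-checks.
cmdscale_coords <- function(D, k) {
  suppressWarnings(stats::cmdscale(stats::as.dist(D), k = k))
}
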