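# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-derivations, sharing no code with the package.

# Brute-force Delaunay edge oracle via the empty-circumcircle property.
# Circles through points i and j have centers m + t*u on the perpendicular
# bisector; each other point p is strictly inside such a circle for a
# half-line of t values, so an empty circle exists iff the intersection of
# the allowed half-lines is non-empty (1-D feasibility).
oracle_delaunay_edges <- function(x, y, tol = 1e-9) {
  n <- length(x)
  scale2 <- max(diff(range(x)), diff(range(y)), 1)^2
  edges <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m <- c((x[i] + x[j]) / 2, (y[i] + y[j]) / 2)
      dir <- c(x[j] - x[i], y[j] - y[i])
      u <- c(-dir[2L], dir[1L]) / sqrt(sum(dir^2))
      lo <- -Inf
      hi <- Inf
      feasible <- TRUE
      for (p in setdiff(seq_len(n), c(i, j))) {
        # p inside circle centered at m + t*u  <=>  A + B*t < 0
        A <- (m[1L] - x[p])^2 + (m[2L] - y[p])^2 -
          (m[1L] - x[i])^2 - (m[2L] - y[i])^2
        B <- 2 * (u[1L] * (x[i] - x[p]) + u[2L] * (y[i] - y[p]))
        if (abs(B) < tol * scale2) {
          if (A < -tol * scale2) { feasible <- FALSE; break }
        } else if (B > 0) {
          lo <- max(lo, -A / B)   # allowed: t >= -A/B
        } else {
          hi <- min(hi, -A / B)   # allowed: t <= -A/B
        }
      }
      if (feasible && lo <= hi + tol * scale2) {
        edges <- rbind(edges, c(i, j))
      }
    }
  }
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2L)
  edges
}

edge_key <- function(edges) {
  if (nrow(edges) == 0L) return(character(0))
  sort(paste(pmin(edges[, 1L], edges[, 2L]),
             pmax(edges[, 1L], edges[, 2L]), sep = "-"))
}

# Exhaustive k-medoids oracle: minimum total distance over every k-subset
# of candidate medoids.
oracle_kmedoids_cost <- function(d, k) {
  subsets <- utils::combn(nrow(d), k)
  best <- Inf
  for (s in seq_len(ncol(subsets))) {
    cost <- sum(apply(d[, subsets[, s], drop = FALSE], 1L, min))
    if (cost < best) best <- cost
  }
  best
}

# all k-subsets as a list of index vectors (for all-subset initialisation)
all_subsets <- function(n, k) {
  m <- utils::combn(n, k)
  lapply(seq_len(ncol(m)), function(i) m[, i])
}

# Exhaustive two-sided Mann-Whitney permutation p-value
oracle_permutation_p <- function(x1, x2) {
  pooled <- c(x1, x2)
  n1 <- length(x1)
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- u_stat(seq_len(n1))
  mu <- n1 * length(x2) / 2
  splits <- utils::combn(length(pooled), n1)
  us <- apply(splits, 2L, u_stat)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# chi-squared distance re-derived with plain arithmetic
oracle_chisq <- function(a, b) {
  total <- 0
  for (k in seq_along(a)) {
    if (a[k] + b[k] > 0) total <- total + (a[k] - b[k])^2 / (a[k] + b[k])
  }
  total
}

# adjusted Rand index (mclust's implementation, used as external check)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
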