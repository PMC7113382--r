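# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: literal formulas, brute-force enumeration, and
# generic numerical optimization.

# All-pairs shortest paths by Floyd-Warshall (hop counts, Inf if unreachable).
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      dk <- d[i, k] + d[k, ]
      d[i, ] <- pmin(d[i, ], dk)
    }
  }
  d
}

# Literal evaluation of the efficiency formula on a node subset: mean of
# 1/d over ordered pairs drawn from `nodes`, 1/Inf = 0.
oracle_efficiency <- function(d, nodes = seq_len(nrow(d))) {
  total <- 0
  m <- length(nodes)
  for (i in nodes) {
    for (j in nodes) {
      if (i != j) total <- total + 1 / d[i, j]
    }
  }
  total / (m * (m - 1))
}

# Random symmetric 0/1 adjacency with zero diagonal.
random_adjacency <- function(n, p = 0.2) {
  a <- matrix(0L, n, n)
  ut <- which(upper.tri(a))
  a[ut] <- as.integer(stats::runif(length(ut)) < p)
  a + t(a)
}

# Pearson correlation of two vectors from the textbook sum formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Pooled-variance two-sample t from the textbook formula.
oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# Benjamini-Hochberg step-up adjustment coded from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# OLS coefficients via the pseudoinverse / normal equations.
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

# Numerical maximum-likelihood fit of a recursive path model: minimizes
# F_ML = log det Sigma(theta) - log det S + tr(S Sigma^-1) - p over edge
# coefficients and endogenous residual log-variances, with the exogenous
# block fixed at its sample covariance. Returns the edge coefficients in
# the order of `edges`.
oracle_ml_path <- function(data, edges, variables) {
  X <- as.matrix(data[variables])
  n <- nrow(X)
  p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  endo <- unique(edges$to)
  exo <- setdiff(variables, endo)
  exo_i <- match(exo, variables)
  endo_i <- match(endo, variables)
  n_e <- nrow(edges)
  fml <- function(theta) {
    B <- matrix(0, p, p)
    for (k in seq_len(n_e)) {
      B[match(edges$to[k], variables), match(edges$from[k], variables)] <-
        theta[k]
    }
    Psi <- matrix(0, p, p)
    Psi[exo_i, exo_i] <- S[exo_i, exo_i]
    diag(Psi)[endo_i] <- exp(theta[n_e + seq_along(endo_i)])
    A <- solve(diag(p) - B)
    Sig <- A %*% Psi %*% t(A)
    v <- determinant(Sig, logarithm = TRUE)$modulus -
      determinant(S, logarithm = TRUE)$modulus +
      sum(diag(S %*% solve(Sig))) - p
    as.numeric(v)
  }
  init <- c(rep(0, n_e), rep(0, length(endo_i)))
  opt <- optim(init, fml, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  list(coefficients = opt$par[seq_len(n_e)], f_ml = opt$value)
}

# Small helper: analysis stage of the pipeline on an in-memory cohort
# (modwt -> level-4 correlation -> 5% threshold -> efficiency -> comparison).
analyze_cohort <- function(cohort, level = 4, density = 0.05) {
  adjs <- lapply(cohort$timeseries, function(x) {
    w <- modwt(x, levels = 6)
    threshold_to_density(correlation_matrix(wavelet_band_series(w, level)),
                         density)
  })
  eff <- cohort_efficiency(adjs, cohort$parcels)
  compare_cohort(eff, cohort$manifest)
}

# Validation-scale cohort configuration: Power-atlas-proportional network
# sizes at a third of the full region count.
validation_config <- function(seed, rho_ic = 0.35, rho_hc = 0.60, ...) {
  cohort_config(n_regions = 88,
                network_sizes = c(DMN = 19, SN = 6, FPN = 8),
                rho_within = c(IC = rho_ic, HC = rho_hc),
                seed = seed, ...)
}
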