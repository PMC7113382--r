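#' Residualize variables against nuisance covariates
#'
#' Replaces each target column with its OLS residual against an intercept
#' plus the covariate columns, then drops the covariates — the standard
#' preparation before a mediation/path analysis where nuisance variables
#' (sex, age, other substance use) must not masquerade as structural
#' effects. Factor covariates are expanded via the usual treatment coding.
#'
#' @param data Data frame with no missing values.
#' @param target_columns Columns to residualize (dependent and mediating
#'   variables).
#' @param covariate_columns Columns to regress out.
#' @return `data` with targets replaced by residuals and covariate columns
#'   removed.
#' @export
residualize <- function(data, target_columns, covariate_columns) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(target_columns, covariate_columns), names(data))
  if (length(missing_cols)) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(data[c(target_columns, covariate_columns)])) {
    stop("missing values are not supported; complete cases required")
  }
  X <- stats::model.matrix(~ ., data = data[covariate_columns])
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  for (tc in target_columns) {
    if (!is.numeric(data[[tc]])) stop("target column must be numeric: ", tc)
    data[[tc]] <- unname(qr.resid(qrx, data[[tc]]))
  }
  data[setdiff(names(data), covariate_columns)]
}

#' Specify a recursive path model
#'
#' A directed acyclic model among observed variables, given as a set of
#' `source -> target` edges. Variables with no incoming edge are exogenous.
#'
#' @param edges Either a character vector of `"source -> target"` lines or
#'   a two-column data frame (`from`, `to`).
#' @param variables Optional explicit variable ordering; defaults to order
#'   of first appearance.
#' @param exogenous Optional explicit exogenous set (no variable in it may
#'   receive an edge). By default every variable without an incoming edge
#'   is exogenous. Fixing the set explicitly keeps a variable "endogenous"
#'   (modeled with a residual variance only) even after all its incoming
#'   paths are trimmed away, which is what [trim_model()] does.
#' @return An object of class `waveconn_path_spec` with `variables`,
#'   `edges` (data frame), and `exogenous`.
#' @export
#' @examples
#' path_model_spec(c("group -> m", "m -> y", "group -> y"))
path_model_spec <- function(edges, variables = NULL, exogenous = NULL) {
  if (is.character(edges)) {
    lines <- trimws(edges[nzchar(trimws(edges))])
    parts <- strsplit(lines, "->", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("each edge must have the form 'source -> target'")
    }
    edges <- data.frame(from = trimws(vapply(parts, `[`, "", 1L)),
                        to = trimws(vapply(parts, `[`, "", 2L)),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  if (nrow(edges) == 0L) stop("model needs at least one edge")
  if (anyDuplicated(paste(edges$from, edges$to))) stop("duplicate edge in model")
  if (any(edges$from == edges$to)) stop("self-loop in model")
  vars <- variables %||% unique(c(rbind(edges$from, edges$to)))
  unknown <- setdiff(unique(c(edges$from, edges$to)), vars)
  if (length(unknown)) {
    stop("edge endpoint(s) not in variables: ", paste(unknown, collapse = ", "))
  }
  # Kahn's algorithm: verify acyclicity and get a topological order
  remaining <- edges
  order_out <- character(0)
  pool <- vars
  while (length(pool)) {
    free <- setdiff(pool, remaining$to)
    if (!length(free)) stop("model graph contains a cycle (must be recursive)")
    order_out <- c(order_out, free)
    remaining <- remaining[!(remaining$from %in% free), , drop = FALSE]
    pool <- setdiff(pool, free)
  }
  if (is.null(exogenous)) {
    exogenous <- setdiff(vars, unique(edges$to))
  } else {
    bad <- intersect(exogenous, edges$to)
    if (length(bad)) {
      stop("exogenous variable(s) receive edges: ", paste(bad, collapse = ", "))
    }
    if (length(setdiff(exogenous, vars))) stop("unknown exogenous variable")
  }
  structure(
    list(variables = vars, edges = edges, exogenous = exogenous,
         topological = order_out),
    class = "waveconn_path_spec"
  )
}

#' Read a path model spec from a text file
#'
#' One `source -> target` edge per line; blank lines and `#` comments are
#' ignored.
#'
#' @param path File path.
#' @return A `waveconn_path_spec`.
#' @export
read_path_spec <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  path_model_spec(lines[nzchar(trimws(lines))])
}

#' @export
print.waveconn_path_spec <- function(x, ...) {
  cat(sprintf("Recursive path model: %d variables, %d edges\n",
              length(x$variables), nrow(x$edges)))
  cat(paste0("  ", x$edges$from, " -> ", x$edges$to, collapse = "\n"), "\n")
  invisible(x)
}

# Precompile a spec against a variable ordering: per-endogenous index lists
# for the fast covariance-algebra coefficient solve used by the bootstrap.
.compile_spec <- function(spec, var_names) {
  idx <- match(spec$variables, var_names)
  if (anyNA(idx)) {
    stop("data lacks model variable(s): ",
         paste(spec$variables[is.na(idx)], collapse = ", "))
  }
  endo <- setdiff(spec$variables, spec$exogenous)
  list(
    vars = spec$variables,
    endo = endo,
    exo = spec$exogenous,
    data_idx = idx,
    eq = lapply(endo, function(tgt) {
      list(target = match(tgt, spec$variables),
           sources = match(spec$edges$from[spec$edges$to == tgt],
                           spec$variables))
    })
  )
}

# Coefficients and residual variances from an ML covariance matrix S
# (p x p, over spec$variables order). Returns list(B, psi) where B[i, j] is
# the coefficient of variable j in the equation for variable i.
.path_solve <- function(S, comp) {
  p <- nrow(S)
  B <- matrix(0, p, p)
  psi <- numeric(p)
  for (e in comp$eq) {
    s <- e$sources; t <- e$target
    if (length(s) == 0L) { # endogenous variable with all paths trimmed away
      psi[t] <- S[t, t]
      next
    }
    beta <- solve(S[s, s, drop = FALSE], S[s, t])
    B[t, s] <- beta
    psi[t] <- S[t, t] - drop(crossprod(S[s, t], beta))
  }
  list(B = B, psi = psi)
}

# Model-implied covariance from coefficients, residual variances, and the
# sample covariance of the exogenous block.
.implied_sigma <- function(S, comp, B, psi) {
  p <- nrow(S)
  exo_idx <- match(comp$exo, comp$vars)
  endo_idx <- match(comp$endo, comp$vars)
  Psi <- matrix(0, p, p)
  Psi[exo_idx, exo_idx] <- S[exo_idx, exo_idx]
  diag(Psi)[endo_idx] <- psi[endo_idx]
  A <- solve(diag(p) - B)
  A %*% Psi %*% t(A)
}

#' Fit a recursive path model by maximum likelihood
#'
#' Estimates the free path coefficients and residual variances of an
#' acyclic (recursive) model among observed variables. For such models
#' with complete data and no cross-equation constraints the maximum of the
#' multivariate-normal likelihood is attained at the equation-by-equation
#' OLS solution, which is what is computed; the ML discrepancy
#' \deqn{F_{ML} = \ln|\Sigma(\theta)| - \ln|S| + tr(S\Sigma(\theta)^{-1}) - p}
#' is then evaluated at that optimum to give the chi-square test of exact
#' fit (`(n-1) F_ML`), CFI against the independence baseline, and RMSEA.
#' Degrees of freedom are `p(p+1)/2` minus the number of free parameters
#' (edges, endogenous residual variances, and the exogenous covariance
#' block).
#'
#' @param spec A [path_model_spec()].
#' @param data Data frame containing every model variable (numeric). Means
#'   are not modeled; columns are centered internally.
#' @return An object of class `waveconn_path_fit`: `estimates` (data frame
#'   with unstandardized and standardized coefficients, SEs, p-values),
#'   `residual_variances`, `r_squared`, `chi_square`, `df`, `p_fit`,
#'   `cfi`, `rmsea`, `n`.
#' @export
fit_path_model <- function(spec, data) {
  stopifnot(inherits(spec, "waveconn_path_spec"), is.data.frame(data))
  comp <- .compile_spec(spec, names(data))
  X <- as.matrix(data[spec$variables])
  if (!is.numeric(X) || anyNA(X)) stop("model variables must be numeric and complete")
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("need more observations than variables")
  Xc <- sweep(X, 2L, colMeans(X))
  S <- crossprod(Xc) / n # ML covariance (divisor n)
  if (!all(is.finite(S)) || det(S) <= 0) {
    stop("sample covariance is not positive definite")
  }

  sol <- .path_solve(S, comp)
  sigma_hat <- .implied_sigma(S, comp, sol$B, sol$psi)

  # per-equation standard errors (OLS, residual df = n - k - 1 for the
  # implicit intercept)
  est <- spec$edges
  est$estimate <- est$se <- est$statistic <- est$p <- est$std <- NA_real_
  df_resid <- rep(NA_real_, nrow(est))
  for (e in comp$eq) {
    s <- e$sources; t <- e$target
    k <- length(s)
    if (k == 0L) next
    beta <- sol$B[t, s]
    sigma2 <- sol$psi[t] * n / (n - k - 1)
    covb <- sigma2 * solve(S[s, s, drop = FALSE] * n)
    rows <- which(est$to == spec$variables[t])
    ord <- match(match(est$from[rows], spec$variables), s)
    est$estimate[rows] <- beta[ord]
    est$se[rows] <- sqrt(diag(covb))[ord]
    df_resid[rows] <- n - k - 1
  }
  est$statistic <- est$estimate / est$se
  est$p <- 2 * stats::pt(-abs(est$statistic), df = df_resid)
  sds <- sqrt(diag(sigma_hat))
  est$std <- est$estimate * sds[match(est$from, spec$variables)] /
    sds[match(est$to, spec$variables)]
  est <- est[c("from", "to", "estimate", "se", "statistic", "p", "std")]

  # fit statistics
  f_ml <- determinant(sigma_hat, logarithm = TRUE)$modulus -
    determinant(S, logarithm = TRUE)$modulus +
    sum(diag(S %*% solve(sigma_hat))) - p
  f_ml <- max(as.numeric(f_ml), 0)
  chi_square <- (n - 1) * f_ml
  q <- length(comp$exo)
  n_free <- nrow(spec$edges) + length(comp$endo) + q * (q + 1) / 2
  df <- p * (p + 1) / 2 - n_free
  if (df < 0) stop("model is over-parameterized (negative degrees of freedom)")
  p_fit <- if (df > 0) stats::pchisq(chi_square, df, lower.tail = FALSE) else NA_real_
  # independence baseline: all covariances zero, variances free
  chi_b <- (n - 1) * (sum(log(diag(S))) -
                        as.numeric(determinant(S, logarithm = TRUE)$modulus))
  df_b <- p * (p - 1) / 2
  denom <- max(chi_b - df_b, chi_square - df, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chi_square - df, 0) / denom
  cfi <- min(max(cfi, 0), 1)
  rmsea <- if (df > 0) sqrt(max(chi_square - df, 0) / (df * (n - 1))) else 0

  endo_idx <- match(comp$endo, spec$variables)
  r2 <- 1 - sol$psi[endo_idx] / diag(sigma_hat)[endo_idx]

  structure(
    list(spec = spec, estimates = est,
         residual_variances = stats::setNames(sol$psi[endo_idx], comp$endo),
         r_squared = stats::setNames(r2, comp$endo),
         chi_square = chi_square, df = df, p_fit = p_fit,
         cfi = cfi, rmsea = rmsea, n = n,
         sample_cov = S, implied_cov = sigma_hat),
    class = "waveconn_path_fit"
  )
}

#' @export
print.waveconn_path_fit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Recursive path model fit (n = %d): chi-square = %.2f, df = %d, p = %s\n",
    x$n, x$chi_square, x$df,
    if (is.na(x$p_fit)) "NA (saturated)" else format.pval(x$p_fit, digits)))
  cat(sprintf("CFI = %.3f, RMSEA = %.3f\n", x$cfi, x$rmsea))
  print(x$estimates, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Bootstrap confidence interval for an indirect effect
#'
#' Point estimate and nonparametric case-resampling bootstrap percentile
#' confidence interval for the product of coefficients along a mediator
#' chain (e.g. group -> DMN efficiency -> Stroop score). Each bootstrap
#' replicate resamples subjects with replacement and refits the full
#' model; replicates whose fit fails (singular resampled covariance) are
#' dropped and counted, and more than 5% failures is an error.
#'
#' @param spec A [path_model_spec()]; every consecutive pair in `path`
#'   must be one of its edges.
#' @param data Data frame with the model variables.
#' @param path Character vector of variables along the chain, e.g.
#'   `c("group", "m", "y")`.
#' @param n_boot Number of bootstrap replicates (>= 1000 recommended).
#' @param seed Seed; results are bit-reproducible under `(seed, n_boot)`.
#' @param level Confidence level (default 0.95).
#' @return An object of class `waveconn_indirect`: `path`,
#'   `point_estimate`, `ci_low`, `ci_high`, `boot_estimates`, `n_boot`,
#'   `n_failed`, `seed`, `level`.
#' @export
indirect_effect <- function(spec, data, path, n_boot = 1000L, seed = 1L,
                            level = 0.95) {
  stopifnot(inherits(spec, "waveconn_path_spec"), length(path) >= 2,
            n_boot >= 1)
  for (i in seq_len(length(path) - 1L)) {
    ok <- any(spec$edges$from == path[i] & spec$edges$to == path[i + 1L])
    if (!ok) {
      stop(sprintf("path step '%s -> %s' is not an edge of the model",
                   path[i], path[i + 1L]))
    }
  }
  comp <- .compile_spec(spec, names(data))
  X <- as.matrix(data[spec$variables])
  n <- nrow(X)
  steps <- cbind(match(path[-length(path)], spec$variables),
                 match(path[-1L], spec$variables))
  product_along <- function(B) prod(B[cbind(steps[, 2L], steps[, 1L])])

  point <- {
    Xc <- sweep(X, 2L, colMeans(X))
    product_along(.path_solve(crossprod(Xc) / n, comp)$B)
  }

  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      Xb <- sweep(Xb, 2L, colMeans(Xb))
      tryCatch(product_along(.path_solve(crossprod(Xb) / n, comp)$B),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  n_failed <- sum(is.na(boot))
  if (n_failed > 0.05 * n_boot) {
    stop(sprintf("%d of %d bootstrap replicates failed to fit",
                 n_failed, n_boot))
  }
  boot_ok <- boot[!is.na(boot)]
  alpha <- (1 - level) / 2
  ci <- stats::quantile(boot_ok, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(
    list(path = path, point_estimate = point,
         ci_low = ci[1L], ci_high = ci[2L],
         boot_estimates = boot_ok, n_boot = as.integer(n_boot),
         n_failed = n_failed, seed = seed, level = level),
    class = "waveconn_indirect"
  )
}

#' @export
print.waveconn_indirect <- function(x, digits = 3, ...) {
  cat(sprintf("Indirect effect %s: %.4f, %g%% bootstrap CI [%.4f, %.4f] (%d reps)\n",
              paste(x$path, collapse = " -> "), x$point_estimate,
              100 * x$level, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Trim nonsignificant paths from a model
#'
#' Backward elimination: repeatedly refit and remove the single path with
#' the largest p-value above `alpha` (ties broken by lexicographic edge
#' order, so the procedure is deterministic), until every remaining path
#' is significant. Each removal frees one parameter, so model degrees of
#' freedom strictly increase along the way.
#'
#' @param spec Initial [path_model_spec()].
#' @param data Data frame with the model variables.
#' @param alpha Significance threshold for keeping a path (default 0.05).
#' @return List with the trimmed `spec`, its `fit`, and `removed` (data
#'   frame of eliminated edges in removal order).
#' @export
trim_model <- function(spec, data, alpha = 0.05) {
  removed <- spec$edges[0, , drop = FALSE]
  repeat {
    fit <- fit_path_model(spec, data)
    est <- fit$estimates
    cand <- which(est$p > alpha)
    if (!length(cand)) break
    worst <- cand[order(-est$p[cand], est$from[cand], est$to[cand])][1L]
    keep <- spec$edges[-which(spec$edges$from == est$from[worst] &
                                spec$edges$to == est$to[worst]), ,
                       drop = FALSE]
    if (nrow(keep) == 0L) break # an edgeless model is not representable
    removed <- rbind(removed, est[worst, c("from", "to")])
    # keep the endogenous/exogenous designation of the initial model so
    # each removal frees exactly one parameter
    spec <- path_model_spec(keep, variables = spec$variables,
                            exogenous = spec$exogenous)
  }
  list(spec = spec, fit = fit, removed = removed)
}
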