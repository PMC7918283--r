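# Maximum-entropy reference model for polygon edge-count distributions.
#
# The entropically ideal network maximises the Shannon entropy of p_n
# subject to normalisation, a fixed mean edge count <n>, and one further
# moment constraint sum g(n) p_n = c. The solution is the exponential family
# p_n = exp(-lambda0 - lambda1 n - lambda2 g(n)); the multipliers are found
# by minimising the convex dual (log-partition plus linear terms), which is
# equivalent to root-finding on the constraint residuals but better behaved.
#
# The printed form of the third constraint is typographically ambiguous in
# the source literature; following the Lemaitre-law maximum-entropy
# tradition the default is g(n) = 1/n, and g is pluggable.

#' Solve the maximum-entropy polygon distribution
#'
#' Finds `p_n` on an integer support maximising entropy subject to
#' `sum(p_n) = 1`, `sum(n p_n) = mean_n` and `sum(g(n) p_n) = c_target`.
#'
#' @param mean_n target mean edge count
#' @param c_target target value of the third constraint (defaults to the
#'   value attained by the two-constraint solution, making the third
#'   constraint inactive when not supplied)
#' @param support integer vector of allowed edge counts (default 3:20)
#' @param g the third-constraint function of n (default `1/n`)
#' @param n_starts multi-start count for the dual optimisation (the fitting
#'   procedure is prone to failure for extreme constraint sets, so several
#'   starting multipliers are tried)
#' @param tol residual tolerance on the constraints
#' @return list with `p` (named vector over the support), `lambda`
#'   (lambda0, lambda1, lambda2), `residuals`, `entropy`, `converged`
#' @export
#' @examples
#' solve_maxent(mean_n = 6)$p
solve_maxent <- function(mean_n, c_target = NULL, support = 3:20,
                         g = function(n) 1 / n, n_starts = 8, tol = 1e-10) {
  support <- sort(unique(as.integer(support)))
  if (length(support) < 1) stop("empty support", call. = FALSE)
  if (mean_n < min(support) || mean_n > max(support))
    stop("`mean_n` must lie within the support range", call. = FALSE)
  gn <- vapply(support, g, numeric(1))
  if (length(support) == 1) {
    p <- setNames(1, support)
    return(list(p = p, lambda = c(lambda0 = 0, lambda1 = 0, lambda2 = 0),
                residuals = c(norm = 0, mean_n = 0, c = 0),
                entropy = 0, converged = TRUE))
  }
  two_constraints <- is.null(c_target)

  # convex dual: psi(l) = log Z(l) + l1 mean_n + l2 c_target
  dual <- function(l, use2) {
    e <- -l[1] * support - (if (use2) l[2] * gn else 0)
    m <- max(e)
    lz <- m + log(sum(exp(e - m)))
    lz + l[1] * mean_n + (if (use2) l[2] * c_target else 0)
  }
  grad <- function(l, use2) {
    e <- -l[1] * support - (if (use2) l[2] * gn else 0)
    w <- exp(e - max(e)); w <- w / sum(w)
    g1 <- mean_n - sum(support * w)
    if (use2) c(g1, c_target - sum(gn * w)) else g1
  }
  solve_dual <- function(use2) {
    # deterministic spread of starting multipliers (no RNG side effects)
    vals <- c(0, -0.5, 0.5, -2, 2, -5, 5, 10)[seq_len(max(n_starts, 2))]
    starts <- if (use2) lapply(vals, function(v) c(v, -v / 2)) else
      lapply(vals, function(v) v)
    best <- NULL
    for (st in starts) {
      fit <- tryCatch(
        optim(st, dual, grad, use2 = use2, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-15)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    best
  }
  use2 <- !two_constraints
  best <- solve_dual(use2)
  if (is.null(best))
    return(list(p = NULL, lambda = NULL, residuals = NULL, entropy = NA_real_,
                converged = FALSE))
  # Newton polish on the convex dual (Hessian = covariance of (n, g(n)))
  l <- best$par
  for (it in 1:50) {
    e <- -l[1] * support - (if (use2) l[2] * gn else 0)
    w <- exp(e - max(e)); w <- w / sum(w)
    gr <- if (use2) c(mean_n - sum(support * w), c_target - sum(gn * w)) else
      mean_n - sum(support * w)
    if (max(abs(gr)) < 1e-13) break
    if (use2) {
      mn <- sum(support * w); mg <- sum(gn * w)
      H <- matrix(c(sum(support^2 * w) - mn^2,
                    sum(support * gn * w) - mn * mg,
                    sum(support * gn * w) - mn * mg,
                    sum(gn^2 * w) - mg^2), 2, 2)
      step <- tryCatch(solve(H + diag(1e-14, 2), gr), error = function(e) NULL)
    } else {
      H <- sum(support^2 * w) - sum(support * w)^2
      step <- gr / max(H, 1e-14)
    }
    if (is.null(step) || !all(is.finite(step))) break
    l <- l - step
  }
  best$par <- l
  l1 <- best$par[1]; l2 <- if (use2) best$par[2] else 0
  e <- -l1 * support - l2 * gn
  m <- max(e)
  z <- sum(exp(e - m))
  p <- exp(e - m) / z
  lambda0 <- m + log(z)
  res <- c(norm = abs(sum(p) - 1),
           mean_n = abs(sum(support * p) - mean_n),
           c = if (use2) abs(sum(gn * p) - c_target) else 0)
  list(p = setNames(p, support),
       lambda = c(lambda0 = lambda0, lambda1 = l1, lambda2 = l2),
       residuals = res,
       entropy = -sum(ifelse(p > 0, p * log(p), 0)),
       converged = all(res < tol))
}

#' Fit the maximum-entropy model to an observed polygon distribution
#'
#' Takes the constraints (observed `<n>` and observed `sum g(n) p_n`) from
#' the data, solves for the maximum-entropy distribution on the same pooled
#' support, and reports the Kullback-Leibler divergence observed||fitted
#' together with per-n residuals. In self-assembled polymer networks the
#' residuals are diagnostic: angular strain suppresses triangles below and
#' enriches squares above the entropic expectation.
#'
#' @param observed a `cw_polygons` object, an integer vector of polygon edge
#'   counts, or a data frame with columns n and p (or count)
#' @param support fitting support; observed sizes outside it are pooled into
#'   the nearest boundary bin
#' @param g third-constraint function, see [solve_maxent()]
#' @return an object of class `cw_maxent_fit` with observed and fitted
#'   distributions, multipliers, divergence and convergence status
#' @export
fit_maxent <- function(observed, support = 3:20, g = function(n) 1 / n) {
  if (inherits(observed, "cw_polygons"))
    observed <- vapply(observed$polygons, function(p) p$n, numeric(1))
  if (is.data.frame(observed)) {
    pcol <- if ("p" %in% names(observed)) observed$p else observed$count
    obs <- setNames(pcol / sum(pcol), observed$n)
  } else {
    tb <- table(observed)
    obs <- setNames(as.numeric(tb) / sum(tb), names(tb))
  }
  if (length(obs) < 2 && length(unique(names(obs))) < 2) {
    # degenerate observed distribution: the fit is the observation itself
    n0 <- as.integer(names(obs)[1])
    out <- structure(
      list(support = n0, observed = setNames(1, n0), fitted = setNames(1, n0),
           lambda = c(lambda0 = 0, lambda1 = 0, lambda2 = 0),
           divergence = 0, residuals = setNames(0, n0), converged = TRUE,
           mean_n = n0, c_value = g(n0)),
      class = "cw_maxent_fit")
    return(out)
  }
  support <- sort(unique(as.integer(support)))
  ns <- as.integer(names(obs))
  pooled <- pmin(pmax(ns, min(support)), max(support))
  obs_p <- vapply(support, function(n) sum(obs[pooled == n]), numeric(1))
  names(obs_p) <- support
  mean_n <- sum(support * obs_p)
  c_val <- sum(vapply(support, g, numeric(1)) * obs_p)
  sol <- solve_maxent(mean_n, c_val, support = support, g = g)
  fitted <- sol$p
  div <- if (!is.null(fitted))
    sum(ifelse(obs_p > 0, obs_p * log(obs_p / fitted), 0)) else NA_real_
  structure(
    list(support = support, observed = obs_p, fitted = fitted,
         lambda = sol$lambda, divergence = div,
         residuals = if (!is.null(fitted)) obs_p - fitted else NULL,
         converged = isTRUE(sol$converged),
         mean_n = mean_n, c_value = c_val),
    class = "cw_maxent_fit")
}

#' @export
print.cw_maxent_fit <- function(x, ...) {
  cat(sprintf("<cw_maxent_fit> support %d..%d, <n> = %.3f, KL = %.4g, %s\n",
              min(x$support), max(x$support), x$mean_n, x$divergence,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @describeIn fit_maxent tidy per-n table: observed, fitted, residual
#' @param x a `cw_maxent_fit`
#' @param ... unused
#' @export
tidy.cw_maxent_fit <- function(x, ...) {
  tibble::tibble(n = as.integer(names(x$observed)),
                 observed = as.numeric(x$observed),
                 fitted = if (is.null(x$fitted)) NA_real_ else
                   as.numeric(x$fitted),
                 residual = if (is.null(x$residuals)) NA_real_ else
                   as.numeric(x$residuals))
}

#' @describeIn fit_maxent one-row summary: divergence, multipliers,
#'   convergence
#' @export
glance.cw_maxent_fit <- function(x, ...) {
  tibble::tibble(mean_n = x$mean_n, c_value = x$c_value,
                 kl_divergence = x$divergence,
                 lambda0 = x$lambda[["lambda0"]],
                 lambda1 = x$lambda[["lambda1"]],
                 lambda2 = x$lambda[["lambda2"]],
                 converged = x$converged)
}
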