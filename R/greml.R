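## ---------------------------------------------------------------------------
## GREML: variance-component estimation with AI-REML (EM warm start)
##
## Model: y = X b + sum_k g_k + e,  g_k ~ N(0, A_k sigma2_k),  e ~ N(0, I sigma2_e)
## Restricted log-likelihood (constant terms dropped):
##   lR = -1/2 [ log|V| + log|X' V^-1 X| + y' P y ],
##   V = sum_k sigma2_k A_k + sigma2_e I,
##   P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1
## ---------------------------------------------------------------------------

## one dense evaluation of the restricted likelihood and its by-products
.reml_eval_dense <- function(theta, y, X, Alist) {
  n <- length(y); k <- length(Alist)
  V <- diag(theta[k + 1L], n)
  for (j in seq_len(k)) V <- V + theta[j] * Alist[[j]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vinv <- chol2inv(ch)
  W <- Vinv %*% X
  XtVX <- crossprod(X, W)
  cX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(cX)) return(NULL)
  beta <- backsolve(cX, forwardsolve(t(cX), crossprod(W, y)))
  Py <- Vinv %*% y - W %*% beta
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(cX))) + sum(y * Py))
  list(ll = as.numeric(ll), Vinv = Vinv, W = W, XtVX = XtVX,
       beta = as.numeric(beta), Py = as.numeric(Py))
}

## score vector and average-information matrix at a dense evaluation
.reml_grad_dense <- function(ev, y, X, Alist) {
  k <- length(Alist); n <- length(y)
  Py <- ev$Py
  Q <- matrix(0, n, k + 1L)
  for (j in seq_len(k)) Q[, j] <- Alist[[j]] %*% Py
  Q[, k + 1L] <- Py
  Pv <- function(v) ev$Vinv %*% v - ev$W %*% solve(ev$XtVX, crossprod(ev$W, v))
  PQ <- Pv(Q)
  AI <- 0.5 * crossprod(Q, PQ)
  trPA <- numeric(k + 1L)
  XtVXinv <- solve(ev$XtVX)
  for (j in seq_len(k)) {
    AW <- Alist[[j]] %*% ev$W
    trPA[j] <- sum(ev$Vinv * Alist[[j]]) - sum(XtVXinv * crossprod(ev$W, AW))
  }
  trPA[k + 1L] <- sum(diag(ev$Vinv)) - sum(XtVXinv * crossprod(ev$W))
  score <- -0.5 * (trPA - colSums(Py * Q))
  list(score = score, AI = AI)
}

## spectral analogue: one genetic component with eigenvalues d (V diagonal)
.reml_eval_diag <- function(theta, y, X, d) {
  v <- theta[1L] * d + theta[2L]
  if (any(v <= 0)) return(NULL)
  W <- X / v
  XtVX <- crossprod(X, W)
  cX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(cX)) return(NULL)
  beta <- backsolve(cX, forwardsolve(t(cX), crossprod(W, y)))
  Py <- y / v - W %*% beta
  ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(cX))) + sum(y * Py))
  list(ll = as.numeric(ll), v = v, W = W, XtVX = XtVX,
       beta = as.numeric(beta), Py = as.numeric(Py))
}

.reml_grad_diag <- function(ev, y, X, d) {
  Py <- ev$Py
  Q <- cbind(d * Py, Py)
  Pv <- function(vv) vv / ev$v - ev$W %*% solve(ev$XtVX, crossprod(ev$W, vv))
  PQ <- Pv(Q)
  AI <- 0.5 * crossprod(Q, PQ)
  XtVXinv <- solve(ev$XtVX)
  trPA <- c(sum(d / ev$v) - sum(XtVXinv * crossprod(ev$W, d * ev$W)),
            sum(1 / ev$v) - sum(XtVXinv * crossprod(ev$W)))
  score <- -0.5 * (trPA - colSums(Py * Q))
  list(score = score, AI = AI)
}

## generic AI-REML driver over an abstract evaluator
.reml_iterate <- function(y, X, evalf, gradf, k, constrain, max_iter, tol, n_em,
                          var_floor) {
  vp <- stats::var(y)
  theta <- rep(vp / (k + 1L), k + 1L)
  floor_v <- var_floor * vp
  ev <- evalf(theta)
  .assert(!is.null(ev), "restricted likelihood not evaluable at the starting values")
  ll <- ev$ll
  converged <- FALSE
  singular_ai <- FALSE
  it <- 0L
  AI <- NULL
  while (it < max_iter) {
    it <- it + 1L
    g <- gradf(ev)
    AI <- g$AI
    if (it <= n_em) {
      ## EM step: guaranteed ascent, robust far from the optimum
      delta <- theta^2 * (2 * g$score) / length(y)
      prop <- theta + delta
    } else {
      ## active set: components clamped at the floor whose score still
      ## points outward stay fixed, so the AI step is well-conditioned
      free <- !(constrain & theta <= floor_v * (1 + 1e-6) & g$score < 0)
      if (!any(free)) free <- rep(TRUE, length(theta))
      AIf <- AI[free, free, drop = FALSE]
      rc <- tryCatch(rcond(AIf), error = function(e) 0)
      delta <- numeric(length(theta))
      if (rc < 1e-12) {
        if (!singular_ai)
          warning("average-information matrix is near-singular; variance components may be non-identifiable",
                  call. = FALSE)
        singular_ai <- TRUE
        delta[free] <- (theta^2 * (2 * g$score) / length(y))[free]
      } else {
        step <- tryCatch(solve(AIf, g$score[free]), error = function(e) NULL)
        if (is.null(step)) step <- (theta^2 * (2 * g$score) / length(y))[free]
        delta[free] <- step
      }
      prop <- theta + delta
    }
    if (constrain) prop <- pmax(prop, floor_v)
    ev_new <- evalf(prop)
    halve <- 0L
    while ((is.null(ev_new) || ev_new$ll < ll - 1e-10) && halve < 12L) {
      delta <- delta / 2
      prop <- theta + delta
      if (constrain) prop <- pmax(prop, floor_v)
      ev_new <- evalf(prop)
      halve <- halve + 1L
    }
    if (is.null(ev_new)) break
    d_ll <- ev_new$ll - ll
    theta <- prop; ev <- ev_new; ll <- ev$ll
    if (it > n_em && abs(d_ll) < tol) { converged <- TRUE; break }
  }
  rc_final <- tryCatch(rcond(AI), error = function(e) 0)
  if (!is.finite(rc_final) || rc_final < 1e-12) singular_ai <- TRUE
  list(theta = theta, ll = ll, ev = ev, AI = AI, n_iter = it,
       converged = converged, singular_ai = singular_ai)
}

## restricted log-likelihood of the null model (V = sigma2_e I), same
## dropped-constant convention as above
.reml_null <- function(y, X) {
  n <- length(y); p <- ncol(X)
  qrX <- qr(X)
  rss <- sum(qr.resid(qrX, y)^2)
  s2 <- rss / (n - p)
  ldXX <- 2 * sum(log(abs(diag(qr.R(qrX)))))
  ll <- -0.5 * ((n - p) * log(s2) + ldXX + (n - p))
  list(ll = ll, sigma2 = s2)
}

#' Fit a GREML variance-component model (AI-REML with EM warm start)
#'
#' Estimates the variance explained by one or several genetic relatedness
#' matrices for a phenotype (binary disease status is analyzed as a 0/1
#' quantitative trait on the observed scale, the standard GCTA practice for
#' case-control data, with liability rescaling done afterwards by
#' [observed_to_liability()]). Optimization starts with a few
#' expectation-maximization steps and then switches to average-information
#' updates with step-halving; convergence is declared when the restricted
#' log-likelihood changes by less than `tol`.
#'
#' With a single GRM the model is refit in the GRM's eigenbasis, where the
#' covariance is diagonal and each iteration costs O(n) instead of O(n^3);
#' the two paths maximize the same restricted likelihood.
#'
#' @param y Numeric phenotype vector (0/1 for disease status).
#' @param X Covariate design matrix including an intercept; must have full
#'   column rank.
#' @param grms A `"grm"` object or list of them (one variance component
#'   each); GCTA binary GRM path prefixes are accepted and read with
#'   [read_gcta_grm()].
#' @param constrain Clamp variance components to a small positive floor
#'   (`1e-8` of the phenotypic variance) instead of allowing negative
#'   estimates (default `TRUE`).
#' @param max_iter,tol Iteration cap (default 100) and log-likelihood
#'   convergence tolerance (default 1e-6).
#' @param n_em Number of initial EM iterations before AI updates (default 3).
#' @param method `"auto"` (spectral when a single GRM is supplied),
#'   `"dense"`, or `"spectral"`.
#' @return An object of class `"greml"`; see [summary.greml()]. Key fields:
#'   `sigma2` (named variance components, residual last), `se_sigma2`,
#'   `h2_obs` and `se_h2` (observed-scale heritability and its standard
#'   error from the inverse AI matrix by the delta method), `loglik`,
#'   `loglik_null`, `lrt`, `df`, `p_lrt` (0.5:0.5 chi-square mixture for one
#'   component; conservative chi-square with k degrees of freedom for k
#'   components), `n_iter`, `converged`.
#' @references Yang J, Lee SH, Goddard ME, Visscher PM (2011) GCTA: a tool
#'   for genome-wide complex trait analysis. Am J Hum Genet 88:76-82.
#' @examples
#' g <- simulate_genotypes(300, 400, seed = 2)
#' y <- rbinom(300, 1, 0.5)
#' fit <- reml_fit(y, cbind(1, rnorm(300)), compute_grm(g))
#' fit$h2_obs
#' @export
reml_fit <- function(y, X, grms, constrain = TRUE, max_iter = 100, tol = 1e-6,
                     n_em = 3, method = c("auto", "dense", "spectral")) {
  method <- match.arg(method)
  if (inherits(grms, "grm")) grms <- list(grms)
  if (is.character(grms)) grms <- lapply(grms, read_gcta_grm)
  grms <- lapply(grms, function(g) if (is.character(g)) read_gcta_grm(g) else g)
  .assert(length(grms) >= 1L && all(vapply(grms, inherits, TRUE, "grm")),
          "'grms' must be a grm object, a list of them, or GCTA GRM path prefixes")
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  .assert(nrow(X) == n, "nrow(X) must equal length(y)")
  .assert(all(vapply(grms, function(g) nrow(g$values), 1L) == n),
          "GRM dimensions must match length(y)")
  .assert(qr(X)$rank == ncol(X), "covariate design matrix is singular")
  k <- length(grms)
  if (method == "auto") method <- if (k == 1L) "spectral" else "dense"
  .assert(!(method == "spectral" && k > 1L),
          "spectral method supports a single GRM only")

  null <- .reml_null(y, X)

  if (method == "spectral") {
    eig <- eigen(grms[[1L]]$values, symmetric = TRUE)
    d <- pmax(eig$values, 0)
    ys <- as.numeric(crossprod(eig$vectors, y))
    Xs <- crossprod(eig$vectors, X)
    res <- .reml_iterate(ys, Xs,
                         evalf = function(th) .reml_eval_diag(th, ys, Xs, d),
                         gradf = function(ev) .reml_grad_diag(ev, ys, Xs, d),
                         k = 1L, constrain = constrain, max_iter = max_iter,
                         tol = tol, n_em = n_em, var_floor = 1e-8)
    Py <- as.numeric(eig$vectors %*% res$ev$Py)
  } else {
    Alist <- lapply(grms, `[[`, "values")
    res <- .reml_iterate(y, X,
                         evalf = function(th) .reml_eval_dense(th, y, X, Alist),
                         gradf = function(ev) .reml_grad_dense(ev, y, X, Alist),
                         k = k, constrain = constrain, max_iter = max_iter,
                         tol = tol, n_em = n_em, var_floor = 1e-8)
    Py <- res$ev$Py
  }
  if (!res$converged)
    warning("REML did not converge in ", max_iter, " iterations", call. = FALSE)

  theta <- res$theta
  comp_names <- c(if (k == 1L) "V(G)" else sprintf("V(G%d)", seq_len(k)), "V(e)")
  names(theta) <- comp_names
  covtheta <- tryCatch(solve(res$AI), error = function(e)
    matrix(NA_real_, k + 1L, k + 1L))
  se_theta <- sqrt(pmax(diag(covtheta), 0))
  G <- sum(theta[seq_len(k)]); Tot <- G + theta[k + 1L]
  h2 <- G / Tot
  grad <- c(rep((Tot - G) / Tot^2, k), -G / Tot^2)
  se_h2 <- sqrt(max(0, as.numeric(t(grad) %*% covtheta %*% grad)))

  lrt <- max(0, 2 * (res$ll - null$ll))
  p_lrt <- if (k == 1L) 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  else stats::pchisq(lrt, df = k, lower.tail = FALSE)

  fixef <- res$ev$beta
  names(fixef) <- colnames(X) %||% sprintf("x%d", seq_len(ncol(X)))
  vcov_fixef <- solve(res$ev$XtVX)
  dimnames(vcov_fixef) <- list(names(fixef), names(fixef))

  structure(list(
    sigma2 = theta, se_sigma2 = stats::setNames(se_theta, comp_names),
    cov_sigma2 = covtheta,
    h2_obs = h2, se_h2 = se_h2,
    loglik = res$ll, loglik_null = null$ll, lrt = lrt,
    df = if (k == 1L) 1L else k, p_lrt = p_lrt,
    n_iter = res$n_iter, converged = res$converged,
    singular_ai = res$singular_ai,
    fixef = fixef, vcov_fixef = vcov_fixef,
    Py = Py, y = y,
    n = n, n_snps = vapply(grms, function(g) as.numeric(g$n_snps), 0),
    method = method, call = match.call()
  ), class = "greml")
}

#' Fit a GREML model with a formula interface
#'
#' Formula front end to [reml_fit()]: the left-hand side is the phenotype,
#' the right-hand side the fixed-effect covariates (an intercept is added as
#' usual), and the random genetic effects are given by `grms`.
#'
#' @param formula Model formula, e.g. `status ~ sex + age`.
#' @param data Data frame holding the formula's variables (e.g. a
#'   `cohort_table`).
#' @param grms A `"grm"` object or list of them.
#' @param ... Passed on to [reml_fit()].
#' @return A `"greml"` fit.
#' @examples
#' sim <- simulate_cohort(n_cases = 60, n_controls = 60, n_snps = 150, seed = 3)
#' fit <- greml(status ~ sex, data = sim$cohort, grms = compute_grm(sim$geno))
#' summary(fit)
#' @export
greml <- function(formula, data, grms, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- reml_fit(y, X, grms, ...)
  fit$call <- match.call()
  fit$formula <- formula
  fit
}

#' @export
print.greml <- function(x, digits = 4, ...) {
  cat("GREML fit (", x$method, " AI-REML, ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$n_iter, " iterations)\n", sep = "")
  cat(sprintf("  n = %d; GRM SNP counts: %s\n", x$n,
              paste(x$n_snps, collapse = ", ")))
  comp <- format(round(x$sigma2, digits))
  cat("  variance components:\n")
  for (i in seq_along(comp))
    cat(sprintf("    %-6s %s (SE %s)\n", names(comp)[i], comp[i],
                format(round(x$se_sigma2[i], digits))))
  cat(sprintf("  h2 (observed scale) = %.4f (SE %.4f)\n", x$h2_obs, x$se_h2))
  cat(sprintf("  LRT = %.4f, df = %d, p = %.3g\n", x$lrt, x$df, x$p_lrt))
  invisible(x)
}

#' Summarize a GREML fit
#'
#' @param object A `"greml"` fit.
#' @param ... Unused.
#' @return An object of class `"summary.greml"` with the variance-component
#'   table, observed-scale heritability, and the likelihood-ratio test.
#' @export
summary.greml <- function(object, ...) {
  k <- length(object$sigma2) - 1L
  vp <- sum(object$sigma2)
  tab <- data.frame(Variance = unname(object$sigma2),
                    SE = unname(object$se_sigma2),
                    row.names = names(object$sigma2))
  tab <- rbind(tab, Vp = c(vp, NA))
  tab <- rbind(tab, `V(G)/Vp` = c(object$h2_obs, object$se_h2))
  structure(list(components = tab, h2_obs = object$h2_obs,
                 se_h2 = object$se_h2, loglik = object$loglik,
                 loglik_null = object$loglik_null, lrt = object$lrt,
                 df = object$df, p_lrt = object$p_lrt, n = object$n,
                 converged = object$converged, fixef = object$fixef),
            class = "summary.greml")
}

#' @export
print.summary.greml <- function(x, digits = 4, ...) {
  cat("GREML variance components:\n")
  print(round(x$components, digits))
  cat(sprintf("logL = %.4f, logL0 = %.4f, LRT = %.4f (df %d), p = %.3g, n = %d\n",
              x$loglik, x$loglik_null, x$lrt, x$df, x$p_lrt, x$n))
  if (!x$converged) cat("warning: fit did not converge\n")
  invisible(x)
}

#' @export
coef.greml <- function(object, ...) object$fixef

#' @export
vcov.greml <- function(object, ...) object$vcov_fixef

#' @export
logLik.greml <- function(object, ...) {
  structure(object$loglik, df = length(object$sigma2) + length(object$fixef),
            class = "logLik")
}

#' @export
fitted.greml <- function(object, ...) {
  ## BLUP decomposition: e_hat = sigma2_e P y, fitted = y - e_hat
  object$y - object$sigma2[length(object$sigma2)] * object$Py
}

#' @export
residuals.greml <- function(object, ...) {
  object$sigma2[length(object$sigma2)] * object$Py
}

#' Principal components from a genetic relatedness matrix
#'
#' Leading eigenvectors of the GRM, the standard covariates for population
#' structure. Each eigenvector is unit-normalized, with a deterministic sign
#' convention: the loading of largest magnitude is positive.
#'
#' @param grm A `"grm"` object.
#' @param k Number of components (`0 <= k < N`); `k = 0` gives an empty
#'   covariate block.
#' @return N x k matrix of eigenvectors, columns `PC1`, `PC2`, ...
#' @export
pcs_from_grm <- function(grm, k) {
  .assert(inherits(grm, "grm"), "'grm' must be a grm object")
  n <- nrow(grm$values)
  .assert(k >= 0 && k < n, "'k' must satisfy 0 <= k < N")
  if (k == 0) return(matrix(numeric(0), n, 0))
  eig <- eigen(grm$values, symmetric = TRUE)
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  colnames(V) <- sprintf("PC%d", seq_len(k))
  rownames(V) <- grm$sample_ids
  V
}

#' Partition genetic variance across the components of a multi-GRM fit
#'
#' @param fit A `"greml"` fit.
#' @return Data frame with one row per genetic component: `component`,
#'   `share_h2` (share of total genetic variance, summing to 1) and
#'   `share_phenotype` (share of phenotypic variance). All shares are `NA`
#'   when the total genetic variance is (numerically) zero.
#' @export
h2_partition <- function(fit) {
  .assert(inherits(fit, "greml"), "'fit' must be a greml fit")
  k <- length(fit$sigma2) - 1L
  g <- fit$sigma2[seq_len(k)]
  tot_g <- sum(g)
  vp <- sum(fit$sigma2)
  if (tot_g <= 1e-6 * vp) {
    return(data.frame(component = names(g), share_h2 = NA_real_,
                      share_phenotype = NA_real_, row.names = NULL))
  }
  data.frame(component = names(g), share_h2 = unname(g / tot_g),
             share_phenotype = unname(g / vp), row.names = NULL)
}

#' Write a GCTA-style .hsq variance-component report
#'
#' Emits the familiar `Source / Variance / SE` table with `logL`, `logL0`,
#' `LRT`, `df`, `Pval` and `n` rows, so fits can be diffed against GCTA
#' output.
#'
#' @param fit A `"greml"` fit.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hsq <- function(fit, path) {
  .assert(inherits(fit, "greml"), "'fit' must be a greml fit")
  k <- length(fit$sigma2) - 1L
  src <- names(fit$sigma2)
  vp <- sum(fit$sigma2)
  lines <- c("Source\tVariance\tSE",
             sprintf("%s\t%.6f\t%.6f", src, fit$sigma2, fit$se_sigma2),
             sprintf("Vp\t%.6f\tNA", vp),
             sprintf("V(G)/Vp\t%.6f\t%.6f", fit$h2_obs, fit$se_h2),
             sprintf("logL\t%.6f", fit$loglik),
             sprintf("logL0\t%.6f", fit$loglik_null),
             sprintf("LRT\t%.6f", fit$lrt),
             sprintf("df\t%d", fit$df),
             sprintf("Pval\t%.6g", fit$p_lrt),
             sprintf("n\t%d", fit$n))
  writeLines(lines, path)
  invisible(path)
}
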