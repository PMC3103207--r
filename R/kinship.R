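#' Pedigree additive (numerator) relationship matrix
#'
#' Henderson's tabular method: founders are unrelated and non-inbred,
#' `A[i,i] = 1 + 0.5 * A[sire, dam]`, and for j preceding i,
#' `A[i,j] = 0.5 * (A[j, sire] + A[j, dam])`.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (0 or NA for
#'   unknown), sorted so parents precede offspring.
#' @return n x n symmetric matrix with dimnames = ids.
#' @export
additive_relationship <- function(ped) {
  n <- nrow(ped)
  id <- ped$id
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  bad <- (!is.na(si) & si >= seq_len(n)) | (!is.na(di) & di >= seq_len(n))
  if (any(bad))
    stop("pedigree must be sorted parents-first (or contains a cycle)")
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (is.na(s)) 0 else A[j, s]) +
                    (if (is.na(d)) 0 else A[j, d]))
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + 0.5 * (if (is.na(s) || is.na(d)) 0 else A[s, d])
  }
  A
}

# profile REML log-likelihood pieces after eigen-rotation; lambda = s2a/s2e
reml_profile <- function(log_lambda, d, ystar, Xstar) {
  lambda <- exp(log_lambda)
  w <- 1 / (lambda * d + 1)
  n <- length(ystar); p <- ncol(Xstar)
  XtWX <- crossprod(Xstar, Xstar * w)
  XtWy <- crossprod(Xstar, ystar * w)
  R <- chol(XtWX)
  b <- backsolve(R, forwardsolve(t(R), XtWy))
  r <- ystar - Xstar %*% b
  rss <- sum(w * r^2)
  s2e <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(s2e) + sum(log(lambda * d + 1)) +
                2 * sum(log(diag(R))) + (n - p))
  list(ll = ll, b = b, s2e = s2e, s2a = lambda * s2e, lambda = lambda)
}

# full REML log-likelihood as a function of (s2a, s2e), for the observed
# information matrix
reml_loglik_vc <- function(s2a, s2e, d, ystar, Xstar) {
  v <- s2a * d + s2e
  w <- 1 / v
  XtWX <- crossprod(Xstar, Xstar * w)
  XtWy <- crossprod(Xstar, ystar * w)
  b <- solve(XtWX, XtWy)
  r <- ystar - Xstar %*% b
  -0.5 * (sum(log(v)) + determinant(XtWX)$modulus[1] + sum(w * r^2))
}

#' REML fit of the animal model
#'
#' Fits `y = Xb + Za + e` with `a ~ N(0, A sigma2_a)` and
#' `e ~ N(0, I sigma2_e)` by restricted maximum likelihood, where `X`
#' carries an intercept and (when both sexes are present) a sex effect.
#' An eigendecomposition of `A` reduces each REML evaluation to a
#' one-dimensional problem in `lambda = sigma2_a / sigma2_e`, maximized
#' by Brent search; standard errors come from the observed information
#' matrix at the optimum.  Individuals with missing phenotype or sex are
#' dropped (the relationship matrix is subset accordingly, which is the
#' correct marginal model).
#'
#' @param y numeric phenotype vector (NA allowed), aligned with rows of `A`.
#' @param sex integer/factor fixed-effect covariate aligned with `y`.
#' @param A additive relationship matrix from [additive_relationship()].
#' @param lambda_range search range for `log(lambda)`.
#' @param tol convergence tolerance on `lambda`.
#' @param eigen_A optional pre-computed `eigen(A[keep, keep])` (list with
#'   `values`, `vectors`) to reuse across repeated fits on the same
#'   pedigree subset; it must match the usable-phenotype subset exactly.
#' @return object of class `reml_fit`: variance components `sigma2_a`,
#'   `sigma2_e`, heritability `h2 = sigma2_a / (sigma2_a + sigma2_e)`,
#'   standard errors, REML log-likelihood, `boundary` flag, fixed-effect
#'   estimates, and the rotated quantities reused by
#'   [grammar_residuals()].
#' @export
reml_fit <- function(y, sex, A, lambda_range = c(-14, 14), tol = 1e-8,
                     eigen_A = NULL) {
  n_all <- length(y)
  stopifnot(nrow(A) == n_all)
  if (missing(sex) || is.null(sex)) sex <- rep(1L, n_all)
  drop_sex <- !is.na(y) & is.na(sex)
  if (any(drop_sex))
    warning(sum(drop_sex), " phenotyped individual(s) dropped for missing sex")
  keep <- which(!is.na(y) & !is.na(sex))
  if (length(keep) < 3) stop("fewer than 3 usable phenotypes")
  yk <- y[keep]
  sexk <- factor(sex[keep])
  X <- if (nlevels(sexk) >= 2) model.matrix(~sexk) else
    matrix(1, length(keep), 1)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design")
  eg <- if (!is.null(eigen_A)) {
    if (length(eigen_A$values) != length(keep))
      stop("eigen_A does not match the usable-phenotype subset")
    eigen_A
  } else eigen(A[keep, keep, drop = FALSE], symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ystar <- drop(crossprod(U, yk))
  Xstar <- crossprod(U, X)

  opt <- optimize(function(ll) reml_profile(ll, d, ystar, Xstar)$ll,
                  interval = lambda_range, maximum = TRUE,
                  tol = max(tol, 1e-10))
  fit <- reml_profile(opt$maximum, d, ystar, Xstar)
  s2a <- fit$s2a; s2e <- fit$s2e
  h2 <- s2a / (s2a + s2e)
  boundary <- opt$maximum <= lambda_range[1] + 0.05

  # observed information in (s2a, s2e) by central differences
  f <- function(th) reml_loglik_vc(th[1], th[2], d, ystar, Xstar)
  th <- c(max(s2a, 1e-8 * s2e), s2e)
  hstep <- pmax(1e-4 * th, 1e-8)
  Hm <- matrix(NA_real_, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- hstep[i]; ej[j] <- hstep[j]
    Hm[i, j] <- (f(th + ei + ej) - f(th + ei - ej) -
                 f(th - ei + ej) + f(th - ei - ej)) /
      (4 * hstep[i] * hstep[j])
  }
  se <- c(NA_real_, NA_real_); se_h2 <- NA_real_
  Iobs <- -Hm
  ok <- all(is.finite(Iobs))
  if (ok && all(eigen(Iobs, symmetric = TRUE, only.values = TRUE)$values > 0)) {
    Vth <- solve(Iobs)
    se <- sqrt(pmax(diag(Vth), 0))
    grad <- c(s2e, -s2a) / (s2a + s2e)^2   # d h2 / d(s2a, s2e)
    se_h2 <- sqrt(max(drop(t(grad) %*% Vth %*% grad), 0))
  }

  structure(list(
    sigma2_a = s2a, sigma2_e = s2e, h2 = h2,
    se_sigma2_a = se[1], se_sigma2_e = se[2], se_h2 = se_h2,
    loglik = fit$ll, boundary = boundary,
    beta = drop(fit$b), X = X, keep = keep,
    eigen = list(U = U, d = d), y = yk,
    ids = rownames(A)[keep]
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "animal model REML: sigma2_a = %.4f  sigma2_e = %.4f  h2 = %.3f (SE %.3f)%s\n",
    x$sigma2_a, x$sigma2_e, x$h2, x$se_h2,
    if (x$boundary) "  [boundary]" else ""))
  invisible(x)
}

#' GRAMMAR residuals from a fitted animal model
#'
#' Computes `e_hat = y - X b_hat - Z a_hat` with `a_hat` the BLUP of the
#' additive effects at the REML estimates, via the closed-form identity
#' `e_hat = sigma2_e V^{-1} (y - X b_hat)` with
#' `V = sigma2_a A + sigma2_e I`, evaluated in the eigenbasis of `A`.
#'
#' @param fit a converged [reml_fit()].
#' @return named numeric vector of residuals (names = individual ids).
#' @export
grammar_residuals <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  r <- fit$y - drop(fit$X %*% fit$beta)
  rstar <- drop(crossprod(fit$eigen$U, r))
  ehat <- fit$sigma2_e * drop(fit$eigen$U %*%
    (rstar / (fit$sigma2_a * fit$eigen$d + fit$sigma2_e)))
  names(ehat) <- fit$ids
  ehat
}
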