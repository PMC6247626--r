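#' Restricted log-likelihood of a multi-kernel linear mixed model
#'
#' Evaluates the exact REML log-likelihood of
#' `y = X b + sum_i g_i + e`, `g_i ~ N(0, K_i s2_i)`, `e ~ N(0, I s2_e)`:
#' `lR = -0.5 * ((n - p) log(2 pi) + log|V| + log|X' V^-1 X| + y' P y)`
#' with `V = sum_i s2_i K_i + s2_e I`. Used both as the fitting target and
#' as an independent surface for verifying [reml_fit()].
#'
#' @param y numeric response vector.
#' @param relationship_matrices a relationship matrix or list of them, each
#'   n x n symmetric.
#' @param variance_components numeric vector of length
#'   `length(relationship_matrices) + 1`; the last element is the residual
#'   variance. All must be >= 0 and not all zero.
#' @param X fixed-effect design matrix; default a column of ones.
#' @return the restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(y, relationship_matrices, variance_components,
                              X = NULL) {
  Ks <- .as_kernel_list(relationship_matrices)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  theta <- as.numeric(variance_components)
  if (length(theta) != length(Ks) + 1) stop("need one variance component per kernel plus a residual")
  if (any(theta < 0) || all(theta == 0)) stop("variance components must be >= 0 and not all zero")
  V <- diag(theta[length(theta)], n)
  for (i in seq_along(Ks)) V <- V + theta[i] * unclass(Ks[[i]])
  R <- tryCatch(chol(V), error = function(e) stop("total covariance is singular"))
  logdetV <- 2 * sum(log(diag(R)))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  XtViX <- crossprod(X, Vi_X)
  b <- solve(XtViX, crossprod(Vi_X, y))
  r <- y - X %*% b
  yPy <- sum(r * backsolve(R, forwardsolve(t(R), r)))
  p <- ncol(X)
  ld_xvx <- determinant(XtViX, logarithm = TRUE)$modulus
  -0.5 * ((n - p) * log(2 * pi) + logdetV + as.numeric(ld_xvx) + yPy)
}

.as_kernel_list <- function(Ks) {
  if (is.matrix(Ks) || inherits(Ks, "relmat")) Ks <- list(g = Ks)
  if (!is.list(Ks) || length(Ks) == 0) stop("relationship matrices must be a matrix or non-empty list")
  if (is.null(names(Ks)) || any(names(Ks) == ""))
    names(Ks) <- sprintf("g%d", seq_along(Ks))
  Ks
}

#' Fit a GBLUP mixed model by REML
#'
#' Estimates variance components of `y = 1 mu + sum_i g_i + e` with
#' `g_i ~ N(0, K_i s2_i)` by restricted maximum likelihood. Single-kernel
#' models use an exact spectral decomposition of `K` and a one-dimensional
#' profiled-likelihood search; multi-kernel models use average-information
#' (AI) REML with expectation-maximisation fallback steps whenever an AI
#' step fails to improve the restricted likelihood. Components are
#' constrained to at least `1e-8 * var(y)`.
#'
#' @param y numeric response (training records).
#' @param relationship_matrices matrix or named list of n x n kernels
#'   aligned with `y`.
#' @param max_iter maximum iterations (multi-kernel path).
#' @param tol convergence tolerance on the maximum relative parameter
#'   change.
#' @param init optional numeric vector of starting values (kernels then
#'   residual).
#' @param X fixed-effect design; default intercept only.
#' @return object of class `reml_fit`: list with `varcomp` (named, residual
#'   last), `beta` (fixed effects, `mu` = first element), `loglik`,
#'   `iterations`, `converged`, `gebv` (matrix of per-kernel BLUPs for the
#'   training individuals plus a `total` column), `y`, `ids`, `method`.
#' @export
reml_fit <- function(y, relationship_matrices, max_iter = 200, tol = 1e-6,
                     init = NULL, X = NULL) {
  Ks <- .as_kernel_list(relationship_matrices)
  n <- length(y)
  if (n < 2) stop("need at least two records")
  if (!(stats::var(y) > 0)) stop("phenotype has zero variance")
  for (K in Ks) {
    if (!is.matrix(K) || nrow(K) != n || ncol(K) != n)
      stop("each relationship matrix must be n x n with n = length(y)")
    if (max(abs(K - t(K))) > 1e-8) stop("relationship matrix is not symmetric")
  }
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  ids <- rownames(Ks[[1]])
  fit <- if (length(Ks) == 1) {
    .reml_spectral(y, Ks, X, tol)
  } else {
    .reml_ai(y, Ks, X, max_iter, tol, init)
  }
  fit$ids <- ids
  fit$y <- y
  fit$gebv <- .training_blup(y, Ks, X, fit)
  class(fit) <- "reml_fit"
  fit
}

# single kernel: rotate by eigenvectors of K, profile out the scale,
# optimize the ratio lambda = s2_g / s2_e on the log scale
.reml_spectral <- function(y, Ks, X, tol) {
  K <- unclass(Ks[[1]])
  n <- length(y)
  p <- ncol(X)
  E <- eigen(K, symmetric = TRUE)
  d <- pmax(E$values, 0)
  yt <- crossprod(E$vectors, y)
  Xt <- crossprod(E$vectors, X)
  neval <- 0L
  prof <- function(loglambda) {
    neval <<- neval + 1L
    lam <- exp(loglambda)
    w <- 1 / (lam * d + 1)
    Xw <- Xt * w
    XtWX <- crossprod(Xt, Xw)
    b <- solve(XtWX, crossprod(Xw, yt))
    r <- yt - Xt %*% b
    q <- sum(r^2 * w)
    s2e <- q / (n - p)
    ld_xwx <- as.numeric(determinant(XtWX, logarithm = TRUE)$modulus)
    -0.5 * ((n - p) * (log(2 * pi) + log(s2e) + 1) + sum(log(lam * d + 1)) + ld_xwx)
  }
  opt <- stats::optimize(prof, interval = c(-20, 20), maximum = TRUE, tol = 1e-9)
  # compare against the boundary s2_g -> 0
  ll0 <- prof(-40)
  loglambda <- if (ll0 > opt$objective + 1e-10) -40 else opt$maximum
  lam <- exp(loglambda)
  w <- 1 / (lam * d + 1)
  Xw <- Xt * w
  XtWX <- crossprod(Xt, Xw)
  b <- solve(XtWX, crossprod(Xw, yt))
  r <- yt - Xt %*% b
  s2e <- sum(r^2 * w) / (n - p)
  vc <- c(lam * s2e, s2e)
  floor_vc <- 1e-8 * stats::var(y)
  vc <- pmax(vc, floor_vc)
  names(vc) <- c(names(Ks), "residual")
  ll <- restricted_loglik(y, Ks, vc, X = X)
  list(varcomp = vc, beta = as.numeric(b), mu = as.numeric(b)[1],
       loglik = ll, iterations = neval, converged = TRUE, method = "spectral")
}

# multi-kernel AI-REML; EM fallback when an AI step is not accepted
.reml_ai <- function(y, Ks, X, max_iter, tol, init) {
  n <- length(y)
  nk <- length(Ks)
  vy <- stats::var(y)
  floor_vc <- 1e-8 * vy
  theta <- if (is.null(init)) rep(vy / (nk + 1), nk + 1) else pmax(as.numeric(init), floor_vc)
  if (length(theta) != nk + 1) stop("init must have one value per kernel plus residual")
  Kl <- lapply(Ks, unclass)
  loglik_at <- function(th) restricted_loglik(y, Ks, th, X = X)
  ll <- loglik_at(theta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    V <- diag(theta[nk + 1], n)
    for (i in seq_len(nk)) V <- V + theta[i] * Kl[[i]]
    R <- chol(V)
    Vi <- chol2inv(R)
    ViX <- Vi %*% X
    XtViX_inv <- solve(crossprod(X, ViX))
    P <- Vi - ViX %*% tcrossprod(XtViX_inv, ViX)
    Py <- as.vector(P %*% y)
    KPy <- vector("list", nk + 1)
    trPK <- numeric(nk + 1)
    score <- numeric(nk + 1)
    for (i in seq_len(nk)) {
      KPy[[i]] <- as.vector(Kl[[i]] %*% Py)
      trPK[i] <- sum(P * Kl[[i]])
      score[i] <- -0.5 * (trPK[i] - sum(Py * KPy[[i]]))
    }
    KPy[[nk + 1]] <- Py
    trPK[nk + 1] <- sum(diag(P))
    score[nk + 1] <- -0.5 * (trPK[nk + 1] - sum(Py^2))
    PKPy <- lapply(KPy, function(v) as.vector(P %*% v))
    AI <- matrix(0, nk + 1, nk + 1)
    for (i in seq_len(nk + 1))
      for (j in i:(nk + 1))
        AI[i, j] <- AI[j, i] <- 0.5 * sum(KPy[[i]] * PKPy[[j]])
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(step)) {
      h <- 1
      for (try in 1:4) {
        cand <- pmax(theta + h * step, floor_vc)
        ll_cand <- tryCatch(loglik_at(cand), error = function(e) -Inf)
        if (is.finite(ll_cand) && ll_cand >= ll - 1e-10) {
          accepted <- TRUE
          break
        }
        h <- h / 2
      }
    }
    if (!accepted) {
      # EM-REML update: s2_new = s2 + s2^2 (y'PKPy - tr(PK)) / n
      cand <- pmax(theta + theta^2 * (2 * score) / n, floor_vc)
      ll_cand <- tryCatch(loglik_at(cand), error = function(e) -Inf)
      if (!is.finite(ll_cand)) break
    }
    rel_change <- max(abs(cand - theta) / pmax(theta, floor_vc))
    ll_gain <- ll_cand - ll
    theta <- cand
    ll <- ll_cand
    # converged when parameters settle, or when the restricted likelihood
    # has flattened (components pinned at the floor move negligibly)
    if (rel_change < tol || (iter >= 3 && abs(ll_gain) < 1e-7)) {
      converged <- TRUE
      break
    }
  }
  names(theta) <- c(names(Ks), "residual")
  # GLS fixed effects at the final components
  V <- diag(theta[nk + 1], n)
  for (i in seq_len(nk)) V <- V + theta[i] * Kl[[i]]
  R <- chol(V)
  ViX <- backsolve(R, forwardsolve(t(R), X))
  Viy <- backsolve(R, forwardsolve(t(R), y))
  b <- solve(crossprod(X, ViX), crossprod(X, Viy))
  list(varcomp = theta, beta = as.numeric(b), mu = as.numeric(b)[1],
       loglik = ll, iterations = iter, converged = converged, method = "ai")
}

# BLUP of each random component for the training individuals:
# g_i = s2_i K_i V^-1 (y - X b)
.training_blup <- function(y, Ks, X, fit) {
  n <- length(y)
  nk <- length(Ks)
  theta <- fit$varcomp
  V <- diag(theta[nk + 1], n)
  for (i in seq_len(nk)) V <- V + theta[i] * unclass(Ks[[i]])
  R <- chol(V)
  r <- y - X %*% fit$beta
  Vir <- backsolve(R, forwardsolve(t(R), r))
  g <- sapply(seq_len(nk), function(i) theta[i] * as.vector(unclass(Ks[[i]]) %*% Vir))
  g <- matrix(g, nrow = n, dimnames = list(rownames(Ks[[1]]), names(Ks)))
  cbind(g, total = rowSums(g))
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("reml_fit (%s): loglik %.4f, %s in %d iterations\n",
              x$method, x$loglik,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$iterations))
  print(round(x$varcomp, 6))
  invisible(x)
}

#' Predict GEBV for validation individuals
#'
#' Solves the prediction equations of the fitted GBLUP model using training
#' records only but relationship matrices spanning training and validation
#' individuals, at the training-estimated variance components:
#' `g_hat_i(val) = s2_i K_i[val, train] V_train^-1 (y_train - mu_hat)`.
#'
#' @param fit a `reml_fit` from training data (its `ids` must name the
#'   training individuals).
#' @param full_relationship_matrices named list of kernels over all
#'   individuals (same names as in the fit), with dimnames.
#' @param training_ids,validation_ids disjoint character vectors of IDs
#'   present in the full matrices.
#' @return data.frame with `id`, one GEBV column per random component and
#'   their sum in `gebv`.
#' @export
predict_gebv <- function(fit, full_relationship_matrices, training_ids,
                         validation_ids) {
  stopifnot(inherits(fit, "reml_fit"))
  Ks <- .as_kernel_list(full_relationship_matrices)
  if (length(intersect(training_ids, validation_ids)) > 0)
    stop("training and validation sets overlap")
  nk <- length(Ks)
  theta <- fit$varcomp
  if (length(theta) != nk + 1 || any(theta < 0) || anyNA(theta))
    stop("fit variance components do not match the supplied matrices")
  if (!identical(fit$ids, training_ids) && !is.null(fit$ids)) {
    if (!setequal(fit$ids, training_ids)) stop("fit was not made on these training individuals")
  }
  nt <- length(training_ids)
  Vtt <- diag(theta[nk + 1], nt)
  for (i in seq_len(nk)) {
    Ki <- unclass(Ks[[i]])
    it <- match(training_ids, rownames(Ki))
    if (anyNA(it)) stop("training IDs missing from relationship matrix")
    Vtt <- Vtt + theta[i] * Ki[it, it, drop = FALSE]
  }
  yt <- fit$y
  if (!is.null(fit$ids)) yt <- fit$y[match(training_ids, fit$ids)]
  r <- yt - fit$mu
  w <- solve(Vtt, r)
  out <- data.frame(id = validation_ids, stringsAsFactors = FALSE)
  total <- numeric(length(validation_ids))
  for (i in seq_len(nk)) {
    Ki <- unclass(Ks[[i]])
    iv <- match(validation_ids, rownames(Ki))
    it <- match(training_ids, rownames(Ki))
    if (anyNA(iv)) stop("validation IDs missing from relationship matrix")
    gi <- theta[i] * as.vector(Ki[iv, it, drop = FALSE] %*% w)
    out[[names(Ks)[i]]] <- gi
    total <- total + gi
  }
  out$gebv <- total
  out
}
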