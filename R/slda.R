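#' Ledoit-Wolf shrinkage covariance estimate
#'
#' Analytic shrinkage of the empirical covariance toward a scaled identity:
#' `Sigma = (1 - gamma) S + gamma nu I` with `S` the (biased, denominator n)
#' sample covariance of the column-centered data, `nu = trace(S)/p`, and
#' `gamma` the analytic Ledoit-Wolf optimum clipped to `[0, 1]`.
#'
#' @param x Samples x features numeric matrix (at least 2 rows).
#' @param center Center columns at their sample mean first (default `TRUE`;
#'   set `FALSE` when `x` is already class-centered).
#' @return List with `sigma` (p x p shrunk covariance), `gamma` (shrinkage
#'   intensity) and `nu` (the identity target scale).
#' @export
ledoit_wolf_cov <- function(x, center = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stop("Ledoit-Wolf estimation needs at least 2 samples")
  xc <- if (center) sweep(x, 2, colMeans(x)) else x
  s <- crossprod(xc) / n
  nu <- sum(diag(s)) / p
  tr_s2 <- sum(s * s)
  d2 <- tr_s2 / p - nu^2                       # dispersion around the target
  if (d2 <= .Machine$double.eps * nu^2) {
    gamma <- 0
  } else {
    sq_norms <- rowSums(xc^2)
    b2bar <- (sum(sq_norms^2) - n * tr_s2) / (n^2 * p)
    gamma <- min(b2bar, d2) / d2
    gamma <- min(max(gamma, 0), 1)
  }
  sigma <- (1 - gamma) * s
  diag(sigma) <- diag(sigma) + gamma * nu
  list(sigma = sigma, gamma = gamma, nu = nu)
}

#' Fit a shrinkage-LDA binary classifier
#'
#' Linear discriminant with Ledoit-Wolf regularized pooled covariance:
#' `w = Sigma^{-1} (mu_1 - mu_0)`, `b = -w . (mu_0 + mu_1) / 2`. The pooled
#' covariance is estimated from class-centered samples. The decision value
#' `d(x) = w . x + b` is positive for the second class of `classes`.
#'
#' @param x Trials x features matrix.
#' @param y Labels with exactly two distinct values; the class order is the
#'   order of first appearance unless `y` is a factor.
#' @param gamma Optional fixed shrinkage intensity in `[0, 1]`; by default the
#'   analytic Ledoit-Wolf value is used.
#' @return An `slda_model` with weights `w`, bias `b`, shrinkage `gamma` and
#'   `classes`.
#' @export
slda_fit <- function(x, y, gamma = NULL) {
  x <- as.matrix(x)
  classes <- if (is.factor(y)) levels(droplevels(y)) else unique(as.character(y))
  y <- as.character(y)
  if (length(classes) != 2) stop("slda_fit requires exactly two classes")
  i0 <- y == classes[1]; i1 <- y == classes[2]
  if (!any(i0) || !any(i1)) stop("both classes must be present")
  mu0 <- colMeans(x[i0, , drop = FALSE])
  mu1 <- colMeans(x[i1, , drop = FALSE])
  xc <- rbind(sweep(x[i0, , drop = FALSE], 2, mu0),
              sweep(x[i1, , drop = FALSE], 2, mu1))
  lw <- ledoit_wolf_cov(xc, center = FALSE)
  if (!is.null(gamma)) {
    stopifnot(gamma >= 0, gamma <= 1)
    sigma <- (1 - gamma) * crossprod(xc) / nrow(xc)
    diag(sigma) <- diag(sigma) + gamma * lw$nu
    lw$sigma <- sigma
    lw$gamma <- gamma
  }
  w <- tryCatch(solve(lw$sigma, mu1 - mu0),
                error = function(e)
                  solve(lw$sigma + diag(1e-10 * lw$nu, ncol(x)), mu1 - mu0))
  b <- -sum(w * (mu0 + mu1)) / 2
  structure(list(w = w, b = b, gamma = lw$gamma, nu = lw$nu,
                 classes = classes, p = ncol(x)),
            class = "slda_model")
}

#' Predict from a shrinkage-LDA model
#'
#' @param object An `slda_model`.
#' @param newdata Trials x features matrix.
#' @param type `"decision"` for signed decision values (positive means the
#'   second class), `"class"` for hard labels.
#' @param ... Unused.
#' @return Numeric decision values or a character vector of class labels.
#' @export
predict.slda_model <- function(object, newdata,
                               type = c("decision", "class"), ...) {
  type <- match.arg(type)
  d <- as.numeric(as.matrix(newdata) %*% object$w + object$b)
  if (type == "decision") d else object$classes[(d > 0) + 1L]
}

#' @export
print.slda_model <- function(x, ...) {
  cat(sprintf("<slda_model> %s vs %s: %d features, shrinkage gamma = %.3f\n",
              x$classes[1], x$classes[2], x$p, x$gamma))
  invisible(x)
}
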