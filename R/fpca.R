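#' B-spline basis on a race domain
#'
#' A basis of `n_basis` B-splines of a given order (4 = cubic) on
#' \[0, domain\] with equally spaced interior knots. The number of interior
#' knots is `n_basis - order`. All inner products used downstream are exact
#' integrals computed from this basis's Gram matrix, not grid quadrature.
#'
#' @param domain Race distance in metres (upper end of the domain).
#' @param n_basis Number of basis functions; must not exceed the number of
#'   observation points a profile provides.
#' @param order Spline order (degree + 1); default 4, cubic.
#' @return An object of class `kayak_basis` with the full knot vector and the
#'   Gram matrix `G` of exact pairwise L2 inner products.
#' @export
bspline_basis <- function(domain, n_basis, order = 4) {
  if (n_basis < order) stop("n_basis must be at least the spline order")
  n_interior <- n_basis - order
  interior <- if (n_interior > 0) {
    seq(0, domain, length.out = n_interior + 2)[-c(1, n_interior + 2)]
  } else {
    numeric(0)
  }
  knots <- c(rep(0, order), interior, rep(domain, order))
  b <- structure(
    list(
      domain = c(0, domain), order = order, n_basis = n_basis,
      interior_knots = interior, knots = knots
    ),
    class = "kayak_basis"
  )
  b$G <- basis_gram(b)
  b
}

#' @export
print.kayak_basis <- function(x, ...) {
  cat(
    "B-spline basis: order", x$order, ",", x$n_basis, "functions on [0,",
    x$domain[2], "] m,", length(x$interior_knots), "interior knots\n"
  )
  invisible(x)
}

#' Evaluate basis functions
#'
#' @param basis A `kayak_basis`.
#' @param x Evaluation points inside the domain.
#' @return Matrix, `length(x)` by `n_basis`.
#' @export
eval_basis <- function(basis, x) {
  if (any(x < basis$domain[1] - 1e-12) || any(x > basis$domain[2] + 1e-12)) {
    stop("evaluation points outside the basis domain")
  }
  x <- pmin(pmax(x, basis$domain[1]), basis$domain[2])
  splines::splineDesign(basis$knots, x, ord = basis$order)
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch.
gauss_legendre <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

# Exact Gram matrix of the basis: piecewise-polynomial integrands of degree
# 2(order-1) are integrated exactly by order-point Gauss-Legendre per span.
basis_gram <- function(basis) {
  gl <- gauss_legendre(basis$order)
  breaks <- unique(c(basis$domain[1], basis$interior_knots, basis$domain[2]))
  G <- matrix(0, basis$n_basis, basis$n_basis)
  for (s in seq_len(length(breaks) - 1)) {
    a <- breaks[s]; b <- breaks[s + 1]
    xs <- (a + b) / 2 + (b - a) / 2 * gl$nodes
    ws <- (b - a) / 2 * gl$weights
    B <- eval_basis(basis, xs)
    G <- G + t(B) %*% (B * ws)
  }
  (G + t(G)) / 2
}

#' Least-squares smoothing of one or more profiles
#'
#' Fits basis coefficients to gridded normalised-velocity values by ordinary
#' least squares; the residual at the grid points is orthogonal to the span
#' of the basis evaluated there. No roughness penalty is applied.
#'
#' @param values Numeric vector of values at `grid`, or a matrix with one
#'   profile per row.
#' @param grid Observation distances (segment midpoints) in metres.
#' @param basis A `kayak_basis` with `n_basis <= length(grid)`.
#' @return Coefficient vector, or matrix with one row per profile.
#' @export
smooth_profile <- function(values, grid, basis) {
  X <- eval_basis(basis, grid)
  if (basis$n_basis > length(grid)) {
    stop("basis has more functions (", basis$n_basis, ") than grid points (", length(grid), ")")
  }
  qx <- qr(X)
  if (qx$rank < basis$n_basis) {
    stop("rank-deficient design: reduce n_basis or refine the grid")
  }
  if (is.matrix(values)) {
    if (ncol(values) != length(grid)) stop("values and grid dimensions differ")
    t(qr.coef(qx, t(values)))
  } else {
    if (length(values) != length(grid)) stop("values and grid lengths differ")
    as.numeric(qr.coef(qx, values))
  }
}

#' Functional PCA of smoothed pacing profiles
#'
#' Curves are mean-centred and the eigenproblem is solved in
#' basis-coefficient space through the Cholesky factor of the basis Gram
#' matrix, so the eigenfunctions are exactly orthonormal under the L2 inner
#' product on the race domain and the scores are exact integrals. Components
#' are ordered by decreasing eigenvalue (score variance). Each eigenfunction
#' is oriented so that its value at the location of its maximum absolute
#' value is positive.
#'
#' @param profiles Tidy profile tibble from [pacing_profiles()] (one event
#'   only), or a numeric matrix of gridded values (profiles in rows) if
#'   `grid` is supplied.
#' @param K Number of components to retain (default 4).
#' @param basis Optional `kayak_basis`; by default cubic with 8 functions for
#'   500 m and 12 for 1000 m.
#' @param grid Required when `profiles` is a matrix: observation distances.
#' @return A `kayak_fpca` object: `basis`, `mean_coefs`, `eigenfunctions`
#'   (coefficient matrix, one column per component), `eigenvalues` (all
#'   retained, for variance fractions), `varexp`, `K`, and `scores` (tibble
#'   of per-race scores when race metadata was available).
#' @export
fit_fpca <- function(profiles, K = 4, basis = NULL, grid = NULL) {
  if (is.matrix(profiles)) {
    if (is.null(grid)) stop("`grid` is required for matrix input")
    Y <- profiles
    meta <- NULL
  } else {
    wide <- tidy_to_wide(profiles)
    Y <- wide$Y
    grid <- wide$grid
    meta <- wide$meta
  }
  if (is.null(basis)) basis <- default_basis_for_grid(grid)
  if (nrow(Y) < K + 1) stop("need at least K + 1 = ", K + 1, " curves")
  C <- smooth_profile(Y, grid, basis)
  mean_coefs <- colMeans(C)
  Cc <- sweep(C, 2, mean_coefs)
  L <- t(chol(basis$G))
  # scores are b = t(L) %*% cc in the whitened frame; PCA there is standard
  W <- Cc %*% L
  V <- crossprod(W) / (nrow(W) - 1)
  e <- eigen(V, symmetric = TRUE)
  rank <- sum(e$values > max(e$values, 0) * 1e-12)
  if (K > max(rank, 1)) {
    stop("K = ", K, " exceeds the available rank (", rank, ")")
  }
  lambda <- pmax(e$values, 0)
  U <- solve(t(L), e$vectors) # coefficient-space eigenfunctions, orthonormal under G
  # sign convention: positive at the argmax of |phi_k|
  xs <- seq(basis$domain[1], basis$domain[2], length.out = 401)
  Bx <- eval_basis(basis, xs)
  for (k in seq_len(ncol(U))) {
    vals <- Bx %*% U[, k]
    if (vals[which.max(abs(vals))] < 0) U[, k] <- -U[, k]
  }
  model <- structure(
    list(
      basis = basis, mean_coefs = mean_coefs,
      eigenfunctions = U[, seq_len(K), drop = FALSE],
      eigenvalues = lambda, K = K,
      varexp = lambda[seq_len(K)] / sum(lambda),
      n_curves = nrow(Y), grid = grid
    ),
    class = "kayak_fpca"
  )
  sc <- compute_scores(model, C)
  if (!is.null(meta)) {
    model$scores <- dplyr::bind_cols(meta, tibble::as_tibble(sc))
  } else {
    model$scores <- tibble::as_tibble(sc)
  }
  model
}

default_basis_for_grid <- function(grid) {
  p <- max(grid) + min(grid) # midpoint grids: 25,...,p-25
  n_basis <- if (length(grid) >= 20) 12 else 8
  bspline_basis(p, n_basis)
}

tidy_to_wide <- function(profiles) {
  prof <- profiles |>
    dplyr::arrange(.data$athlete_id, .data$race_index, .data$distance_m)
  wide <- prof |>
    dplyr::select(dplyr::any_of(c("athlete_id", "race_index", "age_group", "event_type", "phase")),
      "distance_m", "norm_velocity"
    ) |>
    tidyr::pivot_wider(names_from = "distance_m", values_from = "norm_velocity")
  value_cols <- setdiff(names(wide), c("athlete_id", "race_index", "age_group", "event_type", "phase"))
  Y <- as.matrix(wide[, value_cols])
  if (anyNA(Y)) stop("profiles are not on a common distance grid")
  list(
    Y = Y, grid = as.numeric(value_cols),
    meta = wide[, setdiff(names(wide), value_cols), drop = FALSE]
  )
}

#' PC scores of smoothed curves
#'
#' Scores are exact L2 inner products of each eigenfunction with the
#' mean-centred curve, computed through the basis Gram matrix:
#' beta_k = u_k' G (c - mean_coefs).
#'
#' @param model A `kayak_fpca`.
#' @param curves Basis-coefficient vector or matrix (one curve per row), or a
#'   tidy profile tibble which is smoothed with the model's basis first.
#' @return Matrix of scores, one row per curve, columns `PC1`...`PCK`.
#' @export
compute_scores <- function(model, curves) {
  if (is.data.frame(curves)) {
    wide <- tidy_to_wide(curves)
    if (length(wide$grid) != length(model$grid) || any(wide$grid != model$grid)) {
      stop("curve grid does not match the fitted model's grid")
    }
    curves <- smooth_profile(wide$Y, wide$grid, model$basis)
  }
  if (!is.matrix(curves)) curves <- matrix(curves, nrow = 1)
  if (ncol(curves) != model$basis$n_basis) {
    stop("coefficient length does not match the model's basis")
  }
  Cc <- sweep(curves, 2, model$mean_coefs)
  S <- Cc %*% (model$basis$G %*% model$eigenfunctions)
  colnames(S) <- paste0("PC", seq_len(model$K))
  S
}

#' Reconstruct curves from scores
#'
#' Truncated expansion f = mean + sum_{k <= K_used} beta_k Phi_k, returned as
#' basis coefficients. L2 reconstruction error is non-increasing in `K_used`.
#'
#' @param model A `kayak_fpca`.
#' @param scores Score vector or matrix (rows = curves).
#' @param K_used Number of leading components to use (0 gives the mean).
#' @return Basis-coefficient matrix, one row per curve.
#' @export
reconstruct <- function(model, scores, K_used = model$K) {
  if (K_used > model$K) stop("K_used exceeds the fitted K")
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1)
  out <- matrix(rep(model$mean_coefs, nrow(scores)),
    nrow = nrow(scores), byrow = TRUE
  )
  if (K_used > 0) {
    out <- out + scores[, seq_len(K_used), drop = FALSE] %*%
      t(model$eigenfunctions[, seq_len(K_used), drop = FALSE])
  }
  out
}

#' Fraction of variance explained per component
#'
#' lambda_k over the sum of all retained eigenvalues; non-increasing in k.
#'
#' @param model A `kayak_fpca`.
#' @return Numeric vector of length `K`.
#' @export
variance_explained <- function(model) {
  tot <- sum(model$eigenvalues)
  if (tot <= 0) stop("all eigenvalues are zero; variance fractions undefined")
  model$eigenvalues[seq_len(model$K)] / tot
}

#' Evaluate fPCA functions on a distance grid
#'
#' @param model A `kayak_fpca`.
#' @param x Distances in metres.
#' @param what `"mean"` or `"eigenfunctions"`.
#' @return Vector (mean) or matrix (one column per eigenfunction).
#' @export
eval_fpca <- function(model, x, what = c("mean", "eigenfunctions")) {
  what <- match.arg(what)
  B <- eval_basis(model$basis, x)
  if (what == "mean") as.numeric(B %*% model$mean_coefs) else B %*% model$eigenfunctions
}

#' @export
print.kayak_fpca <- function(x, ...) {
  cat("Functional PCA:", x$n_curves, "curves,", x$K, "components\n")
  cat(
    "variance explained:",
    paste(sprintf("PC%d %.1f%%", seq_len(x$K), 100 * x$varexp), collapse = ", "),
    sprintf("(cumulative %.2f%%)\n", 100 * sum(x$varexp))
  )
  invisible(x)
}

#' Serialise an fPCA model to JSON
#'
#' Writes the basis specification, mean coefficients, eigenfunction
#' coefficients and eigenvalues; [read_fpca_json()] restores the model.
#'
#' @param model A `kayak_fpca`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fpca_json <- function(model, path) {
  obj <- list(
    basis = list(
      domain = model$basis$domain, order = model$basis$order,
      n_basis = model$basis$n_basis
    ),
    grid = model$grid,
    mean_coefs = model$mean_coefs,
    eigenfunctions = model$eigenfunctions,
    eigenvalues = model$eigenvalues,
    K = model$K
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fpca_json
#' @export
read_fpca_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- bspline_basis(obj$basis$domain[2], obj$basis$n_basis, obj$basis$order)
  model <- structure(
    list(
      basis = basis, mean_coefs = obj$mean_coefs,
      eigenfunctions = matrix(obj$eigenfunctions, ncol = obj$K),
      eigenvalues = obj$eigenvalues, K = obj$K,
      varexp = obj$eigenvalues[seq_len(obj$K)] / sum(obj$eigenvalues),
      n_curves = NA_integer_, grid = obj$grid
    ),
    class = "kayak_fpca"
  )
  model
}
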