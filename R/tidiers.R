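#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an fPCA model
#'
#' One row per component: eigenvalue (score variance), fraction of variance
#' explained and its cumulative sum.
#'
#' @param x A `kayak_fpca`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.kayak_fpca <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_len(x$K)),
    eigenvalue = x$eigenvalues[seq_len(x$K)],
    varexp = x$varexp,
    cumulative = cumsum(x$varexp)
  )
}

#' @rdname tidy.kayak_fpca
#' @export
glance.kayak_fpca <- function(x, ...) {
  tibble::tibble(
    n_curves = x$n_curves, K = x$K, n_basis = x$basis$n_basis,
    varexp_total = sum(x$varexp)
  )
}

#' Tidy a fitted HMM
#'
#' One row per state, PC dimension and coefficient (intercept or covariate
#' indicator), plus the state's emission SD on the intercept rows' scale.
#'
#' @param x A `kayak_hmm`.
#' @param ... Unused.
#' @return A tibble with columns `state`, `component`, `term`, `estimate`.
#' @export
tidy.kayak_hmm <- function(x, ...) {
  B <- x$params$B
  terms <- dimnames(B)[[3]]
  purrr::map_dfr(seq_len(x$params$n_states), function(j) {
    purrr::map_dfr(seq_len(x$params$dims), function(i) {
      tibble::tibble(
        state = j, component = paste0("PC", i), term = terms,
        estimate = as.numeric(B[i, j, ])
      )
    })
  })
}

#' @rdname tidy.kayak_hmm
#' @export
glance.kayak_hmm <- function(x, ...) {
  tibble::tibble(
    n_states = x$params$n_states, n_obs = x$n_obs, n_params = x$n_params,
    loglik = x$loglik, aic = x$aic, converged = x$converged,
    n_restarts = nrow(x$restarts)
  )
}

#' @rdname tidy.kayak_fpca
#' @export
tidy.kayak_hmm_scan <- function(x, ...) x$table
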