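# Markov smoothing of the tissue signal matrix with smoothness-rate stopping.

#' Smoothness rate between consecutive diffusion states
#'
#' For the state at step t, compares `M^(t+1) X` against `M^t X`:
#' `Err = M^(t+1)X - M^t X`, `K = M^(t+1)X + M^t X`,
#' `SSE = sum(Err^2)`, `SST = sum(K^2)`, and `R = SSE / SST`, with sums
#' running jointly over all genes and all tissue columns. R near 0 means
#' a further step barely changes the signal (the network is approaching
#' its smooth limit); an all-zero signal is defined to have `R = 0`.
#'
#' @param M a [transition_matrix()] object or matrix.
#' @param X signal matrix with one row per node.
#' @param t non-negative integer step at which to evaluate.
#' @param operator passed to [apply_power()].
#' @return list with `sse`, `sst`, `r`.
#' @export
smoothness_rate <- function(M, X, t = 0, operator = c("left", "transpose")) {
  operator <- match.arg(operator)
  Xt <- apply_power(M, X, t, operator)
  Xt1 <- apply_power(M, Xt, 1L, operator)
  err <- Xt1 - Xt
  K <- Xt1 + Xt
  sse <- sum(err^2)
  sst <- sum(K^2)
  if (sst > 0) {
    r <- sse / sst
  } else {
    warning("all-zero signal: smoothness rate defined as 0")
    r <- 0
  }
  list(sse = sse, sst = sst, r = r)
}

#' Diffuse the tissue signal matrix over the network
#'
#' Iterates `S^t = M^t S*` by repeated application of the Markov
#' operator (never re-multiplying from scratch) and stops at the first
#' step t whose smoothness rate `R(t) <= r_threshold`, returning `S^t` —
#' the state *before* the extra step used in the comparison, so the
#' signal is never knowingly over-smoothed. If `t_max` is hit first the
#' result carries `capped = TRUE`.
#'
#' On bipartite structures the walk can oscillate and R may never fall
#' below the threshold; the `t_max` cap (default 50) guards against
#' that. On a connected non-bipartite graph the state converges to the
#' stationary profile and termination is guaranteed.
#'
#' @param M a [transition_matrix()].
#' @param S_star G x T tissue signal matrix ([tissue_signal()]), rows
#'   aligned to the operator's nodes.
#' @param r_threshold stopping threshold in (0, 1); default 0.05.
#' @param t_max safety cap on the number of steps; default 50.
#' @param operator `"left"` (default) or `"transpose"`, see
#'   [apply_power()].
#' @param per_column if `TRUE`, stop only when every column's own
#'   SSE/SST ratio is at or below the threshold (non-default variant).
#' @return Object of class `diffusion_result`: list with `smoothed`
#'   (the accepted `S^t`), `t_stop`, `diagnostics` (data frame of
#'   t, sse, sst, r for steps 1..t_stop), `capped`, `config`.
#' @export
run_diffusion <- function(M, S_star, r_threshold = 0.05, t_max = 50L,
                          operator = c("left", "transpose"),
                          per_column = FALSE) {
  operator <- match.arg(operator)
  if (!is.numeric(r_threshold) || r_threshold <= 0 || r_threshold >= 1)
    stop("'r_threshold' must lie in (0, 1)")
  if (!is.numeric(t_max) || t_max < 1) stop("'t_max' must be >= 1")
  X0 <- as.matrix(S_star)
  if (any(X0 < 0)) stop("signal matrix must be non-negative")
  cur <- apply_power(M, X0, 1L, operator)   # state at t = 1
  rows <- vector("list", t_max)
  t <- 1L
  capped <- FALSE
  repeat {
    nxt <- apply_power(M, cur, 1L, operator)
    if (any(!is.finite(nxt)))
      stop("numerical failure: non-finite values at diffusion step ", t + 1L)
    err <- nxt - cur
    K <- nxt + cur
    sse <- sum(err^2)
    sst <- sum(K^2)
    r <- if (sst > 0) sse / sst else 0
    rows[[t]] <- data.frame(t = t, sse = sse, sst = sst, r = r)
    done <- if (per_column) {
      col_sst <- colSums(K^2)
      col_r <- ifelse(col_sst > 0, colSums(err^2) / col_sst, 0)
      all(col_r <= r_threshold)
    } else r <= r_threshold
    if (done) break
    if (t >= t_max) {
      capped <- TRUE
      break
    }
    cur <- nxt
    t <- t + 1L
  }
  structure(list(smoothed = cur,
                 t_stop = t,
                 diagnostics = do.call(rbind, rows[seq_len(t)]),
                 capped = capped,
                 config = list(r_threshold = r_threshold, t_max = t_max,
                               operator = operator,
                               per_column = per_column)),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  last <- x$diagnostics[nrow(x$diagnostics), ]
  cat(sprintf("diffusion result: stopped at t = %d with R = %.4g%s (threshold %.3g)\n",
              x$t_stop, last$r, if (x$capped) " [t_max-capped]" else "",
              x$config$r_threshold))
  invisible(x)
}
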