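## Null models for pure genetic drift: how much allele-frequency change and
## allele loss a neutral Wright-Fisher process can produce.

#' Drift bound on allele-frequency change
#'
#' The variance of a neutral Wright-Fisher allele frequency after `t`
#' generations, starting from frequency `p0` in a population of size `N`,
#' is `p0 (1 - p0) (1 - exp(-t / (2 N)))`.  This function returns `k_sd`
#' standard deviations of that distribution: the magnitude of change that
#' drift alone can plausibly produce.
#'
#' @param p0 Initial allele frequency.
#' @param t Elapsed generations (>= 0).
#' @param N (Effective) population size (>= 1).
#' @param k_sd Number of standard deviations (default 3).
#' @return The bound, a single number.
#' @examples
#' wf_sd_bound(0.0377, t = 50, N = 500)  # ~0.126: drift cannot move far
#' @export
wf_sd_bound <- function(p0, t, N, k_sd = 3) {
  if (!is_prob(p0) || length(p0) != 1L) stop_("`p0` must be in [0, 1]")
  if (t < 0) stop_("`t` must be >= 0")
  if (N < 1) stop_("`N` must be >= 1")
  k_sd * sqrt(p0 * (1 - p0) * (1 - exp(-t / (2 * N))))
}

#' Generations elapsed for a number of years
#'
#' The study organism completes roughly ten generations per year
#' (egg-to-mature-adult period of about 36 days), so field sampling dates
#' translate to generations at that rate.
#'
#' @param years Number of years.
#' @param per_year Generations per year (default 10).
#' @return Number of generations.
#' @export
years_to_generations <- function(years, per_year = 10) years * per_year

#' Exact Wright-Fisher probability of allele loss
#'
#' Absorption probability at zero copies after `t` binomial Wright-Fisher
#' transitions on the `2N + 1` copy-number states, starting from
#' `round(2 N p0)` copies.  Serves as the exact finite-population
#' counterpart of [kimura_loss_prob()].
#'
#' @param p0 Initial allele frequency.
#' @param t Generations (>= 1 unless `p0` is 0 or 1, which are absorbing).
#' @param N Diploid (effective) population size.
#' @param max_N Guard for the dense `(2N+1)^2` transition matrix; for `N`
#'   above this cap an error suggests the diffusion method.  Default 2000.
#' @return List (class `"loss_prob"`) with `prob_loss`, `method`, the copy
#'   count used, and diagnostics.
#' @examples
#' wf_markov_loss_prob(0.5, t = 1, N = 2)$prob_loss  # dbinom(0, 4, 0.5)
#' @export
wf_markov_loss_prob <- function(p0, t, N, max_N = 2000L) {
  if (!is_prob(p0) || length(p0) != 1L) stop_("`p0` must be in [0, 1]")
  if (N < 1) stop_("`N` must be >= 1")
  if (p0 == 0) return(loss_result(1, "markov-chain", N = N, t = t, j0 = 0))
  if (p0 == 1)
    return(loss_result(0, "markov-chain", N = N, t = t, j0 = 2 * N))
  if (t < 1) stop_("`t` must be >= 1")
  if (N > max_N)
    stop_("N = %d exceeds the dense-matrix cap (%d); use kimura_loss_prob()",
          N, max_N)
  n2 <- 2L * as.integer(N)
  j0 <- as.integer(round(n2 * p0))
  P <- outer(0:n2, 0:n2, function(i, j) dbinom(j, n2, i / n2))
  v <- numeric(n2 + 1L); v[j0 + 1L] <- 1
  for (g in seq_len(as.integer(t))) v <- as.vector(v %*% P)
  loss_result(v[1L], "markov-chain", N = N, t = t, j0 = j0)
}

loss_result <- function(prob, method, ...) {
  structure(c(list(prob_loss = prob, method = method), list(...)),
            class = "loss_prob")
}

#' @export
print.loss_prob <- function(x, ...) {
  cat(sprintf("P(allele lost by generation %s) = %.6g   [%s]\n",
              format(x$t), x$prob_loss, x$method))
  invisible(x)
}

## Terminating Gauss hypergeometric 2F1(1-i, i+2; 2; z) via the Jacobi
## P^{(1,1)} three-term recurrence: P_{i-1}^{(1,1)}(1 - 2 z) =
## i * 2F1(1-i, i+2; 2; z).  The recurrence is stable and the values stay
## O(1) on [0, 1]; direct polynomial summation of the hypergeometric
## series suffers catastrophic cancellation for large i.
hyp_series <- function(i_max, z) {
  x <- 1 - 2 * z
  P <- numeric(i_max)            # P[n] = P_n^{(1,1)}(x), n = 1..i_max
  Pm2 <- 1                        # P_0
  P[1L] <- 2 * x                  # P_1
  if (i_max >= 2L) for (n in 2:i_max) {
    P[n] <- ((n + 1) * (2 * n + 1) * x * P[n - 1L] -
               n * (n + 1) * (if (n == 2L) Pm2 else P[n - 2L])) /
      (n * (n + 2))
  }
  i <- seq_len(i_max)
  F <- numeric(i_max)
  F[1L] <- 1                      # 2F1(0, 3; 2; z) = 1
  if (i_max >= 2L)
    F[2:i_max] <- P[1:(i_max - 1L)] / i[2:i_max]
  F
}

#' Diffusion (Kimura) probability of allele loss
#'
#' Probability that a neutral allele at initial frequency `p0` has been
#' lost by generation `t` in a population of effective size `N`, from the
#' eigenfunction expansion of the pure-drift diffusion:
#' \deqn{f(0, t) = q + \sum_{i \ge 1} (2i + 1) p q (-1)^i
#'   \,{}_2F_1(1 - i,\, i + 2;\, 2;\, q)\, e^{-i (i + 1) t / (4N)}}
#' with `q = 1 - p0`.  The terminating hypergeometric factors are evaluated
#' through a stable Jacobi-polynomial recurrence; the series is truncated
#' when a term falls below `tol` (cap `max_terms`).
#'
#' @inheritParams wf_markov_loss_prob
#' @param tol Truncation threshold on term magnitude (default `1e-12`).
#' @param max_terms Series cap (default 10000); non-convergence errors out
#'   with diagnostics.
#' @return List (class `"loss_prob"`) with `prob_loss`, `method`,
#'   `terms_used`.
#' @examples
#' kimura_loss_prob(0.22, t = 40, N = 180)$prob_loss  # ~0.013 -> "1%"
#' @export
kimura_loss_prob <- function(p0, t, N, tol = 1e-12, max_terms = 10000L) {
  if (!is_prob(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1)
    stop_("`p0` must lie strictly inside (0, 1) for the diffusion series")
  if (t < 1) stop_("`t` must be >= 1")
  if (N < 1) stop_("`N` must be >= 1")
  q <- 1 - p0
  block <- 64L
  s <- q
  i_hi <- 0L
  F <- numeric(0)
  repeat {
    new_hi <- min(max_terms, i_hi + block)
    F <- hyp_series(new_hi, q)    # recompute; cheap (O(i) recurrence)
    i <- (i_hi + 1L):new_hi
    terms <- (2 * i + 1) * p0 * q * (-1)^i * F[i] *
      exp(-i * (i + 1) * t / (4 * N))
    s <- s + sum(terms)
    i_hi <- new_hi
    if (max(abs(terms)) < tol) break
    if (i_hi >= max_terms)
      stop_("Kimura series did not converge within %d terms (last |term| %.3g)",
            max_terms, max(abs(terms)))
  }
  loss_result(min(max(s, 0), 1), "diffusion-series", N = N, t = t,
              terms_used = i_hi)
}

#' Probability of allele loss by drift
#'
#' Front end dispatching to the Kimura diffusion series or the exact
#' Wright-Fisher Markov chain.
#'
#' @inheritParams wf_markov_loss_prob
#' @param method `"kimura"` (diffusion) or `"markov"` (exact chain).
#' @param ... Passed on to the chosen backend.
#' @return A `"loss_prob"` object.
#' @export
loss_prob <- function(p0, t, N, method = c("kimura", "markov"), ...) {
  method <- match.arg(method)
  switch(method,
         kimura = kimura_loss_prob(p0, t, N, ...),
         markov = wf_markov_loss_prob(p0, t, N, ...))
}

#' Effective population size for a target loss probability
#'
#' Finds the `N` at which the probability that an allele at initial
#' frequency `p0` is lost within `t` generations equals `target_prob`, by
#' bracketed root search (loss probability is monotone decreasing in `N`).
#'
#' @inheritParams kimura_loss_prob
#' @param target_prob Desired loss probability, strictly in (0, 1).
#' @param interval Search bracket for `N` (default `c(10, 1e6)`).
#' @param method Backend passed to [loss_prob()].
#' @return The effective population size (numeric).
#' @examples
#' ne_for_loss_prob(0.22, t = 40, target_prob = 0.05)  # ~122
#' @export
ne_for_loss_prob <- function(p0, t, target_prob, interval = c(10, 1e6),
                             method = "kimura") {
  if (!is_prob(target_prob) || target_prob <= 0 || target_prob >= 1)
    stop_("`target_prob` must lie strictly inside (0, 1)")
  f <- function(N) loss_prob(p0, t, N, method = method)$prob_loss -
    target_prob
  lo <- f(interval[1L]); hi <- f(interval[2L])
  if (sign(lo) == sign(hi))
    stop_("target probability %.3g not attainable for N in [%g, %g]",
          target_prob, interval[1L], interval[2L])
  uniroot(f, interval, tol = 1e-4)$root
}
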