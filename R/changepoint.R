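# Penalized changepoint detection for exponentially distributed IMDs.
#
# The observation model: within a segment the IMDs are i.i.d. exponential;
# the segment cost is twice the negative maximised log-likelihood with
# additive constants dropped, 2 m (log S - log m) for a segment of m
# observations summing to S. The total objective of a segmentation is the
# sum of segment costs plus a penalty for every changepoint.

#' Exponential segment cost
#'
#' Cost of fitting one exponential rate to observations `a..b` of `x`:
#' `2 m (log S - log m)` with `m = b - a + 1` and `S = sum(x[a:b])`. This is
#' twice the negative maximised exponential log-likelihood up to an additive
#' constant that cancels across segmentations.
#'
#' @param x Positive numeric vector of observations.
#' @param a,b Integer segment bounds, `1 <= a <= b <= length(x)`.
#' @return The segment cost (scalar).
#' @examples
#' exp_segment_cost(c(1, 1), 1, 2)        # 0
#' exp_segment_cost(rep(100, 4), 1, 4)    # 8 * log(100)
#' @export
exp_segment_cost <- function(x, a, b) {
  stopifnot(a >= 1, b >= a, b <= length(x))
  s <- sum(x[a:b])
  m <- b - a + 1
  if (s <= 0) abort("Segment sum must be positive for the exponential cost.")
  2 * m * (log(s) - log(m))
}

#' BIC-style changepoint penalty
#'
#' Penalty per additional changepoint: `2 * log(n)`, accounting for one free
#' exponential rate plus one changepoint location per extra segment.
#'
#' @param n Sequence length, `n >= 2`.
#' @return The penalty value.
#' @export
bic_penalty <- function(n) {
  if (n < 2) abort("BIC penalty requires a sequence of length >= 2.")
  2 * log(n)
}

resolve_penalty <- function(penalty, n) {
  if (is.numeric(penalty)) {
    if (penalty <= 0) abort("`penalty` must be positive.")
    penalty
  } else if (identical(penalty, "bic")) {
    bic_penalty(max(n, 2))
  } else {
    abort('`penalty` must be a positive number or "bic".')
  }
}

new_cpt_result <- function(res, n, method, penalty_value, min_seg_len) {
  structure(
    list(
      changepoints = as.integer(res$changepoints),
      objective = as.numeric(res$objective),
      n = as.integer(n),
      method = method,
      penalty_value = penalty_value,
      min_seg_len = as.integer(min_seg_len)
    ),
    class = "cpt_result"
  )
}

#' @export
print.cpt_result <- function(x, ...) {
  cat(sprintf(
    "<cpt_result> %s, n = %d, penalty = %.4g: %d changepoint(s), objective %.4f\n",
    x$method, x$n, x$penalty_value, length(x$changepoints) - 1L, x$objective
  ))
  invisible(x)
}

#' Changepoint detection under an exponential observation model
#'
#' Segments a positive sequence (intermutation distances) by penalized
#' likelihood. `"pelt"` (the default) and `"segneigh"` are exact: they return
#' the global minimiser of the penalized objective (SegNeigh additionally
#' honours a segment budget). `"binseg"` is the greedy recursive
#' approximation and `"amoc"` allows at most one change.
#'
#' @param x Positive numeric vector.
#' @param method One of `"pelt"`, `"binseg"`, `"segneigh"`, `"amoc"`.
#' @param penalty Positive number, or `"bic"` for `2 * log(length(x))`.
#' @param min_seg_len Minimal number of observations per segment (default 2).
#' @param max_segments Segment budget for `"binseg"`/`"segneigh"`
#'   (default: unbounded).
#' @return A `cpt_result`: list with `changepoints` (last observation index
#'   of every segment; the final element is always `length(x)`),
#'   `objective`, and the parameters used. Sequences shorter than
#'   `2 * min_seg_len` are returned as a single segment.
#' @examples
#' x <- c(rep(1000, 10), rep(10, 10))
#' cpt_exponential(x)
#' @export
cpt_exponential <- function(x, method = c("pelt", "binseg", "segneigh", "amoc"),
                            penalty = "bic", min_seg_len = 2L,
                            max_segments = NULL) {
  method <- match.arg(method)
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0) abort("`x` is empty.")
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("All observations must be positive and finite.")
  }
  min_seg_len <- as.integer(min_seg_len)
  if (min_seg_len < 1) abort("`min_seg_len` must be >= 1.")
  beta <- resolve_penalty(penalty, n)
  q <- as.integer(max_segments %||% n)
  res <- switch(method,
    pelt = cpp_pelt_exp(x, beta, min_seg_len),
    binseg = cpp_binseg_exp(x, beta, min_seg_len, q),
    segneigh = cpp_segneigh_exp(x, beta, min_seg_len, q),
    amoc = cpp_amoc_exp(x, beta, min_seg_len)
  )
  new_cpt_result(res, n, method, beta, min_seg_len)
}

#' Brute-force optimal partitioning (test oracle)
#'
#' Exact penalized optimal partitioning by exhaustive dynamic programming in
#' pure R, without pruning. Independent of the compiled search algorithms;
#' intended as a reference on short sequences.
#'
#' @inheritParams cpt_exponential
#' @return A `cpt_result` (see [cpt_exponential()]).
#' @export
cpt_brute_force <- function(x, penalty = "bic", min_seg_len = 2L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0) abort("`x` is empty.")
  if (any(x <= 0)) abort("All observations must be positive.")
  min_seg_len <- as.integer(min_seg_len)
  beta <- resolve_penalty(penalty, n)
  cs <- cumsum(c(0, x))
  segcost <- function(a, t) {  # cost of observations (a+1)..t
    m <- t - a
    2 * m * (log(cs[t + 1] - cs[a + 1]) - log(m))
  }
  if (n < 2 * min_seg_len) {
    return(new_cpt_result(
      list(changepoints = n, objective = segcost(0, n)),
      n, "brute_force", beta, min_seg_len
    ))
  }
  F <- rep(NA_real_, n + 1)
  last <- integer(n + 1)
  ncp <- integer(n + 1)
  F[1] <- -beta
  for (t in min_seg_len:n) {
    # admissible last changepoints: tau = 0 (no split) or tau >= min_seg_len
    # with at least min_seg_len observations remaining
    taus <- 0L
    if (t >= 2 * min_seg_len) taus <- c(0L, seq(min_seg_len, t - min_seg_len))
    best <- Inf; bncp <- 0L; btau <- 0L
    for (tau in taus) {
      val <- F[tau + 1] + segcost(tau, t) + beta
      cand_ncp <- ncp[tau + 1] + (tau > 0L)
      if (val < best ||
          (val == best && (cand_ncp < bncp ||
                           (cand_ncp == bncp && tau < btau)))) {
        best <- val; bncp <- cand_ncp; btau <- tau
      }
    }
    F[t + 1] <- best
    last[t + 1] <- btau
    ncp[t + 1] <- bncp
  }
  cps <- integer(0)
  t <- n
  while (t > 0) {
    cps <- c(t, cps)
    t <- last[t + 1]
  }
  new_cpt_result(list(changepoints = cps, objective = F[n + 1]),
                 n, "brute_force", beta, min_seg_len)
}
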