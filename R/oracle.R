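#' Threshold-crossing problem for the analytic oracle
#'
#' Describes the probability question shared by every Boolean neuron update:
#' given independent uniform draws `X_i, Y_j` on the unit interval, what is
#' `P(sum a_i X_i - sum b_j Y_j > DT)`?  Weights are the SyS values of the
#' active excitatory / inhibitory synaptic terms.
#'
#' @param excitatory,inhibitory Numeric vectors of non-negative weights
#'   (possibly empty).
#' @param threshold Non-negative DT value.
#' @return An object of class `threshold_problem`.
#' @export
threshold_problem <- function(excitatory = numeric(), inhibitory = numeric(),
                              threshold = 0.15) {
  stopifnot(all(excitatory >= 0), all(inhibitory >= 0),
            length(threshold) == 1, threshold >= 0)
  structure(list(excitatory = as.numeric(excitatory),
                 inhibitory = as.numeric(inhibitory),
                 threshold = as.numeric(threshold)),
            class = "threshold_problem")
}

#' Exact firing probability of a threshold crossing
#'
#' Computes `P(sum a_i X_i - sum b_j Y_j > DT)` for independent uniform
#' draws.  Closed forms are used for up to two active terms:
#'
#' * no active terms: 0 (the strict inequality `0 > DT` is false for
#'   `DT >= 0`);
#' * one excitatory weight `a`: `max(0, 1 - DT/a)`;
#' * two excitatory weights: complement of the area of the clipped triangle
#'   `{a x + b y <= DT}` in the unit square;
#' * one excitatory and one inhibitory weight: exact piecewise integral of
#'   the clipped line.
#'
#' Three or more terms use the exact inclusion-exclusion distribution of a
#' sum of independent scaled uniforms: after substituting `Y -> 1 - Y` each
#' inhibitory term becomes a positive uniform term minus its weight, so the
#' whole signed sum is a shifted sum `T` of uniforms on `[0, w_i]` with
#' `P(T <= t) = (n! prod w_i)^{-1} sum_J (-1)^{|J|} (t - sum_{i in J} w_i)_+^n`.
#' Ties at the threshold have probability zero under continuous draws, so
#' the strict inequality convention is unobservable.
#'
#' @param problem A [threshold_problem()].
#' @return The firing probability.
#' @examples
#' firing_probability(threshold_problem(1.5, numeric(), 0.15))       # 0.9
#' firing_probability(threshold_problem(1.5, 1.5, 0.15))             # 0.405
#' firing_probability(threshold_problem(c(1.5, 1.5), numeric(), 0.15)) # 0.995
#' @export
firing_probability <- function(problem) {
  stopifnot(inherits(problem, "threshold_problem"))
  a <- problem$excitatory[problem$excitatory > 0]
  b <- problem$inhibitory[problem$inhibitory > 0]
  d <- problem$threshold
  ne <- length(a); ni <- length(b)
  if (ne == 0) return(0)                       # -sum(bY) <= 0 <= d always
  if (ne == 1 && ni == 0) return(max(0, min(1, 1 - d / a)))
  if (ne == 2 && ni == 0) {
    # F(d) = P(a1 X + a2 Y <= d) by inclusion-exclusion on the unit square
    cdf_sum2 <- function(d, a1, a2) {
      if (d <= 0) return(0)
      if (d >= a1 + a2) return(1)
      v <- d^2
      if (d > a1) v <- v - (d - a1)^2
      if (d > a2) v <- v - (d - a2)^2
      v / (2 * a1 * a2)
    }
    return(1 - cdf_sum2(d, a[1], a[2]))
  }
  if (ne == 1 && ni == 1) {
    # P(aX - bY > d) = integral over y of P(X > (d + b y)/a)
    if (d >= a) return(0)
    ystar <- min(1, (a - d) / b)
    return(ystar - (d * ystar + b * ystar^2 / 2) / a)
  }
  uniform_sum_tail(c(a, b), d + sum(b))
}

# P(sum of independent U[0, w_i] > t), exact, by inclusion-exclusion over
# subsets of the weights.  Term counts in the circuit are tiny (<= 3), so
# the 2^n sum is trivial.
uniform_sum_tail <- function(w, t) {
  n <- length(w)
  if (t <= 0) return(1)
  if (t >= sum(w)) return(0)
  cdf <- 0
  for (mask in 0:(2^n - 1)) {
    J <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    arg <- t - sum(w[J])
    if (arg > 0) cdf <- cdf + (-1)^length(J) * arg^n
  }
  cdf <- cdf / (factorial(n) * prod(w))
  min(1, max(0, 1 - cdf))
}

#' Monte-Carlo estimate of a threshold-crossing probability
#'
#' Brute-force companion to [firing_probability()]: draws every term
#' independently and reports the empirical crossing frequency with its
#' binomial standard error.
#'
#' @param problem A [threshold_problem()].
#' @param n_draws Number of Monte-Carlo replicates.
#' @return List with `estimate`, `se` and `n_draws`.
#' @export
mc_firing_probability <- function(problem, n_draws = 100000L) {
  stopifnot(inherits(problem, "threshold_problem"), n_draws >= 1)
  s <- numeric(n_draws)
  for (w in problem$excitatory) if (w > 0) s <- s + w * stats::runif(n_draws)
  for (w in problem$inhibitory) if (w > 0) s <- s - w * stats::runif(n_draws)
  p <- mean(s > problem$threshold)
  list(estimate = p, se = sqrt(max(p * (1 - p), 1e-12) / n_draws),
       n_draws = n_draws)
}

# Conditional firing tables for the stationary one-sample analysis.
# All entries depend only on the (homogeneous scalar) parameters, not on
# the afferent probabilities, so they are computed once per configuration.
dcn_conditionals <- function(cfg) {
  s <- lapply(cfg$sys, function(v) v[1])
  d <- lapply(cfg$dt, function(v) v[1])
  fp <- function(exc, inh, dt) firing_probability(threshold_problem(exc, inh, dt))
  pur <- array(0, dim = c(2, 2, 2))  # [granule+1, climbing+1, interneuron+1]
  for (g in 0:1) for (c in 0:1) for (i in 0:1)
    pur[g + 1, c + 1, i + 1] <- fp(c(if (g) s$granule_purkinje,
                                     if (c) s$cf_purkinje),
                                   if (i) s$ii_purkinje else numeric(),
                                   d$purkinje)
  dcn <- array(0, dim = c(2, 2, 2))  # [mossy+1, climbing+1, purkinje+1]
  for (m in 0:1) for (c in 0:1) for (p in 0:1)
    dcn[m + 1, c + 1, p + 1] <- fp(c(if (m) s$mf_dcn, if (c) s$cf_dcn),
                                   if (p) s$purkinje_dcn else numeric(),
                                   d$dcn)
  list(granule_m1_g0 = fp(s$mf_granule, numeric(), d$granule),
       granule_m1_g1 = fp(s$mf_granule, s$golgi_granule, d$granule),
       golgi_given_granule = fp(s$granule_golgi, numeric(), d$golgi),
       ii_given_granule = fp(s$granule_ii, numeric(), d$ii),
       purkinje = pur, dcn = dcn)
}

#' Stationary one-sample DCN firing probability
#'
#' Exact marginal firing probability of the DCN for homogeneous parameters
#' and i.i.d. Bernoulli afferents, obtained by total probability over all
#' Boolean states of the intermediate neurons.  The Golgi-to-granule
#' feedback acts with a one-sample delay, which makes the chain non-i.i.d.;
#' the stationary Golgi probability is found by fixed-point iteration
#' (start 0, stop when the change falls below `tol`).
#'
#' The within-sample dependencies are respected: the interneuron can only
#' fire given a granule spike, the Purkinje conditional is mixed over the
#' joint (granule, interneuron) distribution given the mossy state, and the
#' DCN conditional is mixed over the Purkinje state given both afferents.
#'
#' @param mf_prob,cf_prob Mossy / climbing fibre firing probabilities
#'   (vectors of equal length are recycled elementwise).
#' @param cfg A [sim_config()] with homogeneous (scalar) parameters.
#' @param tol Fixed-point convergence tolerance.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @param tables Precomputed [dcn_conditionals()] (internal fast path).
#' @return Vector of DCN firing probabilities.
#' @examples
#' dcn_marginal(0.5, 0.5, sim_config(n_cmc = 1))
#' @export
dcn_marginal <- function(mf_prob, cf_prob, cfg, tol = 1e-10, max_iter = 1000L,
                         tables = NULL) {
  stopifnot(all(mf_prob >= 0 & mf_prob <= 1), all(cf_prob >= 0 & cf_prob <= 1))
  k <- max(length(mf_prob), length(cf_prob))
  mf_prob <- rep_len(mf_prob, k); cf_prob <- rep_len(cf_prob, k)
  tb <- if (is.null(tables)) dcn_conditionals(cfg) else tables
  vapply(seq_len(k), function(i)
    dcn_marginal_one(mf_prob[i], cf_prob[i], tb, tol, max_iter), numeric(1))
}

dcn_marginal_one <- function(pm, pc, tb, tol, max_iter) {
  # stationary Golgi probability q via the granule/Golgi loop
  q <- 0
  for (it in seq_len(max_iter)) {
    pg <- pm * ((1 - q) * tb$granule_m1_g0 + q * tb$granule_m1_g1)
    qn <- pg * tb$golgi_given_granule
    if (abs(qn - q) < tol) { q <- qn; break }
    q <- qn
    if (it == max_iter)
      stop("Golgi fixed point did not converge", call. = FALSE)
  }
  p_gr_given_m <- c(0, (1 - q) * tb$granule_m1_g0 + q * tb$granule_m1_g1)
  f_ii <- tb$ii_given_granule
  total <- 0
  for (m in 0:1) for (c in 0:1) {
    pmc <- (if (m) pm else 1 - pm) * (if (c) pc else 1 - pc)
    if (pmc == 0) next
    # Purkinje probability given the afferent pair
    pp <- 0
    for (g in 0:1) {
      pg <- if (g) p_gr_given_m[m + 1] else 1 - p_gr_given_m[m + 1]
      if (pg == 0) next
      if (g) {
        pp <- pp + pg * ((1 - f_ii) * tb$purkinje[2, c + 1, 1] +
                           f_ii * tb$purkinje[2, c + 1, 2])
      } else {
        pp <- pp + pg * tb$purkinje[1, c + 1, 1]
      }
    }
    total <- total + pmc * ((1 - pp) * tb$dcn[m + 1, c + 1, 1] +
                              pp * tb$dcn[m + 1, c + 1, 2])
  }
  total
}

#' Tabulated oracle self-check
#'
#' Compares the analytic firing probability with a Monte-Carlo estimate for
#' a set of threshold problems and reports z-scores.  Used by the
#' `oracle-check` command-line verb.
#'
#' @param problems List of [threshold_problem()]s; defaults to the three
#'   canonical single/double-term cases at the reference parameters.
#' @param n_draws Monte-Carlo replicates per problem.
#' @return Data frame with columns `excitatory`, `inhibitory`, `threshold`,
#'   `analytic`, `mc`, `se`, `z`.
#' @export
oracle_check <- function(problems = NULL, n_draws = 100000L) {
  if (is.null(problems))
    problems <- list(threshold_problem(1.5, numeric(), 0.15),
                     threshold_problem(1.5, 1.5, 0.15),
                     threshold_problem(c(1.5, 1.5), numeric(), 0.15),
                     threshold_problem(c(1.5, 1.5), 1.5, 0.15))
  rows <- lapply(problems, function(p) {
    an <- firing_probability(p)
    mc <- mc_firing_probability(p, n_draws)
    data.frame(excitatory = paste(p$excitatory, collapse = "+"),
               inhibitory = paste(p$inhibitory, collapse = "+"),
               threshold = p$threshold, analytic = an,
               mc = mc$estimate, se = mc$se,
               z = (mc$estimate - an) / max(mc$se, 1e-12))
  })
  do.call(rbind, rows)
}
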