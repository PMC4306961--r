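# Allele-recovery probability model.
#
# Reads from one amplicon are modelled as i.i.d. draws over m + 1 categories:
# "correct copy of allele i" with probability q_i = p * w_i / sum(w), and
# "erroneous read" with probability 1 - p, where p is the per-read probability
# of a correct sequence and w the allele amplification weights. The genotype
# is considered safely recoverable from n reads when every allele category
# holds at least k copies; the model computes that probability exactly by
# inclusion-exclusion over the events {allele i has fewer than k copies}, and
# the minimum n at which it reaches a stated confidence.

#' Per-read allele profile
#'
#' @param p_correct Probability that a single read carries a correct allele
#'   sequence (the observed proportion of correct reads).
#' @param weights Positive amplification weights, one per allele: \code{1} for
#'   a haplotype, \code{c(1, 1)} for two alleles amplifying equally,
#'   \code{c(2, 1)} when one allele amplifies half as well as the other.
#' @return An object of class \code{allele_profile} with the per-allele read
#'   probabilities \code{q = p_correct * weights / sum(weights)}.
#' @examples
#' allele_profile(0.88)            # haplotype
#' allele_profile(0.84, c(2, 1))   # biased biallelic locus
#' @export
allele_profile <- function(p_correct, weights = 1) {
  if (!is.numeric(p_correct) || length(p_correct) != 1 ||
      is.na(p_correct) || p_correct < 0 || p_correct > 1) {
    stop("p_correct must be a single probability in [0, 1]")
  }
  weights <- as.numeric(weights)
  if (!length(weights) || any(is.na(weights)) || any(weights <= 0)) {
    stop("weights must be positive reals, one per allele")
  }
  structure(
    list(p_correct = p_correct, weights = weights,
         q = p_correct * weights / sum(weights)),
    class = "allele_profile"
  )
}

#' @export
print.allele_profile <- function(x, ...) {
  m <- length(x$weights)
  cat("Allele profile: p_correct =", x$p_correct, "| m =", m,
      "allele(s), weights", paste(x$weights, collapse = ":"), "\n")
  cat("  per-read allele probabilities q:",
      paste(signif(x$q, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Recovery target
#'
#' @param k Minimum number of identical correct copies required per allele.
#' @param confidence Probability threshold the recovery probability must
#'   reach.
#' @return An object of class \code{recovery_target}.
#' @export
recovery_target <- function(k = 3L, confidence = 0.999) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1) {
    stop("confidence must lie strictly between 0 and 1")
  }
  structure(list(k = k, confidence = confidence), class = "recovery_target")
}

as_profile <- function(profile) {
  if (inherits(profile, "allele_profile")) profile
  else allele_profile(profile)
}

#' Probability of recovering every allele at least k times
#'
#' Exact probability that, among \code{n} reads drawn with category
#' probabilities \code{(q_1, ..., q_m, 1 - sum(q))}, every allele category
#' holds at least \code{k} reads. Computed by inclusion-exclusion over the
#' events \{allele i has fewer than k copies\}, with the joint terms as
#' explicit multinomial sums evaluated in log space. For a haplotype
#' (\code{m = 1}) this equals the binomial upper tail
#' \eqn{P(X \ge k), X \sim Bin(n, p)}.
#'
#' @param n Total number of reads; may be a vector.
#' @param profile An \code{\link{allele_profile}}, or a bare probability
#'   (treated as a haplotype profile).
#' @param k Minimum copies per allele.
#' @return Probability in [0, 1], one per element of \code{n}.
#' @examples
#' recovery_probability(10, allele_profile(0.5), k = 3) # 0.9453125
#' @export
recovery_probability <- function(n, profile, k = 3L) {
  profile <- as_profile(profile)
  k <- as.integer(k)
  if (any(is.na(n)) || any(n < 0)) stop("n must be non-negative")
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  vapply(as.integer(n), recovery_probability_one, numeric(1),
         q = profile$q, k = k)
}

recovery_probability_one <- function(n, q, k) {
  m <- length(q)
  if (n < m * k) return(0)
  total <- 1
  # count vectors with every entry < k, reused for every subset size
  for (sz in seq_len(m)) {
    subsets <- utils::combn(m, sz, simplify = FALSE)
    counts <- as.matrix(expand.grid(rep(list(0:(k - 1)), sz)))
    csum <- rowSums(counts)
    lfact_counts <- rowSums(lgamma(counts + 1))
    for (S in subsets) {
      qs <- q[S]
      qrest <- 1 - sum(qs)
      lq <- counts %*% matrix(log(qs), ncol = 1)
      ok <- csum <= n
      lp <- lgamma(n + 1) - lfact_counts[ok] - lgamma(n - csum[ok] + 1) +
        lq[ok] +
        ifelse(n - csum[ok] > 0, (n - csum[ok]) * log(qrest), 0)
      total <- total + (-1)^sz * sum(exp(lp))
    }
  }
  min(max(total, 0), 1)
}

#' Minimum coverage reaching a confidence target
#'
#' Smallest total read number \code{n} such that
#' \code{recovery_probability(n, profile, k) >= confidence}. Found by
#' exponential bracketing followed by bisection, both justified by the
#' monotonicity of the recovery probability in \code{n}.
#'
#' @param profile An \code{\link{allele_profile}} (or bare probability).
#' @param target A \code{\link{recovery_target}}.
#' @return An object of class \code{coverage_result}: list with
#'   \code{profile}, \code{target}, \code{n_min} and \code{prob_at_n_min}.
#' @examples
#' min_coverage(allele_profile(0.88))$n_min # 7
#' @export
min_coverage <- function(profile, target = recovery_target()) {
  profile <- as_profile(profile)
  stopifnot(inherits(target, "recovery_target"))
  if (profile$p_correct <= 0) {
    stop("unreachable confidence: p_correct is 0, no coverage suffices")
  }
  k <- target$k
  cc <- target$confidence
  m <- length(profile$q)

  lo <- m * k - 1L             # always below target (probability 0 at m*k - 1)
  hi <- m * k
  while (recovery_probability(hi, profile, k) < cc) {
    lo <- hi
    hi <- hi * 2L
    if (hi > 1e8) stop("unreachable confidence: coverage search exceeded 1e8")
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (recovery_probability(mid, profile, k) >= cc) hi <- mid else lo <- mid
  }
  structure(
    list(profile = profile, target = target, n_min = hi,
         prob_at_n_min = recovery_probability(hi, profile, k)),
    class = "coverage_result"
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat("Minimum coverage: ", x$n_min, " reads (P = ",
      format(x$prob_at_n_min, digits = 6), " >= ",
      x$target$confidence, ", k = ", x$target$k, ")\n", sep = "")
  invisible(x)
}

#' Monte Carlo estimate of the recovery probability
#'
#' Independent simulation cross-check for
#' \code{\link{recovery_probability}}: draws \code{reps} multinomial samples
#' of size \code{n} over the allele categories plus the error category and
#' reports the fraction in which every allele holds at least \code{k} reads.
#'
#' @param n Total reads per sample.
#' @param profile An \code{\link{allele_profile}} (or bare probability).
#' @param k Minimum copies per allele.
#' @param reps Number of Monte Carlo replicates.
#' @param seed Integer seed; results are reproducible for a fixed seed and do
#'   not disturb the caller's RNG stream.
#' @return List with \code{estimate}, binomial \code{se} and \code{reps}.
#' @export
mc_recovery <- function(n, profile, k = 3L, reps = 10000L, seed = 1L) {
  profile <- as_profile(profile)
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) stop("reps must be a positive integer")
  q <- profile$q
  m <- length(q)
  est <- with_seed(seed, {
    draws <- stats::rmultinom(reps, n, c(q, 1 - sum(q)))
    mean(colSums(draws[seq_len(m), , drop = FALSE] >= k) == m)
  })
  list(estimate = est, se = sqrt(est * (1 - est) / reps), reps = reps)
}

#' Correct-read proportions consistent with a printed coverage
#'
#' Inverse check: the set of per-read correct probabilities p for which
#' \code{\link{min_coverage}} returns exactly \code{n_printed}, located on a
#' p-grid. Because the minimum coverage is non-increasing in p, the set is an
#' interval.
#'
#' @param n_printed The coverage value to invert.
#' @param weights Allele amplification weights of the profile shape.
#' @param target A \code{\link{recovery_target}}.
#' @param grid_step Resolution of the p grid.
#' @return Numeric vector \code{c(p_lo, p_hi)} spanning the matching grid
#'   points, or \code{numeric(0)} if no p on the grid maps to
#'   \code{n_printed}.
#' @export
consistent_p_interval <- function(n_printed, weights = 1,
                                  target = recovery_target(),
                                  grid_step = 0.001) {
  stopifnot(inherits(target, "recovery_target"))
  m <- length(weights)
  if (n_printed < m * target$k) return(numeric(0))
  grid <- seq(grid_step, 1, by = grid_step)
  # n_min(p) == n_printed  <=>  P(n_printed; p) >= c  and  P(n_printed-1; p) < c
  hit <- vapply(grid, function(p) {
    prof <- allele_profile(p, weights)
    at_n <- recovery_probability(n_printed, prof, target$k)
    if (at_n < target$confidence) return(FALSE)
    recovery_probability(n_printed - 1L, prof, target$k) < target$confidence
  }, logical(1))
  if (!any(hit)) return(numeric(0))
  range(grid[hit])
}
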