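#' @include AllClasses.R
NULL

#' Deterministic allele-frequency recursion under additive selection
#'
#' With genotype fitnesses 1, 1+s, 1+2s for 0/1/2 copies of the selected
#' haplotype, the expected frequency after one generation of selection and
#' random mating is
#' \deqn{x' = \frac{(1+2s)x^2 + x(1-x)(1+s)}{(1+2s)x^2 + 2x(1-x)(1+s) + (1-x)^2}.}
#' 0 and 1 are absorbing; for `s = 0` the frequency is unchanged.
#'
#' @param x current frequency in `[0, 1]` (vectorised).
#' @param s selection coefficient (`s > -0.5` keeps the denominator
#'   positive).
#' @return Frequency at the next generation.
#' @examples
#' selectionRecursion(0.05, 0.1)   # ~0.0547
#' @export
selectionRecursion <- function(x, s) {
  stopifnot(all(x >= 0 & x <= 1), s > -0.5)
  num <- (1 + 2 * s) * x^2 + x * (1 - x) * (1 + s)
  den <- (1 + 2 * s) * x^2 + 2 * x * (1 - x) * (1 + s) + (1 - x)^2
  num / den
}

#' Expected selected-allele frequency trajectory
#'
#' Iterates [selectionRecursion()] from an initial frequency; element `t+1`
#' of the result is the expected frequency at generation `t`.
#'
#' @param x0 initial frequency.
#' @param s selection coefficient.
#' @param T number of generations to iterate.
#' @return Numeric vector of length `T + 1`, starting at `x0`.
#' @export
expectedTrajectory <- function(x0, s, T) {
  out <- numeric(T + 1)
  out[1] <- x0
  for (t in seq_len(T)) out[t + 1] <- selectionRecursion(out[t], s)
  out
}

#' Exponential rate of ancestry-tract lengths under hybrid isolation
#'
#' Under a hybrid-isolation model (one admixture pulse followed by
#' isolation), the genetic length of tracts of an ancestry contributing
#' proportion `m` is approximately exponential with rate `(1 - m) * T` per
#' Morgan after `T` generations: a tract is broken by a crossover falling
#' on it (rate 1 per Morgan per meiosis) that recombines it onto the other
#' ancestry (probability `1 - m`).  On the X chromosome the effective
#' recombination rate is two-thirds of the autosomal one (female-only
#' crossovers), so the rate scales by 2/3.  The law holds for the
#' single-pulse model only; multi-wave histories are not approximated here.
#'
#' @param m ancestry proportion, strictly between 0 and 1.
#' @param T generations since admixture, `>= 1`.
#' @param xScale apply the X-chromosome 2/3 scaling.
#' @return Rate per Morgan; mean tract length is `1/rate` Morgan.
#' @examples
#' expectedTractRate(0.8, 50)   # 10 per Morgan, mean 0.1 Morgan
#' @export
expectedTractRate <- function(m, T, xScale = FALSE) {
  if (m <= 0 || m >= 1) stop("m must lie strictly between 0 and 1")
  stopifnot(T >= 1)
  (1 - m) * T * (if (xScale) 2 / 3 else 1)
}

#' Chi-square goodness of fit of counts to a Poisson law
#'
#' Bins observed counts by value, pools bins from both tails until every
#' expected count is at least 5, and compares to the Poisson(`lambda`)
#' expectation with a chi-square test on (bins - 1) degrees of freedom.
#'
#' @param counts integer event counts (e.g. de novo mutations per
#'   haplotype).
#' @param lambda Poisson mean under the null.
#' @return List with `statistic`, `df`, `p.value`, `bins`.
#' @export
poissonGof <- function(counts, lambda) {
  if (!length(counts)) stop("empty input")
  stopifnot(lambda > 0)
  n <- length(counts)
  hi <- max(counts, ceiling(lambda))
  kk <- 0:hi
  pk <- dpois(kk, lambda)
  pk[length(pk)] <- pk[length(pk)] + (1 - sum(pk))  # upper tail into last bin
  obs <- tabulate(counts + 1L, nbins = hi + 1L)
  obs[length(obs)] <- obs[length(obs)] + sum(counts > hi)
  exp <- n * pk
  # pool from the left, then from the right, until expected >= 5
  while (length(exp) > 2 && exp[1] < 5) {
    exp[2] <- exp[2] + exp[1]; obs[2] <- obs[2] + obs[1]
    exp <- exp[-1]; obs <- obs[-1]
  }
  while (length(exp) > 2 && exp[length(exp)] < 5) {
    k <- length(exp)
    exp[k - 1] <- exp[k - 1] + exp[k]; obs[k - 1] <- obs[k - 1] + obs[k]
    exp <- exp[-k]; obs <- obs[-k]
  }
  stat <- sum((obs - exp)^2 / exp)
  df <- length(exp) - 1L
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE), bins = length(exp))
}

#' Kolmogorov-Smirnov test of lengths against an exponential law
#'
#' @param lengths observed tract lengths (same unit as `rate`'s inverse,
#'   typically Morgan).
#' @param rate exponential rate under the null (e.g. from
#'   [expectedTractRate()]).
#' @return List with `statistic` and `p.value`.
#' @export
ksExponential <- function(lengths, rate) {
  if (!length(lengths)) stop("empty input")
  stopifnot(rate > 0)
  kt <- suppressWarnings(ks.test(lengths, "pexp", rate = rate))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}
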