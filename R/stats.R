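# Proportion statistics: the ARS x association independence construction,
# chi-square homogeneity tests on group-formation tables, and the Marascuilo
# pairwise-proportion procedure.

#' Expected ARS membership of associated pairs under independence
#'
#' If a fraction `f_ars` of all locations is in ARS behaviour and ARS is
#' independent of pair association, an associated fix pair has probability
#' `(1 - f)^2` of containing no ARS member, `f^2` of containing two, and the
#' complement of exactly one.
#'
#' @param f_ars ARS fraction of all locations, strictly in (0, 1).
#' @return Named numeric `c(p0, p1, p2)` summing to 1 exactly.
#' @export
ars_association_expected <- function(f_ars) {
  if (length(f_ars) != 1 || !is.finite(f_ars) || f_ars <= 0 || f_ars >= 1) {
    stop("f_ars must be a single value strictly between 0 and 1",
         call. = FALSE)
  }
  p0 <- (1 - f_ars)^2
  p2 <- f_ars^2
  c(p0 = p0, p1 = 1 - p0 - p2, p2 = p2)
}

#' Chi-square test of ARS/association independence
#'
#' Pearson goodness-of-fit of the observed (0, 1, 2)-members-in-ARS counts
#' against the independence expectation from [ars_association_expected()],
#' on 2 degrees of freedom, no continuity correction.
#'
#' @param observed Integer vector `c(n0, n1, n2)` of associated pairs with
#'   0, 1 and 2 members in ARS.
#' @param f_ars ARS fraction of all locations.
#' @return List: `statistic`, `df` (2), `p_value`, `expected` (proportions),
#'   `observed`.
#' @export
ars_association_test <- function(observed, f_ars) {
  if (length(observed) != 3 || any(observed < 0)) {
    stop("observed must be three non-negative counts", call. = FALSE)
  }
  n <- sum(observed)
  if (n == 0) stop("no observed pairs", call. = FALSE)
  p <- ars_association_expected(f_ars)
  expected <- n * p
  if (any(expected == 0)) stop("zero expected cell", call. = FALSE)
  if (any(expected < 5)) {
    warning("expected cell count below 5; chi-square approximation is poor",
            call. = FALSE)
  }
  stat <- sum((observed - expected)^2 / expected)
  list(statistic = stat, df = 2,
       p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE),
       expected = p, observed = observed)
}

#' Chi-square test of homogeneity
#'
#' Standard Pearson chi-square on an r x c count table, df = (r-1)(c-1), no
#' continuity correction.
#'
#' @param tab Matrix of counts with positive row and column sums.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
homogeneity_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate count table", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Marascuilo pairwise comparison of proportions
#'
#' For k group proportions, the pair (i, j) is significantly different when
#' `|p_i - p_j|` exceeds the critical range
#' `sqrt(chi2[1 - alpha, k - 1]) * sqrt(p_i(1-p_i)/n_i + p_j(1-p_j)/n_j)`.
#'
#' @param props Proportions per group, each in `[0, 1]`.
#' @param ns Group sizes (>= 1).
#' @param alpha Simultaneous significance level, in (0, 1); default 0.05.
#' @return Tibble with one row per unordered pair: `i`, `j`, `diff`,
#'   `critical`, `significant`.
#' @export
marascuilo <- function(props, ns, alpha = 0.05) {
  k <- length(props)
  stopifnot(length(ns) == k, k >= 2)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (any(props < 0 | props > 1)) stop("proportions outside [0, 1]",
                                       call. = FALSE)
  if (any(ns < 1)) stop("group sizes must be >= 1", call. = FALSE)
  crit_mult <- sqrt(stats::qchisq(1 - alpha, df = k - 1))
  pairs <- utils::combn(k, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  critical <- crit_mult * sqrt(props[i] * (1 - props[i]) / ns[i] +
                                 props[j] * (1 - props[j]) / ns[j])
  d <- abs(props[i] - props[j])
  tibble::tibble(i = i, j = j, diff = d, critical = critical,
                 significant = d > critical)
}

#' Simulate ARS states of associated pairs
#'
#' Null/alternative generator for calibration of
#' [ars_association_test()]: each member of a pair is in ARS with
#' probability `f_ars`; with probability `dependence` the two members share
#' a single draw (both or neither in ARS), which raises the same-state cells
#' by `dependence * f(1-f)` relative to independence. `dependence = 0` is
#' the exact null.
#'
#' @param n_pairs Number of associated pairs.
#' @param f_ars ARS fraction.
#' @param dependence Mixture weight of the shared-state component, in
#'   `[0, 1]`; default 0.2 is the generator's planted-dependence effect.
#' @return Integer counts `c(n0, n1, n2)`.
#' @export
simulate_ars_pair_counts <- function(n_pairs, f_ars, dependence = 0.2) {
  stopifnot(n_pairs >= 1, dependence >= 0, dependence <= 1)
  shared <- stats::runif(n_pairs) < dependence
  s1 <- stats::runif(n_pairs) < f_ars
  s2 <- ifelse(shared, s1, stats::runif(n_pairs) < f_ars)
  k <- s1 + s2
  c(n0 = sum(k == 0), n1 = sum(k == 1), n2 = sum(k == 2))
}
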