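#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes Spearman's rho on mid-ranks (average ranks for ties). For small
#' samples (`n <= exact_n`, default 8) the two-sided p-value is exact, by
#' enumeration of all permutations of one margin; for larger samples it uses
#' the t-approximation with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @param exact_n Largest sample size for which the permutation-exact
#'   p-value is computed. Above this the t-approximation is used.
#' @return A one-row tibble with columns `rho`, `p`, `n` and `method`.
#' @seealso [partial_spearman()] for the confound-controlled version.
#' @export
#' @examples
#' spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))
spearman <- function(x, y, exact_n = 8L) {
  res <- spearman_rho_p(x, y, exact_n = exact_n)
  tibble(
    rho = res[["rho"]], p = res[["p"]], n = length(x),
    method = if (length(x) <= exact_n) "exact" else "t-approximation"
  )
}

# Fast internal path returning c(rho = , p = ); used by the batteries.
spearman_rho_p <- function(x, y, exact_n = 8L) {
  check_paired(x, y, min_n = 3L)
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("Spearman correlation is undefined for a constant vector.")
  }
  rho <- cor(rx, ry)
  if (n <= exact_n) {
    p <- spearman_perm_p(rx, ry)
  } else {
    p <- spearman_t_p(rho, n)
  }
  c(rho = rho, p = p)
}

spearman_t_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tval), df = n - 2)
}

# Exact two-sided permutation p-value: the proportion of the n!
# permutations of one rank vector whose |rho| is at least the observed.
spearman_perm_p <- function(rx, ry) {
  n <- length(rx)
  perms <- all_permutations(n)
  cx <- (rx - mean(rx)) / sd(rx)
  cy <- (ry - mean(ry)) / sd(ry)
  rho_all <- as.vector(matrix(cy[perms], nrow = nrow(perms)) %*% cx) / (n - 1)
  rho_obs <- sum(cx * cy) / (n - 1)
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

# Permutation matrices are memoised per size; n <= 8 keeps this small.
perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  if (n == 1L) {
    out <- matrix(1L, 1L, 1L)
  } else {
    sub <- all_permutations(n - 1L)
    out <- do.call(rbind, lapply(seq_len(n), function(i) {
      rest <- seq_len(n)[-i]
      cbind(rep.int(i, nrow(sub)), matrix(rest[sub], nrow(sub)))
    }))
  }
  perm_cache[[key]] <- out
  out
}

#' First-order partial Spearman correlation
#'
#' Rank correlation between `x` and `y` after removing the contribution of a
#' control variable `z`: ranks are taken first, then the first-order partial
#' Pearson formula is applied,
#' \deqn{\rho_{xy\cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'   {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}}
#' with all `r` Spearman coefficients. The p-value comes from a t-statistic
#' with `n - 3` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`.
#' @param z Control variable, same length.
#' @return A one-row tibble with columns `rho`, `p`, `n` and `method`.
#' @export
#' @examples
#' set.seed(1)
#' z <- rnorm(50); x <- z + rnorm(50); y <- z + rnorm(50)
#' partial_spearman(x, y, z)
partial_spearman <- function(x, y, z) {
  res <- partial_spearman_rho_p(x, y, z)
  tibble(
    rho = res[["rho"]], p = res[["p"]], n = length(x),
    method = "rank-transform partial"
  )
}

partial_spearman_rho_p <- function(x, y, z) {
  check_paired(x, y, min_n = 4L)
  check_paired(x, z, min_n = 4L)
  n <- length(x)
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  if (sd(rx) == 0 || sd(ry) == 0 || sd(rz) == 0) {
    abort("Partial Spearman correlation is undefined for a constant vector.")
  }
  r_xy <- cor(rx, ry); r_xz <- cor(rx, rz); r_yz <- cor(ry, rz)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    abort(
      "Degenerate control: the control variable is rank-identical to x or y."
    )
  }
  rho <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  rho <- max(-1, min(1, rho))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 3) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df = n - 3)
  }
  c(rho = rho, p = p)
}

#' Residual-based partial Spearman estimator
#'
#' Alternative estimator of the partial rank correlation: both variables are
#' rank-transformed, each is regressed on the ranked control, and the Pearson
#' correlation of the two residual vectors is reported. Agrees asymptotically
#' with [partial_spearman()]; kept as an independent cross-check.
#'
#' @inheritParams partial_spearman
#' @return A one-row tibble with columns `rho`, `p`, `n` and `method`.
#' @export
partial_spearman_residual <- function(x, y, z) {
  check_paired(x, y, min_n = 4L)
  check_paired(x, z, min_n = 4L)
  n <- length(x)
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  if (sd(rz) == 0) abort("Control variable is constant.")
  res_x <- stats::residuals(stats::lm(rx ~ rz))
  res_y <- stats::residuals(stats::lm(ry ~ rz))
  if (sd(res_x) == 0 || sd(res_y) == 0) {
    abort("Degenerate control: residuals are constant.")
  }
  rho <- cor(res_x, res_y)
  tval <- rho * sqrt((n - 3) / max(1 - rho^2, 1e-300))
  tibble(
    rho = rho, p = 2 * pt(-abs(tval), df = n - 3), n = n,
    method = "rank-residual partial"
  )
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups, with mid-ranks for ties. The p-value is
#' exact (full enumeration of group assignments) when the pooled sample size
#' is at most `exact_limit` and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections is used.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param alternative One of `"two.sided"` (default), `"greater"` (`a` tends
#'   larger), `"less"`.
#' @param exact_limit Largest pooled size for which the exact enumeration is
#'   attempted.
#' @return A one-row tibble with columns `u` (the U statistic of group `a`),
#'   `p`, `n_a`, `n_b` and `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(a, b, alternative = c("two.sided", "greater", "less"),
                         exact_limit = 12L) {
  alternative <- match.arg(alternative)
  if (length(a) == 0 || length(b) == 0) {
    abort("Both groups must be non-empty.")
  }
  stopifnot(is.numeric(a), is.numeric(b))
  if (anyNA(a) || anyNA(b)) abort("Missing values are not allowed.")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  pooled <- c(a, b)
  r_all <- rank(pooled)
  u_a <- sum(r_all[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (n <= exact_limit && !has_ties) {
    p <- mw_exact_p(u_a, n_a, n_b, alternative)
    method <- "exact"
  } else {
    p <- mw_normal_p(u_a, r_all, n_a, n_b, alternative)
    method <- "normal approximation"
  }
  tibble(u = u_a, p = p, n_a = n_a, n_b = n_b, method = method)
}

# Exact null distribution of U by enumeration of all C(n, n_a) assignments
# of the tie-free ranks 1..n to group a.
mw_exact_p <- function(u_obs, n_a, n_b, alternative) {
  n <- n_a + n_b
  sel <- utils::combn(n, n_a)
  u_all <- colSums(matrix(seq_len(n)[sel], nrow = n_a)) -
    n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  switch(alternative,
    two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9),
    greater   = mean(u_all >= u_obs - 1e-9),
    less      = mean(u_all <= u_obs + 1e-9)
  )
}

mw_normal_p <- function(u_obs, r_all, n_a, n_b, alternative) {
  n <- n_a + n_b
  mu <- n_a * n_b / 2
  tie_tab <- table(r_all)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  sigma <- sqrt(sigma2)
  z <- switch(alternative,
    # continuity correction shrinks towards, but never across, the mean
    two.sided = max(abs(u_obs - mu) - 0.5, 0) / sigma,
    greater   = (u_obs - mu - 0.5) / sigma,
    less      = -(u_obs - mu + 0.5) / sigma
  )
  p <- if (alternative == "two.sided") 2 * stats::pnorm(-z) else stats::pnorm(-z)
  min(p, 1)
}

#' One-tailed binomial sign test
#'
#' Exact upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`. Used
#' to test whether, say, 9 of 10 compartment-level correlations sharing a
#' sign departs from the 50% expected at random.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability, in (0, 1). Default 0.5.
#' @return The exact tail p-value (bare numeric, vectorized over `k`).
#' @export
#' @examples
#' binomial_one_tailed(9, 10)  # 0.0107..., prints as 0.011
#' binomial_one_tailed(8, 10)  # 0.0547..., prints as 0.055
binomial_one_tailed <- function(k, n, p0 = 0.5) {
  if (any(p0 <= 0) || any(p0 >= 1)) abort("`p0` must lie strictly in (0, 1).")
  if (any(k < 0) || any(k > n)) abort("`k` must satisfy 0 <= k <= n.")
  pbinom(k - 1, size = n, prob = p0, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: on ascending-sorted p-values,
#' `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1 and mapped back to the
#' input order. Thin validated wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (anyNA(p)) abort("Missing p-values are not allowed.")
  if (any(p < 0) || any(p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

check_paired <- function(x, y, min_n) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) {
    abort("Input vectors must have equal length.")
  }
  if (length(x) < min_n) {
    abort(sprintf("At least %d paired observations are required.", min_n))
  }
  if (anyNA(x) || anyNA(y)) abort("Missing values are not allowed.")
  invisible(TRUE)
}
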