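#' Two-sample Student's t-test
#'
#' Two-tailed pooled-variance t-test (default) or Welch's t-test. Thin,
#' degenerate-safe wrapper around [stats::t.test()]: when both groups have
#' zero variance the statistic is undefined and the result is flagged
#' degenerate (equal means, p `NA`) or reported as the p = 0 limit (unequal
#' means) instead of raising an error.
#'
#' @param a,b Numeric vectors, each of length at least 2.
#' @param welch Use the Welch-Satterthwaite unequal-variance form.
#' @return An object of class `test_result`: list with `method`,
#'   `statistic` (t), `df`, `p_two_sided`, `n_a`, `n_b`, `degenerate`.
#' @examples
#' students_t(c(1, 2, 3), c(2, 3, 4))
#' @export
students_t <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 2, length(b) >= 2, !anyNA(a), !anyNA(b))
  method <- if (welch) "welch_t" else "students_t"
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(test_result(method, NA_real_,
                         df = length(a) + length(b) - 2, p = NA_real_,
                         n_a = length(a), n_b = length(b), degenerate = TRUE))
    }
    return(test_result(method, sign(mean(a) - mean(b)) * Inf,
                       df = length(a) + length(b) - 2, p = 0,
                       n_a = length(a), n_b = length(b), degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  test_result(method, unname(ht$statistic), df = unname(ht$parameter),
              p = ht$p.value, n_a = length(a), n_b = length(b),
              degenerate = FALSE)
}

#' Exact and approximate Mann-Whitney U test
#'
#' The U statistic is computed from midranks (`U = R_a - n_a (n_a + 1) / 2`,
#' with `R_a` the rank sum of the first group). In exact mode the null
#' distribution is built by enumerating all `choose(n_a + n_b, n_a)`
#' assignments of the observed pooled values to the two groups — ties are
#' thereby handled by enumeration over the actual values — and the two-sided
#' p-value is the null probability of a deviation `|U - n_a n_b / 2|` at
#' least as extreme as observed. The approximate mode uses the normal
#' approximation with tie-corrected variance and continuity correction.
#' Exact is the default up to a combined sample size of 20.
#'
#' @param a,b Numeric vectors, non-empty.
#' @param mode `"auto"` (exact when `n_a + n_b <= 20`), `"exact"`, or
#'   `"normal_approx"`.
#' @return A `test_result` with `statistic` = U (first group), `p_two_sided`,
#'   `n_a`, `n_b`, and `tie_note` = `TRUE` when the pooled values contain ties.
#' @examples
#' # complete separation at n = 5 vs 5: the exact two-sided minimum, 2/252
#' mann_whitney(1:5, 6:10)$p_two_sided
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  stopifnot(!anyNA(a), !anyNA(b))
  n_a <- length(a); n_b <- length(b); N <- n_a + n_b
  if (mode == "auto") mode <- if (N <= 20) "exact" else "normal_approx"
  r <- rank(c(a, b))  # midranks
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (mode == "exact") {
    if (N > 22)
      stop("exact enumeration limited to combined n <= 22; use normal_approx",
           call. = FALSE)
    idx <- utils::combn(N, n_a)
    Ra <- colSums(matrix(r[idx], nrow = n_a))
    U_all <- Ra - n_a * (n_a + 1) / 2
    p <- mean(abs(U_all - mu) >= abs(U - mu) - 1e-9)
    method <- "mann_whitney_exact"
  } else {
    tab <- table(r)
    sigma2 <- n_a * n_b / 12 * ((N + 1) - sum(tab^3 - tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all values tied: U is constant under the null
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "mann_whitney_normal"
  }
  out <- test_result(method, U, df = NA_real_, p = p,
                     n_a = n_a, n_b = n_b, degenerate = FALSE)
  out$tie_note <- ties
  out
}

#' Holm step-down multiple-testing adjustment
#'
#' Validating front end to [stats::p.adjust()] with `method = "holm"`
#' (step-down with monotonicity enforcement, capped at 1). `NA` entries are
#' propagated and do not count towards the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values, same length and order.
#' @export
holm_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "holm")
}

test_result <- function(method, statistic, df, p, n_a, n_b, degenerate = FALSE) {
  structure(
    list(method = method, statistic = statistic, df = df, p_two_sided = p,
         n_a = n_a, n_b = n_b, degenerate = degenerate, tie_note = FALSE),
    class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: stat = %.4g%s, p = %.4g (n = %d vs %d)%s%s\n",
              x$method, x$statistic,
              if (!is.na(x$df)) sprintf(", df = %.3g", x$df) else "",
              x$p_two_sided, x$n_a, x$n_b,
              if (x$degenerate) ", DEGENERATE" else "",
              if (x$tie_note) ", ties" else ""))
  invisible(x)
}
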