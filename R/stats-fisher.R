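# Exact combinatorial statistics used by every enrichment stage.
#
# The Fisher machinery is implemented from the hypergeometric definition
# in log-space (log-gamma factorials, probabilities exponentiated at the
# end) so that every enrichment p-value in the package comes from one
# audited kernel rather than from scattered library calls.

validate_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!vapply(cells, is_count, logical(1)))) {
    stop("contingency table cells must be single non-negative integers",
         call. = FALSE)
  }
  if (sum(cells) < 1) {
    stop("all-zero contingency table: the test is undefined", call. = FALSE)
  }
  as.integer(cells)
}

#' Hypergeometric point probability
#'
#' Probability of observing `a` focal-by-focal counts in a 2x2 table with
#' fixed margins `row1`, `col1` and total `N`, i.e. the hypergeometric
#' pmf. Computed in log-space via `lchoose` for numerical stability.
#'
#' @param a observed count(s); may be a vector over the support.
#' @param row1 first row margin.
#' @param col1 first column margin.
#' @param N table total.
#' @return numeric vector of probabilities, same length as `a`.
#' @examples
#' hypergeom_pmf(3, 3, 3, 6)  # 1/20
#' @export
hypergeom_pmf <- function(a, row1, col1, N) {
  if (!is_count(row1) || !is_count(col1) || !is_count(N)) {
    stop("margins must be single non-negative integers", call. = FALSE)
  }
  if (row1 > N || col1 > N) {
    stop("inconsistent margins: row1 and col1 cannot exceed N", call. = FALSE)
  }
  lo <- max(0, row1 + col1 - N)
  hi <- min(row1, col1)
  if (any(!is.numeric(a)) || any(is.na(a)) || any(a != floor(a))) {
    stop("`a` must be integer-valued", call. = FALSE)
  }
  if (any(a < lo) || any(a > hi)) {
    stop("`a` outside the hypergeometric support [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  exp(lchoose(col1, a) + lchoose(N - col1, row1 - a) - lchoose(N, row1))
}

# p-value core on a validated table; returns list(p, or, direction)
fisher_core <- function(a, b, c, d, rel_tol = 1e-7) {
  N <- a + b + c + d
  row1 <- a + b
  col1 <- a + c
  lo <- max(0L, row1 + col1 - N)
  hi <- min(row1, col1)
  support <- lo:hi
  logpmf <- lchoose(col1, support) + lchoose(N - col1, row1 - support) -
    lchoose(N, row1)
  pmf <- exp(logpmf)
  obs <- pmf[a - lo + 1L]
  p <- min(1, sum(pmf[pmf <= obs * (1 + rel_tol)]))

  ad <- as.numeric(a) * d
  bc <- as.numeric(b) * c
  if (ad > 0 && bc > 0) {
    or <- ad / bc
  } else if (ad > 0) {
    or <- Inf
  } else if (bc > 0) {
    or <- 0
  } else {
    or <- NA_real_
  }
  direction <- if (is.na(or) || or == 1) "none" else
    if (or > 1) "enriched" else "depleted"
  list(p = p, odds_ratio = or, direction = direction)
}

#' Two-sided Fisher exact test for 2x2 tables
#'
#' Exact two-sided test by pmf comparison: the p-value is the sum of the
#' hypergeometric pmf over all tables with the observed margins whose
#' probability does not exceed the observed table's probability times
#' `1 + 1e-7` (the relative tolerance absorbs floating-point ties).
#'
#' The unconditional odds ratio `(a*d)/(b*c)` is reported with zero-cell
#' conventions: `Inf` if only `b*c` is zero (direction `"enriched"`),
#' `0` if only `a*d` is zero (`"depleted"`), `NA` with direction
#' `"none"` if both vanish. No continuity/Haldane correction is applied.
#'
#' @param a,b,c,d cell counts (`a` = focal-by-focal; rows index membership
#'   of set 1, columns membership of set 2). Vectors are recycled to a
#'   common length and tested row-wise.
#' @return a tibble with columns `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p_two_sided`, `direction`.
#' @examples
#' fisher_exact(3, 0, 0, 3)   # p = 0.1
#' fisher_exact(8, 12, 2, 78) # odds ratio 26
#' @export
fisher_exact <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  res <- purrr::pmap(list(a, b, c, d), function(a, b, c, d) {
    cl <- validate_table(a, b, c, d)
    fisher_core(cl[[1]], cl[[2]], cl[[3]], cl[[4]])
  })
  tibble(
    a = as.integer(a), b = as.integer(b),
    c = as.integer(c), d = as.integer(d),
    odds_ratio = purrr::map_dbl(res, "odds_ratio"),
    p_two_sided = purrr::map_dbl(res, "p"),
    direction = purrr::map_chr(res, "direction")
  )
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR adjustment: with order statistics `p_(1) <= ... <= p_(n)`,
#' `q_(i) = min_{j >= i} p_(j) * n / j`, capped at 1, returned in the
#' input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values aligned with `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.5))
#' @export
bh_fdr <- function(p) {
  if (!length(p)) stop("`p` must be non-empty", call. = FALSE)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}
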