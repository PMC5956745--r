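#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The statistic `W` is the Mann-Whitney count of pairs `(x_i, y_j)` with
#' `x_i > y_j`, counting one half per tie. The two-sided p-value comes
#' from the exact null permutation distribution when the samples are
#' tie-free and `n_x * n_y <= max_exact`; otherwise from the mid-rank
#' normal approximation with tie-corrected variance and continuity
#' correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param max_exact Largest `n_x * n_y` for which the exact null is used.
#' @return One-row tibble: `statistic` (W), `p_value`, `method`, `n_x`,
#'   `n_y`.
#' @export
wilcoxon_rank_sum <- function(x, y, max_exact = 10000) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) abort("Both samples must be non-empty.")
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))  # mid-ranks
  w <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2  # = #{x_i > y_j} + ties/2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && nx * ny <= max_exact) {
    # exact two-sided p from the null distribution of the Mann-Whitney count
    p_lo <- stats::pwilcox(w, nx, ny)
    p_hi <- 1 - stats::pwilcox(w - 1, nx, ny)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    n <- nx + ny
    tie_tab <- table(r)
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                                (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  tibble::tibble(statistic = w, p_value = p, method = method,
                 n_x = nx, n_y = ny)
}
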