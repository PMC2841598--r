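# Bivariate Granger causality via nested OLS autoregressions.
#
# Conventions (standard for the bivariate F-test): an intercept is included
# in both models; the usable window at lag p is the T - p rows t = p+1..T
# (no presample padding); the unrestricted model has 2p + 1 parameters, the
# restricted p + 1, so the error degrees of freedom are (T - p) - (2p + 1).

# Design matrix of lagged values: rows t = (p+1)..T, columns lag 1..p.
.lag_design <- function(x, p) {
  T <- length(x)
  emb <- stats::embed(x, p + 1L)      # col 1 = x_t, col j+1 = x_{t-j}
  list(y = emb[, 1L], lags = emb[, -1L, drop = FALSE])
}

# Least-squares fit through a QR decomposition; tolerates rank deficiency
# (degenerate flag, residuals are still the projection residuals).
.ols <- function(X, y) {
  qr_x <- qr(X)
  coef <- qr.coef(qr_x, y)
  res <- qr.resid(qr_x, y)
  list(coef = coef, residuals = res, rss = sum(res^2),
       rank = qr_x$rank, degenerate = qr_x$rank < ncol(X))
}

#' Fit the restricted autoregression
#'
#' OLS fit of `x_t` on an intercept and its own `p` lags over the
#' `length(x) - p` usable rows. Its residual sum of squares is the
#' `RSS_0` of the Granger F-test.
#'
#' @param x Numeric series.
#' @param p Lag order (>= 1); requires `length(x) >= 2p + 2`.
#' @return An `ar_fit` list: `kind`, `p`, `coef` (intercept, own lags),
#'   `residuals`, `rss`, `n_obs`, `degenerate`.
#' @export
fit_restricted <- function(x, p) {
  p <- as.integer(p)
  stopifnot(p >= 1L, is.numeric(x))
  if (length(x) < 2L * p + 2L) stop("series too short for lag order ", p)
  d <- .lag_design(x, p)
  X <- cbind(intercept = 1, d$lags)
  colnames(X) <- c("intercept", paste0("own_lag", seq_len(p)))
  f <- .ols(X, d$y)
  structure(c(list(kind = "restricted", p = p, n_obs = length(d$y)), f),
            class = "ar_fit")
}

#' Fit the unrestricted autoregression
#'
#' OLS fit of `x_t` on an intercept, `p` own lags, and `p` lags of the
#' putative cause `y`. Its residual sum of squares is the `RSS_1` of the
#' Granger F-test; by model nesting `RSS_1 <= RSS_0` up to floating-point
#' tolerance.
#'
#' @param x Response series.
#' @param y Candidate causal series (same length as `x`).
#' @param p Lag order (>= 1); requires `length(x) >= 2p + 2`.
#' @return An `ar_fit` list as in [fit_restricted()], with the `y` lag
#'   weights appended to `coef`.
#' @export
fit_unrestricted <- function(x, y, p) {
  p <- as.integer(p)
  stopifnot(p >= 1L, is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L * p + 2L) stop("series too short for lag order ", p)
  dx <- .lag_design(x, p)
  dy <- .lag_design(y, p)
  X <- cbind(1, dx$lags, dy$lags)
  colnames(X) <- c("intercept", paste0("own_lag", seq_len(p)),
                   paste0("cross_lag", seq_len(p)))
  f <- .ols(X, dx$y)
  structure(c(list(kind = "unrestricted", p = p, n_obs = length(dx$y)), f),
            class = "ar_fit")
}

#' @export
print.ar_fit <- function(x, ...) {
  cat(sprintf("%s AR fit, p = %d, n = %d, RSS = %.6g%s\n", x$kind, x$p,
              x$n_obs, x$rss, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Granger F statistic from nested residual sums of squares
#'
#' \deqn{S = \frac{(RSS_0 - RSS_1)/p}{RSS_1/(n - 2p - 1)}}
#' compared against the F(p, n - 2p - 1) upper tail. A tiny negative
#' improvement (floating-point noise on nested fits) is clamped to 0.
#' `rss1 = 0` (perfect unrestricted fit) yields `S = Inf`, p-value 0, and
#' a degeneracy warning.
#'
#' @param rss0 Restricted residual sum of squares.
#' @param rss1 Unrestricted residual sum of squares.
#' @param p Lag order tested (numerator degrees of freedom).
#' @param n_obs Rows used in the fits; must exceed `2p + 1`.
#' @return List with `statistic`, `df1`, `df2`, `p_value`.
#' @export
granger_statistic <- function(rss0, rss1, p, n_obs) {
  p <- as.integer(p); n_obs <- as.integer(n_obs)
  stopifnot(p >= 1L, rss0 >= 0, rss1 >= 0)
  df1 <- p
  df2 <- n_obs - 2L * p - 1L
  if (df2 < 1L) stop("n_obs too small: no residual degrees of freedom")
  if (rss1 <= 0) {
    warning("perfect unrestricted fit (RSS_1 = 0); statistic is infinite")
    return(list(statistic = Inf, df1 = df1, df2 = df2, p_value = 0))
  }
  num <- rss0 - rss1
  if (num < 0) {
    if (num < -1e-10 * max(rss0, 1)) {
      warning("RSS_0 < RSS_1 beyond tolerance; clamping statistic to 0")
    }
    num <- 0
  }
  S <- (num / df1) / (rss1 / df2)
  list(statistic = S, df1 = df1, df2 = df2,
       p_value = stats::pf(S, df1, df2, lower.tail = FALSE))
}

#' Default maximum lag order
#'
#' `min(4, floor((T - 2) / 4))`, floored at 1, so that even short
#' time courses (e.g. 21 differenced points) remain testable with at least
#' one residual degree of freedom at the largest candidate lag.
#'
#' @param T Series length.
#' @return Integer lag bound >= 1.
#' @export
default_p_max <- function(T) {
  max(1L, min(4L, as.integer(floor((T - 2) / 4))))
}

#' Select the lag order by AIC
#'
#' For each candidate order `p = 1..p_max`, fits the bivariate order-`p`
#' vector autoregression of `(x, y)` by OLS over a common estimation
#' window (the rows usable at `p_max`, so scores are comparable across
#' `p`), estimates the 2x2 residual covariance `sigma`, and scores
#' \deqn{AIC(p) = \ln\det\hat\sigma + 2 m^2 p / n}
#' with process dimension `m = 2` and window length `n`. The minimising
#' `p` is returned; ties go to the smallest `p` (parsimony).
#'
#' @param x,y Numeric series of equal length `>= 2 p_max + 2`.
#' @param p_max Largest candidate order (>= 1).
#' @return An `aic_record` list: `p`, `aic`, `sigma` (2x2), `m`, `n`,
#'   and the full `aic_values` grid (NA where a candidate was skipped).
#' @export
select_lag_aic <- function(x, y, p_max = default_p_max(length(x))) {
  p_max <- as.integer(p_max)
  stopifnot(p_max >= 1L, length(x) == length(y))
  T <- length(x)
  if (T < 2L * p_max + 2L) stop("series too short for p_max = ", p_max)
  n <- T - p_max
  rows <- (p_max + 1L):T
  Y <- cbind(x[rows], y[rows])
  xl <- sapply(seq_len(p_max), function(l) x[rows - l])
  yl <- sapply(seq_len(p_max), function(l) y[rows - l])
  xl <- matrix(xl, nrow = n); yl <- matrix(yl, nrow = n)
  m <- 2L
  aic <- rep(NA_real_, p_max)
  sigmas <- vector("list", p_max)
  for (p in seq_len(p_max)) {
    X <- cbind(1, xl[, seq_len(p), drop = FALSE], yl[, seq_len(p), drop = FALSE])
    E <- qr.resid(qr(X), Y)
    sig <- crossprod(E) / n
    d <- det(sig)
    if (!is.finite(d) || d <= 0) {
      warning("singular residual covariance at p = ", p, "; candidate skipped")
      next
    }
    sigmas[[p]] <- sig
    aic[p] <- log(d) + 2 * m^2 * p / n
  }
  if (all(is.na(aic))) stop("degenerate pair: no lag order admissible")
  best <- which.min(aic)   # which.min takes the first (smallest p) on ties
  structure(list(p = best, aic = aic[best], sigma = sigmas[[best]],
                 m = m, n = n, aic_values = aic),
            class = "aic_record")
}

#' Test whether `y` Granger-causes `x`
#'
#' Composes lag selection (AIC, unless a fixed `p` is given), the
#' restricted and unrestricted OLS fits, and the F-test of the exclusion
#' hypothesis "the lags of `y` contribute nothing to predicting `x`".
#' Series should already be stationary (e.g. first-differenced) — the
#' test itself runs no stationarity check. Degenerate fits (constant or
#' collinear series) never raise: they yield a no-edge result with a
#' recorded reason, which is what an all-pairs scan needs.
#'
#' @param x Response series.
#' @param y Candidate causal series.
#' @param alpha Significance level of the F-test, default 0.05.
#' @param p `"auto"` (AIC selection) or a fixed integer lag order.
#' @param p_max Lag-selection bound when `p = "auto"`.
#' @return A `granger_result` list: `statistic`, `p` (lag used), `df1`,
#'   `df2`, `p_value`, `alpha`, `reject`, `reason` (NULL unless
#'   degenerate).
#' @export
granger_test <- function(x, y, alpha = 0.05, p = "auto",
                         p_max = default_p_max(length(x))) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  no_edge <- function(reason, lag = NA_integer_) {
    structure(list(statistic = 0, p = lag, df1 = NA_integer_,
                   df2 = NA_integer_, p_value = 1, alpha = alpha,
                   reject = FALSE, reason = reason),
              class = "granger_result")
  }
  res <- tryCatch({
    lag <- if (identical(p, "auto")) select_lag_aic(x, y, p_max)$p
           else as.integer(p)
    fr <- fit_restricted(x, lag)
    fu <- fit_unrestricted(x, y, lag)
    if (fu$rss <= 0 && fr$rss <= 0) {
      return(no_edge("perfect fit in both models", lag))
    }
    st <- suppressWarnings(granger_statistic(fr$rss, fu$rss, lag, fu$n_obs))
    structure(list(statistic = st$statistic, p = lag, df1 = st$df1,
                   df2 = st$df2, p_value = st$p_value, alpha = alpha,
                   reject = st$p_value < alpha, reason = NULL),
              class = "granger_result")
  }, error = function(e) no_edge(conditionMessage(e)))
  res
}

#' @export
print.granger_result <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat(sprintf("Granger test: degenerate (%s)\n", x$reason))
  } else {
    cat(sprintf("Granger test: S = %.4g, F(%d, %d), p-value = %.4g, %s at alpha = %g\n",
                x$statistic, x$df1, x$df2, x$p_value,
                if (x$reject) "REJECT H0 (causal)" else "no evidence", x$alpha))
  }
  invisible(x)
}

#' All-pairs Granger causality scan
#'
#' Runs [granger_test()] for every ordered gene pair — `n (n - 1)`
#' directed tests for `n` genes — and records the F statistic of each
#' rejected direction. Entry `(i, j)` is the statistic for the direction
#' `j -> i` (row j predicts row i) if that test rejects at `alpha`, else
#' 0; the diagonal is 0. Degenerate pairs score 0 and are listed in the
#' `"degenerate"` attribute.
#'
#' @param m Numeric expression matrix, genes in rows (already
#'   preprocessed: the scan applies no differencing).
#' @param alpha Significance level, default 0.05.
#' @param p `"auto"` or a fixed lag order.
#' @param p_max Lag-selection bound.
#' @param share_lag If TRUE, the AIC lag is selected once per unordered
#'   pair and reused for both directions; default FALSE (per-direction
#'   selection).
#' @return A `directed_strength` matrix (n x n) with attributes `alpha`,
#'   `p_max`, `n_tests` (count of directed tests performed), and
#'   `degenerate` (data frame of skipped pairs, possibly empty).
#' @export
pairwise_causality <- function(m, alpha = 0.05, p = "auto",
                               p_max = default_p_max(ncol(m)),
                               share_lag = FALSE) {
  m <- .check_expr(m)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 genes")
  ids <- rownames(m)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  n_tests <- 0L
  degen <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      lag <- p
      if (share_lag && identical(p, "auto")) {
        a <- min(i, j); b <- max(i, j)
        lag <- tryCatch(select_lag_aic(m[a, ], m[b, ], p_max)$p,
                        error = function(e) "auto")
      }
      r <- granger_test(m[i, ], m[j, ], alpha = alpha, p = lag, p_max = p_max)
      n_tests <- n_tests + 1L
      if (!is.null(r$reason)) {
        degen[[length(degen) + 1L]] <-
          data.frame(target = ids[i], source = ids[j], reason = r$reason)
      } else if (r$reject) {
        S[i, j] <- r$statistic
      }
    }
  }
  attr(S, "alpha") <- alpha
  attr(S, "p_max") <- p_max
  attr(S, "n_tests") <- n_tests
  attr(S, "degenerate") <-
    if (length(degen)) do.call(rbind, degen)
    else data.frame(target = character(), source = character(),
                    reason = character())
  class(S) <- c("directed_strength", class(S))
  S
}

#' @export
print.directed_strength <- function(x, ...) {
  cat(sprintf("Directed causality strengths: %d genes, %d tests, %d rejected directions (alpha = %g)\n",
              nrow(x), attr(x, "n_tests"), sum(x > 0), attr(x, "alpha")))
  invisible(x)
}
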