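#' First-difference an expression matrix
#'
#' Replaces each gene's profile by successive differences
#' (value at t+1 minus value at t), the standard device for removing
#' slow trends and approximating stationarity before autoregressive
#' testing. The output keeps the later time label of each difference.
#'
#' @param m Numeric matrix, genes in rows, ordered time points in columns
#'   (>= 2 columns).
#' @return Matrix with one fewer column.
#' @export
first_difference <- function(m) {
  m <- .check_expr(m)
  if (ncol(m) < 2) stop("first_difference needs at least 2 time points")
  out <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  out
}

#' Filter flat expression profiles
#'
#' Removes genes whose temporal fluctuation is negligible relative to the
#' dataset. A gene is dropped iff its temporal range (max - min) is below
#' `k` times a reference scale `sigma_ref`, the median of per-gene
#' temporal standard deviations. With the default `k = 2` this is a
#' scale-free "2-sigma" flat-profile filter. If `sigma_ref` is 0 (every
#' profile constant) nothing is removed and a warning is issued.
#'
#' @param m Numeric expression matrix (genes x time, >= 2 columns).
#' @param k Non-negative multiplier on the reference sigma. Default 2.
#' @return List with `matrix` (surviving genes, input row order preserved)
#'   and `removed` (character vector of dropped gene ids).
#' @export
filter_flat <- function(m, k = 2.0) {
  m <- .check_expr(m)
  if (ncol(m) < 2) stop("filter_flat needs at least 2 time points")
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  sds <- apply(m, 1, stats::sd)
  sigma_ref <- stats::median(sds)
  if (sigma_ref == 0) {
    warning("reference sigma is 0 (all profiles flat); nothing removed")
    return(list(matrix = m, removed = character()))
  }
  ranges <- apply(m, 1, function(r) max(r) - min(r))
  drop <- ranges < k * sigma_ref
  if (all(drop)) warning("all genes filtered as flat; returning empty matrix")
  list(matrix = m[!drop, , drop = FALSE], removed = rownames(m)[drop])
}

#' Rank genes by spectral power and keep the strongest
#'
#' Scores each gene by the sum of squared discrete-Fourier-transform
#' magnitudes over the nonzero frequencies (the DC bin is excluded, so a
#' constant offset contributes nothing) and returns the `top_n` genes by
#' descending score, ties broken by input order. Used to pre-select the
#' most dynamically active genes from a large array before all-pairs
#' causality testing.
#'
#' @param m Numeric expression matrix (genes x time).
#' @param top_n How many genes to keep (1 <= top_n <= nrow(m)).
#' @return The selected submatrix, rows ordered by descending score; the
#'   scores are attached as attribute `"spectral_power"`.
#' @export
rank_by_spectral_power <- function(m, top_n) {
  m <- .check_expr(m)
  top_n <- as.integer(top_n)
  if (top_n < 1L) stop("top_n must be positive")
  if (top_n > nrow(m)) stop("top_n exceeds the number of genes")
  scores <- apply(m, 1, function(r) {
    mag2 <- Mod(stats::fft(r))^2
    sum(mag2[-1])      # both half-spectra of the real DFT, DC excluded
  })
  ord <- order(-scores, seq_along(scores))[seq_len(top_n)]
  out <- m[ord, , drop = FALSE]
  attr(out, "spectral_power") <- scores[ord]
  out
}

# Shared input validation: numeric matrix, finite, unique non-empty rownames.
.check_expr <- function(m) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expression input must be a numeric matrix (genes x time points)")
  }
  if (any(!is.finite(m))) stop("expression matrix contains non-finite values")
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  blank <- is.na(rownames(m)) | rownames(m) == ""
  rownames(m)[blank] <- paste0("g", which(blank))
  if (anyDuplicated(rownames(m))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  m
}
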