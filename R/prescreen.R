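#' Prescreen highly correlated predictors
#'
#' Greedy single pass over the columns in their listed order: a column is
#' dropped when its absolute Pearson correlation with an already-retained
#' column exceeds `threshold`, so of any highly correlated pair the
#' earlier-listed column is kept as the representative. Typical use is to thin
#' a biomarker panel before model fitting (e.g. at a 0.7 threshold).
#'
#' @param x Numeric matrix or data frame of candidate predictors (at least 2
#'   columns, each with nonzero variance).
#' @param threshold Absolute-correlation cutoff in (0, 1); default 0.7.
#' @return A list with `retained` (column indices), `retained_names`, and
#'   `dropped`, a tibble of (kept, dropped, r) triples recording, for each
#'   dropped column, the retained column that triggered the drop and their
#'   sample correlation.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3)
#' x <- cbind(x, x[, 1] + rnorm(100, sd = 0.01))
#' prescreen_correlated(x)
#' @export
prescreen_correlated <- function(x, threshold = 0.7) {
  x <- as.matrix(x)
  if (!is.numeric(x) || ncol(x) < 2) {
    abort("`x` must be a numeric matrix with at least 2 columns.")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0 ||
      threshold >= 1) {
    abort("`threshold` must lie in (0, 1).")
  }
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(x)))
  vars <- apply(x, 2, stats::var)
  if (any(vars == 0)) {
    abort(sprintf("Column `%s` has zero variance.", nm[which(vars == 0)[1]]))
  }
  cm <- stats::cor(x)
  retained <- integer(0)
  kept_of <- integer(0)
  r_of <- numeric(0)
  dropped <- integer(0)
  for (j in seq_len(ncol(x))) {
    hit <- retained[abs(cm[retained, j]) > threshold]
    if (length(hit) > 0) {
      dropped <- c(dropped, j)
      kept_of <- c(kept_of, hit[1])
      r_of <- c(r_of, cm[hit[1], j])
    } else {
      retained <- c(retained, j)
    }
  }
  list(
    retained = retained,
    retained_names = nm[retained],
    dropped = tibble::tibble(kept = nm[kept_of], dropped = nm[dropped],
                             r = r_of)
  )
}
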