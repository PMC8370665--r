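#' Gray-level histogram
#'
#' @param img gray matrix with integer values in `[0, levels - 1]`.
#' @param levels number of gray levels L.
#' @return object of class `gray_histogram`: list with integer `counts`
#'   (length L), `total`, `levels`, and normalized probabilities `p`
#'   (summing to 1).
#' @export
gray_histogram <- function(img, levels = 256L) {
  counts <- tabulate(as.integer(img) + 1L, nbins = levels)
  structure(list(counts = counts, total = sum(counts), levels = levels,
                 p = counts / sum(counts)), class = "gray_histogram")
}

#' Otsu threshold with full between/within-class bookkeeping
#'
#' Scans every candidate threshold `t` (class 1 = levels `0..t`, class 2 =
#' levels `t+1..L-1` on the intensity scale), computing class weights, class
#' means, class variances, the weighted within-class variance and the
#' between-class variance, and returns the `t` maximizing the between-class
#' variance (ties broken toward the smallest `t`). The decomposition
#' `within + between = total variance` holds at every candidate threshold.
#'
#' @param hist a [gray_histogram()] (or a gray matrix, converted with 256
#'   levels).
#' @return object of class `otsu_stats`: list with `threshold` (intensity
#'   value; foreground/bright class is `> threshold`), `t_index` (1-based bin
#'   index), `w1`, `w2`, `m1`, `m2`, `var1`, `var2`, `wcv`, `bcv`,
#'   `total_var`, `global_mean`, and the full `bcv_curve`/`wcv_curve` over
#'   candidate thresholds.
#' @export
otsu_threshold <- function(hist) {
  if (is.matrix(hist)) hist <- gray_histogram(hist)
  stopifnot(inherits(hist, "gray_histogram"))
  L <- hist$levels
  p <- hist$p
  if (sum(p > 0) < 2) stop("histogram must have at least two nonzero bins")
  v <- 0:(L - 1)                       # intensity value of each bin
  m_T <- sum(v * p)
  total_var <- sum((v - m_T)^2 * p)

  w1 <- cumsum(p)[1:(L - 1)]
  w2 <- 1 - w1
  s1 <- cumsum(v * p)[1:(L - 1)]
  m1 <- ifelse(w1 > 0, s1 / w1, 0)
  m2 <- ifelse(w2 > 0, (m_T - s1) / w2, 0)
  q1 <- cumsum(v^2 * p)[1:(L - 1)]
  var1 <- ifelse(w1 > 0, q1 / w1 - m1^2, 0)
  var2 <- ifelse(w2 > 0, (sum(v^2 * p) - q1) / w2 - m2^2, 0)
  wcv <- w1 * var1 + w2 * var2
  bcv <- w1 * (m1 - m_T)^2 + w2 * (m2 - m_T)^2

  valid <- w1 > 0 & w2 > 0
  bcv_search <- ifelse(valid, bcv, -Inf)
  t_idx <- which.max(bcv_search)       # smallest index on ties
  structure(list(
    threshold = v[t_idx], t_index = t_idx,
    w1 = w1[t_idx], w2 = w2[t_idx],
    m1 = m1[t_idx], m2 = m2[t_idx],
    var1 = var1[t_idx], var2 = var2[t_idx],
    wcv = wcv[t_idx], bcv = bcv[t_idx],
    total_var = total_var, global_mean = m_T,
    bcv_curve = bcv, wcv_curve = wcv, valid = valid
  ), class = "otsu_stats")
}
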