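#' Two-channel image pair for colocalization analysis
#'
#' @param channel_r,channel_g equal-shape non-negative intensity matrices
#'   (conventionally the "red" and second channel).
#' @param mask optional logical matrix restricting the analysis region;
#'   default full frame.
#' @param t_r,t_g intensity thresholds used by the Manders coefficients;
#'   default is Otsu's threshold computed per channel.
#' @return object of class `channel_pair`.
#' @export
channel_pair <- function(channel_r, channel_g, mask = NULL,
                         t_r = NULL, t_g = NULL) {
  stopifnot(is.matrix(channel_r), is.matrix(channel_g))
  if (!all(dim(channel_r) == dim(channel_g))) {
    stop("channel shapes differ", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(channel_r), ncol(channel_r))
  stopifnot(all(dim(mask) == dim(channel_r)))
  if (is.null(t_r)) t_r <- otsu_threshold(channel_r)
  if (is.null(t_g)) t_g <- otsu_threshold(channel_g)
  if (t_r < 0 || t_g < 0) stop("thresholds must be >= 0", call. = FALSE)
  structure(list(channel_r = channel_r, channel_g = channel_g, mask = mask,
                 t_r = t_r, t_g = t_g),
            class = "channel_pair")
}

masked_values <- function(pair) {
  list(r = pair$channel_r[pair$mask], g = pair$channel_g[pair$mask])
}

#' Pearson's correlation coefficient between two channels
#'
#' Standard product-moment correlation over masked pixels; range -1 to 1.
#' A constant channel makes the statistic undefined and raises an error.
#'
#' @param pair a [channel_pair()].
#' @return PCC in `[-1, 1]`.
#' @export
pearson_cc <- function(pair) {
  v <- masked_values(pair)
  if (length(v$r) < 2) stop("need at least 2 masked pixels", call. = FALSE)
  if (sd(v$r) == 0 || sd(v$g) == 0) {
    stop("PCC undefined: a channel is constant over the mask", call. = FALSE)
  }
  cor(v$r, v$g)
}

#' Manders overlap coefficients
#'
#' `M1` is the proportion of channel-r intensity on pixels where channel g
#' exceeds its threshold; `M2` is the symmetric quantity for channel g over
#' the channel-r threshold. Both lie in `[0, 1]`.
#'
#' @param pair a [channel_pair()].
#' @return named numeric vector `c(M1, M2)`.
#' @export
manders <- function(pair) {
  v <- masked_values(pair)
  if (sum(v$r) <= 0 || sum(v$g) <= 0) {
    stop("Manders coefficients undefined: a channel sums to zero", call. = FALSE)
  }
  c(M1 = sum(v$r[v$g > pair$t_g]) / sum(v$r),
    M2 = sum(v$g[v$r > pair$t_r]) / sum(v$g))
}

#' Intensity correlation quotient
#'
#' For each masked pixel the product of the two channels' deviations from
#' their means is computed; the ICQ is the fraction of nonzero products
#' that are positive, minus 0.5. Range -0.5 (segregation) to 0.5
#' (colocalization). Zero products are excluded from both numerator and
#' denominator, making the limit cases exact.
#'
#' @param pair a [channel_pair()].
#' @return ICQ in `[-0.5, 0.5]`.
#' @export
icq <- function(pair) {
  v <- masked_values(pair)
  if (sd(v$r) == 0 || sd(v$g) == 0) {
    stop("ICQ undefined: a channel is constant over the mask", call. = FALSE)
  }
  prod_ <- (v$r - mean(v$r)) * (v$g - mean(v$g))
  nz <- prod_[prod_ != 0]
  if (!length(nz)) stop("ICQ undefined: all deviation products are zero",
                        call. = FALSE)
  mean(nz > 0) - 0.5
}

#' All four colocalization statistics at once
#'
#' @param pair a [channel_pair()].
#' @return object of class `coloc_result`: list with `M1`, `M2`, `PCC`,
#'   `ICQ`, `n_pixels`.
#' @export
coloc_stats <- function(pair) {
  m <- manders(pair)
  structure(list(M1 = unname(m["M1"]), M2 = unname(m["M2"]),
                 PCC = pearson_cc(pair), ICQ = icq(pair),
                 n_pixels = sum(pair$mask)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result: M1 %.3f, M2 %.3f, PCC %.3f, ICQ %.3f (%d px)>\n",
              x$M1, x$M2, x$PCC, x$ICQ, x$n_pixels))
  invisible(x)
}
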