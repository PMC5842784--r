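#' Fisher Z transformation of correlation values
#'
#' All aggregation of metabolic correlations in this package happens on the
#' Fisher-Z scale (`atanh(r)`) and is inverse-transformed (`tanh`) only at the
#' reporting boundary. Averaging on the Z scale differs from averaging raw
#' correlations: `tanh((atanh(0) + atanh(0.5)) / 2)` is about 0.268, not 0.25.
#'
#' Values with `|r|` within `1e-12` of 1 are clamped before `atanh` to avoid
#' infinities; the number of clamped entries is attached as attribute
#' `"n_clamped"` when nonzero.
#'
#' @param r numeric vector or matrix of correlations, `|r| <= 1` (up to a
#'   `1e-12` numerical slack).
#' @param z numeric vector or matrix of Fisher-Z values.
#' @return `fisher_z()` returns Z-scale values; `inverse_fisher()` returns
#'   correlations in (-1, 1).
#' @examples
#' fisher_z(0.5)            # 0.5493061
#' inverse_fisher(fisher_z(0.9))
#' @export
fisher_z <- function(r) {
  bad <- !is.na(r) & abs(r) > 1 + 1e-12
  if (any(bad)) {
    stop("correlation values outside [-1, 1]: ",
         paste(utils::head(format(r[bad]), 5L), collapse = ", "))
  }
  clamp <- 1 - 1e-12
  n_clamped <- sum(!is.na(r) & abs(r) >= clamp & abs(r) > 0)
  r <- pmin(pmax(r, -clamp), clamp)
  z <- atanh(r)
  if (n_clamped > 0L) attr(z, "n_clamped") <- n_clamped
  z
}

#' @rdname fisher_z
#' @export
inverse_fisher <- function(z) tanh(z)

# Z-scale mean of a correlation vector, reported back on the correlation
# scale. The workhorse behind every "metabolic correlation strength".
zmean_r <- function(r) {
  tanh(mean(fisher_z(r)))
}
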