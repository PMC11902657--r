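#' Context-aware feature enhancement (CAFE)
#'
#' A non-local self-attention block with a residual connection. The input
#' map is flattened over space; three learnable linear transforms produce
#' query/key/value sets at reduced channel width `C_r`; a row-stochastic
#' affinity matrix (softmax of query-key dot products) aggregates the
#' values; a learnable output projection restores `C` channels before the
#' residual add. The output projection is zero-initialized, so a freshly
#' initialized module is exactly the identity map.
#'
#' @param channels Input channel count `C`.
#' @param reduced Reduced width `C_r` (default `max(1, C/2)`).
#' @param seed Integer seed.
#' @return `cafe_init()` returns the parameter list `w_theta`, `w_phi`,
#'   `w_g` (each `C x C_r`) and the output projection `w_out`
#'   (`C_r x C`, zeros) with bias `b_out`.
#' @export
cafe_init <- function(channels, reduced = max(1L, channels %/% 2L),
                      seed = 1L) {
  stopifnot(reduced >= 1, reduced <= channels)
  sd0 <- 1 / sqrt(channels)
  with_local_seed(seed, list(
    w_theta = matrix(stats::rnorm(channels * reduced, sd = sd0),
                     channels, reduced),
    w_phi = matrix(stats::rnorm(channels * reduced, sd = sd0),
                   channels, reduced),
    w_g = matrix(stats::rnorm(channels * reduced, sd = sd0),
                 channels, reduced),
    w_out = matrix(0, reduced, channels),
    b_out = numeric(channels)
  ))
}

#' @rdname cafe_init
#' @param f Feature map `H x W x C` (array or `ag_tensor`).
#' @param params Parameters from [cafe_init()].
#' @return `qkv_transform()` returns a list of the three projected
#'   position-feature matrices (`N x C_r`, `N = H*W`).
#' @export
qkv_transform <- function(f, params) {
  d <- dim(ag_value(f))
  if (nrow(ag_value(params$w_theta)) != d[3]) {
    stop("projection width does not match the feature map channels")
  }
  m <- ag_reshape(f, c(d[1] * d[2], d[3]))
  list(theta = ag_matmul(m, params$w_theta),
       phi = ag_matmul(m, params$w_phi),
       g = ag_matmul(m, params$w_g))
}

#' @rdname cafe_init
#' @param theta,phi Projected position-feature matrices (`N x C_r`).
#' @return `cafe_affinity()` returns the `N x N` row-stochastic affinity
#'   matrix (row-wise softmax of `theta %*% t(phi)`).
#' @export
cafe_affinity <- function(theta, phi) {
  if (nrow(ag_value(theta)) != nrow(ag_value(phi)) ||
      ncol(ag_value(theta)) != ncol(ag_value(phi))) {
    stop("theta and phi must have matching shapes")
  }
  ag_softmax_rows(ag_matmul(theta, ag_t(phi)))
}

#' @rdname cafe_init
#' @param aff Affinity matrix from [cafe_affinity()].
#' @param g Value matrix (`N x C_r`).
#' @return `cafe_aggregate()` returns the context map `Y` projected back to
#'   `C` channels (`N x C` matrix).
#' @export
cafe_aggregate <- function(aff, g, params) {
  y <- ag_matmul(aff, g)
  ag_add_rowvec(ag_matmul(y, params$w_out), params$b_out)
}

#' @rdname cafe_init
#' @param y Context matrix (`N x C`) from [cafe_aggregate()].
#' @return `residual_enhance()` returns `f + y` reshaped to `H x W x C`.
#' @export
residual_enhance <- function(f, y) {
  d <- dim(ag_value(f))
  if (nrow(ag_value(y)) != d[1] * d[2] || ncol(ag_value(y)) != d[3]) {
    stop("context shape does not match the feature map")
  }
  ag_add(f, ag_reshape(y, d))
}

#' @rdname cafe_init
#' @return `cafe_forward()` returns the enhanced `H x W x C` map.
#' @export
cafe_forward <- function(f, params) {
  qkv <- qkv_transform(f, params)
  aff <- cafe_affinity(qkv$theta, qkv$phi)
  y <- cafe_aggregate(aff, qkv$g, params)
  residual_enhance(f, y)
}
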