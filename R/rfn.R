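#' Recursive feature fusion network (RFN)
#'
#' RFN fuses `M` multi-level backbone feature maps into one map at a
#' reference resolution and then refines it over `T` recurrent iterations.
#' The base fusion operator resizes every level to the reference resolution
#' (bilinear), projects each to a common channel width with a learnable
#' 1x1 transform, and sums. Refinement uses a convolutional gated
#' recurrent (ConvGRU) cell: update gate `z`, reset gate `r`, candidate
#' `h~ = act(conv([x; r*h]))`, and `h' = (1-z)*h + z*h~`.
#'
#' @param width Common channel width after per-level projection.
#' @param ref_level Which level's spatial size is the reference (default 2,
#'   the second-finest, as a compute/accuracy compromise).
#' @param iterations Number of recurrent refinement passes `T` (>= 1).
#' @param activation Candidate activation, `"tanh"` (default) or
#'   `"identity"`.
#' @param gate_override `NULL` for learned gates, `"candidate"` to force
#'   the update gate fully toward the candidate, `"keep"` to force it to
#'   retain the previous state (used for fixed-point checks).
#' @return `rfn_config()` returns a config list.
#' @export
rfn_config <- function(width = 128, ref_level = 2, iterations = 3,
                       activation = c("tanh", "identity"),
                       gate_override = NULL) {
  stopifnot(width >= 1, iterations >= 1)
  if (!is.null(gate_override)) {
    gate_override <- match.arg(gate_override, c("candidate", "keep"))
  }
  list(width = as.integer(width), ref_level = as.integer(ref_level),
       iterations = as.integer(iterations),
       activation = match.arg(activation), gate_override = gate_override)
}

#' @rdname rfn_config
#' @param channels_in Integer vector: channel count of each input level
#'   (length `M`).
#' @param cfg An `rfn_config()`.
#' @param seed Integer seed.
#' @return `rfn_init()` returns the parameter list: per-level projections
#'   `proj_w`/`proj_b` and ConvGRU kernels `gru_wz`, `gru_wr`, `gru_wc`
#'   with biases.
#' @export
rfn_init <- function(channels_in, cfg = rfn_config(), seed = 1L) {
  w <- cfg$width
  with_local_seed(seed, {
    proj <- lapply(channels_in, function(cm) {
      list(w = matrix(stats::rnorm(cm * w, sd = sqrt(2 / cm)), cm, w),
           b = numeric(w))
    })
    gru_kernel <- function() {
      matrix(stats::rnorm(9 * 2 * w * w, sd = sqrt(2 / (9 * 2 * w))),
             9 * 2 * w, w)
    }
    list(M = length(channels_in), proj = proj,
         gru_wz = gru_kernel(), gru_bz = numeric(w),
         gru_wr = gru_kernel(), gru_br = numeric(w),
         gru_wc = gru_kernel(), gru_bc = numeric(w))
  })
}

# Resize-project-sum base fusion R({F_m}) at the reference resolution.
rfn_base_fuse <- function(features, params, cfg) {
  if (length(features) != params$M) {
    stop(sprintf("expected %d feature levels, got %d", params$M,
                 length(features)))
  }
  ref <- dim(ag_value(features[[cfg$ref_level]]))
  fused <- NULL
  for (m in seq_along(features)) {
    fm <- features[[m]]
    dm <- dim(ag_value(fm))
    if (dm[1] != ref[1] || dm[2] != ref[2]) {
      fm <- ag_resize_bilinear(fm, ref[1], ref[2])
    }
    pm <- ag_reshape(
      ag_add_rowvec(
        ag_matmul(ag_reshape(fm, c(ref[1] * ref[2], dm[3])),
                  params$proj[[m]]$w),
        params$proj[[m]]$b),
      c(ref[1], ref[2], cfg$width))
    fused <- if (is.null(fused)) pm else ag_add(fused, pm)
  }
  fused
}

conv_gru_gate <- function(xh, w, b) {
  ag_sigmoid(ag_conv2d(xh, w, b, kh = 3, kw = 3, stride = 1, pad = 1))
}

#' @rdname rfn_config
#' @param features List of `M` feature maps (`H_m x W_m x C_m`), spatial
#'   sizes strictly decreasing with level.
#' @param state `NULL` for the initial pass, otherwise the fusion state
#'   returned by a previous call.
#' @param params Parameters from [rfn_init()].
#' @return `rfn_fuse()` returns a fusion state: list with `fused` (the map
#'   at the reference resolution) and iteration counter `t`.
#' @export
rfn_fuse <- function(features, state = NULL, params, cfg = rfn_config()) {
  x <- rfn_base_fuse(features, params, cfg)
  if (is.null(state)) {
    return(list(fused = x, t = 1L))
  }
  h <- state$fused
  xh <- ag_concat_c(x, h)
  one <- array(1, dim = dim(ag_value(h)))
  z <- switch(
    if (is.null(cfg$gate_override)) "learned" else cfg$gate_override,
    learned = conv_gru_gate(xh, params$gru_wz, params$gru_bz),
    candidate = one,
    keep = array(0, dim = dim(ag_value(h))))
  r <- conv_gru_gate(xh, params$gru_wr, params$gru_br)
  cand_in <- ag_concat_c(x, ag_mul(r, h))
  cand <- ag_conv2d(cand_in, params$gru_wc, params$gru_bc,
                    kh = 3, kw = 3, stride = 1, pad = 1)
  if (cfg$activation == "tanh") cand <- ag_tanh(cand)
  fused <- ag_add(ag_mul(ag_sub(one, z), h), ag_mul(z, cand))
  list(fused = fused, t = state$t + 1L)
}

#' @rdname rfn_config
#' @return `recursive_refine()` returns the final fused feature map
#'   `F_RFN` (reference resolution, `width` channels) after `iterations`
#'   passes.
#' @export
recursive_refine <- function(features, params, cfg = rfn_config()) {
  if (cfg$iterations < 1) stop("iterations must be >= 1")
  state <- NULL
  for (t in seq_len(cfg$iterations)) {
    state <- rfn_fuse(features, state, params, cfg)
  }
  state$fused
}
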