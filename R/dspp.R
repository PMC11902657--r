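#' Dynamic spatial pyramid pooling (DSPP)
#'
#' DSPP pools a feature map over `L` pyramid levels (an `R_l x R_l` grid of
#' near-equal cells per level), scores each cell with a learnable mapping,
#' normalizes the scores to a spatial attention grid per level, and weights
#' the levels themselves with a softmax over learnable logits. The literal
#' output is the attention-weighted aggregate vector
#' `X = sum_l W_l sum_{r,c} a_rc^(l) x_rc^(l)`; for detection the module
#' additionally emits an `enhanced_map`: the input modulated by the
#' upsampled, level-weighted attention (rescaled to unit mean) and passed
#' through a learnable channel-mixing transform initialized to the
#' identity, so the module starts as a pass-through.
#'
#' @param grid_sizes Strictly increasing cells-per-side for each level.
#' @param pool_kind `"max"` or `"average"` cell pooling.
#' @return `pyramid_config()` returns a config list.
#' @export
pyramid_config <- function(grid_sizes = c(1, 2, 4, 6),
                           pool_kind = c("max", "average")) {
  stopifnot(length(grid_sizes) >= 1, all(grid_sizes >= 1),
            all(diff(grid_sizes) > 0))
  list(L = length(grid_sizes), grid_sizes = as.integer(grid_sizes),
       pool_kind = match.arg(pool_kind))
}

#' @rdname pyramid_config
#' @param channels Channel count `C` of the feature maps the parameters
#'   will be applied to.
#' @param cfg A `pyramid_config()`.
#' @param seed Integer seed for the cell-score initialization.
#' @return `dspp_init()` returns a named list of parameter arrays:
#'   `alpha` (level logits), `phi_w`/`phi_b` (cell-score projection),
#'   `mix_w`/`mix_b` (channel mixing, identity-initialized).
#' @export
dspp_init <- function(channels, cfg = pyramid_config(), seed = 1L) {
  with_local_seed(seed, list(
    alpha = numeric(cfg$L),
    phi_w = matrix(stats::rnorm(channels, sd = 1 / sqrt(channels)),
                   channels, 1),
    phi_b = 0,
    mix_w = diag(channels),
    mix_b = numeric(channels)
  ))
}

#' @rdname pyramid_config
#' @param f A feature map, `H x W x C` (array or `ag_tensor`).
#' @param r Cells per side at this level (`r <= min(H, W)`).
#' @return `pooled_cells()` returns an `r x r x C` grid of pooled cell
#'   vectors.
#' @export
pooled_cells <- function(f, r, pool_kind = "max") {
  ag_cellpool(f, r, kind = if (pool_kind == "max") "max" else "average")
}

#' @rdname pyramid_config
#' @param alpha Level logits (length `L` vector or `ag_tensor`).
#' @return `level_weights()` returns the softmax-normalized level weights.
#' @export
level_weights <- function(alpha) ag_softmax(alpha)

#' @rdname pyramid_config
#' @param cells Pooled cells from [pooled_cells()], `r x r x C`.
#' @param phi_w,phi_b Learnable cell-score projection (`C x 1` and scalar).
#' @return `spatial_attention()` returns an `r x r` attention grid summing
#'   to 1.
#' @export
spatial_attention <- function(cells, phi_w, phi_b) {
  d <- dim(ag_value(cells))
  m <- ag_reshape(cells, c(d[1] * d[2], d[3]))
  scores <- ag_add(ag_matmul(m, phi_w), phi_b)
  ag_reshape(ag_softmax(scores), c(d[1], d[2]))
}

#' @rdname pyramid_config
#' @param params Parameters from [dspp_init()].
#' @return `dspp_forward()` returns a list: `descriptor` (length-`C`
#'   aggregate), `level_weights`, `attention` (list of per-level grids) and
#'   `enhanced_map` (`H x W x C`). When called on plain arrays all entries
#'   are plain; on `ag_tensor`s the graph is recorded.
#' @export
dspp_forward <- function(f, params, cfg = pyramid_config()) {
  d <- dim(ag_value(f))
  if (max(cfg$grid_sizes) > min(d[1], d[2])) {
    stop("finest pyramid grid exceeds the feature map size")
  }
  w_lvl <- level_weights(params$alpha)
  att <- vector("list", cfg$L)
  desc <- NULL
  mod <- NULL
  for (l in seq_len(cfg$L)) {
    r <- cfg$grid_sizes[l]
    cells <- pooled_cells(f, r, cfg$pool_kind)
    a <- spatial_attention(cells, params$phi_w, params$phi_b)
    att[[l]] <- a
    wl <- ag_index(w_lvl, l)
    # attention-weighted cell aggregate: a (as 1 x r^2) times cell matrix
    m <- ag_reshape(cells, c(r * r, d[3]))
    dl <- ag_mul(ag_matmul(ag_reshape(a, c(1, r * r)), m), wl)
    desc <- if (is.null(desc)) dl else ag_add(desc, dl)
    # upsampled attention, rescaled to unit mean over the grid (x r^2)
    u <- cell_membership_matrix(d[1], r)
    v <- cell_membership_matrix(d[2], r)
    up <- ag_reshape(ag_linxform(ag_reshape(a, c(r, r, 1)), u, v),
                     c(d[1], d[2]))
    ml <- ag_mul(up, ag_mul(wl, r * r))
    mod <- if (is.null(mod)) ml else ag_add(mod, ml)
  }
  modulated <- ag_mul_map(f, mod)
  mixed <- ag_add_rowvec(
    ag_matmul(ag_reshape(modulated, c(d[1] * d[2], d[3])), params$mix_w),
    params$mix_b)
  descriptor <- if (is_ag(desc)) ag_reshape(desc, d[3]) else
    as.vector(ag_value(desc))
  list(descriptor = descriptor,
       level_weights = w_lvl,
       attention = att,
       enhanced_map = ag_reshape(mixed, d))
}
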