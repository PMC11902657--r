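#' @section Automatic differentiation:
#' The detector is trained with a compact reverse-mode automatic
#' differentiation core. Every operator accepts either plain numeric arrays
#' (in which case it simply computes the value -- used for inference and for
#' oracle tests) or `ag_tensor` graph nodes (used during training, where a
#' tape of vector-Jacobian products is recorded and replayed by
#' [ag_backward()]). Feature maps are `H x W x C` arrays.
#' @name autodiff
NULL

.ag_env <- new.env(parent = emptyenv())
.ag_env$counter <- 0L
.ag_env$cache <- new.env(parent = emptyenv())

#' Graph tensors
#'
#' `ag_param()` wraps a numeric array as a differentiable leaf;
#' `ag_const()` wraps a non-differentiable value (rarely needed -- plain
#' arrays are treated as constants automatically). `ag_value()` unwraps
#' either kind; `is_ag()` tests for a graph node.
#'
#' @param value A numeric vector, matrix or array.
#' @return An `ag_tensor` environment.
#' @export
ag_param <- function(value) new_ag(value, list(), list(), is_param = TRUE)

#' @rdname ag_param
#' @export
ag_const <- function(value) new_ag(value, list(), list(), is_param = FALSE)

#' @rdname ag_param
#' @param x Any object.
#' @export
is_ag <- function(x) inherits(x, "ag_tensor")

#' @rdname ag_param
#' @export
ag_value <- function(x) if (is_ag(x)) x$value else x

new_ag <- function(value, parents, vjps, is_param = FALSE) {
  e <- new.env(parent = emptyenv())
  .ag_env$counter <- .ag_env$counter + 1L
  e$id <- .ag_env$counter
  e$value <- value
  e$parents <- parents
  e$vjps <- vjps
  e$is_param <- is_param
  e$grad <- NULL
  class(e) <- "ag_tensor"
  e
}

#' @export
print.ag_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat(sprintf("<ag_tensor> %s%s\n",
              if (is.null(d)) paste0("len ", length(x$value))
              else paste(d, collapse = " x "),
              if (x$is_param) " (param)" else ""))
  invisible(x)
}

# Build an op result: if no argument is a graph node, return the plain value.
ag_op <- function(value, args, vjps) {
  live <- vapply(args, is_ag, logical(1))
  if (!any(live)) return(value)
  new_ag(value, args[live], vjps[live])
}

#' Reverse pass
#'
#' Accumulates gradients of a scalar `loss` node into every reachable
#' `ag_tensor`'s `$grad` field.
#'
#' @param loss An `ag_tensor` holding a length-1 value.
#' @export
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$value) == 1)
  # iterative topological sort (post-order DFS)
  order <- vector("list", 64); n_ord <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L)); n_st <- 1L
  while (n_st > 0L) {
    fr <- stack[[n_st]]; stack[[n_st]] <- NULL; n_st <- n_st - 1L
    node <- fr$node
    key <- as.character(node$id)
    if (fr$stage == 1L) {
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      n_st <- n_st + 1L; stack[[n_st]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (is.null(visited[[as.character(p$id)]])) {
          n_st <- n_st + 1L; stack[[n_st]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
    }
  }
  for (i in seq_len(n_ord)) order[[i]]$grad <- NULL
  loss$grad <- 1
  for (i in rev(seq_len(n_ord))) {
    node <- order[[i]]
    g <- node$grad
    if (is.null(g)) next
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      contrib <- node$vjps[[j]](g)
      p$grad <- if (is.null(p$grad)) contrib else p$grad + contrib
    }
  }
  invisible(loss)
}

same_shape <- function(g, like) {
  v <- ag_value(like)
  if (!is.null(dim(v))) dim(g) <- dim(v)
  g
}

# ---- elementwise ops --------------------------------------------------------

#' Differentiable array operators
#'
#' Elementwise and linear-algebra operators shared by the detector modules.
#' Each accepts plain numerics or `ag_tensor`s; with plain inputs the plain
#' result is returned.
#'
#' @param a,b,x Operands (arrays or `ag_tensor`s). Binary elementwise ops
#'   require equal shapes, or one scalar operand.
#' @name ag-ops
NULL

#' @rdname ag-ops
#' @export
ag_add <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  red_a <- if (length(av) == 1 && length(bv) > 1) function(g) sum(g) else identity
  red_b <- if (length(bv) == 1 && length(av) > 1) function(g) sum(g) else identity
  ag_op(av + bv, list(a, b),
        list(function(g) red_a(same_shape(g, a)),
             function(g) red_b(same_shape(g, b))))
}

#' @rdname ag-ops
#' @export
ag_sub <- function(a, b) ag_add(a, ag_scale(b, -1))

#' @rdname ag-ops
#' @param s A plain numeric scalar.
#' @export
ag_scale <- function(x, s) {
  ag_op(ag_value(x) * s, list(x), list(function(g) same_shape(g * s, x)))
}

#' @rdname ag-ops
#' @export
ag_mul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  red_a <- if (length(av) == 1 && length(bv) > 1) function(g) sum(g) else identity
  red_b <- if (length(bv) == 1 && length(av) > 1) function(g) sum(g) else identity
  ag_op(av * bv, list(a, b),
        list(function(g) red_a(same_shape(g * bv, a)),
             function(g) red_b(same_shape(g * av, b))))
}

#' @rdname ag-ops
#' @export
ag_matmul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(av %*% bv, list(a, b),
        list(function(g) g %*% t(bv), function(g) t(av) %*% g))
}

#' @rdname ag-ops
#' @export
ag_sum <- function(x) {
  xv <- ag_value(x)
  ag_op(sum(xv), list(x),
        list(function(g) same_shape(rep(g, length(xv)), x)))
}

#' @rdname ag-ops
#' @export
ag_mean <- function(x) ag_scale(ag_sum(x), 1 / length(ag_value(x)))

#' @rdname ag-ops
#' @export
ag_relu <- function(x) {
  xv <- ag_value(x)
  mask <- xv > 0
  ag_op(xv * mask, list(x), list(function(g) same_shape(g * mask, x)))
}

#' @rdname ag-ops
#' @export
ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-ag_value(x)))
  ag_op(s, list(x), list(function(g) same_shape(g * s * (1 - s), x)))
}

#' @rdname ag-ops
#' @export
ag_tanh <- function(x) {
  tv <- tanh(ag_value(x))
  ag_op(tv, list(x), list(function(g) same_shape(g * (1 - tv^2), x)))
}

#' @rdname ag-ops
#' @export
ag_exp <- function(x) {
  ev <- exp(ag_value(x))
  ag_op(ev, list(x), list(function(g) same_shape(g * ev, x)))
}

#' @rdname ag-ops
#' @export
ag_log <- function(x) {
  xv <- ag_value(x)
  ag_op(log(xv), list(x), list(function(g) same_shape(g / xv, x)))
}

#' @rdname ag-ops
#' @param p A plain numeric exponent.
#' @export
ag_pow <- function(x, p) {
  xv <- ag_value(x)
  ag_op(xv^p, list(x), list(function(g) same_shape(g * p * xv^(p - 1), x)))
}

#' @rdname ag-ops
#' @export
ag_softplus <- function(x) {
  xv <- ag_value(x)
  # stable: log(1 + exp(x)) = max(x, 0) + log1p(exp(-|x|))
  v <- pmax(xv, 0) + log1p(exp(-abs(xv)))
  s <- 1 / (1 + exp(-xv))
  ag_op(v, list(x), list(function(g) same_shape(g * s, x)))
}

#' @rdname ag-ops
#' @param beta Smooth-L1 transition point (plain scalar > 0).
#' @export
ag_smooth_l1 <- function(x, beta) {
  d <- ag_value(x)
  inner <- abs(d) < beta
  v <- ifelse(inner, 0.5 * d^2 / beta, abs(d) - 0.5 * beta)
  dd <- ifelse(inner, d / beta, sign(d))
  ag_op(v, list(x), list(function(g) same_shape(g * dd, x)))
}

# ---- softmax ----------------------------------------------------------------

#' @rdname ag-ops
#' @export
ag_softmax <- function(x) {
  xv <- as.vector(ag_value(x))
  e <- exp(xv - max(xv))
  s <- e / sum(e)
  ag_op(s, list(x),
        list(function(g) same_shape(s * (g - sum(g * s)), x)))
}

#' @rdname ag-ops
#' @export
ag_softmax_rows <- function(x) {
  xv <- ag_value(x)
  m <- apply(xv, 1, max)
  e <- exp(xv - m)
  s <- e / rowSums(e)
  ag_op(s, list(x),
        list(function(g) s * (g - rowSums(g * s))))
}

# ---- shape ops --------------------------------------------------------------

#' @rdname ag-ops
#' @param v A length-`ncol(x)` vector added to every row.
#' @export
ag_add_rowvec <- function(x, v) {
  xv <- ag_value(x); vv <- ag_value(v)
  ag_op(sweep(xv, 2, vv, "+"), list(x, v),
        list(identity, function(g) colSums(g)))
}

#' @rdname ag-ops
#' @export
ag_t <- function(x) {
  ag_op(t(ag_value(x)), list(x), list(function(g) t(g)))
}

#' @rdname ag-ops
#' @param i A single index into the flattened value.
#' @export
ag_index <- function(x, i) {
  xv <- ag_value(x)
  ag_op(xv[i], list(x),
        list(function(g) {
          out <- array(0, dim = if (is.null(dim(xv))) length(xv) else dim(xv))
          out[i] <- g
          out
        }))
}

#' @rdname ag-ops
#' @param dims New dimension vector.
#' @export
ag_reshape <- function(x, dims) {
  xv <- ag_value(x)
  v <- xv
  dim(v) <- dims
  ag_op(v, list(x), list(function(g) same_shape(g, x)))
}

#' @rdname ag-ops
#' @param idx Integer row indices (may repeat).
#' @export
ag_rows <- function(x, idx) {
  xv <- ag_value(x)
  n <- nrow(xv)
  dup <- anyDuplicated(idx) > 0
  ag_op(xv[idx, , drop = FALSE], list(x),
        list(function(g) {
          out <- matrix(0, n, ncol(xv))
          if (!dup) {
            out[idx, ] <- g
          } else {
            for (r in seq_along(idx)) {
              out[idx[r], ] <- out[idx[r], ] + g[r, ]
            }
          }
          out
        }))
}

#' @rdname ag-ops
#' @export
ag_concat_cols <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  na <- ncol(av)
  ag_op(cbind(av, bv), list(a, b),
        list(function(g) g[, seq_len(na), drop = FALSE],
             function(g) g[, na + seq_len(ncol(bv)), drop = FALSE]))
}

#' @rdname ag-ops
#' @export
ag_concat_c <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  da <- dim(av); db <- dim(bv)
  stopifnot(da[1] == db[1], da[2] == db[2])
  v <- array(c(av, bv), dim = c(da[1], da[2], da[3] + db[3]))
  ag_op(v, list(a, b),
        list(function(g) g[, , seq_len(da[3]), drop = FALSE],
             function(g) g[, , da[3] + seq_len(db[3]), drop = FALSE]))
}

# ---- per-channel bilinear / pooling transforms ------------------------------

# Apply out[,,c] = A %*% x[,,c] %*% t(B) for constant matrices A, B.
# Covers bilinear resizing, average cell pooling and piecewise-constant
# attention upsampling; the adjoint is t(A) %*% g %*% B.
#' @rdname ag-ops
#' @param A,B Plain matrices applied per channel (`A X B^T`).
#' @export
ag_linxform <- function(x, A, B) {
  xv <- ag_value(x)
  d <- dim(xv)
  C <- d[3]
  v <- array(0, dim = c(nrow(A), nrow(B), C))
  for (cc in seq_len(C)) v[, , cc] <- A %*% xv[, , cc] %*% t(B)
  ag_op(v, list(x),
        list(function(g) {
          out <- array(0, dim = d)
          for (cc in seq_len(C)) out[, , cc] <- t(A) %*% g[, , cc] %*% B
          out
        }))
}

# Interpolation matrix mapping n_in samples to n_out (bilinear, clamped).
interp_matrix <- function(n_out, n_in) {
  key <- sprintf("ip_%d_%d", n_out, n_in)
  hit <- .ag_env$cache[[key]]
  if (!is.null(hit)) return(hit)
  A <- matrix(0, n_out, n_in)
  if (n_in == 1) {
    A[, 1] <- 1
  } else {
    pos <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
    pos <- pmin(pmax(pos, 0), n_in - 1)
    i0 <- pmin(floor(pos), n_in - 2)
    frac <- pos - i0
    A[cbind(seq_len(n_out), i0 + 1)] <- 1 - frac
    A[cbind(seq_len(n_out), i0 + 2)] <-
      A[cbind(seq_len(n_out), i0 + 2)] + frac
  }
  .ag_env$cache[[key]] <- A
  A
}

#' @rdname ag-ops
#' @param h_out,w_out Output spatial size.
#' @export
ag_resize_bilinear <- function(x, h_out, w_out) {
  d <- dim(ag_value(x))
  ag_linxform(x, interp_matrix(h_out, d[1]), interp_matrix(w_out, d[2]))
}

# Near-equal partition of n into r spans (floor/ceil split, deterministic).
partition_spans <- function(n, r) {
  stopifnot(r >= 1, r <= n)
  edges <- floor(seq(0, n, length.out = r + 1) + 0.5)
  # guard against empty spans for awkward n/r combinations
  edges <- pmax(edges, seq(0, r))
  edges <- pmin(edges, n - rev(seq(0, r)))
  lapply(seq_len(r), function(i) (edges[i] + 1):edges[i + 1])
}

# 0/1-normalized averaging matrix for a span partition (rows sum to 1).
pool_matrix <- function(n, r) {
  spans <- partition_spans(n, r)
  A <- matrix(0, r, n)
  for (i in seq_len(r)) A[i, spans[[i]]] <- 1 / length(spans[[i]])
  A
}

# Piecewise-constant upsample matrix (each output sample copies its cell).
cell_membership_matrix <- function(n, r) {
  spans <- partition_spans(n, r)
  A <- matrix(0, n, r)
  for (i in seq_len(r)) A[spans[[i]], i] <- 1
  A
}

#' @rdname ag-ops
#' @param r Cells per side of the pooling grid.
#' @param kind `"max"` or `"average"`.
#' @export
ag_cellpool <- function(x, r, kind = c("average", "max")) {
  kind <- match.arg(kind)
  xv <- ag_value(x)
  d <- dim(xv)
  if (r > min(d[1], d[2])) {
    stop(sprintf("pyramid grid %d exceeds feature map %d x %d", r, d[1], d[2]))
  }
  if (kind == "average") {
    return(ag_linxform(x, pool_matrix(d[1], r), pool_matrix(d[2], r)))
  }
  spans_r <- partition_spans(d[1], r)
  spans_c <- partition_spans(d[2], r)
  v <- array(0, dim = c(r, r, d[3]))
  amax <- array(0L, dim = c(r, r, d[3]))
  for (i in seq_len(r)) for (j in seq_len(r)) {
    blk <- xv[spans_r[[i]], spans_c[[j]], , drop = FALSE]
    bd <- dim(blk)
    bm <- matrix(blk, nrow = bd[1] * bd[2], ncol = bd[3])
    w <- max.col(t(bm), ties.method = "first")
    v[i, j, ] <- bm[cbind(w, seq_len(bd[3]))]
    # store linear index into x for backward
    sub <- arrayInd(w, .dim = bd[1:2])
    amax[i, j, ] <- spans_r[[i]][sub[, 1]] +
      (spans_c[[j]][sub[, 2]] - 1) * d[1] +
      (seq_len(d[3]) - 1) * d[1] * d[2]
  }
  ag_op(v, list(x),
        list(function(g) {
          # cells are disjoint and channels offset the linear index, so
          # every argmax position is unique: plain assignment is exact
          out <- array(0, dim = d)
          out[as.vector(amax)] <- as.vector(g)
          out
        }))
}

# Broadcast-multiply an H x W map over every channel of an H x W x C tensor.
#' @rdname ag-ops
#' @param m An `H x W` modulation map (array or `ag_tensor`).
#' @export
ag_mul_map <- function(x, m) {
  xv <- ag_value(x); mv <- ag_value(m)
  d <- dim(xv)
  mrep <- array(mv, dim = d)
  ag_op(xv * mrep, list(x, m),
        list(function(g) g * mrep,
             function(g) {
               gm <- matrix(g * xv, nrow = d[1] * d[2], ncol = d[3])
               matrix(rowSums(gm), d[1], d[2])
             }))
}

# ---- convolution ------------------------------------------------------------

conv_index <- function(hp, wp, C, kh, kw, stride, h_out, w_out) {
  key <- sprintf("cv_%d_%d_%d_%d_%d_%d", hp, wp, C, kh, kw, stride)
  hit <- .ag_env$cache[[key]]
  if (!is.null(hit)) return(hit)
  base_i <- rep(seq(1, by = stride, length.out = h_out), times = w_out)
  base_j <- rep(seq(1, by = stride, length.out = w_out), each = h_out)
  base <- base_i + (base_j - 1) * hp
  off <- as.vector(outer(
    as.vector(outer(0:(kh - 1), (0:(kw - 1)) * hp, "+")),
    (0:(C - 1)) * hp * wp, "+"))
  idx <- outer(base, off, "+")
  .ag_env$cache[[key]] <- idx
  idx
}

#' 2D convolution (HWC layout)
#'
#' `x` is `H x W x C_in`; the kernel is supplied as a
#' `(kh*kw*C_in) x C_out` matrix whose rows run over (dy, dx, input
#' channel) in that nesting order, plus a length-`C_out` bias. Zero padding,
#' square stride. Implemented by im2col + matrix multiply.
#'
#' @param x Input tensor or array, `H x W x C_in`.
#' @param w Kernel matrix `(kh*kw*C_in) x C_out` (array or `ag_tensor`).
#' @param b Bias vector, length `C_out`.
#' @param kh,kw Kernel height/width.
#' @param stride Stride (same in both directions).
#' @param pad Zero padding on every side.
#' @return `H_out x W_out x C_out` tensor/array.
#' @export
ag_conv2d <- function(x, w, b, kh = 3, kw = 3, stride = 1, pad = 1) {
  xv <- ag_value(x); wv <- ag_value(w); bv <- ag_value(b)
  d <- dim(xv)
  hp <- d[1] + 2 * pad; wp <- d[2] + 2 * pad
  h_out <- (hp - kh) %/% stride + 1
  w_out <- (wp - kw) %/% stride + 1
  xp <- array(0, dim = c(hp, wp, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- xv
  idx <- conv_index(hp, wp, d[3], kh, kw, stride, h_out, w_out)
  cols <- xp[idx]
  dim(cols) <- dim(idx)
  y <- cols %*% wv
  y <- sweep(y, 2, bv, "+")
  out <- y
  dim(out) <- c(h_out, w_out, ncol(wv))
  as_gm <- function(g) {
    dim(g) <- c(h_out * w_out, ncol(wv))
    g
  }
  ag_op(out, list(x, w, b), list(
    function(g) {
      dcols <- as_gm(g) %*% t(wv)
      dxp <- numeric(hp * wp * d[3])
      # for a fixed kernel offset the im2col positions are distinct, so
      # the scatter-add vectorizes column by column
      for (o in seq_len(ncol(idx))) {
        io <- idx[, o]
        dxp[io] <- dxp[io] + dcols[, o]
      }
      dim(dxp) <- c(hp, wp, d[3])
      dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , drop = FALSE]
    },
    function(g) t(cols) %*% as_gm(g),
    function(g) colSums(as_gm(g))))
}
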