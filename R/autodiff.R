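# Reverse-mode automatic differentiation on a flat tape.
#
# Values are plain numeric matrices/arrays. A node is an environment holding
# the value ($v), the accumulated gradient ($g), its parent nodes ($p), a
# backward closure ($bw) mapping the node's gradient to per-parent gradients,
# and a flag ($req) saying whether anything upstream needs a gradient.
# Interior nodes are recorded on the tape in creation order, so a single
# reverse sweep is a valid topological order.

#' Create a fresh autodiff tape
#'
#' @return A tape environment to pass to `ad_*` operations.
#' @keywords internal
tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$k <- 0L
  tp
}

ad_node <- function(tp, val, parents = NULL, bw = NULL, req = TRUE) {
  n <- new.env(parent = emptyenv())
  n$v <- val
  n$g <- NULL
  n$p <- parents
  n$bw <- bw
  n$req <- req
  if (!is.null(bw) && req) {
    tp$k <- tp$k + 1L
    if (tp$k > length(tp$nodes)) length(tp$nodes) <- 2L * tp$k
    tp$nodes[[tp$k]] <- n
  }
  n
}

#' Wrap a constant (no gradient) value
#' @keywords internal
ad_const <- function(tp, val) ad_node(tp, val, req = FALSE)

#' Wrap a trainable leaf value
#' @keywords internal
ad_leaf <- function(tp, val) ad_node(tp, val, req = TRUE)

any_req <- function(...) {
  for (p in list(...)) if (!is.null(p) && isTRUE(p$req)) return(TRUE)
  FALSE
}

#' Run the reverse sweep from a scalar loss node
#' @keywords internal
ad_backward <- function(tp, loss) {
  stopifnot(length(loss$v) == 1L)
  loss$g <- 1
  if (tp$k < 1L) return(invisible(NULL))
  for (i in tp$k:1L) {
    n <- tp$nodes[[i]]
    if (is.null(n$g)) next
    gs <- n$bw(n$g)
    ps <- n$p
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      gj <- gs[[j]]
      if (is.null(p) || is.null(gj) || !p$req) next
      p$g <- if (is.null(p$g)) gj else p$g + gj
    }
  }
  invisible(NULL)
}

## ---- elementwise and linear-algebra primitives ----

ad_add <- function(tp, a, b) {
  ad_node(tp, a$v + b$v, list(a, b), function(g) list(g, g),
          req = any_req(a, b))
}

ad_sub <- function(tp, a, b) {
  ad_node(tp, a$v - b$v, list(a, b), function(g) list(g, -g),
          req = any_req(a, b))
}

# matrix + bias row-vector broadcast over rows
ad_add_bias <- function(tp, a, b) {
  bv <- as.numeric(b$v)
  val <- sweep(a$v, 2L, bv, "+")
  ad_node(tp, val, list(a, b),
          function(g) list(g, colSums(g)),
          req = any_req(a, b))
}

ad_mul <- function(tp, a, b) {
  ad_node(tp, a$v * b$v, list(a, b),
          function(g) list(g * b$v, g * a$v),
          req = any_req(a, b))
}

# multiply by a fixed numeric (scalar or array), e.g. dropout masks
ad_mul_const <- function(tp, a, k) {
  ad_node(tp, a$v * k, list(a), function(g) list(g * k), req = a$req)
}

# add a fixed numeric (scalar or array)
ad_add_const <- function(tp, a, k) {
  ad_node(tp, a$v + k, list(a), function(g) list(g), req = a$req)
}

ad_matmul <- function(tp, a, b) {
  ad_node(tp, a$v %*% b$v, list(a, b),
          function(g) list(g %*% t(b$v), crossprod(a$v, g)),
          req = any_req(a, b))
}

ad_t <- function(tp, a) {
  ad_node(tp, t(a$v), list(a), function(g) list(t(g)), req = a$req)
}

# fused affine map: x %*% W + b (bias broadcast over rows)
ad_linear_op <- function(tp, x, W, b) {
  n <- nrow(x$v)
  val <- x$v %*% W$v
  val <- val + rep(b$v, each = n)
  ad_node(tp, val, list(x, W, b),
          function(g) list(g %*% t(W$v), crossprod(x$v, g), colSums(g)),
          req = any_req(x, W, b))
}

# Batched block-diagonal multi-head attention. q is (S*Tq) x d, k and v are
# (S*Tkv) x d; sample i's queries attend only to sample i's keys/values.
ad_attention_op <- function(tp, q, k, v, S, Tq, Tkv, heads) {
  d <- ncol(q$v)
  dh <- d %/% heads
  sc <- 1 / sqrt(dh)
  out <- matrix(0, S * Tq, d)
  attn <- vector("list", S * heads)
  for (i in seq_len(S)) {
    qi <- ((i - 1L) * Tq + 1L):(i * Tq)
    ki <- ((i - 1L) * Tkv + 1L):(i * Tkv)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      s <- tcrossprod(q$v[qi, cols, drop = FALSE],
                      k$v[ki, cols, drop = FALSE]) * sc
      s <- exp(s - apply(s, 1L, max))
      a <- s / rowSums(s)
      attn[[(i - 1L) * heads + h]] <- a
      out[qi, cols] <- a %*% v$v[ki, cols, drop = FALSE]
    }
  }
  ad_node(tp, out, list(q, k, v),
          function(g) {
            dq <- matrix(0, S * Tq, d)
            dk <- matrix(0, S * Tkv, d)
            dv <- matrix(0, S * Tkv, d)
            for (i in seq_len(S)) {
              qi <- ((i - 1L) * Tq + 1L):(i * Tq)
              ki <- ((i - 1L) * Tkv + 1L):(i * Tkv)
              for (h in seq_len(heads)) {
                cols <- ((h - 1L) * dh + 1L):(h * dh)
                a <- attn[[(i - 1L) * heads + h]]
                go <- g[qi, cols, drop = FALSE]
                vv <- v$v[ki, cols, drop = FALSE]
                da <- tcrossprod(go, vv)
                dv[ki, cols] <- crossprod(a, go)
                ds <- a * (da - rowSums(da * a)) * sc
                dq[qi, cols] <- ds %*% k$v[ki, cols, drop = FALSE]
                dk[ki, cols] <- crossprod(ds, q$v[qi, cols, drop = FALSE])
              }
            }
            list(dq, dk, dv)
          },
          req = any_req(q, k, v))
}

ad_relu <- function(tp, a) {
  m <- a$v > 0
  ad_node(tp, a$v * m, list(a), function(g) list(g * m), req = a$req)
}

ad_sigmoid <- function(tp, a) {
  s <- 1 / (1 + exp(-a$v))
  ad_node(tp, s, list(a), function(g) list(g * s * (1 - s)), req = a$req)
}

ad_tanh <- function(tp, a) {
  th <- tanh(a$v)
  ad_node(tp, th, list(a), function(g) list(g * (1 - th^2)), req = a$req)
}

ad_exp <- function(tp, a) {
  e <- exp(a$v)
  ad_node(tp, e, list(a), function(g) list(g * e), req = a$req)
}

# log with a floor so targets with zero-probability entries never yield NaN
ad_log <- function(tp, a, eps = 1e-12) {
  cl <- pmax(a$v, eps)
  ad_node(tp, log(cl), list(a),
          function(g) list(ifelse(a$v > eps, g / a$v, 0)),
          req = a$req)
}

ad_square <- function(tp, a) {
  ad_node(tp, a$v^2, list(a), function(g) list(2 * g * a$v), req = a$req)
}

ad_mean_all <- function(tp, a) {
  n <- length(a$v)
  ad_node(tp, mean(a$v), list(a),
          function(g) list(array(as.numeric(g) / n, dim = dim_of(a$v))),
          req = a$req)
}

ad_sum_all <- function(tp, a) {
  ad_node(tp, sum(a$v), list(a),
          function(g) list(array(as.numeric(g), dim = dim_of(a$v))),
          req = a$req)
}

dim_of <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# column means over rows of a matrix -> 1 x d
ad_colmeans <- function(tp, a) {
  n <- nrow(a$v)
  ad_node(tp, matrix(colMeans(a$v), 1L), list(a),
          function(g) list(matrix(rep(as.numeric(g) / n, each = n), n)),
          req = a$req)
}

## ---- row-wise normalizations ----

ad_softmax_rows <- function(tp, a) {
  x <- a$v - apply(a$v, 1L, max)
  e <- exp(x)
  y <- e / rowSums(e)
  ad_node(tp, y, list(a),
          function(g) list(y * (g - rowSums(g * y))),
          req = a$req)
}

ad_layernorm_rows <- function(tp, x, gamma, beta, eps = 1e-5) {
  n <- nrow(x$v)
  mu <- rowMeans(x$v)
  xc <- x$v - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gv <- as.numeric(gamma$v)
  bv <- as.numeric(beta$v)
  y <- xhat * rep(gv, each = n) + rep(bv, each = n)
  ad_node(tp, y, list(x, gamma, beta),
          function(g) {
            dxhat <- g * rep(gv, each = n)
            dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
            list(dx, colSums(g * xhat), colSums(g))
          },
          req = any_req(x, gamma, beta))
}

ad_l2norm_rows <- function(tp, a, eps = 1e-12) {
  r <- sqrt(rowSums(a$v^2) + eps)
  y <- a$v / r
  ad_node(tp, y, list(a),
          function(g) list(g / r - a$v * (rowSums(g * a$v) / r^3)),
          req = a$req)
}

## ---- indexing / shaping ----

ad_rows <- function(tp, a, idx) {
  idx <- as.integer(idx)
  ad_node(tp, a$v[idx, , drop = FALSE], list(a),
          function(g) {
            out <- matrix(0, nrow(a$v), ncol(a$v))
            acc <- rowsum(g, group = idx)
            out[as.integer(rownames(acc)), ] <- acc
            list(out)
          },
          req = a$req)
}

ad_cols <- function(tp, a, idx) {
  idx <- as.integer(idx)
  ad_node(tp, a$v[, idx, drop = FALSE], list(a),
          function(g) {
            out <- matrix(0, nrow(a$v), ncol(a$v))
            out[, idx] <- out[, idx] + g
            list(out)
          },
          req = a$req)
}

ad_rbind <- function(tp, nodes) {
  rows <- vapply(nodes, function(n) nrow(n$v), integer(1))
  off <- cumsum(c(0L, rows))
  ad_node(tp, do.call(rbind, lapply(nodes, function(n) n$v)), nodes,
          function(g) lapply(seq_along(nodes), function(j) {
            g[(off[j] + 1L):off[j + 1L], , drop = FALSE]
          }),
          req = do.call(any_req, nodes))
}

ad_cbind <- function(tp, nodes) {
  cols <- vapply(nodes, function(n) ncol(n$v), integer(1))
  off <- cumsum(c(0L, cols))
  ad_node(tp, do.call(cbind, lapply(nodes, function(n) n$v)), nodes,
          function(g) lapply(seq_along(nodes), function(j) {
            g[, (off[j] + 1L):off[j + 1L], drop = FALSE]
          }),
          req = do.call(any_req, nodes))
}

ad_reshape <- function(tp, a, dims) {
  old <- dim_of(a$v)
  v <- a$v
  dim(v) <- dims
  ad_node(tp, v, list(a),
          function(g) { dim(g) <- old; list(g) },
          req = a$req)
}

# scale by a fixed scalar
ad_scale <- function(tp, a, k) ad_mul_const(tp, a, k)

## ---- single-channel 2D convolution (multi output channel) ----

pad_matrix <- function(x, ph, pw) {
  if (ph == 0L && pw == 0L) return(x)
  out <- matrix(0, nrow(x) + 2L * ph, ncol(x) + 2L * pw)
  out[(ph + 1L):(ph + nrow(x)), (pw + 1L):(pw + ncol(x))] <- x
  out
}

conv2_valid <- function(x, w) {
  kh <- nrow(w); kw <- ncol(w)
  oh <- nrow(x) - kh + 1L; ow <- ncol(x) - kw + 1L
  out <- matrix(0, oh, ow)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    if (w[i, j] != 0)
      out <- out + w[i, j] * x[i:(i + oh - 1L), j:(j + ow - 1L)]
  }
  out
}

# x: H x W map; w: kh x kw x C kernels; b: length-C bias; pad: c(ph, pw)
# value: oh x ow x C array
ad_conv2d <- function(tp, x, w, b, pad = c(0L, 2L)) {
  ph <- as.integer(pad[1]); pw <- as.integer(pad[2])
  kh <- dim(w$v)[1]; kw <- dim(w$v)[2]; C <- dim(w$v)[3]
  xp <- pad_matrix(x$v, ph, pw)
  oh <- nrow(xp) - kh + 1L; ow <- ncol(xp) - kw + 1L
  val <- array(0, c(oh, ow, C))
  for (cc in seq_len(C))
    val[, , cc] <- conv2_valid(xp, w$v[, , cc]) + b$v[cc]
  ad_node(tp, val, list(x, w, b),
          function(g) {
            dxp <- matrix(0, nrow(xp), ncol(xp))
            dw <- array(0, dim(w$v))
            db <- numeric(C)
            for (cc in seq_len(C)) {
              gc <- g[, , cc, drop = TRUE]
              if (is.null(dim(gc))) gc <- matrix(gc, oh, ow)
              db[cc] <- sum(gc)
              wv <- w$v[, , cc]
              for (i in seq_len(kh)) for (j in seq_len(kw)) {
                ri <- i:(i + oh - 1L); cj <- j:(j + ow - 1L)
                dxp[ri, cj] <- dxp[ri, cj] + wv[i, j] * gc
                dw[i, j, cc] <- sum(xp[ri, cj] * gc)
              }
            }
            dx <- dxp[(ph + 1L):(ph + nrow(x$v)), (pw + 1L):(pw + ncol(x$v)),
                      drop = FALSE]
            list(dx, dw, db)
          },
          req = any_req(x, w, b))
}
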