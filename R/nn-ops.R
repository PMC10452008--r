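# Convolution and pooling ops.  Feature maps are stored as (H, W, C, N)
# column-major arrays (the natural layout for R and for the png/tiff readers);
# the compiled im2col/col2im kernels do the patch extraction, R's BLAS does the
# matrix products.

conv_out_dim <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

conv2d_val <- function(xv, wv, bv, stride, pad, groups) {
  d <- dim(xv)
  H <- d[1L]; W <- d[2L]; Cin <- d[3L]; N <- d[4L]
  wd <- dim(wv)
  kh <- wd[1L]; kw <- wd[2L]; Cg <- wd[3L]; Cout <- wd[4L]
  stopifnot(Cin == Cg * groups, Cout %% groups == 0L)
  Coutg <- Cout %/% groups
  oH <- conv_out_dim(H, kh, stride, pad)
  oW <- conv_out_dim(W, kw, stride, pad)
  out <- array(0, dim = c(oH, oW, Cout, N))
  for (n in seq_len(N)) {
    for (g in seq_len(groups)) {
      ci <- ((g - 1L) * Cg + 1L):(g * Cg)
      co <- ((g - 1L) * Coutg + 1L):(g * Coutg)
      cols <- im2col_cpp(aslice(aslice(xv, 4L, n), 3L, ci), H, W, Cg,
                         kh, kw, stride, stride, pad, pad, 0)
      wm <- matrix(aslice(wv, 4L, co), nrow = kh * kw * Cg)
      out[, , co, n] <- array(crossprod(cols, wm), dim = c(oH, oW, Coutg))
    }
  }
  if (!is.null(bv)) {
    out <- out + expand_to(array(bv, dim = c(1L, 1L, Cout, 1L)), dim(out))
  }
  out
}

#' Differentiable 2-d convolution (NHWC-free, (H,W,C,N) layout)
#'
#' Cross-correlation with square stride and zero padding, supporting grouped
#' convolution.  Weights have dim `(kh, kw, in_channels/groups, out_channels)`.
#'
#' @param x input `tg_tensor` of dim (H, W, C, N).
#' @param w weight `tg_tensor`.
#' @param b optional bias `tg_tensor` of length out_channels.
#' @param stride,pad integer stride and zero padding (same on both axes).
#' @param groups number of channel groups.
#' @return output `tg_tensor` of dim (H', W', out_channels, N).
#' @export
tg_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, groups = 1L) {
  xv <- x$v; wv <- w$v
  bv <- if (is.null(b)) NULL else as.numeric(b$v)
  out <- conv2d_val(xv, wv, bv, stride, pad, groups)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  d <- dim(xv); wd <- dim(wv)
  H <- d[1L]; W <- d[2L]; N <- d[4L]
  kh <- wd[1L]; kw <- wd[2L]; Cg <- wd[3L]; Cout <- wd[4L]
  Coutg <- Cout %/% groups
  oHW <- prod(dim(out)[1:2])
  backfn <- function(g) {
    dx <- array(0, dim = d)
    dw <- array(0, dim = wd)
    for (n in seq_len(N)) {
      for (gr in seq_len(groups)) {
        ci <- ((gr - 1L) * Cg + 1L):(gr * Cg)
        co <- ((gr - 1L) * Coutg + 1L):(gr * Coutg)
        cols <- im2col_cpp(aslice(aslice(xv, 4L, n), 3L, ci), H, W, Cg,
                           kh, kw, stride, stride, pad, pad, 0)
        dom <- matrix(aslice(aslice(g, 4L, n), 3L, co), nrow = oHW)
        dw[, , , co] <- dw[, , , co, drop = FALSE] +
          array(cols %*% dom, dim = c(kh, kw, Cg, Coutg))
        wm <- matrix(aslice(wv, 4L, co), nrow = kh * kw * Cg)
        dcols <- wm %*% t(dom)
        dx[, , ci, n] <- dx[, , ci, n, drop = FALSE] +
          array(col2im_cpp(dcols, H, W, Cg, kh, kw, stride, stride, pad, pad),
                dim = c(H, W, Cg, 1L))
      }
    }
    db <- if (is.null(bv)) NULL else as.vector(sum_keepdim(g, c(1L, 2L, 4L)))
    if (is.null(bv)) list(dx, dw) else list(dx, dw, array(db, dim = Cout))
  }
  tg_op(out, parents, backfn)
}

#' Differentiable transposed convolution, kernel = stride = 2
#'
#' Exact x2 upsampling: every input pixel expands into a disjoint 2x2 output
#' block, so there is no overlap ambiguity or output cropping.  Weights have
#' dim `(2, 2, in_channels, out_channels)`.
#'
#' @inheritParams tg_conv2d
#' @return output `tg_tensor` of dim (2H, 2W, out_channels, N).
#' @export
tg_conv_transpose2d <- function(x, w, b = NULL) {
  xv <- x$v; wv <- w$v
  d <- dim(xv); wd <- dim(wv)
  H <- d[1L]; W <- d[2L]; Cin <- d[3L]; N <- d[4L]
  stopifnot(wd[1L] == 2L, wd[2L] == 2L, wd[3L] == Cin)
  Cout <- wd[4L]
  out <- array(0, dim = c(2L * H, 2L * W, Cout, N))
  wmats <- list()
  for (i in 1:2) for (j in 1:2) {
    wmats[[paste(i, j)]] <- array(wv[i, j, , ], dim = c(Cin, Cout))
  }
  for (n in seq_len(N)) {
    xm <- matrix(aslice(xv, 4L, n), nrow = H * W)
    for (i in 1:2) for (j in 1:2) {
      o <- xm %*% wmats[[paste(i, j)]]
      out[seq(i, 2L * H, 2L), seq(j, 2L * W, 2L), , n] <-
        array(o, dim = c(H, W, Cout))
    }
  }
  bv <- if (is.null(b)) NULL else as.numeric(b$v)
  if (!is.null(bv)) {
    out <- out + expand_to(array(bv, dim = c(1L, 1L, Cout, 1L)), dim(out))
  }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  backfn <- function(g) {
    dx <- array(0, dim = d)
    dw <- array(0, dim = wd)
    for (n in seq_len(N)) {
      xm <- matrix(aslice(xv, 4L, n), nrow = H * W)
      dxm <- matrix(0, nrow = H * W, ncol = Cin)
      for (i in 1:2) for (j in 1:2) {
        go <- matrix(g[seq(i, 2L * H, 2L), seq(j, 2L * W, 2L), , n],
                     nrow = H * W)
        dxm <- dxm + go %*% t(wmats[[paste(i, j)]])
        dw[i, j, , ] <- array(dw[i, j, , ], dim = c(Cin, Cout)) +
          crossprod(xm, go)
      }
      dx[, , , n] <- array(dxm, dim = c(H, W, Cin, 1L))
    }
    db <- if (is.null(bv)) NULL else as.vector(sum_keepdim(g, c(1L, 2L, 4L)))
    if (is.null(bv)) list(dx, dw) else list(dx, dw, array(db, dim = Cout))
  }
  tg_op(out, parents, backfn)
}

#' Differentiable max pooling
#'
#' Max pooling with square kernel, stride and zero padding (padded positions
#' never win the max).  The default (k = 3, stride = 2, pad = 1) halves even
#' spatial dims exactly.
#'
#' @param x input `tg_tensor` of dim (H, W, C, N).
#' @param k,stride,pad kernel size, stride, padding.
#' @return pooled `tg_tensor`.
#' @export
tg_maxpool2d <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x$v)
  r <- maxpool2d_cpp(x$v, d[1L], d[2L], d[3L], d[4L], k, stride, pad)
  oH <- conv_out_dim(d[1L], k, stride, pad)
  oW <- conv_out_dim(d[2L], k, stride, pad)
  out <- array(r$out, dim = c(oH, oW, d[3L], d[4L]))
  amax <- r$argmax
  tg_op(out, list(x), function(g) {
    list(array(maxpool2d_bwd_cpp(as.numeric(g), amax, prod(d)), dim = d))
  })
}

#' Differentiable 2x2 average pooling (stride 2)
#'
#' @param x input `tg_tensor` with even spatial dims.
#' @return pooled `tg_tensor` at half resolution.
#' @export
tg_avgpool2d <- function(x) {
  d <- dim(x$v)
  H <- d[1L]; W <- d[2L]
  if (H %% 2L != 0L || W %% 2L != 0L) {
    stop("average pooling requires even spatial dims, got ", H, "x", W)
  }
  o1 <- seq(1L, H, 2L); o2 <- seq(2L, H, 2L)
  p1 <- seq(1L, W, 2L); p2 <- seq(2L, W, 2L)
  v <- x$v
  out <- (v[o1, p1, , , drop = FALSE] + v[o2, p1, , , drop = FALSE] +
          v[o1, p2, , , drop = FALSE] + v[o2, p2, , , drop = FALSE]) / 4
  tg_op(out, list(x), function(g) {
    dx <- array(0, dim = d)
    gq <- g / 4
    dx[o1, p1, , ] <- gq
    dx[o2, p1, , ] <- gq
    dx[o1, p2, , ] <- gq
    dx[o2, p2, , ] <- gq
    list(dx)
  })
}
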