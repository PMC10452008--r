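# Differentiable operations.  Each op computes its value eagerly and registers
# a closure returning vector-Jacobian products w.r.t. its parents.  Binary ops
# are strict about shapes; broadcasting is explicit through tg_expand().

same_dims <- function(a, b) identical(dim(a$v), dim(b$v))

#' Elementwise tensor arithmetic
#'
#' `tg_add`, `tg_sub`, `tg_mul`, `tg_div` operate elementwise on tensors of
#' identical shape; the second argument of `tg_add`/`tg_sub` may also be a
#' plain scalar.  `tg_smul` multiplies by a plain scalar, `tg_scale` by a
#' scalar *tensor* (so the scalar also receives gradient).
#'
#' @param a,b `tg_tensor` operands (equal dims).
#' @param s scalar: plain numeric for `tg_smul`, length-1 `tg_tensor` for
#'   `tg_scale`.
#' @param x a `tg_tensor`.
#' @return a `tg_tensor`.
#' @name tensor-arith
NULL

#' @rdname tensor-arith
#' @export
tg_add <- function(a, b) {
  if (is.numeric(b) && length(b) == 1L) {
    return(tg_op(a$v + b, list(a), function(g) list(g)))
  }
  stopifnot(same_dims(a, b))
  tg_op(a$v + b$v, list(a, b), function(g) list(g, g))
}

#' @rdname tensor-arith
#' @export
tg_sub <- function(a, b) {
  if (is.numeric(b) && length(b) == 1L) {
    return(tg_op(a$v - b, list(a), function(g) list(g)))
  }
  stopifnot(same_dims(a, b))
  tg_op(a$v - b$v, list(a, b), function(g) list(g, -g))
}

#' @rdname tensor-arith
#' @export
tg_mul <- function(a, b) {
  stopifnot(same_dims(a, b))
  tg_op(a$v * b$v, list(a, b), function(g) list(g * b$v, g * a$v))
}

#' @rdname tensor-arith
#' @export
tg_div <- function(a, b) {
  stopifnot(same_dims(a, b))
  tg_op(a$v / b$v, list(a, b),
        function(g) list(g / b$v, -g * a$v / (b$v * b$v)))
}

#' @rdname tensor-arith
#' @export
tg_smul <- function(a, s) {
  stopifnot(is.numeric(s), length(s) == 1L)
  tg_op(a$v * s, list(a), function(g) list(g * s))
}

#' @rdname tensor-arith
#' @export
tg_scale <- function(x, s) {
  stopifnot(length(s$v) == 1L)
  sv <- as.numeric(s$v)
  tg_op(x$v * sv, list(x, s),
        function(g) list(g * sv, array(sum(g * x$v), dim = 1L)))
}

#' @rdname tensor-arith
#' @export
tg_neg <- function(a) tg_op(-a$v, list(a), function(g) list(-g))

#' Elementwise nonlinearities
#'
#' Rectified linear unit, logistic sigmoid, square root, square and
#' exponential, all elementwise and differentiable.
#'
#' @param x a `tg_tensor`.
#' @return a `tg_tensor` of the same shape.
#' @name tensor-nonlin
NULL

#' @rdname tensor-nonlin
#' @export
tg_relu <- function(x) {
  m <- x$v > 0
  tg_op(x$v * m, list(x), function(g) list(g * m))
}

#' @rdname tensor-nonlin
#' @export
tg_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  tg_op(s, list(x), function(g) list(g * s * (1 - s)))
}

#' @rdname tensor-nonlin
#' @export
tg_sqrt <- function(x) {
  s <- sqrt(x$v)
  tg_op(s, list(x), function(g) list(g * 0.5 / s))
}

#' @rdname tensor-nonlin
#' @export
tg_square <- function(x) tg_op(x$v * x$v, list(x), function(g) list(2 * g * x$v))

#' @rdname tensor-nonlin
#' @export
tg_exp <- function(x) {
  s <- exp(x$v)
  tg_op(s, list(x), function(g) list(g * s))
}

#' Reductions, reshaping and broadcasting
#'
#' `tg_sum` reduces to a scalar; `tg_mean_kd` averages over `dims` keeping
#' them as singletons; `tg_expand` broadcasts singleton dims up to `target`;
#' `tg_reshape` and `tg_aperm` are the differentiable counterparts of
#' `array()` re-dimensioning and `aperm()`.
#'
#' @param x a `tg_tensor`.
#' @param dims integer vector of dimensions to reduce.
#' @param target,newdim integer vector of target dimensions.
#' @param perm permutation of the dimension indices.
#' @return a `tg_tensor`.
#' @name tensor-shape
NULL

#' @rdname tensor-shape
#' @export
tg_sum <- function(x) {
  d <- dim(x$v)
  tg_op(array(sum(x$v), dim = 1L), list(x),
        function(g) list(array(as.numeric(g), dim = d)))
}

#' @rdname tensor-shape
#' @export
tg_mean_kd <- function(x, dims) {
  d <- dim(x$v)
  cnt <- prod(d[dims])
  tg_op(sum_keepdim(x$v, dims) / cnt, list(x),
        function(g) list(expand_to(g, d) / cnt))
}

#' @rdname tensor-shape
#' @export
tg_expand <- function(x, target) {
  d <- dim(x$v)
  red <- which(d == 1L & target > 1L)
  tg_op(expand_to(x$v, target), list(x),
        function(g) list(sum_keepdim(g, red)))
}

#' @rdname tensor-shape
#' @export
tg_reshape <- function(x, newdim) {
  d <- dim(x$v)
  stopifnot(prod(d) == prod(newdim))
  tg_op(array(x$v, dim = newdim), list(x),
        function(g) list(array(g, dim = d)))
}

#' @rdname tensor-shape
#' @export
tg_aperm <- function(x, perm) {
  tg_op(aperm(x$v, perm), list(x), function(g) list(aperm(g, order(perm))))
}

#' Matrix products, softmax, concatenation and slicing
#'
#' `tg_matmul` is the 2-d matrix product, `tg_t` the matrix transpose.
#' `tg_softmax_rows` applies a numerically stable softmax across each row of a
#' matrix.  `tg_concat`/`tg_slice` concatenate or index tensors along one
#' dimension.
#'
#' @param a,b matrix-shaped `tg_tensor`s.
#' @param x a `tg_tensor`.
#' @param xs list of `tg_tensor`s with equal dims except `along`.
#' @param along,idx dimension index and indices within it.
#' @return a `tg_tensor`.
#' @name tensor-linalg
NULL

#' @rdname tensor-linalg
#' @export
tg_matmul <- function(a, b) {
  av <- a$v; bv <- b$v
  tg_op(av %*% bv, list(a, b),
        function(g) list(g %*% t(bv), crossprod(av, g)))
}

#' @rdname tensor-linalg
#' @export
tg_t <- function(a) tg_op(t(a$v), list(a), function(g) list(t(g)))

#' @rdname tensor-linalg
#' @export
tg_softmax_rows <- function(x) {
  v <- x$v - apply(x$v, 1L, max)
  e <- exp(v)
  s <- e / rowSums(e)
  tg_op(s, list(x), function(g) list(s * (g - rowSums(g * s))))
}

#' @rdname tensor-linalg
#' @export
tg_concat <- function(xs, along) {
  vs <- lapply(xs, function(x) x$v)
  sizes <- vapply(vs, function(v) dim(v)[along], numeric(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  tg_op(acat(vs, along), xs, function(g) {
    lapply(seq_along(xs), function(i) {
      aslice(g, along, seq.int(starts[i], ends[i]))
    })
  })
}

#' @rdname tensor-linalg
#' @export
tg_slice <- function(x, along, idx) {
  d <- dim(x$v)
  tg_op(aslice(x$v, along, idx), list(x),
        function(g) list(ascatter(d, along, idx, g)))
}
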