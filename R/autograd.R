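# Minimal tape-based reverse-mode automatic differentiation over numeric
# arrays.  Every differentiable quantity is a `tg_tensor` node: an environment
# holding the value, the accumulated gradient, its parents and a vector-Jacobian
# closure.  Nodes are created in program order; backward() walks the implicit
# tape in reverse creation order.  This is deliberately small -- just the ops
# the segmentation network needs -- and every op is covered by finite-difference
# tests.

.tg <- new.env(parent = emptyenv())
.tg$count <- 0L
.tg$grad_on <- TRUE

new_node <- function(v, req = FALSE, parents = NULL, backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$grad <- NULL
  n$req <- req
  .tg$count <- .tg$count + 1L
  if (.tg$count >= 2147483000L) .tg$count <- 0L  # creation order only matters within one graph
  n$idx <- .tg$count
  n$parents <- parents
  n$backfn <- backfn
  class(n) <- "tg_tensor"
  n
}

#' Create an autodiff tensor
#'
#' Wraps a numeric array (or vector, promoted to a 1-d array) as a node of the
#' autodiff tape.  Tensors with `requires_grad = TRUE` are learnable
#' parameters: [tg_backward()] accumulates gradients into their `$grad` field.
#'
#' @param v numeric vector or array.
#' @param requires_grad should gradients be tracked for this tensor?
#' @return an object of class `tg_tensor` (an environment with fields `v`,
#'   `grad`, `req`).
#' @export
tg_tensor <- function(v, requires_grad = FALSE) {
  if (is.null(dim(v))) v <- array(as.numeric(v), dim = length(v))
  storage.mode(v) <- "double"
  new_node(v, req = requires_grad)
}

#' @rdname tg_tensor
#' @export
tg_param <- function(v) tg_tensor(v, requires_grad = TRUE)

is_node <- function(x) inherits(x, "tg_tensor")

#' @export
print.tg_tensor <- function(x, ...) {
  cat("<tg_tensor", paste(dim(x$v), collapse = "x"),
      if (x$req) "(grad)" else "", ">\n")
  invisible(x)
}

# Record an op on the tape (unless gradients are globally off or no parent
# requires them, in which case the result is a detached constant node).
tg_op <- function(v, parents, backfn) {
  if (.tg$grad_on && any(vapply(parents, function(p) p$req, logical(1)))) {
    new_node(v, req = TRUE, parents = parents, backfn = backfn)
  } else {
    new_node(v)
  }
}

#' Evaluate an expression without recording the autodiff tape
#'
#' Intermediate results inside `expr` are detached constants, so inference
#' passes keep no backward state and intermediates can be garbage collected.
#'
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
tg_no_grad <- function(expr) {
  old <- .tg$grad_on
  .tg$grad_on <- FALSE
  on.exit(.tg$grad_on <- old)
  expr
}

#' Reverse-mode backward pass
#'
#' Seeds the scalar `loss` node with gradient 1 and propagates vector-Jacobian
#' products through the tape in reverse creation order, accumulating gradients
#' on every reachable tensor with `requires_grad = TRUE`.
#'
#' @param loss a scalar (length-1) `tg_tensor`.
#' @return `loss`, invisibly.
#' @export
tg_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$v) == 1L)
  nodes <- vector("list", 256L)
  nn <- 0L
  stack <- list(loss)
  seen <- new.env(parent = emptyenv())
  while (length(stack) > 0L) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$idx)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    for (p in nd$parents) {
      if (p$req) stack[[length(stack) + 1L]] <- p
    }
  }
  nodes <- nodes[seq_len(nn)]
  ord <- order(vapply(nodes, function(n) n$idx, numeric(1)), decreasing = TRUE)
  loss$grad <- array(1, dim = dim(loss$v))
  for (i in ord) {
    nd <- nodes[[i]]
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      g <- gs[[j]]
      if (is.null(g) || !p$req) next
      if (is.null(dim(g))) g <- array(g, dim = dim(p$v))
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

#' Clear accumulated gradients on a set of parameters
#' @param params list of `tg_tensor` parameters.
#' @export
tg_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

## ---- plain-array helpers ---------------------------------------------------

# Broadcast an array with singleton dims up to `target`.
expand_to <- function(a, target) {
  da <- dim(a)
  stopifnot(length(da) == length(target), all(da == target | da == 1L))
  if (all(da == target)) return(a)
  idx <- lapply(seq_along(da), function(k) {
    if (da[k] == 1L && target[k] > 1L) rep(1L, target[k]) else seq_len(da[k])
  })
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Sum over the given dims, keeping them as singletons.
sum_keepdim <- function(a, dims) {
  d <- dim(a)
  for (k in dims) {
    if (d[k] == 1L) next
    nd <- length(d)
    perm <- c(k, seq_len(nd)[-k])
    s <- colSums(matrix(aperm(a, perm), nrow = d[k]))
    rest <- d[-k]
    d[k] <- 1L
    a <- aperm(array(s, dim = c(1L, rest)), order(perm))
  }
  a
}

# Concatenate arrays along one dim (all other dims equal).
acat <- function(arrays, along) {
  d <- dim(arrays[[1L]])
  nd <- length(d)
  perm <- c(seq_len(nd)[-along], along)
  mats <- lapply(arrays, function(a) {
    matrix(aperm(a, perm), nrow = prod(dim(a)[-along]))
  })
  m <- do.call(cbind, mats)
  total <- sum(vapply(arrays, function(a) dim(a)[along], numeric(1)))
  aperm(array(m, dim = c(d[-along], total)), order(perm))
}

# Take indices along one dim (keeping dims).
aslice <- function(a, along, idx) {
  ix <- lapply(dim(a), seq_len)
  ix[[along]] <- idx
  do.call(`[`, c(list(a), ix, list(drop = FALSE)))
}

# Place `g` into a zero array of dim `d` at `idx` along `along`.
ascatter <- function(d, along, idx, g) {
  z <- array(0, dim = d)
  ix <- lapply(d, seq_len)
  ix[[along]] <- idx
  do.call(`[<-`, c(list(z), ix, list(g)))
}
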