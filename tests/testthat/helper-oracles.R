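# Independent oracles used across the suite.  These deliberately use naive
# loops / set arithmetic so they share no code with the implementations they
# check.

# central-difference numeric gradient of scalar-valued f at array v
fd_grad <- function(f, v, eps = 1e-5) {
  g <- array(0, dim = dim(v))
  for (i in seq_along(v)) {
    vp <- v; vp[i] <- vp[i] + eps
    vm <- v; vm[i] <- vm[i] - eps
    g[i] <- (f(vp) - f(vm)) / (2 * eps)
  }
  g
}

# check implementation gradient of make_loss (node -> scalar node) at v
expect_grad_matches <- function(make_loss, v, tol = 1e-6) {
  x <- tg_param(v)
  tg_backward(make_loss(x))
  ng <- fd_grad(function(vv) as.numeric(make_loss(tg_tensor(vv))$v), v)
  expect_lt(max(abs(x$grad - ng)) / max(1, max(abs(ng))), tol)
}

# set-arithmetic segmentation metrics via explicit pixel sets
oracle_overlap <- function(a, p) {
  A <- which(a == 1)
  P <- which(p == 1)
  I <- length(intersect(A, P))
  list(dsc = if (length(A) + length(P) == 0) 1 else
         2 * I / (length(A) + length(P)),
       ji = if (length(union(A, P)) == 0) 1 else I / length(union(A, P)),
       rvd = if (length(A) == 0) NA_real_ else
         (length(P) - length(A)) / length(A))
}

# exhaustive pair-counting AUC: P(X1 > X0) with ties worth 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (x1 in pos) for (x0 in neg) {
    tot <- tot + if (x1 > x0) 1 else if (x1 == x0) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# brute-force batch/instance/layer statistics of a (H, W, C, N) array
oracle_norm_stats <- function(x) {
  d <- dim(x)
  C <- d[3]; N <- d[4]
  mu_in <- array(0, c(C, N)); var_in <- array(0, c(C, N))
  for (c in seq_len(C)) for (n in seq_len(N)) {
    v <- x[, , c, n]
    mu_in[c, n] <- mean(v)
    var_in[c, n] <- mean((v - mean(v))^2)
  }
  mu_bn <- numeric(C); var_bn <- numeric(C)
  for (c in seq_len(C)) {
    v <- x[, , c, ]
    mu_bn[c] <- mean(v)
    var_bn[c] <- mean((v - mean(v))^2)
  }
  mu_ln <- numeric(N); var_ln <- numeric(N)
  for (n in seq_len(N)) {
    v <- x[, , , n]
    mu_ln[n] <- mean(v)
    var_ln[n] <- mean((v - mean(v))^2)
  }
  list(mu_in = mu_in, var_in = var_in, mu_bn = mu_bn, var_bn = var_bn,
       mu_ln = mu_ln, var_ln = var_ln)
}

# apply a pure normalizer limit to x using oracle statistics
oracle_normalize <- function(x, kind, gamma = NULL, beta = NULL, eps = 1e-5) {
  st <- oracle_norm_stats(x)
  d <- dim(x)
  out <- array(0, dim = d)
  for (c in seq_len(d[3])) for (n in seq_len(d[4])) {
    mu <- switch(kind, bn = st$mu_bn[c], `in` = st$mu_in[c, n],
                 ln = st$mu_ln[n])
    v <- switch(kind, bn = st$var_bn[c], `in` = st$var_in[c, n],
                ln = st$var_ln[n])
    g <- if (is.null(gamma)) 1 else gamma[c]
    b <- if (is.null(beta)) 0 else beta[c]
    out[, , c, n] <- g * (x[, , c, n] - mu) / sqrt(v + eps) + b
  }
  out
}

random_mask <- function(h = 8, w = 8, p = 0.4) {
  matrix(rbinom(h * w, 1, p), h, w)
}

node_val <- function(x) x$v

# zero every learnable weight of a module in place
zero_module_params <- function(module) {
  for (p in collect_params(module)) p$v <- array(0, dim = dim(p$v))
  invisible(module)
}
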