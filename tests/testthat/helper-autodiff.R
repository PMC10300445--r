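# Independent reverse-mode autodiff oracle for the surrogate-gradient
# check. A tape of nodes is built while evaluating the network forward
# with the exact hard-threshold dynamics; the spike node carries the
# exponential surrogate exp(-2 x^2) as its custom vjp. Gradients are then
# obtained by generic reverse accumulation over the tape -- a mechanism
# deliberately different from the hand-derived BPTT recurrences in the
# package.

ad_tape <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env
}

ad_node <- function(tape, value, parents = list(), vjp = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$vjp <- vjp
  tape$nodes[[length(tape$nodes) + 1L]] <- nd
  nd
}

ad_const <- function(tape, v) ad_node(tape, v)
ad_param <- ad_const

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b),
          function(g) list(g, g))
}

# constant scalar * node
ad_smul <- function(tape, a, s) {
  ad_node(tape, s * a$value, list(a), function(g) list(s * g))
}

# elementwise product of two nodes
ad_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ad_node(tape, av * bv, list(a, b),
          function(g) list(g * bv, g * av))
}

ad_matmul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ad_node(tape, av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), crossprod(av, g)))
}

# mat scaled by the k-th component of a vector-valued node
ad_tapmul <- function(tape, mat, vec, k) {
  mv <- mat$value; w <- vec$value[k]
  ad_node(tape, w * mv, list(mat, vec),
          function(g) {
            dv <- numeric(length(vec$value))
            dv[k] <- sum(g * mv)
            list(w * g, dv)
          })
}

# hard threshold forward, surrogate derivative backward
ad_spike <- function(tape, vmid, theta) {
  x <- vmid$value - theta
  ad_node(tape, (x >= 0) + 0, list(vmid),
          function(g) list(g * exp(-2 * x^2)))
}

# value (1 - s) with pass-through gradient -g
ad_one_minus <- function(tape, s) {
  ad_node(tape, 1 - s$value, list(s), function(g) list(-g))
}

ad_backward <- function(tape, out, seed_grad) {
  for (nd in tape$nodes) nd$grad <- NULL
  out$grad <- seed_grad
  for (i in rev(seq_along(tape$nodes))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$vjp)) next
    pg <- nd$vjp(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      p$grad <- if (is.null(p$grad)) pg[[j]] else p$grad + pg[[j]]
    }
  }
}

# Forward + backward of an snn_network on a batch, fully on the tape.
# Returns loss and gradients named like snnwm's trainable parameter list.
ad_net_gradients <- function(net, spikes3, labels, loss = "cross_entropy",
                             detach_reset = FALSE) {
  tape <- ad_tape()
  B <- dim(spikes3)[1]; Tn <- net$T
  lif <- net$lif
  # parameter nodes
  W1n <- lapply(net$layers, function(l) ad_param(tape, l$W1))
  w2n <- lapply(net$layers, function(l) ad_param(tape, l$w2))
  Whn <- ad_param(tape, net$head$W)
  wtn <- ad_param(tape, net$head$w_time)
  # per-timestep input constants (B x Ni)
  Xt <- lapply(seq_len(Tn), function(t) {
    ad_const(tape, matrix(spikes3[, t, ], nrow = B))
  })
  for (l in seq_along(net$layers)) {
    P <- lapply(Xt, function(x) ad_matmul(tape, x, W1n[[l]]))
    # drive nodes per timestep
    It <- vector("list", Tn)
    if (net$mode == "classic") {
      It <- P
    } else if (net$mode == "overlap") {
      for (t in seq_len(Tn)) {
        acc <- NULL
        for (k in seq_along(net$layers[[l]]$w2)) {
          d <- k - 1L
          if (t - d < 1L) next
          term <- ad_tapmul(tape, P[[t - d]], w2n[[l]], k)
          acc <- if (is.null(acc)) term else ad_add(tape, acc, term)
        }
        It[[t]] <- acc
      }
    } else { # segment
      L <- net$mem_len
      for (m in seq_len(Tn %/% L) - 1L) {
        acc <- NULL
        for (p in seq_len(L)) {
          term <- ad_tapmul(tape, P[[m * L + p]], w2n[[l]], p)
          acc <- if (is.null(acc)) term else ad_add(tape, acc, term)
        }
        for (p in seq_len(L)) It[[m * L + p]] <- acc
      }
    }
    # LIF dynamics on the tape
    V <- ad_const(tape, matrix(lif$v_rest, B, ncol(net$layers[[l]]$W1)))
    St <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      vmid <- ad_add(tape, ad_smul(tape, V, lif$leak), It[[t]])
      s <- ad_spike(tape, vmid, lif$theta)
      St[[t]] <- s
      s_reset <- if (detach_reset) ad_const(tape, s$value) else s
      keep <- ad_mul(tape, vmid, ad_one_minus(tape, s_reset))
      V <- ad_add(tape, keep, ad_smul(tape, s_reset, lif$v_rest))
    }
    Xt <- St
  }
  Q <- lapply(Xt, function(s) ad_matmul(tape, s, Whn))
  logits <- NULL
  for (t in seq_len(Tn)) {
    term <- ad_tapmul(tape, Q[[t]], wtn, t)
    logits <- if (is.null(logits)) term else ad_add(tape, logits, term)
  }
  lo <- logits$value
  Y <- matrix(0, B, ncol(lo)); Y[cbind(seq_len(B), labels + 1L)] <- 1
  if (loss == "cross_entropy") {
    e <- exp(lo - apply(lo, 1, max)); pr <- e / rowSums(e)
    lval <- -mean(log(pr[cbind(seq_len(B), labels + 1L)]))
    dlogits <- (pr - Y) / B
  } else {
    lval <- sum((lo - Y)^2) / B
    dlogits <- 2 * (lo - Y) / B
  }
  ad_backward(tape, logits, dlogits)
  zero_if_null <- function(g, tmpl) if (is.null(g)) tmpl * 0 else g
  out <- list()
  for (l in seq_along(net$layers)) {
    out[[paste0("L", l, ".W1")]] <- zero_if_null(W1n[[l]]$grad, net$layers[[l]]$W1)
    if (net$mode != "classic") {
      out[[paste0("L", l, ".w2")]] <- as.numeric(zero_if_null(w2n[[l]]$grad,
                                                              net$layers[[l]]$w2))
    }
  }
  out[["head.W"]] <- zero_if_null(Whn$grad, net$head$W)
  if (net$readout == "fusion") {
    out[["head.w_time"]] <- as.numeric(zero_if_null(wtn$grad, net$head$w_time))
  }
  list(loss = lval, gradients = out)
}
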