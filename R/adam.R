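# Adam optimizer over nested parameter trees (lists of numeric arrays).
# Parameters, gradients, and moment estimates all share the same shape.

.tree_zero <- function(p) {
  if (is.list(p)) lapply(p, .tree_zero) else p * 0
}

.tree_add <- function(a, b) {
  if (is.list(a)) mapply(.tree_add, a, b, SIMPLIFY = FALSE) else a + b
}

.adam_init <- function(params) {
  list(m = .tree_zero(params), v = .tree_zero(params), t = 0L)
}

# returns list(params = updated tree, state = updated state)
.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  step_leaf <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(rec, p, g, m, v, SIMPLIFY = FALSE)
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      step_leaf(p, g, m, v)
    }
  }
  out <- rec(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}
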