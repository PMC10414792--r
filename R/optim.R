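# minimal Adam optimiser state shared by the CNN and embedding trainers

adam_state <- function(dim) {
  list(m = array(0, dim), v = array(0, dim))
}

adam_update <- function(state, grad, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad * grad
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(state = state, step = lr * mhat / (sqrt(vhat) + eps))
}
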