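#' Warmup learning-rate schedule
#'
#' The inverse-square-root schedule with linear warmup used for transformer
#' training: `model_dim^(-0.5) * min(step^(-0.5), step * warmup_steps^(-1.5))`.
#' The two branches meet at `step == warmup_steps`; the rate increases
#' linearly before the warmup point and decays as `step^(-0.5)` after it.
#'
#' @param model_dim Model dimension.
#' @param step Optimisation step (>= 1); vectorised.
#' @param warmup_steps Warmup length in steps (default 4000).
#' @return Positive learning rate(s).
#' @export
#' @examples
#' lr_at_step(32, 4000)  # peak: 32^-0.5 * 4000^-0.5
lr_at_step <- function(model_dim, step, warmup_steps = 4000) {
  if (any(step < 1)) stop("`step` must be >= 1", call. = FALSE)
  if (warmup_steps < 1) stop("`warmup_steps` must be >= 1", call. = FALSE)
  model_dim^(-0.5) * pmin(step^(-0.5), step * warmup_steps^(-1.5))
}

# Adam optimisation loop shared by the predictor and generator trainers.
#
# step_fn(par, idx)  -> list(loss, grad) on the minibatch rows `idx`
# eval_fn(par)       -> held-out loss (checkpoint selection, per epoch)
# lr_fn(step)        -> learning rate
# weight_decay       -> decoupled L2 penalty applied with the learning rate
#
# Runs under the caller's RNG state (shuffling; any stochastic step_fn
# internals such as dropout masks or conditioning draws). Returns the best
# checkpoint (lowest held-out loss) plus the per-epoch history.
train_adam <- function(par, step_fn, eval_fn, n, batch_size, epochs, lr_fn,
                       weight_decay = 0, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, verbose = FALSE) {
  m <- numeric(length(par))
  v <- numeric(length(par))
  step <- 0L
  best <- list(loss = Inf, par = par, epoch = 0L)
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    tr_loss <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + batch_size - 1, n)]
      step <- step + 1L
      res <- step_fn(par, idx)
      tr_loss[bi] <- res$loss
      g <- res$grad
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      lr <- lr_fn(step)
      par <- par - lr * ((m / (1 - beta1^step)) / (sqrt(v / (1 - beta2^step)) + eps) +
                         weight_decay * par)
    }
    held <- eval_fn(par)
    if (held < best$loss) best <- list(loss = held, par = par, epoch = ep)
    history[[ep]] <- tibble(epoch = ep, train_loss = mean(tr_loss),
                            held_out_loss = held)
    if (verbose)
      log_inform("epoch %d/%d: train %.4f, held-out %.4f", ep, epochs,
                 mean(tr_loss), held)
  }
  list(par = best$par, best_epoch = best$epoch, best_loss = best$loss,
       history = dplyr::bind_rows(history), final_par = par)
}
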