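#' Generator configuration
#'
#' Hyperparameters of the autoregressive peptide generator: a decoder-only
#' transformer (default 3 layers, model dimension 64, 6 attention heads,
#' batch size 128) trained with next-token cross-entropy under the
#' [lr_at_step()] warmup schedule. Each training sample is conditioned with
#' probability `conditional_fraction` (default 0.5) on its own cleavage
#' profile — the vector of panel Z-scores rounded to the nearest tenth,
#' injected through a learned linear map in place of the START token's
#' embedding — and otherwise starts from the plain START token, so one model
#' serves both unconditional and conditional sampling.
#'
#' @param n_layers,model_dim,n_heads Architecture (6 heads over 64
#'   dimensions run as 6 heads of width 10 with a projection back to 64).
#' @param batch_size,epochs,warmup_steps Optimisation.
#' @param conditional_fraction Per-sample probability of conditional
#'   training (0 disables the tag pathway).
#' @param max_generated_length Hard cap on sampled peptide length; sampling
#'   stops with a forced STOP there.
#' @param val_fraction Held-out fraction of the training data used for
#'   checkpoint selection (lowest held-out loss).
#' @param seed Master seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_layers = 3, model_dim = 64, n_heads = 6,
                             batch_size = 128, epochs = 50,
                             conditional_fraction = 0.5,
                             max_generated_length = 20, warmup_steps = 4000,
                             val_fraction = 0.1, seed = 1) {
  structure(
    list(n_layers = as.integer(n_layers), model_dim = as.integer(model_dim),
         n_heads = as.integer(n_heads), batch_size = as.integer(batch_size),
         epochs = as.integer(epochs),
         conditional_fraction = conditional_fraction,
         max_generated_length = as.integer(max_generated_length),
         warmup_steps = as.integer(warmup_steps),
         val_fraction = val_fraction, seed = as.integer(seed)),
    class = "generator_config"
  )
}

generator_cpp_cfg <- function(config, n_prot, scheme) {
  dh <- config$model_dim %/% config$n_heads
  list(V = as.integer(scheme$n_tokens), D = config$model_dim,
       H = config$n_heads, dh = as.integer(dh), L = config$n_layers,
       F = 4L * config$model_dim, M = as.integer(scheme$n_tokens),
       Mtag = as.integer(n_prot), causal = TRUE)
}

#' Train the conditional peptide generator
#'
#' Cross-entropy next-token training on the library's sequences. Conditioning
#' tags are the peptides' own Z-score rows rounded to the nearest tenth; each
#' sample is conditional with probability `conditional_fraction`, drawn
#' independently per sample and epoch. A random `val_fraction` of the library
#' is held out for checkpoint selection and never trained on.
#'
#' @param lib Library tibble; Z columns are required when
#'   `conditional_fraction > 0`.
#' @param config A [generator_config()].
#' @param proteases Panel; inferred when `NULL`.
#' @return A `peptide_generator` object.
#' @export
train_generator <- function(lib, config = generator_config(), proteases = NULL) {
  proteases <- infer_proteases(lib, proteases)
  if (length(proteases) == 0 && config$conditional_fraction > 0)
    stop("conditional training requires Z-score columns", call. = FALSE)
  scheme <- token_scheme("generator", max_length = max(nchar(lib$sequence)))
  tok <- token_matrix(lib$sequence, scheme)
  n <- nrow(tok$tokens)
  tags <- if (length(proteases)) round(zscore_matrix(lib, proteases), 1)
          else matrix(0, n, 1)
  cpp_cfg <- generator_cpp_cfg(config, max(1L, length(proteases)), scheme)
  n_conditional <- 0L
  fit <- with_seed(config$seed, {
    n_val <- max(1L, ceiling(config$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    va_use <- runif(length(val_idx)) < config$conditional_fraction
    par <- cpp_tf_init(cpp_cfg)
    step_fn <- function(par, idx) {
      rows <- tr_idx[idx]
      use_tag <- runif(length(rows)) < config$conditional_fraction
      n_conditional <<- n_conditional + sum(use_tag)
      cpp_dec_loss_grad(par, tok$tokens[rows, , drop = FALSE],
                        tok$lengths[rows], tags[rows, , drop = FALSE],
                        use_tag, cpp_cfg, TRUE)
    }
    eval_fn <- function(par) {
      cpp_dec_loss_grad(par, tok$tokens[val_idx, , drop = FALSE],
                        tok$lengths[val_idx], tags[val_idx, , drop = FALSE],
                        va_use, cpp_cfg, FALSE)$loss
    }
    train_adam(par, step_fn, eval_fn, n = length(tr_idx),
               batch_size = config$batch_size, epochs = config$epochs,
               lr_fn = function(step)
                 lr_at_step(config$model_dim, step, config$warmup_steps))
  })
  structure(
    list(par = fit$par, config = config, cpp_cfg = cpp_cfg,
         proteases = proteases, scheme = scheme, history = fit$history,
         best_epoch = fit$best_epoch, best_loss = fit$best_loss,
         n_params = length(fit$par), n_train = n,
         n_conditional_samples = n_conditional,
         train_length = max(nchar(lib$sequence))),
    class = "peptide_generator"
  )
}

#' @export
print.peptide_generator <- function(x, ...) {
  cat(sprintf("<peptide_generator> %d layers, dim %d, %s parameters; best epoch %d (loss %.3f)\n",
              x$config$n_layers, x$config$model_dim,
              format(x$n_params, big.mark = ","), x$best_epoch, x$best_loss))
  invisible(x)
}

#' Log-probability of peptides under the generator
#'
#' Sum over positions of the log conditional probability of each token given
#' its prefix (and the conditioning tag, if supplied), including the STOP
#' term; always <= 0.
#'
#' @param model A `peptide_generator`.
#' @param sequences Character vector of peptides.
#' @param tag Optional numeric conditioning profile (length = panel size).
#' @return Numeric vector of log-probabilities (nats).
#' @export
sequence_log_probability <- function(model, sequences, tag = NULL) {
  toks <- tokenize(validate_peptides(sequences), model$scheme)
  vapply(toks, function(tok) {
    n <- length(tok)
    logits <- cpp_dec_logits(model$par, tok[-n], tag, model$cpp_cfg)
    lp <- 0
    for (i in seq_len(n - 1)) {
      l <- logits[i, ]
      lp <- lp + l[tok[i + 1] + 1] - max(l) - log(sum(exp(l - max(l))))
    }
    lp
  }, numeric(1))
}

#' Repeat penalty on sampling logits
#'
#' Sign-aware scaling of the previous token's logit only (the CTRL
#' convention): positive logits are divided by the penalty and negative
#' logits multiplied by it, discouraging consecutive repeats of one residue.
#' `penalty = 1` is the identity.
#'
#' @param logits Numeric vector of next-token logits.
#' @param previous_token 1-based index of the previously sampled token in
#'   `logits`, or `NULL`/`NA` for none.
#' @param penalty Penalty factor >= 1 (default 1.2).
#' @return The adjusted logits.
#' @export
#' @examples
#' apply_repeat_penalty(c(2.4, 0.5), previous_token = 1, penalty = 1.2)
apply_repeat_penalty <- function(logits, previous_token, penalty = 1.2) {
  stopifnot(penalty >= 1)
  if (is.null(previous_token) || is.na(previous_token)) return(logits)
  l <- logits[previous_token]
  logits[previous_token] <- if (l > 0) l / penalty else l * penalty
  logits
}

#' Sample peptides from the generator
#'
#' Autoregressive ancestral sampling: tokens are drawn from
#' `softmax(logits / temperature)` with the repeat penalty applied to the
#' previously sampled residue, until STOP or `max_length` (where STOP is
#' forced and flagged). PAD and START are never sampled. Deterministic under
#' a fixed seed.
#'
#' @param model A `peptide_generator`.
#' @param n Number of sequences.
#' @param temperature Softmax temperature (> 0); 1 for unconditional
#'   sampling, 1.2 for conditional design runs.
#' @param repeat_penalty See [apply_repeat_penalty()].
#' @param tag Optional conditioning profile (numeric vector of panel
#'   Z-scores, rounded to tenths), or a matrix/tibble of profiles cycled
#'   over the `n` samples.
#' @param seed Integer seed.
#' @param max_length Cap on sampled length; default from the configuration.
#' @return Tibble: `sequence`, `length`, `forced_stop`, `conditional`.
#' @export
sample_peptides <- function(model, n, temperature = 1, repeat_penalty = 1.2,
                            tag = NULL, seed = 1, max_length = NULL) {
  stopifnot(temperature > 0)
  max_length <- max_length %||% model$config$max_generated_length
  v <- model$scheme$vocab
  start_tok <- v[["START"]]
  stop_tok <- v[["STOP"]]
  allowed <- c(setNames(1:20, AA_ALPHABET), STOP = stop_tok)  # sampleable tokens
  tags <- NULL
  if (!is.null(tag)) {
    tags <- if (is.matrix(tag) || is.data.frame(tag))
      as.matrix(tag) else matrix(tag, nrow = 1)
  }
  use_tag <- !is.null(tags)
  tag_mat <- if (use_tag) {
    tags[(seq_len(n) - 1) %% nrow(tags) + 1, , drop = FALSE]
  } else {
    matrix(0, n, max(1L, length(model$proteases)))
  }
  with_seed(seed, {
    # synchronous ancestral sampling: all unfinished sequences share a prefix
    # length, so each step is one batched forward pass
    prefixes <- matrix(start_tok, n, 1L)
    done <- logical(n)
    forced <- logical(n)
    toks <- matrix(NA_integer_, n, max_length)
    lens <- integer(n)
    for (t in seq_len(max_length)) {
      act <- which(!done)
      if (length(act) == 0) break
      logits <- cpp_dec_logits_batch(model$par,
                                     prefixes[act, , drop = FALSE],
                                     tag_mat[act, , drop = FALSE],
                                     !done[act] & use_tag, model$cpp_cfg)
      for (j in seq_along(act)) {
        i <- act[j]
        l <- logits[j, allowed + 1]
        if (lens[i] > 0)
          l <- apply_repeat_penalty(l, toks[i, lens[i]], repeat_penalty)
        p <- exp((l - max(l)) / temperature)
        p <- p / sum(p)
        pick <- sample.int(length(allowed), 1, prob = p)
        if (pick == length(allowed)) {       # STOP
          done[i] <- TRUE
        } else {
          lens[i] <- lens[i] + 1L
          toks[i, lens[i]] <- pick
        }
      }
      if (t == max_length) {
        forced[!done] <- TRUE
        break
      }
      prefixes <- cbind(prefixes, 0L)
      prefixes[!done, t + 1L] <- toks[!done, t]
    }
    seqs <- vapply(seq_len(n), function(i) {
      if (lens[i] == 0) "" else paste(AA_ALPHABET[toks[i, seq_len(lens[i])]],
                                      collapse = "")
    }, character(1))
    tibble(sequence = seqs, length = lens, forced_stop = forced,
           conditional = use_tag)
  })
}

#' Filter raw generations by length and train-set identity
#'
#' Removes sampled peptides whose length differs from the target register
#' and exact string matches to the training library, and reports the counts
#' of each removal class.
#'
#' @param peptides Tibble with a `sequence` column (or character vector).
#' @param length Target length (default 10).
#' @param train Training library tibble (or `NULL` to skip the exact-match
#'   filter).
#' @return A list: `peptides` (the retained tibble) and `report` (counts:
#'   `n_in`, `n_length_filtered`, `n_exact_filtered`, `n_out`,
#'   `n_forced_stop` when available).
#' @export
filter_generations <- function(peptides, length = 10, train = NULL) {
  if (!is.data.frame(peptides)) peptides <- tibble(sequence = peptides)
  n_in <- nrow(peptides)
  keep_len <- nchar(peptides$sequence) == length
  n_len <- sum(!keep_len)
  out <- peptides[keep_len, , drop = FALSE]
  n_exact <- 0L
  if (!is.null(train)) {
    exact <- out$sequence %in% train$sequence
    n_exact <- sum(exact)
    out <- out[!exact, , drop = FALSE]
  }
  report <- list(
    n_in = n_in, n_length_filtered = n_len, n_exact_filtered = n_exact,
    n_out = nrow(out),
    n_forced_stop = if ("forced_stop" %in% names(peptides))
      sum(peptides$forced_stop) else NA_integer_
  )
  log_inform("filtered generations: %d in, %d off-length, %d exact train matches, %d kept",
             report$n_in, report$n_length_filtered, report$n_exact_filtered,
             report$n_out)
  list(peptides = out, report = report)
}

#' Seed profiles for conditional generation
#'
#' Ranks a predicted library by target efficiency (`zhat` for the target) or
#' target selectivity (the selectivity score over the predicted profile) and
#' returns the top `k` cleavage profiles rounded to the nearest tenth, ready
#' to use as conditioning tags.
#'
#' @param predictions Tibble with `zhat_*` columns (from
#'   [predict.cleavage_ensemble()]), or a library tibble with Z columns.
#' @param target Target protease name.
#' @param objective `"efficiency"` or `"selectivity"`.
#' @param k Number of seed profiles (default 50).
#' @return Tibble of `k` rows, one column per protease (rounded profiles),
#'   with attribute `target`.
#' @export
conditional_seed_profiles <- function(predictions, target,
                                      objective = c("efficiency", "selectivity"),
                                      k = 50) {
  objective <- match.arg(objective)
  zhat <- if (any(startsWith(names(predictions), "zhat_")))
    score_matrix(predictions, prefix = "zhat_") else score_matrix(predictions)
  if (!target %in% colnames(zhat))
    stop(sprintf("target '%s' not in panel", target), call. = FALSE)
  if (k > nrow(zhat)) stop("`k` exceeds the library size", call. = FALSE)
  key <- if (objective == "efficiency") zhat[, target]
         else selectivity_score(zhat, target)
  ord <- order(key, decreasing = TRUE)[seq_len(k)]
  out <- as_tibble(round(zhat[ord, , drop = FALSE], 1))
  attr(out, "target") <- target
  attr(out, "objective") <- objective
  out
}

#' @exportS3Method generics::tidy
tidy.peptide_generator <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.peptide_generator <- function(x, ...) {
  tibble(n_layers = x$config$n_layers, model_dim = x$config$model_dim,
         n_params = x$n_params, n_train = x$n_train,
         best_epoch = x$best_epoch, best_held_out_loss = x$best_loss,
         conditional_fraction = x$config$conditional_fraction,
         n_conditional_samples = x$n_conditional_samples)
}
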