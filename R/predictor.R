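#' Predictor configuration
#'
#' Hyperparameters of the multi-output cleavage-score regressor. The default
#' transformer is a 2-layer encoder (model dimension 32, 6 attention heads,
#' batch size 64) trained with the warmup schedule of [lr_at_step()]; the
#' default bidirectional LSTM has 2 layers of hidden size 32 with dropout
#' 0.25 after each layer, batch size 32 and a constant learning rate of
#' 5e-3. Both use a 32-dimensional embedding and 70 epochs of Adam. With 6
#' heads over a 32-dimensional model, attention uses 6 heads of width 5
#' (internal width 30) with an output projection back to 32.
#'
#' @param backbone `"transformer"` or `"lstm"`.
#' @param n_layers,model_dim,n_heads,dropout,embedding_dim Architecture.
#' @param batch_size,epochs,lr_schedule,lr,warmup_steps Optimisation;
#'   `lr_schedule` is `"eq1_warmup"` (transformer default) or `"constant"`
#'   (LSTM default, rate `lr`).
#' @param val_fraction Fraction of the training data held out per ensemble
#'   member for checkpoint selection (default 0.2, an 80/20 resplit).
#' @param seed Master seed; member `k` trains under seed `seed + k`.
#' @return A `predictor_config` list.
#' @export
predictor_config <- function(backbone = c("transformer", "lstm"),
                             n_layers = 2, model_dim = 32, n_heads = 6,
                             dropout = 0.25, embedding_dim = 32,
                             batch_size = NULL, epochs = 70,
                             lr_schedule = NULL, lr = 5e-3,
                             warmup_steps = 4000, weight_decay = 1e-3,
                             val_fraction = 0.2, seed = 1) {
  backbone <- match.arg(backbone)
  batch_size <- batch_size %||% if (backbone == "transformer") 64L else 32L
  lr_schedule <- lr_schedule %||%
    if (backbone == "transformer") "eq1_warmup" else "constant"
  stopifnot(lr_schedule %in% c("eq1_warmup", "constant"))
  structure(
    list(backbone = backbone, n_layers = as.integer(n_layers),
         model_dim = as.integer(model_dim), n_heads = as.integer(n_heads),
         dropout = dropout, embedding_dim = as.integer(embedding_dim),
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         lr_schedule = lr_schedule, lr = lr,
         warmup_steps = as.integer(warmup_steps),
         weight_decay = weight_decay,
         val_fraction = val_fraction, seed = as.integer(seed)),
    class = "predictor_config"
  )
}

# C++-side config for one backbone
predictor_cpp_cfg <- function(config, n_prot, scheme) {
  if (config$backbone == "transformer") {
    dh <- config$model_dim %/% config$n_heads
    list(V = as.integer(scheme$n_tokens), D = config$model_dim,
         H = config$n_heads, dh = as.integer(dh),
         L = config$n_layers, F = 4L * config$model_dim,
         M = as.integer(n_prot), Mtag = 0L, causal = FALSE,
         dropout = config$dropout)
  } else {
    list(V = as.integer(scheme$n_tokens), De = config$embedding_dim,
         hid = config$model_dim, L = config$n_layers,
         M = as.integer(n_prot), dropout = config$dropout)
  }
}

lr_fn_for <- function(config) {
  if (config$lr_schedule == "eq1_warmup") {
    function(step) lr_at_step(config$model_dim, step, config$warmup_steps)
  } else {
    function(step) config$lr
  }
}

# Train one ensemble member on an internal train/validation resplit.
train_predictor_member <- function(tok, Z, config, cpp_cfg, member_seed) {
  n <- nrow(tok$tokens)
  with_seed(member_seed, {
    n_val <- max(1L, ceiling(config$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    tr_tok <- tok$tokens[tr_idx, , drop = FALSE]
    tr_len <- tok$lengths[tr_idx]
    tr_Z <- Z[tr_idx, , drop = FALSE]
    va_tok <- tok$tokens[val_idx, , drop = FALSE]
    va_len <- tok$lengths[val_idx]
    va_Z <- Z[val_idx, , drop = FALSE]
    is_tf <- config$backbone == "transformer"
    par <- if (is_tf) cpp_tf_init(cpp_cfg) else cpp_lstm_init(cpp_cfg)
    step_fn <- function(par, idx) {
      if (is_tf) {
        cpp_enc_loss_grad(par, tr_tok[idx, , drop = FALSE], tr_len[idx],
                          tr_Z[idx, , drop = FALSE], cpp_cfg, TRUE, TRUE)
      } else {
        cpp_lstm_loss_grad(par, tr_tok[idx, , drop = FALSE], tr_len[idx],
                           tr_Z[idx, , drop = FALSE], cpp_cfg, TRUE, TRUE)
      }
    }
    eval_fn <- function(par) {
      if (is_tf) {
        cpp_enc_loss_grad(par, va_tok, va_len, va_Z, cpp_cfg, FALSE)$loss
      } else {
        cpp_lstm_loss_grad(par, va_tok, va_len, va_Z, cpp_cfg, FALSE, FALSE)$loss
      }
    }
    fit <- train_adam(par, step_fn, eval_fn, n = length(tr_idx),
                      batch_size = config$batch_size, epochs = config$epochs,
                      lr_fn = lr_fn_for(config),
                      weight_decay = config$weight_decay)
    fit[c("par", "best_epoch", "best_loss", "history")]
  })
}

#' Train a cleavage-score predictor ensemble
#'
#' Trains `K` independent copies of the configured backbone, each on its own
#' random train/validation resplit of the input library, keeping for each
#' member the checkpoint with the lowest validation loss. At prediction time
#' the ensemble mean is the score estimate and the across-member standard
#' deviation is the uncertainty.
#'
#' @param lib Library tibble with Z-score columns (the training data).
#' @param config A [predictor_config()].
#' @param K Ensemble size (default 5).
#' @param proteases Panel columns; inferred when `NULL`.
#' @return A `cleavage_ensemble` object.
#' @export
train_predictor_ensemble <- function(lib, config = predictor_config(), K = 5,
                                     proteases = NULL) {
  proteases <- infer_proteases(lib, proteases)
  if (length(proteases) == 0) stop("library has no Z-score columns", call. = FALSE)
  if (nrow(lib) < 2) stop("need at least 2 training peptides", call. = FALSE)
  Z <- zscore_matrix(lib, proteases)
  if (any(!is.finite(Z))) stop("non-finite Z-scores in training data", call. = FALSE)
  scheme <- token_scheme("predictor", max_length = max(nchar(lib$sequence)))
  tok <- token_matrix(lib$sequence, scheme)
  cpp_cfg <- predictor_cpp_cfg(config, length(proteases), scheme)
  members <- lapply(seq_len(K), function(k) {
    log_inform("training ensemble member %d/%d (%s)", k, K, config$backbone)
    train_predictor_member(tok, Z, config, cpp_cfg,
                           member_seed = derive_seed(config$seed, k))
  })
  structure(
    list(members = members, config = config, cpp_cfg = cpp_cfg,
         proteases = proteases, scheme = scheme, K = K,
         n_params = length(members[[1]]$par), n_train = nrow(lib)),
    class = "cleavage_ensemble"
  )
}

#' @export
print.cleavage_ensemble <- function(x, ...) {
  cat(sprintf("<cleavage_ensemble> %s, K = %d, %d proteases, %s parameters/member\n",
              x$config$backbone, x$K, length(x$proteases),
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

#' Predict cleavage scores with uncertainty
#'
#' Deterministic inference (no dropout sampling): the returned `zhat_*`
#' columns are the across-member mean predictions and `sigma_*` the sample
#' standard deviation over the K members (zero when K = 1).
#'
#' @param object A `cleavage_ensemble`.
#' @param newdata Character vector of peptides, or a tibble with a
#'   `sequence` column.
#' @param ... Unused.
#' @return A tibble: `sequence`, then `zhat_<protease>` and
#'   `sigma_<protease>` columns.
#' @export
predict.cleavage_ensemble <- function(object, newdata, ...) {
  seqs <- if (is.data.frame(newdata)) newdata$sequence else newdata
  seqs <- validate_peptides(seqs)
  tok <- token_matrix(seqs, object$scheme)
  is_tf <- object$config$backbone == "transformer"
  preds <- lapply(object$members, function(m) {
    if (is_tf) {
      cpp_enc_predict(m$par, tok$tokens, tok$lengths, object$cpp_cfg)
    } else {
      cpp_lstm_predict(m$par, tok$tokens, tok$lengths, object$cpp_cfg)
    }
  })
  arr <- simplify2array(preds)                      # n x M x K
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  zhat <- apply(arr, c(1, 2), mean)
  sigma <- if (object$K > 1) apply(arr, c(1, 2), sd) else zhat * 0
  colnames(zhat) <- paste0("zhat_", object$proteases)
  colnames(sigma) <- paste0("sigma_", object$proteases)
  dplyr::bind_cols(tibble(sequence = seqs), as_tibble(zhat), as_tibble(sigma))
}

#' Evaluate predictions against true scores
#'
#' Per-protease mean absolute error, Pearson correlation, and ROC-AUC for
#' the binary task "true score >= Z_t" at each requested threshold.
#'
#' @param predictions Prediction tibble from [predict.cleavage_ensemble()]
#'   (or any tibble with `zhat_*` columns), or a numeric matrix.
#' @param truth Library tibble with Z columns, or numeric matrix, row-aligned
#'   with `predictions`.
#' @param thresholds Z-score thresholds for the classification view
#'   (default `c(0, 1, 1.5, 2, 2.5)`).
#' @param proteases Panel; inferred when `NULL`.
#' @return Long tibble: `protease`, `metric` (`mae`, `pearson_r`, `auc`),
#'   `z_threshold` (`NA` except for AUC rows), `value`. Thresholds that leave
#'   one class empty give `NA` AUC with a warning.
#' @export
evaluate_predictions <- function(predictions, truth,
                                 thresholds = c(0, 1, 1.5, 2, 2.5),
                                 proteases = NULL) {
  zhat <- score_matrix(predictions, prefix = "zhat_")
  proteases <- proteases %||% colnames(zhat)
  z <- score_matrix(truth, proteases = proteases)
  stopifnot(nrow(zhat) == nrow(z))
  rows <- list()
  for (p in proteases) {
    ph <- zhat[, p]
    pt <- z[, p]
    rows[[length(rows) + 1]] <- tibble(
      protease = p, metric = c("mae", "pearson_r"), z_threshold = NA_real_,
      value = c(mean(abs(ph - pt)), cor(ph, pt))
    )
    for (t in thresholds) {
      lab <- pt >= t
      auc <- if (length(unique(lab)) < 2) {
        warning(sprintf("AUC undefined for %s at Z_t = %g (single class)", p, t),
                call. = FALSE)
        NA_real_
      } else {
        as.numeric(pROC::auc(pROC::roc(factor(lab, levels = c(FALSE, TRUE)), ph,
                                       quiet = TRUE, direction = "<")))
      }
      rows[[length(rows) + 1]] <- tibble(protease = p, metric = "auc",
                                         z_threshold = t, value = auc)
    }
  }
  dplyr::bind_rows(rows)
}

#' @exportS3Method generics::tidy
tidy.cleavage_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$members, function(m, k) {
    dplyr::mutate(m$history, member = k, .before = 1)
  })
}

#' @exportS3Method generics::glance
glance.cleavage_ensemble <- function(x, ...) {
  tibble(
    backbone = x$config$backbone, K = x$K,
    n_params = x$n_params, n_train = x$n_train,
    epochs = x$config$epochs,
    best_held_out_loss = min(vapply(x$members, `[[`, numeric(1), "best_loss"))
  )
}
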