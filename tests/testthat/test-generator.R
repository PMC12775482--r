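# Generator mechanics on small models; the steering property at scale lives
# in test-acceptance.R.

tiny_gen_cfg <- function(...) {
  defaults <- list(n_layers = 1, model_dim = 12, n_heads = 2, batch_size = 16,
                   epochs = 10, warmup_steps = 30)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

# a generator whose logits are identically zero (uniform next-token law)
uniform_generator <- function(M = 2) {
  cfg <- tiny_gen_cfg()
  scheme <- token_scheme("generator")
  cpp_cfg <- cleavekit:::generator_cpp_cfg(cfg, M, scheme)
  par <- numeric(cleavekit:::cpp_tf_nparams(cpp_cfg))
  structure(list(par = par, config = cfg, cpp_cfg = cpp_cfg,
                 proteases = sprintf("P%02d", seq_len(M)), scheme = scheme,
                 n_params = length(par), train_length = 10L),
            class = "peptide_generator")
}

test_that("log-probabilities factorise and are uniform for a null model", {
  g <- uniform_generator()
  V <- g$scheme$n_tokens
  # zero parameters -> uniform over the V tokens at every position
  expect_equal(sequence_log_probability(g, "ACD"), 4 * log(1 / V))
  expect_equal(sequence_log_probability(g, "AAAAAAAAAA"), 11 * log(1 / V))
  expect_lte(sequence_log_probability(g, "PLGLAG"), 0)

  # summed log-probabilities equal the log of the product of stepwise terms
  withr::with_seed(1, g$par <- rnorm(length(g$par), sd = 0.3))
  lp <- sequence_log_probability(g, "PLGL")
  toks <- tokenize("PLGL", g$scheme)[[1]]
  step_p <- numeric(0)
  for (i in seq_len(length(toks) - 1)) {
    logits <- cleavekit:::cpp_dec_logits(g$par, toks[1:i], NULL, g$cpp_cfg)
    l <- logits[i, ]
    step_p <- c(step_p, exp(l[toks[i + 1] + 1]) / sum(exp(l)))
  }
  expect_equal(exp(lp), prod(step_p), tolerance = 1e-10)

  # total mass: STOP-first plus all length-1 continuations is at most 1
  start <- g$scheme$vocab[["START"]]
  stop_tok <- g$scheme$vocab[["STOP"]]
  l0 <- cleavekit:::cpp_dec_logits(g$par, start, NULL, g$cpp_cfg)[1, ]
  p0 <- exp(l0 - max(l0)); p0 <- p0 / sum(p0)
  mass <- p0[stop_tok + 1]
  for (x in 1:20) {
    lx <- cleavekit:::cpp_dec_logits(g$par, c(start, x), NULL, g$cpp_cfg)[2, ]
    px <- exp(lx - max(lx)); px <- px / sum(px)
    mass <- mass + p0[x + 1] * px[stop_tok + 1]
  }
  expect_lte(mass, 1)
  expect_gt(mass, 0)
})

test_that("repeat penalty rescales only the previous token's logit", {
  l <- c(2.4, -1, 0.5)
  expect_identical(apply_repeat_penalty(l, 1, penalty = 1), l)
  expect_equal(apply_repeat_penalty(l, 1, penalty = 1.2), c(2.0, -1, 0.5))
  expect_equal(apply_repeat_penalty(l, 2, penalty = 1.2), c(2.4, -1.2, 0.5))
  expect_identical(apply_repeat_penalty(l, NULL), l)

  # Monte-Carlo: penalised chains produce fewer immediate repeats
  base <- c(A = 1.5, B = 1.5)
  run_chain <- function(penalty, n = 10000) {
    prev <- 1L
    reps <- 0L
    for (i in seq_len(n)) {
      li <- apply_repeat_penalty(base, prev, penalty)
      p <- exp(li) / sum(exp(li))
      tok <- sample.int(2, 1, prob = p)
      reps <- reps + (tok == prev)
      prev <- tok
    }
    reps / n
  }
  withr::with_seed(2, {
    r_plain <- run_chain(1)
    r_pen <- run_chain(1.2)
  })
  expect_lt(r_pen, r_plain)
})

test_that("sampling is seeded, temperature-consistent and greedy in the cold limit", {
  g <- uniform_generator()
  withr::with_seed(3, g$par <- rnorm(length(g$par), sd = 0.4))

  s1 <- sample_peptides(g, 25, seed = 4)
  s2 <- sample_peptides(g, 25, seed = 4)
  expect_identical(s1, s2)
  expect_true(all(s1$length <= g$config$max_generated_length))
  expect_true(all(s1$forced_stop | s1$length < g$config$max_generated_length))

  # near-zero temperature reproduces greedy argmax decoding
  greedy <- function(model, max_len = 20) {
    v <- model$scheme$vocab
    allowed <- c(setNames(1:20, AA_ALPHABET), STOP = v[["STOP"]])
    prefix <- v[["START"]]
    prev <- NULL
    repeat {
      logits <- cleavekit:::cpp_dec_logits(model$par, prefix, NULL, model$cpp_cfg)
      l <- logits[nrow(logits), allowed + 1]
      if (!is.null(prev)) l <- apply_repeat_penalty(l, which(names(allowed) == prev), 1.2)
      pick <- names(allowed)[which.max(l)]
      if (pick == "STOP" || (length(prefix) - 1) >= max_len) break
      prefix <- c(prefix, allowed[[pick]])
      prev <- pick
    }
    paste(AA_ALPHABET[prefix[-1]], collapse = "")
  }
  cold <- sample_peptides(g, 3, temperature = 1e-9, seed = 5)
  expect_equal(unique(cold$sequence), greedy(g))

  # one-step empirical frequencies match softmax(logits / T) within 3 SE
  Tt <- 1.3
  n <- 30000
  draws <- sample_peptides(g, n, temperature = Tt, repeat_penalty = 1,
                           seed = 6, max_length = 1)
  first <- substr(draws$sequence, 1, 1)
  start <- g$scheme$vocab[["START"]]
  l0 <- cleavekit:::cpp_dec_logits(g$par, start, NULL, g$cpp_cfg)[1, ]
  allowed_idx <- c(2:21, g$scheme$vocab[["STOP"]] + 1)
  p <- exp((l0[allowed_idx] - max(l0[allowed_idx])) / Tt)
  p <- p / sum(p)
  names(p) <- c(AA_ALPHABET, "")
  obs <- as.numeric(table(factor(first, levels = c(AA_ALPHABET, ""))))
  for (j in seq_along(p)) {
    se <- sqrt(p[j] * (1 - p[j]) / n)
    expect_lt(abs(obs[j] / n - p[j]), 3 * se + 1e-6)
  }
})

test_that("conditioning pathway is exercised exactly as configured", {
  lib <- tiny_library(n = 60, M = 2, seed = 7)
  g0 <- suppressMessages(train_generator(lib, tiny_gen_cfg(conditional_fraction = 0,
                                                           epochs = 2, seed = 8)))
  expect_identical(g0$n_conditional_samples, 0L)

  g1 <- suppressMessages(train_generator(lib, tiny_gen_cfg(conditional_fraction = 1,
                                                           epochs = 2, seed = 8)))
  expect_gt(g1$n_conditional_samples, 0L)

  nolib <- peptide_library(random_peptides(10))
  expect_error(suppressMessages(train_generator(nolib, tiny_gen_cfg())),
               "Z-score")
})

test_that("the generator memorises a single repeated sequence", {
  lib <- peptide_library(rep("PLGLAGKKRA", 48), id = sprintf("r%02d", 1:48))
  lib$P1 <- rep(1, 48)
  cfg <- tiny_gen_cfg(epochs = 40, warmup_steps = 20, batch_size = 8,
                      conditional_fraction = 0, seed = 9, val_fraction = 0.1)
  g <- suppressMessages(train_generator(lib, cfg))
  # per-token cross-entropy well below log(2)
  expect_lt(g$best_loss, log(2))
  lp <- sequence_log_probability(g, "PLGLAGKKRA")
  expect_gt(lp / 11, log(0.5))
})

test_that("generation filtering removes off-length and train-identical peptides", {
  train <- peptide_library(c("AAAAAAAAAA", "CCCCCCCCCC"))
  gen <- tibble::tibble(sequence = c("AAAAAAAAA", "AAAAAAAAAA", "DDDDDDDDDD",
                                     "EEEEEEEEEEE"))
  fl <- suppressMessages(filter_generations(gen, length = 10, train = train))
  expect_identical(fl$peptides$sequence, "DDDDDDDDDD")
  expect_equal(fl$report$n_length_filtered, 2)
  expect_equal(fl$report$n_exact_filtered, 1)
  expect_equal(fl$report$n_in - fl$report$n_out,
               fl$report$n_length_filtered + fl$report$n_exact_filtered)

  # count conservation on random input
  withr::with_seed(10, {
    pool <- tibble::tibble(sequence = c(random_peptides(100, 10),
                                        random_peptides(30, 9),
                                        train$sequence))
  })
  fl2 <- suppressMessages(filter_generations(pool, length = 10, train = train))
  expect_equal(fl2$report$n_in - fl2$report$n_out,
               fl2$report$n_length_filtered + fl2$report$n_exact_filtered)
  expect_false(any(fl2$peptides$sequence %in% train$sequence))
})

test_that("seed profiles are the top-k rounded rows under the chosen objective", {
  withr::with_seed(11, {
    zhat <- matrix(rnorm(3000), 1000, 3,
                   dimnames = list(NULL, c("P01", "P02", "P03")))
    preds <- tibble::as_tibble(zhat)
    names(preds) <- paste0("zhat_", colnames(zhat))
  })
  # efficiency: top-k by target column, against a full-sort oracle
  sp <- conditional_seed_profiles(preds, "P02", "efficiency", k = 50)
  ord <- order(zhat[, "P02"], decreasing = TRUE)[1:50]
  expect_equal(as.matrix(sp), round(zhat[ord, ], 1), ignore_attr = TRUE)
  expect_true(all(abs(as.matrix(sp) * 10 - round(as.matrix(sp) * 10)) < 1e-9))

  # selectivity: dominant row wins at k = 1
  dom <- rbind(c(5, -1, -1), zhat)
  colnames(dom) <- colnames(zhat)
  preds2 <- tibble::as_tibble(dom)
  names(preds2) <- paste0("zhat_", colnames(dom))
  sp2 <- conditional_seed_profiles(preds2, "P01", "selectivity", k = 1)
  expect_equal(unname(as.numeric(sp2[1, ])), c(5, -1, -1))
  expect_error(conditional_seed_profiles(preds, "P01", k = 5000), "exceeds")
})
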