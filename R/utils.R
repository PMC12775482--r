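# Internal helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so seeded package functions do not perturb the
# user's random stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% .Machine$integer.max)
}

log_inform <- function(...) {
  message("INFO [cleavekit] ", sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Columns of a library/prediction tibble that are not per-protease scores.
RESERVED_COLS <- c("id", "sequence", "group", "provenance", "length",
                   "forced_stop", "conditional", "score", "rank")

# Infer the protease panel from a wide tibble: every non-reserved numeric
# column is treated as one protease's score column.
infer_proteases <- function(data, proteases = NULL) {
  if (!is.null(proteases)) return(proteases)
  cand <- setdiff(names(data), RESERVED_COLS)
  cand <- cand[vapply(data[cand], is.numeric, logical(1))]
  cand <- cand[!startsWith(cand, "sigma_") & !startsWith(cand, "zhat_")]
  cand
}

# Extract an n x M numeric score matrix from a tibble (protease columns),
# matrix, or named vector.
score_matrix <- function(x, proteases = NULL, prefix = NULL) {
  if (is.matrix(x)) {
    if (!is.null(proteases)) x <- x[, proteases, drop = FALSE]
    return(x)
  }
  if (is.numeric(x) && !is.null(names(x))) {
    return(matrix(x, nrow = 1, dimnames = list(NULL, names(x))))
  }
  if (is.data.frame(x)) {
    if (!is.null(prefix)) {
      cols <- names(x)[startsWith(names(x), prefix)]
      m <- as.matrix(x[cols])
      colnames(m) <- sub(paste0("^", prefix), "", cols)
      if (!is.null(proteases)) m <- m[, proteases, drop = FALSE]
      return(m)
    }
    proteases <- infer_proteases(x, proteases)
    m <- as.matrix(x[proteases])
    return(m)
  }
  stop("cannot interpret `x` as a score matrix", call. = FALSE)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || x <= 0 || x >= 1)
    stop(sprintf("`%s` must be a single number strictly between 0 and 1", name),
         call. = FALSE)
}
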