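#' Design objective for substrate nomination
#'
#' Efficiency designs are ranked by the uncertainty-aware cleavage score
#' `zhat - sigma`; selectivity designs are ranked by the predicted
#' selectivity score without any uncertainty filter. Both are then reduced
#' to pairwise-unique k-mers.
#'
#' @param target Target protease.
#' @param mode `"efficiency"` or `"selectivity"`.
#' @param n_nominees Substrates to nominate (default 24).
#' @param diversity_k k-mer length for the diversity filter (default 5).
#' @param uncertainty_aware Subtract sigma from the ranking score? Defaults
#'   to `TRUE` for efficiency, `FALSE` for selectivity.
#' @return A `design_objective` list.
#' @export
design_objective <- function(target, mode = c("efficiency", "selectivity"),
                             n_nominees = 24, diversity_k = 5,
                             uncertainty_aware = NULL) {
  mode <- match.arg(mode)
  structure(
    list(target = target, mode = mode, n_nominees = as.integer(n_nominees),
         diversity_k = as.integer(diversity_k),
         uncertainty_aware = uncertainty_aware %||% (mode == "efficiency")),
    class = "design_objective"
  )
}

#' Uncertainty-aware cleavage score
#'
#' `zhat - sigma` for the target protease: the ensemble prediction penalised
#' by one ensemble standard deviation.
#'
#' @param predictions Prediction tibble with `zhat_*` and `sigma_*` columns.
#' @param target Target protease.
#' @return Numeric vector.
#' @export
uncertainty_aware_score <- function(predictions, target) {
  zhat <- score_matrix(predictions, prefix = "zhat_")
  sigma <- score_matrix(predictions, prefix = "sigma_")
  if (!target %in% colnames(zhat))
    stop(sprintf("target '%s' not in panel", target), call. = FALSE)
  unname(zhat[, target] - sigma[, target])
}

#' Reduce a scored peptide set to globally unique k-mers
#'
#' Greedy pass in descending score order (ties broken lexicographically by
#' sequence): a peptide is kept only if none of its overlapping k-mers has
#' been claimed by an already-kept peptide; kept peptides claim all their
#' k-mers. The output therefore contains every k-mer at most once, and the
#' filter is idempotent.
#'
#' @param data Tibble with a `sequence` column.
#' @param score Tidy-selected score column used for ranking (defaults to a
#'   column named `score`), or a numeric vector.
#' @param k k-mer length (default 5).
#' @return The retained rows of `data`, in descending score order.
#' @export
kmer_diversity_filter <- function(data, score = NULL, k = 5) {
  if (!is.data.frame(data)) data <- tibble(sequence = data)
  s <- if (is.numeric(score)) score
       else if (is.character(score)) data[[score]]
       else data[["score"]] %||% rep(0, nrow(data))
  if (any(nchar(data$sequence) < k))
    stop(sprintf("all peptides must have length >= k = %d", k), call. = FALSE)
  ord <- order(-s, data$sequence, method = "radix")
  claimed <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(nrow(data))
  for (i in ord) {
    kms <- kmers_of(data$sequence[i], k)
    if (!any(vapply(kms, exists, logical(1), envir = claimed, inherits = FALSE))) {
      keep[i] <- TRUE
      for (km in kms) assign(km, TRUE, envir = claimed)
    }
  }
  data[ord[keep[ord]], , drop = FALSE]
}

# overlapping k-mers of one sequence
kmers_of <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character(0))
  substring(sequence, 1:(n - k + 1), k:n)
}

#' Site-independent baseline sampler
#'
#' Samples peptides position-by-position from the empirical per-position
#' amino-acid frequencies of a source set, ignoring all inter-position
#' dependence — the standard null model for sequence-design comparisons.
#'
#' @param source Library tibble or character vector of equal-length
#'   peptides.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Character vector of sampled peptides.
#' @export
site_independent_sample <- function(source, n, seed = 1) {
  seqs <- if (is.data.frame(source)) source$sequence else source
  if (length(seqs) == 0) stop("empty source set", call. = FALSE)
  L <- unique(nchar(seqs))
  if (length(L) != 1)
    stop("source peptides must have uniform length", call. = FALSE)
  chars <- do.call(rbind, strsplit(seqs, ""))
  with_seed(seed, {
    cols <- lapply(seq_len(L), function(i) {
      tab <- table(factor(chars[, i], levels = AA_ALPHABET))
      sample(AA_ALPHABET, n, replace = TRUE, prob = as.numeric(tab))
    })
    do.call(paste0, cols)
  })
}

#' Nominate substrates for synthesis
#'
#' The full nomination workflow: score a pool of generated peptides with the
#' objective's ranking score (uncertainty-aware target score for efficiency,
#' predicted selectivity for selectivity), reduce to unique k-mers, and take
#' the top `n_nominees`.
#'
#' @param generations Tibble of candidate peptides (a `sequence` column;
#'   other columns are carried through as provenance).
#' @param predictions Prediction tibble covering all candidates, row-aligned
#'   with `generations` (or with a matching `sequence` column).
#' @param objective A [design_objective()].
#' @return Tibble of nominees with `score`, `rank`, `zhat_<target>`,
#'   `sigma_<target>`, `selectivity_<target>` and provenance columns, in
#'   non-increasing score order. Warns when fewer than `n_nominees` survive.
#' @export
nominate <- function(generations, predictions, objective) {
  stopifnot(inherits(objective, "design_objective"))
  if ("sequence" %in% names(predictions) &&
      !identical(generations$sequence, predictions$sequence)) {
    predictions <- predictions[match(generations$sequence, predictions$sequence), ]
    if (anyNA(predictions$sequence))
      stop("predictions do not cover all generations", call. = FALSE)
  }
  tgt <- objective$target
  zhat <- score_matrix(predictions, prefix = "zhat_")
  sigma <- score_matrix(predictions, prefix = "sigma_")
  sel <- selectivity_score(zhat, tgt)
  s <- switch(objective$mode,
    efficiency = if (objective$uncertainty_aware)
      zhat[, tgt] - sigma[, tgt] else zhat[, tgt],
    selectivity = sel
  )
  pool <- generations
  pool$score <- s
  pool[[paste0("zhat_", tgt)]] <- zhat[, tgt]
  pool[[paste0("sigma_", tgt)]] <- sigma[, tgt]
  pool[[paste0("selectivity_", tgt)]] <- sel
  kept <- kmer_diversity_filter(pool, score = pool$score, k = objective$diversity_k)
  if (nrow(kept) < objective$n_nominees)
    warning(sprintf("only %d nominees survive the diversity filter (requested %d)",
                    nrow(kept), objective$n_nominees), call. = FALSE)
  out <- head(kept, objective$n_nominees)
  out$rank <- seq_len(nrow(out))
  out
}
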