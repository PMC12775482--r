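#' Levenshtein edit distance between peptides
#'
#' Standard unit-cost edit distance (insertions, deletions, substitutions),
#' computed with base R's generalised distance machinery. Vectorised over
#' both arguments: with two vectors it returns the full distance matrix.
#'
#' @param a,b Character vectors of sequences.
#' @return If both arguments have length 1, a single non-negative integer;
#'   otherwise the `length(a)` x `length(b)` integer distance matrix.
#' @export
#' @examples
#' levenshtein("PLGL", "PLGV")
levenshtein <- function(a, b) {
  d <- adist(a, b, costs = list(insertions = 1, deletions = 1, substitutions = 1))
  storage.mode(d) <- "integer"
  if (length(a) == 1 && length(b) == 1) d[1, 1] else d
}

#' Split a library into train and test sets
#'
#' Uniform random partition without replacement. The test set size is
#' `ceiling(test_fraction * n)` so an 80/20 split of 18,583 peptides yields a
#' 3,717-peptide test set.
#'
#' @param lib Library tibble.
#' @param test_fraction Fraction held out (strictly between 0 and 1).
#' @param seed Integer seed; the partition is deterministic given the seed.
#' @return A list with tibbles `train` and `test` (disjoint, exhaustive).
#' @export
split_train_test <- function(lib, test_fraction = 0.2, seed = 1) {
  assert_fraction(test_fraction, "test_fraction")
  n <- nrow(lib)
  if (n < 2) stop("need at least 2 peptides to split", call. = FALSE)
  n_test <- ceiling(test_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_test))
  list(train = lib[-idx, , drop = FALSE], test = lib[idx, , drop = FALSE])
}

#' Remove test peptides homologous to the training set
#'
#' Retains exactly the test peptides whose minimum Levenshtein distance to
#' any training peptide is at least `min_distance` (the screen-analysis
#' convention removes test sequences at distance < 3 from training).
#'
#' @param test,train Library tibbles.
#' @param min_distance Minimum edit distance to retain (>= 1).
#' @return The filtered test tibble; the number removed is reported.
#' @export
homology_filter <- function(test, train, min_distance = 3) {
  if (nrow(train) == 0) stop("training set is empty", call. = FALSE)
  stopifnot(min_distance >= 1)
  d <- adist(test$sequence, train$sequence)
  keep <- apply(d, 1, min) >= min_distance
  log_inform("homology filter removed %d / %d test peptides (distance < %d)",
             sum(!keep), nrow(test), min_distance)
  test[keep, , drop = FALSE]
}
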