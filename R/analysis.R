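#' Substrate register position labels
#'
#' Protease-substrate positions in Schechter-Berger nomenclature for an
#' even-length register centred on the scissile bond: for length 10,
#' `P5 P4 P3 P2 P1 P1' P2' P3' P4' P5'`.
#'
#' @param L Peptide length (even).
#' @return Character vector of position labels.
#' @export
position_labels <- function(L = 10) {
  h <- L / 2
  c(paste0("P", h:1), paste0("P", 1:h, "'"))
}

#' Position-specific amino-acid composition (IceLogo matrix)
#'
#' Per-position residue frequencies of a peptide set, optionally expressed
#' as fold change over a reference composition: `"natural"` divides by the
#' average amino-acid frequencies in nature ([NATURAL_AA_FREQS]), and
#' `"background"` by a user-supplied reference (e.g. the screen library's
#' composition). Reference frequencies are floored at a small pseudo
#' frequency so fold changes stay finite.
#'
#' @param peptides Character vector or library tibble (uniform length).
#' @param normalization `"raw"`, `"natural"` or `"background"`.
#' @param reference Named residue frequency vector (required for
#'   `"background"`); position-independent.
#' @param pseudo_freq Floor applied to reference frequencies.
#' @return An `icelogo` tibble: `position`, `position_label`, `residue`,
#'   `color_class`, `frequency`, and `fold_change` unless raw. Attributes
#'   record the normalisation and reference used.
#' @export
icelogo <- function(peptides, normalization = c("raw", "natural", "background"),
                    reference = NULL, pseudo_freq = 1e-4) {
  normalization <- match.arg(normalization)
  seqs <- if (is.data.frame(peptides)) peptides$sequence else peptides
  seqs <- validate_peptides(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("peptides must have uniform length", call. = FALSE)
  if (normalization == "background" && is.null(reference))
    stop("background normalisation needs a `reference` frequency table",
         call. = FALSE)
  ref <- switch(normalization,
    raw = NULL,
    natural = NATURAL_AA_FREQS,
    background = {
      r <- reference[AA_ALPHABET]
      names(r) <- AA_ALPHABET
      r[is.na(r)] <- 0
      r / sum(r)
    })
  if (!is.null(ref)) ref <- pmax(ref, pseudo_freq)
  chars <- do.call(rbind, strsplit(seqs, ""))
  labs <- if (L %% 2 == 0) position_labels(L) else as.character(seq_len(L))
  rows <- lapply(seq_len(L), function(i) {
    f <- as.numeric(table(factor(chars[, i], levels = AA_ALPHABET))) / length(seqs)
    out <- tibble(position = i, position_label = labs[i],
                  residue = AA_ALPHABET,
                  color_class = unname(AA_COLOR_CLASS[AA_ALPHABET]),
                  frequency = f)
    if (!is.null(ref)) out$fold_change <- f / unname(ref)
    out
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "normalization") <- normalization
  attr(out, "reference") <- ref
  class(out) <- c("icelogo", class(out))
  out
}

#' Write an IceLogo matrix as TSV
#'
#' Positions x residues, with a metadata comment header recording the
#' normalisation mode.
#'
#' @param logo An [icelogo()] tibble.
#' @param path Output path.
#' @param value `"frequency"` or `"fold_change"`.
#' @export
write_icelogo <- function(logo, path, value = c("frequency", "fold_change")) {
  value <- match.arg(value)
  wide <- tidyr::pivot_wider(logo[c("position_label", "residue", value)],
                             names_from = "residue",
                             values_from = dplyr::all_of(value))
  writeLines(sprintf("# icelogo normalization=%s value=%s",
                     attr(logo, "normalization"), value), path)
  readr::write_tsv(wide, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Position-wise Kullback-Leibler divergence between peptide sets
#'
#' KL(P || Q) per position in nats, with an additive pseudocount on residue
#' counts, plus the mean over the requested positions (e.g. the positions
#' flanking the scissile bond).
#'
#' @param p_set,q_set Peptide vectors or library tibbles of one common
#'   length.
#' @param positions Integer positions to average over (`NULL` = all).
#' @param alpha Additive pseudocount on counts (default 1).
#' @return List: `per_position` tibble (`position`, `kl`) and `mean_kl`.
#' @export
position_kl <- function(p_set, q_set, positions = NULL, alpha = 1) {
  p <- if (is.data.frame(p_set)) p_set$sequence else p_set
  q <- if (is.data.frame(q_set)) q_set$sequence else q_set
  if (length(p) == 0 || length(q) == 0) stop("empty peptide set", call. = FALSE)
  L <- unique(c(nchar(p), nchar(q)))
  if (length(L) != 1) stop("peptide sets must share one length", call. = FALSE)
  pc <- do.call(rbind, strsplit(p, ""))
  qc <- do.call(rbind, strsplit(q, ""))
  kl <- vapply(seq_len(L), function(i) {
    cp <- table(factor(pc[, i], levels = AA_ALPHABET)) + alpha
    cq <- table(factor(qc[, i], levels = AA_ALPHABET)) + alpha
    fp <- as.numeric(cp) / sum(cp)
    fq <- as.numeric(cq) / sum(cq)
    sum(fp * log(fp / fq))
  }, numeric(1))
  positions <- positions %||% seq_len(L)
  list(per_position = tibble(position = seq_len(L), kl = kl),
       mean_kl = mean(kl[positions]))
}

#' Census of overlapping k-mers
#'
#' Position-independent counts of all overlapping k-mers in a peptide set.
#'
#' @param peptides Peptide vector or library tibble.
#' @param k k-mer length.
#' @return Tibble `kmer`, `count`, sorted by descending count then k-mer.
#' @export
kmer_census <- function(peptides, k) {
  seqs <- if (is.data.frame(peptides)) peptides$sequence else peptides
  if (any(nchar(seqs) < k)) stop("k exceeds a peptide length", call. = FALSE)
  all_k <- unlist(lapply(seqs, kmers_of, k = k))
  tab <- sort(table(all_k), decreasing = TRUE)
  tibble(kmer = names(tab), count = as.integer(tab)) %>%
    dplyr::arrange(dplyr::desc(.data$count), .data$kmer)
}

#' Cumulative frequency curve of a k-mer census
#'
#' Unique k-mers sorted by descending count; the curve accumulates the
#' fraction of all k-mer occurrences covered by the top `rank` k-mers. It is
#' non-decreasing and ends at 1.
#'
#' @param census A [kmer_census()] tibble.
#' @return Tibble `rank`, `kmer`, `cumulative_fraction`.
#' @export
kmer_cdf <- function(census) {
  tibble(rank = seq_len(nrow(census)), kmer = census$kmer,
         cumulative_fraction = cumsum(census$count) / sum(census$count))
}

#' Shared and unique k-mers between two sets
#'
#' Partitions the union of two k-mer censuses into shared, A-only and B-only
#' fractions (of unique k-mers), with the top occurring k-mers of each
#' subset.
#'
#' @param census_a,census_b [kmer_census()] tibbles.
#' @param top Number of top k-mers to report per subset.
#' @return List: `fractions` tibble (`subset`, `n`, `fraction`) and
#'   `top_kmers` tibble (`subset`, `kmer`, `count`).
#' @export
shared_breakdown <- function(census_a, census_b, top = 3) {
  a <- census_a$kmer
  b <- census_b$kmer
  shared <- intersect(a, b)
  a_only <- setdiff(a, b)
  b_only <- setdiff(b, a)
  n_union <- length(shared) + length(a_only) + length(b_only)
  fractions <- tibble(
    subset = c("shared", "a_only", "b_only"),
    n = c(length(shared), length(a_only), length(b_only)),
    fraction = c(length(shared), length(a_only), length(b_only)) / n_union
  )
  counts <- function(kms, census) {
    d <- census[census$kmer %in% kms, ]
    head(d[order(-d$count, d$kmer), ], top)
  }
  comb <- dplyr::full_join(census_a, census_b, by = "kmer",
                           suffix = c("_a", "_b")) %>%
    dplyr::mutate(count = rowSums(cbind(.data$count_a, .data$count_b),
                                  na.rm = TRUE))
  top_kmers <- dplyr::bind_rows(
    dplyr::mutate(counts(shared, comb[c("kmer", "count")]), subset = "shared"),
    dplyr::mutate(counts(a_only, census_a), subset = "a_only"),
    dplyr::mutate(counts(b_only, census_b), subset = "b_only")
  )
  list(fractions = fractions, top_kmers = top_kmers[c("subset", "kmer", "count")])
}

#' Biophysical properties of peptides
#'
#' Standard sequence-derived indices: aliphatic index
#' `100 (f_A + 2.9 f_V + 3.9 (f_I + f_L))`, mean Kyte-Doolittle hydropathy,
#' Boman (protein-interaction) index as the mean residue solubility value,
#' net charge at a given pH by Henderson-Hasselbalch over an EMBOSS-style
#' pKa set, and isoelectric point by bisection to |charge| < 1e-4.
#'
#' @param peptides Peptide vector or library tibble.
#' @param ph pH for the net-charge column (default 7).
#' @return Tibble: `sequence`, `aliphatic_index`, `hydrophobicity`,
#'   `boman_index`, `net_charge`, `isoelectric_point`.
#' @export
biophysical_properties <- function(peptides, ph = 7) {
  seqs <- if (is.data.frame(peptides)) peptides$sequence else peptides
  seqs <- validate_peptides(seqs)
  if (any(nchar(seqs) == 0)) stop("empty sequence", call. = FALSE)
  rows <- lapply(seqs, function(s) {
    aa <- strsplit(s, "")[[1]]
    n <- length(aa)
    f <- function(x) sum(aa == x) / n
    tibble(
      sequence = s,
      aliphatic_index = 100 * (f("A") + 2.9 * f("V") + 3.9 * (f("I") + f("L"))),
      hydrophobicity = mean(KD_HYDROPATHY[aa]),
      boman_index = mean(BOMAN_SCALE[aa]),
      net_charge = peptide_charge(aa, ph),
      isoelectric_point = peptide_pi(aa)
    )
  })
  dplyr::bind_rows(rows)
}

peptide_charge <- function(aa, ph) {
  pos_pka <- c(PKA_SET$nterm, PKA_SET$positive[aa[aa %in% names(PKA_SET$positive)]])
  neg_pka <- c(PKA_SET$cterm, PKA_SET$negative[aa[aa %in% names(PKA_SET$negative)]])
  sum(1 / (1 + 10^(ph - pos_pka))) - sum(1 / (1 + 10^(neg_pka - ph)))
}

peptide_pi <- function(aa, tol = 1e-4) {
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    ch <- peptide_charge(aa, mid)
    if (abs(ch) < tol) return(mid)
    if (ch > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Cluster proteases by their activity profiles
#'
#' Builds the activity matrix of the union of each protease's top-scoring
#' substrates (scored across the whole panel) and clusters the protease
#' columns by average-linkage agglomeration on correlation distance
#' (1 - Pearson). Flat groups are cut either at a dissimilarity `h` or into
#' `k` groups.
#'
#' @param scores Wide tibble or matrix of substrate-by-protease scores
#'   (`zhat_*` prediction columns are recognised).
#' @param n_top Top substrates per protease entering the profile matrix
#'   (default 25).
#' @param k,h Flat-cut parameters passed to [stats::cutree()] (`k` groups
#'   by default 5 when neither is given).
#' @return An `activity_clust` list: `hclust`, `groups` (named integer
#'   vector), `profiles` (the substrate x protease matrix), `newick`.
#' @export
activity_clustering <- function(scores, n_top = 25, k = NULL, h = NULL) {
  z <- if (is.data.frame(scores) && any(startsWith(names(scores), "zhat_")))
    score_matrix(scores, prefix = "zhat_") else score_matrix(scores)
  if (ncol(z) < 2) stop("need at least 2 proteases to cluster", call. = FALSE)
  rows <- unique(unlist(lapply(seq_len(ncol(z)), function(j)
    order(z[, j], decreasing = TRUE)[seq_len(min(n_top, nrow(z)))])))
  prof <- z[rows, , drop = FALSE]
  const <- apply(prof, 2, sd) < 1e-12
  if (any(const))
    stop("constant activity column (correlation undefined) for: ",
         paste(colnames(prof)[const], collapse = ", "), call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(prof))
  hc <- stats::hclust(d, method = "average")
  if (is.null(k) && is.null(h)) k <- min(5, ncol(prof))
  groups <- stats::cutree(hc, k = k, h = h)
  structure(
    list(hclust = hc, groups = groups, profiles = prof,
         newick = ape::write.tree(ape::as.phylo(hc))),
    class = "activity_clust"
  )
}

#' @export
print.activity_clust <- function(x, ...) {
  cat(sprintf("<activity_clust> %d proteases, %d groups\n",
              length(x$groups), length(unique(x$groups))))
  print(split(names(x$groups), x$groups))
  invisible(x)
}
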