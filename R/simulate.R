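#' Build a synthetic protease panel
#'
#' Constructs a ground-truth cleavage model that mimics the statistical
#' structure of a panel-wide substrate screen: each protease scores a peptide
#' as a sum of position-specific residue preferences (a position-weight
#' matrix) plus subsite-cooperativity bonuses for specific contiguous k-mers
#' at specific start positions. Proteases are organised into families that
#' share a base position-weight matrix (plus small idiosyncratic deviations)
#' and share their cooperativity motifs, mirroring the shared substrate
#' preferences of protease subclasses. Exactly one designated protease
#' additionally carries a private motif shared with no other panel member, so
#' that selective substrate design against this panel has a known solution.
#'
#' @param M Number of proteases (default 18, the reference panel size).
#' @param L Substrate length (default 10).
#' @param n_families Number of protease families (default 5).
#' @param n_coop Family cooperativity motifs (default 5 per family).
#' @param coop_k Motif length (default 3; cleavage motifs in this field are
#'   typically tripeptides such as P-X-X).
#' @param noise_sd Gaussian observation noise added to raw scores when
#'   simulating a library (default 0.5).
#' @param w_sd,w_idio Spread of the family position-weight matrices and of
#'   the per-protease idiosyncratic deviation from the family matrix.
#' @param bonus_range,private_bonus Uniform range for family motif bonuses
#'   and the (stronger) private-motif bonus.
#' @param seed Integer seed; panels are deterministic given the seed.
#' @return An object of class `protease_panel`.
#' @export
#' @examples
#' panel <- build_panel(M = 6, n_families = 3, seed = 1)
#' panel$private_protease
build_panel <- function(M = 18, L = 10, n_families = 5, n_coop = 5, coop_k = 3,
                        noise_sd = 0.5, w_sd = 0.5, w_idio = 0.15,
                        bonus_range = c(1.5, 2.5), private_bonus = 3,
                        seed = 1) {
  if (M < 1 || L < 5 || n_families < 1 || n_families > M)
    stop("invalid panel geometry: need M >= 1, L >= 5, 1 <= n_families <= M",
         call. = FALSE)
  if (coop_k > L) stop("cooperativity k-mer longer than substrate", call. = FALSE)
  with_seed(seed, {
    proteases <- sprintf("P%02d", seq_len(M))
    family <- sort(rep_len(seq_len(n_families), M))
    names(family) <- proteases
    rand_kmer <- function() paste(sample(AA_ALPHABET, coop_k, replace = TRUE),
                                  collapse = "")
    # distinct motifs across the whole panel
    motifs <- character(0)
    draw_motif <- function() {
      repeat {
        m <- rand_kmer()
        if (!m %in% motifs) return(m)
      }
    }
    fam_W <- lapply(seq_len(n_families), function(f) {
      matrix(rnorm(L * 20, sd = w_sd), L, 20, dimnames = list(NULL, AA_ALPHABET))
    })
    fam_terms <- vector("list", n_families)
    for (f in seq_len(n_families)) {
      km <- character(n_coop)
      for (j in seq_len(n_coop)) { km[j] <- draw_motif(); motifs <- c(motifs, km[j]) }
      fam_terms[[f]] <- tibble(
        pos = sample.int(L - coop_k + 1, n_coop, replace = TRUE),
        kmer = km,
        bonus = runif(n_coop, bonus_range[1], bonus_range[2])
      )
    }
    W <- lapply(seq_len(M), function(m) {
      fam_W[[family[m]]] + matrix(rnorm(L * 20, sd = w_idio), L, 20)
    })
    names(W) <- proteases
    coop <- dplyr::bind_rows(lapply(seq_len(M), function(m) {
      dplyr::mutate(fam_terms[[family[m]]], protease = proteases[m], .before = 1)
    }))
    private_protease <- proteases[1]
    private_motif <- draw_motif()
    coop <- dplyr::bind_rows(coop, tibble(
      protease = private_protease,
      pos = sample.int(L - coop_k + 1, 1),
      kmer = private_motif,
      bonus = private_bonus
    ))
    structure(
      list(proteases = proteases, L = as.integer(L), W = W, coop = coop,
           family = family, noise_sd = noise_sd, coop_k = as.integer(coop_k),
           private_protease = private_protease, private_motif = private_motif,
           seed = as.integer(seed)),
      class = "protease_panel"
    )
  })
}

#' @export
print.protease_panel <- function(x, ...) {
  cat(sprintf("<protease_panel> %d proteases, L = %d, %d families\n",
              length(x$proteases), x$L, length(unique(x$family))))
  cat(sprintf("  private motif '%s' on %s; noise_sd = %g\n",
              x$private_motif, x$private_protease, x$noise_sd))
  invisible(x)
}

#' Ground-truth raw cleavage score
#'
#' The simulator's additive ground truth: position-weight contributions plus
#' cooperativity bonuses for each motif present at its designated start
#' position.
#'
#' @param panel A [build_panel()] object.
#' @param sequences Character vector of peptides of length `panel$L`.
#' @param protease A single protease name, or `NULL` for the full matrix.
#' @return Numeric vector (one protease) or matrix (peptides x proteases).
#' @export
true_score <- function(panel, sequences, protease = NULL) {
  stopifnot(inherits(panel, "protease_panel"))
  sequences <- validate_peptides(sequences)
  if (any(nchar(sequences) != panel$L))
    stop(sprintf("peptides must have length %d", panel$L), call. = FALSE)
  prots <- protease %||% panel$proteases
  chars <- do.call(rbind, strsplit(sequences, ""))
  idx <- matrix(match(chars, AA_ALPHABET), nrow = nrow(chars))
  out <- matrix(0, length(sequences), length(prots),
                dimnames = list(NULL, prots))
  for (p in prots) {
    Wm <- panel$W[[p]]
    s <- numeric(length(sequences))
    for (i in seq_len(panel$L)) s <- s + Wm[i, ][idx[, i]]
    terms <- panel$coop[panel$coop$protease == p, ]
    for (j in seq_len(nrow(terms))) {
      hit <- substr(sequences, terms$pos[j], terms$pos[j] + nchar(terms$kmer[j]) - 1) ==
        terms$kmer[j]
      s <- s + terms$bonus[j] * hit
    }
    out[, p] <- s
  }
  if (!is.null(protease) && length(protease) == 1) out[, 1] else out
}

#' Simulate a substrate library from a synthetic panel
#'
#' Draws peptides as a mixture of uniform-random background sequences and
#' sequences with one panel motif implanted at its designated position
#' (probability `motif_fraction`), scores them with the panel's ground truth
#' plus i.i.d. Gaussian noise, and standardises each protease column to mean
#' 0 and unit standard deviation — mirroring per-screen normalisation.
#' Columns with zero variance are mapped to all-zero scores with a warning.
#'
#' @param panel A [build_panel()] object.
#' @param n Number of peptides (>= 10).
#' @param motif_fraction Probability a peptide carries an implanted motif.
#' @param seed Integer seed.
#' @param calibration Optional calibration tibble (the `calibration`
#'   attribute of an earlier simulated library). When supplied, the new
#'   batch is standardised with that screen's per-protease mean and s.d.
#'   instead of its own — the way a follow-up batch is placed on an
#'   existing screen's Z scale — so its columns are not re-centred.
#' @return A library tibble with a `group` column (`background` or
#'   `motif:<kmer>`) and attributes `calibration` (per-protease mean/sd of
#'   the noisy raw scores, for scoring new peptides on the same scale via
#'   [true_zscores()]) and `panel`.
#' @export
simulate_library <- function(panel, n = 5000, motif_fraction = 0.3, seed = 1,
                             calibration = NULL) {
  stopifnot(inherits(panel, "protease_panel"))
  if (n < 10) stop("need n >= 10 to simulate a library", call. = FALSE)
  if (motif_fraction < 0 || motif_fraction > 1)
    stop("`motif_fraction` must be in [0, 1]", call. = FALSE)
  with_seed(seed, {
    L <- panel$L
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""), character(1))
    terms <- dplyr::distinct(panel$coop, .data$kmer, .data$pos)
    implant <- runif(n) < motif_fraction
    group <- rep("background", n)
    if (any(implant) && nrow(terms) > 0) {
      pick <- sample.int(nrow(terms), sum(implant), replace = TRUE)
      w <- which(implant)
      for (j in seq_along(w)) {
        km <- terms$kmer[pick[j]]
        substr(seqs[w[j]], terms$pos[pick[j]],
               terms$pos[pick[j]] + nchar(km) - 1) <- km
      }
      group[w] <- paste0("motif:", terms$kmer[pick])
    }
    raw <- true_score(panel, seqs)
    noisy <- raw + matrix(rnorm(length(raw), sd = panel$noise_sd), nrow(raw))
    if (is.null(calibration)) {
      mu <- colMeans(noisy)
      sdv <- apply(noisy, 2, sd)
      degenerate <- sdv < 1e-12
      if (any(degenerate)) {
        warning("zero-variance score column(s) mapped to all-zero Z: ",
                paste(colnames(noisy)[degenerate], collapse = ", "), call. = FALSE)
        sdv[degenerate] <- 1
        noisy[, degenerate] <- mu[degenerate][col(noisy[, degenerate, drop = FALSE])]
      }
    } else {
      stopifnot(all(calibration$protease == panel$proteases))
      mu <- calibration$mean
      sdv <- calibration$sd
    }
    Z <- sweep(sweep(noisy, 2, mu), 2, sdv, "/")
    lib <- peptide_library(seqs, Z = Z, group = group)
    attr(lib, "calibration") <- tibble(protease = panel$proteases,
                                       mean = unname(mu), sd = unname(sdv))
    attr(lib, "panel") <- panel
    log_inform("simulated %d peptides x %d proteases (motif fraction %.2f)",
               n, length(panel$proteases), motif_fraction)
    lib
  })
}

#' Score new peptides on a simulated library's Z scale
#'
#' Applies the panel ground truth to new peptides and standardises with the
#' calibration recorded when the library was simulated, giving the "true"
#' Z-score a peptide would have received in that screen (without observation
#' noise).
#'
#' @param panel A [build_panel()] object.
#' @param sequences Peptides of panel length.
#' @param calibration The `calibration` attribute of a [simulate_library()]
#'   result (or a compatible tibble with `protease`, `mean`, `sd`).
#' @return Matrix (peptides x proteases) of calibrated true Z-scores.
#' @export
true_zscores <- function(panel, sequences, calibration) {
  raw <- true_score(panel, sequences)
  stopifnot(all(calibration$protease == colnames(raw)))
  sweep(sweep(raw, 2, calibration$mean), 2, calibration$sd, "/")
}

#' Serialise a panel to JSON (and back)
#'
#' @param panel A [build_panel()] object.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  doc <- list(
    proteases = panel$proteases, L = panel$L,
    W = lapply(panel$W, function(m) as.data.frame(m)),
    coop = panel$coop, family = as.list(panel$family),
    noise_sd = panel$noise_sd, coop_k = panel$coop_k,
    private_protease = panel$private_protease,
    private_motif = panel$private_motif, seed = panel$seed
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- lapply(doc$W, function(d) {
    m <- as.matrix(d)
    colnames(m) <- AA_ALPHABET
    m
  })
  structure(
    list(proteases = doc$proteases, L = as.integer(doc$L), W = W[doc$proteases],
         coop = as_tibble(doc$coop), family = unlist(doc$family),
         noise_sd = doc$noise_sd, coop_k = as.integer(doc$coop_k),
         private_protease = doc$private_protease,
         private_motif = doc$private_motif, seed = as.integer(doc$seed)),
    class = "protease_panel"
  )
}
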