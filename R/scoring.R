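#' Substrate selectivity score
#'
#' Selectivity of a substrate for a target protease: its score for the
#' target minus the mean of its scores across the other `M - 1` panel
#' proteases,
#' \deqn{S_{s,m} = Z_{s,m} - \frac{1}{M-1}\sum_{i \ne m} Z_{s,i}.}
#' Applies equally to measured profiles, predicted profiles and corrected
#' efficiencies.
#'
#' @param x A score matrix (rows = substrates), a wide tibble with protease
#'   columns (`zhat_*` prediction columns are recognised), or a single named
#'   profile vector.
#' @param target Target protease name.
#' @param proteases Panel restriction; inferred when `NULL`.
#' @return Numeric vector of selectivity scores (one per row).
#' @export
#' @examples
#' selectivity_score(c(P1 = 2, P2 = 0, P3 = 0), "P1")
selectivity_score <- function(x, target, proteases = NULL) {
  z <- if (is.data.frame(x) && any(startsWith(names(x), "zhat_")))
    score_matrix(x, prefix = "zhat_") else score_matrix(x, proteases)
  if (ncol(z) < 2) stop("selectivity needs a panel of at least 2 proteases",
                        call. = FALSE)
  if (!target %in% colnames(z))
    stop(sprintf("target '%s' not in panel", target), call. = FALSE)
  others <- setdiff(colnames(z), target)
  unname(z[, target] - rowMeans(z[, others, drop = FALSE]))
}

#' Cleavage efficiencies from screen kinetics
#'
#' Reduces fluorogenic screen kinetics to per-substrate cleavage
#' efficiencies in \[0, 1\] for each protease. Replicates are averaged
#' first. The per-substrate activity readout is the endpoint fold change in
#' fluorescence (last over first timepoint) or the linear cleavage rate
#' (fluorescence units/min). A substrate is called cleaved when its readout
#' exceeds the no-enzyme control mean plus three standard deviations (when
#' control wells are present) or a fixed fold-change floor otherwise.
#' Efficiency is 0 for non-cleaved substrates, exactly 1 for the most active
#' substrate, and `FC_x / (FC_max - FC_minbar)` (clipped to \[0, 1\]) for
#' the rest, where `FC_minbar` is the mean readout of the non-cleaved
#' substrates (set `use_fc_min = FALSE` for the plain `FC_x / FC_max`
#' reading).
#'
#' @param kinetics Long tibble: `substrate`, `protease`, `replicate`,
#'   `time_min`, `fluorescence`. Rows whose `protease` equals
#'   `control_label` are treated as no-enzyme controls.
#' @param mode `"endpoint_fold_change"` or `"rate"`.
#' @param control_label Protease label marking no-enzyme control wells.
#' @param fc_floor Cleavage call floor used when no controls are present.
#' @param use_fc_min Subtract the mean non-cleaved readout in the
#'   denominator?
#' @return Tibble: `substrate`, `protease`, `activity`, `cleaved`,
#'   `efficiency`.
#' @export
efficiency_from_screen <- function(kinetics,
                                   mode = c("endpoint_fold_change", "rate"),
                                   control_label = "none", fc_floor = 1.2,
                                   use_fc_min = TRUE) {
  mode <- match.arg(mode)
  needed <- c("substrate", "protease", "replicate", "time_min", "fluorescence")
  if (!all(needed %in% names(kinetics)))
    stop("kinetics table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  per_rep <- kinetics %>%
    dplyr::group_by(.data$substrate, .data$protease, .data$replicate) %>%
    dplyr::arrange(.data$time_min, .by_group = TRUE) %>%
    dplyr::summarise(
      activity = if (mode == "endpoint_fold_change") {
        dplyr::last(.data$fluorescence) / dplyr::first(.data$fluorescence)
      } else {
        (dplyr::last(.data$fluorescence) - dplyr::first(.data$fluorescence)) /
          (dplyr::last(.data$time_min) - dplyr::first(.data$time_min))
      },
      .groups = "drop"
    )
  avg <- per_rep %>%
    dplyr::group_by(.data$substrate, .data$protease) %>%
    dplyr::summarise(activity = mean(.data$activity), .groups = "drop")
  controls <- avg[avg$protease == control_label, ]
  avg <- avg[avg$protease != control_label, ]
  cut <- if (nrow(controls) > 0) {
    mean(controls$activity) + 3 * sd(controls$activity)
  } else {
    if (mode == "rate") 0 else fc_floor
  }
  avg$cleaved <- avg$activity > cut
  out <- avg %>%
    dplyr::group_by(.data$protease) %>%
    dplyr::group_modify(function(d, key) {
      d$efficiency <- 0
      if (!any(d$cleaved)) {
        warning(sprintf("no cleaved substrates for %s; efficiencies all zero",
                        key$protease[1]), call. = FALSE)
        return(d)
      }
      fc_max <- max(d$activity[d$cleaved])
      fc_min <- if (use_fc_min && any(!d$cleaved)) mean(d$activity[!d$cleaved]) else 0
      denom <- fc_max - fc_min
      e <- d$activity / denom
      e <- pmin(pmax(e, 0), 1)
      e[!d$cleaved] <- 0
      e[d$cleaved & d$activity == fc_max] <- 1
      d$efficiency <- e
      d
    }) %>%
    dplyr::ungroup()
  out
}

#' Calibrate per-protease cleavage thresholds
#'
#' For each protease, finds the predicted-score cut that best separates
#' cleaved from non-cleaved substrates along the ROC — the operating point
#' maximising Youden's J (sensitivity + specificity - 1), with ties broken
#' at the midpoint of the optimal score interval. Proteases without both
#' classes (or absent from the data) receive the mean of the fitted
#' thresholds, flagged as imputed.
#'
#' @param data Long tibble: `protease`, `zhat`, `cleaved` (logical).
#' @param panel Full panel of proteases the table must cover; proteases not
#'   fittable from `data` are imputed. Defaults to those present.
#' @param low_j Warn when the best Youden's J is at or below this value.
#' @return A `threshold_table` tibble: `protease`, `threshold`, `imputed`,
#'   `youden_j`, `n_cleaved`, `n_noncleaved`.
#' @export
fit_cleavage_thresholds <- function(data, panel = NULL, low_j = 0.2) {
  stopifnot(all(c("protease", "zhat", "cleaved") %in% names(data)))
  panel <- panel %||% unique(data$protease)
  fit_one <- function(d) {
    s <- d$zhat
    y <- d$cleaved
    if (length(unique(y)) < 2) return(NULL)
    u <- sort(unique(s))
    cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
    j <- vapply(cand, function(t) {
      sens <- mean(s[y] > t)
      spec <- mean(s[!y] <= t)
      sens + spec - 1
    }, numeric(1))
    best <- which(j == max(j))
    # contiguous run of optimal cuts -> midpoint of the optimal interval
    run <- best[seq_len(which.max(c(diff(best) != 1, TRUE)))]
    lo <- if (run[1] == 1) u[1] - 1 else u[run[1] - 1]
    hi <- if (run[length(run)] == length(cand)) u[length(u)] + 1
          else u[run[length(run)]]
    list(threshold = (lo + hi) / 2, j = max(j),
         n_pos = sum(y), n_neg = sum(!y))
  }
  fitted <- list()
  for (p in intersect(panel, unique(data$protease))) {
    f <- fit_one(data[data$protease == p, ])
    if (!is.null(f)) fitted[[p]] <- f
  }
  if (length(fitted) == 0)
    stop("no protease has both cleaved and non-cleaved labels", call. = FALSE)
  mean_t <- mean(vapply(fitted, `[[`, numeric(1), "threshold"))
  rows <- lapply(panel, function(p) {
    if (p %in% names(fitted)) {
      f <- fitted[[p]]
      if (f$j <= low_j)
        warning(sprintf("low-confidence threshold for %s (Youden's J = %.2f)",
                        p, f$j), call. = FALSE)
      tibble(protease = p, threshold = f$threshold, imputed = FALSE,
             youden_j = f$j, n_cleaved = f$n_pos, n_noncleaved = f$n_neg)
    } else {
      tibble(protease = p, threshold = mean_t, imputed = TRUE,
             youden_j = NA_real_, n_cleaved = NA_integer_,
             n_noncleaved = NA_integer_)
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("threshold_table", class(out))
  out
}

#' Classify substrates as cleaved from predicted scores
#'
#' A substrate is called cleaved for a protease when its predicted score is
#' strictly greater than that protease's calibrated threshold.
#'
#' @param predictions Wide tibble with `zhat_*` columns (or a score matrix).
#' @param thresholds A [fit_cleavage_thresholds()] table.
#' @return Long tibble: `substrate` (row index or id), `protease`, `zhat`,
#'   `threshold`, `cleaved`.
#' @export
classify_cleaved <- function(predictions, thresholds) {
  zhat <- if (is.data.frame(predictions) && any(startsWith(names(predictions), "zhat_")))
    score_matrix(predictions, prefix = "zhat_") else score_matrix(predictions)
  miss <- setdiff(colnames(zhat), thresholds$protease)
  if (length(miss))
    stop("thresholds missing for: ", paste(miss, collapse = ", "), call. = FALSE)
  ids <- if (is.data.frame(predictions) && "id" %in% names(predictions))
    predictions$id else as.character(seq_len(nrow(zhat)))
  tmap <- setNames(thresholds$threshold, thresholds$protease)
  out <- as_tibble(zhat) %>%
    dplyr::mutate(substrate = ids, .before = 1) %>%
    tidyr::pivot_longer(-"substrate", names_to = "protease", values_to = "zhat") %>%
    dplyr::mutate(threshold = unname(tmap[.data$protease]),
                  cleaved = .data$zhat > .data$threshold)
  out
}

#' Sensitivity, specificity and accuracy of cleavage calls
#'
#' @param calls Tibble with logical columns `cleaved` (predicted) and
#'   `cleaved_true`, and a `protease` column.
#' @return Tibble per protease: `sensitivity`, `specificity`, `accuracy`.
#' @export
classification_metrics <- function(calls) {
  stopifnot(all(c("protease", "cleaved", "cleaved_true") %in% names(calls)))
  calls %>%
    dplyr::group_by(.data$protease) %>%
    dplyr::summarise(
      sensitivity = sum(.data$cleaved & .data$cleaved_true) /
        sum(.data$cleaved_true),
      specificity = sum(!.data$cleaved & !.data$cleaved_true) /
        sum(!.data$cleaved_true),
      accuracy = mean(.data$cleaved == .data$cleaved_true),
      .groups = "drop"
    )
}

#' Corrected cleavage efficiency from predicted scores
#'
#' Transforms predicted Z-scores into screen-calibrated efficiencies: for
#' each protease the threshold is subtracted, substrates at or below the
#' threshold get efficiency 0 (non-cleaved), and positive excesses are
#' scaled by the column's maximum excess, so the best-cleaved substrate per
#' protease scores exactly 1:
#' \deqn{\hat E_{s,m} = (\hat Z_{s,m} - T_m) / \max_s(\hat Z_{s,m} - T_m)}
#' when \eqn{\hat Z_{s,m} > T_m}, else 0.
#'
#' @param predictions Wide tibble with `zhat_*` columns, or a score matrix.
#' @param thresholds A [fit_cleavage_thresholds()] table.
#' @return Matrix (substrates x proteases) of corrected efficiencies.
#' @export
corrected_efficiency <- function(predictions, thresholds) {
  zhat <- if (is.data.frame(predictions) && any(startsWith(names(predictions), "zhat_")))
    score_matrix(predictions, prefix = "zhat_") else score_matrix(predictions)
  if (length(zhat) == 0) stop("empty score matrix", call. = FALSE)
  tmap <- setNames(thresholds$threshold, thresholds$protease)
  miss <- setdiff(colnames(zhat), names(tmap))
  if (length(miss))
    stop("thresholds missing for: ", paste(miss, collapse = ", "), call. = FALSE)
  E <- zhat
  for (p in colnames(zhat)) {
    excess <- zhat[, p] - tmap[[p]]
    pos <- excess > 0
    col <- numeric(nrow(zhat))
    if (any(pos)) col[pos] <- excess[pos] / max(excess[pos])
    E[, p] <- col
  }
  E
}

#' Corrected selectivity from corrected efficiencies
#'
#' The selectivity form applied to corrected efficiencies: target efficiency
#' minus the mean of the other proteases' efficiencies. Because corrected
#' efficiencies lie in \[0, 1\], the result is bounded in \[-1, 1\]; 1 means
#' uniquely cleaved by the target.
#'
#' @param E Corrected-efficiency matrix from [corrected_efficiency()] (or a
#'   wide tibble).
#' @param target Target protease.
#' @return Numeric vector per substrate.
#' @export
corrected_selectivity <- function(E, target) {
  selectivity_score(E, target)
}

#' Assign activity quadrants
#'
#' Splits substrates by efficiency and selectivity cuts (strict
#' inequalities define "high").
#'
#' @param efficiency,selectivity Numeric vectors.
#' @param e_cut,s_cut Quadrant cuts (defaults 0.4 and 2.4).
#' @return Factor with levels `low_eff_low_sel`, `low_eff_high_sel`,
#'   `high_eff_low_sel`, `high_eff_high_sel`.
#' @export
#' @examples
#' quadrant_assign(c(0.5, 0.4), c(3, 2.4))
quadrant_assign <- function(efficiency, selectivity, e_cut = 0.4, s_cut = 2.4) {
  he <- efficiency > e_cut
  hs <- selectivity > s_cut
  factor(
    dplyr::case_when(
      he & hs ~ "high_eff_high_sel",
      he & !hs ~ "high_eff_low_sel",
      !he & hs ~ "low_eff_high_sel",
      TRUE ~ "low_eff_low_sel"
    ),
    levels = c("low_eff_low_sel", "low_eff_high_sel",
               "high_eff_low_sel", "high_eff_high_sel")
  )
}

#' Read screen kinetics from CSV
#'
#' Long format: `substrate,protease,replicate,time_min,fluorescence`.
#'
#' @param path CSV path.
#' @return Kinetics tibble.
#' @export
read_kinetics <- function(path) {
  k <- readr::read_csv(path, col_types = readr::cols(
    substrate = readr::col_character(), protease = readr::col_character(),
    replicate = readr::col_character(), time_min = readr::col_double(),
    fluorescence = readr::col_double()), progress = FALSE)
  if (any(k$fluorescence < 0)) stop("negative fluorescence in ", path, call. = FALSE)
  log_inform("read %d kinetic measurements from %s", nrow(k), path)
  k
}
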