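#' Frequency of overlap between specific and nonspecific intensities
#'
#' The proportion of nonspecific reference samples whose amplification
#' intensity reaches or exceeds the minimum intensity observed among the
#' specific reference tissue samples.  0 means perfect separation, 1 means
#' every nonspecific sample overlaps the specific range.
#'
#' Missing intensities are treated as non-amplifying (0): overlap is a
#' detection-oriented statistic.
#'
#' @param specific numeric intensities of specific reference samples
#'   (nonempty).
#' @param nonspecific numeric intensities of nonspecific reference samples
#'   (nonempty).
#' @return A fraction in `[0, 1]`.
#' @export
frequency_of_overlap <- function(specific, nonspecific) {
  specific <- ifelse(is.na(specific), 0, specific)
  nonspecific <- ifelse(is.na(nonspecific), 0, nonspecific)
  if (length(specific) == 0L)
    stop("frequency of overlap is undefined without specific reference samples")
  if (length(nonspecific) == 0L)
    stop("no nonspecific reference samples supplied")
  mean(nonspecific >= min(specific))
}

#' Choose the scoring dye for a marker
#'
#' Each marker is read on two dyes (FAM and HEX).  The dye used for all
#' downstream statistics is picked from the per-dye frequencies of overlap:
#' if both are zero, one dye is picked at random (seeded R RNG); if exactly
#' one is zero, that dye is picked; otherwise the dye with the lower
#' frequency of overlap wins (ties at a positive overlap go to FAM for
#' determinism).
#'
#' @param freq_overlap_F,freq_overlap_H frequencies of overlap in `[0, 1]`
#'   for the FAM and HEX channels.
#' @return `"FAM"` or `"HEX"`.
#' @export
select_dye <- function(freq_overlap_F, freq_overlap_H) {
  stopifnot(freq_overlap_F >= 0, freq_overlap_F <= 1,
            freq_overlap_H >= 0, freq_overlap_H <= 1)
  if (freq_overlap_F == 0 && freq_overlap_H == 0)
    return(sample(c("FAM", "HEX"), 1L))
  if (freq_overlap_F == 0) return("FAM")
  if (freq_overlap_H == 0) return("HEX")
  if (freq_overlap_F <= freq_overlap_H) "FAM" else "HEX"
}

#' Two-sample (Welch) specificity t-test
#'
#' Two-sided Welch t-test comparing specific against nonspecific reference
#' intensities.  The sign convention is positive t when the specific mean
#' exceeds the nonspecific mean.
#'
#' @param specific,nonspecific numeric vectors, each of length >= 2
#'   (missing values removed first).
#' @return A list with `t_stat` and `p_value`.
#' @export
specificity_t_test <- function(specific, nonspecific) {
  specific <- specific[!is.na(specific)]
  nonspecific <- nonspecific[!is.na(nonspecific)]
  if (length(specific) < 2L || length(nonspecific) < 2L)
    stop("both groups need >= 2 observations; ",
         "with a single specific sample use one_sample_t_test()")
  tt <- stats::t.test(specific, nonspecific, var.equal = FALSE,
                      alternative = "two.sided")
  list(t_stat = unname(tt$statistic), p_value = tt$p.value)
}

#' One-sample specificity t-test
#'
#' Used when only one specific reference sample is available: two-sided
#' one-sample t-test of the nonspecific intensities against the single
#' specific value.  t is negative when the nonspecific mean falls below the
#' specific value.  Zero variance among the nonspecific samples yields
#' `t = -Inf` (or `+Inf`) with `p_value = 0` and `zero_variance = TRUE`.
#'
#' @param nonspecific numeric vector of length >= 2 (missing values
#'   removed).
#' @param specific_value the single specific reference intensity.
#' @return A list with `t_stat`, `p_value` and `zero_variance`.
#' @export
one_sample_t_test <- function(nonspecific, specific_value) {
  nonspecific <- nonspecific[!is.na(nonspecific)]
  if (length(nonspecific) < 2L)
    stop("need >= 2 nonspecific observations")
  if (stats::sd(nonspecific) == 0) {
    d <- mean(nonspecific) - specific_value
    t <- if (d == 0) 0 else sign(d) * Inf
    return(list(t_stat = t, p_value = if (d == 0) 1 else 0,
                zero_variance = TRUE))
  }
  tt <- stats::t.test(nonspecific, mu = specific_value,
                      alternative = "two.sided")
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       zero_variance = FALSE)
}

#' Benjamini-Yekutieli adjustment of p-values
#'
#' Step-up false-discovery-rate control valid under arbitrary dependence:
#' each rank-i p-value is multiplied by m * c(m) / i with
#' c(m) = sum(1/(1:m)), then cumulative minima are taken from the largest
#' rank down, capped at 1.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_p_values_BY <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BY")
}

#' Detect passive-reference (ROX) outlier samples
#'
#' Reactions with a near-absent ROX signal (e.g. dirt particles blocking
#' the chamber) distort dye intensities that are expressed relative to ROX,
#' so such samples are dropped.  A sample is an outlier when its ROX
#' intensity falls below `median(rox) - k_mad * mad(rox)`; the screen is
#' low-side only.
#'
#' @param rox named numeric vector of per-sample ROX intensities (>= 3
#'   samples).
#' @param k_mad MAD multiplier (default 3); `Inf` disables the screen.
#' @return Character vector of excluded sample ids (names of `rox`), empty
#'   when no outlier is found.
#' @export
detect_rox_outliers <- function(rox, k_mad = 3) {
  if (length(rox) < 3L) stop("need >= 3 samples to screen ROX outliers")
  if (!is.finite(k_mad)) return(character(0))
  cutoff <- stats::median(rox) - k_mad * stats::mad(rox)
  names(rox)[rox < cutoff]
}

#' Evaluate marker specificity on an intensity plate
#'
#' For every marker in the panel: drops ROX-outlier samples, computes the
#' frequency of overlap on both dyes between the marker's specific
#' reference tissues (samples of the target species) and its nonspecific
#' references (reference tissues of every other species), selects the
#' scoring dye, runs a Welch two-sample t-test (or a one-sample t-test when
#' only one specific sample is available), and finally applies a
#' Benjamini-Yekutieli adjustment jointly across all evaluated markers.
#' Separation is `min(specific) - max(nonspecific)` on the chosen dye.
#'
#' @param plate an [intensity_table()].
#' @param panel data frame with columns `marker_id` and `species` (e.g. a
#'   `panel_design`).
#' @param k_mad ROX-outlier MAD multiplier (default 3; `Inf` disables).
#' @param alpha significance level recorded for reporting (default 0.05).
#' @return A data frame of class `marker_evaluation` with one row per
#'   marker: per-dye overlap frequencies, `chosen_dye`, `t_stat`,
#'   `p_value`, `p_adjusted`, `min_specific`, `max_nonspecific`,
#'   `separation`, group sizes, `test` (`"welch"`, `"one_sample"` or
#'   `"none"`) and `evaluable`.  Attributes: `excluded_samples`, `alpha`.
#' @export
evaluate_markers <- function(plate, panel, k_mad = 3, alpha = 0.05) {
  stopifnot(inherits(plate, "intensity_table"))
  excluded <- plate_rox_outliers(plate, k_mad)
  pl <- plate[!plate$sample_id %in% excluded, , drop = FALSE]
  ref <- pl[pl$role %in% c("specific_reference", "nonspecific_reference"), ,
            drop = FALSE]
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    mk <- panel$marker_id[i]
    target <- panel$species[i]
    d <- ref[ref$marker_id == mk, , drop = FALSE]
    spec <- d[d$species == target, , drop = FALSE]
    nonspec <- d[d$species != target, , drop = FALSE]
    base <- data.frame(marker_id = mk, target_species = target,
                       stringsAsFactors = FALSE)
    if (nrow(spec) == 0L || nrow(nonspec) == 0L) {
      return(cbind(base, freq_overlap_F = NA_real_, freq_overlap_H = NA_real_,
                   chosen_dye = NA_character_, freq_overlap = NA_real_,
                   min_specific = NA_real_, max_nonspecific = NA_real_,
                   separation = NA_real_, t_stat = NA_real_,
                   p_value = NA_real_, n_specific = nrow(spec),
                   n_nonspecific = nrow(nonspec), test = "none",
                   evaluable = FALSE, stringsAsFactors = FALSE))
    }
    fo_F <- frequency_of_overlap(spec$I_F, nonspec$I_F)
    fo_H <- frequency_of_overlap(spec$I_H, nonspec$I_H)
    dye <- select_dye(fo_F, fo_H)
    sv <- ifelse(is.na(spec[[paste0("I_", substr(dye, 1, 1))]]), 0,
                 spec[[paste0("I_", substr(dye, 1, 1))]])
    nv <- ifelse(is.na(nonspec[[paste0("I_", substr(dye, 1, 1))]]), 0,
                 nonspec[[paste0("I_", substr(dye, 1, 1))]])
    sv_meas <- spec[[paste0("I_", substr(dye, 1, 1))]]
    nv_meas <- nonspec[[paste0("I_", substr(dye, 1, 1))]]
    sv_meas <- sv_meas[!is.na(sv_meas)]
    nv_meas <- nv_meas[!is.na(nv_meas)]
    if (length(sv_meas) >= 2L && length(nv_meas) >= 2L) {
      tt <- specificity_t_test(sv_meas, nv_meas)
      test <- "welch"
    } else if (length(sv_meas) == 1L && length(nv_meas) >= 2L) {
      tt <- one_sample_t_test(nv_meas, sv_meas)
      test <- "one_sample"
    } else {
      tt <- list(t_stat = NA_real_, p_value = NA_real_)
      test <- "none"
    }
    cbind(base, freq_overlap_F = fo_F, freq_overlap_H = fo_H,
          chosen_dye = dye,
          freq_overlap = if (dye == "FAM") fo_F else fo_H,
          min_specific = min(sv), max_nonspecific = max(nv),
          separation = min(sv) - max(nv),
          t_stat = tt$t_stat, p_value = tt$p_value,
          n_specific = nrow(spec), n_nonspecific = nrow(nonspec),
          test = test, evaluable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  ok <- out$evaluable & !is.na(out$p_value)
  out$p_adjusted[ok] <- adjust_p_values_BY(out$p_value[ok])
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted <= alpha
  rownames(out) <- NULL
  attr(out, "excluded_samples") <- excluded
  attr(out, "alpha") <- alpha
  class(out) <- c("marker_evaluation", "data.frame")
  out
}

#' @export
print.marker_evaluation <- function(x, ...) {
  cat("Marker evaluation:", nrow(x), "marker(s);",
      sum(x$significant), "significant at alpha =", attr(x, "alpha"),
      "(BY-adjusted)\n")
  ex <- attr(x, "excluded_samples")
  if (length(ex)) cat("ROX-outlier samples excluded:",
                      paste(ex, collapse = ", "), "\n")
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}

#' Rank markers and select the final panel
#'
#' Within each target species, markers are ordered by increasing frequency
#' of overlap on the chosen dye and then by decreasing separation between
#' the minimum specific and maximum nonspecific sample (stable sort).  The
#' best `n_keep` markers per species are retained; species left with fewer
#' than `min_markers_per_species` evaluable markers are reported in the
#' shortfall attribute.
#'
#' @param evaluations a [evaluate_markers()] result.
#' @param min_markers_per_species minimum panel size per species
#'   (default 4).
#' @param n_keep markers to keep per species (default
#'   `min_markers_per_species`); `NULL` keeps all evaluable markers.
#' @return A `marker_evaluation` data frame restricted and ordered to the
#'   final panel, with a `shortfall` attribute.
#' @export
rank_and_select <- function(evaluations, min_markers_per_species = 4,
                            n_keep = min_markers_per_species) {
  ev <- evaluations[evaluations$evaluable, , drop = FALSE]
  parts <- lapply(split(ev, ev$target_species), function(d) {
    d <- d[order(d$freq_overlap, -d$separation), , drop = FALSE]
    if (!is.null(n_keep)) d <- utils::head(d, n_keep)
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  n_av <- table(factor(out$target_species,
                       levels = unique(evaluations$target_species)))
  short <- names(n_av)[n_av < min_markers_per_species]
  attr(out, "shortfall") <- data.frame(
    species = short, n_available = as.integer(n_av[short]),
    min_required = rep(as.integer(min_markers_per_species), length(short)),
    stringsAsFactors = FALSE)
  attr(out, "alpha") <- attr(evaluations, "alpha")
  attr(out, "excluded_samples") <- attr(evaluations, "excluded_samples")
  class(out) <- c("marker_evaluation", "data.frame")
  out
}
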