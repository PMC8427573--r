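#' Per-marker detection baselines
#'
#' The detection threshold for a marker is the larger of a fixed floor
#' (0.2, an intensity indicating low amplification) and the highest
#' intensity observed on the marker's chosen dye among the nonspecific
#' reference tissues present in the same run.  Intensities at or below the
#' baseline are "not amplifying".  Markers without nonspecific references
#' in the run fall back to the floor and are flagged.
#'
#' @param plate an [intensity_table()] for one run.
#' @param panel data frame with columns `marker_id`, `species` and
#'   `chosen_dye` (from [evaluate_markers()]/[rank_and_select()], columns
#'   `target_species` accepted too).
#' @param floor baseline floor (default 0.2).
#' @param k_mad ROX-outlier MAD multiplier applied before taking maxima
#'   (default 3).
#' @return Data frame of class `marker_baselines`: `marker_id`, `species`,
#'   `dye`, `baseline`, `floor_fallback`.
#' @export
compute_baselines <- function(plate, panel, floor = 0.2, k_mad = 3) {
  stopifnot(inherits(plate, "intensity_table"), floor >= 0)
  panel <- .normalize_panel(panel)
  excluded <- plate_rox_outliers(plate, k_mad)
  pl <- plate[!plate$sample_id %in% excluded, , drop = FALSE]
  ref <- pl[pl$role %in% c("specific_reference", "nonspecific_reference"), ,
            drop = FALSE]
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    mk <- panel$marker_id[i]
    dye <- panel$chosen_dye[i]
    nonspec <- ref[ref$marker_id == mk & ref$species != panel$species[i], ,
                   drop = FALSE]
    v <- nonspec[[.dye_col(dye)]]
    v <- ifelse(is.na(v), 0, v)
    data.frame(marker_id = mk, species = panel$species[i], dye = dye,
               baseline = if (length(v)) max(floor, max(v)) else floor,
               floor_fallback = length(v) == 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "floor") <- floor
  attr(out, "excluded_samples") <- excluded
  class(out) <- c("marker_baselines", "data.frame")
  out
}

# accept either evaluate_markers output (target_species) or panel_design
# (species, no chosen_dye -> needs one) as a panel definition
.normalize_panel <- function(panel) {
  panel <- as.data.frame(panel)
  if (!"species" %in% names(panel) && "target_species" %in% names(panel))
    panel$species <- panel$target_species
  if (!all(c("marker_id", "species") %in% names(panel)))
    stop("panel needs columns 'marker_id' and 'species'")
  if (!"chosen_dye" %in% names(panel)) {
    if ("dye" %in% names(panel)) panel$chosen_dye <- panel$dye
    else stop("panel needs a 'chosen_dye' (or 'dye') column")
  }
  panel
}

#' Call amplifying markers for one sample
#'
#' A marker amplifies in a sample when its chosen-dye intensity is strictly
#' above the marker's baseline; an intensity equal to the baseline, a
#' missing well, or a missing marker counts as not amplifying.
#'
#' @param sample_intensities rows of an [intensity_table()] for one sample.
#' @param baselines a [compute_baselines()] result.
#' @return Data frame: `marker_id`, `species`, `intensity`, `baseline`,
#'   `amplifying`.
#' @export
call_sample <- function(sample_intensities, baselines) {
  idx <- match(baselines$marker_id, sample_intensities$marker_id)
  val <- vapply(seq_len(nrow(baselines)), function(i) {
    if (is.na(idx[i])) return(0)                    # missing -> not amplifying
    v <- sample_intensities[[.dye_col(baselines$dye[i])]][idx[i]]
    if (is.na(v)) 0 else v
  }, numeric(1))
  data.frame(marker_id = baselines$marker_id, species = baselines$species,
             intensity = val, baseline = baselines$baseline,
             amplifying = val > baselines$baseline, stringsAsFactors = FALSE)
}

#' Species presence under the minimum-k amplifying-marker rule
#'
#' A species is deemed present when at least one combination of `k` of its
#' panel markers all amplify.  The combinatorial check over all size-k
#' marker subsets is equivalent to simply requiring `n_amplifying >= k`;
#' both routes are implemented (`method`), and `detect_species()` with
#' `method = "combinations"` enumerates subsets explicitly.
#'
#' @param amplifying logical vector of per-marker amplification calls for
#'   one (sample, species) pair, or for `method = "count"` an integer
#'   `n_amplifying` is accepted too (with `n_markers`).
#' @param k minimum number of amplifying markers required (>= 1).
#' @param n_markers total markers carried for the species (needed when
#'   `amplifying` is a count).
#' @param method `"count"` (default) or `"combinations"`.
#' @return `TRUE`/`FALSE`; `k` larger than the species' panel gives `FALSE`
#'   with a warning.
#' @export
detect_species <- function(amplifying, k, n_markers = NULL,
                           method = c("count", "combinations")) {
  method <- match.arg(method)
  stopifnot(k >= 1)
  if (is.logical(amplifying)) {
    n_amp <- sum(amplifying)
    m <- length(amplifying)
  } else {
    if (method == "combinations")
      stop("the combinatorial check needs the per-marker logical vector")
    n_amp <- as.integer(amplifying)
    m <- if (is.null(n_markers)) n_amp else n_markers
  }
  if (k > m) {
    warning("k = ", k, " exceeds the ", m, " marker(s) carried; ",
            "species cannot be detected")
    return(FALSE)
  }
  if (method == "count") return(n_amp >= k)
  any(apply(utils::combn(length(amplifying), k), 2,
            function(ix) all(amplifying[ix])))
}

#' Build the species call matrix for a plate
#'
#' Applies [call_sample()] to every non-excluded sample and tabulates, per
#' (sample, species), the number of amplifying panel markers and the
#' presence call at each threshold k.  ROX-outlier samples are dropped from
#' the matrix (and hence from every downstream denominator).
#'
#' @param plate an [intensity_table()].
#' @param baselines a [compute_baselines()] result.
#' @param k integer thresholds (default `1:4`).
#' @param roles sample roles to call (default `"field_sample"`).
#' @param k_mad ROX-outlier MAD multiplier (default 3).
#' @return Data frame of class `species_call_matrix`: `sample_id`,
#'   `species`, `n_markers`, `n_amplifying`, and one logical
#'   `present_at_<k>` column per threshold.  Attributes: `k`,
#'   `excluded_samples`.
#' @export
call_species <- function(plate, baselines, k = 1:4,
                         roles = "field_sample", k_mad = 3) {
  stopifnot(inherits(plate, "intensity_table"), all(k >= 1))
  excluded <- plate_rox_outliers(plate, k_mad)
  pl <- plate[!plate$sample_id %in% excluded & plate$role %in% roles, ,
              drop = FALSE]
  samples <- unique(pl$sample_id)
  species <- unique(baselines$species)
  rows <- lapply(samples, function(s) {
    calls <- call_sample(pl[pl$sample_id == s, , drop = FALSE], baselines)
    n_amp <- tapply(calls$amplifying, calls$species, sum)
    n_mk <- tapply(calls$amplifying, calls$species, length)
    d <- data.frame(sample_id = s, species = species,
                    n_markers = as.integer(n_mk[species]),
                    n_amplifying = as.integer(n_amp[species]),
                    stringsAsFactors = FALSE)
    for (kk in k)
      d[[paste0("present_at_", kk)]] <- d$n_amplifying >= kk
    d
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character(0), species = character(0),
                      n_markers = integer(0), n_amplifying = integer(0))
  rownames(out) <- NULL
  attr(out, "k") <- as.integer(k)
  attr(out, "excluded_samples") <- excluded
  class(out) <- c("species_call_matrix", "data.frame")
  out
}

#' Negative-control QC
#'
#' Lists every (negative control, marker) pair whose chosen-dye intensity
#' exceeds the marker's baseline.  An empty result is a pass: the water
#' control never amplified.
#'
#' @param plate an [intensity_table()] containing >= 1 negative control
#'   (a warning is raised otherwise).
#' @param baselines a [compute_baselines()] result.
#' @return Data frame of class `nc_report` with columns `sample_id`,
#'   `marker_id`, `intensity`, `baseline`; attribute `pass`.
#' @export
verify_negative_controls <- function(plate, baselines) {
  nc <- plate[plate$role == "negative_control", , drop = FALSE]
  if (nrow(nc) == 0L) {
    warning("no negative control present on the plate")
    out <- data.frame(sample_id = character(0), marker_id = character(0),
                      intensity = numeric(0), baseline = numeric(0))
    attr(out, "pass") <- NA
    class(out) <- c("nc_report", "data.frame")
    return(out)
  }
  rows <- lapply(unique(nc$sample_id), function(s) {
    calls <- call_sample(nc[nc$sample_id == s, , drop = FALSE], baselines)
    bad <- calls[calls$amplifying, , drop = FALSE]
    if (nrow(bad) == 0L) return(NULL)
    data.frame(sample_id = s, marker_id = bad$marker_id,
               intensity = bad$intensity, baseline = bad$baseline,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character(0), marker_id = character(0),
                      intensity = numeric(0), baseline = numeric(0))
  rownames(out) <- NULL
  attr(out, "pass") <- nrow(out) == 0L
  class(out) <- c("nc_report", "data.frame")
  out
}

#' @export
print.nc_report <- function(x, ...) {
  p <- attr(x, "pass")
  if (isTRUE(p)) cat("Negative-control QC: PASS (no amplification)\n")
  else if (isFALSE(p)) {
    cat("Negative-control QC: FAIL,", nrow(x), "amplifying well(s)\n")
    print.data.frame(x, digits = 3)
  } else cat("Negative-control QC: no control present\n")
  invisible(x)
}

#' Summarize species detections across samples
#'
#' For each threshold k: the number and percentage of samples with at least
#' one detected species, and the mean and range of species per sample among
#' samples with a detection.  Per species: the frequency of occurrence, the
#' percentage of all analyzed samples in which the species was detected
#' (these can sum past 100% because a sample may contain several species).
#'
#' @param calls a [call_species()] result.
#' @return A list of class `detection_summary` with elements `n_samples`,
#'   `per_k` (data frame: `k`, `n_detected`, `pct_detected`,
#'   `mean_species`, `min_species`, `max_species`) and `per_species` (data
#'   frame of occurrence percentages per k).
#' @export
summarize_detections <- function(calls) {
  ks <- attr(calls, "k")
  samples <- unique(calls$sample_id)
  n <- length(samples)
  per_k <- do.call(rbind, lapply(ks, function(kk) {
    col <- paste0("present_at_", kk)
    nsp <- tapply(calls[[col]], calls$sample_id, sum)[samples]
    det <- nsp[nsp >= 1]
    data.frame(k = kk, n_detected = length(det),
               pct_detected = if (n) 100 * length(det) / n else 0,
               mean_species = if (length(det)) mean(det) else NA_real_,
               min_species = if (length(det)) min(det) else NA_integer_,
               max_species = if (length(det)) max(det) else NA_integer_)
  }))
  per_species <- do.call(rbind, lapply(unique(calls$species), function(sp) {
    d <- calls[calls$species == sp, , drop = FALSE]
    row <- data.frame(species = sp, stringsAsFactors = FALSE)
    for (kk in ks)
      row[[paste0("pct_k", kk)]] <-
        if (n) 100 * sum(d[[paste0("present_at_", kk)]]) / n else 0
    row
  }))
  structure(list(n_samples = n, per_k = per_k, per_species = per_species,
                 excluded_samples = attr(calls, "excluded_samples")),
            class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat("Detection summary over", x$n_samples, "sample(s)")
  if (length(x$excluded_samples))
    cat(" (", length(x$excluded_samples), " ROX outlier(s) excluded)", sep = "")
  cat("\n")
  for (i in seq_len(nrow(x$per_k))) {
    r <- x$per_k[i, ]
    cat(sprintf("  k >= %d: %d sample(s) (%.0f%%) with >= 1 species",
                r$k, r$n_detected, r$pct_detected))
    if (!is.na(r$mean_species))
      cat(sprintf("; mean %.1f species/sample (range %d-%d)",
                  r$mean_species, r$min_species, r$max_species))
    cat("\n")
  }
  invisible(x)
}
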