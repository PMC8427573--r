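#' Intensity table
#'
#' Per-well endpoint-PCR intensities: one row per (sample, marker) with the
#' FAM and HEX amplification intensities (expressed relative to the passive
#' ROX reference, dimensionless), the raw ROX intensity, and the sample's
#' role.  Roles: `specific_reference` / `nonspecific_reference` (tissue of
#' a known species; `species` says which), `negative_control` (water), or
#' `field_sample` (e.g. a scat of unknown content).
#'
#' @param df data frame with columns `sample_id`, `marker_id`, `I_F`,
#'   `I_H`, `rox`, `role`, `species` (NA for controls/field samples).
#' @return The validated data frame with class `intensity_table`.
#' @export
intensity_table <- function(df) {
  need <- c("sample_id", "marker_id", "I_F", "I_H", "rox", "role", "species")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  okroles <- c("specific_reference", "nonspecific_reference",
               "negative_control", "field_sample")
  bad <- setdiff(unique(df$role), okroles)
  if (length(bad)) stop("unknown sample roles: ", paste(bad, collapse = ", "))
  rpersample <- tapply(df$role, df$sample_id, function(r) length(unique(r)))
  if (any(rpersample > 1L))
    stop("samples with more than one role: ",
         paste(names(rpersample)[rpersample > 1L], collapse = ", "))
  if (any(df$I_F < 0, na.rm = TRUE) || any(df$I_H < 0, na.rm = TRUE))
    stop("dye intensities must be >= 0")
  df <- df[need]
  df$sample_id <- as.character(df$sample_id)
  df$marker_id <- as.character(df$marker_id)
  df$species <- as.character(df$species)
  df$role <- as.character(df$role)
  rownames(df) <- NULL
  class(df) <- c("intensity_table", "data.frame")
  df
}

#' @export
print.intensity_table <- function(x, ...) {
  cat("Intensity table:", length(unique(x$sample_id)), "sample(s) x",
      length(unique(x$marker_id)), "marker(s)\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$role[!duplicated(x$sample_id)])),
                                table(x$role[!duplicated(x$sample_id)])),
                        collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 3)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more row(s)\n")
  invisible(x)
}

#' Screen a plate for ROX-outlier samples
#'
#' Summarizes each sample's ROX signal as the median over its wells and
#' applies [detect_rox_outliers()].
#'
#' @param plate an [intensity_table()].
#' @param k_mad MAD multiplier (default 3; `Inf` disables the screen).
#' @return Character vector of excluded sample ids.
#' @export
plate_rox_outliers <- function(plate, k_mad = 3) {
  rox <- tapply(plate$rox, plate$sample_id, stats::median, na.rm = TRUE)
  if (length(rox) < 3L || !is.finite(k_mad)) return(character(0))
  detect_rox_outliers(rox, k_mad)
}

# chosen-dye intensity column lookup ("FAM" -> I_F)
.dye_col <- function(dye) paste0("I_", substr(dye, 1, 1))
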