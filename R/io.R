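#' Load a run configuration
#'
#' Reads a plain-text (YAML) key-value configuration, applies defaults,
#' rejects unknown keys and validates parameter ranges.
#'
#' @param path configuration file.
#' @param required character vector of keys (typically paths) that must be
#'   present; a missing one raises an error naming it.
#' @return A named list of class `run_config`.
#' @export
load_config <- function(path, required = character(0)) {
  defaults <- list(
    fasta_dir = NULL, species_map = NULL, plate = NULL, metadata = NULL,
    panel = NULL, out_dir = NULL,
    floor = 0.2, alpha = 0.05, k = 1:4, min_markers = 4,
    min_diagnosticity = 1, k_mad = 3, window_length = 15,
    seed = NULL, log_level = "info")
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("config file not found: ", path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  miss <- required[vapply(cfg[required], is.null, logical(1))]
  if (length(miss))
    stop("missing required configuration keys: ", paste(miss, collapse = ", "))
  if (cfg$floor < 0) stop("floor must be >= 0")
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("alpha must be in (0, 1]")
  if (any(cfg$k < 1)) stop("k thresholds must be >= 1")
  if (cfg$min_diagnosticity < 0 || cfg$min_diagnosticity > 1)
    stop("min_diagnosticity must be in [0, 1]")
  if (cfg$k_mad < 0) stop("k_mad must be >= 0")
  if (cfg$window_length < 1) stop("window_length must be >= 1")
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#' @param cfg a `run_config` (or plain named list).
#' @param path output file.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

.schema_version <- "1"

.header_lines <- function(seed = NULL, inputs = character(0)) {
  h <- paste0("# schema_version: ", .schema_version)
  if (!is.null(seed)) h <- c(h, paste0("# seed: ", seed))
  for (f in inputs)
    h <- c(h, sprintf("# md5 %s: %s", basename(f), unname(tools::md5sum(f))))
  h
}

# tab-separated writer with commented provenance header
.write_tsv <- function(df, path, seed = NULL, inputs = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_lines(seed, inputs), con)
  utils::write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.read_tsv <- function(path, required_cols) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  miss <- setdiff(required_cols, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write / read a marker panel TSV
#' @param panel data frame with at least `marker_id`, `species` (and
#'   `chosen_dye` once a dye is selected).
#' @param path TSV path.
#' @export
write_panel_tsv <- function(panel, path) .write_tsv(panel, path)

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  df <- .read_tsv(path, "marker_id")
  if (!"species" %in% names(df) && !"target_species" %in% names(df))
    stop(path, ": needs a 'species' (or 'target_species') column")
  df
}

#' Write a plate to long-format CSV
#'
#' One row per (sample, marker, channel) with channels FAM, HEX and ROX.
#'
#' @param plate an [intensity_table()].
#' @param plate_path CSV output for the intensities.
#' @param metadata_path optional TSV output for the sample metadata
#'   (`sample_id`, `role`, `species`).
#' @export
write_plate_csv <- function(plate, plate_path, metadata_path = NULL) {
  long <- rbind(
    data.frame(sample_id = plate$sample_id, marker_id = plate$marker_id,
               channel = "FAM", intensity = plate$I_F),
    data.frame(sample_id = plate$sample_id, marker_id = plate$marker_id,
               channel = "HEX", intensity = plate$I_H),
    data.frame(sample_id = plate$sample_id, marker_id = plate$marker_id,
               channel = "ROX", intensity = plate$rox))
  long <- long[order(long$sample_id, long$marker_id, long$channel), ]
  utils::write.csv(long, plate_path, row.names = FALSE, quote = FALSE)
  if (!is.null(metadata_path)) {
    meta <- unique(plate[, c("sample_id", "role", "species")])
    .write_tsv(meta, metadata_path)
  }
  invisible(plate_path)
}

#' Read a long-format plate CSV plus sample metadata
#'
#' The plate CSV has columns `sample_id`, `marker_id`, `channel` (FAM, HEX
#' or ROX) and `intensity`; the metadata TSV maps each `sample_id` to its
#' `role` and `species`.  Malformed rows are rejected with line-numbered
#' messages.
#'
#' @param plate_path plate CSV.
#' @param metadata_path metadata TSV.
#' @return An [intensity_table()].
#' @export
read_plate_csv <- function(plate_path, metadata_path) {
  raw <- utils::read.csv(plate_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("sample_id", "marker_id", "channel", "intensity")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop(plate_path, ": missing column(s): ", paste(miss, collapse = ", "))
  lineno <- seq_len(nrow(raw)) + 1L         # header is line 1
  badch <- !raw$channel %in% c("FAM", "HEX", "ROX")
  if (any(badch))
    stop(plate_path, ": invalid channel on line(s) ",
         paste(utils::head(lineno[badch], 5), collapse = ", "),
         " (expected FAM, HEX or ROX)")
  val <- suppressWarnings(as.numeric(raw$intensity))
  badv <- is.na(val) & !(is.na(raw$intensity) | raw$intensity %in% c("", "NA"))
  if (any(badv))
    stop(plate_path, ": non-numeric intensity on line(s) ",
         paste(utils::head(lineno[badv], 5), collapse = ", "))
  raw$intensity <- val
  key <- paste(raw$sample_id, raw$marker_id, sep = "\r")
  wide <- data.frame(key = unique(key), stringsAsFactors = FALSE)
  for (ch in c("FAM", "HEX", "ROX")) {
    sub <- raw[raw$channel == ch, ]
    wide[[ch]] <- sub$intensity[match(wide$key, paste(sub$sample_id,
                                                      sub$marker_id,
                                                      sep = "\r"))]
  }
  parts <- strsplit(wide$key, "\r", fixed = TRUE)
  meta <- .read_tsv(metadata_path, c("sample_id", "role", "species"))
  sid <- vapply(parts, `[`, character(1), 1L)
  m <- match(sid, meta$sample_id)
  if (anyNA(m))
    stop(metadata_path, ": no metadata for sample(s): ",
         paste(unique(sid[is.na(m)]), collapse = ", "))
  intensity_table(data.frame(
    sample_id = sid,
    marker_id = vapply(parts, `[`, character(1), 2L),
    I_F = wide$FAM, I_H = wide$HEX, rox = wide$ROX,
    role = meta$role[m], species = meta$species[m],
    stringsAsFactors = FALSE))
}

#' Write per-species FASTA alignments
#' @param aln a [species_alignment_set()].
#' @param dir output directory (one `<species>.fasta` per species).
#' @param map_path optional species-map TSV (`species_id`, `sequence_id`,
#'   `role`).
#' @return Named character vector of FASTA paths.
#' @export
write_species_fasta <- function(aln, dir, map_path = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  map <- list()
  for (sp in names(aln$sequences)) {
    ids <- sprintf("%s_seq%d", sp, seq_along(aln$sequences[[sp]]))
    ss <- Biostrings::BStringSet(aln$sequences[[sp]])
    names(ss) <- ids
    p <- file.path(dir, paste0(sp, ".fasta"))
    Biostrings::writeXStringSet(ss, p)
    paths[sp] <- p
    map[[sp]] <- data.frame(species_id = sp, sequence_id = ids,
                            role = unname(aln$roles[sp]),
                            stringsAsFactors = FALSE)
  }
  if (!is.null(map_path)) .write_tsv(do.call(rbind, map), map_path)
  paths
}

#' Write pipeline results
#'
#' Writes the calls TSV, the evaluations TSV and the summary JSON into
#' `out_dir`, each carrying the schema version, the seed and md5 checksums
#' of the declared inputs; output is byte-identical across reruns with the
#' same inputs and seed.
#'
#' @param calls a [call_species()] result (or `NULL`).
#' @param summary a [summarize_detections()] result (or `NULL`).
#' @param evaluations an [evaluate_markers()] result (or `NULL`).
#' @param out_dir output directory (created if needed).
#' @param seed the run seed, recorded in every output.
#' @param inputs character vector of input files to checksum.
#' @return Character vector of written paths.
#' @export
write_results <- function(calls = NULL, summary = NULL, evaluations = NULL,
                          out_dir, seed = NULL, inputs = character(0)) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  written <- character(0)
  if (!is.null(calls)) {
    p <- file.path(out_dir, "calls.tsv")
    .write_tsv(calls, p, seed = seed, inputs = inputs)
    written <- c(written, p)
  }
  if (!is.null(evaluations)) {
    p <- file.path(out_dir, "evaluations.tsv")
    .write_tsv(evaluations, p, seed = seed, inputs = inputs)
    written <- c(written, p)
  }
  if (!is.null(summary)) {
    p <- file.path(out_dir, "summary.json")
    payload <- list(
      schema_version = .schema_version,
      seed = seed,
      inputs = as.list(stats::setNames(
        as.character(tools::md5sum(inputs)), basename(inputs))),
      n_samples = summary$n_samples,
      excluded_samples = summary$excluded_samples,
      per_k = summary$per_k,
      per_species = summary$per_species)
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    written <- c(written, p)
  }
  written
}
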