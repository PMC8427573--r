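#' Find species-diagnostic alignment columns
#'
#' Screens every alignment column for loci that are fixed within the target
#' species and diagnostic against the background: a column qualifies when
#' (i) all target sequences carry the same unambiguous nucleotide (no gap,
#' no IUPAC ambiguity), and (ii) the fraction of other species whose
#' observed alleles exclude that nucleotide is at least `min_diagnosticity`.
#'
#' A background species counts as *sharing* the target allele if any of its
#' sequences can carry it; IUPAC ambiguity codes are expanded to every
#' nucleotide they denote, so ambiguity in the background is treated
#' conservatively (it reduces diagnosticity).  Gaps never share.
#'
#' @param aln a [species_alignment_set()].
#' @param target species id to design markers for; all other species in
#'   `aln` form the background set.
#' @param min_diagnosticity minimum fraction (in `[0, 1]`) of background
#'   species that must lack the target allele.  `1` (default) demands a
#'   fully diagnostic site.
#' @return A data frame of class `diagnostic_loci`, sorted by position, with
#'   columns `target_species`, `position` (1-based alignment column),
#'   `ungapped_position` (coordinate in the first target sequence with gaps
#'   removed), `target_allele`, `diagnosticity`, `fully_diagnostic`,
#'   `conspecific_fixed` (always `TRUE` for emitted loci).
#' @export
find_diagnostic_sites <- function(aln, target, min_diagnosticity = 1) {
  stopifnot(inherits(aln, "species_alignment_set"))
  if (!target %in% names(aln$sequences))
    stop("target species '", target, "' not present in the alignment set")
  if (min_diagnosticity < 0 || min_diagnosticity > 1)
    stop("min_diagnosticity must be in [0, 1]")
  background <- setdiff(names(aln$sequences), target)
  if (length(background) == 0L)
    stop("no background species present; diagnosticity is undefined")
  L <- aln$length
  empty <- data.frame(
    target_species = character(0), position = integer(0),
    ungapped_position = integer(0), target_allele = character(0),
    diagnosticity = numeric(0), fully_diagnostic = logical(0),
    conspecific_fixed = logical(0), stringsAsFactors = FALSE
  )
  if (L == 0L) return(structure(empty, class = c("diagnostic_loci", "data.frame")))

  tm <- .seq_matrix(aln$sequences[[target]])
  # column fixed in target: all identical and a plain A/C/G/T
  fixed_allele <- apply(tm, 2, function(col) {
    u <- unique(col)
    if (length(u) == 1L && u %in% c("A", "C", "G", "T")) u else NA_character_
  })
  # per background species: can any sequence carry a given allele per column?
  bmats <- lapply(aln$sequences[background], .seq_matrix)
  cand <- which(!is.na(fixed_allele))
  if (length(cand) == 0L)
    return(structure(empty, class = c("diagnostic_loci", "data.frame")))
  diag_frac <- vapply(cand, function(j) {
    al <- fixed_allele[j]
    excl <- vapply(bmats, function(bm) {
      sets <- .iupac_expand(bm[, j])
      !any(vapply(sets, function(s) al %in% s, logical(1)))
    }, logical(1))
    mean(excl)
  }, numeric(1))
  keep <- diag_frac >= min_diagnosticity
  pos <- cand[keep]
  # ungapped coordinate in the first target sequence
  gapless <- cumsum(tm[1, ] != "-")
  out <- data.frame(
    target_species = rep(target, length(pos)),
    position = as.integer(pos),
    ungapped_position = as.integer(gapless[pos]),
    target_allele = fixed_allele[pos],
    diagnosticity = diag_frac[keep],
    fully_diagnostic = diag_frac[keep] == 1,
    conspecific_fixed = rep(TRUE, length(pos)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("diagnostic_loci", "data.frame"))
}

#' Score primer windows around a diagnostic locus
#'
#' Models the two locus-specific primers as windows of `window_length`
#' alignment columns that end (forward primer, left window) or start
#' (reverse primer, right window) at the locus, so that the diagnostic
#' nucleotide sits at the amplicon-facing terminal position of each primer
#' (its 3' end on the respective strand).  Each window is scored for
#' conservation within the target species (fraction of columns fixed on a
#' single unambiguous nucleotide) and differentiation against the
#' background (mean per-column fraction of background species whose alleles
#' exclude the target consensus).
#'
#' Windows that would run past the alignment edge are truncated and
#' flagged, not treated as errors.
#'
#' @param aln a [species_alignment_set()].
#' @param locus one row of a `diagnostic_loci` data frame (or a list with
#'   `target_species`, `position`, `target_allele`, `diagnosticity`,
#'   `fully_diagnostic`).
#' @param window_length primer window length in alignment columns
#'   (default 15).
#' @return An object of class `assay_candidate`: a list with the locus
#'   fields plus `left_window`/`right_window` (1-based inclusive bounds),
#'   per-window `conservation` and `differentiation` scores, truncation
#'   flags and `three_prime_diagnostic`.
#' @export
score_assay_windows <- function(aln, locus, window_length = 15) {
  stopifnot(inherits(aln, "species_alignment_set"), window_length >= 1)
  locus <- as.list(locus)
  pos <- as.integer(locus$position)
  L <- aln$length
  if (pos < 1L || pos > L) stop("locus position outside the alignment")
  target <- locus$target_species
  background <- setdiff(names(aln$sequences), target)
  tm <- .seq_matrix(aln$sequences[[target]])
  bmats <- lapply(aln$sequences[background], .seq_matrix)

  left <- c(max(1L, pos - window_length + 1L), pos)
  right <- c(pos, min(L, pos + window_length - 1L))
  left_trunc <- (pos - window_length + 1L) < 1L
  right_trunc <- (pos + window_length - 1L) > L

  score_window <- function(bounds) {
    cols <- seq.int(bounds[1], bounds[2])
    fixed <- vapply(cols, function(j) {
      u <- unique(tm[, j])
      length(u) == 1L && u %in% c("A", "C", "G", "T")
    }, logical(1))
    diff_col <- vapply(cols, function(j) {
      tab <- table(tm[, j][tm[, j] %in% c("A", "C", "G", "T")])
      if (length(tab) == 0L) return(0)
      consensus <- names(tab)[which.max(tab)]
      mean(vapply(bmats, function(bm) {
        sets <- .iupac_expand(bm[, j])
        !any(vapply(sets, function(s) consensus %in% s, logical(1)))
      }, logical(1)))
    }, numeric(1))
    c(conservation = mean(fixed), differentiation = mean(diff_col))
  }
  ls <- score_window(left)
  rs <- score_window(right)
  fully <- isTRUE(locus$fully_diagnostic) ||
    (!is.null(locus$diagnosticity) && locus$diagnosticity == 1)
  structure(
    list(
      target_species = target,
      position = pos,
      target_allele = locus$target_allele,
      diagnosticity = locus$diagnosticity,
      fully_diagnostic = fully,
      left_window = left, right_window = right,
      left_truncated = left_trunc, right_truncated = right_trunc,
      conservation = c(left = unname(ls["conservation"]),
                       right = unname(rs["conservation"])),
      differentiation = c(left = unname(ls["differentiation"]),
                          right = unname(rs["differentiation"])),
      three_prime_diagnostic = fully && (!left_trunc || !right_trunc)
    ),
    class = "assay_candidate"
  )
}

#' @export
print.assay_candidate <- function(x, ...) {
  cat(sprintf(
    "Assay candidate: %s pos %d (%s), diagnosticity %.2f%s\n",
    x$target_species, x$position, x$target_allele, x$diagnosticity,
    if (x$three_prime_diagnostic) ", 3'-diagnostic" else ""))
  cat(sprintf("  windows [%d,%d] / [%d,%d]  conservation %.2f/%.2f  differentiation %.2f/%.2f\n",
              x$left_window[1], x$left_window[2], x$right_window[1],
              x$right_window[2], x$conservation["left"], x$conservation["right"],
              x$differentiation["left"], x$differentiation["right"]))
  invisible(x)
}

#' Assemble a candidate marker panel
#'
#' Ranks scored assay candidates within each target species and keeps at
#' most one per locus (alignment position).  Ranking: fully diagnostic
#' first, then 3'-diagnostic, then higher mean window conservation, then
#' higher mean differentiation, ties broken by lower alignment position.
#' Species ending up with fewer than `min_markers_per_species` candidates
#' are reported in the shortfall table, never silently padded.
#'
#' @param candidates list of [score_assay_windows()] results (may span
#'   several target species).
#' @param min_markers_per_species minimum panel size aimed for per species
#'   (default 4).
#' @param n_keep optional cap on markers kept per species; `NULL` (default)
#'   keeps every distinct locus.
#' @param target_species optional character vector of species the panel was
#'   meant to cover; species with zero candidates (e.g. when no diagnostic
#'   site separates them from the background) then still appear in the
#'   shortfall report.  Defaults to the species present in `candidates`.
#' @return An object of class `panel_design`: a data frame with one row per
#'   selected marker (`marker_id`, `species`, `position`, `target_allele`,
#'   `diagnosticity`, `fully_diagnostic`, `three_prime_diagnostic`,
#'   `conservation`, `differentiation`) carrying a `shortfall` attribute
#'   (data frame `species`, `n_available`, `min_required`).
#' @export
design_panel <- function(candidates, min_markers_per_species = 4,
                         n_keep = NULL, target_species = NULL) {
  if (length(candidates) == 0L) {
    out <- data.frame(marker_id = character(0), species = character(0),
                      position = integer(0), target_allele = character(0),
                      diagnosticity = numeric(0), fully_diagnostic = logical(0),
                      three_prime_diagnostic = logical(0),
                      conservation = numeric(0), differentiation = numeric(0),
                      stringsAsFactors = FALSE)
    sp <- if (is.null(target_species)) character(0) else target_species
    attr(out, "shortfall") <- data.frame(
      species = sp, n_available = rep(0L, length(sp)),
      min_required = rep(as.integer(min_markers_per_species), length(sp)),
      stringsAsFactors = FALSE)
    class(out) <- c("panel_design", "data.frame")
    return(out)
  }
  df <- do.call(rbind, lapply(candidates, function(cc) data.frame(
    species = cc$target_species,
    position = cc$position,
    target_allele = cc$target_allele,
    diagnosticity = cc$diagnosticity,
    fully_diagnostic = cc$fully_diagnostic,
    three_prime_diagnostic = cc$three_prime_diagnostic,
    conservation = mean(cc$conservation),
    differentiation = mean(cc$differentiation),
    stringsAsFactors = FALSE
  )))
  parts <- lapply(split(df, df$species), function(d) {
    o <- order(-d$fully_diagnostic, -d$three_prime_diagnostic,
               -d$conservation, -d$differentiation, d$position)
    d <- d[o, , drop = FALSE]
    d <- d[!duplicated(d$position), , drop = FALSE]    # one assay per locus
    if (!is.null(n_keep)) d <- utils::head(d, n_keep)
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out <- cbind(marker_id = paste0(out$species, "_", out$position), out,
               stringsAsFactors = FALSE)
  levels <- unique(c(df$species, target_species))
  n_av <- table(factor(out$species, levels = levels))
  short <- names(n_av)[n_av < min_markers_per_species]
  attr(out, "shortfall") <- data.frame(
    species = short,
    n_available = as.integer(n_av[short]),
    min_required = rep(as.integer(min_markers_per_species), length(short)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("panel_design", "data.frame")
  out
}

#' @export
print.panel_design <- function(x, ...) {
  cat("Marker panel design:", nrow(x), "candidate marker(s),",
      length(unique(x$species)), "species\n")
  print.data.frame(x, ...)
  sh <- attr(x, "shortfall")
  if (!is.null(sh) && nrow(sh))
    cat("Shortfall:",
        paste(sprintf("%s (%d < %d)", sh$species, sh$n_available,
                      sh$min_required), collapse = "; "), "\n")
  invisible(x)
}
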