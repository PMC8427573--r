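# in-code fixtures and independent oracles shared across test files

# tiny alignment-set builder: aln_set(A = c("ACGT", "ACGT"), ...)
aln_set <- function(..., background = character(0)) {
  seqs <- list(...)
  roles <- setNames(
    ifelse(names(seqs) %in% background, "background", "target"),
    names(seqs))
  species_alignment_set(seqs, roles)
}

# independent exhaustive brute force for diagnostic sites; deliberately
# naive: loops over columns and species with its own IUPAC expansion
brute_force_sites <- function(seqs, target, min_diag = 1) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
                S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
                V = c("A", "C", "G"), H = c("A", "C", "T"),
                D = c("A", "G", "T"), B = c("C", "G", "T"),
                N = c("A", "C", "G", "T"), "-" = character(0))
  L <- nchar(seqs[[target]][1])
  bg <- setdiff(names(seqs), target)
  hits <- list()
  for (j in seq_len(L)) {
    tchars <- unique(substr(seqs[[target]], j, j))
    if (length(tchars) != 1 || !tchars %in% c("A", "C", "G", "T")) next
    excl <- 0
    for (sp in bg) {
      shares <- FALSE
      for (s in seqs[[sp]])
        if (tchars %in% iupac[[substr(s, j, j)]]) { shares <- TRUE; break }
      if (!shares) excl <- excl + 1
    }
    d <- excl / length(bg)
    if (d >= min_diag)
      hits[[length(hits) + 1]] <- data.frame(position = j,
                                             target_allele = tchars,
                                             diagnosticity = d)
  }
  if (length(hits) == 0)
    return(data.frame(position = integer(0), target_allele = character(0),
                      diagnosticity = numeric(0)))
  do.call(rbind, hits)
}

# random alignment generator for property tests
random_aln <- function(n_species, n_seq, L, chars = c("A", "C", "G", "T")) {
  seqs <- lapply(seq_len(n_species), function(i)
    vapply(seq_len(n_seq), function(j)
      paste(sample(chars, L, replace = TRUE), collapse = ""), character(1)))
  names(seqs) <- paste0("sp", seq_len(n_species))
  seqs
}

# hand-coded Welch two-sample t statistic and two-sided p
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# build a reference/nonspecific plate directly; one marker per target
# species, intensities given per role
ref_plate <- function(markers, samples) {
  # markers: data.frame(marker_id, species, chosen_dye)
  # samples: data.frame(sample_id, role, species)
  rows <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i)
    data.frame(sample_id = samples$sample_id[i],
               marker_id = markers$marker_id,
               I_F = 0, I_H = 0, rox = 1,
               role = samples$role[i], species = samples$species[i],
               stringsAsFactors = FALSE)))
  intensity_table(rows)
}

set_intensity <- function(plate, sample_id, marker_id, I_F = NULL,
                          I_H = NULL, rox = NULL) {
  i <- plate$sample_id == sample_id & plate$marker_id == marker_id
  if (!is.null(I_F)) plate$I_F[i] <- I_F
  if (!is.null(I_H)) plate$I_H[i] <- I_H
  if (!is.null(rox)) plate$rox[i] <- rox
  plate
}
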