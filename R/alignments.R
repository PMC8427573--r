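#' Species alignment set
#'
#' A set of aligned nucleotide sequences grouped by species, sharing one
#' alignment coordinate system.  Target species are the ones for which
#' diagnostic markers are designed; background species (e.g. the predator
#' and close relatives such as dog) are screened against but receive no
#' markers.
#'
#' @param sequences named list; one element per species, each a character
#'   vector of aligned sequences (IUPAC nucleotide codes plus `-` for gaps),
#'   all of identical length.
#' @param roles named character vector mapping each species to `"target"` or
#'   `"background"`.
#' @return An object of class `species_alignment_set` with elements
#'   `sequences`, `roles` and `length` (the alignment length).
#' @export
species_alignment_set <- function(sequences, roles) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("'sequences' must be a named list (one element per species)")
  if (!all(names(sequences) %in% names(roles)))
    stop("every species in 'sequences' needs a role in 'roles'")
  roles <- roles[names(sequences)]
  if (!all(roles %in% c("target", "background")))
    stop("roles must be 'target' or 'background'")
  sequences <- lapply(sequences, function(s) toupper(as.character(s)))
  n_per <- vapply(sequences, length, integer(1))
  if (any(n_per == 0L))
    stop("species with no sequences: ",
         paste(names(sequences)[n_per == 0L], collapse = ", "))
  lens <- unlist(lapply(sequences, nchar), use.names = FALSE)
  if (length(unique(lens)) > 1L)
    stop("aligned sequences must all have the same length (found lengths ",
         paste(sort(unique(lens)), collapse = ", "), ")")
  allowed <- c(names(Biostrings::IUPAC_CODE_MAP), "-")
  for (sp in names(sequences)) {
    chars <- unique(strsplit(paste(sequences[[sp]], collapse = ""), "")[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad))
      stop("species '", sp, "': unknown residue characters: ",
           paste(bad, collapse = ", "))
  }
  structure(
    list(sequences = sequences, roles = roles, length = lens[1]),
    class = "species_alignment_set"
  )
}

#' @export
print.species_alignment_set <- function(x, ...) {
  cat("Species alignment set:", length(x$sequences), "species,",
      "alignment length", x$length, "\n")
  n <- vapply(x$sequences, length, integer(1))
  cat(sprintf("  %-20s %-10s %d sequence(s)\n",
              names(x$sequences), unname(x$roles), n), sep = "")
  invisible(x)
}

#' Read per-species FASTA alignments
#'
#' Reads one aligned FASTA file per species (or a single FASTA with a
#' species map) into a [species_alignment_set()].  Sequences must already be
#' aligned: all must have equal length.
#'
#' @param fasta_paths character vector of FASTA paths.  If named, names are
#'   species ids; otherwise `species_map` is required.
#' @param roles named character vector of species roles (`"target"` /
#'   `"background"`).  Species absent from `roles` default to `"target"`.
#' @param species_map optional data frame with columns `species_id`,
#'   `sequence_id` and optionally `role`, assigning each FASTA record (by
#'   its header id, first whitespace-delimited token) to a species.  Used
#'   when all sequences live in one file.
#' @return A [species_alignment_set()].
#' @export
read_species_alignments <- function(fasta_paths, roles = NULL,
                                    species_map = NULL) {
  seqs <- list()
  if (is.null(species_map)) {
    if (is.null(names(fasta_paths)) || any(!nzchar(names(fasta_paths))))
      stop("'fasta_paths' must be named by species id (or give a species_map)")
    for (sp in names(fasta_paths)) {
      ss <- Biostrings::readBStringSet(fasta_paths[[sp]])
      if (length(ss) == 0L)
        stop("FASTA for species '", sp, "' contains no sequences: ",
             fasta_paths[[sp]])
      seqs[[sp]] <- as.character(ss)
    }
  } else {
    need <- c("species_id", "sequence_id")
    if (!all(need %in% names(species_map)))
      stop("species_map needs columns: ", paste(need, collapse = ", "))
    recs <- do.call(c, lapply(unname(fasta_paths), Biostrings::readBStringSet))
    ids <- sub("\\s.*$", "", names(recs))
    miss <- setdiff(species_map$sequence_id, ids)
    if (length(miss))
      stop("species_map sequence ids not found in FASTA: ",
           paste(miss, collapse = ", "))
    for (sp in unique(species_map$species_id)) {
      want <- species_map$sequence_id[species_map$species_id == sp]
      seqs[[sp]] <- as.character(recs)[match(want, ids)]
    }
    if ("role" %in% names(species_map) && is.null(roles))
      roles <- vapply(split(as.character(species_map$role),
                            species_map$species_id),
                      function(r) r[1], character(1))
  }
  if (is.null(roles)) roles <- character(0)
  full <- stats::setNames(rep("target", length(seqs)), names(seqs))
  full[names(roles)[names(roles) %in% names(full)]] <-
    roles[names(roles) %in% names(full)]
  species_alignment_set(seqs, full)
}

# split a species' sequences into an (n_seq x L) character matrix
.seq_matrix <- function(seqs) {
  do.call(rbind, strsplit(seqs, ""))
}

# IUPAC expansion: which of A/C/G/T a character can denote ('-' -> none)
.iupac_expand <- function(ch) {
  map <- Biostrings::IUPAC_CODE_MAP
  out <- map[ch]
  out[is.na(out)] <- ""
  strsplit(unname(out), "")
}
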