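#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator.  The
#' defaults emulate the study conditions the pipeline was built for: a
#' cytochrome-b-length alignment (1140 columns) over 18 target prey species
#' plus 2 background species (the predator and a close domestic relative),
#' 5 sequences per species, endpoint intensities averaging 0.93 for
#' specific and 0.08 for nonspecific reactions (truncated normal, floored
#' at 0), and 80 field scats.
#'
#' @param n_species total species in the alignment (targets first).
#' @param n_targets number of target species (rest are background).
#' @param seqs_per_species aligned sequences per species.
#' @param alignment_length alignment columns.
#' @param n_planted_sites diagnostic sites planted per target species.
#' @param intraspecific_mutation_rate per-column per-sequence substitution
#'   probability, applied only away from planted columns.
#' @param specific_mean,specific_sd intensity model for reactions where the
#'   marker's target DNA is present (defaults 0.93 / 0.1).
#' @param nonspecific_mean,nonspecific_sd intensity model for reactions
#'   without target DNA (defaults 0.08 / 0.05).
#' @param channel_sd independent per-dye noise around the shared latent
#'   amplification level (default 0.02).
#' @param cross_amplification_prob probability a nonspecific reaction
#'   amplifies at specific level, i.i.d. per well (default 0.005, chosen so
#'   that a reference plate with ~57 nonspecific tissues per marker leaves
#'   the large majority of markers with zero frequency of overlap and a
#'   mean overlap of roughly 0.05).
#' @param dropout_prob probability a specific reaction yields no product
#'   (intensity 0; default 0.02 — reference tissue DNA is plentiful, so
#'   dropout is rare there; raise it to emulate degraded scat DNA).
#' @param rox_mean,rox_sd passive-reference model (defaults 1 / 0.1).
#' @param rox_outlier_prob per-sample probability of a near-absent ROX
#'   signal, scaling the sample's ROX by 0.01 (default 0.0125, i.e. about
#'   1 sample in 80).
#' @param n_scats number of field scat samples (default 80).
#' @param mean_extra_prey each scat carries 1 + Poisson(mean_extra_prey)
#'   prey species, capped at `n_targets` (default 0.7).
#' @param tissues_per_species specific reference tissues per target species
#'   (default 3).
#' @param markers_per_species panel markers simulated per target species
#'   (default 4).
#' @param seed integer seed; mandatory, recorded in all outputs.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 20, n_targets = 18,
                              seqs_per_species = 5, alignment_length = 1140,
                              n_planted_sites = 6,
                              intraspecific_mutation_rate = 0.002,
                              specific_mean = 0.93, specific_sd = 0.1,
                              nonspecific_mean = 0.08, nonspecific_sd = 0.05,
                              channel_sd = 0.02,
                              cross_amplification_prob = 0.005,
                              dropout_prob = 0.02,
                              rox_mean = 1, rox_sd = 0.1,
                              rox_outlier_prob = 0.0125,
                              n_scats = 80, mean_extra_prey = 0.7,
                              tissues_per_species = 3,
                              markers_per_species = 4,
                              seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  cfg <- as.list(environment())
  probs <- c("intraspecific_mutation_rate", "cross_amplification_prob",
             "dropout_prob", "rox_outlier_prob")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  for (m in c("specific_mean", "nonspecific_mean", "rox_mean",
              "specific_sd", "nonspecific_sd", "channel_sd", "rox_sd"))
    if (cfg[[m]] < 0) stop(m, " must be >= 0")
  if (cfg$n_targets > cfg$n_species)
    stop("n_targets cannot exceed n_species")
  if (cfg$n_targets < 1 || cfg$n_species < 2)
    stop("need >= 1 target and >= 2 species overall")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "simulation_config")
}

# truncated-at-zero normal draws
.rtnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

.species_names <- function(cfg) {
  targets <- sprintf("target_%02d", seq_len(cfg$n_targets))
  bg <- if (cfg$n_species > cfg$n_targets)
    sprintf("background_%02d", seq_len(cfg$n_species - cfg$n_targets))
  else character(0)
  list(targets = targets, background = bg)
}

#' Simulate aligned sequences with planted diagnostic sites
#'
#' Starts from one random ancestral sequence shared by all species, plants
#' `n_planted_sites` fixed, species-specific substitutions per target
#' species at distinct columns, and then adds intraspecific variation at
#' the stated per-column rate, restricted to non-planted columns.  With at
#' least two background species, each planted column is fully diagnostic
#' for exactly its species.
#'
#' @param config a [simulation_config()].
#' @return A list with `alignment` (a [species_alignment_set()]) and
#'   `truth` (data frame `species`, `position`, `allele`).
#' @export
simulate_alignments <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  nm <- .species_names(config)
  L <- config$alignment_length
  n_plant <- config$n_planted_sites * length(nm$targets)
  if (n_plant > L)
    stop("too many planted sites (", n_plant, ") for alignment length ", L)
  bases <- c("A", "C", "G", "T")
  ancestral <- sample(bases, L, replace = TRUE)
  planted_cols <- sample.int(L, n_plant)
  owner <- rep(nm$targets, each = config$n_planted_sites)
  truth <- data.frame(species = owner, position = as.integer(planted_cols),
                      allele = rep(NA_character_, n_plant),
                      stringsAsFactors = FALSE)
  seqs <- list()
  for (sp in c(nm$targets, nm$background)) {
    proto <- ancestral
    mine <- which(truth$species == sp)
    for (i in mine) {
      j <- truth$position[i]
      al <- sample(setdiff(bases, ancestral[j]), 1L)
      proto[j] <- al
      truth$allele[i] <- al
    }
    mat <- matrix(rep(proto, config$seqs_per_species),
                  nrow = config$seqs_per_species, byrow = TRUE)
    if (config$intraspecific_mutation_rate > 0) {
      free <- setdiff(seq_len(L), planted_cols)
      hits <- which(matrix(stats::runif(length(free) *
                                          config$seqs_per_species) <
                             config$intraspecific_mutation_rate,
                           nrow = config$seqs_per_species), arr.ind = TRUE)
      for (r in seq_len(nrow(hits))) {
        j <- free[hits[r, 2]]
        mat[hits[r, 1], j] <- sample(setdiff(bases, mat[hits[r, 1], j]), 1L)
      }
    }
    seqs[[sp]] <- apply(mat, 1, paste, collapse = "")
  }
  roles <- stats::setNames(
    c(rep("target", length(nm$targets)), rep("background", length(nm$background))),
    c(nm$targets, nm$background))
  truth <- truth[order(truth$species, truth$position), ]
  rownames(truth) <- NULL
  list(alignment = species_alignment_set(seqs, roles), truth = truth)
}

#' Simulate sample truth for a plate
#'
#' Builds the sample sheet the plate simulator needs: specific reference
#' tissues for every target species, nonspecific reference tissues for the
#' background species, one negative control, and `n_scats` field scats
#' whose true prey content is drawn as 1 + Poisson(`mean_extra_prey`)
#' species sampled uniformly among the targets.
#'
#' @param config a [simulation_config()].
#' @param include_references include reference tissues and the negative
#'   control (default `TRUE`).
#' @return A list with `samples` (data frame `sample_id`, `role`,
#'   `species`) and `content` (named list: sample id -> character vector of
#'   species truly present).
#' @export
simulate_scat_truth <- function(config, include_references = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  nm <- .species_names(config)
  samples <- list(); content <- list()
  if (include_references) {
    for (sp in nm$targets) {
      ids <- sprintf("%s_tissue_%d", sp, seq_len(config$tissues_per_species))
      samples[[length(samples) + 1L]] <-
        data.frame(sample_id = ids, role = "specific_reference",
                   species = sp, stringsAsFactors = FALSE)
      for (id in ids) content[[id]] <- sp
    }
    for (sp in nm$background) {
      ids <- sprintf("%s_tissue_%d", sp, seq_len(config$tissues_per_species))
      samples[[length(samples) + 1L]] <-
        data.frame(sample_id = ids, role = "nonspecific_reference",
                   species = sp, stringsAsFactors = FALSE)
      for (id in ids) content[[id]] <- sp
    }
    samples[[length(samples) + 1L]] <-
      data.frame(sample_id = "negative_control_1", role = "negative_control",
                 species = NA_character_, stringsAsFactors = FALSE)
    content[["negative_control_1"]] <- character(0)
  }
  if (config$n_scats > 0) {
    ids <- sprintf("scat_%03d", seq_len(config$n_scats))
    samples[[length(samples) + 1L]] <-
      data.frame(sample_id = ids, role = "field_sample",
                 species = NA_character_, stringsAsFactors = FALSE)
    for (id in ids) {
      n_prey <- min(1L + stats::rpois(1L, config$mean_extra_prey),
                    length(nm$targets))
      content[[id]] <- sample(nm$targets, n_prey)
    }
  }
  list(samples = do.call(rbind, samples), content = content)
}

#' Default synthetic marker panel
#'
#' A panel of `markers_per_species` markers per target species with a
#' deterministic dye assignment (alternating FAM/HEX), used when plates
#' are simulated without a designed panel.
#'
#' @param config a [simulation_config()].
#' @return Data frame: `marker_id`, `species`, `chosen_dye`.
#' @export
synthetic_panel <- function(config) {
  nm <- .species_names(config)
  do.call(rbind, lapply(nm$targets, function(sp) {
    data.frame(
      marker_id = sprintf("%s_mk%d", sp, seq_len(config$markers_per_species)),
      species = sp,
      chosen_dye = rep(c("FAM", "HEX"),
                       length.out = config$markers_per_species),
      stringsAsFactors = FALSE)
  }))
}

#' Simulate a dual-dye intensity plate with known truth
#'
#' For every (sample, marker) well a latent amplification level is drawn
#' from the specific model when the marker's target species is truly in the
#' sample and from the nonspecific model otherwise; with probability
#' `cross_amplification_prob` a nonspecific well is replaced by a
#' specific-level draw (never in negative controls, which carry no template
#' to cross-amplify), and with probability `dropout_prob` a specific well
#' is zeroed.  Both dyes share the latent level plus independent channel
#' noise.  ROX is drawn per well, and whole samples become ROX outliers
#' (ROX x 0.01) with probability `rox_outlier_prob`.
#'
#' @param panel data frame `marker_id`, `species`, `chosen_dye` (e.g.
#'   [synthetic_panel()] or a selected evaluation).
#' @param sample_truth a [simulate_scat_truth()] result.
#' @param config a [simulation_config()].
#' @return An [intensity_table()] with attributes `truth` (the content
#'   list), `rox_outliers` (sample ids injected as outliers) and `seed`.
#' @export
simulate_plate <- function(panel, sample_truth, config) {
  stopifnot(inherits(config, "simulation_config"), nrow(panel) > 0)
  panel <- .normalize_panel(panel)
  set.seed(config$seed + 2L)
  samples <- sample_truth$samples
  content <- sample_truth$content
  out_flag <- stats::runif(nrow(samples)) < config$rox_outlier_prob
  rox_out <- samples$sample_id[out_flag]
  rows <- lapply(seq_len(nrow(samples)), function(si) {
    s <- samples$sample_id[si]
    present <- panel$species %in% content[[s]]
    n <- nrow(panel)
    a <- ifelse(present,
                .rtnorm0(n, config$specific_mean, config$specific_sd),
                .rtnorm0(n, config$nonspecific_mean, config$nonspecific_sd))
    # cross-amplification needs nonspecific template; water wells have none
    cross <- !present & stats::runif(n) < config$cross_amplification_prob &
      samples$role[si] != "negative_control"
    a[cross] <- .rtnorm0(sum(cross), config$specific_mean, config$specific_sd)
    drop <- present & stats::runif(n) < config$dropout_prob
    a[drop] <- 0
    I_F <- pmax(0, a + stats::rnorm(n, 0, config$channel_sd))
    I_H <- pmax(0, a + stats::rnorm(n, 0, config$channel_sd))
    rox <- .rtnorm0(n, config$rox_mean, config$rox_sd)
    if (out_flag[si]) rox <- rox * 0.01
    data.frame(sample_id = s, marker_id = panel$marker_id,
               I_F = I_F, I_H = I_H, rox = rox,
               role = samples$role[si], species = samples$species[si],
               stringsAsFactors = FALSE)
  })
  plate <- intensity_table(do.call(rbind, rows))
  attr(plate, "truth") <- content
  attr(plate, "rox_outliers") <- rox_out
  attr(plate, "seed") <- config$seed
  plate
}

#' Benchmark detection thresholds by Monte Carlo
#'
#' Simulates replicate cohorts of scats with known content, runs the full
#' baseline + k-of-n calling pipeline, and tabulates per threshold k the
#' sensitivity (true (sample, species) pairs detected), the false-positive
#' rate (absent species called present), and the percentage of scats with
#' at least one detection.
#'
#' @param config a [simulation_config()].
#' @param k thresholds (default `1:4`).
#' @param n_replicates replicate plates (default 10; total scats =
#'   `n_replicates * config$n_scats`).
#' @param include_references simulate reference tissues on each plate so
#'   baselines come from the run (default `TRUE`); with `FALSE` baselines
#'   fall back to the 0.2 floor, which makes the false-positive rate
#'   analytically binomial under independent cross-amplification.
#' @param floor baseline floor (default 0.2).
#' @return Data frame of class `threshold_benchmark`: `k`, `sensitivity`,
#'   `fpr`, `pct_detected`, `n_true`, `n_false`.
#' @export
benchmark_thresholds <- function(config, k = 1:4, n_replicates = 10,
                                 include_references = TRUE, floor = 0.2) {
  stopifnot(inherits(config, "simulation_config"))
  panel <- synthetic_panel(config)
  tp <- fp <- tn <- fn <- stats::setNames(numeric(length(k)), k)
  det_samples <- stats::setNames(numeric(length(k)), k)
  n_samples <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * r
    truth <- simulate_scat_truth(cfg, include_references = include_references)
    plate <- simulate_plate(panel, truth, cfg)
    baselines <- compute_baselines(plate, panel, floor = floor)
    calls <- call_species(plate, baselines, k = k)
    content <- attr(plate, "truth")
    kept <- unique(calls$sample_id)
    n_samples <- n_samples + length(kept)
    true_present <- mapply(function(s, sp) sp %in% content[[s]],
                           calls$sample_id, calls$species)
    for (kk in k) {
      col <- paste0("present_at_", kk)
      key <- as.character(kk)
      tp[key] <- tp[key] + sum(calls[[col]] & true_present)
      fp[key] <- fp[key] + sum(calls[[col]] & !true_present)
      fn[key] <- fn[key] + sum(!calls[[col]] & true_present)
      tn[key] <- tn[key] + sum(!calls[[col]] & !true_present)
      nsp <- tapply(calls[[col]], calls$sample_id, sum)[kept]
      det_samples[key] <- det_samples[key] + sum(nsp >= 1)
    }
  }
  out <- data.frame(
    k = as.integer(k),
    sensitivity = as.numeric(tp / pmax(tp + fn, 1)),
    fpr = as.numeric(fp / pmax(fp + tn, 1)),
    pct_detected = as.numeric(100 * det_samples / pmax(n_samples, 1)),
    n_true = as.integer(tp + fn),
    n_false = as.integer(fp + tn))
  attr(out, "n_samples") <- n_samples
  attr(out, "n_replicates") <- n_replicates
  class(out) <- c("threshold_benchmark", "data.frame")
  out
}

#' @export
print.threshold_benchmark <- function(x, ...) {
  cat("Threshold benchmark over", attr(x, "n_samples"), "simulated scat(s)\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}
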