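test_that("frequency of overlap counts nonspecific samples at or above the specific minimum", {
  expect_equal(frequency_of_overlap(c(0.9, 0.8, 1.0),
                                    c(0.1, 0.05, 0.85, 0.9)), 0.5)
  expect_equal(frequency_of_overlap(c(0.9, 0.8), c(0, 0, 0)), 0)
  expect_equal(frequency_of_overlap(c(0.5), c(0.5, 0.6, 0.9)), 1)
  expect_error(frequency_of_overlap(numeric(0), c(0.1)), "undefined")
})

test_that("overlap treats missing intensities as non-amplifying and is monotone", {
  expect_equal(frequency_of_overlap(c(0.9, NA), c(0.1, NA)),
               frequency_of_overlap(c(0.9, 0), c(0.1, 0)))
  set.seed(7)
  for (i in 1:20) {
    spec <- runif(5, 0.5, 1)
    nonspec <- runif(8, 0, 1)
    f0 <- frequency_of_overlap(spec, nonspec)
    f1 <- frequency_of_overlap(spec, c(nonspec, min(spec) + 0.01))
    expect_gte(f1, f0)
    expect_true(f0 >= 0 && f0 <= 1)
  }
})

test_that("dye selection follows the three-case overlap rule", {
  expect_equal(select_dye(0.0, 0.3), "FAM")   # only FAM has null overlap
  expect_equal(select_dye(0.3, 0.0), "HEX")
  expect_equal(select_dye(0.2, 0.1), "HEX")   # lower overlap wins
  expect_equal(select_dye(0.1, 0.2), "FAM")
  expect_equal(select_dye(0.2, 0.2), "FAM")   # positive tie -> FAM
})

test_that("the (0, 0) branch is random but reproducible under a seed", {
  set.seed(11); a <- replicate(20, select_dye(0, 0))
  set.seed(11); b <- replicate(20, select_dye(0, 0))
  expect_identical(a, b)
  expect_setequal(unique(a), c("FAM", "HEX"))  # both dyes reachable
})

test_that("Welch test has the spec'd sign convention and symmetry", {
  same <- c(0.1, 0.2, 0.3)
  r <- specificity_t_test(same, same)
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_value, 1)
  a <- c(0.9, 1.0, 0.8); b <- c(0.1, 0.0, 0.2)
  fwd <- specificity_t_test(a, b)
  rev <- specificity_t_test(b, a)
  expect_gt(fwd$t_stat, 0)
  expect_equal(rev$t_stat, -fwd$t_stat)
  expect_equal(rev$p_value, fwd$p_value)
})

test_that("Welch test agrees with the hand-coded formula oracle", {
  set.seed(42)
  for (i in 1:50) {
    x <- rnorm(sample(2:10, 1), mean = runif(1), sd = runif(1, 0.01, 1))
    y <- rnorm(sample(2:10, 1), mean = runif(1), sd = runif(1, 0.01, 1))
    got <- specificity_t_test(x, y)
    want <- welch_oracle(x, y)
    expect_equal(got$t_stat, want$t, tolerance = 1e-9)
    expect_equal(got$p_value, want$p, tolerance = 1e-9)
  }
})

test_that("undersized groups are routed to the one-sample test", {
  expect_error(specificity_t_test(0.9, c(0.1, 0.2)), "one_sample_t_test")
})

test_that("one-sample test reproduces the closed-form worked example", {
  r <- one_sample_t_test(c(0.05, 0.10, 0.15), 0.9)
  expect_equal(r$t_stat, -27.7128, tolerance = 1e-3)  # (0.1-0.9)/(0.05/sqrt(3))
  expect_false(r$zero_variance)
  eq <- one_sample_t_test(c(0.8, 0.9, 1.0), 0.9)
  expect_equal(eq$t_stat, 0)
  expect_equal(eq$p_value, 1)
})

test_that("zero variance among nonspecific samples is flagged", {
  r <- one_sample_t_test(c(0.1, 0.1), 0.9)
  expect_true(r$zero_variance)
  expect_equal(r$t_stat, -Inf)
  expect_equal(r$p_value, 0)
})

test_that("BY adjustment matches hand-evaluated values", {
  expect_equal(adjust_p_values_BY(0.03), 0.03)  # m = 1, c(1) = 1
  # m = 3, c(3) = 11/6: raw * 3 * (11/6) / rank, then step-up minima
  expect_equal(adjust_p_values_BY(c(0.01, 0.02, 0.04)),
               c(0.055, 0.055, 0.0733), tolerance = 1e-3)
})

test_that("BY output dominates raw p, is capped at 1 and rank-monotone", {
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    q <- adjust_p_values_BY(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
  expect_error(adjust_p_values_BY(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("ROX outlier screen is low-side median minus k MADs", {
  expect_equal(detect_rox_outliers(c(a = 1, b = 1, c = 1)), character(0))
  rox <- c(s1 = 1, s2 = 1, s3 = 1, s4 = 1, bad = 0.01)
  expect_equal(detect_rox_outliers(rox), "bad")
  expect_equal(detect_rox_outliers(rox, k_mad = Inf), character(0))
  # high-side values are never excluded
  expect_equal(detect_rox_outliers(c(s1 = 1, s2 = 1, s3 = 1, hi = 100)),
               character(0))
  expect_error(detect_rox_outliers(c(a = 1, b = 1)), ">= 3")
})

test_that("well-separated plates evaluate as fully specific", {
  markers <- data.frame(marker_id = c("mA", "mB"), species = c("A", "B"),
                        chosen_dye = c("FAM", "HEX"))
  samples <- data.frame(
    sample_id = c("A1", "A2", "A3", "B1", "B2", "B3", "W1", "W2", "W3"),
    role = c(rep("specific_reference", 6), rep("nonspecific_reference", 3)),
    species = c("A", "A", "A", "B", "B", "B", "wolf", "wolf", "wolf"))
  plate <- ref_plate(markers, samples)
  for (s in c("A1", "A2", "A3")) {
    i <- match(s, c("A1", "A2", "A3"))
    plate <- set_intensity(plate, s, "mA", I_F = 0.9 + 0.01 * i,
                           I_H = 0.85 + 0.02 * i)
  }
  for (s in c("B1", "B2", "B3")) {
    i <- match(s, c("B1", "B2", "B3"))
    plate <- set_intensity(plate, s, "mB", I_F = 0.8 + 0.02 * i,
                           I_H = 0.95 + 0.01 * i)
  }
  # nonspecific wells stay at 0 intensity
  set.seed(5)
  ev <- evaluate_markers(plate, markers)
  expect_true(all(ev$evaluable))
  expect_equal(ev$freq_overlap, c(0, 0))
  expect_true(all(ev$p_adjusted <= 0.05))
  expect_true(all(ev$t_stat > 0))
  expect_true(all(ev$separation > 0))
  expect_equal(ev$n_specific, c(3, 3))
  expect_equal(ev$n_nonspecific, c(6, 6))  # other-species refs count too
})

test_that("markers without specific references are flagged unevaluable", {
  markers <- data.frame(marker_id = c("mA", "mC"), species = c("A", "C"),
                        chosen_dye = "FAM")
  samples <- data.frame(
    sample_id = c("A1", "A2", "W1"),
    role = c("specific_reference", "specific_reference",
             "nonspecific_reference"),
    species = c("A", "A", "wolf"))
  plate <- ref_plate(markers, samples)
  set.seed(1)
  ev <- evaluate_markers(plate, markers)
  expect_false(ev$evaluable[ev$marker_id == "mC"])
  expect_true(is.na(ev$p_adjusted[ev$marker_id == "mC"]))
})

test_that("a single specific sample triggers the one-sample test", {
  markers <- data.frame(marker_id = "mF", species = "fallow",
                        chosen_dye = "FAM")
  samples <- data.frame(
    sample_id = c("F1", "N1", "N2", "N3"),
    role = c("specific_reference", rep("nonspecific_reference", 3)),
    species = c("fallow", "wolf", "wolf", "wolf"))
  plate <- ref_plate(markers, samples)
  plate <- set_intensity(plate, "F1", "mF", I_F = 0.9)
  plate$I_F[plate$sample_id != "F1"] <- c(0.05, 0.10, 0.15)
  set.seed(1)
  ev <- evaluate_markers(plate, markers)
  expect_equal(ev$test, "one_sample")
  expect_equal(ev$t_stat, -27.7128, tolerance = 1e-3)
})

test_that("BY adjustment is applied once across all evaluated markers", {
  cfg <- simulation_config(n_species = 5, n_targets = 3, n_scats = 0,
                           alignment_length = 120, seed = 33)
  truth <- simulate_scat_truth(cfg)
  panel <- synthetic_panel(cfg)
  plate <- simulate_plate(panel, truth, cfg)
  set.seed(2)
  ev <- evaluate_markers(plate, panel)
  ok <- ev$evaluable & !is.na(ev$p_value)
  expect_equal(ev$p_adjusted[ok], p.adjust(ev$p_value[ok], method = "BY"))
})

test_that("ranking orders by overlap then separation and reports shortfalls", {
  ev <- data.frame(
    marker_id = c("m1", "m2", "m3"), target_species = "A",
    freq_overlap = c(0, 0, 0.1), separation = c(0.5, 0.7, 0.9),
    evaluable = TRUE, stringsAsFactors = FALSE)
  class(ev) <- c("marker_evaluation", "data.frame")
  sel <- rank_and_select(ev, min_markers_per_species = 4, n_keep = NULL)
  expect_equal(sel$marker_id, c("m2", "m1", "m3"))
  expect_equal(attr(sel, "shortfall")$species, "A")
  # exact ties preserve input order (stable sort)
  tie <- ev; tie$freq_overlap <- 0; tie$separation <- 0.5
  class(tie) <- c("marker_evaluation", "data.frame")
  expect_equal(rank_and_select(tie, 1, n_keep = NULL)$marker_id,
               c("m1", "m2", "m3"))
  # a species with exactly the minimum is kept whole
  sel4 <- rank_and_select(ev, min_markers_per_species = 3, n_keep = 3)
  expect_equal(nrow(sel4), 3)
  expect_equal(nrow(attr(sel4, "shortfall")), 0)
})
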