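test_that("simulate_reference returns the requested length, is seeded, and hits the GC target", {
  ref <- simulate_reference(16569, gc = 0.44, seed = 1)
  expect_equal(ref$length, 16569)
  expect_true(ref$circular)

  ref2 <- simulate_reference(16569, gc = 0.44, seed = 1)
  expect_identical(ref$sequence, ref2$sequence)

  big <- simulate_reference(100000, gc = 0.44, seed = 7)
  ch <- strsplit(big$sequence, "")[[1]]
  gc_obs <- mean(ch %in% c("G", "C"))
  expect_gte(gc_obs, 0.43)
  expect_lte(gc_obs, 0.45)

  expect_error(simulate_reference(500), class = "ancientmt_invalid_argument")
  expect_error(simulate_reference(2000, gc = 1.2),
               class = "ancientmt_invalid_argument")
})

test_that("with all mutation channels off every fragment matches the reference", {
  ref <- simulate_reference(3000, seed = 11)
  sim <- simulate_fragments(
    ref, damage_model(delta5 = 0, delta3 = 0, error_rate = 0),
    library_config(500, seed = 12))
  rb <- strsplit(ref$sequence, "")[[1]][sim$fragments$ref_pos + 1L]
  expect_true(all(sim$fragments$base == rb))
  expect_true(all(sim$truth$origin == "endogenous"))
  expect_true(all(sim$truth$n_damage == 0L))
})

test_that("simulation is deterministic under the seed and the truth table is complete", {
  ref <- simulate_reference(2000, seed = 3)
  lib <- library_config(300, contamination_fraction = 0.1, seed = 4)
  s1 <- simulate_fragments(ref, damage_model(), lib)
  s2 <- simulate_fragments(ref, damage_model(), lib)
  expect_equal(s1$fragments, s2$fragments, ignore_attr = TRUE)
  expect_equal(s1$truth, s2$truth)

  # exactly one truth record per emitted fragment
  ids <- unique(s1$fragments$fragment_id)
  expect_setequal(ids, s1$truth$fragment_id)
  expect_false(any(duplicated(s1$truth$fragment_id)))

  # lengths respect the clamp
  meta <- dplyr::distinct(s1$fragments, fragment_id, read_length)
  expect_true(all(meta$read_length >= 20 & meta$read_length <= 150))
})

test_that("terminal damage is injected at the configured rate (exact binomial check)", {
  ref <- simulate_reference(16569, gc = 0.44, seed = 21)
  sim <- simulate_fragments(
    ref, damage_model(delta5 = 0.4, delta3 = 0, error_rate = 0),
    library_config(20000, seed = 22))
  f <- sim$fragments
  at1 <- f[f$read_pos == 0L, ]
  rb <- strsplit(ref$sequence, "")[[1]][at1$ref_pos + 1L]
  opp <- ifelse(at1$strand == "-", rb == "G", rb == "C")
  ct <- ifelse(at1$strand == "-", rb == "G" & at1$base == "A",
               rb == "C" & at1$base == "T")
  n <- sum(opp)
  x <- sum(ct[opp])
  interval <- qbinom(c(0.005, 0.995), n, 0.4)
  expect_gte(x, interval[1])
  expect_lte(x, interval[2])

  # and the truth table agrees exactly with the observed C->T calls
  truth_n <- sum(sim$truth$n_damage)
  dam_at_0 <- sum(vapply(strsplit(sim$truth$damage_positions, ","),
                         function(p) sum(p == "0"), numeric(1)))
  expect_equal(x, dam_at_0)
  expect_true(truth_n >= x)
})

test_that("contaminant fragments are drawn at the configured fraction and stay undamaged", {
  ref <- simulate_reference(5000, seed = 31)
  sim <- simulate_fragments(
    ref, damage_model(0.4, 0.4, error_rate = 0),
    library_config(10000, contamination_fraction = 0.2, seed = 32))
  n_cont <- sum(sim$truth$origin == "contaminant")
  interval <- qbinom(c(0.005, 0.995), 10000, 0.2)
  expect_gte(n_cont, interval[1])
  expect_lte(n_cont, interval[2])
  expect_true(all(sim$truth$n_damage[sim$truth$origin == "contaminant"] == 0L))

  sim0 <- simulate_fragments(ref, damage_model(),
                             library_config(200, seed = 33))
  expect_true(all(sim0$truth$origin == "endogenous"))
})

test_that("inject_duplicates copies share coordinates, are re-sequenced, and hit the binomial rate", {
  ref <- simulate_reference(4000, seed = 41)
  sim <- simulate_fragments(ref, damage_model(error_rate = 0),
                            library_config(10000, seed = 42))

  # rate 0 is the identity
  out0 <- inject_duplicates(sim$fragments, sim$truth, 0)
  expect_identical(out0$fragments, sim$fragments)

  out <- inject_duplicates(sim$fragments, sim$truth, 0.2, seed = 43)
  n_copies <- nrow(out$truth) - nrow(sim$truth)
  interval <- qbinom(c(0.005, 0.995), 10000, 0.2)
  expect_gte(n_copies, interval[1])
  expect_lte(n_copies, interval[2])

  # copies share start/end/strand with their original and, with error off,
  # the same bases
  copies <- out$truth[out$truth$fragment_id > 10000, ]
  orig_meta <- dplyr::distinct(sim$fragments, fragment_id, ref_start, strand,
                               read_length)
  copy_meta <- dplyr::distinct(out$fragments, fragment_id, ref_start, strand,
                               read_length)
  joined <- dplyr::inner_join(
    copies["fragment_id"] |>
      dplyr::mutate(orig = out$truth$duplicate_set[match(fragment_id, out$truth$fragment_id)]),
    copy_meta, by = "fragment_id") |>
    dplyr::inner_join(orig_meta, by = c(orig = "fragment_id"),
                      suffix = c("", "_orig"))
  expect_true(all(joined$ref_start == joined$ref_start_orig &
                    joined$strand == joined$strand_orig &
                    joined$read_length == joined$read_length_orig))

  one <- copies$fragment_id[1]
  orig_id <- out$truth$duplicate_set[out$truth$fragment_id == one]
  b_copy <- out$fragments[out$fragments$fragment_id == one, c("ref_pos", "base")]
  b_orig <- sim$fragments[sim$fragments$fragment_id == orig_id, c("ref_pos", "base")]
  expect_equal(dplyr::arrange(b_copy, ref_pos), dplyr::arrange(b_orig, ref_pos),
               ignore_attr = TRUE)
})

test_that("repeated duplication grows the original's duplicate set", {
  ref <- simulate_reference(2000, seed = 51)
  sim <- simulate_fragments(ref, damage_model(error_rate = 0),
                            library_config(1, seed = 52))
  out <- inject_duplicates(sim$fragments, sim$truth, 0.999, seed = 53)
  out <- inject_duplicates(out$fragments, out$truth, 0.999, seed = 54)
  expect_true(all(out$truth$duplicate_set == 1L))
  expect_gte(nrow(out$truth), 3)
  expect_equal(dplyr::n_distinct(out$fragments$fragment_id), nrow(out$truth))
})
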