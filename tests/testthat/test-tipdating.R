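test_that("jc_distance matches the closed form and rejects saturated input", {
  expect_equal(jc_distance("ACGTACGT", "ACGTACGT"), 0)

  # p = 0.03: 3 mismatches in 100 sites
  a <- strrep("A", 100)
  b <- paste0(strrep("C", 3), strrep("A", 97))
  expect_equal(jc_distance(a, b), -0.75 * log(1 - 4 / 3 * 0.03),
               tolerance = 1e-12)
  expect_equal(jc_distance(a, b), 0.0306165, tolerance = 1e-5)

  # N-only overlap -> error
  expect_error(jc_distance("NNNN", "ACGT"),
               class = "ancientmt_undefined_distance")
  # p >= 0.75 -> undefined
  expect_error(jc_distance(strrep("A", 100), strrep("C", 100)),
               class = "ancientmt_undefined_distance")
})

test_that("neighbour joining recovers an additive four-taxon tree exactly", {
  # tree ((a:1,b:2):1,(c:3,d:4):1) gives an additive distance matrix
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 6
  d["a", "d"] <- d["d", "a"] <- 7
  d["b", "c"] <- d["c", "b"] <- 7
  d["b", "d"] <- d["d", "b"] <- 8
  d["c", "d"] <- d["d", "c"] <- 7
  tr <- build_nj_tree(d)
  expect_s3_class(tr, "phylo")
  # recovered tree reproduces all pairwise path lengths
  dd <- ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]]
  expect_equal(dd, d, tolerance = 1e-10)
  # topology: a-b form a cherry
  expect_true(ape::is.monophyletic(ape::root(tr, "d"), c("a", "b")))

  expect_error(build_nj_tree(d[1:2, 1:2]),
               class = "ancientmt_invalid_argument")
})

test_that("outgroup rooting preserves path lengths and detects non-monophyly", {
  d <- matrix(c(0, 2, 8, 9,
                2, 0, 8, 9,
                8, 8, 0, 3,
                9, 9, 3, 0), 4, 4,
              dimnames = list(c("i1", "i2", "o1", "o2"),
                              c("i1", "i2", "o1", "o2")))
  tr <- build_nj_tree(d)
  rooted <- root_on_outgroup(tr, c("o1", "o2"))
  expect_true(ape::is.rooted(rooted))
  expect_true(ape::is.monophyletic(rooted, c("o1", "o2")))
  expect_true(ape::is.monophyletic(rooted, c("i1", "i2")))
  # pairwise path lengths unchanged by rooting
  expect_equal(ape::cophenetic.phylo(rooted)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  # root splits the separating branch at its midpoint
  root_node <- ape::Ntip(rooted) + 1
  re <- rooted$edge.length[rooted$edge[, 1] == root_node]
  expect_equal(re[1], re[2])

  expect_error(root_on_outgroup(tr, c("o1", "i1")),
               class = "ancientmt_invalid_argument")
  expect_error(root_on_outgroup(tr, "nope"),
               class = "ancientmt_invalid_argument")
})

test_that("strict-clock fit recovers the simulated rate and rejects degenerate dates", {
  ages <- c(cal_panel_ages(), og1 = 160000, og2 = 158000)
  rate <- 2.5e-8
  rates <- vapply(1:5, function(s) {
    tr <- simulate_dated_tree(ages, theta = 30000, seed = 400 + s)
    sim <- simulate_clock_alignment(tr, rate, 30000, ages, seed = 410 + s)
    ps <- difference_matrix(sim$alignment)
    d <- matrix(0, length(ages), length(ages),
                dimnames = list(names(sim$alignment), names(sim$alignment)))
    for (i in seq_along(ages)) for (j in seq_along(ages)) {
      if (i != j) {
        p <- ps$n_diff[i, j] / ps$n_compared[i, j]
        d[i, j] <- -0.75 * log(1 - 4 / 3 * p)
      }
    }
    tree <- build_nj_tree(d)
    rooted <- root_on_outgroup(tree, c("og1", "og2"))
    fit <- fit_strict_clock(rooted, cal_panel_ages())
    expect_equal(fit$n_calibration, 15)
    fit$rate
  }, numeric(1))
  expect_lt(abs(mean(rates) / rate - 1), 0.1)

  # all tips at the same date -> degenerate regression
  tr <- simulate_dated_tree(c(a = 0, b = 0, c = 0, d = 0), seed = 5)
  sim <- simulate_clock_alignment(tr, 1e-7, 1000, c(a = 0, b = 0, c = 0, d = 0),
                                  seed = 6)
  tree <- build_nj_tree(as.matrix(ape::dist.dna(
    ape::as.DNAbin(t(sapply(sim$alignment, function(s) strsplit(s, "")[[1]]))),
    model = "JC69")))
  expect_error(fit_strict_clock(tree, c(a = 0, b = 0, c = 0)),
               class = "ancientmt_invalid_argument")
})

test_that("tip-date estimation handles the identity case and fails cleanly at rate 0", {
  ages <- c(cal_panel_ages(), og1 = 160000, og2 = 158000)
  tr <- simulate_dated_tree(ages, theta = 30000, seed = 420)
  sim <- simulate_clock_alignment(tr, 2.5e-8, 16000, ages, seed = 421)
  aln <- sim$alignment
  # query identical to the calibration tip dated 45,000
  aln <- c(aln, q = unname(aln["c15"]))
  est <- estimate_tip_date(aln, cal_panel_ages(), "q", c("og1", "og2"),
                           n_boot = 100, seed = 422)
  expect_true(est$ci_low <= est$point && est$point <= est$ci_high)
  # the query must date close to its twin: within the bootstrap interval
  expect_true(est$ci_low <= 45000 + 5000 && est$ci_high >= 45000 - 5000)
  expect_true(est$rate > 0)

  # determinism of the bootstrap under the seed
  est2 <- estimate_tip_date(aln, cal_panel_ages(), "q", c("og1", "og2"),
                            n_boot = 100, seed = 422)
  expect_equal(est$point, est2$point)
  expect_equal(est$ci_low, est2$ci_low)

  # rate 0: all sequences identical -> undefined distances / flat regression
  sim0 <- simulate_clock_alignment(tr, 0, 2000, ages, seed = 423)
  expect_error(
    estimate_tip_date(sim0$alignment, cal_panel_ages(), "c01",
                      c("og1", "og2"), n_boot = 10, seed = 424),
    class = "ancientmt_clock_failure")
})

test_that("date estimates are invariant under taxon relabelling", {
  ages <- c(cal_panel_ages(), og1 = 160000, og2 = 158000, q = 45000)
  tr <- simulate_dated_tree(ages, theta = 30000, seed = 430)
  sim <- simulate_clock_alignment(tr, 2.5e-8, 8000, ages, seed = 431)
  est1 <- estimate_tip_date(sim$alignment, cal_panel_ages(), "q",
                            c("og1", "og2"), n_boot = 20, seed = 432)
  # relabel calibration tips consistently
  aln2 <- sim$alignment
  names(aln2) <- sub("^c", "tip", names(aln2))
  ages2 <- cal_panel_ages()
  names(ages2) <- sub("^c", "tip", names(ages2))
  est2 <- estimate_tip_date(aln2, ages2, "q", c("og1", "og2"),
                            n_boot = 20, seed = 432)
  expect_equal(est1$point, est2$point, tolerance = 1e-9)
})
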