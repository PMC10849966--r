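test_that("select_mode follows the contamination threshold with a conservative tie rule", {
  expect_equal(select_mode(0.02), "all_fragments")
  expect_equal(select_mode(0.12), "deaminated_only")
  expect_equal(select_mode(0.05), "deaminated_only")
  est <- structure(list(point = 0.01), class = "contamination_estimate")
  expect_equal(select_mode(est), "all_fragments")
})

test_that("mask_terminal_damage excludes exactly terminal read-orientation C->T", {
  ref <- reference_genome(strrep("C", 100), name = "allC")
  # + strand: C->T at read position 2 masked; interior T kept
  fr1 <- mk_frag(1, 0, paste0("CCT", strrep("C", 7), "T", strrep("C", 49)))
  m1 <- mask_terminal_damage(fr1, ref, window = 7)
  expect_true(m1[fr1$read_pos == 2])
  expect_false(m1[fr1$read_pos == 10])

  # - strand: reference G read A, 3 bases from the fragment's RIGHT
  # reference end = read position 3 -> masked
  refg <- reference_genome(strrep("G", 100), name = "allG")
  b <- strsplit(strrep("G", 20), "")[[1]]
  b[20 - 3] <- "A"  # ref offset 16, read_pos = 19 - 16 = 3
  fr2 <- mk_frag(2, 0, paste(b, collapse = ""), strand = "-")
  m2 <- mask_terminal_damage(fr2, refg, window = 7)
  expect_true(m2[fr2$read_pos == 3])
  expect_equal(sum(m2), 1)

  # non-C->T mismatches are never masked
  fr3 <- mk_frag(3, 0, paste0("G", strrep("C", 19)))
  expect_false(any(mask_terminal_damage(fr3, ref)))
})

test_that("consensus calling enforces coverage, support, and tie rules at the boundaries", {
  ref <- tiny_ref(40)
  params <- consensus_params()
  site_frag <- function(ids, base) {
    dplyr::bind_rows(lapply(ids, function(i) {
      mk_frag(i, 10, paste0(strrep(base, 1), strrep("N", 19)))
    }))
  }
  rs <- function(g) strsplit(g$sequence, "")[[1]]

  # 5 fragments all A at site 11 -> A; with the remaining sites N
  g5 <- call_consensus(site_frag(1:5, "A"), ref, params)
  expect_equal(rs(g5)[11], "A")
  expect_equal(sum(rs(g5) != "N"), 1)

  # 4 fragments -> N (coverage below 5)
  g4 <- call_consensus(site_frag(1:4, "A"), ref, params)
  expect_equal(rs(g4)[11], "N")

  # 8 C / 2 G -> support exactly 0.80 passes (inclusive)
  fr <- dplyr::bind_rows(site_frag(1:8, "C"), site_frag(9:10, "G"))
  g80 <- call_consensus(fr, ref, params)
  expect_equal(rs(g80)[11], "C")
  site <- g80$sites[g80$sites$pos == 11, ]
  expect_equal(site$support, 0.8)

  # 7 C / 3 G -> support 0.7 fails
  fr7 <- dplyr::bind_rows(site_frag(1:7, "C"), site_frag(8:10, "G"))
  expect_equal(rs(call_consensus(fr7, ref, params))[11], "N")

  # 5 C / 5 G tie -> N even though coverage passes
  frt <- dplyr::bind_rows(site_frag(1:5, "C"), site_frag(6:10, "G"))
  gt <- call_consensus(frt, ref, consensus_params(min_support = 0.51))
  expect_equal(rs(gt)[11], "N")
})

test_that("per-site calls equal an independent brute-force tally on random sites", {
  ref <- simulate_reference(3000, seed = 301)
  sim <- simulate_fragments(ref, damage_model(0.4, 0.4, error_rate = 0.005),
                            library_config(3000, seed = 302))
  params <- consensus_params()
  g <- call_consensus(sim$fragments, ref, params)

  f <- sim$fragments
  rb <- strsplit(ref$sequence, "")[[1]][f$ref_pos + 1]
  minus <- f$strand == "-"
  is_ct <- ifelse(minus, rb == "G" & f$base == "A", rb == "C" & f$base == "T")
  terminal <- f$read_pos < 7 | f$read_pos >= f$read_length - 7
  masked <- is_ct & terminal

  sites <- withr::with_seed(303, sample.int(3000, 1000))
  called_seq <- strsplit(g$sequence, "")[[1]]
  for (s in sites) {
    keep <- f$ref_pos == s - 1 & !masked & f$base != "N"
    tab <- table(f$base[keep])
    expected <- "N"
    if (sum(tab) >= params$min_coverage) {
      top <- names(tab)[tab == max(tab)]
      if (length(top) == 1 && max(tab) / sum(tab) >= params$min_support) {
        expected <- top
      }
    }
    if (expected != called_seq[s]) {
      fail(sprintf("site %d: brute force %s, package %s", s, expected,
                   called_seq[s]))
    }
  }
  succeed()
})

test_that("raising thresholds never converts an N into a call", {
  ref <- simulate_reference(2000, seed = 311)
  sim <- simulate_fragments(ref, damage_model(0.4, 0.4, error_rate = 0.01),
                            library_config(2000, seed = 312))
  g1 <- call_consensus(sim$fragments, ref, consensus_params(min_coverage = 5,
                                                            min_support = 0.8))
  g2 <- call_consensus(sim$fragments, ref, consensus_params(min_coverage = 8,
                                                            min_support = 0.8))
  g3 <- call_consensus(sim$fragments, ref, consensus_params(min_coverage = 5,
                                                            min_support = 0.95))
  n1 <- strsplit(g1$sequence, "")[[1]] == "N"
  n2 <- strsplit(g2$sequence, "")[[1]] == "N"
  n3 <- strsplit(g3$sequence, "")[[1]] == "N"
  expect_true(all(!(n1 & !n2)))   # N stays N under stricter coverage
  expect_true(all(!(n1 & !n3)))   # and under stricter support
})

test_that("deaminated_only mode uses only flagged fragments", {
  ref <- simulate_reference(2000, seed = 321)
  sim <- simulate_fragments(ref, damage_model(0.5, 0.5, error_rate = 0),
                            library_config(4000, seed = 322))
  cls <- classify_deaminated(sim$fragments, ref)
  g <- call_consensus(sim$fragments, ref,
                      consensus_params(mode = "deaminated_only"),
                      deaminated = cls)
  expect_equal(g$mode_used, "deaminated_only")
  keep <- cls$fragment_id[cls$deaminated]
  frags_deam <- sim$fragments[sim$fragments$fragment_id %in% keep, ]
  cov <- pileup(frags_deam, ref,
                mask = mask_terminal_damage(frags_deam, ref))$coverage_masked
  expect_equal(g$sites$coverage_masked, cov)
})

test_that("consensus genomes round-trip through FASTA and the site TSV", {
  ref <- tiny_ref(60)
  g <- call_consensus(mk_frag(1, 0, strrep("A", 40)), ref, consensus_params())
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_consensus(g, fa, tsv)
  back <- read_fasta(fa)
  expect_equal(unname(back[1]), g$sequence)
  expect_equal(names(back), g$name)
  sites <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(sites), 60)

  # coverage 1 everywhere -> all-N genome serialises to pure N
  expect_equal(g$sequence, strrep("N", 60))
})
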