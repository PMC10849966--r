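# Hand-built fragment rows for exact-case tests.
# `bases_ref` is the observed sequence in REFERENCE orientation over
# [ref_start, ref_start + len); read_pos follows the strand.
mk_frag <- function(id, ref_start, bases_ref, strand = "+", mapq = 37,
                    L = NULL) {
  b <- strsplit(bases_ref, "", fixed = TRUE)[[1]]
  len <- length(b)
  j <- seq_len(len) - 1L
  rp <- if (is.null(L)) ref_start + j else (ref_start + j) %% L
  read_pos <- if (strand == "+") j else len - 1L - j
  tibble::tibble(
    fragment_id = as.integer(id), ref_start = as.integer(ref_start),
    strand = strand, mapq = as.integer(mapq), read_length = len,
    ref_pos = as.integer(rp),
    read_pos = as.integer(read_pos),
    base = b
  )
}

mk_frags <- function(...) dplyr::bind_rows(...)

# fixed small circular reference for exact-case tests
tiny_ref <- function(n = 60, pattern = "ACGT") {
  s <- strrep(pattern, ceiling(n / nchar(pattern)))
  reference_genome(substr(s, 1, n), name = "tiny")
}

# mutate a sequence string at 1-based positions to given bases
mutate_seq <- function(seq, pos, bases) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[pos] <- bases
  paste(ch, collapse = "")
}

# mask random positions to N
mask_n <- function(seq, n_mask, seed) {
  withr::with_seed(seed, {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    ch[sample.int(length(ch), n_mask)] <- "N"
    paste(ch, collapse = "")
  })
}

# standard dated calibration panel used in clock tests: 15 calibration
# genomes spanning 0-45 kyr BP plus two old outgroups
cal_panel_ages <- function() {
  c(c01 = 0, c02 = 0, c03 = 2000, c04 = 5000, c05 = 8000, c06 = 12000,
    c07 = 16000, c08 = 20000, c09 = 25000, c10 = 30000, c11 = 34000,
    c12 = 38000, c13 = 41000, c14 = 43000, c15 = 45000)
}
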