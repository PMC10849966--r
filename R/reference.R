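#' Construct a (circular) reference genome object
#'
#' Container for the mitochondrial reference the fragments are aligned to.
#' mtDNA is circular, so coordinates are interpreted modulo the genome
#' length throughout the package; linear references are supported with
#' `circular = FALSE`.
#'
#' @param sequence A single string over A/C/G/T (ambiguity codes are
#'   rejected for simulated references).
#' @param name Sequence name used in SAM/FASTA headers.
#' @param circular Logical; treat coordinates modulo length.
#' @return An object of class `ref_genome` with fields `name`, `sequence`,
#'   `length` and `circular`.
#' @export
reference_genome <- function(sequence, name = "ref", circular = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L) {
    abort("`sequence` must be a single non-empty string",
          class = "ancientmt_invalid_argument")
  }
  sequence <- toupper(sequence)
  structure(
    list(name = as.character(name), sequence = sequence,
         length = nchar(sequence), circular = isTRUE(circular)),
    class = "ref_genome"
  )
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("<ref_genome> %s: %d bp, %s\n", x$name, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

# character vector of reference bases, recycled circularly for 0-based
# positions `pos0` (which may exceed length for wrapped fragments)
ref_base_at <- function(ref, pos0) {
  seq_chars(ref$sequence)[(pos0 %% ref$length) + 1L]
}

#' Simulate a random circular reference genome
#'
#' Draws an i.i.d. base sequence at a target GC content. Used as a
#' stand-in for the 16,569 bp human mtDNA reference coordinate system in
#' simulations.
#'
#' @param length Genome length in bp (>= 1000 for realistic simulation).
#' @param gc Target GC fraction in (0, 1).
#' @param seed Integer seed; identical seeds give identical sequences.
#' @param name Sequence name.
#' @return A [reference_genome()] object.
#' @export
simulate_reference <- function(length, gc = 0.44, seed = NULL, name = "sim_mt") {
  stopifnot_scalar_number(length, "length", lower = 1)
  if (length < 1000) {
    abort("simulated references must be at least 1,000 bp",
          class = "ancientmt_invalid_argument")
  }
  stopifnot_scalar_number(gc, "gc")
  if (gc <= 0 || gc >= 1) {
    abort("`gc` must be strictly between 0 and 1",
          class = "ancientmt_invalid_argument")
  }
  bases <- with_seed_or_not(seed, sample(
    DNA_BASES, size = length, replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ))
  reference_genome(paste(bases, collapse = ""), name = name, circular = TRUE)
}

#' Read / write FASTA sequences as named character strings
#'
#' Thin wrappers around ape's FASTA I/O returning the representation the
#' rest of the package uses: a named character vector of upper-case
#' sequences (N allowed).
#'
#' @param path File path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  chars <- as.character(dna)
  out <- vapply(chars, function(x) toupper(paste(x, collapse = "")), character(1))
  setNames(out, names(dna))
}

#' @param sequences Named character vector of sequences.
#' @rdname read_fasta
#' @return `write_fasta()`: the path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    abort("`sequences` must be a named character vector",
          class = "ancientmt_invalid_argument")
  }
  lines <- character(0)
  for (i in seq_along(sequences)) {
    body <- gsub("(.{70})", "\\1\n", sequences[[i]])
    body <- sub("\n$", "", body)
    lines <- c(lines, paste0(">", names(sequences)[i]), body)
  }
  writeLines(lines, path)
  invisible(path)
}
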