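#' Specification of a toy transcriptome and read simulation
#'
#' Parameters for the toy substrate of the expression noise-floor procedure:
#' a transcriptome of random-composition sequences including families of
#' near-duplicate transcripts (the realistic source of read misassignment),
#' and single-end reads with uniform positional coverage, Poisson-distributed
#' counts and per-base substitution errors.
#'
#' @param n_transcripts total number of transcripts.
#' @param length_range length-2 integer range of transcript lengths, nt.
#' @param n_families number of near-duplicate families.
#' @param family_size members per family (default 2, i.e. pairs).
#' @param divergence substitutions per site within a family, in \[0, 0.2\].
#' @param read_length read length, nt; must be below the minimum transcript
#'   length.
#' @param error_rate per-base substitution error rate, in \[0, 0.25).
#' @param seed integer seed.
#' @return A `read_sim_spec` object.
#' @export
read_sim_spec <- function(n_transcripts = 300, length_range = c(300, 600),
                          n_families = 20, family_size = 2,
                          divergence = 0.02, read_length = 100,
                          error_rate = 0.001, seed = NULL) {
  if (read_length >= min(length_range)) {
    stop("read_length must be below the minimum transcript length")
  }
  if (error_rate < 0 || error_rate >= 0.25) stop("error_rate must lie in [0, 0.25)")
  if (divergence < 0 || divergence > 0.2) stop("divergence must lie in [0, 0.2]")
  if (n_families * (family_size - 1) >= n_transcripts) {
    stop("too many family members for n_transcripts")
  }
  structure(list(n_transcripts = n_transcripts, length_range = length_range,
                 n_families = n_families, family_size = family_size,
                 divergence = divergence, read_length = read_length,
                 error_rate = error_rate, seed = seed),
            class = "read_sim_spec")
}

BASES <- c("A", "C", "G", "T")

random_sequence <- function(len) {
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

mutate_sequence <- function(seq, divergence) {
  if (divergence == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < divergence)
  for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1)
  paste(ch, collapse = "")
}

#' Generate a toy transcriptome
#'
#' Independent random-composition sequences plus `n_families` families whose
#' extra members are point-mutated copies of a base sequence at the stated
#' divergence. Families create k-mer sharing and hence realistic read
#' misassignment for the noise-floor procedure.
#'
#' @param spec a [read_sim_spec()].
#' @return A `toy_transcriptome`: list with `sequences` (named character
#'   vector, ids `t0001`...) and `families` (data frame transcript_id,
#'   family_id; singletons have `family_id = NA`).
#' @export
gen_toy_transcriptome <- function(spec) {
  stopifnot(inherits(spec, "read_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n_extra <- spec$n_families * (spec$family_size - 1)
  n_indep <- spec$n_transcripts - n_extra
  lens <- sample(seq(spec$length_range[1], spec$length_range[2]), n_indep,
                 replace = TRUE)
  base_seqs <- vapply(lens, random_sequence, character(1))
  seqs <- base_seqs
  fam <- rep(NA_integer_, n_indep)
  if (spec$n_families > 0) {
    # the last n_families independent sequences seed the families
    fam_base_idx <- (n_indep - spec$n_families + 1L):n_indep
    fam[fam_base_idx] <- seq_len(spec$n_families)
    for (fi in seq_len(spec$n_families)) {
      for (k in seq_len(spec$family_size - 1)) {
        seqs <- c(seqs, mutate_sequence(base_seqs[fam_base_idx[fi]], spec$divergence))
        fam <- c(fam, fi)
      }
    }
  }
  ids <- sprintf("t%04d", seq_along(seqs))
  names(seqs) <- ids
  structure(list(sequences = seqs,
                 families = data.frame(transcript_id = ids, family_id = fam)),
            class = "toy_transcriptome")
}

#' @export
print.toy_transcriptome <- function(x, ...) {
  cat(sprintf("<toy_transcriptome> %d transcripts (%d in %d families)\n",
              length(x$sequences), sum(!is.na(x$families$family_id)),
              length(unique(stats::na.omit(x$families$family_id)))))
  invisible(x)
}

#' Simulate single-end reads from a transcriptome
#'
#' Per transcript the read count is Poisson around its requested abundance;
#' read start positions are uniform along the transcript; substitution errors
#' are applied per base at `error_rate`. Each read carries its true source
#' transcript, used only by tests and never by the quantifier.
#'
#' @param transcriptome a `toy_transcriptome` (or named character vector of
#'   sequences).
#' @param abundances named numeric vector of expected read counts, keyed by
#'   transcript id (zero allowed; ids absent from the transcriptome are an
#'   error).
#' @param spec a [read_sim_spec()] (supplies read length and error rate).
#' @param seed optional integer seed.
#' @return A `read_set`: list with `reads` (character vector) and
#'   `true_source` (transcript ids).
#' @export
gen_reads <- function(transcriptome, abundances, spec, seed = NULL) {
  seqs <- if (inherits(transcriptome, "toy_transcriptome")) {
    transcriptome$sequences
  } else transcriptome
  unknown <- setdiff(names(abundances), names(seqs))
  if (length(unknown)) {
    stop("abundance given for unknown transcript(s): ",
         paste(unknown, collapse = ", "))
  }
  if (any(abundances < 0)) stop("abundances must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  rl <- spec$read_length
  counts <- stats::rpois(length(abundances), abundances)
  names(counts) <- names(abundances)
  reads <- character(0)
  src <- character(0)
  for (tid in names(counts)[counts > 0]) {
    s <- seqs[[tid]]
    L <- nchar(s)
    starts <- sample.int(L - rl + 1L, counts[[tid]], replace = TRUE)
    reads <- c(reads, substring(s, starts, starts + rl - 1L))
    src <- c(src, rep(tid, counts[[tid]]))
  }
  if (spec$error_rate > 0 && length(reads) > 0) {
    reads <- apply_read_errors(reads, spec$error_rate)
  }
  structure(list(reads = reads, true_source = src, read_length = rl),
            class = "read_set")
}

# vectorised per-base substitution: the expected number of errors is
# n_reads * read_length * rate; error positions are drawn jointly.
apply_read_errors <- function(reads, rate) {
  rl <- nchar(reads[1])
  n_err <- stats::rbinom(1, length(reads) * rl, rate)
  if (n_err == 0) return(reads)
  pos <- sample.int(length(reads) * rl, n_err)
  ridx <- (pos - 1L) %/% rl + 1L
  cidx <- (pos - 1L) %% rl + 1L
  for (j in seq_len(n_err)) {
    old <- substr(reads[ridx[j]], cidx[j], cidx[j])
    substr(reads[ridx[j]], cidx[j], cidx[j]) <- sample(setdiff(BASES, old), 1)
  }
  reads
}

#' Write a toy transcriptome to FASTA
#' @param transcriptome a `toy_transcriptome`.
#' @param path output FASTA path.
#' @export
write_transcriptome_fasta <- function(transcriptome, path) {
  x <- Biostrings::DNAStringSet(transcriptome$sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a transcriptome from FASTA
#' @param path FASTA path.
#' @return A `toy_transcriptome` with all `family_id` NA (families unknown
#'   for external input).
#' @export
read_transcriptome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  structure(list(sequences = seqs,
                 families = data.frame(transcript_id = names(seqs),
                                       family_id = NA_integer_)),
            class = "toy_transcriptome")
}

#' Write a read set to FASTQ (constant quality)
#' @param read_set a `read_set` from [gen_reads()].
#' @param path output FASTQ path.
#' @export
write_reads_fastq <- function(read_set, path) {
  x <- Biostrings::DNAStringSet(read_set$reads)
  names(x) <- sprintf("read%06d", seq_along(read_set$reads))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::PhredQuality(
                                vapply(nchar(read_set$reads),
                                       function(n) paste(rep("I", n), collapse = ""),
                                       character(1))))
  invisible(path)
}
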