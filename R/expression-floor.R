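#' Toy k-mer read quantifier
#'
#' Assigns each read to the transcript sharing the most k-mers with it: a
#' unique best match takes the read; ties (the misassignment mechanism
#' between near-duplicate transcripts) are broken by a seeded uniform draw;
#' reads sharing no k-mer with any transcript stay unassigned. This honours
#' the contract of a pseudo-alignment quantifier while remaining fully
#' inspectable; real quantifier outputs can enter the pipeline as plain
#' count tables instead.
#'
#' @param read_set a `read_set` from [gen_reads()] (or list with a `reads`
#'   character vector).
#' @param transcriptome a `toy_transcriptome`.
#' @param k k-mer size (default 15); must be below the read length.
#' @param seed integer seed for tie-breaking.
#' @return Named integer vector of read counts per transcript (every
#'   transcript present, zeros included), with attribute `n_unassigned`.
#' @export
quantify_reads <- function(read_set, transcriptome, k = 15, seed = 1) {
  seqs <- transcriptome$sequences
  if (length(seqs) == 0) stop("empty transcriptome")
  reads <- read_set$reads
  counts <- stats::setNames(integer(length(seqs)), names(seqs))
  if (length(reads) == 0) {
    attr(counts, "n_unassigned") <- 0L
    return(counts)
  }
  if (k >= min(nchar(reads))) stop("k must be below the read length")
  idx <- kmer_index(seqs, k)
  rk <- read_kmers(reads, k)
  hits <- idx[rk, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  set.seed(seed)
  n_assigned_tbl <- NULL
  if (nrow(hits) > 0) {
    shared <- hits[, .N, by = c("read_id", "tid")]
    best <- shared[, {
      mx <- max(N)
      cand <- tid[N == mx]
      list(tid = if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)])
    }, by = "read_id"]
    tb <- table(best$tid)
    counts[names(tb)] <- as.integer(tb)
    attr(counts, "n_unassigned") <- length(reads) - nrow(best)
  } else {
    attr(counts, "n_unassigned") <- length(reads)
  }
  counts
}

# k-mer -> transcript index as a keyed data.table (unique pairs)
kmer_index <- function(seqs, k) {
  tabs <- lapply(names(seqs), function(tid) {
    s <- seqs[[tid]]
    n <- nchar(s) - k + 1L
    data.table::data.table(kmer = unique(substring(s, 1:n, k:(n + k - 1L))),
                           tid = tid)
  })
  dt <- data.table::rbindlist(tabs)
  data.table::setkey(dt, kmer)
  dt
}

# unique k-mers per read
read_kmers <- function(reads, k) {
  rl <- nchar(reads)
  stopifnot(length(unique(rl)) == 1L) # toy simulator emits fixed-length reads
  n <- rl[1] - k + 1L
  km <- vapply(1:n, function(i) substring(reads, i, i + k - 1L),
               character(length(reads)))
  dt <- data.table::data.table(read_id = rep(seq_along(reads), n),
                               kmer = as.vector(km))
  unique(dt)
}

#' Estimate the count noise floor by hold-out simulation
#'
#' The quantification noise floor is the distribution of read counts falsely
#' assigned to transcripts that contributed no reads. Per round, `n_heldout`
#' transcripts are removed at random; reads are simulated from the remainder
#' and quantified against the full transcriptome; the mean count landing on
#' the held-out transcripts is recorded. After `n_rounds` rounds the round
#' means are screened for normality (Shapiro-Wilk; a warning, not an error,
#' when p < 0.05) and their mean defines the rate of a Poisson noise law.
#'
#' @param transcriptome a `toy_transcriptome`.
#' @param spec a [read_sim_spec()] for the simulated reads.
#' @param abundances named expected read counts per transcript; default
#'   uniform at `mean_abundance`.
#' @param mean_abundance expected reads per transcript for the default
#'   uniform profile (default 30).
#' @param n_heldout transcripts removed per round (default 50).
#' @param n_rounds hold-out rounds (default 10).
#' @param k quantifier k-mer size (default 15).
#' @param seed integer seed driving the whole procedure.
#' @return A `noise_model`: list with `lambda_noise`, `round_means`,
#'   `n_heldout`, `n_rounds`, `normality_p`.
#' @export
estimate_noise_distribution <- function(transcriptome, spec,
                                        abundances = NULL,
                                        mean_abundance = 30,
                                        n_heldout = 50, n_rounds = 10,
                                        k = 15, seed = 1) {
  ids <- names(transcriptome$sequences)
  if (n_heldout >= length(ids)) stop("n_heldout must be below the transcriptome size")
  if (n_rounds < 2) stop("need at least 2 rounds")
  if (is.null(abundances)) {
    abundances <- stats::setNames(rep(mean_abundance, length(ids)), ids)
  }
  set.seed(seed)
  round_seeds <- sample.int(.Machine$integer.max, n_rounds)
  round_means <- numeric(n_rounds)
  for (r in seq_len(n_rounds)) {
    set.seed(round_seeds[r])
    held <- sample(ids, n_heldout)
    ab <- abundances[setdiff(ids, held)]
    rs <- gen_reads(transcriptome, ab, spec, seed = round_seeds[r] %% 1000000L)
    if (length(rs$reads) == 0) stop("round ", r, " yielded zero reads")
    counts <- quantify_reads(rs, transcriptome, k = k, seed = round_seeds[r] %% 1000L)
    round_means[r] <- mean(counts[held])
  }
  normality_p <- tryCatch(stats::shapiro.test(round_means)$p.value,
                          error = function(e) NA_real_)
  if (is.finite(normality_p) && normality_p < 0.05) {
    warning("round means deviate from normality (Shapiro-Wilk p = ",
            format(normality_p, digits = 3), ")")
  }
  structure(list(lambda_noise = mean(round_means), round_means = round_means,
                 n_heldout = n_heldout, n_rounds = n_rounds,
                 normality_p = normality_p),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "<noise_model> lambda_noise %.4g (%d rounds x %d held out; Shapiro-Wilk p = %.3g)\n",
    x$lambda_noise, x$n_rounds, x$n_heldout, x$normality_p))
  invisible(x)
}

#' Upper tail of the Poisson noise law
#'
#' P(X >= c) for X ~ Poisson(lambda), evaluated through the regularized
#' incomplete gamma function so non-integer mean counts are handled
#' continuously (no rounding); for integer c this equals the direct tail sum.
#'
#' @param c_bar observed mean count (>= 0).
#' @param lambda Poisson rate (>= 0).
#' @return Tail probability; 1 when `c_bar` is 0.
#' @export
poisson_tail <- function(c_bar, lambda) {
  if (any(c_bar < 0) || any(lambda < 0)) stop("c_bar and lambda must be non-negative")
  ifelse(c_bar <= 0, 1, stats::pgamma(lambda, shape = c_bar, lower.tail = TRUE))
}

#' Call transcripts expressed above the noise floor
#'
#' Per transcript the mean count across samples (circadian time points) is
#' compared to the Poisson noise law: the probability of the observed mean
#' arising solely from noise is the Poisson upper tail, adjusted across all
#' transcripts by Benjamini-Hochberg; transcripts with adjusted p <= `alpha`
#' are called expressed.
#'
#' @param counts matrix of non-negative counts, transcripts in rows
#'   (rownames = transcript ids), samples in columns; a named vector is
#'   treated as a one-sample matrix.
#' @param noise a `noise_model` (or a bare lambda value).
#' @param alpha significance level on adjusted p (default 0.05).
#' @param round_means if `TRUE`, round mean counts to integers before the
#'   tail test (sensitivity mode; default uses the continuous tail).
#' @return Data frame (transcript_id, mean_count, p_raw, p_adj, expressed).
#' @export
call_expressed <- function(counts, noise, alpha = 0.05, round_means = FALSE) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1,
                                             dimnames = list(names(counts), NULL))
  if (any(counts < 0)) stop("negative counts")
  lambda <- if (inherits(noise, "noise_model")) noise$lambda_noise else as.numeric(noise)
  if (lambda < 0) stop("lambda_noise must be non-negative")
  cbar <- rowMeans(counts)
  if (round_means) cbar <- round(cbar)
  p_raw <- poisson_tail(cbar, lambda)
  p_adj <- bh_adjust(p_raw)
  data.frame(transcript_id = rownames(counts) %||% as.character(seq_along(cbar)),
             mean_count = cbar, p_raw = p_raw, p_adj = p_adj,
             expressed = p_adj <= alpha, row.names = NULL)
}
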