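make_floor_fixture <- function(n = 40, n_families = 4, divergence = 0.02,
                               seed = 10) {
  spec <- read_sim_spec(n_transcripts = n, n_families = n_families,
                        divergence = divergence, length_range = c(200, 300),
                        read_length = 80, error_rate = 0, seed = seed)
  list(spec = spec, tx = gen_toy_transcriptome(spec))
}

test_that("reads without homologs are assigned to their true source", {
  fx <- make_floor_fixture(n = 20, n_families = 0)
  ab <- setNames(rep(10, 20), names(fx$tx$sequences))
  rs <- gen_reads(fx$tx, ab, fx$spec, seed = 1)
  cts <- quantify_reads(rs, fx$tx, k = 15, seed = 1)
  truth <- table(rs$true_source)
  expect_equal(as.integer(cts[names(truth)]), as.integer(truth))
  expect_equal(attr(cts, "n_unassigned"), 0)
})

test_that("identical-pair reads split about 50/50 and aliens stay unassigned", {
  spec <- read_sim_spec(n_transcripts = 10, n_families = 1, divergence = 0,
                        length_range = c(250, 300), read_length = 80,
                        error_rate = 0, seed = 5)
  tx <- gen_toy_transcriptome(spec)
  pair <- tx$families$transcript_id[!is.na(tx$families$family_id)]
  ab <- setNames(rep(0, 10), names(tx$sequences))
  ab[pair[1]] <- 2000
  rs <- gen_reads(tx, ab, spec, seed = 2)
  cts <- quantify_reads(rs, tx, k = 15, seed = 3)
  n <- length(rs$reads)
  # 3-sigma binomial band around the even split
  expect_lt(abs(cts[[pair[1]]] - n / 2), 3 * sqrt(n * 0.25))
  expect_equal(cts[[pair[1]]] + cts[[pair[2]]], n)

  set.seed(9)
  alien <- list(reads = paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                              collapse = ""))
  cts2 <- quantify_reads(alien, tx, k = 31, seed = 1)
  expect_equal(sum(cts2), 0)
  expect_equal(attr(cts2, "n_unassigned"), 1)
  expect_error(quantify_reads(rs, list(sequences = character(0))), "empty")
})

test_that("the Poisson tail via incomplete gamma equals direct summation", {
  direct_tail <- function(c0, lambda) {
    # sum_{j >= c0} e^-lambda lambda^j / j!, up to far past the mass
    j <- c0:(c0 + 400)
    sum(exp(-lambda + j * log(lambda) - lgamma(j + 1)))
  }
  for (lambda in c(0.5, 2, 10, 50)) {
    for (c0 in c(1, 2, 5, 10, 100)) {
      expect_equal(poisson_tail(c0, lambda), direct_tail(c0, lambda),
                   tolerance = 1e-10)
    }
  }
  expect_equal(poisson_tail(0, 5), 1)
  expect_equal(poisson_tail(10, 2), 4.649808e-05, tolerance = 1e-6)
})

test_that("expression calls flip exactly at the adjusted-p threshold", {
  lam <- 2
  counts <- matrix(c(0, 3, 5, 9, 30), ncol = 1,
                   dimnames = list(paste0("t", 1:5), NULL))
  calls <- call_expressed(counts, lam, alpha = 0.05)
  expect_equal(calls$expressed, calls$p_adj <= 0.05)
  expect_false(calls$expressed[calls$mean_count == 0])
  expect_equal(calls$p_raw[1], 1)
  expect_true(calls$expressed[calls$mean_count == 30])
  expect_equal(calls$p_adj, bh_adjust(calls$p_raw))
  expect_error(call_expressed(matrix(-1), lam), "negative")
})

test_that("the hold-out procedure defaults to 50 transcripts and 10 rounds", {
  expect_equal(formals(estimate_noise_distribution)$n_heldout, 50)
  expect_equal(formals(estimate_noise_distribution)$n_rounds, 10)
  expect_equal(formals(call_expressed)$alpha, 0.05)
})

test_that("a transcriptome without k-mer sharing yields a zero noise floor", {
  fx <- make_floor_fixture(n = 40, n_families = 0)
  nm <- suppressWarnings(estimate_noise_distribution(
    fx$tx, fx$spec, mean_abundance = 10, n_heldout = 8, n_rounds = 4, seed = 3))
  expect_equal(nm$lambda_noise, 0)
  expect_equal(nm$round_means, rep(0, 4))
})

test_that("identical-sequence families raise the noise floor at equal depth", {
  for (s in 1:3) {
    plain <- make_floor_fixture(n = 40, n_families = 0, seed = 100 + s)
    fam <- make_floor_fixture(n = 40, n_families = 6, divergence = 0,
                              seed = 100 + s)
    nm0 <- suppressWarnings(estimate_noise_distribution(
      plain$tx, plain$spec, mean_abundance = 15, n_heldout = 10, n_rounds = 4,
      seed = s))
    nm1 <- suppressWarnings(estimate_noise_distribution(
      fam$tx, fam$spec, mean_abundance = 15, n_heldout = 10, n_rounds = 4,
      seed = s))
    expect_gt(nm1$lambda_noise, nm0$lambda_noise)
  }
})

test_that("the noise floor is reproducible for a fixed seed", {
  fx <- make_floor_fixture(n = 30, n_families = 3, divergence = 0.02)
  nm1 <- suppressWarnings(estimate_noise_distribution(
    fx$tx, fx$spec, mean_abundance = 10, n_heldout = 6, n_rounds = 3, seed = 42))
  nm2 <- suppressWarnings(estimate_noise_distribution(
    fx$tx, fx$spec, mean_abundance = 10, n_heldout = 6, n_rounds = 3, seed = 42))
  expect_identical(nm1$round_means, nm2$round_means)
})
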