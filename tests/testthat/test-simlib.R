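test_that("library sampling is seed-reproducible and respects degenerate designs", {
  d2 <- default_cdr2_design()
  d3 <- default_cdr3_design()
  a <- sample_library(d2, d3, 200, seed = 11)
  b <- sample_library(d2, d3, 200, seed = 11)
  expect_identical(a, b)
  c <- sample_library(d2, d3, 200, seed = 12)
  expect_false(identical(a$clone, c$clone))

  single2 <- cdr_design("s2", lapply(1:4, function(j)
    position_frequency(paste0("p", j), c(G = 1))))
  single3 <- cdr_design("s3", lapply(1:7, function(j)
    position_frequency(paste0("p", j), c(S = 1))))
  mono <- sample_library(single2, single3, 50, seed = 1)
  expect_identical(unique(mono$clone), "GGGG:SSSSSSS")
})

test_that("empirical per-position frequencies recover the design marginals", {
  d2 <- default_cdr2_design()
  d3 <- default_cdr3_design()
  n <- 1e5
  lib <- sample_library(d2, d3, n, seed = 7)
  check_marginals <- function(seqs, design) {
    for (j in seq_along(design$positions)) {
      f <- design$positions[[j]]$freq
      f <- f[f > 0]
      obs <- table(factor(substr(seqs, j, j), levels = names(f))) / length(seqs)
      # 4-sigma binomial bound per residue
      bound <- 4 * sqrt(f * (1 - f) / n)
      expect_true(all(abs(as.numeric(obs) - f) <= bound + 1e-12),
                  info = paste(design$name, j))
    }
  }
  check_marginals(lib$cdr2, d2)
  check_marginals(lib$cdr3, d3)
})

test_that("construction simulation produces the configured error pattern", {
  clones <- sprintf("clone%03d", 1:400)
  clean <- simulate_construction(clones, double_rate = 0, frameshift_rate = 0,
                                 seed = 5)
  expect_true(all(clean$category == "good"))
  expect_true(all(is.na(clean$frameshift_position)))

  fs <- simulate_construction(clones, double_rate = 0, frameshift_rate = 1,
                              hotspot = c(181, 216), seed = 5)
  expect_true(all(fs$category == "frameshift"))
  expect_true(all(fs$frameshift_position >= 181 & fs$frameshift_position <= 216))
  expect_error(simulate_construction(clones, frameshift_rate = 0.5,
                                     hotspot = c(10, 5)), "hotspot")

  # doubles carry two plasmids; goods carry one
  mix <- simulate_construction(clones, seed = 9)
  expect_true(all(is.na(mix$plasmid2[mix$category != "double"])))
  expect_true(all(!is.na(mix$plasmid2[mix$category == "double"])))

  # category rates reproduce the 24-colony pattern in expectation:
  # 8/24 frameshift, 5/19 double among correct
  reps <- 1000
  counts <- vapply(seq_len(reps), function(r) {
    col <- simulate_construction(sprintf("c%d", 1:24), seed = r)
    c(fs = sum(col$category == "frameshift"),
      dbl = sum(col$category == "double"))
  }, c(fs = 0, dbl = 0))
  mean_fs <- mean(counts["fs", ])
  mean_dbl <- mean(counts["dbl", ])
  se_fs <- sd(counts["fs", ]) / sqrt(reps)
  se_dbl <- sd(counts["dbl", ]) / sqrt(reps)
  expect_lt(abs(mean_fs - 24 * 8 / 24), 4 * se_fs)
  expect_lt(abs(mean_dbl - 24 * (16 / 24) * (5 / 19)), 4 * se_dbl)
})

test_that("QC simulation yields valid summaries across many random runs", {
  set.seed(42)
  for (r in 1:200) {
    n_col <- sample(30:100, 1)
    col <- simulate_construction(sprintf("c%d", seq_len(n_col)),
                                 double_rate = runif(1, 0, 0.5),
                                 frameshift_rate = runif(1, 0, 0.8),
                                 seed = r)
    qc <- simulate_qc(col, n_picked = sample(5:24, 1),
                      fail_rate = runif(1, 0, 0.3), seed = r + 1000)
    expect_s3_class(qc, "qc_summary")  # constructor enforces all invariants
    expect_identical(qc$n_good + qc$n_frameshift + qc$n_failed, qc$n_sampled)
    expect_lte(qc$n_double, qc$n_good)
  }
  col <- simulate_construction(sprintf("c%d", 1:50), seed = 1)
  all_fail <- simulate_qc(col, 20, fail_rate = 1, seed = 2)
  expect_identical(all_fail$n_failed, all_fail$n_sampled)
  clean <- simulate_construction(sprintf("c%d", 1:50), double_rate = 0,
                                 frameshift_rate = 0, seed = 3)
  perfect <- simulate_qc(clean, 20, fail_rate = 0, seed = 4)
  expect_identical(perfect$n_good, 20L)
})

test_that("trypsin filtering removes exactly the frameshifted colonies", {
  clones <- sprintf("c%d", 1:300)
  col <- simulate_construction(clones, seed = 21)
  kept <- trypsin_filter(col)
  expect_identical(nrow(kept), sum(col$category != "frameshift"))
  expect_false(any(kept$category == "frameshift"))
  all_fs <- simulate_construction(clones, frameshift_rate = 1, seed = 22)
  expect_identical(nrow(trypsin_filter(all_fs)), 0L)
  none_fs <- simulate_construction(clones, frameshift_rate = 0, seed = 23)
  expect_identical(trypsin_filter(none_fs), none_fs)
  # filtered fraction tracks the frameshift rate (binomial 4-sigma bound)
  f <- 1 / 3
  big <- simulate_construction(sprintf("c%d", 1:5000), frameshift_rate = f,
                               seed = 24)
  removed <- 1 - nrow(trypsin_filter(big)) / 5000
  expect_lt(abs(removed - f), 4 * sqrt(f * (1 - f) / 5000))
})

test_that("panning enrichment matches the closed-form expectation", {
  m <- panning_model(c(3, 1))
  post <- simulate_panning(c(0.5, 0.5), m)
  expect_equal(post, c(0.75, 0.25))
  # uniform weights leave frequencies unchanged
  expect_equal(simulate_panning(c(0.2, 0.3, 0.5), panning_model(c(2, 2, 2))),
               c(0.2, 0.3, 0.5))
  # a single clone with all the weight takes over
  expect_equal(simulate_panning(c(0.9, 0.1), panning_model(c(0, 1))), c(0, 1))
  expect_error(simulate_panning(c(1, 0), panning_model(c(0, 5))), "zero")
  expect_error(panning_model(c(0, 0)))
  # two rounds compound the enrichment
  two <- simulate_panning(c(0.5, 0.5), panning_model(c(3, 1), rounds = 2))
  expect_equal(two, c(0.9, 0.1))
  # stochastic elution: mean over many draws within 3 sigma of expectation
  draws <- vapply(1:400, function(s)
    simulate_panning(c(0.5, 0.5), m, n_eluted = 25, seed = s)[1], 1.0)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.75), 3 * se)
})
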