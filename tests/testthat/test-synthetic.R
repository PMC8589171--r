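test_that("prototype sampling has the configured shape and spread", {
  cfg <- synthetic_config(seed = 1)
  set.seed(1)
  pr <- generate_prototypes(cfg)
  expect_equal(dim(pr), c(5L, 10L))

  # degenerate sd collapses every prototype onto the origin
  cfg0 <- synthetic_config(prototype_sd = 0, seed = 1)
  set.seed(1)
  expect_true(all(generate_prototypes(cfg0) == 0))

  # law of large numbers: the sample sd of many entries approaches 10
  big <- synthetic_config(n_prototypes_true = 10000, latent_dim = 10, seed = 2)
  set.seed(2)
  entries <- as.vector(generate_prototypes(big))
  expect_lt(abs(sd(entries) - 10) / 10, 0.02)
})

test_that("latent patients scatter around their prototypes", {
  cfg <- synthetic_config(seed = 4)
  set.seed(4)
  pr <- generate_prototypes(cfg)
  lat <- generate_latent_patients(pr, cfg)
  expect_equal(nrow(lat$latent_z), 10000L)
  expect_equal(lat$prototype_label, rep(1:5, each = 2000))

  # CLT bound on the per-prototype sample means; 4 sd/sqrt(n) keeps the
  # joint false-alarm rate across all 50 coordinates negligible
  bound <- 4 * cfg$patient_sd / sqrt(cfg$patients_per_prototype)
  for (i in 1:5) {
    mu <- colMeans(lat$latent_z[lat$prototype_label == i, ])
    expect_true(all(abs(mu - pr[i, ]) < bound))
  }

  # zero spread makes every patient identical to its prototype
  cfg0 <- synthetic_config(patient_sd = 0, patients_per_prototype = 3, seed = 4)
  set.seed(4)
  pr0 <- generate_prototypes(cfg0)
  lat0 <- generate_latent_patients(pr0, cfg0)
  expect_equal(lat0$latent_z, pr0[lat0$prototype_label, ],
               ignore_attr = TRUE)

  expect_error(generate_latent_patients(pr[, 1:3], cfg), "matrix")
})

test_that("true remission probabilities follow the two-layer softmax", {
  cfg <- small_synth_config(seed = 9)
  set.seed(9)
  fns <- remission_function_set(cfg)
  expect_length(fns, 3L)
  expect_equal(dim(fns[[1]]$W1), c(4L, 5L))
  expect_equal(dim(fns[[1]]$W2), c(5L, 2L))

  # zero latent vector: ReLU output zero, both logits zero, softmax 1/2
  expect_equal(true_remission_probability(fns, rep(0, 4), 0L), 0.5)

  # independent hand-rolled evaluation: ReLU(z W1) W2 then 2-way softmax
  set.seed(10)
  z <- rnorm(4)
  for (j in 0:2) {
    f <- fns[[j + 1]]
    hidden <- pmax(as.vector(z %*% f$W1), 0)
    logits <- as.vector(hidden %*% f$W2)
    oracle <- exp(logits[2]) / (exp(logits[1]) + exp(logits[2]))
    expect_equal(true_remission_probability(fns, z, j), oracle,
                 tolerance = 1e-12)
  }

  expect_error(true_remission_probability(fns, z, 3L), "treatment")
})

test_that("treatment assignment is uniform and outcomes are Bernoulli draws", {
  cfg <- synthetic_config(seed = 6)
  set.seed(6)
  pr <- generate_prototypes(cfg)
  lat <- generate_latent_patients(pr, cfg)
  fns <- remission_function_set(cfg)
  out <- assign_treatments_and_outcomes(lat$latent_z, fns, cfg)

  # binomial 99% bounds around N/k for each arm at N = 10,000, k = 4
  counts <- tabulate(out$t + 1L, nbins = 4L)
  p <- 1 / 4
  bound <- 2.576 * sqrt(10000 * p * (1 - p))
  expect_true(all(abs(counts - 2500) < bound))

  # every counterfactual entry defined and strictly inside (0,1)
  expect_equal(dim(out$p_true), c(10000L, 4L))
  expect_true(all(out$p_true > 0 & out$p_true < 1))

  # empirical remission frequency per arm tracks the mean true
  # probability of that arm (Monte-Carlo agreement at n = 10^4)
  for (j in 0:3) {
    idx <- out$t == j
    expect_lt(abs(mean(out$y[idx]) - mean(out$p_true[idx, j + 1])), 0.05)
  }
})

test_that("decoding produces the observed feature block plus noise columns", {
  cfg <- synthetic_config(seed = 8)
  set.seed(8)
  z <- matrix(rnorm(200 * 10), 200, 10)
  dec <- decode_to_observed(z, cfg)
  expect_equal(ncol(dec$x), 20L)

  # the decoded block is a rank-<=10 linear image of the latent space
  expect_lte(qr(dec$x[, 1:16])$rank, 10L)

  # zero latent input leaves only the irrelevant noise columns
  dec0 <- decode_to_observed(matrix(0, 50, 10), cfg)
  expect_true(all(dec0$x[, 1:16] == 0))
  expect_true(sd(dec0$x[, 17:20]) > 0)
})

test_that("cohort generation is seeded, complete and self-consistent", {
  cfg <- small_synth_config(seed = 21)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$x, co2$x)
  expect_identical(co1$y, co2$y)
  expect_identical(co1$p_true, co2$p_true)

  co3 <- generate_cohort(small_synth_config(seed = 22))
  expect_false(identical(co1$x, co3$x))
  expect_false(identical(co1$fns[[1]]$W1, co3$fns[[1]]$W1))

  expect_equal(nrow(co1$x), 180L)
  expect_equal(ncol(co1$x), 8L)
  expect_true(all(co1$t %in% 0:2))
  expect_true(all(co1$y %in% 0:1))
  expect_true(all(co1$p_true > 0 & co1$p_true < 1))

  # treatment allocation carries no feature signal: the observed
  # association between an arm indicator and the features is within the
  # permutation null (loose check)
  co <- generate_cohort(synthetic_config(seed = 31,
                                         patients_per_prototype = 400))
  arm0 <- as.integer(co$t == 0)
  score <- function(lab) max(abs(cor(co$x, lab)))
  obs <- score(arm0)
  set.seed(31)
  null <- replicate(99, score(sample(arm0)))
  expect_gt(mean(null >= obs), 0.01)
})

test_that("cohorts round-trip through the CSV writer", {
  co <- generate_cohort(small_synth_config(seed = 12))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  back <- read_cohort(dir)
  expect_equal(back$x, co$x, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$t, co$t)
  expect_identical(back$y, co$y)
  expect_equal(back$p_true, co$p_true, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$config$seed, co$config$seed)
})
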