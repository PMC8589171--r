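test_that("encoder and decoder honor shape contracts and hand-set weights", {
  cfg <- dpnn_config(n_prototypes = 5, input_dim = 20, latent_dim = 10,
                     encoder_hidden = 14, classifier_hidden = 16,
                     n_treatments = 4, seed = 2)
  model <- dpnn_init(cfg)
  x <- matrix(rnorm(7 * 20), 7, 20)
  codes <- encode(model, x)
  expect_equal(dim(codes), c(7L, 10L))
  expect_equal(dim(reconstruct(model, codes)), c(7L, 20L))
  expect_error(encode(model, x[, 1:5]), "columns")
  expect_error(reconstruct(model, codes[, 1:3]), "columns")

  # zero weights give zero codes
  zm <- zero_weights(model)
  expect_true(all(encode(zm, x) == 0))

  # identity-like weights pass nonnegative inputs straight through:
  # encoder hidden = input dim, latent = input dim, all biases zero
  cfg_id <- dpnn_config(n_prototypes = 2, input_dim = 4, latent_dim = 4,
                        encoder_hidden = 4, classifier_hidden = 3,
                        n_treatments = 2, seed = 3)
  mid <- dpnn_init(cfg_id)
  mid$We1 <- diag(4); mid$be1[] <- 0
  mid$We2 <- diag(4); mid$be2[] <- 0
  xp <- matrix(runif(6 * 4), 6, 4)  # nonnegative, so the ReLU is inactive
  expect_equal(encode(mid, xp), xp, ignore_attr = TRUE)
  mid$Wd1 <- diag(4); mid$bd1[] <- 0
  mid$Wd2 <- diag(4); mid$bd2[] <- 0
  expect_equal(reconstruct(mid, xp), xp, ignore_attr = TRUE)
})

test_that("prototype distances are squared Euclidean and match a loop", {
  cfg <- dpnn_config(n_prototypes = 2, input_dim = 4, latent_dim = 2,
                     n_treatments = 2, seed = 4)
  model <- dpnn_init(cfg)
  model$P <- rbind(c(3, 4), c(0, 0))
  d <- prototype_distances(model, matrix(c(0, 0), 1))
  expect_equal(d[1, 1], 25)           # 3-4-5 triangle, squared
  expect_equal(d[1, 2], 0)

  # brute-force pairwise loop oracle
  cfg2 <- dpnn_config(n_prototypes = 4, input_dim = 6, latent_dim = 3,
                      n_treatments = 2, seed = 5)
  m2 <- dpnn_init(cfg2)
  set.seed(5)
  codes <- matrix(rnorm(3 * 3), 3, 3)
  d2 <- prototype_distances(m2, codes)
  for (i in 1:3) for (j in 1:4)
    expect_equal(d2[i, j], sum((codes[i, ] - m2$P[j, ])^2),
                 tolerance = 1e-10)

  # plain Euclidean behind the config switch
  cfg3 <- dpnn_config(n_prototypes = 4, input_dim = 6, latent_dim = 3,
                      n_treatments = 2, seed = 5, distance = "euclidean")
  m3 <- dpnn_init(cfg3)
  expect_equal(prototype_distances(m3, codes), sqrt(d2), tolerance = 1e-10)
})

test_that("the classifier outputs probabilities and is deterministic", {
  cfg <- small_dpnn_config()
  model <- dpnn_init(cfg)
  d <- matrix(runif(10 * 3, 0, 5), 10, 3)
  tr <- rep(0:2, length.out = 10)

  # zeroed output layer: logits vanish, probability 1/2 everywhere
  mz <- model; mz$wc2[] <- 0; mz$bc2[] <- 0
  expect_equal(classify(mz, d, tr), rep(0.5, 10))

  # squashing contract over many random weight draws
  set.seed(6)
  for (i in 1:50) {
    mr <- model
    mr$Wc1[] <- rnorm(length(mr$Wc1), sd = 2)
    mr$wc2[] <- rnorm(length(mr$wc2), sd = 2)
    p <- classify(mr, d, tr)
    expect_true(all(p >= 0 & p <= 1))
  }

  expect_identical(classify(model, d, tr), classify(model, d, tr))
  expect_error(classify(model, d, rep(5L, 10)), "range")
})

test_that("the prototype outcome matrix pairs every prototype with every arm", {
  cfg <- small_dpnn_config()   # 3 prototypes x 3 treatments
  model <- dpnn_init(cfg)
  yp <- prototype_outcome_matrix(model)
  expect_equal(dim(yp), c(3L, 3L))
  expect_true(all(yp >= 0 & yp <= 1))

  # identical prototypes have identical distance vectors, hence rows
  mi <- model
  mi$P <- matrix(rep(mi$P[1, ], each = 3), 3)
  ypi <- prototype_outcome_matrix(mi)
  expect_equal(ypi[1, ], ypi[2, ])
  expect_equal(ypi[2, ], ypi[3, ])

  mz <- model; mz$wc2[] <- 0; mz$bc2[] <- 0
  expect_true(all(prototype_outcome_matrix(mz) == 0.5))

  # agrees with the R-side forward pass fed the explicit representation
  dp <- prototype_distances(model, model$P); diag(dp) <- 0
  for (j in 0:2)
    expect_equal(yp[, j + 1], classify(model, dp, rep(j, 3)))
})

test_that("cross-entropy and reconstruction losses match their formulas", {
  expect_equal(loss_accuracy(0.5, 1), -log(0.5), tolerance = 1e-7)
  expect_lt(loss_accuracy(1 - 1e-9, 1), 1e-6)

  # four mixed samples against a hand-computed sum
  p <- c(0.9, 0.2, 0.6, 0.4); y <- c(1, 0, 0, 1)
  hand <- -(log(0.9) + log(0.8) + log(0.4) + log(0.4)) / 4
  expect_equal(loss_accuracy(p, y), hand, tolerance = 1e-12)
  expect_equal(loss_accuracy(p, y, average = FALSE), hand * 4,
               tolerance = 1e-12)

  x <- rbind(c(3, 4))
  expect_equal(loss_reconstruction(x, rbind(c(0, 0))), 5)
  expect_equal(loss_reconstruction(x, x), 0)
  set.seed(7)
  a <- matrix(rnorm(12), 4, 3); b <- matrix(rnorm(12), 4, 3)
  loop <- mean(sapply(1:4, function(i) sqrt(sum((a[i, ] - b[i, ])^2))))
  expect_equal(loss_reconstruction(a, b), loop, tolerance = 1e-12)
  expect_error(loss_reconstruction(a, b[1:2, ]), "shapes")
})

test_that("variance terms reproduce the worked examples and invariances", {
  # frozen values computed with the explicit loop oracle (divisor = #prototypes)
  expect_equal(intra_variance(yp_high_intra), 0.20904444, tolerance = 1e-6)
  expect_equal(inter_variance(yp_low_intra), 0.19611111, tolerance = 1e-6)
  expect_lt(intra_variance(yp_low_intra), 0.001)

  for (yp in list(yp_high_intra, yp_low_intra)) {
    orc <- variance_oracle(yp)
    expect_equal(intra_variance(yp), orc$intra, tolerance = 1e-12)
    expect_equal(inter_variance(yp), orc$inter, tolerance = 1e-12)
  }

  cst <- matrix(0.5, 3, 4)
  expect_equal(intra_variance(cst), 0)
  expect_equal(inter_variance(cst), 0)
  same_rows <- matrix(rep(c(0.2, 0.5, 0.9, 0.4), each = 3), 3)
  expect_equal(inter_variance(same_rows), 0)

  # row permutations leave intra unchanged; column permutations leave
  # inter unchanged; joint permutations leave both unchanged
  set.seed(8)
  yp <- matrix(runif(12), 3, 4)
  expect_equal(intra_variance(yp[c(3, 1, 2), ]), intra_variance(yp))
  expect_equal(inter_variance(yp[, c(4, 2, 1, 3)]), inter_variance(yp))
  expect_equal(intra_variance(yp[c(2, 3, 1), c(4, 2, 1, 3)]),
               intra_variance(yp[, c(4, 2, 1, 3)]))

  # the alternative normalizer just rescales by the number of arms
  expect_equal(intra_variance(yp, "lk") * ncol(yp), intra_variance(yp))
})

test_that("the prototype variance loss is a negated convex combination", {
  expect_equal(loss_prototype_variance(matrix(0.5, 3, 4), alpha = 0.85), 0)
  v <- loss_prototype_variance(yp_high_intra, alpha = 0.85)
  expect_equal(v, -(0.85 * intra_variance(yp_high_intra) +
                    0.15 * inter_variance(yp_high_intra)),
               tolerance = 1e-12)
  expect_lte(v, 0)
  expect_equal(loss_prototype_variance(yp_high_intra, alpha = 1 - 1e-12),
               -intra_variance(yp_high_intra), tolerance = 1e-6)
})

test_that("the combined loss is the weighted sum of its parts", {
  expect_equal(combined_loss(0.7, 10, -0.2, 0.01, 0.05), 0.79)
  expect_equal(combined_loss(0.7, 10, -0.2, 0, 0), 0.7)
  expect_error(combined_loss(1, 1, -1, -0.1, 0.1))
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- small_dpnn_config(lambda1 = 0.01, lambda2 = 0.05, alpha = 0.85)
  model <- dpnn_init(cfg)
  set.seed(42)
  x <- matrix(rnorm(5 * 8), 5, 8)          # 5-sample micro-batch
  tr <- sample(0:2, 5, TRUE)
  y <- sample(0:1, 5, TRUE)
  lg <- dpnn_loss_gradient(model, x, tr, y)

  # loss components recomputed through the R-side forward pass
  codes <- encode(model, x)
  probs <- classify(model, prototype_distances(model, codes), tr)
  expect_equal(lg$L1, loss_accuracy(probs, y), tolerance = 1e-10)
  expect_equal(lg$L2, loss_reconstruction(x, reconstruct(model, codes)),
               tolerance = 1e-10)
  yp <- prototype_outcome_matrix(model)
  expect_equal(lg$L3, loss_prototype_variance(yp, cfg$alpha),
               tolerance = 1e-10)
  expect_equal(lg$loss,
               combined_loss(lg$L1, lg$L2, lg$L3, cfg$lambda1, cfg$lambda2),
               tolerance = 1e-12)

  h <- 1e-5
  loss_at <- function(m) dpnn_loss_gradient(m, x, tr, y, with_grad = FALSE)$loss
  for (nm in names(lg$grad)) {
    g <- lg$grad[[nm]]
    fd <- g * 0
    for (i in seq_along(model[[nm]])) {
      mp <- model; mp[[nm]][i] <- mp[[nm]][i] + h
      mm <- model; mm[[nm]][i] <- mm[[nm]][i] - h
      fd[i] <- (loss_at(mp) - loss_at(mm)) / (2 * h)
    }
    expect_lt(max(abs(fd - g)) / max(max(abs(g)), 1e-8), 1e-4,
              label = paste("finite-difference gradient mismatch in", nm))
  }
})

test_that("one optimization step moves the prototypes", {
  co <- generate_cohort(small_synth_config(seed = 30))
  cfg <- small_dpnn_config(lambda2 = 0.05, epochs = 1,
                           batch_size = nrow(co$x))  # exactly one step
  before <- dpnn_init(cfg)
  after <- train_dpnn(co, cfg)
  expect_false(identical(before$P, after$P))
  expect_gt(max(abs(before$P - after$P)), 0)
})

test_that("without prototypes and variance loss training reduces to a
           plain autoencoder + classifier that learns a separable toy", {
  toy <- separable_cohort(n = 300)
  cfg <- dpnn_config(n_prototypes = 2, input_dim = 6, latent_dim = 3,
                     encoder_hidden = 6, classifier_hidden = 8,
                     n_treatments = 2, lambda2 = 0, use_prototypes = FALSE,
                     learning_rate = 0.01, epochs = 15, batch_size = 32,
                     seed = 11)
  model <- train_dpnn(toy, cfg)
  trace <- attr(model, "epoch_loss")
  expect_lt(trace[length(trace)], trace[1])
  init <- dpnn_init(cfg)
  l1_init <- dpnn_loss_gradient(init, toy$x, toy$t, toy$y,
                                with_grad = FALSE)$L1
  l1_final <- dpnn_loss_gradient(model, toy$x, toy$t, toy$y,
                                 with_grad = FALSE)$L1
  expect_lt(l1_final, l1_init)
})

test_that("checkpoints round-trip through JSON", {
  cfg <- small_dpnn_config(epochs = 1)
  co <- generate_cohort(small_synth_config(seed = 13))
  model <- train_dpnn(co, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_dpnn(model, path)
  back <- load_dpnn(path)
  x <- co$x[1:9, ]
  expect_equal(predict_all_treatments(back, x),
               predict_all_treatments(model, x), tolerance = 1e-12)
  expect_equal(back$config$lambda2, model$config$lambda2)
})
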