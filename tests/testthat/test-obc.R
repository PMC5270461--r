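# small partitions built by hand: Pi rows are member SSDs over the states

test_that("effective densities mix member SSDs with conditional priors", {
  Pi <- rbind(c(0.7, 0.3), c(0.1, 0.9), c(0.5, 0.5))
  cls <- fake_controlled_class(mass = c(0.3, 0.9, 0.7),
                               mass_controlled = c(0.1, 0.8, 0.6),
                               lambda = c(0.25, 0.25, 0.5), Pi = Pi)
  part <- partition_prognosis(cls, list(alpha = 0.5, beta1 = 0.15,
                                        beta2 = 0.05))
  # labels: member 1 -> class 2 (shift .2 >= .15), members 2, 3 -> class 3
  expect_equal(part$labels, c(2L, 3L, 3L))
  dens <- effective_densities(part)
  expect_equal(dens$f[2, ], Pi[1, ])               # single-member class
  expect_equal(dens$f[3, ], (Pi[2, ] * 0.25 + Pi[3, ] * 0.5) / 0.75)
  expect_equal(dens$f[1, ], c(0, 0))               # empty class
  expect_equal(rowSums(dens$f)[dens$c > 0], c(1, 1))
  # c_i f_i = sum of lambda-weighted member SSDs (prior/conditional identity)
  expect_equal(dens$f[3, ] * dens$c[3], Pi[2, ] * 0.25 + Pi[3, ] * 0.5)
})

test_that("OBC takes the prior-weighted argmax and breaks ties to the smallest label", {
  Pi <- rbind(c(0.8, 0.2), c(0.8, 0.2))            # identical sampling dists
  cls <- fake_controlled_class(mass = c(0.4, 0.8),
                               mass_controlled = c(0.1, 0.6),
                               lambda = c(0.5, 0.5), Pi = Pi)
  part <- partition_prognosis(cls, list(alpha = 0.5, beta1 = 1, beta2 = 0.1))
  expect_equal(part$labels, c(1L, 3L))
  fit <- obc_classifier(part)
  # exact score ties at every state: smallest class index wins
  expect_equal(fit$psi, c(1L, 1L))
  expect_equal(fit$expected_error, 0.5, tolerance = 1e-12)
})

test_that("two-network one-gene toy matches hand-computed decisions and error", {
  # member A: pi = (.9, .1) label 1 with prior 2/3
  # member B: pi = (.2, .8) label 2 with prior 1/3
  # scores state 0: (.6, .0667) -> 1; state 1: (.0667, .2667) -> 2
  # error = miss A on state 1 + miss B on state 0 = 2/3*.1 + 1/3*.2 = 2/15
  Pi <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  cls <- fake_controlled_class(mass = c(0.2, 0.9),
                               mass_controlled = c(0.1, 0.2),
                               lambda = c(2, 1) / 3, Pi = Pi)
  part <- partition_prognosis(cls, list(alpha = 0.15, beta1 = 1,
                                        beta2 = 0.5))
  expect_equal(part$labels, c(1L, 3L))
  fit <- obc_classifier(part)
  expect_equal(fit$psi, c(1L, 3L))
  expect_equal(fit$expected_error, 2 / 15, tolerance = 1e-12)
  expect_equal(predict(fit, c(0, 1)), c(1L, 3L))
  # per-network correct-classification probabilities (mass on own states)
  expect_equal(fit$correct_prob, c(0.9, 0.8))
  # conservation: error = 1 - prior-average correct probability
  expect_equal(fit$expected_error,
               1 - sum(cls$lambda * fit$correct_prob), tolerance = 1e-12)
})

test_that("no classifier on a 2-gene toy beats the OBC error", {
  set.seed(41)
  m <- 6
  Pi <- t(replicate(m, { w <- rexp(4); w / sum(w) }))
  lambda <- { w <- rexp(m); w / sum(w) }
  cls <- fake_controlled_class(mass = runif(m, 0.4, 0.9),
                               mass_controlled = runif(m, 0.05, 0.35),
                               lambda = lambda, Pi = Pi)
  part <- partition_prognosis(cls, "auto")
  fit <- obc_classifier(part)
  errs <- numeric(0)
  for (code in 0:(4^4 - 1)) {                      # all 256 decision maps
    psi <- (code %/% 4^(0:3)) %% 4 + 1L
    errs <- c(errs, expected_error(part, psi))
  }
  expect_gte(min(errs), fit$expected_error - 1e-12)
  expect_equal(min(errs), fit$expected_error, tolerance = 1e-12)
  # never worse than always guessing the most probable class
  expect_lte(fit$expected_error, 1 - max(part$class_prob) + 1e-12)
})

test_that("posteriors normalize, agree with the decision rule and with sampling", {
  set.seed(42)
  R <- rand_regmat(3)
  uc <- uncertainty_class(R, p = 0.1, U = 0:3, rem = 1, add = 1,
                          gamma = 0.5)
  skip_if(length(uc$members) < 4, "class too small under this draw")
  cc <- control_class(uc, cgene = 2)
  part <- partition_prognosis(cc, "auto")
  fit <- obc_classifier(part)
  post <- state_posteriors(part)
  expect_equal(rowSums(post), rep(1, 8), tolerance = 1e-10)
  agree <- apply(post, 1, which.max)
  expect_equal(as.integer(agree), fit$psi)
  # Monte-Carlo: draw a network from Lambda, then a state from its SSD;
  # label frequencies at a fixed observed state track the posterior row
  n_draws <- 40000
  ridx <- sample.int(length(part$labels), n_draws, replace = TRUE,
                     prob = part$lambda)
  x_obs <- vapply(ridx, function(k)
    sample.int(8, 1, prob = part$Pi[k, ]), integer(1))
  x0 <- which.max(colSums(part$Pi * part$lambda))  # well-visited state
  sel <- x_obs == x0
  freq <- tabulate(part$labels[ridx][sel], nbins = 4) / sum(sel)
  se <- sqrt(post[x0, ] * (1 - post[x0, ]) / sum(sel))
  expect_true(all(abs(freq - post[x0, ]) <= 3 * se + 1e-3))
})

test_that("expected error decomposes over classes and networks", {
  set.seed(43)
  m <- 8
  Pi <- t(replicate(m, { w <- rexp(8); w / sum(w) }))
  lambda <- { w <- rexp(m); w / sum(w) }
  cls <- fake_controlled_class(mass = runif(m, 0.3, 0.9),
                               mass_controlled = runif(m, 0.05, 0.3),
                               lambda = lambda, Pi = Pi)
  part <- partition_prognosis(cls, "auto")
  fit <- obc_classifier(part)
  # per-class error contributions sum to the total
  expect_equal(sum(fit$class_error), fit$expected_error,
               tolerance = 1e-12)
  # epsilon-hat = sum_i c_i E_{Lambda_i}[eps_R]; eps_R = 1 - correct_prob
  eps_R <- 1 - fit$correct_prob
  by_class <- vapply(1:4, function(i) {
    sel <- part$labels == i
    if (!any(sel)) return(0)
    part$class_prob[i] * sum(part$lambda_cond[sel] * eps_R[sel])
  }, numeric(1))
  expect_equal(sum(by_class), fit$expected_error, tolerance = 1e-12)
  # constant classifier on a single populated class is error-free there
  one <- fake_controlled_class(mass = 0.9, mass_controlled = 0.1,
                               lambda = 1, Pi = matrix(c(0.3, 0.7), 1))
  p1 <- partition_prognosis(one, list(alpha = 0.5, beta1 = 0.5,
                                      beta2 = 0.5))
  expect_equal(expected_error(p1, rep(p1$labels, 2)), 0)
})
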