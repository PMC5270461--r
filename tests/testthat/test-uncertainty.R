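test_that("mutation enumeration covers removals, signed additions and combinations", {
  R <- regulatory_matrix(rbind(c(1L, -1L), c(0L, 1L)), c("a", "b"))
  # 3 edges, 1 zero cell: removals 3; additions 2; combined 3*2
  rem_only <- enumerate_mutations(R, rem = 1, add = 0)
  expect_length(rem_only, 3)
  add_only <- enumerate_mutations(R, rem = 0, add = 1)
  expect_length(add_only, 2)
  both <- enumerate_mutations(R, rem = 1, add = 1)
  expect_length(both, 3 + 2 + 6)
  expect_length(enumerate_mutations(R, rem = 0, add = 0), 0)
  # mutation counts and distinctness
  l <- vapply(both, `[[`, integer(1), "l")
  expect_equal(sort(unique(l)), c(1L, 2L))
  expect_equal(sum(l == 2L), 6)
  keys <- vapply(both, function(m) paste(m$entries, collapse = ","),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  # edits record the change relative to the original
  e <- both[[1]]$edits
  expect_named(e, c("i", "j", "from", "to"))
  expect_true(all(e$to == 0 | e$from == 0))
})

test_that("cell-cycle matrix yields one removal candidate per edge", {
  fx <- load_fixture("cellcycle")
  expect_length(enumerate_mutations(fx$R, rem = 1, add = 0), 39)
})

test_that("geometric prior weights levels by gamma^l split evenly within a level", {
  expect_equal(mutation_prior(rep(1L, 5), gamma = 0.5), rep(0.2, 5))
  # gamma = 1: each level gets equal aggregate mass
  lam <- mutation_prior(c(1L, 1L, 2L, 2L, 2L), gamma = 1)
  expect_equal(sum(lam[1:2]), sum(lam[3:5]))
  # direct arithmetic: N_1 = 2, N_2 = 4 at gamma = 0.5
  lam2 <- mutation_prior(c(1L, 1L, 2L, 2L, 2L, 2L), gamma = 0.5)
  w <- c(0.25, 0.25, 0.0625, 0.0625, 0.0625, 0.0625)
  expect_equal(lam2, w / sum(w))
  expect_equal(sum(lam2), 1)
  expect_true(all(lam2 > 0))
  expect_error(mutation_prior(integer(0)), "empty")
})

test_that("class filtering keeps ties and enforces both thresholds", {
  set.seed(31)
  R <- rand_regmat(4)
  U <- c(0:3)
  uc <- uncertainty_class(R, p = 0.05, U, rem = 1, add = 1, gamma = 0.5)
  expect_true(all(uc$mass >= uc$healthy_mass - 1e-15))
  expect_true(all(uc$mass >= uc$single_mean - 1e-15))
  expect_equal(sum(uc$lambda), 1, tolerance = 1e-12)
  expect_equal(dim(uc$Pi), c(length(uc$members), 16))
  expect_equal(rowSums(uc$Pi), rep(1, length(uc$members)),
               tolerance = 1e-9)
  # with an empty undesirable set every candidate ties at mass 0: all kept
  uc0 <- uncertainty_class(R, p = 0.05, integer(0), rem = 1, add = 0)
  expect_equal(length(uc0$members), uc0$n_candidates)
})

test_that("raising the inclusion threshold never adds members", {
  set.seed(32)
  R <- rand_regmat(4)
  U <- c(0, 1, 4, 5, 10, 11)
  uc <- uncertainty_class(R, p = 0.05, U, rem = 1, add = 1)
  thr <- sort(c(uc$healthy_mass, uc$single_mean, uc$single_mean * 1.2,
                max(uc$mass)))
  kept <- vapply(thr, function(t) sum(uc$mass >= t), integer(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("prognosis partition applies the four printed rules", {
  # mass* < alpha with a large shift is class 2
  cls <- fake_controlled_class(mass = 0.6, mass_controlled = 0.1,
                               lambda = 1, Pi = matrix(1, 1, 1))
  part <- partition_prognosis(cls, list(alpha = 0.3, beta1 = 0.2,
                                        beta2 = 0.2))
  expect_equal(part$labels, 2L)
  # degenerate thresholds: everything is class 1
  cls2 <- fake_controlled_class(mass = c(0.5, 0.9),
                                mass_controlled = c(0.2, 0.8),
                                lambda = c(0.5, 0.5),
                                Pi = matrix(0.5, 2, 2))
  part2 <- partition_prognosis(cls2, list(alpha = 1, beta1 = 1, beta2 = 1))
  expect_equal(part2$labels, c(1L, 1L))
  expect_error(partition_prognosis(cls2, list(alpha = 0, beta1 = 1,
                                              beta2 = 1)),
               "alpha")
})

test_that("auto thresholds split a 4-member class one per prognosis class", {
  cls <- fake_controlled_class(mass = c(0.15, 0.5, 0.9, 0.75),
                               mass_controlled = c(0.1, 0.2, 0.6, 0.7),
                               lambda = rep(0.25, 4),
                               Pi = matrix(0.25, 4, 4))
  th <- auto_thresholds(cls)
  part <- partition_prognosis(cls, th)
  expect_equal(sort(part$labels), 1:4)
  # identical members cannot be separated
  flat <- fake_controlled_class(mass = rep(0.5, 4),
                                mass_controlled = rep(0.2, 4),
                                lambda = rep(0.25, 4),
                                Pi = matrix(0.25, 4, 4))
  expect_error(auto_thresholds(flat), "indistinguishable")
  expect_error(auto_thresholds(fake_controlled_class(
    0.5, 0.1, 1, matrix(1, 1, 1))), "at least 4")
})

test_that("class probabilities and conditional priors are consistent", {
  set.seed(33)
  R <- rand_regmat(4)
  U <- 0:7
  uc <- uncertainty_class(R, p = 0.05, U, rem = 1, add = 1, gamma = 0.5)
  skip_if(length(uc$members) < 4, "class too small under this draw")
  cc <- control_class(uc, cgene = 2)
  expect_true(all(cc$shift >= -1e-9))              # control never hurts
  part <- partition_prognosis(cc, "auto")
  expect_equal(sum(part$class_prob), 1, tolerance = 1e-12)
  for (i in 1:4) {
    sel <- part$labels == i
    if (any(sel))
      expect_equal(sum(part$lambda_cond[sel]), 1, tolerance = 1e-10)
  }
})
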