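test_that("uniform distribution has zero interactions and logZ = n log 2", {
  for (n in c(2, 4)) {
    u <- state_distribution(rep(1 / 2^n, 2^n))
    J <- full_order_interactions(u)
    expect_true(all(abs(J$J) < 1e-12))
    expect_equal(J$logZ, n * log(2), tolerance = 1e-12)
  }
})

test_that("first- and second-order solutions match the conditional log-odds", {
  # n = 3 with P(000) = 0.4 and P(100) = 0.2 forces J_1 = log 0.5
  probs <- c(0.4, 0.2, rep(0.4 / 6, 6))
  d <- state_distribution(probs)
  J <- full_order_interactions(d)
  expect_equal(interaction(J, 1), log(0.5), tolerance = 1e-12)
  expect_equal(recursive_interaction(d, 1), log(0.5), tolerance = 1e-12)
  # J_12 = log(P110/P010) - J_1
  d2 <- random_distribution(3, seed = 2)
  expect_equal(interaction(full_order_interactions(d2), c(1, 2)),
               log(state_prob(d2, "110") / state_prob(d2, "010")) -
                 log(state_prob(d2, "100") / state_prob(d2, "000")),
               tolerance = 1e-12)
})

test_that("product distributions have logit first order and nothing higher", {
  p <- c(0.2, 0.5, 0.7, 0.35)
  J <- full_order_interactions(product_distribution(p))
  for (i in 1:4) expect_equal(interaction(J, i), log(p[i] / (1 - p[i])),
                              tolerance = 1e-10)
  tab <- interaction_table(J)
  expect_true(all(abs(tab$J[tab$order >= 2]) < 1e-10))
})

test_that("the recursion and the Moebius inversion agree on every subset", {
  d <- oracle_random_dist(5, seed = 31)
  J <- full_order_interactions(d)
  for (mask in 1:31) {
    subset <- which(bitwAnd(bitwShiftR(mask, 0:4), 1L) == 1L)
    expect_equal(recursive_interaction(d, subset), J$J[mask + 1],
                 tolerance = 1e-9)
    expect_equal(oracle_interaction(d, subset), J$J[mask + 1],
                 tolerance = 1e-9)
  }
})

test_that("basic form vanishes under independence and builds higher orders", {
  pd <- product_distribution(c(0.3, 0.6, 0.4))
  for (H in 0:1) expect_equal(basic_form(pd, 1, 2, H), 0, tolerance = 1e-12)

  d <- random_distribution(3, seed = 4)
  J <- full_order_interactions(d)
  expect_equal(basic_form(d, 1, 2, 1) - basic_form(d, 1, 2, 0),
               interaction(J, c(1, 2, 3)), tolerance = 1e-10)

  d4 <- random_distribution(4, seed = 5)
  J4 <- full_order_interactions(d4)
  expect_equal((basic_form(d4, 1, 2, c(1, 1)) - basic_form(d4, 1, 2, c(0, 1))) -
                 (basic_form(d4, 1, 2, c(1, 0)) - basic_form(d4, 1, 2, c(0, 0))),
               interaction(J4, 1:4), tolerance = 1e-10)
})

test_that("forward model and inversion are mutually inverse", {
  expect_equal(mep_distribution(effective_interactions(numeric(4), 0, 2))$probs,
               rep(0.25, 4))
  # single node, J = log 3 gives the logistic value 0.75
  d1 <- known_interaction_distribution(c("1" = log(3)), n = 1)
  expect_equal(state_prob(d1, "1"), 0.75, tolerance = 1e-12)

  for (seed in 1:5) {
    J_spec <- withr::with_seed(seed, {
      stats::setNames(stats::rnorm(4),
                      c("2", "1,4", "2,3,6", sample(c("1,2", "3,5", "4,6"), 1)))
    })
    d <- known_interaction_distribution(J_spec, n = 6)
    J <- full_order_interactions(d)
    for (key in names(J_spec)) {
      expect_equal(interaction(J, as.integer(strsplit(key, ",")[[1]])),
                   unname(J_spec[key]), tolerance = 1e-9)
    }
    tab <- interaction_table(J)
    expect_true(all(abs(tab$J[!tab$subset %in% names(J_spec)]) < 1e-9))
    # and forward evaluation reproduces the distribution
    expect_equal(mep_distribution(J)$probs, d$probs, tolerance = 1e-10)
  }
})

test_that("interactions containing a conditionally independent pair vanish", {
  ring_dep <- dependency_graph(ring4_network()$graph)
  d <- markov_factorized_distribution(ring_dep, seed = 3)
  J <- full_order_interactions(d)
  expect_lt(abs(interaction(J, c(1, 3))), 1e-9)
  expect_lt(abs(interaction(J, c(2, 4))), 1e-9)
  tab <- interaction_table(J)
  expect_true(all(abs(tab$J[tab$order >= 3]) < 1e-9))
})

test_that("zero-probability states are an error unless pseudocounts are on", {
  probs <- c(0, 0.5, 0.25, 0.25)
  d <- state_distribution(probs)
  expect_error(full_order_interactions(d), "00")
  J <- full_order_interactions(d, pseudocount = 1)
  expect_equal(J$pseudocount, 1)
  expect_true(all(is.finite(J$J)))
})

test_that("iterative scaling reproduces constrained moments", {
  d <- random_distribution(4, seed = 21)
  # m = 1: the max-entropy fit is the product of marginals
  f1 <- fit_low_order(d, m = 1)
  marg <- unname(moments(d, 1))
  expect_equal(mep_distribution(f1)$probs, product_distribution(marg)$probs,
               tolerance = 1e-10)
  # m = 2: all first and second moments match
  f2 <- fit_low_order(d, m = 2, tol = 1e-10)
  m2 <- moments(mep_distribution(f2), 2)
  expect_equal(unname(m2), unname(moments(d, 2)), tolerance = 1e-8)
  # m = n: the only feasible solution is the distribution itself
  fn <- fit_low_order(d, m = 4, tol = 1e-10)
  expect_equal(mep_distribution(fn)$probs, d$probs, tolerance = 1e-8)
  # entropy decreases as constraints are added, down to the empirical value
  s <- c(distribution_entropy(mep_distribution(f1)),
         distribution_entropy(mep_distribution(f2)),
         distribution_entropy(mep_distribution(fn)))
  expect_true(all(diff(s) < 1e-9))
  expect_gte(s[3] + 1e-9, distribution_entropy(d))
})

test_that("iterative scaling reports non-convergence", {
  d <- random_distribution(4, seed = 22)
  expect_error(fit_low_order(d, m = 2, tol = 1e-14, max_iter = 1L),
               "did not converge")
})

test_that("interactions survive a JSON round trip", {
  J <- full_order_interactions(random_distribution(3, seed = 8))
  path <- withr::local_tempfile(fileext = ".json")
  write_interactions(J, path)
  J2 <- read_interactions(path)
  expect_equal(J2$J, J$J, tolerance = 1e-12)
  expect_equal(J2$logZ, J$logZ, tolerance = 1e-12)
})
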