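test_that("bounded Brent search finds interior and boundary minima", {
  q <- brent_minimize(function(x) (x - 0.3)^2, 0, 1)
  expect_equal(q$minimum, 0.3, tolerance = 1e-4)

  m <- brent_minimize(function(x) x, 0, 5)
  expect_identical(m$minimum, 0)   # boundary minimum returned exactly

  ## cos on [0, 5]: compare against a dense grid
  grid <- seq(0, 5, length.out = 20001)
  gbest <- grid[which.min(cos(grid))]
  b <- brent_minimize(cos, 0, 5, tol = 1e-8)
  expect_equal(b$minimum, gbest, tolerance = 1e-4)
  expect_equal(b$minimum, pi, tolerance = 1e-6)
})

test_that("fits recover the generating parent for concordant samples", {
  st <- study_setup(samples = c(H = 2, P1 = 2, P2 = 2, O = 1))
  ## every individual clade matches the species clades of tau2 = ((H,P2),P1)
  nwk2 <- "(((((H_1,H_2),(P2_1,P2_2))),(P1_1,P1_2)),O_1);"
  D2 <- replicated_sample(nwk2, 10)
  fit2 <- fit_hybrid_model(D2, st$S, st$map)
  expect_lt(fit2$gamma, 1e-4)
  expect_equal(fit2$lnL,
               hyb_log_likelihood(fit2$gamma, fit2$t, D2, st$S, st$map),
               tolerance = 1e-9)

  ## swapped to tau1-concordant: gamma at the opposite bound
  nwk1 <- "(((((H_1,H_2),(P1_1,P1_2))),(P2_1,P2_2)),O_1);"
  fit1 <- fit_hybrid_model(replicated_sample(nwk1, 10), st$S, st$map)
  expect_gt(fit1$gamma, 1 - 1e-4)

  ## tidy/glance carry the estimates
  td <- tidy(fit2)
  expect_equal(td$estimate[td$term == "gamma"], fit2$gamma)
  expect_true(glance(fit2)$converged)
})

test_that("cyclic Brent matches a grid-search oracle on seeded datasets", {
  st <- study_setup(samples = c(H = 2, P1 = 2, P2 = 1, O = 1))
  taus <- decompose_parental_trees(st$S)
  cfgs <- expand.grid(gamma = seq(0, 1, length.out = 11),
                      t1 = seq(0.2, 4.8, length.out = 7),
                      t2 = seq(0.2, 4.8, length.out = 7),
                      t3 = seq(0.2, 4.8, length.out = 7))
  set.seed(2024)
  for (rep in 1:5) {
    gtrue <- runif(1)
    D <- lapply(1:10, function(i) {
      tau <- if (runif(1) < gtrue) taus$tau1 else taus$tau2
      tr <- simulate_gene_tree(tau, st$samples)
      tr$edge.length <- NULL
      tr
    })
    fit <- fit_hybrid_model(D, st$S, st$map)
    expect_gte(fit$gamma, 0)
    expect_lte(fit$gamma, 1)
    eval_fn <- hybcoal:::.prep_likelihood(D, st$S, st$map)
    grid_best <- -Inf
    tgrid <- unique(cfgs[, c("t1", "t2", "t3")])
    for (r in seq_len(nrow(tgrid))) {
      tv <- as.numeric(tgrid[r, ])
      for (g in seq(0, 1, length.out = 11)) {
        grid_best <- max(grid_best, eval_fn(g, tv))
      }
    }
    expect_gte(fit$lnL, grid_best - 1e-3)
  }
})

test_that("likelihood-ratio test uses the boundary-mixture null", {
  ## p-value mapping, against an independent chi-square tail via the normal
  st <- study_setup(samples = c(H = 2, P1 = 2, P2 = 2, O = 1))
  D2 <- replicated_sample("(((((H_1,H_2),(P2_1,P2_2))),(P1_1,P1_2)),O_1);", 10)
  lrt <- likelihood_ratio_test(D2, st$S, st$map)
  expect_equal(lrt$delta, 0, tolerance = 1e-6)
  expect_equal(lrt$p_value, 1, tolerance = 1e-4)
  expect_false(reject_at(lrt, 0.05))

  ## the survival function of chisq_1 is 2*(1-Phi(sqrt(x)))
  delta <- 3.841459
  p_indep <- 0.5 * 2 * (1 - pnorm(sqrt(delta)))
  expect_equal(0.5 * pchisq(delta, 1, lower.tail = FALSE), p_indep,
               tolerance = 1e-9)
  expect_equal(p_indep, 0.025, tolerance = 1e-6)
})

test_that("nesting inequality and determinism hold across seeded datasets", {
  st <- study_setup(samples = c(H = 2, P1 = 2, P2 = 1, O = 1))
  taus <- decompose_parental_trees(st$S)
  set.seed(77)
  for (rep in 1:6) {
    D <- lapply(1:8, function(i) {
      tau <- if (i %% 3 == 0) taus$tau1 else taus$tau2
      tr <- simulate_gene_tree(tau, st$samples)
      tr$edge.length <- NULL
      tr
    })
    lrt <- likelihood_ratio_test(D, st$S, st$map)
    expect_gte(lrt$fit_alt$lnL, lrt$fit_null$lnL - 1e-6)
    expect_gte(lrt$delta, 0)
    ## identical inputs give bit-identical fits (optimization is not random)
    fit_a <- fit_hybrid_model(D, st$S, st$map)
    fit_b <- fit_hybrid_model(D, st$S, st$map)
    expect_identical(fit_a$gamma, fit_b$gamma)
    expect_identical(fit_a$t, fit_b$t)
    expect_identical(fit_a$lnL, fit_b$lnL)
  }
})

test_that("iterating the hybrid assignment tabulates all three designations", {
  st <- study_setup(samples = c(H = 2, P1 = 2, P2 = 1, O = 1))
  taus <- decompose_parental_trees(st$S)
  set.seed(5)
  D <- lapply(1:6, function(i) {
    tr <- simulate_gene_tree(taus$tau2, st$samples)
    tr$edge.length <- NULL
    tr
  })
  tab <- iterate_hybrid_assignments(D, c("H", "P1", "P2"), "O", st$map)
  expect_equal(nrow(tab), 3)
  expect_setequal(tab$hybrid, c("H", "P1", "P2"))
  expect_true(all(tab$gamma_hat >= 0 & tab$gamma_hat <= 1))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  expect_error(iterate_hybrid_assignments(D, c("H", "P1"), "O", st$map),
               "three ingroup")
})
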