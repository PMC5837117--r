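test_that("pair state space enumerates unordered deme pairs plus absorption", {
  sp <- pair_state_space(4)
  expect_equal(sp$n_states, 4 * 5 / 2)
  expect_equal(nrow(unique(sp$pairs)), sp$n_states)
  expect_equal(sp$index(3, 2), sp$index(2, 3))   # unordered lookup
})

test_that("two-island generator carries the stated coalescence/migration rates", {
  g <- build_pair_generator(epoch(0, c(1, 1), matrix(c(0, 1, 1, 0), 2, 2)))
  i11 <- g$space$index(1, 1); i12 <- g$space$index(1, 2)
  expect_equal(g$Q[i11, 4], 1)      # coalescence at rate 1/s
  expect_equal(g$Q[i11, i12], 1)    # two lineages each leaving at M/2
  expect_equal(g$Q[i11, i11], -2)
  i22 <- g$space$index(2, 2)
  expect_equal(g$Q[i12, i11], 1/2)  # the lineage in deme 2 joins deme 1
  expect_equal(g$Q[i12, i22], 1/2)  # or the lineage in deme 1 joins deme 2

  single <- build_pair_generator(epoch(0, 1))
  expect_equal(single$Q, matrix(c(-1, 1, 0, 0), 2, 2, byrow = TRUE))
})

test_that("random valid epochs yield proper generators", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    mig <- matrix(stats::runif(n * n, 0, 3), n, n); diag(mig) <- 0
    g <- build_pair_generator(epoch(0, stats::runif(n, 0.2, 5), mig))
    expect_equal(rowSums(g$Q), rep(0, nrow(g$Q)), tolerance = 1e-12)
    off <- g$Q; diag(off) <- 0
    expect_true(all(off >= 0))
    expect_true(all(g$Q[nrow(g$Q), ] == 0))   # absorbing row
  }
})

test_that("panmictic coalescence times are standard exponential", {
  m <- panmictic_model()
  sf <- survival_and_density(m, sampling_scheme(1, 1), c(0, 0.5, 2))
  expect_equal(sf$S, exp(-c(0, 0.5, 2)))
  expect_equal(sf$f, exp(-c(0, 0.5, 2)))
  cu <- exact_iicr(m, sampling_scheme(1, 1), make_time_grid(0.01, 10, 16))
  expect_equal(cu$values, rep(1, 16))
})

test_that("instantaneous rates at the sampling time follow the local deme", {
  m <- make_custom_model(list(epoch(0, c(2, 0.5),
                                    matrix(c(0, 1, 1, 0), 2, 2))))
  same1 <- survival_and_density(m, sampling_scheme(1, 1), 0)
  expect_equal(same1$S, 1)
  expect_equal(same1$f, 1 / 2)              # 1 / s_1
  same2 <- survival_and_density(m, sampling_scheme(2, 2), 0)
  expect_equal(same2$f, 2)                  # 1 / s_2
  diff12 <- survival_and_density(m, sampling_scheme(1, 2), 0)
  expect_equal(diff12$f, 0)
  # IICR(0) is the analytic limit: local size, or +Inf across demes
  expect_equal(exact_iicr(m, sampling_scheme(1, 1), c(0, 1))$values[1], 2)
  expect_equal(exact_iicr(m, sampling_scheme(1, 2), c(0, 1))$values[1], Inf)
})

test_that("two-island survival matches an independent 2x2 eigen oracle", {
  # lumped (same, different) chain for n = 2, M = 1, assembled from scratch
  Q <- matrix(c(-(1 + 1), 1,
                1, -1), 2, 2, byrow = TRUE)
  eg <- eigen(Q)
  p0 <- c(1, 0)
  for (t in c(0.3, 1, 2.5)) {
    pt <- as.vector((p0 %*% eg$vectors) %*%
                      (exp(eg$values * t) * solve(eg$vectors)))
    sf <- survival_and_density(make_n_island(2, 1), sampling_scheme(1, 1), t)
    expect_equal(sf$S, sum(pt), tolerance = 1e-12)
    expect_equal(sf$f, pt[1], tolerance = 1e-12)   # absorption flux from "same"
  }
})

test_that("closed-form n-island curve matches the matrix-exponential route", {
  g <- make_time_grid(1e-3, 1e2, 64)
  for (scheme in c("same", "different")) {
    samp <- if (scheme == "same") sampling_scheme(1, 1) else sampling_scheme(1, 2)
    e <- exact_iicr(make_n_island(5, 1), samp, g)
    cf <- nisland_iicr_closed_form(5, 1, scheme, g)
    expect_lt(max(abs(e$values - cf$values) / cf$values), 1e-10)
  }
  expect_error(nisland_iicr_closed_form(1, 1), "n must be")
})

test_that("survival is monotone, density integrates to one", {
  grid <- make_time_grid(1e-3, 300, 200)
  for (m in list(make_n_island(3, 0.5), make_stepping_stone(4, 1),
                 split_two_island(), asymmetric_two_island())) {
    sf <- survival_and_density(m, sampling_scheme(1, 1), grid)
    expect_true(all(diff(sf$S) <= 1e-12))
    expect_true(all(sf$f >= 0))
    total <- stats::integrate(function(t)
      survival_and_density(m, sampling_scheme(1, 1), t)$f,
      0, Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("beta asymptote matches its printed form and the lumped spectrum", {
  expect_equal(beta_asymptote(2, 1), (3 - sqrt(5)) / 2, tolerance = 1e-12)
  expect_equal(beta_asymptote(2, 1), 0.3819660, tolerance = 1e-7)
  expect_equal(beta_asymptote(10, 0.1), 0.01009166, tolerance = 1e-6)
  # beta is the smallest-magnitude eigenvalue of the lumped transient chain
  for (cfg in list(c(2, 1), c(7, 0.3), c(10, 10))) {
    n <- cfg[1]; M <- cfg[2]; gam <- M / (n - 1)
    Q <- matrix(c(-(1 + M), M, gam, -gam), 2, 2, byrow = TRUE)
    expect_equal(beta_asymptote(n, M), min(abs(eigen(Q)$values)),
                 tolerance = 1e-12)
  }
  expect_equal(beta_asymptote(2, 1e6), 0.5, tolerance = 1e-5)
  # the large-t IICR approaches 1/beta
  v <- exact_iicr(make_n_island(10, 0.1), sampling_scheme(1, 1), c(150, 200))
  expect_equal(v$values[2], 1 / beta_asymptote(10, 0.1), tolerance = 1e-6)
})

test_that("diversity effective size and small-M plateau formulas evaluate", {
  expect_equal(nei_takahata_ne(2, 1, 1), 2.5)
  expect_equal(nei_takahata_ne(10, 1000, 0.1), 1000 * (10 + 81), tolerance = 1e-12)
  expect_equal(nei_takahata_ne(5, 1, 1e6), 5, tolerance = 1e-5)
  expect_error(nei_takahata_ne(2, 1, 0), "M must be")

  expect_equal(small_m_plateau(10, 1000, 0.1), 90000)
  expect_equal(small_m_plateau(2, 1, 1), 1)
  # small-M expansion: plateau formula within 1% of the exact 1/beta
  expect_equal(small_m_plateau(10, 1000, 1e-4) /
                 (1000 / beta_asymptote(10, 1e-4)), 1, tolerance = 0.01)
})

test_that("the split model shadows the two-island curve before the split", {
  m <- split_two_island()
  g <- make_time_grid(1e-2, 1.99, 48)
  ex <- exact_iicr(m, sampling_scheme(1, 1), g)
  cf <- nisland_iicr_closed_form(2, 1, "same", g)
  expect_lt(max(abs(ex$values - cf$values) / cf$values), 1e-10)
  # beyond the split the ancestor is panmictic of size 2
  expect_equal(exact_iicr(m, sampling_scheme(1, 1), c(25, 30))$values[2], 2,
               tolerance = 1e-10)
})

test_that("an immediate split reduces to the panmictic ancestor", {
  m <- add_population_split(make_n_island(2, 1), T = 1e-9, ancestral_size = 1)
  g <- make_time_grid(1e-3, 10, 24)
  expect_equal(exact_iicr(m, sampling_scheme(1, 1), g)$values, rep(1, 24),
               tolerance = 1e-6)
})

test_that("stationary models are invariant to an artificial epoch boundary", {
  base <- make_n_island(5, 0.5)
  dup <- make_custom_model(list(
    base$epochs[[1]],
    epoch(3, rep(1, 5), base$epochs[[1]]$migration)))
  g <- make_time_grid(0.1, 50, 32)
  for (samp in list(sampling_scheme(1, 1), sampling_scheme(1, 2))) {
    a <- exact_iicr(base, samp, g)$values
    b <- exact_iicr(dup, samp, g)$values
    expect_equal(b, a, tolerance = 1e-12)
  }
})

test_that("same- and different-deme curves share the ancient plateau", {
  for (m in list(make_n_island(10, 0.1), make_stepping_stone(5, 1))) {
    vs <- exact_iicr(m, sampling_scheme(1, 1), c(60, 61))$values[1]
    vd <- exact_iicr(m, sampling_scheme(1, 2), c(60, 61))$values[1]
    expect_lt(abs(vs - vd) / vs, 1e-3)
  }
})

test_that("stepping stones plateau above the matched n-island value", {
  for (cfg in list(list(m = make_stepping_stone(5, 1), n = 5, M = 1),
                   list(m = make_stepping_stone(c(3, 3), 1), n = 9, M = 1))) {
    plateau <- exact_iicr(cfg$m, sampling_scheme(1, 1), c(120, 150))$values[2]
    expect_gt(plateau, 1 / beta_asymptote(cfg$n, cfg$M))
  }
})

test_that("different-deme sampling shows the recent-expansion divergence", {
  vals <- exact_iicr(make_n_island(10, 0.1), sampling_scheme(1, 2),
                     c(1e-6, 1e-3, 1))$values
  expect_gt(vals[1], 1e4)
  expect_true(all(diff(vals) < 0))   # blows up toward the sampling time
})

test_that("unreachable coalescence errors unless explicitly allowed", {
  m <- disconnected_model()
  expect_error(exact_iicr(m, sampling_scheme(1, 2), c(1, 2)), "not certain")
  expect_warning(
    cu <- exact_iicr(m, sampling_scheme(1, 2), c(1, 2), allow_infinite = TRUE),
    "zero coalescence density")
  expect_true(all(is.infinite(cu$values)))
  # same-deme sampling in an isolated deme is still a plain coalescent
  sf <- survival_and_density(m, sampling_scheme(1, 1), 1)
  expect_equal(sf$S, exp(-1))
})
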