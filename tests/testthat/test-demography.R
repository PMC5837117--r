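test_that("n-island builder produces symmetric equal-share migration", {
  m <- make_n_island(2, 1)
  expect_equal(m$epochs[[1]]$migration, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(m$epochs[[1]]$deme_sizes, c(1, 1))

  m10 <- make_n_island(10, 0.1)
  off <- m10$epochs[[1]]$migration[1, -1]
  expect_equal(off, rep(0.1 / 9, 9))

  m1 <- make_n_island(1, 0)
  expect_equal(length(m1$epochs[[1]]$deme_sizes), 1L)
  expect_equal(m1$epochs[[1]]$migration, matrix(0, 1, 1))

  expect_error(make_n_island(0, 1), "positive")
  expect_error(make_n_island(5, -1), "negative")
  expect_error(make_n_island(1, 1), "single deme")
})

test_that("bounded 1D stepping stone splits each deme's total rate over its neighbours", {
  m <- make_stepping_stone(3, 1)
  mig <- m$epochs[[1]]$migration
  expect_equal(mig[2, ], c(0.5, 0, 0.5))     # middle deme: two neighbours
  expect_equal(mig[1, ], c(0, 1, 0))         # edge deme: one neighbour
  expect_equal(mig[3, ], c(0, 1, 0))
  expect_equal(rowSums(mig), rep(1, 3))      # equal-split rule keeps totals at M

  expect_equal(length(make_stepping_stone(1, 0)$epochs[[1]]$deme_sizes), 1L)
  expect_error(make_stepping_stone(1, 1), "single deme")
  expect_error(make_stepping_stone(integer(0), 1), "positive integer")
})

test_that("2D lattice adjacency counts and circular row totals are right", {
  m <- make_stepping_stone(c(3, 3), 1)
  deg <- rowSums(m$epochs[[1]]$migration > 0)
  # row-major 3x3: corners have 2 neighbours, edges 3, the centre 4
  expect_equal(deg, c(2, 3, 2, 3, 4, 3, 2, 3, 2))
  expect_equal(unname(rowSums(m$epochs[[1]]$migration)), rep(1, 9))

  ring <- make_stepping_stone(5, 2, circular = TRUE)
  expect_equal(unname(rowSums(ring$epochs[[1]]$migration)), rep(2, 5))
  expect_equal(unname(rowSums(ring$epochs[[1]]$migration > 0)), rep(2, 5))

  per_link <- make_stepping_stone(3, 0.3, rate_mode = "per_link")
  expect_equal(per_link$epochs[[1]]$migration[2, ], c(0.3, 0, 0.3))
})

test_that("a two-deme stepping stone is the two-island model", {
  a <- make_n_island(2, 0.7)
  b <- make_stepping_stone(2, 0.7)
  expect_equal(a$epochs[[1]]$migration, b$epochs[[1]]$migration)
  expect_equal(a$epochs[[1]]$deme_sizes, b$epochs[[1]]$deme_sizes)
})

test_that("continent-island model is conservative by default", {
  m <- make_continent_island(10, 1)
  expect_equal(m$epochs[[1]]$deme_sizes, c(10, 1))
  expect_equal(m$epochs[[1]]$migration[2, 1], 1)    # island immigration M
  expect_equal(m$epochs[[1]]$migration[1, 2], 0.1)  # continent immigration M/ratio
  # expected migrant genes per generation match in the two directions
  sz <- m$epochs[[1]]$deme_sizes
  expect_equal(sz[1] * m$epochs[[1]]$migration[1, 2],
               sz[2] * m$epochs[[1]]$migration[2, 1])

  eq <- make_continent_island(1, 1)
  expect_equal(eq$epochs[[1]]$migration, make_n_island(2, 1)$epochs[[1]]$migration)
  expect_error(make_continent_island(0.5, 1), "size_ratio")
})

test_that("custom model validation rejects invariant violations", {
  expect_s3_class(asymmetric_two_island(), "demographic_model")
  expect_s3_class(panmictic_model(), "demographic_model")
  expect_error(epoch(0, c(1, 1), matrix(c(0, -0.5, 1, 0), 2, 2)),
               "negative migration rate")
  expect_error(epoch(0, c(1, -1)), "deme sizes")
  expect_error(make_custom_model(list(epoch(0, 1), epoch(0, 1))),
               "strictly increasing")
  expect_error(make_custom_model(list(epoch(1, 1))), "start at time 0")
  expect_error(
    make_custom_model(list(epoch(0, c(1, 1)),
                           epoch(1, c(1, 1), remap = list(map = c(1, 3))))),
    "outside the deme range")
  expect_error(
    make_custom_model(list(epoch(0, c(1, 1)), epoch(1, 1))),
    "remap")
})

test_that("builders re-validate idempotently", {
  for (m in list(make_n_island(4, 0.5), make_stepping_stone(c(2, 3), 1),
                 make_continent_island(10, 1), split_two_island())) {
    again <- make_custom_model(m$epochs, N_ref = m$N_ref, label = m$label)
    expect_equal(again, m)
  }
})

test_that("population splits append a remapped ancestral epoch", {
  m <- split_two_island()
  expect_length(m$epochs, 2)
  e2 <- m$epochs[[2]]
  expect_equal(e2$start_time, 2)
  expect_equal(e2$deme_sizes, 2)
  expect_equal(e2$remap$map, c(1L, 1L))

  # nested splits: three demes merge at T = 1 (demes 2,3) and T = 3 (all)
  base <- make_n_island(3, 1)
  m2 <- add_population_split(base, T = 1, derived = c(2, 3),
                             ancestral_size = 2, ancestral_M = 1)
  m3 <- add_population_split(m2, T = 3, ancestral_size = 3)
  expect_length(m3$epochs, 3)
  expect_equal(m3$epochs[[2]]$remap$map, c(1L, 2L, 2L))
  expect_equal(m3$epochs[[2]]$deme_sizes, c(1, 2))
  expect_equal(m3$epochs[[3]]$remap$map, c(1L, 1L))

  expect_error(add_population_split(m, T = 1), "beyond")
  expect_error(add_population_split(base, T = 2, derived = 5), "unknown deme")
})

test_that("sampling schemes validate deme indices", {
  expect_true(sampling_scheme(1, 1)$same_deme)
  expect_false(sampling_scheme(1, 2)$same_deme)
  expect_error(sampling_scheme(0, 1), "positive")
  expect_error(exact_iicr(make_n_island(2, 1), sampling_scheme(1, 3), c(1, 2)),
               "absent")
})

test_that("JSON serialization round-trips models and text", {
  presets <- list(make_n_island(10, 0.1), make_stepping_stone(c(3, 3), 1),
                  make_continent_island(10, 1), split_two_island(),
                  asymmetric_two_island())
  for (m in presets) {
    txt <- model_to_json(m)
    back <- model_from_json(txt)
    expect_equal(back, m)
    expect_identical(model_to_json(back), txt)   # byte-for-byte re-emission
    expect_match(model_hash(m), "^[0-9a-f]{32}$")
  }
  expect_error(model_from_json('{"N_ref": 1}'), "epochs")
})
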