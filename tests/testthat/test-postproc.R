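test_that("von Mises stress matches its closed forms", {
  expect_equal(von_mises(diag(c(3, 0, 0))), 3)
  expect_equal(von_mises(5 * diag(3)), 0)          # hydrostatic
  tau <- 0.7
  S <- matrix(0, 3, 3); S[1, 2] <- S[2, 1] <- tau  # pure shear
  expect_equal(von_mises(S), sqrt(3) * tau)
  expect_error(von_mises(matrix(1:9, 3, 3)), "not symmetric")
})

test_that("maximum principal value matches eigen and the cubic-root oracle", {
  expect_equal(max_principal(diag(c(3, 1, -2))), 3)
  S <- diag(c(2, 2, 0)); S[1, 2] <- S[2, 1] <- 0.5
  expect_equal(max_principal(S), 2.5)              # [[a,b],[b,a]] -> a + |b|
  set.seed(13)
  comps <- matrix(rnorm(6000), ncol = 6)
  vec <- pfmsim:::maxp_vec(comps)
  for (i in seq_len(25)) {
    S <- matrix(0, 3, 3)
    diag(S) <- comps[i, 1:3]
    S[1, 2] <- S[2, 1] <- comps[i, 4]
    S[1, 3] <- S[3, 1] <- comps[i, 5]
    S[2, 3] <- S[3, 2] <- comps[i, 6]
    # characteristic-polynomial root oracle
    c2 <- -sum(diag(S))
    c1 <- S[1, 1] * S[2, 2] + S[1, 1] * S[3, 3] + S[2, 2] * S[3, 3] -
          S[1, 2]^2 - S[1, 3]^2 - S[2, 3]^2
    c0 <- -det(S)
    roots <- polyroot(c(c0, c1, c2, 1))
    expect_equal(max_principal(S), max(Re(roots)), tolerance = 1e-10)
    expect_equal(vec[i], max_principal(S), tolerance = 1e-10)
  }
  # full vectorized check against eigen across all rows
  ref <- apply(comps, 1, function(r) {
    S <- matrix(c(r[1], r[4], r[5], r[4], r[2], r[6], r[5], r[6], r[3]), 3, 3)
    max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  })
  expect_equal(vec, ref, tolerance = 1e-9)
})

test_that("invariants are rotation invariant", {
  set.seed(17)
  S <- matrix(rnorm(9), 3, 3); S <- (S + t(S)) / 2
  for (i in 1:5) {
    R <- random_rotation(i + 30)
    Sr <- R %*% S %*% t(R)
    expect_lt(abs(von_mises(Sr) - von_mises(S)), 1e-10)
    expect_lt(abs(max_principal(Sr) - max_principal(S)), 1e-10)
  }
})

test_that("displacement extrema scan the dense monitors correctly", {
  run <- list(monitors = data.frame(
    t = c(0, 0.01, 0.02, 0.03),
    uZ_max = c(0, 2, 5, 3),
    uX_span = c(0, 1, 2, 7)))
  class(run) <- "pfm_run"
  ext <- displacement_extrema(run)
  expect_equal(ext$max_uZ, 5); expect_equal(ext$t_uZ, 0.02)
  expect_equal(ext$uX_span, 7); expect_equal(ext$t_uX, 0.03)
  run0 <- list(monitors = data.frame(t = 0, uZ_max = 0, uX_span = 0))
  class(run0) <- "pfm_run"
  ext0 <- displacement_extrema(run0)
  expect_equal(c(ext0$max_uZ, ext0$t_uZ, ext0$uX_span, ext0$t_uX), rep(0, 4))
  bad <- list(monitors = data.frame()); class(bad) <- "pfm_run"
  expect_error(displacement_extrema(bad), "empty")
})

test_that("extension ratios reproduce the published arithmetic", {
  expect_equal(unname(extension_ratios(50.684, 140.21)),
               c(126.71, 200.30), tolerance = 1e-4)
  expect_equal(unname(extension_ratios(52.509, 129.38)),
               c(131.27, 184.83), tolerance = 1e-4)
  expect_equal(unname(extension_ratios(0, 0)), c(0, 0))
  # the D80 vertical ratio computes to 125.90%, not the printed 128.90%
  # (a transposition typo in the source table); the arithmetic is not
  # "corrected" towards the printed value
  expect_equal(unname(extension_ratios(50.358, 127.11))[1], 125.895,
               tolerance = 1e-3)
  expect_equal(unname(extension_ratios(50.358, 127.11))[2], 181.59,
               tolerance = 1e-3)
  expect_error(extension_ratios(1, 1, height = 0), "input error")
  expect_error(extension_ratios(-1, 1), "input error")
})

test_that("peak report recovers argmax values and is internally consistent", {
  run <- short_run()
  rep <- peak_report(run)
  expect_s3_class(rep, "pfm_metrics")
  mon <- run$monitors
  expect_equal(rep$max_eq_stress, max(mon$vm_max))
  expect_equal(rep$t_eq_stress, mon$t[which.max(mon$vm_max)])
  expect_equal(rep$max_p_strain, max(mon$pe_max))
  # end-time values never exceed the running peak
  expect_lte(rep$end_eq_stress, rep$max_eq_stress)
  expect_lte(rep$end_p_strain, rep$max_p_strain)
  # ratios equal extension_ratios applied to the report's own extrema
  rat <- extension_ratios(rep$max_uZ, rep$uX_span,
                          run$params$height, run$params$length)
  expect_equal(rep$ratio_Z_pct, unname(rat["ratio_Z"]))
  expect_equal(rep$ratio_X_pct, unname(rat["ratio_X"]))
  # occurrence times within the simulated window
  tcols <- c("t_eq_stress", "t_p_stress", "t_p_strain", "t_uZ", "t_uX")
  for (tc in tcols) {
    expect_gte(rep[[tc]], 0)
    expect_lte(rep[[tc]], run$config$duration)
  }
})
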