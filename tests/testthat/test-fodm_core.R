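test_that("divergence entropy reproduces analytic two-term values", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), 1)     # exactly 1 bit
  # analytic: 1 - 0.5*log2(3); cross-checked by the direct-sum oracle
  p <- c(0.5, 0.5); q <- c(0.25, 0.75)
  expect_equal(kl_divergence(p, q), 1 - 0.5 * log2(3), tolerance = 1e-15)
  expect_equal(kl_divergence(p, q), kl_oracle(p, q), tolerance = 1e-15)
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "infinite")
  expect_error(kl_divergence(c(0.5, 0.5), c(0.3, 0.3, 0.4)), "aligned")
})

test_that("divergence entropy is nonnegative, zero iff equal (Gibbs)", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    p <- rand_profile(n)
    q <- rand_profile(n)
    expect_gte(kl_divergence(p, q), 0)
    expect_equal(kl_divergence(p, p), 0)
    if (max(abs(p$values - q$values)) > 1e-9)
      expect_gt(kl_divergence(p, q), 0)
  }
})

test_that("RD hits its endpoints and composes from the KL oracle", {
  set.seed(2)
  T_ <- rand_profile(10, "T")
  R_ <- uniform_profile(10)
  expect_equal(rd(T_, T_, R_), 0)          # O = T
  expect_equal(rd(R_, T_, R_), 1)          # O = R
  O <- rand_profile(10)
  expect_equal(rd(O, T_, R_),
               kl_oracle(O$values, T_$values) /
                 (kl_oracle(O$values, T_$values) +
                    kl_oracle(O$values, R_$values)),
               tolerance = 1e-12)
  expect_gte(rd(O, T_, R_), 0)
  expect_lte(rd(O, T_, R_), 1)
})

test_that("RD is invariant to the logarithm base of the divergences", {
  set.seed(4)
  O <- rand_profile(15); T_ <- rand_profile(15, "T")
  R_ <- uniform_profile(15)
  rd_bits <- rd(O, T_, R_)
  d_ot <- kl_divergence(O, T_, base = exp(1))
  d_or <- kl_divergence(O, R_, base = exp(1))
  expect_equal(d_ot / (d_ot + d_or), rd_bits, tolerance = 1e-12)
})

test_that("M profile: K = 0 recovers T; flat T is the identity", {
  set.seed(6)
  T_ <- rand_profile(12, "T")
  expect_equal(m_profile(T_, 0)$values, T_$values, tolerance = 1e-15)
  flat <- hydro_profile(rep(1, 8), "T")
  expect_warning(m <- m_profile(flat, 2.0), "flat")
  expect_equal(m$values, flat$values)
  expect_error(m_profile(T_, -0.1), "nonnegative")
})

test_that("M is normalized, continuous in K, and inverts at large K", {
  set.seed(8)
  T_ <- rand_profile(20, "T")
  for (k in c(0, 0.3, 1, 2.5, 10))
    expect_equal(sum(m_profile(T_, k)$values), 1, tolerance = 1e-9)
  # continuity: small dK, small L1 change
  m1 <- m_profile(T_, 1.0)$values
  m2 <- m_profile(T_, 1.001)$values
  expect_lt(sum(abs(m1 - m2)), 1e-3)
  # very large K: the position of T's maximum becomes M's minimum
  big <- m_profile(T_, 500)$values
  expect_equal(which.min(big), which.max(T_$values))
})

test_that("optimal K search equals the brute-force grid minimum", {
  set.seed(10)
  T_ <- rand_profile(25, "T")
  O <- rand_profile(25)
  grid <- seq(0, 5, by = 0.1)
  scan <- optimize_k(O, T_, grid)
  brute <- vapply(grid, function(k)
    kl_oracle(O$values, m_profile(T_, k)$values), numeric(1))
  expect_equal(scan$k_opt, grid[which.min(brute)])
  expect_equal(scan$dkl_min, min(brute), tolerance = 1e-12)
  expect_equal(scan$curve$dkl, brute, tolerance = 1e-12)
  # O = T pins the optimum at K = 0 with zero divergence
  s0 <- optimize_k(T_, T_, grid)
  expect_equal(s0$k_opt, 0)
  expect_equal(s0$dkl_min, 0)
})

test_that("ties in the K scan break toward the smallest K", {
  flat <- hydro_profile(rep(1, 6), "T")     # M(K) = T for every K
  O <- rand_profile(6)
  suppressWarnings(scan <- optimize_k(O, flat, seq(0, 2, by = 0.1)))
  expect_equal(scan$k_opt, 0)
  expect_equal(length(unique(round(scan$curve$dkl, 12))), 1L)
})

test_that("a manufactured O = M(K*) is recovered exactly on the grid", {
  set.seed(12)
  T_ <- rand_profile(30, "T")
  for (k_star in c(0.5, 1.5, 3.0)) {
    O <- m_profile(T_, k_star)
    scan <- optimize_k(O, T_)
    expect_equal(scan$k_opt, k_star)
    expect_equal(scan$dkl_min, 0, tolerance = 1e-12)
  }
})

test_that("K recovery stays within one grid step under documented noise", {
  # Dirichlet concentration 5e5: per-entry sd below half the one-step
  # perturbation scale of M for n = 60 (see synthetic_spec docs)
  for (seed in 1:5) {
    for (k_star in c(0.5, 1.5)) {
      syn <- generate_synthetic(synthetic_spec(
        n = 60, assignment = "k_target", k_target = k_star,
        dirichlet = 5e5, seed = seed))
      T_ <- theoretical_profile(fit_gaussian(syn$atoms), syn$atoms)
      scan <- optimize_k(syn$o_profile, T_)
      expect_lte(abs(scan$k_opt - k_star), 0.1 + 1e-12)
    }
  }
})

test_that("RD_Kopt endpoints and composition behave", {
  set.seed(14)
  T_ <- rand_profile(12, "T")
  expect_equal(rd_kopt(T_, T_, m_profile(T_, 0)), 0)   # O = T
  # sharpened O keeps the optimum at K = 0, forcing RD_Kopt = 0.5
  sharp <- hydro_profile(T_$values^1.05, "O")
  scan <- optimize_k(sharp, T_)
  expect_equal(scan$k_opt, 0)
  M0 <- m_profile(T_, scan$k_opt)
  expect_equal(rd_kopt(sharp, T_, M0), 0.5, tolerance = 1e-12)
  # random case: composition of the KL oracle
  O <- rand_profile(12)
  sc <- optimize_k(O, T_)
  M <- m_profile(T_, sc$k_opt)
  expect_equal(rd_kopt(O, T_, M),
               kl_oracle(O$values, T_$values) /
                 (kl_oracle(O$values, T_$values) +
                    kl_oracle(O$values, M$values)),
               tolerance = 1e-12)
})

test_that("fragment restricted to the whole unit reproduces the unit result", {
  syn <- generate_synthetic(synthetic_spec(n = 40,
                                           assignment = "core_sorted",
                                           seed = 17))
  unit <- suppressWarnings(
    fod_analyze(syn$atoms, hydrophobicity = syn$hydrophobicity))
  frag <- suppressWarnings(
    fragment_status(syn$atoms, attr(unit, "field"), c(1, 40),
                    hydrophobicity = syn$hydrophobicity))
  expect_equal(frag$rd, unit$rd, tolerance = 1e-12)
  expect_equal(frag$k_opt, unit$k_opt)
  expect_equal(frag$rd_kopt, unit$rd_kopt, tolerance = 1e-12)
  expect_equal(frag$n_residues, unit$n_residues)
})

test_that("fragment profiles renormalize locally and use the local T max", {
  syn <- generate_synthetic(synthetic_spec(n = 50, assignment = "shuffled",
                                           seed = 19))
  unit <- suppressWarnings(
    fod_analyze(syn$atoms, hydrophobicity = syn$hydrophobicity))
  field <- attr(unit, "field")
  frag <- suppressWarnings(
    fragment_status(syn$atoms, field, c(35, 50),
                    hydrophobicity = syn$hydrophobicity,
                    fragment_label = "tail"))
  expect_equal(frag$n_residues, 16L)
  expect_equal(sum(frag$profiles$T$values), 1, tolerance = 1e-9)
  expect_equal(sum(frag$profiles$O$values), 1, tolerance = 1e-9)
  expect_equal(sum(frag$profiles$M$values), 1, tolerance = 1e-9)
  expect_equal(frag$fragment_label, "tail")
  expect_gte(frag$rd, 0); expect_lte(frag$rd, 1)
  # too-short fragments are rejected
  expect_error(
    suppressWarnings(fragment_status(syn$atoms, field, c(50, 50),
                                     hydrophobicity = syn$hydrophobicity)),
    "at least 2|matches no")
})

test_that("result writers emit parseable JSON and CSV", {
  syn <- generate_synthetic(synthetic_spec(n = 30,
                                           assignment = "core_sorted",
                                           seed = 23))
  res <- suppressWarnings(
    fod_analyze(syn$atoms, hydrophobicity = syn$hydrophobicity,
                unit_label = "synthetic-30"))
  js <- tempfile(fileext = ".json")
  write_fod_results(res, js, format = "json", include_kscan = TRUE,
                    config = list(cutoff = 9))
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$results[[1]]$unit_label, "synthetic-30")
  expect_equal(parsed$results[[1]]$rd, res$rd, tolerance = 1e-12)
  expect_equal(length(parsed$results[[1]]$kscan), 51L)  # one row per K
  cs <- tempfile(fileext = ".csv")
  write_fod_results(res, cs, format = "csv")
  df <- utils::read.csv(cs)
  expect_equal(df$RD, res$rd, tolerance = 1e-12)
  expect_equal(df$K_opt, res$k_opt)
})
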