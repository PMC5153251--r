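test_that("alkyl series extraction keeps 14n+1 ions and records absences", {
  sp <- ei_spectrum(c(57, 60, 71, 85, 99), c(10, 99, 8, 6, 4))
  ser <- alkyl_series(sp)
  expect_identical(ser$mz[ser$present], c(57, 71, 85, 99))
  expect_false(60 %in% ser$mz)
  # absent members are absent, not zero
  expect_true(all(is.na(ser$intensity[!ser$present])))
  # series span follows the parent mass when known
  sp26 <- gen_ei_spectrum(hydrocarbon(26))
  ser26 <- alkyl_series(sp26)
  expect_identical(range(ser26$mz), c(43, 351))
  expect_true(all(ser26$present))
  expect_error(alkyl_series(ei_spectrum(c(57, 71), c(1, 1))),
               "insufficient")
})

test_that("noiseless decay parameters are recovered to 6 significant digits", {
  m <- 14 * (3:25) + 1
  fit <- fit_decay(data.frame(mz = m, intensity = 1000 * exp(-0.02 * m)))
  expect_equal(coef(fit)[["A"]], 1000, tolerance = 1e-6)
  expect_equal(coef(fit)[["lambda"]], 0.02, tolerance = 1e-6)
  expect_true(all(abs(residuals(fit)) < 1e-6))
})

test_that("a single 5x ion is excluded and the rate survives within 10%", {
  m <- 14 * (3:25) + 1
  I <- 1000 * exp(-0.02 * m)
  I[m == 141] <- 5 * I[m == 141]
  fit <- fit_decay(data.frame(mz = m, intensity = I))
  expect_identical(fit$excluded, 141)
  expect_lt(abs(coef(fit)[["lambda"]] - 0.02) / 0.02, 0.10)
})

test_that("decay rate is recovered within 15% under lognormal noise", {
  m <- 14 * (3:32) + 1
  ok <- 0L
  for (s in 1:50) {
    set.seed(s)
    I <- 1000 * exp(-0.02 * m) * exp(stats::rnorm(length(m), 0, 0.1))
    fit <- fit_decay(data.frame(mz = m, intensity = I))
    if (abs(coef(fit)[["lambda"]] - 0.02) / 0.02 <= 0.15) ok <- ok + 1L
  }
  expect_gte(ok / 50, 0.95)
})

test_that("flat series warns and produces no enhanced ions", {
  m <- 14 * (3:12) + 1
  expect_warning(fit <- fit_decay(data.frame(mz = m, intensity = rep(5, 10))),
                 "flat")
  expect_true(fit$flat)
  expect_identical(nrow(enhanced_ions(fit)), 0L)
})

test_that("enhanced-ion detection finds the diagnostic pair and is monotone",
{
  fit_lin <- fit_decay(alkyl_series(gen_ei_spectrum(hydrocarbon(26))))
  expect_identical(nrow(enhanced_ions(fit_lin)), 0L)
  fit_br <- fit_decay(alkyl_series(gen_ei_spectrum(hydrocarbon(29, 9))))
  expect_identical(enhanced_ions(fit_br)$mz, c(141, 309))
  expect_identical(nrow(enhanced_ions(fit_br, tau = Inf)), 0L)
  # monotone non-increasing in tau (set inclusion)
  taus <- c(1.5, 2, 3, 4.9, 5.1)
  sets <- lapply(taus, function(t) enhanced_ions(fit_br, tau = t)$mz)
  for (i in seq_along(taus)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("branch counting pairs complementary ions at M + 28", {
  bp <- estimate_branch_count(c(141, 309), parent_mass = 422)
  expect_identical(bp$k, 1L)
  expect_equal(unname(bp$pairs[1, ]), c(141, 309))
  expect_identical(estimate_branch_count(numeric(0), 422)$k, 0L)
  # midpoint ion self-pairs
  mid <- estimate_branch_count(225, 422)
  expect_identical(mid$k, 1L)
  expect_equal(unname(mid$pairs[1, ]), c(225, 225))
  # unpairable ions: k = 0 with a warning, ions reported
  expect_warning(odd <- estimate_branch_count(150, 422), "pairable")
  expect_identical(odd$k, 0L)
  expect_equal(odd$unpaired, 150)
  # branch count never exceeds the number of enhanced ions
  expect_lte(estimate_branch_count(c(141, 225, 309), 422)$k, 3L)
})

test_that("pair inversion yields canonical structures or rejects", {
  pair <- estimate_branch_count(c(141, 309), 422)$pairs
  cands <- infer_branch_positions(pair, 422)
  expect_length(cands, 1L)
  expect_identical(format(cands[[1]]), "9-methylnonacosane")
  mid <- matrix(c(225, 225), 1, dimnames = list(NULL, c("low", "high")))
  expect_identical(format(infer_branch_positions(mid, 422)[[1]]),
                   "15-methylnonacosane")
  # non-integer locant rejects the pair
  bad <- matrix(c(140, 310), 1, dimnames = list(NULL, c("low", "high")))
  expect_length(infer_branch_positions(bad, 422), 0L)
  # parent mass must be an alkane mass
  expect_error(infer_branch_positions(pair, 421), "alkane")
})

test_that("end-to-end identification recovers structure and checks RI", {
  lad <- make_uniform_ladder()
  curves <- build_ri_curves(make_ri_reference(per_branch = -35))
  truth <- hydrocarbon(29, 9)
  target_ri <- 100 * 30 - 35  # the reference model's C30 monomethyl value
  rt <- stats::approx(lad$carbon_number * 100, lad$rt_min, target_ri)$y
  sp <- gen_ei_spectrum(truth)
  sp$rt <- rt
  res <- identify_compound(sp, ladder = lad, curves = curves)
  expect_false(res$inconclusive)
  expect_identical(res$branch_count, 1L)
  expect_identical(format(res$candidates[[1]]), "9-methylnonacosane")
  expect_identical(res$ri_check[[1]]$verdict, "pass")
  # linear alkane: no branches, RI at 100 n
  sp26 <- gen_ei_spectrum(hydrocarbon(26))
  sp26$rt <- stats::approx(lad$carbon_number * 100, lad$rt_min, 2600)$y
  res26 <- identify_compound(sp26, ladder = lad, curves = curves)
  expect_identical(res26$branch_count, 0L)
  expect_identical(format(res26$candidates[[1]]), "Hexacosane")
  expect_equal(res26$ri, 2600)
  # flat spectrum flagged inconclusive, not an error
  flat <- ei_spectrum(14 * (3:12) + 1, rep(3, 10), parent_mass = 422)
  res_flat <- identify_compound(flat)
  expect_true(res_flat$inconclusive)
})

test_that("monomethyl structures round-trip through the whole workflow", {
  # noiseless: every backbone and branch position recovers exactly
  for (L in c(23, 29, 37)) {
    for (b in 2:floor((L + 1) / 2)) {
      truth <- hydrocarbon(L, b)
      res <- identify_compound(gen_ei_spectrum(truth))
      expect_identical(res$branch_count, 1L)
      expect_length(res$candidates, 1L)
      expect_identical(res$candidates[[1]]$branch_positions,
                       truth$branch_positions)
    }
  }
  # noisy replicates at the generator's default enhancement
  set.seed(2024)
  ok <- 0L
  n_rep <- 60L
  for (s in seq_len(n_rep)) {
    L <- sample(23:37, 1)
    b <- sample(2:(L - 1), 1)
    truth <- hydrocarbon(L, b)
    sp <- gen_ei_spectrum(truth, noise_sigma = 0.15, seed = 7000L + s)
    res <- identify_compound(sp)
    if (length(res$candidates) == 1L &&
        identical(res$candidates[[1]]$branch_positions,
                  truth$branch_positions)) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok / n_rep, 0.9)
})

test_that("dimethyl spectra resolve via the k-specific complement sum", {
  res <- identify_compound(gen_ei_spectrum(hydrocarbon(31, c(5, 9))))
  expect_identical(res$branch_count, 2L)
  keys <- vapply(res$candidates,
                 function(s) paste(s$branch_positions, collapse = ","),
                 character(1))
  expect_true("5,9" %in% keys)
})
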