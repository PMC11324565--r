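test_that("pseudo-Aroclor profiles hit the target average exactly and reproducibly", {
  p <- pseudo_aroclor(6.34, seed = 1)
  expect_equal(average_chlorine(p), 6.34, tolerance = 0.01 / 6.34)
  expect_equal(average_chlorine(pseudo_aroclor(6.4, seed = 2)), 6.40,
               tolerance = 0.01 / 6.4)
  expect_identical(p$mole_percent, pseudo_aroclor(6.34, seed = 1)$mole_percent)
  expect_false(identical(p$mole_percent,
                         pseudo_aroclor(6.34, seed = 2)$mole_percent))
  # tetra-octa support only
  ncl <- congener_table()$n_cl[match(as.integer(names(p$mole_percent)),
                                     congener_table()$bz)]
  expect_true(all(ncl >= 4 & ncl <= 8))
  expect_error(pseudo_aroclor(4.2, seed = 1), "\\[5.5, 7.5\\]")
})

test_that("all-zero rates freeze the profile and moles are conserved", {
  sp <- simulation_spec(base_rates = c(ortho = 0, meta = 0, para = 0),
                        times = c(0, 30, 60), seed = 3)
  tc <- simulate_dechlor(sp)
  for (p in tc$profiles) {
    expect_equal(p$mole_percent, tc$profiles[[1]]$mole_percent)
  }
  sp2 <- simulation_spec(times = c(0, 15, 21, 45, 112), seed = 3)
  tc2 <- simulate_dechlor(sp2)
  sums <- rowSums(attr(tc2, "ledger")$mole_fractions)
  expect_true(max(abs(sums - 1)) <= 1e-9)
})

test_that("meta-only decay of PCB153 matches the closed-form exp(-2kt)", {
  k <- 0.03
  init <- congener_profile("PCB153", 100, system = "cf")
  sp <- simulation_spec(initial = init,
                        base_rates = c(ortho = 0, meta = k, para = 0),
                        lag = 0, times = c(0, 2, 5, 10, 20), seed = 1)
  tc <- simulate_dechlor(sp)
  nf <- attr(tc, "noise_free")
  x153 <- vapply(nf$profiles, function(p) {
    v <- p$mole_percent["153"]
    if (is.na(v)) 0 else unname(v) / 100
  }, numeric(1))
  expect_equal(x153, exp(-2 * k * c(0, 2, 5, 10, 20)), tolerance = 1e-9)
})

test_that("lag delays the dynamics as a hard shift", {
  init <- congener_profile("PCB153", 100)
  k <- 0.05
  sp <- simulation_spec(initial = init,
                        base_rates = c(ortho = 0, meta = k, para = 0),
                        lag = 10, times = c(0, 5, 10, 15), seed = 1)
  nf <- attr(simulate_dechlor(sp), "noise_free")
  avg <- vapply(nf$profiles, average_chlorine, numeric(1))
  expect_equal(avg[1:3], rep(6, 3))  # untouched through the lag
  expect_lt(avg[4], 6)
})

test_that("the chloride ledger equals the average-chlorine decline exactly", {
  sp <- simulation_spec(times = c(0, 15, 21, 45, 112), seed = 11)
  tc <- simulate_dechlor(sp)
  nf <- attr(tc, "noise_free")
  for (t1 in c(21, 112)) {
    d_avg <- average_chlorine(profile_at(nf, 0)) -
      average_chlorine(profile_at(nf, t1))
    expect_equal(ledger_chloride(tc, t1), d_avg, tolerance = 1e-6)
    # and therefore matches the rate computed by the metrics module
    r <- dechlorination_rate(nf, 0, t1)
    expect_equal(r$rate,
                 ledger_chloride(tc, t1) * total_molar_concentration(nf, 0) / t1,
                 tolerance = 1e-6)
  }
})

test_that("average chlorine and positional pools decline monotonically (noise-free)", {
  sp <- simulation_spec(base_rates = c(ortho = 0.001, meta = 0.01, para = 0.003),
                        times = c(0, 10, 20, 40, 80, 120), lag = 5, seed = 9)
  nf <- attr(simulate_dechlor(sp), "noise_free")
  avg <- vapply(nf$profiles, average_chlorine, numeric(1))
  expect_true(all(diff(avg) <= 1e-12))
  for (pos in c("ortho", "meta", "para")) {
    pr <- positional_removal(nf, 0, 120)
    expect_gte(pr$removal_fraction[pr$position == pos], 0)
  }
  ns <- vapply(nf$profiles, function(p) {
    pr <- positional_removal(dechlor_timecourse(list(p)), p$time, p$time)
    pr$n_t0
  }, numeric(3))
  expect_true(all(apply(ns, 1, function(v) all(diff(v) <= 1e-12))))
})

test_that("noise-free positional trajectories recover the generating rate bias", {
  sp <- simulation_spec(base_rates = c(ortho = 0.001, meta = 0.02, para = 0.005),
                        lag = 0, times = c(0, 30), seed = 5)
  nf <- attr(simulate_dechlor(sp), "noise_free")
  k <- estimate_position_rates(nf, 0, 30)
  expect_true(k[["meta"]] > k[["para"]] && k[["para"]] > k[["ortho"]])
  # with uniform per-site kinetics the pooled estimates are exact
  expect_equal(unname(k), c(0.001, 0.02, 0.005), tolerance = 1e-8)
})

test_that("process multipliers rescale matching reactions", {
  init <- congener_profile("PCB153", 100)
  k <- 0.02
  sp_fast <- simulation_spec(initial = init,
                             base_rates = c(ortho = 0, meta = k, para = 0),
                             process_multipliers = c(N = 3), lag = 0,
                             times = c(0, 10), seed = 1)
  nf <- attr(simulate_dechlor(sp_fast), "noise_free")
  x153 <- unname(nf$profiles[[2]]$mole_percent["153"]) / 100
  expect_equal(x153, exp(-2 * 3 * k * 10), tolerance = 1e-9)
})

test_that("observation noise is seed-reproducible and applied after dynamics", {
  sp <- simulation_spec(sigma = 0.05, times = c(0, 15, 21), seed = 42)
  a <- simulate_dechlor(sp)
  b <- simulate_dechlor(sp)
  expect_identical(lapply(a$profiles, `[[`, "mole_percent"),
                   lapply(b$profiles, `[[`, "mole_percent"))
  # noise-free attribute untouched by sigma
  nf <- attr(a, "noise_free")
  sp0 <- simulation_spec(sigma = 0, times = c(0, 15, 21), seed = 42)
  nf0 <- attr(simulate_dechlor(sp0), "noise_free")
  expect_equal(lapply(nf$profiles, `[[`, "mole_percent"),
               lapply(nf0$profiles, `[[`, "mole_percent"))
  expect_error(simulation_spec(sigma = 0.1, seed = NULL), "seed")
})

test_that("detection limit zeroes trace congeners and renormalizes", {
  sp <- simulation_spec(times = c(0, 112), detection_limit = 0.5, seed = 13)
  tc <- simulate_dechlor(sp)
  obs <- tc$profiles[[2]]$mole_percent
  expect_true(all(obs == 0 | obs >= 0.5 * 100 / (100 + 0.5 * length(obs))))
  expect_equal(sum(obs), 100)
})
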