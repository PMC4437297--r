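make_sweep_stub <- function(f0, g1, g2 = NULL, fe = NULL, n = 10000) {
  if (is.null(g2)) g2 <- rep(0, length(f0))
  if (is.null(fe)) fe <- pmin(0.5 * f0 + 0.2 * g1, 1)
  structure(list(
    summary = data.frame(f0 = f0, f = f0, fe = fe, g1 = g1, g2 = g2),
    config = list(n = n, k_mean = NA, f0_grid = f0,
                  n_realizations = 1, base_seed = 1,
                  params = model_params())),
    class = "opinion_sweep")
}

make_aval_stub <- function(f0, s_star) {
  structure(list(summary = data.frame(f0 = f0, s_star = s_star,
                                      s_star_max = s_star,
                                      mean_s = s_star / 2),
                 config = list()),
            class = "avalanche_profile")
}

test_that("find_critical_points recovers planted peaks with refinement", {
  f0 <- seq(0.1, 0.6, by = 0.02)
  g2 <- exp(-((f0 - 0.30) / 0.05)^2)
  g1 <- pmax(0, f0 - 0.30)
  sw <- make_sweep_stub(f0, g1, g2)
  av <- make_aval_stub(f0, exp(-((f0 - 0.44) / 0.08)^2) * 50)
  cp <- find_critical_points(sw, av)
  expect_lt(abs(cp$f0_c1 - 0.30), 0.005)
  expect_lt(abs(cp$f0_c2 - 0.44), 0.005)
  expect_true(cp$f0_c1 <= cp$f0_c2)
  # peak on the boundary is an error asking for a wider grid
  g2b <- seq(0, 1, length.out = length(f0))
  expect_error(find_critical_points(make_sweep_stub(f0, g1, g2b)),
               "boundary")
})

test_that("classify_order separates steps from continuous growth", {
  f0 <- seq(0, 1, by = 0.02)
  step <- ifelse(f0 > 0.5, 0.6, 0.02)
  expect_warning(o1 <- classify_order(data.frame(f0 = f0, g1 = step)),
                 "finite-size")
  expect_equal(as.character(o1), "first")
  ramp <- pmax(0, f0 - 0.5) * 0.8
  expect_warning(o2 <- classify_order(data.frame(f0 = f0, g1 = ramp)),
                 "finite-size")
  expect_equal(as.character(o2), "second")
  # a jump shrinking as 1/sqrt(n) across sizes is a finite-size artefact
  sizes <- c(2500, 10000, 40000)
  curves <- do.call(rbind, lapply(sizes, function(n) {
    jump <- 4 / sqrt(n)
    data.frame(f0 = f0, g1 = ifelse(f0 > 0.5, 0.05 + jump, 0.05), n = n)
  }))
  expect_equal(as.character(classify_order(curves, jump_threshold = 0.01)),
               "second")
  # a persistent jump stays first order
  curves2 <- do.call(rbind, lapply(sizes, function(n)
    data.frame(f0 = f0, g1 = ifelse(f0 > 0.5, 0.45, 0.02), n = n)))
  expect_equal(as.character(classify_order(curves2)), "first")
})

test_that("fit_zeta recovers planted exponents on noise-free curves", {
  f0c <- 0.30
  f0 <- seq(0.1, 0.6, by = 0.005)
  g2 <- exp(-((f0 - f0c) / 0.01)^2)   # sharp peak pins f0_c1
  for (zeta_true in c(0.5, 1)) {
    g1 <- 0.1 + ifelse(f0 > f0c, 0.8 * (f0 - f0c)^zeta_true, 0)
    sw <- make_sweep_stub(f0, g1, g2)
    cp <- find_critical_points(sw)
    fit <- fit_zeta(sw, cp, side = "above_c1", window = 0.05,
                    g1_c = 0.1)
    expect_lt(abs(fit$zeta - zeta_true), 0.02)
  }
  # approach from below at f0_c2, with the branch endpoint fixed or
  # profiled out as a nuisance parameter
  g1b <- 0.5 - 0.7 * pmax(0.44 - f0, 0)^0.5
  swb <- make_sweep_stub(f0, g1b, g2)
  cpb <- find_critical_points(swb, make_aval_stub(f0,
           exp(-((f0 - 0.44) / 0.01)^2) * 10))
  fitb <- fit_zeta(swb, cpb, side = "below_c2", window = 0.05, g1_c = 0.5)
  expect_lt(abs(fitb$zeta - 0.5), 0.03)
  fitp <- fit_zeta(swb, cpb, side = "below_c2", window = 0.05)
  expect_lt(abs(fitp$zeta - 0.5), 0.03)
  expect_lt(abs(fitp$g1_c - 0.5), 0.02)
  expect_error(fit_zeta(swb, cpb, side = "above_c1", window = 0.001),
               "fewer than 5")
})

test_that("estimate_kc brackets the order change and rejects bad label sets", {
  ks <- seq(4, 5, by = 0.2)
  labels <- c(rep("second", 3), rep("first", 3))
  out <- estimate_kc(ks, labels)
  expect_equal(out$k_c, 4.5)
  expect_equal(out$uncertainty, 0.1)
  expect_error(estimate_kc(ks, rep("second", 6)), "no transition")
  expect_error(estimate_kc(ks, rep("first", 6)), "no transition")
  expect_error(estimate_kc(ks, c("second", "first", "second", "first",
                                 "first", "first")), "non-monotone")
})

test_that("phase diagram lines order correctly and classify societies", {
  lines <- data.frame(k = c(4, 5, 6),
                      f0_c1 = c(0.45, 0.40, 0.35),
                      f0_c2 = c(0.8, 0.75, 0.7),
                      fe_c1 = c(0.25, 0.22, 0.20),
                      fe_c2 = c(0.55, 0.50, 0.45),
                      order = c("second", "first", "first"))
  pd <- structure(list(lines = lines, meta = list(n = 1e4)),
                  class = "phase_diagram")
  expect_true(all(pd$lines$fe_c1 <= pd$lines$fe_c2))
  expect_equal(classify_society(0.0, 4.5, pd), "I")
  expect_equal(classify_society(1.0, 4.5, pd), "III")
  expect_equal(classify_society(0.3, 4.5, pd), "II")
  expect_error(classify_society(0.3, 9, pd), "outside")
  # raising connectivity at fixed fe can tip a society into phase III
  expect_equal(classify_society(0.48, 5.0, pd), "II")
  expect_equal(classify_society(0.48, 5.8, pd), "III")
})

test_that("fit_mean_degree recovers the generating degree from model points", {
  cands <- c(3.5, 4.0, 4.5)
  sw <- run_sweep(1500, 4.0, seq(0.05, 0.95, by = 0.09),
                  n_realizations = 3, base_seed = 77)
  tb <- gen_from_model(sw, 60, 5000, seed = 5)
  pts <- to_ffe(tb)
  pos <- pts[pts$polarity == "positive", c("f", "fe")]
  fit <- fit_mean_degree(pos, cands, n = 1500,
                         f0_grid = seq(0.05, 0.95, by = 0.09),
                         n_realizations = 3, base_seed = 9)
  expect_equal(fit$k, 4.0)
  expect_error(fit_mean_degree(pos[1:5, ], cands), "at least 10")
})
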