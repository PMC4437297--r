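test_that("perturb_one matches the hand-iterated path cascade", {
  # path 1-2-3, all at 0.45: forcing node 1 to 1 lifts node 2 to the mean
  # (1 + 0.45)/2 = 0.725 > q_e, then node 3 follows
  net <- net_path(3)
  p <- model_params(a = 1)
  stable <- relax(opinion_state(rep(0.45, 3), net), p)
  expect_equal(stable$q, rep(0.45, 3))
  r <- perturb_one(stable, 1, p)
  expect_equal(r$size_s, 2L)
  expect_true(r$succeeded)
  expect_equal(stable$q, rep(0.45, 3))   # input untouched
  expect_error(perturb_one(stable, 99, p), "unknown node")
  ext <- relax(opinion_state(c(0.9, 0.45, 0.45), net), p)
  expect_error(perturb_one(ext, 1, p), "not vulnerable")
})

test_that("isolated or saturated triggers give empty avalanches", {
  iso <- opinion_network(matrix(integer(0), ncol = 2), 3)
  st <- opinion_state(c(0.3, 0.2, 0.1), iso)
  p <- model_params(a = 1)
  r <- perturb_one(relax(st, p), 2, p)
  expect_equal(r$size_s, 0L)
  expect_false(r$succeeded)
  # trigger whose neighbours are all already extreme
  star <- net_star(4)
  sst <- opinion_state(c(0.4, 0.9, 0.9, 0.9), star)
  sst <- relax(sst, p)
  vul <- which(sst$q > 0 & sst$q < 0.5)
  if (length(vul) > 0) {
    rr <- perturb_one(sst, vul[1], p)
    expect_equal(rr$size_s, 0L)
  }
})

test_that("avalanche_scan enumerates every vulnerable trigger and restores state", {
  net <- net_path(3)
  p <- model_params(a = 1)
  stable <- relax(opinion_state(rep(0.45, 3), net), p)
  before <- stable$q
  av <- avalanche_scan(stable, p)
  expect_equal(av$n_triggers, 3L)
  expect_equal(av$s_star, 2L)
  expect_equal(sort(av$sizes), c(2L, 2L, 2L))  # each trigger drags the rest
  expect_identical(stable$q, before)
  # no vulnerable nodes -> empty summary
  none <- relax(opinion_state(c(0.9, 0.8, -0.2), net), p)
  av0 <- avalanche_scan(none, p)
  expect_length(av0$sizes, 0)
  expect_true(is.na(av0$mean_s))
})

test_that("avalanche scan agrees with brute-force re-relaxation on random graphs", {
  p <- model_params(a = 1)
  for (seed in 1:5) {
    n <- 30
    edges <- random_edges(n, 0.15, seed)
    net <- opinion_network(edges, n)
    set.seed(seed + 10)
    stable <- relax(init_opinions(net, 0.7), p)
    av <- avalanche_scan(stable, p)
    for (j in seq_along(av$triggers)) {
      q2 <- stable$q
      q2[av$triggers[j]] <- 1
      re <- relax(opinion_state(q2, net), p)
      want <- sum(stable$q > 0 & stable$q < 0.5 & re$q > 0.5 &
                    seq_len(n) != av$triggers[j])
      expect_equal(av$sizes[j], want)
    }
  }
})

test_that("scans are reproducible and ratchet-positive at a = 1", {
  set.seed(20)
  net <- generate_er(300, 5)
  p <- model_params(a = 1)
  stable <- relax(init_opinions(net, 0.6, seed = 21), p)
  a1 <- avalanche_scan(stable, p)
  a2 <- avalanche_scan(stable, p)
  expect_identical(a1$sizes, a2$sizes)
  expect_true(all(a1$sizes >= 0))
})

test_that("fit_tail_envelope recovers the exponent of a cutoff family", {
  # slices share the exponent 1.5 but carry different hard cutoffs, as
  # off-critical avalanche distributions do; the envelope traces the
  # common power law
  set.seed(77)
  slices <- lapply(c(8, 32, 128, 512, 4096), function(cut) {
    s <- rplaw_discrete(40000, alpha = 1.5, xmin = 1)
    s[s <= cut]
  })
  fit <- fit_tail_envelope(slices)
  expect_lt(abs(fit$exponent - 1.5), 0.1)
  expect_error(fit_tail_envelope(slices[1]), "at least 2")
  expect_error(fit_tail_envelope(lapply(1:3, function(i) rep(2L, 100))),
               "envelope too short")
})

test_that("fit_tail recovers a planted exponent and flags misfits", {
  s <- rplaw_discrete(100000, alpha = 1.5, xmin = 1, seed = 42)
  fit <- fit_tail(s, xmin_strategy = "fixed", xmin = 1)
  expect_lt(abs(fit$alpha - 1.5), 0.05)
  expect_equal(fit$n_tail, 100000L)
  # KS-selected xmin on a shifted tail
  s2 <- c(sample(1:3, 5000, replace = TRUE),
          rplaw_discrete(20000, alpha = 2.2, xmin = 4, seed = 7))
  fit2 <- fit_tail(s2)
  expect_lt(abs(fit2$alpha - 2.2), 0.15)
  # geometric sizes: visibly worse KS than a true power law
  set.seed(3)
  geo <- stats::rgeom(20000, 0.2) + 1L
  fg <- fit_tail(geo, xmin_strategy = "fixed", xmin = 1)
  fp <- fit_tail(rplaw_discrete(20000, 1.8, seed = 8),
                 xmin_strategy = "fixed", xmin = 1)
  expect_gt(fg$ks, 3 * fp$ks)
  expect_error(fit_tail(rep(5L, 500)), "degenerate")
  expect_error(fit_tail(1:50), "insufficient tail")
})
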