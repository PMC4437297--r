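test_that("update_node reproduces the worked single-node cases", {
  p <- model_params(a = 0.8, q_e = 0.5)
  expect_equal(update_node(0.5, 0.8, p), 0.8)    # adopt the extreme mean
  expect_equal(update_node(0.5, 0.2, p), 0.5)    # inflexibility range
  expect_equal(update_node(0.5, -0.5, p), 0.3)   # compromise
  expect_equal(update_node(0.7, -0.2, model_params(a = 0)), -0.2)
  expect_equal(update_node(0.5, -0.5, model_params(a = 1)), 0.5)
  # mirror symmetry of the negative side
  expect_equal(update_node(-0.5, -0.8, p), -0.8)
  expect_equal(update_node(-0.5, -0.2, p), -0.5)
  expect_equal(update_node(-0.5, 0.5, p), -0.3)
  # undefined mean (degree-0): hold
  expect_equal(update_node(0.4, NA, p), 0.4)
  # q = 0 conventions
  expect_equal(update_node(0, 0.6, p), 0.2 * 0.6)
  expect_equal(update_node(0, 0.6, model_params(a = 0.8,
               zero_opinion_rule = "adopt")), 0.6)
  expect_error(update_node(1.2, 0, p), "\\[-1, 1\\]")
})

test_that("exactly one rule branch fires on a dense (q, qbar, a) grid", {
  qs <- seq(-1, 1, by = 0.1)
  as <- c(0, 0.25, 0.5, 0.8, 1)
  for (a in as) {
    grid <- expand.grid(q = qs, qbar = qs)
    for (r in seq_len(nrow(grid))) {
      q <- grid$q[r]; qbar <- grid$qbar[r]
      branches <- if (q > 0) {
        c(i = qbar > q,
          ii = qbar <= q && qbar >= (1 - a) * q,
          iii = qbar < (1 - a) * q)
      } else if (q < 0) {
        c(i = qbar < q,
          ii = qbar >= q && qbar <= (1 - a) * q,
          iii = qbar > (1 - a) * q)
      } else c(i = FALSE, ii = FALSE, iii = TRUE)
      expect_equal(sum(branches), 1)
      expect_equal(update_node(q, qbar, model_params(a = a)),
                   oracle_rule(q, qbar, a))
    }
  }
})

test_that("synchronous step matches hand-applied rules and is pure", {
  net <- net_complete(3)
  st <- opinion_state(c(0.9, 0.8, 0.1), net)
  p <- model_params(a = 1)
  st2 <- step_opinions(st, p)
  expect_equal(st2$q, c(0.9, 0.8, 0.85))
  expect_equal(st2$step, 1L)
  expect_equal(st$q, c(0.9, 0.8, 0.1))  # input unmodified
  # a fixed point stays fixed
  st3 <- step_opinions(st2, p)
  st4 <- relax(st2, p)
  expect_true(all(abs(st4$q - 0.9) < 1e-6))
  # opposite-sign pair at a = 1 is frozen
  two <- opinion_state(c(0.5, -0.5), net_path(2))
  expect_equal(step_opinions(two, p)$q, c(0.5, -0.5))
})

test_that("relax finds the stable state, a = 0 gives consensus at the mean", {
  net <- net_complete(3)
  st <- opinion_state(c(0.9, 0.8, 0.1), net)
  r1 <- relax(st, model_params(a = 1, tol = 1e-6))
  expect_true(r1$converged)
  expect_true(all(abs(r1$q - 0.9) < 1e-6))
  r0 <- relax(st, model_params(a = 0))
  expect_true(all(abs(r0$q - 0.6) < 1e-6))
  # complete-graph synchronous averaging conserves the opinion sum
  st5 <- opinion_state(c(0.9, -0.4, 0.3, 0.1, -0.7), net_complete(5))
  one <- step_opinions(st5, model_params(a = 0))
  expect_equal(sum(one$q), sum(st5$q))
  # already-stable state returned unchanged
  stable <- opinion_state(c(0.5, 0.5), net_path(2))
  rs <- relax(stable, model_params(a = 1))
  expect_true(rs$converged)
  expect_equal(rs$q, stable$q)
  expect_lte(rs$step, 1L)
})

test_that("relax detects period-2 cycles and reports the cycle average", {
  # two nodes averaging each other at a = 0 swap opinions forever
  st <- opinion_state(c(0.8, 0.2), net_path(2))
  r <- relax(st, model_params(a = 0))
  expect_true(r$cycle_detected)
  expect_false(r$converged)
  expect_equal(r$q, c(0.5, 0.5))
})

test_that("trajectories stay in [-1, 1], are odd-symmetric, and ratchet at a = 1", {
  for (seed in 1:5) {
    edges <- random_edges(12, 0.3, seed)
    net <- opinion_network(edges, 12)
    set.seed(seed + 100)
    q0 <- runif(12, -1, 1)
    for (a in c(0, 0.5, 1)) {
      p <- model_params(a = a, max_steps = 60)
      st <- opinion_state(q0, net)
      neg <- opinion_state(-q0, net)
      for (t in 1:15) {
        st <- step_opinions(st, p)
        neg <- step_opinions(neg, p)
        expect_true(all(st$q >= -1 & st$q <= 1))
        expect_equal(neg$q, -st$q)  # sign symmetry
      }
    }
    # a = 1 monotone ratchet: |q| never decreases, signs never flip
    p1 <- model_params(a = 1)
    st <- opinion_state(q0, net)
    for (t in 1:20) {
      nxt <- step_opinions(st, p1)
      expect_true(all(abs(nxt$q) >= abs(st$q) - 1e-12))
      expect_true(all(sign(nxt$q) == sign(st$q) | st$q == 0))
      st <- nxt
    }
  }
})

test_that("the neighbour-weighted compromise convention mirrors the worked example", {
  pn <- model_params(a = 0.8, compromise_weight = "neighbors")
  # the single-node diagram example: q = 0.5, a = 0.8, opposing mean -0.5
  expect_equal(update_node(0.5, -0.5, pn), -0.3)
  expect_equal(update_node(-0.5, 0.5, pn), 0.3)
  # rules (i) and (ii) are unchanged by the convention
  expect_equal(update_node(0.5, 0.8, pn), 0.8)
  expect_equal(update_node(0.5, 0.2, pn), 0.5)
  # at a = 1 an opposing mean is adopted outright
  p1 <- model_params(a = 1, compromise_weight = "neighbors")
  expect_equal(update_node(0.5, -0.4, p1), -0.4)
  # and at a = 0 the compromise leaves the opinion unchanged
  p0 <- model_params(a = 0, compromise_weight = "neighbors")
  expect_equal(update_node(0.5, -0.4, p0), 0.5)
})

test_that("relax agrees with the straight-line oracle on small graphs", {
  for (seed in 1:8) {
    n <- sample(3:6, 1)
    edges <- random_edges(n, 0.5, seed)
    net <- opinion_network(edges, n)
    set.seed(seed)
    q0 <- runif(n, -1, 1)
    for (a in c(0, 0.3, 0.7, 1)) {
      got <- relax(opinion_state(q0, net), model_params(a = a))$q
      want <- oracle_relax(q0, edges, n, a)
      expect_equal(got, want, tolerance = 1e-12)
      gotn <- relax(opinion_state(q0, net),
                    model_params(a = a,
                                 compromise_weight = "neighbors"))$q
      wantn <- oracle_relax(q0, edges, n, a, mix = 1 - a)
      expect_equal(gotn, wantn, tolerance = 1e-12)
    }
  }
})

test_that("neighbor_mean averages neighbours and flags isolates", {
  net <- opinion_network(rbind(c(1, 2), c(1, 3)), 4)
  st <- opinion_state(c(0, 0.9, 0.8, 0.5), net)
  expect_equal(neighbor_mean(st, 1), 0.85)
  expect_equal(neighbor_mean(st, 2), 0)
  expect_true(is.na(neighbor_mean(st, 4)))
  expect_error(neighbor_mean(st, 9), "unknown node")
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(model_params(a = 1.2), "a must")
  expect_error(model_params(q_e = 0), "q_e")
  expect_error(model_params(tol = 0), "tol")
  expect_error(model_params(max_steps = 0), "max_steps")
})
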