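test_that("first passage reports the earliest crossing with the nearer sulfur as target", {
  # pair 5-8 dips below 0.5 at frame 5; pair 5-2 at frame 7: single event
  d58 <- c(2, 2, 2, 2, 0.40, 2, 0.45, 2, 0.3, 2)
  d52 <- c(2, 2, 2, 2, 0.60, 2, 0.40, 2, 0.2, 2)
  tr <- scripted_trajectory(d58, d52)
  ev <- detect_first_passage(tr, criterion = swap_criterion(d_cutoff = 0.5))
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$attacker, 5L)
  expect_equal(ev[[1]]$target, 8L)
  expect_equal(ev[[1]]$leaving, 2L)
  expect_equal(ev[[1]]$time, 5)
  expect_equal(ev[[1]]$d_ss, 0.40, tolerance = 1e-12)
  expect_equal(ev[[1]]$verdict, "detected")
  # never below the cutoff: empty
  quiet <- scripted_trajectory(rep(2, 10), rep(2, 10))
  expect_length(detect_first_passage(quiet), 0L)
  # both sulfurs within cutoff in the same frame: nearer one is the target
  tie <- scripted_trajectory(0.45, 0.41)
  evt <- detect_first_passage(tie)
  expect_equal(evt[[1]]$target, 2L)
})

test_that("the detector equals a frame-by-frame exhaustive scan on a 1000-frame stream", {
  topo <- chain_topology(8, c(2L, 5L, 8L), c(2L, 8L))
  tr <- toy_trajectory(topo, n_frames = 1000, step = 0.25, seed = 13)
  for (cutoff in c(0.4, 0.8, 1.5)) {
    want <- oracle_first_passage(tr, topo, cutoff)
    got <- first_passage_table(tr, topo, cutoff)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      want <- want[order(want$thiol, want$member), ]
      g <- got[order(got$thiol, got$member), ]
      expect_equal(g$frame, want$frame)
      expect_equal(g$d, want$d, tolerance = 1e-12)
    }
    # the counted event is the earliest first passage across pairs
    ev <- detect_first_passage(tr, topo, swap_criterion(d_cutoff = cutoff))
    if (!is.null(want)) {
      expect_equal(ev[[1]]$time, min(want$frame))
    } else {
      expect_length(ev, 0L)
    }
  }
})

test_that("detection is threshold-monotone per pair", {
  topo <- chain_topology(8, c(2L, 5L, 8L), c(2L, 8L))
  tr <- toy_trajectory(topo, n_frames = 400, step = 0.3, seed = 17)
  cuts <- c(0.3, 0.5, 0.8, 1.2)
  tabs <- lapply(cuts, function(cc) first_passage_table(tr, topo, cc))
  for (k in seq_len(length(cuts) - 1)) {
    small <- tabs[[k]]; big <- tabs[[k + 1]]
    key <- function(t) paste(t$thiol, t$member)
    expect_true(all(key(small) %in% key(big)))
    # and the first passage cannot happen later at a larger cutoff
    m <- match(key(small), key(big))
    expect_true(all(big$frame[m] <= small$frame))
  }
})

test_that("attack_angle reproduces analytic geometries and random-triple arccos", {
  co <- rbind(c(-1, 0, 0), c(0, 0, 0), c(2, 0, 0))
  expect_equal(attack_angle(co, 1, 2, 3), 180)
  co90 <- rbind(c(0, 1, 0), c(0, 0, 0), c(2, 0, 0))
  expect_equal(attack_angle(co90, 1, 2, 3), 90)
  set.seed(41)
  for (i in 1:20) {
    co <- matrix(rnorm(9), 3, 3)
    u <- co[1, ] - co[2, ]; v <- co[3, ] - co[2, ]
    want <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_equal(attack_angle(co, 1, 2, 3), want, tolerance = 1e-10)
  }
  expect_error(attack_angle(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)),
                            1, 2, 3), "coincident")
  expect_error(attack_angle(co, 1, 1, 3), "differ")
})

test_that("metropolis_accept follows the Boltzmann acceptance law", {
  k <- kT(300)
  # downhill moves are always accepted
  set.seed(1)
  expect_true(all(replicate(100, metropolis_accept(-0.5, k))))
  expect_true(metropolis_accept(0, k))
  # dE = kT ln 2 accepts half the time
  set.seed(2)
  f <- mean(replicate(10000, metropolis_accept(k * log(2), k)))
  expect_equal(f, 0.5, tolerance = 3 * sqrt(0.25 / 10000) / 0.5)
  # acceptance frequency matches exp(-dE/kT) across a dE grid (1e4 draws,
  # three-sigma binomial tolerance)
  set.seed(3)
  for (dE in c(0.5, 1, 2, 4)) {
    p_want <- exp(-dE / k)
    f <- mean(replicate(10000, metropolis_accept(dE, k)))
    expect_lt(abs(f - p_want), 3 * sqrt(p_want * (1 - p_want) / 10000) + 1e-6)
  }
  # doubling kT never decreases acceptance for dE > 0
  for (dE in c(0.5, 2, 5))
    expect_gte(exp(-dE / (2 * k)), exp(-dE / k))
})

test_that("metropolis_swap freezes the environment bit-for-bit and reports dE", {
  fx <- build_i27_star(seed = 9)
  # manufacture a detected geometry: move thiol 32 next to sulfur 55
  co <- fx$frame$coords
  co[32, ] <- co[55, ] + c(0.42, 0.1, 0)
  frame <- cg_frame(co)
  ev <- swap_event(0, 32, 55, 24, sqrt(sum((co[32, ] - co[55, ])^2)),
                   verdict = "detected")
  crit <- swap_criterion("metropolis")
  cfg <- simulation_config()
  set.seed(5)
  dec <- metropolis_swap(frame, fx$topology, ev, potential_params(), crit,
                         cfg)
  expect_true(dec$verdict %in% c("accepted", "rejected"))
  expect_true(is.finite(dec$dE))
  mobile <- dsxchange:::relax_region(co, c(32, 55, 24), crit$relax_radius)
  expect_identical(dec$reactant[!mobile, ], co[!mobile, ])
  expect_identical(dec$product[!mobile, ], co[!mobile, ])
  # minimization decreased (or kept) both subsystem energies
  e0r <- total_energy(frame, fx$topology, potential_params(), force = 480,
                      moving_mask = mobile)
  er <- total_energy(dec$reactant, fx$topology, potential_params(),
                     force = 480, moving_mask = mobile)
  expect_lte(er, e0r + 1e-9)
  # frozen-environment contract makes subsystem dE equal full-system dE
  prod_topo <- apply_swap(fx$topology,
                          dsxchange:::within_verdict(ev, "accepted"))
  dE_full <- total_energy(dec$product, prod_topo, potential_params(),
                          force = 480) -
    total_energy(dec$reactant, fx$topology, potential_params(), force = 480)
  expect_equal(dec$dE, dE_full, tolerance = 1e-7)
})

test_that("distance-only hybrid accepts every detection; cutoff 0 is a plain clamp", {
  fx <- build_i27_star(seed = 10)
  cfg <- simulation_config(seed = 11, n_steps = 4000L, output_stride = 400L)
  # cutoff 0 disables swapping entirely: identical to run_force_clamp
  hy0 <- run_hybrid(fx$frame, fx$topology, potential_params(), cfg,
                    swap_criterion(d_cutoff = 0))
  plain <- run_force_clamp(fx$frame, fx$topology, potential_params(), cfg)
  expect_identical(hy0$trajectory$coords, plain$coords)
  expect_length(hy0$events, 0L)
  # manufactured near-contact start with a wide cutoff: immediate detection,
  # verdict accepted, topology rewired
  co <- fx$frame$coords
  co[32, ] <- co[55, ] + c(0.45, 0.05, 0)
  hy <- run_hybrid(cg_frame(co), fx$topology, potential_params(),
                   simulation_config(seed = 12, n_steps = 2000L,
                                     output_stride = 200L),
                   swap_criterion(d_cutoff = 0.6))
  expect_gte(length(hy$events), 1L)
  expect_true(all(vapply(hy$events, function(e) e$verdict, "") ==
                  "accepted"))
  expect_setequal(hy$topology$disulfide,
                  c(hy$events[[1]]$attacker, hy$events[[1]]$target))
  # virtual counting leaves the topology untouched but still counts one event
  hyv <- run_hybrid(cg_frame(co), fx$topology, potential_params(),
                    simulation_config(seed = 12, n_steps = 2000L,
                                      output_stride = 200L),
                    swap_criterion(d_cutoff = 0.6), virtual = TRUE)
  expect_equal(hyv$topology$disulfide, c(24L, 55L))
  expect_length(hyv$events, 1L)
  # ran to full length despite the early event
  expect_equal(max(hyv$trajectory$times), 2.0, tolerance = 0.15)
})

test_that("hybrid runs are reproducible and the angle filter drops flat geometries", {
  fx <- build_i27_star(seed = 12)
  cfg <- simulation_config(seed = 21, n_steps = 3000L, output_stride = 300L)
  h1 <- run_hybrid(fx$frame, fx$topology, potential_params(), cfg)
  h2 <- run_hybrid(fx$frame, fx$topology, potential_params(), cfg)
  expect_identical(h1$trajectory$coords, h2$trajectory$coords)
  expect_equal(events_table(h1$events), events_table(h2$events))
  # angle_min = 180 can never be satisfied: no event survives the filter
  co <- fx$frame$coords
  co[32, ] <- co[55, ] + c(0.45, 0.05, 0)
  hyf <- run_hybrid(cg_frame(co), fx$topology, potential_params(),
                    simulation_config(seed = 12, n_steps = 500L,
                                      output_stride = 100L),
                    swap_criterion(d_cutoff = 0.6, angle_min = 180))
  expect_length(hyf$events, 0L)
})
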