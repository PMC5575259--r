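test_that("regioselectivity reproduces the 18/12 arithmetic and flags zero denominators", {
  ev <- data.frame(trajectory = 1:30, target = rep(c(55L, 24L), c(18, 12)),
                   verdict = "accepted")
  res <- regioselectivity(ev, n_bootstrap = 0)
  expect_identical(res$n55, 18L)
  expect_identical(res$n24, 12L)
  expect_identical(res$ratio, 1.5)
  expect_false(res$infinite)
  # all events on one sulfur: infinite ratio, flagged
  ev55 <- data.frame(trajectory = 1:5, target = rep(55L, 5),
                     verdict = "accepted")
  res55 <- regioselectivity(ev55, n_bootstrap = 100)
  expect_true(res55$infinite)
  expect_identical(res55$ratio, Inf)
  # invariant under trajectory reordering and bootstrap seed
  res_b <- regioselectivity(ev[sample(1:30), ], n_bootstrap = 0)
  expect_identical(res_b$ratio, res$ratio)
  r1 <- regioselectivity(ev, n_bootstrap = 200, seed = 1)
  r2 <- regioselectivity(ev, n_bootstrap = 200, seed = 2)
  expect_identical(r1$ratio, r2$ratio)
})

test_that("bootstrap SE of the 18/12 ratio matches the exact resampling distribution", {
  ev <- data.frame(trajectory = 1:30, target = rep(c(55L, 24L), c(18, 12)),
                   verdict = "accepted")
  res <- regioselectivity(ev, n_bootstrap = 20000, seed = 4)
  # exact enumeration oracle: X* ~ Bin(30, 18/30), ratio X*/(30 - X*),
  # zero-denominator draws excluded (the redraw rule), sd of the result
  x <- 0:29
  w <- dbinom(x, 30, 0.6); w <- w / sum(w)
  r <- x / (30 - x)
  want <- sqrt(sum(w * r^2) - sum(w * r)^2)
  expect_equal(res$bootstrap_se, want, tolerance = 0.03)
  # the heavy-tailed n = 30 ratio makes the exact bootstrap sd exceed the
  # first-order delta approximation by ~30%; both are recorded here
  expect_gt(want, oracle_ratio_se(18, 12))
})

test_that("angle survival curves match uniform closed form and counting oracle", {
  # uniform angles on [80, 180]: P(angle > theta) = (180 - theta)/100
  set.seed(8)
  a <- runif(4000, 80, 180)
  confs <- data.frame(target = 55L, angle = a)
  ap <- angle_probability(confs, theta_grid = c(0, 90, 130, 170))
  expect_equal(ap$curves$p_55, c(1, 0.9, 0.5, 0.1), tolerance = 0.05)
  expect_equal(ap$curves$p_55[1], 1)  # theta = 0 on a non-empty set
  expect_true("24" %in% ap$undefined)  # empty set flagged
  # two targets: exhaustive counting oracle
  confs2 <- data.frame(target = rep(c(55L, 24L), each = 500),
                       angle = c(runif(500, 100, 180), runif(500, 80, 160)))
  th <- seq(0, 180, 20)
  ap2 <- angle_probability(confs2, theta_grid = th)
  for (i in seq_along(th)) {
    expect_equal(ap2$curves$p_55[i],
                 sum(confs2$angle[confs2$target == 55] > th[i]) / 500)
    expect_equal(ap2$curves$p_24[i],
                 sum(confs2$angle[confs2$target == 24] > th[i]) / 500)
  }
  expect_equal(ap2$curves$ratio, ap2$curves$p_55 / ap2$curves$p_24)
})

test_that("unfolding statistics: first crossings, step curves, empty cases", {
  topo <- chain_topology(2)
  mk <- function(dists, times = seq_along(dists)) {
    co <- array(0, c(2, 3, length(dists)))
    co[2, 1, ] <- dists
    cg_trajectory(co, times, topo)
  }
  # all trajectories crossing at t = 1: step function at 1
  trs <- list(mk(c(25, 25, 25)), mk(c(30, 30, 30)))
  us <- unfolding_statistics(trs, threshold = 20)
  expect_equal(us$fraction, 1)
  expect_equal(us$times, c(1, 1))
  expect_equal(us$curve$cumfreq, c(0.5, 1))
  expect_true(all(diff(us$curve$cumfreq) >= 0))
  # no crossings: fraction 0, empty curve
  none <- unfolding_statistics(list(mk(c(1, 2, 3))), threshold = 20)
  expect_equal(none$fraction, 0)
  expect_equal(nrow(none$curve), 0L)
  # mixed: curve bounded by the unfolded fraction
  mix <- unfolding_statistics(list(mk(c(1, 25, 25)), mk(c(1, 1, 1))),
                              threshold = 20)
  expect_equal(mix$fraction, 0.5)
  expect_lte(max(mix$curve$cumfreq), mix$fraction)
})

test_that("distance distributions are normalized densities with six pairs", {
  topo <- chain_topology(8, c(2L, 5L, 8L), c(2L, 8L))
  topo2 <- chain_topology(8, c(1L, 2L, 5L, 7L, 8L), c(2L, 8L))
  tr <- toy_trajectory(topo2, n_frames = 150, step = 0.2, seed = 3)
  dd <- ss_distance_distributions(tr, topo2, breaks = seq(0, 40, 0.2))
  expect_equal(nrow(dd$pairs), 6L)  # 3 thiols x 2 sulfurs
  for (h in dd$histograms) {
    integral <- sum(h$density * diff(h$breaks))
    expect_equal(integral, 1, tolerance = 1e-9)
  }
  # a static frame gives delta-like histograms at the frame distances
  one <- cg_trajectory(tr$coords[, , 1, drop = FALSE], 1, topo2)
  d1 <- ss_distance_distributions(one, topo2)
  for (key in names(d1$distances)) {
    ij <- as.integer(strsplit(key, "-")[[1]])
    want <- sqrt(sum((tr$coords[ij[1], , 1] - tr$coords[ij[2], , 1])^2))
    expect_equal(d1$distances[[key]], want)
  }
})

test_that("loop PCA removes rigid motion, finds planar modes, matches dense eigensolve", {
  topo <- chain_topology(10)
  base <- matrix(rnorm(30, sd = 0.4), 10, 3)
  rigid <- array(0, c(10, 3, 8))
  set.seed(14)
  for (f in 1:8) {
    th <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    rigid[, , f] <- base %*% t(R) + matrix(runif(3, -2, 2), 10, 3,
                                           byrow = TRUE)
  }
  tr <- cg_trajectory(rigid, 1:8, topo)
  pr <- suppressWarnings(loop_pca(tr, loop_range = 1:10,
                                  unfolded_only = FALSE))
  expect_lt(max(pr$eigenvalues), 1e-12)  # superposition removes rigid motion

  # planar breathing along one collective direction: mode 1 carries all of it
  breath <- array(0, c(10, 3, 12))
  dirn <- matrix(rnorm(30), 10, 3)
  for (f in 1:12) breath[, , f] <- base + (f / 12) * 0.3 * dirn
  trb <- cg_trajectory(breath, 1:12, topo)
  prb <- suppressWarnings(loop_pca(trb, loop_range = 1:10,
                                   unfolded_only = FALSE))
  # superposition leaks a sliver of variance into rotational alignment
  expect_equal(prb$eigenvalues[1] / sum(prb$eigenvalues), 1,
               tolerance = 5e-3)

  # eigenvalues equal a direct covariance eigendecomposition (no
  # superposition needed when frames are already aligned)
  still <- array(0, c(10, 3, 10))
  set.seed(15)
  for (f in 1:10) still[, , f] <- base + matrix(rnorm(30, sd = 0.05), 10, 3)
  trs <- cg_trajectory(still, 1:10, topo)
  prs <- suppressWarnings(loop_pca(trs, loop_range = 1:10,
                                   unfolded_only = FALSE, max_iter = 50))
  X <- prs$superposed
  C <- cov(X) * (nrow(X) - 1) / nrow(X)
  want <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
  expect_equal(prs$eigenvalues, pmax(want, 0), tolerance = 1e-9)

  # reconstruction identity: mean + scores . eigenvectors = superposed frame
  rec <- sweep(prs$projections %*% t(prs$eigenvectors), 2,
               colMeans(X), `+`)
  expect_equal(rec, X, tolerance = 1e-9)
  # orthonormal modes, non-increasing spectrum, variance fractions in [0,1]
  expect_equal(crossprod(prs$eigenvectors), diag(30), tolerance = 1e-9)
  expect_true(all(diff(prs$eigenvalues) <= 1e-12))
  expect_gte(prs$variance_fraction_12, 0)
  expect_lte(prs$variance_fraction_12, 1)
})

test_that("Shrake-Rupley SASA: closed forms, overlap, invariances, MC oracle", {
  r <- 0.25; p <- 0.14
  # isolated sphere
  expect_equal(as.numeric(sasa(matrix(0, 1, 3), radii = r, probe = p)),
               4 * pi * (r + p)^2, tolerance = 1e-12)
  # two fully overlapping identical beads count once
  two <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_equal(as.numeric(sasa(two, radii = r, probe = p)),
               4 * pi * (r + p)^2, tolerance = 1e-12)
  # translation invariance is exact; rotation is invariant up to the
  # angular resolution of the 960-point lattice
  set.seed(19)
  co <- matrix(rnorm(9, sd = 0.3), 3, 3)
  a0 <- as.numeric(sasa(co, radii = r, probe = p))
  expect_equal(as.numeric(sasa(co + 3, radii = r, probe = p)), a0,
               tolerance = 1e-9)
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  expect_equal(as.numeric(sasa(co %*% R, radii = r, probe = p)), a0,
               tolerance = 0.01)
  # non-decreasing in probe radius for a single bead
  probes <- seq(0, 0.3, 0.05)
  areas <- vapply(probes, function(pp)
    as.numeric(sasa(matrix(0, 1, 3), radii = r, probe = pp)), numeric(1))
  expect_true(all(diff(areas) > 0))
  # three-bead toy configuration vs Monte-Carlo surface integration
  tri <- rbind(c(0, 0, 0), c(0.45, 0, 0), c(0.2, 0.4, 0))
  got <- as.numeric(sasa(tri, radii = r, probe = p, n_points = 960))
  want <- oracle_sasa_mc(tri, r, p, n_mc = 100000)
  expect_equal(got, want, tolerance = 0.01)
})

test_that("KS comparison of SASA groups hits the exact D endpoints", {
  x <- c(1.2, 1.4, 1.7, 2.0, 2.2, 2.5)
  same <- compare_sasa_groups(x, x, x, stride = 1)
  expect_equal(same$ks_statistic, 0)
  expect_equal(same$p_value, 1)
  disj <- compare_sasa_groups(c(x, x + 10), x, x + 10, stride = 1)
  expect_equal(disj$ks_statistic, 1)
  expect_lt(disj$p_value, 0.01)
  expect_match(disj$direction, "more compact")
  # under-populated groups skip the test with a warning
  expect_warning(res <- compare_sasa_groups(x, x[1], x, stride = 1),
                 "skipped")
  expect_true(is.na(res$ks_statistic))
})

test_that("decorrelation stride finds the ACF zero crossing", {
  set.seed(23)
  white <- rnorm(500)
  expect_lte(decorrelation_stride(white), 3L)
  slow <- as.numeric(stats::filter(rnorm(2000), rep(0.98, 1),
                                   method = "recursive"))
  expect_gt(decorrelation_stride(slow), 10L)
  expect_equal(decorrelation_stride(rep(1, 50)), 1L)
})

test_that("attack_conformations collects every sub-cutoff frame with its angle", {
  d58 <- c(2, 0.45, 2, 0.30, 2)
  d52 <- c(2, 0.80, 2, 0.45, 2)
  tr <- scripted_trajectory(d58, d52)
  confs <- attack_conformations(tr, d_cutoff = 0.5)
  # frames 2 and 4 qualify; frame 4 has both sulfurs in range
  expect_equal(sort(unique(confs$frame)), c(2L, 4L))
  expect_equal(nrow(confs), 3L)
  expect_true(all(confs$d_ss < 0.5))
  expect_true(all(confs$angle >= 0 & confs$angle <= 180))
})
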