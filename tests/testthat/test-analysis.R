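# analysis operators, each against an independent oracle where one exists

test_that("smoothing is length-preserving, idempotent on constants, and
           matches a brute-force window mean", {
  const <- rep(3.2, 40)
  expect_equal(smooth_series(const, "uniform", 7), const)
  expect_equal(smooth_series(const, "gaussian", 10), const)

  expect_equal(smooth_series(c(0, 3, 0), "uniform", 3)[2], 1.0)

  set.seed(9)
  x <- cumsum(rnorm(300))
  for (w in c(5, 50)) {
    sm <- smooth_series(x, "uniform", w)
    left <- (w - 1) %/% 2
    right <- w - 1 - left
    # brute-force oracle with reflected boundaries
    reflect <- c(rev(x[1:left]), x, rev(x[(300 - right + 1):300]))
    oracle <- vapply(seq_along(x), function(i)
      mean(reflect[i:(i + w - 1)]), numeric(1))
    expect_equal(sm, oracle, tolerance = 1e-12)
  }
  expect_error(smooth_series(1:5, "uniform", 9), "window")
  expect_error(smooth_series(1:5, "uniform", 0), "window")
})

test_that("rupture detection finds constructed sawtooth peaks", {
  # sawtooth with peaks of heights 2.0, 3.0, 1.5
  ramp <- function(peak, up, down) c(seq(0, peak, length.out = up),
                                     seq(peak, 0.1, length.out = down)[-1])
  x <- c(ramp(2, 40, 20), ramp(3, 40, 20), ramp(1.5, 40, 20))
  ev <- detect_ruptures(x, min_prominence = 0.5, min_separation = 10)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$peak_force, c(2, 3, 1.5))
  expect_true(all(ev$window_start < ev$peak_index))
  expect_true(all(ev$window_end > ev$peak_index))

  # a strictly monotone ramp has no events (terminal rise excluded)
  expect_equal(nrow(detect_ruptures(seq(0, 5, length.out = 100))), 0)
})

test_that("rupture detection agrees with an exhaustive prominence scan", {
  set.seed(14)
  for (rep in 1:5) {
    x <- cumsum(rnorm(400))
    prom_min <- 0.3 * diff(range(x))
    sep <- 15
    ev <- detect_ruptures(x, min_prominence = prom_min, min_separation = sep)

    # oracle: O(n^2) prominence for every interior strict local maximum
    n <- length(x)
    peaks <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1
    prom <- vapply(peaks, function(p) {
      l <- p; lm <- x[p]
      while (l > 1 && x[l - 1] <= x[p]) { l <- l - 1; lm <- min(lm, x[l]) }
      r <- p; rm <- x[p]
      while (r < n && x[r + 1] <= x[p]) { r <- r + 1; rm <- min(rm, x[r]) }
      x[p] - max(lm, rm)
    }, numeric(1))
    cand <- peaks[prom >= prom_min]
    keep <- integer()
    for (p in cand[order(x[cand], decreasing = TRUE)])
      if (!length(keep) || all(abs(keep - p) >= sep)) keep <- c(keep, p)
    expect_equal(ev$peak_index, sort(keep))
  }
})

test_that("rupture detection is equivariant to uniform force rescaling", {
  set.seed(4)
  x <- abs(cumsum(rnorm(300)))
  e1 <- detect_ruptures(x, min_separation = 10)
  e2 <- detect_ruptures(10 * x, min_separation = 10)
  expect_equal(e2$peak_index, e1$peak_index)
  expect_equal(e2$peak_force, 10 * e1$peak_force)
})

test_that("rupture statistics report mean, SEM and replica bookkeeping", {
  expect_equal(rupture_statistics(list(10, 10, 10))$sem, 0)
  st <- rupture_statistics(list(1, 2, 3))
  expect_equal(st$mean, 2)
  expect_equal(st$sem, sd(1:3) / sqrt(3), tolerance = 1e-12)
  expect_equal(st$sem, 0.577, tolerance = 1e-3)

  # one replica missing event 2
  evs <- list(c(5, 7), c(6, 8), c(5.5))
  st2 <- rupture_statistics(evs, event_index = 2)
  expect_equal(st2$n, 2)
  expect_equal(st2$n_total, 3)
  expect_error(rupture_statistics(list(1), 1), "insufficient")
  expect_error(rupture_statistics(evs, event_index = 3), "insufficient")
})

test_that("Bell-Evans fit recovers exact lines and extrapolates", {
  v <- c(0.1, 1, 10)
  f <- 10 + 5 * log(v)
  fit <- bell_evans_fit(v, f)
  expect_equal(unname(coef(fit)), c(10, 5), tolerance = 1e-10)
  expect_equal(predict(fit, velocity = 1), 10, tolerance = 1e-10)
  expect_error(bell_evans_fit(c(1, 1, 1), c(2, 3, 4)), "singular")
})

test_that("Bell-Evans slope confidence intervals achieve nominal coverage", {
  set.seed(31)
  a <- 20; b <- 6; sigma <- 1
  v <- rep(c(1e-3, 1e-2, 1e-1), each = 30)
  hits <- 0
  for (k in 1:100) {
    f <- a + b * log(v) + rnorm(length(v), 0, sigma)
    fit <- bell_evans_fit(v, f)
    ci <- confint(fit$lm)["lv", ]
    if (ci[1] <= b && b <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("WLC fit recovers parameters from noise-free curves", {
  p_true <- 4; L_true <- 100; kT <- 1
  x <- seq(5, 90, length.out = 40)
  f <- (kT / p_true) * (0.25 / (1 - x / L_true)^2 - 0.25 + x / L_true)
  fit <- wlc_fit(x, f, kT = kT)
  expect_equal(fit$p, p_true, tolerance = 0.01)
  expect_equal(fit$L, L_true, tolerance = 0.01)
  expect_gt(fit$L, max(x))

  # small-extension slope: F ~ 3 kT x / (2 p L)
  slope <- predict(fit, 1e-3) / 1e-3
  expect_equal(slope, 3 * kT / (2 * p_true * L_true), tolerance = 0.02)

  # points at/beyond the contour estimate are rejected before fitting
  x2 <- c(x, 106, 110)
  f2 <- c(f, 50, 80)
  fit2 <- wlc_fit(x2, f2, kT = kT, L_start = 105)
  expect_equal(fit2$n_rejected, 2)
  expect_equal(fit2$p, p_true, tolerance = 0.01)
})

test_that("NH projections track helix orientation", {
  topo <- helix_topology(12)
  up <- build_ideal_helix(12, axis = c(0, 0, 1))
  dn <- build_ideal_helix(12, axis = c(0, 0, -1))
  flat <- build_ideal_helix(12, axis = c(1, 0, 0))
  tr <- fake_trajectory(list(up, up, up), topo)
  nh <- nh_projection(tr, 1)
  expect_true(all(nh >= 0.85))
  expect_equal(diff(range(nh)), 0, tolerance = 1e-12)

  tr_dn <- fake_trajectory(list(dn), topo)
  expect_equal(nh_projection(tr_dn, 1)[1], -nh[1], tolerance = 1e-9)

  tr_flat <- fake_trajectory(list(flat), topo)
  expect_lt(abs(nh_projection(tr_flat, 1)[1]), 0.3)
})

test_that("turning detection reads the spring-energy fraction at the crossing", {
  nh <- c(rep(-1, 39), rep(0, 61))        # crossing at frame 40
  # symmetric triangular spring-energy peak at frame 40 (so smoothing does
  # not displace the maximum)
  es <- c(seq(0.1, 5, length.out = 40), seq(5, 0.1, length.out = 40)[-1],
          rep(0.1, 21))
  rec <- detect_turning(nh, es)
  expect_equal(rec$turning_frame, 40)
  expect_equal(rec$delta_frames, 0)
  expect_equal(rec$fraction, 1, tolerance = 0.05)
  expect_true(rec$contributes)

  # crossing long after the maximum at decayed energy
  nh2 <- c(rep(-1, 89), rep(0, 11))
  es2 <- c(seq(0.1, 5, length.out = 30), seq(5, 0.2, length.out = 70))
  rec2 <- detect_turning(nh2, es2)
  expect_equal(rec2$turning_frame, 90)
  expect_gt(rec2$delta_frames, 40)
  expect_lt(rec2$fraction, 0.5)
  expect_false(rec2$contributes)

  # no crossing: sentinel record
  rec3 <- detect_turning(rep(-0.9, 50), es[1:50])
  expect_true(rec3$no_turning)
  expect_true(is.na(rec3$turning_frame))
  expect_false(rec3$contributes)
})

test_that("contact fractions are referenced and match brute-force counting", {
  sys <- test_bundle()
  topo <- sys$topology
  conf <- sys$conformation
  conf_far <- conf
  h1 <- with(topo$helices, start[1]:end[1])
  for (m in c("N", "CA", "C")) conf_far[[m]][h1, 1] <-
    conf_far[[m]][h1, 1] + 100
  set.seed(2)
  conf_mid <- perturb_conf(conf, 0.4)
  tr <- fake_trajectory(list(conf, conf_mid, conf_far), topo)

  cf <- contact_fraction(tr, 1, reference_frame = 1)
  expect_equal(cf[1], 1.0)
  expect_equal(cf[3], 0.0)

  # brute-force oracle for the middle frame
  p <- energy_params()
  cb <- derived_sites(conf_mid)$CB
  hx <- topo$residues$helix
  cnt <- 0
  for (i in which(hx == 1)) for (j in which(!is.na(hx) & hx != 1))
    if (sqrt(sum((cb[i, ] - cb[j, ])^2)) <= p$contact_cutoff) cnt <- cnt + 1
  cb0 <- derived_sites(conf)$CB
  cnt0 <- 0
  for (i in which(hx == 1)) for (j in which(!is.na(hx) & hx != 1))
    if (sqrt(sum((cb0[i, ] - cb0[j, ])^2)) <= p$contact_cutoff) cnt0 <- cnt0 + 1
  expect_equal(cf[2], cnt / cnt0, tolerance = 1e-12)
})

test_that("H-bond fraction and helicity timelines span native to unfolded", {
  n <- 20
  topo <- helix_topology(n)
  native <- build_ideal_helix(n)
  ext <- extended_chain(n)
  # half-unfolded: residues 1-10 helical, 11-20 extended
  half <- build_ideal_helix(10)
  half_ext <- extended_chain(10)
  shift <- half$C[10, ] - half_ext$N[1, ] + c(2, 0, 0)
  for (m in c("N", "CA", "C")) half_ext[[m]] <- sweep(half_ext[[m]], 2, -shift)
  half_conf <- list(N = rbind(half$N, half_ext$N),
                    CA = rbind(half$CA, half_ext$CA),
                    C = rbind(half$C, half_ext$C))
  class(half_conf) <- "mp_conformation"

  tr <- fake_trajectory(list(native, half_conf, ext), topo)
  hf <- hbond_fraction(tr)
  expect_gte(hf[1], 0.9)
  expect_equal(hf[3], 0)
  expect_true(all(hf >= 0 & hf <= 1))

  hel <- helicity_timeline(tr)
  expect_gte(hel[1, 1], 0.9)
  expect_equal(hel[2, 1], 0.5, tolerance = 0.1)
  expect_equal(hel[3, 1], 0)
})

test_that("replica alignment recovers constructed time shifts", {
  sys <- test_bundle()
  topo <- sys$topology
  conf <- sys$conformation
  nf <- 80
  base_spring <- dnorm(seq_len(nf), 45, 6)
  base_sig <- sin(seq_len(nf) / 7)
  mk <- function(shift) {
    tr <- fake_trajectory(rep(list(conf), nf), topo,
                          spring_energy = c(rep(0, shift),
                                            base_spring)[1:nf],
                          frame_interval = 1)
    tr$breakdown[, "hb"] <- c(rep(base_sig[1], shift), base_sig)[1:nf]
    tr
  }
  t0 <- mk(0); t30 <- mk(30)
  win <- list(data.frame(event = 1L, window_start = 1L, window_end = nf),
              data.frame(event = 1L, window_start = 1L, window_end = nf))

  # single replica: average equals the smoothed, negated signal
  one <- align_average_responses(list(t0), win[1], signals = "hb",
                                 smooth_window = 5)
  sm <- smooth_series(t0$breakdown[, "hb"], "uniform", 5)
  expect_equal(unname(one[[1]]$mean[, "hb"]), -sm, tolerance = 1e-12)
  expect_true(all(one[[1]]$sd == 0))

  # two identical replicas: SD identically zero
  two <- align_average_responses(list(t0, t0), win, signals = "hb",
                                 smooth_window = 5)
  expect_true(all(two[[1]]$sd == 0))

  # a 30-frame shift is undone by the alignment: where both replicas
  # contribute, the pointwise SD vanishes (identical signals)
  pair <- align_average_responses(list(t0, t30), win, signals = "hb",
                                  smooth_window = 5)
  # keep clear of both replicas' series ends, where the reflected-boundary
  # smoothing of the shifted copy differs
  both <- pair[[1]]$n == 2
  interior <- both & pair[[1]]$offsets > -20 & pair[[1]]$offsets < 0
  expect_true(sum(interior) > 15)
  expect_lt(max(pair[[1]]$sd[interior, "hb"]), 1e-10)
})

test_that("loss ordering reports first-crossing frames per replica", {
  sys <- test_bundle()
  topo <- sys$topology
  conf <- sys$conformation
  conf_apart <- conf              # helices separated: contacts lost
  h1 <- with(topo$helices, start[1]:end[1])
  for (m in c("N", "CA", "C")) conf_apart[[m]][h1, 1] <-
    conf_apart[[m]][h1, 1] + 100
  ext <- extended_chain(nrow(topo$residues))  # everything lost

  confs <- c(rep(list(conf), 3), rep(list(conf_apart), 3), rep(list(ext), 3))
  tr <- fake_trajectory(confs, topo)
  lo <- loss_ordering(list(tr))
  expect_equal(lo$per_replica$contact_frame[1], 4)
  expect_equal(lo$per_replica$hbond_frame[1], 7)
  expect_equal(lo$contacts_first_fraction, 1)

  # identical series: equal frames, ordering fraction 0
  tr2 <- fake_trajectory(c(rep(list(conf), 2), rep(list(ext), 2)), topo)
  lo2 <- loss_ordering(list(tr2))
  expect_equal(lo2$per_replica$contact_frame, lo2$per_replica$hbond_frame)
})

test_that("FEC extraction subsamples frames and records metadata", {
  sys <- build_single_helix_probe("", residues_per_helix = 8,
                                  membrane_thickness = 12, relax_iter = 50)
  tr <- run_pulling(sys, pulling_protocol(n_steps = 5000, frame_interval = 10,
                                          velocity = 0.01, seed = 1))
  expect_equal(n_frames(tr), 501)
  fec <- extract_fec(tr, every = 5, smooth_window = 50)
  expect_equal(length(fec$force), 101)
  expect_equal(fec$force_pN, map_force_units(fec$force), tolerance = 1e-12)
  expect_identical(fec$smoothing$method, "uniform")
  expect_identical(fec$smoothing$window, 50L)
  expect_equal(length(fec$force_smooth), length(fec$force))
})
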