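# analysis module: FEC extraction and smoothing, rupture detection, replica
# alignment, NH-projection rotation analysis, contact/H-bond fractions,
# helicity timelines, Bell-Evans and WLC fits.

#' Smooth a series
#'
#' Length-preserving smoothing with reflected boundaries.  `uniform` is a
#' centred moving mean of `window` points; `gaussian` convolves with a
#' Gaussian kernel of `sigma = window / 5`, truncated at 4 sigma.
#'
#' @param x numeric series.
#' @param method `"uniform"` or `"gaussian"`.
#' @param window window size in points (>= 1, <= length of the series).
#' @return smoothed series, same length as `x`.
#' @examples
#' smooth_series(c(0, 3, 0), "uniform", 3)  # centre value 1
#' @export
smooth_series <- function(x, method = c("uniform", "gaussian"), window = 50) {
  method <- match.arg(method)
  n <- length(x)
  if (window < 1) stop("invalid argument: window must be >= 1")
  if (window > n) stop("invalid argument: window larger than series length")
  if (method == "uniform") {
    w <- as.integer(window)
    if (w == 1) return(x)
    kern <- rep(1 / w, w)
    left <- (w - 1L) %/% 2L
    right <- w - 1L - left
  } else {
    sigma <- window / 5
    half <- max(1L, as.integer(ceiling(4 * sigma)))
    kk <- (-half):half
    kern <- exp(-kk^2 / (2 * sigma^2))
    kern <- kern / sum(kern)
    left <- right <- half
  }
  pad_l <- if (left > 0) rev(x[seq_len(min(left, n))]) else numeric(0)
  if (length(pad_l) < left) pad_l <- c(rep(pad_l[1], left - length(pad_l)), pad_l)
  pad_r <- if (right > 0) rev(x[seq(n - min(right, n) + 1, n)]) else numeric(0)
  if (length(pad_r) < right) pad_r <- c(pad_r, rep(pad_r[length(pad_r)], right - length(pad_r)))
  xp <- c(pad_l, x, pad_r)
  out <- stats::filter(xp, kern, sides = 1)
  # sides = 1 puts the window ending at each index; shift so the kernel is
  # centred with `left` points before and `right` after
  as.numeric(out[(left + right + 1):(left + right + n)])
}

#' Extract a force-extension curve
#'
#' Subsamples the trajectory (every `every`-th frame) and smooths the force
#' with a centred moving average.  Forces are carried both in reduced units
#' (kBT/A) and in pN at the 300 K mapping.
#'
#' @param traj an `mp_trajectory`.
#' @param every frame stride (default every 5th frame).
#' @param smooth_window moving-average window in points.
#' @param method smoothing method, see [smooth_series()].
#' @return an `mp_fec` with extension, raw and smoothed force series, the
#'   frame indices used and smoothing metadata.
#' @export
extract_fec <- function(traj, every = 5, smooth_window = 50,
                        method = "uniform") {
  stopifnot(inherits(traj, "mp_trajectory"))
  nf <- n_frames(traj)
  if (nf < 1) stop("invalid argument: empty trajectory")
  idx <- seq(1, nf, by = every)
  force <- traj$force[idx]
  w <- as.integer(min(smooth_window, length(idx)))
  structure(list(extension = traj$extension[idx],
                 force = force,
                 force_smooth = smooth_series(force, method, w),
                 force_pN = map_force_units(force),
                 frames = idx, steps = traj$steps[idx],
                 smoothing = list(method = method, window = w,
                                  requested_window = smooth_window,
                                  every = every),
                 seed = traj$seed),
            class = "mp_fec")
}

#' @export
print.mp_fec <- function(x, ...) {
  cat(sprintf("FEC: %d points (every %d frames), %s smoothing window %d\n",
              length(x$force), x$smoothing$every, x$smoothing$method,
              x$smoothing$window))
  cat(sprintf("  peak smoothed force %.2f kBT/A (%.1f pN at 300 K)\n",
              max(x$force_smooth), map_force_units(max(x$force_smooth))))
  invisible(x)
}

#' @param x an `mp_fec`.
#' @param pN plot force in pN (300 K mapping) instead of kBT/A.
#' @param ... passed to [plot()].
#' @rdname extract_fec
#' @export
plot.mp_fec <- function(x, pN = TRUE, ...) {
  f <- if (pN) map_force_units(x$force_smooth) else x$force_smooth
  plot(x$extension, f, type = "l", xlab = "extension (A)",
       ylab = if (pN) "force (pN)" else "force (kBT/A)", ...)
  invisible(x)
}

# strict local maxima of a series with plateau handling: equal runs are
# compressed and the centre index of a plateau-peak is reported
local_maxima <- function(x) {
  r <- rle(x)
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(v)
  if (k < 3) return(integer())
  idx <- which(v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k]) + 1
  as.integer(floor((starts[idx] + ends[idx]) / 2))
}

# scipy-style prominence: scan each side until a higher value (or boundary),
# take the minimum of each stretch, prominence = peak - max(minL, minR)
peak_prominence <- function(x, p) {
  n <- length(x)
  i <- p - 1; lmin <- x[p]
  while (i >= 1 && x[i] <= x[p]) { lmin <- min(lmin, x[i]); i <- i - 1 }
  j <- p + 1; rmin <- x[p]
  while (j <= n && x[j] <= x[p]) { rmin <- min(rmin, x[j]); j <- j + 1 }
  x[p] - max(lmin, rmin)
}

#' Detect rupture events in a force-extension curve
#'
#' Finds local maxima of the smoothed force with prominence at least
#' `min_prominence` and pairwise separation at least `min_separation`
#' points (higher peaks win).  Event windows extend to the flanking force
#' minima between retained peaks.  A terminal monotone force rise (the
#' contour-length limit) produces no local maximum and is therefore never
#' reported as a rupture.
#'
#' @param fec an `mp_fec`, or a plain numeric series of (smoothed) forces.
#' @param min_prominence minimum peak prominence, in force units of the
#'   series; default 20 percent of the series range.
#' @param min_separation minimum distance between peaks, points.
#' @return an `mp_ruptures` data.frame with columns `event`, `peak_index`,
#'   `peak_force`, `extension` (NA for plain series), `window_start`,
#'   `window_end`.
#' @export
detect_ruptures <- function(fec, min_prominence = NULL, min_separation = 50) {
  x <- if (inherits(fec, "mp_fec")) fec$force_smooth else as.numeric(fec)
  ext <- if (inherits(fec, "mp_fec")) fec$extension else rep(NA_real_, length(x))
  if (is.null(min_prominence)) min_prominence <- 0.2 * diff(range(x))
  cand <- local_maxima(x)
  if (length(cand)) {
    prom <- vapply(cand, function(p) peak_prominence(x, p), numeric(1))
    cand <- cand[prom >= min_prominence]
  }
  # enforce separation, keeping higher peaks first
  if (length(cand) > 1) {
    ord <- cand[order(x[cand], decreasing = TRUE)]
    kept <- integer()
    for (p in ord)
      if (!length(kept) || all(abs(kept - p) >= min_separation))
        kept <- c(kept, p)
    cand <- sort(kept)
  }
  if (!length(cand)) {
    out <- data.frame(event = integer(), peak_index = integer(),
                      peak_force = numeric(), extension = numeric(),
                      window_start = integer(), window_end = integer())
    class(out) <- c("mp_ruptures", "data.frame")
    return(out)
  }
  n <- length(x)
  bounds <- c(1, cand, n)
  ws <- we <- integer(length(cand))
  for (k in seq_along(cand)) {
    lo <- bounds[k]; hi <- bounds[k + 2]
    seg_l <- lo:(cand[k])
    seg_r <- (cand[k]):hi
    ws[k] <- seg_l[which.min(x[seg_l])]
    we[k] <- seg_r[which.min(x[seg_r])]
  }
  out <- data.frame(event = seq_along(cand), peak_index = cand,
                    peak_force = x[cand], extension = ext[cand],
                    window_start = ws, window_end = we)
  class(out) <- c("mp_ruptures", "data.frame")
  out
}

#' Rupture-force statistics across replicas
#'
#' Mean and standard error of the peak force of a given event index over a
#' set of replicas; replicas lacking that event are excluded and counted.
#'
#' @param events list of `mp_ruptures` (one per replica), or a list of
#'   numeric vectors of peak forces.
#' @param event_index which event (1-based).
#' @return list with `mean`, `sem`, `n` (replicas contributing) and
#'   `n_total`.
#' @export
rupture_statistics <- function(events, event_index = 1) {
  forces <- vapply(events, function(e) {
    v <- if (inherits(e, "data.frame")) e$peak_force else as.numeric(e)
    if (length(v) >= event_index) v[event_index] else NA_real_
  }, numeric(1))
  ok <- !is.na(forces)
  if (sum(ok) < 2)
    stop("insufficient data: fewer than 2 replicas contain event ",
         event_index)
  f <- forces[ok]
  list(mean = mean(f), sem = sd(f) / sqrt(length(f)), n = length(f),
       n_total = length(forces))
}

# ---------------------------------------------------------------------------
# Bell-Evans and WLC fits
# ---------------------------------------------------------------------------

#' Bell-Evans fit of rupture force versus pulling velocity
#'
#' Least-squares fit of the most-probable rupture force on the natural log
#' of the pulling velocity, `F = a + b ln(v)`, the linear dependence
#' predicted by Bell-Evans theory.  Used to extrapolate simulated rupture
#' forces to slower (experimental) velocities.
#'
#' @param velocities pulling velocities (any consistent unit).
#' @param forces mean rupture forces at each velocity.
#' @return an object of class `mp_bell_evans` with `coef`, `print` and
#'   `predict` methods; `predict(fit, velocity = v)` evaluates the line.
#' @examples
#' fit <- bell_evans_fit(c(0.1, 1, 10), 10 + 5 * log(c(0.1, 1, 10)))
#' coef(fit)
#' predict(fit, velocity = 1)  # intercept
#' @export
bell_evans_fit <- function(velocities, forces) {
  stopifnot(length(velocities) == length(forces))
  if (length(unique(velocities)) < 2)
    stop("singular design: need at least 2 distinct velocities")
  lv <- log(velocities)
  fit <- lm(forces ~ lv)
  structure(list(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
                 lm = fit, velocities = velocities, forces = forces),
            class = "mp_bell_evans")
}

#' @export
coef.mp_bell_evans <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' @export
print.mp_bell_evans <- function(x, ...) {
  cat(sprintf("Bell-Evans fit: F = %.3f + %.3f ln(v)\n", x$a, x$b))
  invisible(x)
}

#' @param object an `mp_bell_evans` fit.
#' @param velocity velocities at which to extrapolate.
#' @param ... ignored.
#' @rdname bell_evans_fit
#' @export
predict.mp_bell_evans <- function(object, velocity, ...) {
  object$a + object$b * log(velocity)
}

#' Worm-like chain fit
#'
#' Fits the interpolation formula
#' `F(x) = (kBT / p) * (1 / (4 (1 - x/L)^2) - 1/4 + x/L)`
#' to a rising FEC segment, estimating the persistence length `p` and
#' contour length `L`.  Points with `x >= L` (beyond the starting contour
#' estimate) are rejected before fitting, and the fitted `L` is constrained
#' above the largest retained extension.
#'
#' @param extension extensions, Angstrom (>= 5 points).
#' @param force forces, kBT/A (or any unit consistent with `kT`).
#' @param kT thermal energy in the force unit times Angstrom (1 for reduced
#'   units).
#' @param L_start starting contour-length estimate; default 5 percent above
#'   the maximum extension.
#' @return an object of class `mp_wlc` with `p`, `L` and the underlying
#'   `nls` fit; `coef`, `print` and `predict` methods are provided.
#' @export
wlc_fit <- function(extension, force, kT = 1, L_start = NULL) {
  stopifnot(length(extension) == length(force))
  if (is.null(L_start)) L_start <- 1.05 * max(extension)
  keep <- extension < L_start
  x <- extension[keep]; f <- force[keep]
  if (length(x) < 5)
    stop("invalid argument: need at least 5 points below the contour estimate")
  p0 <- {
    # small-x expansion F ~ 3 kT x / (2 p L)
    sl <- stats::coef(lm(f ~ x + 0))[[1]]
    max(1e-3, 3 * kT / (2 * max(sl, 1e-8) * L_start))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ (kT / p) * (0.25 / (1 - x / L)^2 - 0.25 + x / L),
                      start = list(p = p0, L = L_start),
                      lower = c(p = 1e-4, L = max(x) * 1.0001),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("WLC fit did not converge: ", conditionMessage(e),
           " (residual range ", paste(signif(range(f), 3), collapse = " to "),
           ")"))
  est <- stats::coef(fit)
  structure(list(p = unname(est["p"]), L = unname(est["L"]), kT = kT,
                 fit = fit, n_used = length(x),
                 n_rejected = sum(!keep)),
            class = "mp_wlc")
}

#' @export
coef.mp_wlc <- function(object, ...) c(p = object$p, L = object$L)

#' @export
print.mp_wlc <- function(x, ...) {
  cat(sprintf("WLC fit: persistence length %.2f A, contour length %.1f A (%d points, %d rejected)\n",
              x$p, x$L, x$n_used, x$n_rejected))
  invisible(x)
}

#' @param object an `mp_wlc` fit.
#' @param extension extensions at which to evaluate the fitted force.
#' @param ... ignored.
#' @rdname wlc_fit
#' @export
predict.mp_wlc <- function(object, extension, ...) {
  (object$kT / object$p) *
    (0.25 / (1 - extension / object$L)^2 - 0.25 + extension / object$L)
}

# ---------------------------------------------------------------------------
# helix rotation, contacts, H-bonds, helicity
# ---------------------------------------------------------------------------

#' NH bond-vector z-projection of a helix
#'
#' Per frame, the mean z-component of the unit NH bond vectors of the
#' residues in a helix.  The vector is oriented so that it points along the
#' helix axis: a transmembrane helix whose N-to-C direction is +z scores
#' near +1, its antiparallel partner near -1, and an unfolded or in-plane
#' segment near 0.  A drop of the second (antiparallel) helix's projection
#' through -0.5 marks its turning during pairwise extraction.
#'
#' @param traj an `mp_trajectory`.
#' @param helix helix index (into the topology's helix table), or an
#'   integer vector of residue indices.
#' @return numeric series, one value per frame.
#' @export
nh_projection <- function(traj, helix) {
  if (length(helix) == 1) {
    m <- traj_metrics(traj)
    return(m$nh[, helix])
  }
  rng <- range(helix)
  hm <- matrix(as.integer(c(rng[1] - 1, rng[2] - 1)), 1, 2)
  out <- cpp_traj_metrics(traj$coords, topo_cpp(traj$topology),
                          pack_params(traj$params, traj$membrane), hm)
  out$nh[, 1]
}

#' Detect the turning of the second helix of a pair
#'
#' The turning frame is the first crossing of the NH projection through
#' `threshold` toward zero (for a down-helix starting near -1 the crossing
#' is upward).  At that frame the Gaussian-smoothed spring energy is read
#' and divided by its window maximum; the helix is deemed to contribute to
#' the rupture event when that fraction is at least `cutoff` and the
#' crossing lies inside the event window.
#'
#' @param nh NH projection series (see [nh_projection()]).
#' @param spring_energy spring-energy series, same length.
#' @param threshold turning threshold on the NH projection.
#' @param cutoff spring-energy fraction above which the turning counts as
#'   part of the rupture.
#' @param window optional `c(start, end)` frame window of the rupture event;
#'   default whole series.
#' @param smooth_window width of the Gaussian smoothing applied to the
#'   spring energy (points; sigma = width / 5).
#' @return a `mp_turning` list: `turning_frame` (NA if no crossing),
#'   `max_frame` (frame of max smoothed spring energy in the window),
#'   `delta_frames`, `fraction`, `contributes`, `no_turning`.
#' @export
detect_turning <- function(nh, spring_energy, threshold = -0.5, cutoff = 0.8,
                           window = NULL, smooth_window = 25) {
  stopifnot(length(nh) == length(spring_energy))
  n <- length(nh)
  if (is.null(window)) window <- c(1, n)
  win <- seq(max(1, window[1]), min(n, window[2]))
  es <- smooth_series(spring_energy, "gaussian", min(smooth_window, n))
  # crossing toward zero from the helix's initial sign: a down-helix starts
  # near -1 and crosses the (negative) threshold upward; an up-helix the
  # mirrored way
  start_sign <- sign(mean(nh[seq_len(min(5, n))]))
  cross <- if (start_sign < 0) which(nh >= threshold) else
    which(nh <= -threshold)
  cross <- cross[cross >= win[1]]
  if (!length(cross)) {
    return(structure(list(turning_frame = NA_integer_, max_frame = NA_integer_,
                          delta_frames = NA_integer_, fraction = NA_real_,
                          contributes = FALSE, no_turning = TRUE),
                     class = "mp_turning"))
  }
  tf <- cross[1]
  mx <- win[which.max(es[win])]
  emax <- es[mx]
  frac <- if (emax > 0) es[tf] / emax else NA_real_
  contributes <- isTRUE(frac >= cutoff) && tf >= win[1] && tf <= win[length(win)]
  structure(list(turning_frame = tf, max_frame = mx,
                 delta_frames = tf - mx, fraction = frac,
                 contributes = contributes, no_turning = FALSE),
            class = "mp_turning")
}

#' @export
print.mp_turning <- function(x, ...) {
  if (x$no_turning) {
    cat("Turning record: no crossing of the threshold\n")
  } else {
    cat(sprintf("Turning at frame %d (%+d frames from spring-energy max), fraction %.2f -> %s\n",
                x$turning_frame, x$delta_frames, x$fraction,
                if (x$contributes) "contributes" else "after the rupture"))
  }
  invisible(x)
}

#' Inter-helix contact fraction of a helix
#'
#' Per frame, the number of C-beta contacts (within the contact cutoff)
#' between the target helix and all other helices, divided by the count at
#' the reference frame.
#'
#' @param traj an `mp_trajectory`.
#' @param helix helix index.
#' @param reference_frame frame whose count defines 1.0.
#' @return numeric series (NA everywhere if the reference count is zero).
#' @export
contact_fraction <- function(traj, helix, reference_frame = 1) {
  stopifnot(reference_frame >= 1, reference_frame <= n_frames(traj))
  m <- traj_metrics(traj)
  cnt <- m$contacts[, helix]
  ref <- cnt[reference_frame]
  if (ref == 0) {
    warning("reference frame has no inter-helix contacts; fraction undefined")
    return(rep(NA_real_, length(cnt)))
  }
  cnt / ref
}

#' Whole-protein inter-helix contact fraction
#'
#' Per frame, the total number of inter-helix C-beta contacts divided by the
#' count at the reference frame.
#'
#' @inheritParams contact_fraction
#' @return numeric series.
#' @export
total_contact_fraction <- function(traj, reference_frame = 1) {
  m <- traj_metrics(traj)
  cnt <- m$contacts_total
  ref <- cnt[reference_frame]
  if (ref == 0) {
    warning("reference frame has no inter-helix contacts; fraction undefined")
    return(rep(NA_real_, length(cnt)))
  }
  cnt / ref
}

#' Native H-bond fraction
#'
#' Per frame, the number of satisfied native H-bonds divided by the native
#' count.
#'
#' @param traj an `mp_trajectory`.
#' @return numeric series in `[0, 1]`.
#' @export
hbond_fraction <- function(traj) {
  nb <- nrow(traj$topology$native_hbonds)
  if (nb == 0) stop("invalid argument: topology has no native H-bonds")
  m <- traj_metrics(traj)
  m$hb_native / nb
}

#' Helicity timeline
#'
#' Per frame and per helix, the fraction of the helix's residues that
#' participate in a satisfied native i -> i-4 H-bond.
#'
#' @param traj an `mp_trajectory`.
#' @return matrix (frames x helices) of helical fractions.
#' @export
helicity_timeline <- function(traj) {
  m <- traj_metrics(traj)
  m$helicity
}

# ---------------------------------------------------------------------------
# replica alignment and loss ordering
# ---------------------------------------------------------------------------

#' Align replicas at maximum spring energy and average their responses
#'
#' For each rupture event, every replica's signal is smoothed, (optionally)
#' negated, and shifted so that its maximum-spring-energy frame sits at
#' offset zero; the aligned replicas are then averaged pointwise with a
#' standard-deviation band.  Interaction-energy signals are negated so that
#' a drop after rupture reads as a loss of interactions.
#'
#' @param trajs list of `mp_trajectory` replicas.
#' @param windows list (per replica) of `mp_ruptures` giving the event
#'   windows in frame indices, e.g. from [detect_ruptures()] mapped back to
#'   frames, or `NULL` to use the whole trajectory as one event.
#' @param signals character vector of breakdown columns to average
#'   (e.g. `c("hb", "sc_sc")`).
#' @param smooth_window uniform smoothing window (points).
#' @param negate negate the signals before averaging.
#' @return list per event: `offsets`, per-signal `mean` and `sd` matrices,
#'   `spring_mean`, and `n` replicas per offset.
#' @export
align_average_responses <- function(trajs, windows = NULL,
                                    signals = c("hb", "sc_sc"),
                                    smooth_window = 50, negate = TRUE) {
  stopifnot(length(trajs) >= 1)
  nrep <- length(trajs)
  if (is.null(windows))
    windows <- lapply(trajs, function(t)
      data.frame(event = 1L, window_start = 1L,
                 window_end = n_frames(t)))
  n_events <- max(vapply(windows, function(w) if (nrow(w)) max(w$event) else 0L,
                         numeric(1)))
  out <- list()
  for (ev in seq_len(n_events)) {
    pieces <- list()
    for (r in seq_len(nrep)) {
      w <- windows[[r]]
      row <- w[w$event == ev, , drop = FALSE]
      if (!nrow(row)) next
      a <- row$window_start[1]; b <- row$window_end[1]
      if (b <= a) { warning("empty window for event ", ev, ", replica ", r,
                            "; skipped"); next }
      tr <- trajs[[r]]
      es <- smooth_series(tr$spring_energy, "uniform",
                          min(smooth_window, n_frames(tr)))
      anchor <- (a:b)[which.max(es[a:b])]
      sig <- sapply(signals, function(s)
        smooth_series(tr$breakdown[, s], "uniform",
                      min(smooth_window, n_frames(tr)))[a:b],
        simplify = FALSE)
      pieces[[length(pieces) + 1]] <-
        list(offsets = (a:b) - anchor,
             sig = if (negate) lapply(sig, function(v) -v) else sig,
             spring = es[a:b])
    }
    if (!length(pieces)) { warning("no replicas for event ", ev); next }
    offs <- range(unlist(lapply(pieces, `[[`, "offsets")))
    grid <- offs[1]:offs[2]
    nsig <- length(signals)
    acc <- array(NA_real_, c(length(grid), length(pieces), nsig))
    spr <- matrix(NA_real_, length(grid), length(pieces))
    for (pi in seq_along(pieces)) {
      pp <- pieces[[pi]]
      pos <- match(pp$offsets, grid)
      for (si in seq_len(nsig)) acc[pos, pi, si] <- pp$sig[[si]]
      spr[pos, pi] <- pp$spring
    }
    mean_m <- sapply(seq_len(nsig), function(si)
      rowMeans(acc[, , si, drop = FALSE], na.rm = TRUE), simplify = TRUE)
    sd_m <- sapply(seq_len(nsig), function(si)
      apply(acc[, , si, drop = FALSE], 1, function(v) {
        v <- v[!is.na(v)]
        if (length(v) >= 2) sd(v) else 0
      }), simplify = TRUE)
    colnames(mean_m) <- colnames(sd_m) <- signals
    out[[ev]] <- list(offsets = grid, mean = mean_m, sd = sd_m,
                      spring_mean = rowMeans(spr, na.rm = TRUE),
                      n = rowSums(!is.na(spr)))
  }
  out
}

#' Order of contact loss versus H-bond loss
#'
#' For each replica, the first frame at which the whole-protein inter-helix
#' contact fraction and the native H-bond fraction drop below `threshold`,
#' plus the fraction of replicas in which contacts are lost first -- the
#' signature of lateral (in-plane) unfolding, where helices separate before
#' their helical structure melts.
#'
#' @param trajs list of `mp_trajectory` replicas.
#' @param threshold loss threshold on both fractions.
#' @return list with `per_replica` data.frame (`contact_frame`,
#'   `hbond_frame`, NA when never crossed) and `contacts_first_fraction`.
#' @export
loss_ordering <- function(trajs, threshold = 0.5) {
  first_below <- function(v) {
    i <- which(v < threshold)
    if (length(i)) i[1] else NA_integer_
  }
  rows <- lapply(trajs, function(tr) {
    cf <- total_contact_fraction(tr)
    hf <- hbond_fraction(tr)
    data.frame(contact_frame = first_below(cf), hbond_frame = first_below(hf))
  })
  df <- do.call(rbind, rows)
  # a threshold never crossed within the run counts as "lost later than the
  # end of the run" for the ordering comparison
  cfx <- ifelse(is.na(df$contact_frame), Inf, df$contact_frame)
  hfx <- ifelse(is.na(df$hbond_frame), Inf, df$hbond_frame)
  ok <- is.finite(cfx) | is.finite(hfx)
  frac <- if (any(ok)) mean(cfx[ok] < hfx[ok]) else NA_real_
  list(per_replica = df, contacts_first_fraction = frac)
}
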