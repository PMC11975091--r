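#' @importFrom stats rnorm runif
NULL

# run expr with a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# hour offsets of the recording states (ring is pre-cut)
.state_times <- c(ring = NA_real_, cut_30min = 0.5, cut_16h = 16,
                  cut_22h = 22, separate = 16, separate_6h = 22)

.protocol_states <- list(
  `1` = c("ring", "cut_30min", "cut_16h", "separate", "separate_6h"),
  `2` = c("ring", "cut_30min", "cut_16h", "cut_22h"))

# recording schedule of one specimen: the intact wall is traced through the
# cut states of protocol 1; separated layers only exist from the separation
# point on (plus their own ring reference)
.schedule_for <- function(protocol, layer) {
  if (is.na(protocol) || !protocol %in% c(1L, 2L)) {
    stop("protocol must be 1 or 2")
  }
  if (protocol == 1L) {
    if (layer == "I") c("ring", "cut_30min", "cut_16h")
    else c("ring", "separate", "separate_6h")
  } else .protocol_states[["2"]]
}

#' Ground-truth parameters of one synthetic specimen
#'
#' Describes an idealized annular-sector specimen: concentric circular arcs
#' of radii `mid_radius -/+ thickness/2`, an initial arc angle (360 deg for
#' an uncut ring; values above 360 model segments closed past a full
#' circle), and a first-order relaxation law for the post-cut evolution of
#' the mid-line curvature and circumferential (membrane) strain:
#' `kappa(t) = kappa_inf + (kappa_0 - kappa_inf) exp(-t / tau)`, with
#' `kappa_inf = kappa_0 * kappa_ratio_inf`, and
#' `strain(t) = membrane_strain_inf_pct * (1 - exp(-t / tau))`.
#' Every derived descriptor (boundary curvatures, lengths, opening angle)
#' then has a closed form, so pipeline output can be checked against exact
#' ground truth.
#'
#' @param mid_radius mid-wall radius in the ring state, mm.
#' @param thickness wall (layer) thickness, mm; must be below
#'   `2 * mid_radius`.
#' @param arc_angle initial arc angle in degrees (360 = uncut ring).
#' @param kappa_ratio_inf asymptotic / initial mid-line curvature ratio;
#'   below 1 the segment opens, above 1 it closes.
#' @param tau_h relaxation time constant in hours. The media-intima layer
#'   relaxes fast (most of the change within 30 minutes, `tau_h ~ 0.2`); the
#'   adventitia keeps creeping over the whole 22 h window (`tau_h ~ 8`).
#' @param membrane_strain_inf_pct asymptotic mid-line strain in percent
#'   (negative = circumferential shortening).
#' @param n_trace_points simulated manual trace points per border
#'   (default 20).
#' @param noise_sd isotropic Gaussian tracing noise, mm (default 0.02,
#'   a realistic manual-clicking error at typical image scales).
#' @param seed integer seed for this specimen's randomness.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(mid_radius, thickness, arc_angle = 360,
                           kappa_ratio_inf = 1, tau_h = 1,
                           membrane_strain_inf_pct = 0,
                           n_trace_points = 20L, noise_sd = 0.02,
                           seed = 1L) {
  if (!is.numeric(mid_radius) || mid_radius <= 0) {
    stop("`mid_radius` must be positive")
  }
  if (!is.numeric(thickness) || thickness <= 0 ||
      thickness >= 2 * mid_radius) {
    stop("`thickness` must be in (0, 2 * mid_radius)")
  }
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  if (n_trace_points < 6L) stop("need at least 6 trace points per border")
  structure(list(mid_radius = mid_radius, thickness = thickness,
                 arc_angle = arc_angle, kappa_ratio_inf = kappa_ratio_inf,
                 tau_h = tau_h,
                 membrane_strain_inf_pct = membrane_strain_inf_pct,
                 n_trace_points = as.integer(n_trace_points),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Closed-form ground truth of a synthetic specimen at a time state
#'
#' @param spec a [synthetic_spec()].
#' @param state one of `ring`, `cut_30min`, `cut_16h`, `cut_22h`,
#'   `separate`, `separate_6h`.
#' @return list with the state's `closed` flag, mid/inner/outer curvatures
#'   and radii, boundary lengths, arc angle `theta_deg` and opening angle
#'   `phi_deg` (`NA` when closed), and the applied membrane strain.
#' @export
state_truth <- function(spec, state) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!state %in% names(.state_times)) {
    stop("unknown time state: ", state)
  }
  kappa0 <- 1 / spec$mid_radius
  theta0 <- spec$arc_angle * pi / 180
  l_mid0 <- theta0 * spec$mid_radius
  t_h <- .state_times[[state]]
  if (state == "ring") {
    kappa_mid <- kappa0
    strain <- 0
  } else {
    decay <- exp(-t_h / spec$tau_h)
    kappa_inf <- kappa0 * spec$kappa_ratio_inf
    kappa_mid <- kappa_inf + (kappa0 - kappa_inf) * decay
    strain <- spec$membrane_strain_inf_pct * (1 - decay)
  }
  l_mid <- l_mid0 * (1 + strain / 100)
  r_mid <- 1 / kappa_mid
  theta <- l_mid * kappa_mid
  r_in <- r_mid - spec$thickness / 2
  r_out <- r_mid + spec$thickness / 2
  if (r_in <= 0) stop("inner radius collapsed: thickness too large for the ",
                      "relaxed curvature")
  closed <- state == "ring" && isTRUE(all.equal(spec$arc_angle, 360))
  theta_deg <- theta * 180 / pi
  list(state = state, closed = closed, t_h = t_h,
       kappa_mid = kappa_mid, r_mid = r_mid,
       kappa_in = 1 / r_in, kappa_out = 1 / r_out,
       r_in = r_in, r_out = r_out,
       length_in = r_in * theta, length_out = r_out * theta,
       theta_deg = theta_deg,
       phi_deg = if (closed) NA_real_ else 180 - theta_deg / 2,
       membrane_strain_pct = strain)
}

#' Generate noisy boundary traces for one specimen state
#'
#' Samples `n_trace_points` points on each of the two concentric arcs of
#' the ground-truth geometry (winding supported past 360 deg), adds
#' isotropic Gaussian tracing noise, and randomizes the center, start angle
#' and travel direction. Deterministic given the spec's seed and the state.
#'
#' @param spec a [synthetic_spec()].
#' @param state time state, see [state_truth()].
#' @return list with `inner` and `outer` [boundary_trace()]s and the
#'   ground-truth list in `truth`.
#' @export
generate_sector_trace <- function(spec, state) {
  tr <- state_truth(spec, state)
  n <- spec$n_trace_points
  .with_seed(as.numeric(spec$seed) * 131 + match(state, names(.state_times)), {
    center <- runif(2, -1, 1)
    start <- runif(1, 0, 2 * pi)
    dir <- sample(c(-1, 1), 1)
    theta <- tr$theta_deg * pi / 180
    ang <- if (tr$closed) {
      start + dir * 2 * pi * (seq_len(n) - 1L) / n
    } else {
      start + dir * theta * (seq_len(n) - 1L) / (n - 1L)
    }
    mk <- function(r, border) {
      pts <- cbind(center[1L] + r * cos(ang), center[2L] + r * sin(ang)) +
        matrix(rnorm(2L * n, sd = spec$noise_sd), ncol = 2L)
      boundary_trace(pts, border, closed = tr$closed)
    }
    list(inner = mk(tr$r_in, "inner"), outer = mk(tr$r_out, "outer"),
         truth = tr)
  })
}

#' Generate the full time series of one specimen
#'
#' Produces traces for every state of the specimen's protocol schedule.
#' Protocol 2 records the separated layer at 30 min, 16 h and 22 h after the
#' radial cut; protocol 1 cuts the intact wall first and separates the
#' layers at 16 h (layer specimens then carry the `separate` /
#' `separate_6h` states).
#'
#' @param spec a [synthetic_spec()].
#' @param protocol 1 or 2.
#' @param layer `"I"`, `"MI"` or `"A"`.
#' @param patient_id,specimen_id identifiers carried into the record.
#' @param states optional explicit state subset (must belong to the
#'   protocol's schedule, chronological).
#' @return object of class `specimen_record`: identifiers, 3 simulated
#'   dial-indicator `thickness_readings`, and `states`, a named list with
#'   the traces and ground truth per time state.
#' @export
generate_specimen_timeseries <- function(spec, protocol = 2L,
                                         layer = c("MI", "A", "I"),
                                         patient_id = "P1",
                                         specimen_id = NULL,
                                         states = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  layer <- match.arg(layer)
  protocol <- as.integer(protocol)
  sched <- .schedule_for(protocol, layer)
  if (!is.null(states)) {
    bad <- setdiff(states, sched)
    if (length(bad) > 0L) {
      stop("states not in protocol ", protocol, " schedule: ",
           paste(bad, collapse = ", "))
    }
    sched <- sched[sched %in% states]
  }
  if (is.null(specimen_id)) {
    specimen_id <- paste(patient_id, layer, protocol, sep = "_")
  }
  recs <- lapply(sched, function(s) generate_sector_trace(spec, s))
  names(recs) <- sched
  readings <- .with_seed(as.numeric(spec$seed) * 131 + 99,
                         spec$thickness + rnorm(3, sd = 0.005))
  structure(list(specimen_id = specimen_id, patient_id = patient_id,
                 layer = layer, protocol = protocol,
                 thickness_readings = readings,
                 thickness_mean = mean(readings),
                 spec = spec, states = recs),
            class = "specimen_record")
}

#' @export
print.specimen_record <- function(x, ...) {
  cat(sprintf("<specimen_record> %s: patient %s, layer %s, protocol %d, %d states\n",
              x$specimen_id, x$patient_id, x$layer, x$protocol,
              length(x$states)))
  invisible(x)
}

#' Cohort generator configuration
#'
#' Per-layer sampling distributions and the imperfect-separation model for a
#' synthetic study cohort. Defaults emulate the published carotid cohort:
#' 17 patients; uncut-ring inner curvatures around 0.362 (MI/intact) and
#' 0.305 (adventitia) 1/mm; MI thickness 0.60 +/- 0.14 mm, intact wall
#' 0.92 +/- 0.15 mm, clean adventitia 0.21 +/- 0.08 mm (residual media adds
#' `f * t_MI` on top, bringing the observed adventitia mean near the
#' published 0.36 mm); the MI layer opening (asymptotic curvature ratio
#' ~ 0.67) quickly (`tau` 0.2 h), the clean adventitia closing (ratio 1.24,
#' pulled down by contamination to ~ 1.13 on average, matching the
#' published final curvature) slowly (`tau` 8 h) with ~ -3.8 % membrane
#' shortening, the intact wall opening like the MI layer.
#'
#' Imperfect separation: each adventitia specimen carries a residual-media
#' fraction `f ~ U(0, f_max)`. Residual media thickens the adventitia
#' (raising A%) and drags its asymptotic curvature ratio toward the MI
#' value, producing the negative A% vs adventitia-curvature association.
#'
#' @param n_patients number of patients (default 17).
#' @param layers layer specimens to emit per patient (`"MI"`, `"A"`).
#' @param protocols protocols to emit (default both); protocol 1 also emits
#'   an intact-wall specimen when `include_intact`.
#' @param include_intact emit intact-wall (`I`) specimens for protocol 1.
#' @param imperfect_separation enable the residual-media coupling.
#' @param f_max upper bound of the residual-media fraction, in `[0, 0.5]`.
#' @param coupling strength of the f -> curvature-ratio pull (default 1,
#'   full interpolation toward the MI ratio at f = 1).
#' @param n_trace_points,noise_sd trace resolution and noise, as in
#'   [synthetic_spec()].
#' @param seed cohort master seed; per-specimen seeds derive from it.
#' @param states optional state subset to emit (e.g. only the final states
#'   for a correlation study); parameter draws are unaffected, only trace
#'   generation is skipped.
#' @param layer_params optional override of the per-layer distribution list;
#'   see the default in the function body for the schema.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 17L, layers = c("MI", "A"),
                          protocols = c(1L, 2L), include_intact = TRUE,
                          imperfect_separation = TRUE, f_max = 0.5,
                          coupling = 1, n_trace_points = 20L,
                          noise_sd = 0.02, seed = 1L, states = NULL,
                          layer_params = NULL) {
  if (f_max < 0 || f_max > 0.5) stop("`f_max` must lie in [0, 0.5]")
  if (n_patients < 1L) stop("need at least one patient")
  if (!all(protocols %in% c(1L, 2L))) stop("protocols must be 1 and/or 2")
  if (!all(layers %in% c("MI", "A"))) stop("layers must be among MI, A")
  defaults <- list(
    MI = list(kappa_in_ring = c(mean = 0.362, sd = 0.051),
              thickness = c(mean = 0.60, sd = 0.14),
              kappa_ratio_inf = c(mean = 0.67, sd = 0.18),
              tau_h = 0.2,
              membrane_strain_inf = c(mean = 3.0, sd = 1.0)),
    # adventitia thickness is the *clean* layer: residual media (fraction f
    # of the MI thickness) is added on top, so the observed mean thickness
    # comes out near the published 0.36 mm at E[f] = 0.25. Likewise the
    # clean closing ratio 1.24 is pulled toward the MI ratio by f, giving a
    # contaminated-average final curvature near the published 0.343 1/mm.
    A = list(kappa_in_ring = c(mean = 0.305, sd = 0.010),
             thickness = c(mean = 0.21, sd = 0.08),
             kappa_ratio_inf = c(mean = 1.24, sd = 0.10),
             tau_h = 8,
             membrane_strain_inf = c(mean = -3.8, sd = 1.0)),
    I = list(kappa_in_ring = c(mean = 0.362, sd = 0.055),
             thickness = c(mean = 0.92, sd = 0.15),
             kappa_ratio_inf = c(mean = 0.66, sd = 0.15),
             tau_h = 4,
             membrane_strain_inf = c(mean = 1.0, sd = 1.0)))
  lp <- if (is.null(layer_params)) defaults else
    utils::modifyList(defaults, layer_params)
  for (ly in names(lp)) {
    r_in_mean <- 1 / lp[[ly]]$kappa_in_ring[["mean"]]
    if (lp[[ly]]$thickness[["mean"]] >= 2 * r_in_mean) {
      stop("infeasible distribution for layer ", ly,
           ": mean thickness exceeds the vessel diameter")
    }
  }
  structure(list(n_patients = as.integer(n_patients), layers = layers,
                 protocols = as.integer(protocols),
                 include_intact = include_intact,
                 imperfect_separation = imperfect_separation,
                 f_max = f_max, coupling = coupling,
                 n_trace_points = as.integer(n_trace_points),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 states = states, layer_params = lp),
            class = "cohort_config")
}

.truncnorm1 <- function(mean, sd, lower, upper = Inf) {
  for (i in 1:100) {
    x <- rnorm(1, mean, sd)
    if (x > lower && x < upper) return(x)
  }
  min(max(mean, lower * 1.01), upper)
}

#' Generate a synthetic specimen cohort with ground truth
#'
#' Draws per-patient vessel geometry and per-layer specimen parameters from
#' the configured distributions, generates every specimen's traced time
#' series, and tabulates the exact ground truth of every specimen x state.
#'
#' @param config a [cohort_config()].
#' @return object of class `ring_cohort`: `specimens` (list of
#'   `specimen_record`s) and `truth` (data.frame, one row per specimen x
#'   state with curvatures, lengths, opening angle, thicknesses, A% and the
#'   residual-media fraction `f`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  lp <- config$layer_params
  specimens <- list()
  truth <- list()
  idx <- 0L
  base_seed <- as.numeric(config$seed) %% 100000
  .with_seed(config$seed, {
    for (p in seq_len(config$n_patients)) {
      pid <- sprintf("P%02d", p)
      # per-patient layer thicknesses, shared across protocols
      t_mi <- .truncnorm1(lp$MI$thickness[["mean"]],
                          lp$MI$thickness[["sd"]], 0.15)
      t_a <- .truncnorm1(lp$A$thickness[["mean"]],
                         lp$A$thickness[["sd"]], 0.06)
      t_i <- .truncnorm1(lp$I$thickness[["mean"]],
                         lp$I$thickness[["sd"]], 0.30)
      for (proto in config$protocols) {
        f <- if (config$imperfect_separation) runif(1, 0, config$f_max) else 0
        t_a_obs <- t_a + f * t_mi
        t_mi_obs <- t_mi * (1 - f)
        a_pct <- adventitia_percentage(t_a_obs, t_mi_obs)
        emit <- config$layers
        if (proto == 1L && config$include_intact) emit <- c(emit, "I")
        for (ly in emit) {
          pars <- lp[[ly]]
          kin <- .truncnorm1(pars$kappa_in_ring[["mean"]],
                             pars$kappa_in_ring[["sd"]], 0.12, 0.8)
          th <- switch(ly, MI = t_mi_obs, A = t_a_obs, I = t_i)
          ratio <- .truncnorm1(pars$kappa_ratio_inf[["mean"]],
                               pars$kappa_ratio_inf[["sd"]], 0.2, 1.8)
          if (ly == "A" && config$imperfect_separation) {
            ratio <- ratio - config$coupling * f *
              (pars$kappa_ratio_inf[["mean"]] -
                 lp$MI$kappa_ratio_inf[["mean"]])
          }
          strain <- rnorm(1, pars$membrane_strain_inf[["mean"]],
                          pars$membrane_strain_inf[["sd"]])
          idx <- idx + 1L
          spec <- synthetic_spec(
            mid_radius = 1 / kin + th / 2, thickness = th,
            arc_angle = 360, kappa_ratio_inf = ratio,
            tau_h = pars$tau_h, membrane_strain_inf_pct = strain,
            n_trace_points = config$n_trace_points,
            noise_sd = config$noise_sd,
            seed = base_seed * 20011 + idx)
          st_req <- if (is.null(config$states)) NULL else
            intersect(.schedule_for(proto, ly), config$states)
          if (!is.null(st_req) && length(st_req) == 0L) next
          rec <- generate_specimen_timeseries(
            spec, protocol = proto, layer = ly, patient_id = pid,
            specimen_id = sprintf("%s_%s_p%d", pid, ly, proto),
            states = st_req)
          rec$f <- f
          rec$a_pct <- if (ly == "I") NA_real_ else a_pct
          specimens[[rec$specimen_id]] <- rec
          for (st in names(rec$states)) {
            tr <- rec$states[[st]]$truth
            truth[[length(truth) + 1L]] <- data.frame(
              specimen_id = rec$specimen_id, patient_id = pid, layer = ly,
              protocol = proto, time_state = st, t_h = tr$t_h,
              closed = tr$closed, kappa_in = tr$kappa_in,
              kappa_out = tr$kappa_out, length_in = tr$length_in,
              length_out = tr$length_out, theta_deg = tr$theta_deg,
              phi_deg = tr$phi_deg,
              membrane_strain_pct = tr$membrane_strain_pct,
              thickness = th, a_pct = rec$a_pct, f = f,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  })
  structure(list(specimens = specimens,
                 truth = do.call(rbind, truth),
                 config = config),
            class = "ring_cohort")
}

#' @export
print.ring_cohort <- function(x, ...) {
  cat(sprintf("<ring_cohort> %d specimens (%d patients), %d truth rows\n",
              length(x$specimens), x$config$n_patients, nrow(x$truth)))
  invisible(x)
}
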