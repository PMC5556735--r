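#' Region-aggregated forcing for calibration
#'
#' Collapses each coastal region to one representative cell (area-weighted
#' mean SST and NPP; summed area), the desk-scale analogue of aggregating
#' observations at the scale of large coastal ecosystems. Because cells are
#' dynamically independent, regional summaries computed on representative
#' cells are the natural reduced model for Monte-Carlo calibration.
#'
#' @param forcing An `fc_forcing`.
#' @param regions A [make_region_mask()] for the same grid.
#' @return List of class `fc_regional_forcing`: `region_id`, `area` (m^2),
#'   `years`, `sst`, `npp` (region x year).
#' @export
regional_forcing <- function(forcing, regions) {
  stopifnot(inherits(forcing, "fc_forcing"), inherits(regions, "fc_regions"))
  oc <- forcing$grid$cell[forcing$grid$ocean]
  rid <- regions$region_id[match(oc, regions$cell)]
  ids <- sort(unique(rid[rid > 0]))
  a <- forcing$grid$area[forcing$grid$ocean]
  sst <- t(vapply(ids, function(r) {
    w <- a[rid == r]
    colSums(forcing$sst[rid == r, , drop = FALSE] * w) / sum(w)
  }, numeric(length(forcing$years))))
  npp <- t(vapply(ids, function(r) {
    w <- a[rid == r]
    colSums(forcing$npp[rid == r, , drop = FALSE] * w) / sum(w)
  }, numeric(length(forcing$years))))
  structure(list(region_id = ids,
                 area = vapply(ids, function(r) sum(a[rid == r]), numeric(1)),
                 years = forcing$years, sst = sst, npp = npp),
            class = "fc_regional_forcing")
}

#' Regional hindcast summaries for one parameter set
#'
#' Runs the coupled hindcast on the representative region cells and returns
#' the two summary statistics the calibration scores: each region's peak
#' annual catch density (t km^-2 yr^-1, equal to g m^-2 yr^-1) over the
#' summary window, and its mean biomass fraction over the final decade.
#'
#' @param params [fc_params()].
#' @param rf A [regional_forcing()].
#' @param scn Scenario (default: the standard 5 %/yr hindcast).
#' @param summary_years Observation-era years over which the peak is taken
#'   (default 1950-2006, clamped to the forcing range); the biomass fraction
#'   is averaged over the last decade of this window.
#' @return Tibble: region_id, peak_catch, biomass_frac.
#' @export
simulate_regional_summaries <- function(params, rf,
                                        scn = scenario(tech_rate = 0.05),
                                        summary_years = NULL) {
  axis <- mass_axis()
  n_sub <- fc_nsub_cells(params, axis, apply(rf$sst, 1, max))
  nr <- length(rf$region_id)
  T0 <- rowMeans(rf$sst[, seq_len(min(10, ncol(rf$sst))), drop = FALSE])
  n0 <- rowMeans(rf$npp[, seq_len(min(10, ncol(rf$npp))), drop = FALSE])
  B <- equilibrium_spectrum(T0, n0, params, axis, dt = 1 / n_sub)
  settle <- fc_cpp_run(B, effort = 0,
                       sst = matrix(T0, nr, 20), npp = matrix(n0, nr, 20),
                       q_year = rep(0, 20), price_year = rep(0, 20),
                       cost_year = rep(0, 20), params = params, axis = axis,
                       n_sub = n_sub, effort_mode = 1L)
  pristine <- rowSums(settle$B, dims = 1)

  years <- rf$years
  out <- fc_cpp_run(settle$B, effort = max(params$E_init, params$E_floor),
                    sst = rf$sst, npp = rf$npp,
                    q_year = catchability_schedule(scn, params, years),
                    price_year = price_schedule(scn, params, years),
                    cost_year = cost_schedule(scn, params, years),
                    params = params, axis = axis, n_sub = n_sub,
                    effort_mode = 0L)
  if (is.null(summary_years)) summary_years <- years[years >= 1950 & years <= 2006]
  iy <- match(summary_years, years)
  late <- tail(iy, 10)
  tibble::tibble(
    region_id = rf$region_id,
    peak_catch = apply(out$harvest[, iy, drop = FALSE], 1, max),
    biomass_frac = rowMeans(out$biomass[, late, drop = FALSE]) / pristine
  )
}

#' Synthetic calibration targets from a reference run
#'
#' Generates the region-aggregated catch and biomass-fraction targets by
#' running the model at a known "truth" parameter set; the calibration is
#' then a parameter-recovery exercise against these synthetic observations.
#'
#' @param rf A [regional_forcing()].
#' @param params_truth The generating parameter set.
#' @param noise_sd Optional lognormal observation noise (sdlog; default 0).
#' @param seed Seed for the noise.
#' @inheritParams simulate_regional_summaries
#' @return Tibble of class `fc_targets`.
#' @export
make_calibration_targets <- function(rf, params_truth = fc_params(),
                                     scn = scenario(tech_rate = 0.05),
                                     noise_sd = 0, seed = 1L) {
  tg <- simulate_regional_summaries(params_truth, rf, scn)
  if (noise_sd > 0) {
    set.seed(seed)
    tg$peak_catch <- tg$peak_catch * rlnorm(nrow(tg), 0, noise_sd)
    tg$biomass_frac <- pmin(tg$biomass_frac * rlnorm(nrow(tg), 0, noise_sd), 1)
  }
  structure(tg, class = c("fc_targets", class(tg)))
}

#' Draw parameter sets from the priors
#'
#' Independent uniform draws on each parameter's stated scale (log-uniform
#' for scale parameters), reproducible under the seed.
#'
#' @param priors A [default_priors()] tibble.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Tibble with one column per calibrated parameter, `n` rows.
#' @export
sample_parameters <- function(priors = default_priors(), n, seed = 1L) {
  set.seed(seed)
  draws <- lapply(seq_len(nrow(priors)), function(i) {
    if (priors$scale[i] == "log") {
      exp(runif(n, log(priors$lower[i]), log(priors$upper[i])))
    } else {
      runif(n, priors$lower[i], priors$upper[i])
    }
  })
  out <- tibble::as_tibble(setNames(draws, priors$name))
  out[seq_len(n), , drop = FALSE]
}

#' Distance between simulated and target regional summaries
#'
#' Weighted root-mean-square of log-ratio misfits across regions and the two
#' summary statistics. Symmetric in log space (a factor 2 overshoot scores
#' the same as a factor 2 undershoot); zero iff the summaries match exactly.
#' A small floor (1e-4) keeps collapsed simulations at large finite distance.
#'
#' @param sim,target Summary tibbles (region_id, peak_catch, biomass_frac).
#' @param w_catch,w_biomass Statistic weights.
#' @return Non-negative scalar distance.
#' @export
score_parameters <- function(sim, target, w_catch = 1, w_biomass = 1) {
  d <- dplyr::inner_join(sim, target, by = "region_id",
                         suffix = c("_sim", "_obs"))
  if (nrow(d) == 0) stop("no common regions between sim and target", call. = FALSE)
  eps <- 1e-4
  lr_c <- log(pmax(d$peak_catch_sim, eps) / pmax(d$peak_catch_obs, eps))
  lr_b <- log(pmax(d$biomass_frac_sim, eps) / pmax(d$biomass_frac_obs, eps))
  sqrt((w_catch * mean(lr_c^2) + w_biomass * mean(lr_b^2)) /
         (w_catch + w_biomass))
}

#' Rejection-ABC acceptance
#'
#' Accepts all draws whose distance is at or below the given quantile of the
#' distance distribution.
#'
#' @param distances Numeric vector.
#' @param quantile_level Acceptance quantile (default 0.05).
#' @return List: `index` (accepted positions), `threshold`.
#' @export
abc_accept <- function(distances, quantile_level = 0.05) {
  thr <- quantile(distances, quantile_level, na.rm = TRUE, names = FALSE)
  list(index = which(distances <= thr), threshold = thr)
}

#' Maximally spread ensemble from the accepted set
#'
#' Greedy max-min selection in prior-normalized parameter space (log scale
#' where the prior is log-uniform): start from the lowest-distance accepted
#' member, then repeatedly add the accepted member whose minimum normalized
#' Euclidean distance to the already-selected members is largest. Yields an
#' ensemble that spans the accepted parameter cloud as widely as possible
#' while every member remains an acceptable fit.
#'
#' @param accepted Tibble of accepted parameter draws.
#' @param distances Their distances.
#' @param priors The priors (for normalization).
#' @param k Ensemble size (default 5).
#' @return List of class `fc_ensemble`: `members` (tibble, k rows, in
#'   selection order), `index` (rows of `accepted`), `distances`.
#' @export
select_ensemble <- function(accepted, distances, priors = default_priors(),
                            k = 5) {
  n <- nrow(accepted)
  if (n < k) {
    stop("only ", n, " accepted parameter sets for an ensemble of ", k,
         "; increase the number of draws or loosen the acceptance quantile",
         call. = FALSE)
  }
  X <- vapply(seq_len(nrow(priors)), function(i) {
    v <- accepted[[priors$name[i]]]
    if (priors$scale[i] == "log") {
      (log(v) - log(priors$lower[i])) / (log(priors$upper[i]) - log(priors$lower[i]))
    } else {
      (v - priors$lower[i]) / (priors$upper[i] - priors$lower[i])
    }
  }, numeric(n))
  X <- matrix(X, nrow = n)
  sel <- which.min(distances)
  while (length(sel) < k) {
    dmin <- vapply(seq_len(n), function(j) {
      if (j %in% sel) return(-Inf)
      min(sqrt(colSums((t(X[sel, , drop = FALSE]) - X[j, ])^2)))
    }, numeric(1))
    sel <- c(sel, which.max(dmin))
  }
  structure(list(members = accepted[sel, , drop = FALSE], index = sel,
                 distances = distances[sel]),
            class = "fc_ensemble")
}

#' @export
print.fc_ensemble <- function(x, ...) {
  cat(sprintf("<fc_ensemble> %d members, distances %s\n",
              nrow(x$members),
              paste(signif(x$distances, 3), collapse = ", ")))
  invisible(x)
}

#' Full Monte-Carlo calibration
#'
#' Samples `n` parameter sets from the priors, scores each against the
#' targets via the reduced regional model, applies rejection-ABC, and selects
#' the maximally spread `k`-member ensemble.
#'
#' @param rf A [regional_forcing()].
#' @param targets A [make_calibration_targets()] tibble (or observed
#'   summaries in the same layout).
#' @param priors Priors tibble.
#' @param n Number of Monte-Carlo draws.
#' @param seed Seed for the draws.
#' @param quantile_level ABC acceptance quantile.
#' @param k Ensemble size.
#' @param base_params Fixed (non-calibrated) parameter slots.
#' @param scn Hindcast scenario used in the simulations.
#' @return List of class `fc_calibration`: `samples` (draws + distance),
#'   `threshold`, `accepted`, `ensemble` (an `fc_ensemble`), `targets`.
#' @export
calibrate <- function(rf, targets, priors = default_priors(), n = 300,
                      seed = 1L, quantile_level = 0.05, k = 5,
                      base_params = fc_params(),
                      scn = scenario(tech_rate = 0.05)) {
  draws <- sample_parameters(priors, n, seed)
  dist <- vapply(seq_len(n), function(i) {
    p <- set_params(base_params, draws[i, ])
    sim <- simulate_regional_summaries(p, rf, scn)
    score_parameters(sim, targets)
  }, numeric(1))
  acc <- abc_accept(dist, quantile_level)
  ens <- select_ensemble(draws[acc$index, , drop = FALSE], dist[acc$index],
                         priors, k)
  samples <- draws
  samples$distance <- dist
  structure(list(samples = samples, threshold = acc$threshold,
                 accepted = draws[acc$index, , drop = FALSE],
                 accepted_distance = dist[acc$index],
                 ensemble = ens, targets = targets, priors = priors),
            class = "fc_calibration")
}

#' @export
print.fc_calibration <- function(x, ...) {
  cat(sprintf("<fc_calibration> %d draws, threshold %.3g, %d accepted\n",
              nrow(x$samples), x$threshold, nrow(x$accepted)))
  print(x$ensemble)
  invisible(x)
}

#' Ensemble members as full parameter sets
#' @param calib An `fc_calibration` or `fc_ensemble`.
#' @param base_params Fixed slots.
#' @return List of `fc_params`.
#' @export
ensemble_params <- function(calib, base_params = fc_params()) {
  m <- if (inherits(calib, "fc_calibration")) calib$ensemble$members else calib$members
  lapply(seq_len(nrow(m)), function(i) set_params(base_params, m[i, ]))
}

#' Parameter-recovery validation of the calibration
#'
#' Generates noise-free targets from a known truth, runs the full
#' calibration, and reports for each calibrated parameter whether the truth
#' lies inside the accepted min-max hull, together with the shrinkage of the
#' accepted range relative to the prior range (on the prior scale).
#'
#' @param truth Generating `fc_params`.
#' @param rf A [regional_forcing()].
#' @param priors,n,seed,quantile_level Calibration settings.
#' @return List of class `fc_recovery`: `report` tibble (name, truth,
#'   acc_min, acc_max, within, shrinkage), `n_within`, `calibration`.
#' @export
recovery_test <- function(truth, rf, priors = default_priors(), n = 300,
                          seed = 1L, quantile_level = 0.05) {
  targets <- make_calibration_targets(rf, truth)
  cal <- calibrate(rf, targets, priors, n = n, seed = seed,
                   quantile_level = quantile_level, base_params = truth)
  rep <- lapply(seq_len(nrow(priors)), function(i) {
    nm <- priors$name[i]
    v <- cal$accepted[[nm]]
    tv <- truth[[nm]]
    tr <- function(x) if (priors$scale[i] == "log") log(x) else x
    tibble::tibble(
      name = nm, truth = tv, acc_min = min(v), acc_max = max(v),
      within = tv >= min(v) & tv <= max(v),
      shrinkage = (tr(max(v)) - tr(min(v))) /
        (tr(priors$upper[i]) - tr(priors$lower[i]))
    )
  })
  rep <- dplyr::bind_rows(rep)
  structure(list(report = rep, n_within = sum(rep$within), calibration = cal),
            class = "fc_recovery")
}

#' @export
print.fc_recovery <- function(x, ...) {
  cat(sprintf("<fc_recovery> truth within accepted hull for %d/%d parameters\n",
              x$n_within, nrow(x$report)))
  print(x$report, n = Inf)
  invisible(x)
}
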