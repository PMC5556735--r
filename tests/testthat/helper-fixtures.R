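# Shared fixtures: small, fast configurations used across test files.

# Coarse desk grid for whole-globe tests (115 ocean cells).
coarse_spec <- function(...) {
  defaults <- list(resolution = 20, year_start = 1850, year_end = 2030,
                   seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(forcing_spec, args)
}

# A productive mid-latitude cell: profitable under the reference economics.
rich_cell <- list(T_c = 12, npp = 50)

# Fixed-effort yield at equilibrium for a batch of (T, npp, F) combinations,
# integrating each to steady state at constant fishing mortality. Used as the
# brute-force oracle against the transient catchability ramp.
equilibrium_yield <- function(T_c, npp, F_levels, params, years = 150,
                              E_fix = 1e-5) {
  axis <- mass_axis()
  nfc <- length(F_levels)
  sp <- spinup_pristine(T_c, npp, params, axis)
  B0 <- array(rep(sp$B, each = nfc), c(nfc, dim(sp$B)))
  n_sub <- fishcast:::fc_nsub_cells(params, axis, rep(T_c, nfc))
  # q_year is global per year, so hold q = 1 and encode each pseudo-cell's
  # fishing mortality in its fixed effort
  out <- fishcast:::fc_cpp_run(
    B0, effort = F_levels,
    sst = matrix(T_c, nfc, years), npp = matrix(npp, nfc, years),
    q_year = rep(1, years), price_year = rep(0, years),
    cost_year = rep(0, years),
    params = params, axis = axis, n_sub = n_sub, effort_mode = 1L)
  rowMeans(out$harvest[, (years - 9):years, drop = FALSE])
}
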