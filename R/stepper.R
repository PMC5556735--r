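# Internal bridge to the C++ integrator. Shapes: B (ncell x ngroup x nbin);
# sst/npp (ncell x nyear); q/price/cost per year. effort may be a scalar.
fc_cpp_run <- function(B, effort, sst, npp, q_year, price_year, cost_year,
                       params, axis, n_sub, effort_mode = 0L) {
  stopifnot(length(dim(B)) == 3, nrow(sst) == dim(B)[1],
            length(q_year) == ncol(sst))
  out <- cpp_run_coupled(
    as.numeric(B), as.numeric(effort),
    sst, npp,
    as.numeric(q_year), as.numeric(price_year), as.numeric(cost_year),
    params,
    fc_psi(axis, params), fc_sel(axis, params),
    as.integer(axis$last_bin),
    axis$m, axis$dm,
    as.integer(n_sub), as.integer(effort_mode)
  )
  out$B <- array(out$B, dim(B))
  out
}
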