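# build a noise-free functional series from operational truth
op_series <- function(tau, pKA, system_emax = 30.7, ligand = "test",
                      n_rep = 3, span = 2, step = 0.5,
                      variant = "rebased", ...) {
  pec50 <- pKA + log10(1 + tau)
  x <- 10^seq(-(pec50 + span), -(pec50 - span), by = step)
  y <- operational_response(x, system_emax, tau, pKA, variant = variant)
  conc_response_series(x, matrix(rep(y, n_rep), ncol = n_rep),
                       ligand = ligand, ...)
}

# build a noise-free functional series from Hill truth
hill_series <- function(pEC50, emax_prime, nH = 1, n_rep = 3,
                        span = 2, step = 0.5, ligand = "test", ...) {
  x <- 10^seq(-(pEC50 + span), -(pEC50 - span), by = step)
  y <- hill_response(x, pEC50, emax_prime, nH)
  conc_response_series(x, matrix(rep(y, n_rep), ncol = n_rep),
                       ligand = ligand, ...)
}

# independent brute-force grid search minimizing SSE (oracle for fitters)
grid_oracle <- function(sse_fn, grids) {
  pars <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  sse <- apply(pars, 1, sse_fn)
  i <- which.min(sse)
  list(par = unlist(pars[i, , drop = FALSE]), sse = sse[i])
}
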