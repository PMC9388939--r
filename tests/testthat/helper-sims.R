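# Shared, lazily computed simulation results for the heavier end-to-end
# checks (built once per test run).

.sim_cache <- new.env(parent = emptyenv())

shared_sims <- function() {
  if (!is.null(.sim_cache$res)) return(.sim_cache$res)
  src <- source_model()
  col <- collimation_model()
  ph <- pediatric_phantom()
  pl <- load_fixture_plans(seed = 101)
  cal <- calibrate_cf(src, col,
                      transport_config(n_histories = 4e5, batches = 20,
                                       seed = 7))
  rep_imrt <- simulate_plan(ph, pl$plan_imrt, src, col,
                            transport_config(n_histories = 2e4, batches = 10,
                                             seed = 211), cal)
  rep_3d <- simulate_plan(ph, pl$plan_3dcrt, src, col,
                          transport_config(n_histories = 2e5, batches = 10,
                                           seed = 311), cal)
  .sim_cache$res <- list(src = src, col = col, phantom = ph, plans = pl,
                         cal = cal, imrt = rep_imrt, d3 = rep_3d)
  .sim_cache$res
}

# numerical quadrature of the Klein-Nishina spectrum: mean scattered-energy
# fraction at incident energy E (independent oracle for the sampler)
kn_mean_eps_quadrature <- function(E) {
  a <- E / 0.51099895
  f <- function(eps) {
    ct <- 1 - (1 - eps) / (a * eps)
    s2 <- pmax(0, 1 - ct^2)
    (1 / eps + eps) * (1 - eps * s2 / (1 + eps^2))
  }
  e0 <- 1 / (1 + 2 * a)
  num <- integrate(function(e) e * f(e), e0, 1, rel.tol = 1e-10)$value
  den <- integrate(f, e0, 1, rel.tol = 1e-10)$value
  num / den
}

# batch-based standard error of a per-batch vector's mean
batch_se <- function(x) sd(x) / sqrt(length(x))
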