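# shared helpers for the test suite

# log-uniform random positive rate draws
draw_rates <- function(n, lo = 1e-2, hi = 1e2) {
  matrix(10^stats::runif(4 * n, log10(lo), log10(hi)), ncol = 4,
         dimnames = list(NULL, c("k_in", "k_d", "k_c", "k_out")))
}

rel_err <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-300))

# the noise-free observable of a scenario on its own grid
scenario_curve <- function(sc) {
  observe(simulate_closed_form(sc$params, times = scenario_times(sc)),
          unit = sc$unit, scenario_id = sc$id)
}
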