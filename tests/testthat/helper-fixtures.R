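# shared fixtures, built once per test run (surface fitting is deterministic)
.fx <- new.env(parent = emptyenv())

fx_reference <- function() {
  if (is.null(.fx$ref)) .fx$ref <- make_reference_surfaces(surface_spec())
  .fx$ref
}

fx_grid <- function() {
  if (is.null(.fx$grid)) .fx$grid <- sample_grid(fx_reference())
  .fx$grid
}

fx_surface <- function(state = "doublet") {
  key <- paste0("surf_", state)
  if (is.null(.fx[[key]])) .fx[[key]] <- fit_rkhs(fx_grid(), state)
  .fx[[key]]
}

fx_model <- function(delta = 7.5, environment = "gas") {
  key <- sprintf("model_%g_%s", delta, environment)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- two_state_model(fx_surface("doublet"), fx_surface("quartet"),
                                  delta = delta, environment = environment)
  }
  .fx[[key]]
}

# synthetic rebinding-ensemble records (no dynamics), for kinetics/analysis tests
fake_ensemble <- function(tau, censored, t_sim = 1000, R0 = NULL, theta0 = NULL,
                          d = NULL) {
  n <- length(tau)
  records <- data.frame(
    id = seq_len(n), seed = rep(1, n), stream = seq_len(n),
    R0 = R0 %||% rep(3, n), theta0 = theta0 %||% rep(150, n),
    tau_ps = ifelse(censored, NA_real_, tau), censored = censored,
    phi_at_rebind = ifelse(censored, NA_real_, 0),
    d_at_rebind = if (is.null(d)) ifelse(censored, NA_real_, 0) else d)
  structure(list(records = records,
                 metadata = list(n = n, t_sim_ps = t_sim, seed = 1,
                                 delta = 7.5, environment = "gas",
                                 solvent = "synthetic", temperature = 300,
                                 failures = integer(0))),
            class = "rebinding_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
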