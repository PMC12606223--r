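# Expensive scenario runs shared across test files (computed once per run).
.run_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.run_cache[[name]])) .run_cache[[name]] <- force(expr)
  .run_cache[[name]]
}

forward_run <- function() {
  cached("forward", suppressWarnings(run_scenario("forward")))
}

perturbed_run <- function() {
  cached("forward_perturbed",
         suppressWarnings(run_scenario("forward_perturbed")))
}

toy_run <- function() {
  cached("toy", suppressWarnings(run_scenario("toy")))
}

# 1 s passive swing of the arm (no excitation, no external force)
passive_run <- function() {
  cached("passive", {
    model <- arm_model()
    suppressWarnings(simulate_arm(
      model, function(t, q, qdot) rep(0, 6), duration = 1, dt = 1e-4,
      init = arm_state(c(0.3, 1.2, -0.1), c(1, -2, 1.5))))
  })
}
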