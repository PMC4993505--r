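# Shared (memoized) benchmark studies for the acceptance tests: the slab
# strategy comparison is expensive, so all criteria read from one run.

.study_cache <- new.env(parent = emptyenv())

memo <- function(name, fn) {
  if (is.null(.study_cache[[name]]))
    .study_cache[[name]] <- fn()
  .study_cache[[name]]
}

adapted_study <- function() memo("adapted", function() {
  rec <- suppressWarnings(run_convergence_study(
    "adapted", e_omega = c(2.5e-2, 1.4e-2, 8e-3),
    adapt_opts = list(max_outer = 5L, max_nodes = 3200)))
  list(rec = rec, meshes = attr(rec, "meshes"))
})

tailored_study <- function() memo("tailored", function() {
  suppressWarnings(run_convergence_study(
    "tailored", h0 = c(2e-3, 8e-4, 3e-4, 1.2e-4, 5e-5),
    nx = c(8L, 12L, 18L, 27L, 40L)))
})

uniform_study <- function() memo("uniform", function() {
  suppressWarnings(run_convergence_study(
    "uniform", target_h = c(0.25, 0.15, 0.09, 0.055, 0.033)))
})

ranvier_demo_cached <- function() memo("ranvier", function() {
  suppressWarnings(run_ranvier_demo(duration = 10))
})
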