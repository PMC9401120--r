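# Shared simulated cohorts for the acceptance-style tests. Generated lazily
# and cached so several test files can reuse the same study-scale cohorts.
# Cohort sizes follow the study design (20 control vs 10 immunized at the
# default desk scale); the calibration suites use a reduced scale (8 vs 8
# animals, ~600 clonotypes) since calibration is a property of the test
# machinery, not of the effect size.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(name, make) {
  if (is.null(.cohort_cache[[name]])) .cohort_cache[[name]] <- make()
  .cohort_cache[[name]]
}

day3_cohort <- function() cached_cohort("day3", function()
  generate_cohort(cohort_config(seed = 7)))

day7_cohort <- function() cached_cohort("day7", function()
  generate_cohort(cohort_config(effect = effect_late(), seed = 7)))

null_config <- function(seed) {
  cohort_config(n_control = 8, n_treated = 8,
                n_clonotypes_target = 600, public_pool_size = 60,
                effect = effect_config(n_specific_per_animal = 0L),
                seed = seed)
}

split_cohort <- function(cohort) {
  list(control = cohort$repertoires[cohort$labels == "control"],
       treated = cohort$repertoires[cohort$labels == "immunized"])
}
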