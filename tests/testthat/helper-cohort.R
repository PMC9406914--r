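# small single-group cohorts used across tests
flat_schema <- function(p) feature_schema(data.frame(group = "f", n = p))

make_cohort <- function(p = 20, n_cases = 30, n_controls = 20,
                        n_informative = 4, effect_size = 2, seed = 1,
                        rho = 0.5) {
  generate_cohort(flat_schema(p),
                  cohort_spec(n_cases = n_cases, n_controls = n_controls,
                              n_informative = min(n_informative, p),
                              effect_size = effect_size,
                              within_subject_rho = rho, seed = seed))
}

# standardized train/test pair from a cohort table
std_split <- function(table, test_fraction = 0.25, seed = 1) {
  sp <- stratified_split(table, test_fraction, seed = seed)
  params <- standardize_fit(sp$train)
  list(train = standardize_apply(sp$train, params),
       test = standardize_apply(sp$test, params),
       params = params, test_idx = sp$test_idx)
}

# tiny deterministic feature table
toy_table <- function() {
  feature_table(matrix(c(1, 2, 3, 4, 5, 5, 5, 5), 4, 2,
                       dimnames = list(NULL, c("f1", "f2"))),
                labels = c(1, 1, 0, 0), subject_ids = c("a", "a", "b", "b"))
}
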