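# Shared fixtures: everything is generated in code at test time.

toy_scenario <- function(...) {
  args <- utils::modifyList(
    list(label = "toy", n_features = 40, n_per_class = 10,
         bio_variance = 0.2, tech_variance = 0.04, n_markers = 5),
    list(...)
  )
  do.call(scenario_config, args)
}

# Hand-crafted dataset from explicit matrices (bio defaults to the
# measured values, i.e. no technical noise).
manual_dataset <- function(values, labels, bio = values, pool_size = 1L,
                           scenario = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  bio <- as.matrix(bio)
  colnames(bio) <- colnames(values)
  labels <- factor(labels, levels = c("control", "case"))
  poolsim:::new_omics_dataset(values, bio, labels,
                              marker_indices = integer(0),
                              gamma_values = numeric(0),
                              pool_size = pool_size, scenario = scenario)
}

# Two well-separated Gaussian classes in `d` dimensions.
separated_dataset <- function(n_per_class = 10, d = 2, gap = 6, sd = 0.5) {
  x <- rbind(
    matrix(stats::rnorm(n_per_class * d, 0, sd), n_per_class),
    matrix(stats::rnorm(n_per_class * d, gap, sd), n_per_class)
  )
  manual_dataset(x, rep(c("control", "case"), each = n_per_class))
}
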