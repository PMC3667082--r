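# Shared fixtures: everything is generated in code at test time.

# Small random log2 expression matrix with unique gene/sample ids.
random_expr <- function(n_genes, n_samples, seed = 1, mean = 8, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean, sd), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# Reduced synthetic configuration for cheap end-to-end tests; the full
# default configuration is exercised in test-acceptance.R.
small_config <- function(seed = 1, ...) {
  args <- list(n_genes = 800, n_normal = 6,
               samples_per_subtype = c(mesenchymal = 10, classical = 10,
                                       neural = 10, proneural = 10),
               samples_per_inducer = 3, n_inducer_controls = 4,
               markers_per_subtype = 40, core_signature_size = 60,
               inducer_private_markers = 10, pair_private_markers = 30,
               seed = seed)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

# Independent brute-force two-sided hypergeometric p-value: probabilities
# from log binomial coefficients (lchoose), naive point-probability sum.
enum_two_sided_p <- function(a, n_a, n_b, N) {
  k <- max(0, n_a + n_b - N):min(n_a, n_b)
  pk <- exp(lchoose(n_a, k) + lchoose(N - n_a, n_b - k) - lchoose(N, n_b))
  pa <- pk[match(a, k)]
  min(1, sum(pk[pk <= pa * (1 + 1e-7)]))
}
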