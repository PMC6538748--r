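# Shared fixtures, all built in code.

test_centroids <- function(seed = 42L) make_centroids(50L, seed = seed)

# a small concordant cohort (no ER discordance) used by several files
test_cohort <- function(n = 120L, seed = 42L, rate = 0, noise = 0.3,
                        centroids = test_centroids()) {
  simulate_cohort(centroids, sim_config(n_samples = n, noise_sd = noise,
                                        er_discordance_rate = rate,
                                        seed = seed))
}

# write a genes x samples matrix to a temp TSV and return the path
tmp_expr_tsv <- function(m, digits = 15L) {
  p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write_expression(m, p, digits = digits)
  p
}

tmp_tsv <- function(df) {
  p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write_tsv15(df, p)
  p
}

# 40-gene pair of anti-correlated centroid-like profiles for classify() toys
toy_panel <- function() {
  g <- paste0("g", sprintf("%02d", 1:40))
  a <- seq(-2, 2, length.out = 40)
  cbind_named <- function(...) {
    m <- cbind(...)
    rownames(m) <- g
    m
  }
  cbind_named(Basal = rev(a), Her2 = a[c(21:40, 1:20)],
              LumA = a, LumB = a + 0.2 * sin(seq_len(40)),
              Normal = a[c(40:21, 20:1)])
}
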