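# shared fixtures, memoized so expensive objects are built once per run

.fx <- new.env(parent = emptyenv())

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

random_aa_seq <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# a scaled-down synthetic world for module tests (the acceptance suite uses
# the full default sizes)
small_synth_config <- function(seed = 42L, ...) {
  args <- list(n_proteins = 60L, n_domains = 80L,
               n_positive_pairs = 40L, n_negative_pairs = 40L,
               n_positive_ddi = 120L, n_negative_ddi = 120L,
               seq_len_range = c(30L, 80L), seed = seed)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

fixture_small <- function() {
  if (is.null(.fx$small)) {
    ds <- generate_dataset(small_synth_config())
    pt <- profile_table(ds$sequences)
    fm <- domain_feature_matrix(pt, ds$locations)
    raw <- build_pair_vectors(fm, ds$ddi_pairs, params = NULL)
    nz <- suppressWarnings(fit_normalizer(fm))
    pv <- build_pair_vectors(fm, ds$ddi_pairs, nz)
    model <- ddi_train(pv$vectors, pv$labels)
    .fx$small <- list(ds = ds, pt = pt, fm = fm, raw = raw, nz = nz,
                      pv = pv, model = model,
                      table = score_table(ds$scores))
  }
  .fx$small
}

# two well-separated Gaussian blobs in d dimensions, labels 0/1
blob_data <- function(n_per_class = 50L, d = 2L, sep = 4) {
  x0 <- matrix(stats::rnorm(n_per_class * d), ncol = d)
  x1 <- matrix(stats::rnorm(n_per_class * d) + sep, ncol = d)
  list(x = rbind(x0, x1),
       y = rep(c(0L, 1L), each = n_per_class))
}

# round half-up to 2 decimals, as printed tables do
round2 <- function(x) floor(x * 100 + 0.5) / 100
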