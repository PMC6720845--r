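test_that("score tables apply the 20th-percentile background rule", {
  sc <- data.frame(id_a = sprintf("d%02d", 1:10),
                   id_b = sprintf("e%02d", 1:10),
                   lambda = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 50))
  tab <- score_table(sc)
  expect_equal(tab$s_max, 50)
  expect_equal(tab$background_score, sort(sc$lambda)[ceiling(0.2 * 10)])
  expect_equal(tab$interaction_cutoff, 1.5)
  # explicit override (the published value for its own data)
  expect_equal(score_table(sc, background_score = 1.74)$background_score, 1.74)
  # orientation-insensitive lookup, background fallback for missing pairs
  expect_equal(lookup_score(tab, "d01", "e01"), 2)
  expect_equal(lookup_score(tab, "e01", "d01"), 2)
  expect_equal(lookup_score(tab, "zz", "d01"), tab$background_score)
  expect_error(score_table(rbind(sc, sc[1, ])), "duplicate")
  expect_error(score_table(transform(sc, lambda = -lambda)), "positive")
})

test_that("domain-pair enumeration is the full cross product", {
  p1 <- protein_record("P1", "dA")
  p2 <- protein_record("P2", c("dB", "dC", "dD"))
  expect_equal(enumerate_domain_pairs(p1, p1)$num_ddi, 1L)
  e <- enumerate_domain_pairs(protein_record("P3", c("dA", "dB")), p2)
  expect_equal(e$num_ddi, 6L)
  expect_equal(nrow(e$pairs), e$num_ddi)
  # duplicate domains in an architecture are kept
  e2 <- enumerate_domain_pairs(protein_record("P4", c("dA", "dA")), p1)
  expect_equal(e2$num_ddi, 2L)
  expect_error(protein_record("P5", character(0)), "empty")
})

test_that("score normalization is the clamped log ratio", {
  s_max <- 7.3
  expect_equal(normalize_score(s_max, s_max), 1)
  expect_equal(normalize_score(1, s_max), 0)
  expect_equal(normalize_score(sqrt(s_max), s_max), 0.5, tolerance = 1e-12)
  expect_equal(normalize_score(0.2, s_max), 0)   # below 1 clamps to 0
  # monotone on [1, s_max]
  lam <- seq(1, s_max, length.out = 50)
  expect_true(all(diff(normalize_score(lam, s_max)) > 0))
  expect_error(normalize_score(-1, s_max), "positive")
  expect_error(normalize_score(2, 0.9), "s_max")
})

test_that("protein-pair d-score equals brute force over enumerated pairs", {
  sc <- data.frame(id_a = c("x1", "x1", "x2"), id_b = c("y1", "y2", "y1"),
                   lambda = c(40, 5, 2))
  tab <- score_table(sc)
  # single-domain proteins with stored lambda = s_max -> exactly 1
  expect_equal(protein_pair_dscore(protein_record("A", "x1"),
                                   protein_record("B", "y1"), tab), 1)
  # unscored pair falls back to the background score
  expect_equal(protein_pair_dscore(protein_record("A", "x9"),
                                   protein_record("B", "y9"), tab),
               normalize_score(tab$background_score, tab$s_max))
  # exhaustive-enumeration oracle on random architectures
  set.seed(40)
  doms <- c("x1", "x2", "y1", "y2", "z1")
  for (i in 1:30) {
    pa <- protein_record("A", sample(doms, sample(1:4, 1), replace = TRUE))
    pb <- protein_record("B", sample(doms, sample(1:4, 1), replace = TRUE))
    brute <- max(vapply(seq_along(pa$domain_ids), function(u)
      max(vapply(seq_along(pb$domain_ids), function(v)
        normalize_score(lookup_score(tab, pa$domain_ids[u], pb$domain_ids[v]),
                        tab$s_max), numeric(1))), numeric(1)))
    expect_equal(protein_pair_dscore(pa, pb, tab), brute)
    # mean aggregation equals the brute-force mean too
    lam <- lookup_score(tab,
                        rep(pa$domain_ids, times = length(pb$domain_ids)),
                        rep(pb$domain_ids, each = length(pa$domain_ids)))
    expect_equal(protein_pair_dscore(pa, pb, tab, aggregate = "mean"),
                 mean(normalize_score(lam, tab$s_max)))
  }
})

test_that("predicted ratio is the classifier count over the cross product", {
  fx <- fixture_small()
  ids <- names(fx$ds$proteins)
  set.seed(41)
  for (i in 1:10) {
    pa <- fx$ds$proteins[[sample(ids, 1)]]
    pb <- fx$ds$proteins[[sample(ids, 1)]]
    ep <- enumerate_domain_pairs(pa, pb)
    pv <- build_pair_vectors(fx$fm, ep$pairs, fx$nz)
    manual <- sum(predict_pairs(fx$model, pv$vectors)) / ep$num_ddi
    got <- predicted_ratio(pa, pb, fx$model, fx$fm, fx$nz)
    expect_equal(got, manual)
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("fusion is the exact linear blend", {
  expect_equal(fuse_scores(1, 1, 0.5, 0.5), 1)
  expect_equal(fuse_scores(0.3, 0.8, 1, 0), 0.3)
  expect_equal(fuse_scores(0.4, 0.8, 0.5, 0.5), 0.6)
  expect_error(fuse_scores(0.5, 0.5, -0.1, 0.5))
  # default weights keep the blend inside [0, 1] and monotone in both inputs
  set.seed(42)
  d <- runif(100); p <- runif(100)
  f <- fuse_scores(d, p)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(fuse_scores(pmin(d + 0.1, 1), p) >= f))
})

test_that("lattice search covers 49 points and honors its tie-breaks", {
  set.seed(43)
  labels <- rep(0:1, each = 60)
  # d alone separates the classes; p is pure noise
  d <- c(runif(60, 0, 0.2), runif(60, 0.5, 1))
  p <- runif(120)
  ls <- lattice_search(d, p, labels)
  expect_equal(nrow(ls$diagnostics), 49L)
  expect_gt(ls$a_weight, 0)
  expect_equal(max(ls$diagnostics$accuracy), 100)
  # scaling both weights leaves the score ranking unchanged
  r1 <- rank(fuse_scores(d, p, 0.1, 0.2))
  r2 <- rank(fuse_scores(d, p, 0.3, 0.6))
  expect_equal(r1, r2)
})

test_that("threshold selection balances fn and fp over the stated grid", {
  # degenerate perfect scores: every threshold is perfect -> smallest grid
  # threshold survives the tie-breaks
  labels <- rep(0:1, each = 20)
  sel <- select_threshold(as.numeric(labels), labels)
  expect_equal(sel$threshold, 0.10)
  expect_equal(nrow(sel$table), 10L)
  expect_equal(sel$table$threshold, seq(0.10, 0.55, by = 0.05))
  expect_equal(nrow(sel$refined), 3L)
  expect_equal(diff(sel$refined$threshold), c(0.01, 0.01), tolerance = 1e-9)

  # constructed set where 0.30 uniquely zeroes |fn - fp|
  scores <- c(0.31, 0.32, 0.33, 0.34, 0.20, 0.05, 0.10, 0.15, 0.26, 0.45)
  labs <- c(rep(1L, 5), rep(0L, 5))
  sel2 <- select_threshold(scores, labs)
  expect_equal(sel2$threshold, 0.30)
  # the per-threshold table rows reproduce compute_metrics on their counts
  for (k in c(1L, 5L, 10L)) {
    row <- sel2$table[k, ]
    m <- suppressWarnings(
      compute_metrics(confusion_counts(row$tp, row$tn, row$fp, row$fn)))
    expect_equal(row$acc, m$acc)
    expect_equal(row$fn_rate, m$fn_rate)
  }
  expect_error(select_threshold(scores, rep(1L, 10)), "both classes")
})

test_that("threshold selection matches exhaustive enumeration", {
  # independent re-implementation of the selection rule, brute force
  brute_pick <- function(scores, labels, cands) {
    key <- t(vapply(cands, function(thr) {
      pred <- as.integer(scores >= thr)
      fn <- sum(pred == 0 & labels == 1) / sum(labels == 1)
      fp <- sum(pred == 1 & labels == 0) / sum(labels == 0)
      c(abs(fn - fp), fn + fp)
    }, numeric(2)))
    cands[order(key[, 1], key[, 2])[1]]
  }
  set.seed(44)
  grid <- seq(0.10, 0.55, by = 0.05)
  for (i in 1:100) {
    n <- sample(c(20, 51, 100), 1)
    labels <- rbinom(n, 1, runif(1, 0.3, 0.7))
    if (length(unique(labels)) < 2) labels[1:2] <- 0:1
    scores <- round(runif(n), 2)
    sel <- select_threshold(scores, labels, grid)
    coarse <- brute_pick(scores, labels, grid)
    refined <- brute_pick(scores, labels,
                          c(coarse, coarse - 0.01, coarse + 0.01))
    expect_equal(sel$threshold, refined)
  }
})

test_that("end-to-end scoring labels by threshold and keeps provenance", {
  fx <- fixture_small()
  pairs <- fx$ds$ppi_pairs
  cfg0 <- fusion_config(chosen_threshold = 0)
  res0 <- predict_ppi(pairs, fx$ds$proteins, fx$model, fx$fm, fx$nz,
                      fx$table, cfg0)
  expect_true(all(res0$predicted_label == 1L))
  cfg2 <- fusion_config(chosen_threshold = 1.01)
  res2 <- predict_ppi(pairs[1:10, ], fx$ds$proteins, fx$model, fx$fm, fx$nz,
                      fx$table, cfg2)
  expect_true(all(res2$predicted_label == 0L))
  expect_true(all(c("d_mn", "p_ij", "p_mn", "label") %in% names(res0)))
  expect_equal(res0$p_mn, fuse_scores(res0$d_mn, res0$p_ij), tolerance = 1e-12)

  # monotonicity: raising a stored lambda (within s_max) never lowers p_mn
  sc <- fx$ds$scores
  stored <- which(sc$lambda < fx$table$s_max / 2)[1:5]
  sc$lambda[stored] <- sc$lambda[stored] * 1.8
  res_up <- predict_ppi(pairs, fx$ds$proteins, fx$model, fx$fm, fx$nz,
                        score_table(sc), cfg0)
  expect_true(all(res_up$p_mn >= res0$p_mn - 1e-12))
})
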