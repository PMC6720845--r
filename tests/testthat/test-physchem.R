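test_that("residue and charge counting follow the counting conventions", {
  r <- count_residues("ACDEFGHIKLMNPQRSTVWY")
  expect_equal(r$n_residues, 20L)
  expect_true(all(r$counts == 1L))
  expect_equal(count_residues("AAAA")$counts[["A"]], 4L)
  expect_equal(sum(count_residues("MKWV")$counts), 4L)

  # His is in neither charge tally
  cases <- list(DDEE = c(4, 0), RKRK = c(0, 4), DRHA = c(1, 1))
  for (s in names(cases))
    expect_equal(unname(charged_counts(s)), cases[[s]], info = s)
})

test_that("sequence validation names the offending position", {
  expect_error(domain_sequence("d1", "ACDX"), "position 4")
  expect_error(domain_sequence("d1", "ABC"), "position 2")  # B is ambiguous
  expect_error(domain_sequence("d1", ""), "empty")
  expect_error(domain_sequence("", "ACD"), "domain_id")
  # lowercase is normalized, not rejected
  expect_equal(domain_sequence("d1", "acd")$sequence, "ACD")
})

test_that("theoretical pI is the root of the net-charge function", {
  set.seed(1)
  for (i in 1:100) {
    s <- random_aa_seq(sample(5:60, 1))
    expect_lt(abs(net_charge(s, theoretical_pi(s))), 0.01)
  }
  expect_lt(theoretical_pi("DDDD"), 7)
  expect_gt(theoretical_pi("KKKK"), 7)
})

test_that("pI matches an independent grid-scan of the charge equation", {
  # independent transcription: Henderson-Hasselbalch with the Bjellqvist
  # constants written out literally, scanned on a 1e-4 pH grid
  grid_pi <- function(seq) {
    cnt <- table(factor(strsplit(seq, "")[[1]], levels = AA20))
    ph <- seq(0, 14, by = 1e-4)
    pos <- 1 / (1 + 10^(ph - 7.5)) +                      # N-terminus
      cnt[["K"]] / (1 + 10^(ph - 10.0)) +
      cnt[["R"]] / (1 + 10^(ph - 12.0)) +
      cnt[["H"]] / (1 + 10^(ph - 5.98))
    neg <- 1 / (1 + 10^(3.55 - ph)) +                     # C-terminus
      cnt[["D"]] / (1 + 10^(4.05 - ph)) +
      cnt[["E"]] / (1 + 10^(4.45 - ph)) +
      cnt[["C"]] / (1 + 10^(9.0 - ph)) +
      cnt[["Y"]] / (1 + 10^(10.0 - ph))
    ph[which.min(abs(pos - neg))]
  }
  set.seed(2)
  seqs <- c("KKKK", "MKWV", replicate(10, random_aa_seq(sample(5:40, 1))))
  for (s in seqs)
    expect_equal(theoretical_pi(s), grid_pi(s), tolerance = 2e-3, info = s)
})

test_that("extinction coefficients follow the Gill-von Hippel terms", {
  expect_equal(unname(extinction_coefficients("W")), c(5500, 5500))
  expect_equal(unname(extinction_coefficients("Y")), c(1490, 1490))
  expect_equal(unname(extinction_coefficients("A")), c(0, 0))
  # cystine term: floor(#Cys / 2) pairs at 125 each, only in ext1
  expect_equal(unname(extinction_coefficients("C")), c(0, 0))
  expect_equal(unname(extinction_coefficients("CC")), c(125, 0))
  expect_equal(unname(extinction_coefficients("CCC")), c(125, 0))
  expect_equal(unname(extinction_coefficients("WYCC")), c(5500 + 1490 + 125,
                                                          5500 + 1490))
})

test_that("instability index is the dipeptide weight sum", {
  w <- diwv_table()
  # a single dipeptide collapses the formula to 5 * DIWV[x, y]
  for (dp in c("MK", "WV", "AC"))
    expect_equal(instability_index(dp),
                 5 * w[substr(dp, 1, 1), substr(dp, 2, 2)], info = dp)
  # hand-sum oracle: 10/4 * (DIWV[M,K] + DIWV[K,W] + DIWV[W,V])
  expect_equal(instability_index("MKWV"), 2.5 * (1.0 + 1.0 - 7.49))
  expect_equal(instability_index("MKWV"), -13.725)
  # constant-weight case: every AA dipeptide has weight 1.0
  L <- 7
  expect_equal(instability_index(strrep("A", L)), 10 * (L - 1) / L)
  expect_error(instability_index("M"), "at least 2")
})

test_that("aliphatic index and GRAVY match their defining formulas", {
  expect_equal(aliphatic_index("AAAA"), 100)
  expect_equal(aliphatic_index("VVVV"), 290)
  expect_equal(aliphatic_index("GGGG"), 0)
  expect_equal(gravy("AAAA"), 1.8)
  expect_equal(gravy("RRRR"), -4.5)
  # hand-sum oracle on a mixed sequence
  set.seed(3)
  s <- random_aa_seq(40)
  kd <- kyte_doolittle()
  expect_equal(gravy(s), sum(kd[strsplit(s, "")[[1]]]) / 40)
  expect_true(all(replicate(50, {
    g <- gravy(random_aa_seq(sample(2:50, 1)))
    g >= -4.5 && g <= 4.5
  })))
})

test_that("atom count and molecular weight obey the condensation laws", {
  expect_equal(atom_count("G"), 10)          # free glycine C2H5NO2
  expect_equal(atom_count("GG"), 17)         # one water removed
  expect_equal(molecular_weight("G"), 75.07, tolerance = 0.01 / 75.07)
  set.seed(4)
  for (i in 1:25) {
    s1 <- random_aa_seq(sample(2:40, 1))
    s2 <- random_aa_seq(sample(2:40, 1))
    expect_equal(atom_count(paste0(s1, s2)),
                 atom_count(s1) + atom_count(s2) - 3)
    expect_equal(molecular_weight(paste0(s1, s2)),
                 molecular_weight(s1) + molecular_weight(s2) - WATER_MASS,
                 tolerance = 1e-6 / 100)
  }
})

test_that("profiles are deterministic and satisfy the type invariants", {
  p <- compute_profile("AAAA")
  expect_equal(p$n_residues, 4)
  expect_equal(p$aliphatic_index, 100)
  expect_equal(p$gravy, 1.8)
  expect_equal(p$n_negative, 0)
  expect_equal(p$n_positive, 0)
  expect_equal(p$ext_coefficient_2, 0)
  expect_identical(compute_profile("MKWVAC"), compute_profile("MKWVAC"))
  expect_error(compute_profile("A"), "length >= 2")

  set.seed(5)
  for (i in 1:200) {
    pr <- compute_profile(random_aa_seq(sample(2:80, 1)))
    expect_lte(pr$n_negative + pr$n_positive, pr$n_residues)
    expect_gt(pr$theoretical_pi, 0); expect_lt(pr$theoretical_pi, 14)
    expect_gte(pr$ext_coefficient_1, pr$ext_coefficient_2)
    expect_gte(pr$ext_coefficient_2, 0)
    expect_equal(sum(pr$aa_composition), 100, tolerance = 1e-11)
    expect_gte(pr$aliphatic_index, 0)
    expect_gt(pr$n_atoms, pr$n_residues)
    expect_true(pr$gravy >= -4.5 && pr$gravy <= 4.5)
  }
})

test_that("shipped constant tables are complete and match published values", {
  kd <- kyte_doolittle()
  expect_length(kd, 20)
  expect_equal(kd[c("A", "R", "I", "W", "G")],
               c(A = 1.8, R = -4.5, I = 4.5, W = -0.9, G = -0.4))
  w <- diwv_table()
  expect_equal(dim(w), c(20, 20))
  expect_equal(w["A", "A"], 1.0)
  expect_equal(w["A", "C"], 44.94)
  expect_equal(w["W", "V"], -7.49)
  expect_equal(w["G", "G"], 13.34)
  expect_equal(w["C", "W"], 24.68)
  pka <- pka_set()
  expect_setequal(pka$group, c("Nterm", "Cterm", "D", "E", "C", "Y", "H",
                               "K", "R"))
  expect_equal(pka$pka[match(c("Nterm", "Cterm", "K", "D", "H"), pka$group)],
               c(7.5, 3.55, 10.0, 4.05, 5.98))
  expect_equal(molecular_weight("W"), 204.2252, tolerance = 1e-6)
  expect_equal(atom_count("W"), 27)
})
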