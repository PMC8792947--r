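PAR <- energy_params()

test_that("a perfect 4-bp helix scores the sum of its three stacks", {
  # ACGU vs ACGU pairs A.U, C.G, G.C, U.A antiparallel; under the default
  # table stack(AU,CG) + stack(CG,GC) + stack(GC,UA) = -2.2 - 2.4 - 2.2
  r <- duplex_energy("ACGU", "ACGU", PAR)
  expect_equal(r$dg_hybrid, -6.8)
  expect_equal(nrow(r$pairing), 4L)
  # antiparallel-monotone pairing
  expect_true(all(diff(r$pairing[, 1]) > 0))
  expect_true(all(diff(r$pairing[, 2]) < 0))
})

test_that("unpairable sequences give the +Inf sentinel", {
  r <- duplex_energy("AAAA", "AAAA", PAR)
  expect_equal(r$dg_hybrid, Inf)
  expect_equal(nrow(r$pairing), 0L)
  expect_equal(fold_mfe("AAAAAAA", integer(0), PAR)$structure, ".......")
  expect_equal(fold_mfe("AAAAAAA", integer(0), PAR)$energy, 0)
})

test_that("duplex DP equals exhaustive chain enumeration", {
  set.seed(31)
  for (r in 1:40) {
    m <- random_rna(sample(3:9, 1))
    t <- random_rna(sample(3:12, 1))
    expect_equal(duplex_energy(m, t, PAR)$dg_hybrid, oracle_duplex(m, t, PAR),
                 tolerance = 1e-6, label = paste(m, t))
  }
})

test_that("fold DP equals exhaustive structure enumeration", {
  expect_equal(fold_mfe("GGGAAAACCC", integer(0), PAR)$energy,
               oracle_fold_mfe("GGGAAAACCC", integer(0), PAR))
  expect_equal(fold_mfe("GGGAAAACCC", 0:2, PAR)$energy, 0)
  set.seed(32)
  for (r in 1:15) {
    s <- random_rna(sample(8:16, 1), gc = runif(1, 0.3, 0.7))
    expect_equal(fold_mfe(s, integer(0), PAR)$energy,
                 oracle_fold_mfe(s, integer(0), PAR),
                 tolerance = 1e-6, label = s)
    fu <- sample(0:(nchar(s) - 1), 2)
    expect_equal(fold_mfe(s, fu, PAR)$energy, oracle_fold_mfe(s, fu, PAR),
                 tolerance = 1e-6, label = paste(s, "constrained"))
  }
})

test_that("traceback structures are valid and score to the DP energy", {
  set.seed(33)
  for (r in 1:20) {
    s <- random_rna(sample(10:40, 1), gc = 0.6)
    f <- fold_mfe(s, integer(0), PAR)
    pairs <- db_to_pairs(f$structure)
    if (nrow(pairs)) {
      # hairpin minimum and allowed pairs
      expect_true(all(pairs[, 2] - pairs[, 1] - 1 >= PAR$min_hairpin))
      ch <- strsplit(s, "")[[1]]
      pn <- vapply(seq_len(nrow(pairs)), function(q)
        oracle_pair_name(ch[pairs[q, 1]], ch[pairs[q, 2]]), "")
      expect_false(anyNA(pn))
    }
    expect_equal(oracle_score(strsplit(s, "")[[1]], pairs, PAR), f$energy,
                 tolerance = 1e-6, label = s)
  }
})

test_that("forcing positions unpaired never lowers the fold energy", {
  set.seed(34)
  for (r in 1:25) {
    s <- random_rna(sample(15:60, 1), gc = 0.6)
    e0 <- fold_mfe(s, integer(0), PAR)$energy
    fu <- sort(sample(0:(nchar(s) - 1), sample(1:5, 1)))
    e1 <- fold_mfe(s, fu, PAR)$energy
    expect_gte(e1, e0 - 1e-9)
    expect_lte(e1, 0)
    # adding one more constraint on top
    extra <- sample(setdiff(0:(nchar(s) - 1), fu), 1)
    e2 <- fold_mfe(s, c(fu, extra), PAR)$energy
    expect_gte(e2, e1 - 1e-9)
  }
})

test_that("opening energy is nonnegative, zero for open sites", {
  expect_equal(opening_energy(strrep("A", 60), 10, 18, flank = 100, PAR), 0)
  # site covering the whole UTR with no flank: constrained fold is empty
  s <- "GGGAAAACCC"
  expect_equal(opening_energy(s, 0, nchar(s), flank = 0, params = PAR),
               -fold_mfe(s, integer(0), PAR)$energy)
  # burying the site in the only hairpin costs that hairpin's stability
  set.seed(35)
  for (r in 1:10) {
    s <- random_rna(sample(20:80, 1), gc = runif(1, 0.3, 0.7))
    st <- sample(0:(nchar(s) - 8), 1)
    dg <- opening_energy(s, st, st + 8, flank = 100, params = PAR)
    expect_gte(dg, 0)
  }
})

test_that("opening energy matches the enumeration oracle on small windows", {
  set.seed(36)
  for (r in 1:8) {
    s <- random_rna(sample(14:18, 1), gc = 0.65)
    st <- sample(0:(nchar(s) - 5), 1)
    got <- opening_energy(s, st, st + 5, flank = 100, params = PAR)
    want <- oracle_fold_mfe(s, st:(st + 4), PAR) - oracle_fold_mfe(s, integer(0), PAR)
    expect_equal(got, want, tolerance = 1e-6, label = s)
  }
})

test_that("dg_total adds hybridization and opening energies", {
  # fully accessible site: dg_total equals dg_hybrid
  utr <- paste0(strrep("A", 40), "CUACCUCA", strrep("A", 40))
  r <- delta_g_total(utr, 40, 48, "UGAGGUAGUAGGUUGUAUAGUU", PAR)
  expect_equal(r$dg_open, 0)
  expect_equal(r$dg_total, r$dg_hybrid)
  expect_lt(r$dg_hybrid, 0)

  # the same site inside a hairpin stem is strictly less accessible
  site <- "CUACCUCA"
  arm <- m6Amir:::rna_revcomp(site)
  hairpin_utr <- paste0(strrep("A", 30), site, "AAAA", arm, strrep("A", 30))
  r2 <- delta_g_total(hairpin_utr, 30, 38, "UGAGGUAGUAGGUUGUAUAGUU", PAR)
  expect_gt(r2$dg_open, 0)
  expect_equal(r2$dg_hybrid, r$dg_hybrid)
  expect_gt(r2$dg_total, r$dg_total)

  # unpairable duplex window propagates the sentinel
  r3 <- delta_g_total(strrep("A", 60), 20, 28, "AAAAAAAA", PAR)
  expect_equal(r3$dg_total, Inf)
})
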