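LET7A <- "UGAGGUAGUAGGUUGUAUAGUU"

test_that("seed patterns are the reverse complements of the seed region", {
  p <- seed_site_patterns(LET7A)
  expect_equal(unname(p["SIX_MER"]), "UACCUC")
  expect_equal(unname(p["SEVEN_MER_A1"]), "UACCUCA")
  expect_equal(unname(p["SEVEN_MER_M8"]), "CUACCUC")
  expect_equal(unname(p["EIGHT_MER"]), "CUACCUCA")
  # all-A seed region complements to runs of U
  q <- seed_site_patterns("UAAAAAAAGG")
  expect_equal(unname(q["SIX_MER"]), "UUUUUU")
  expect_equal(unname(q["EIGHT_MER"]), "UUUUUUUA")
  expect_error(seed_site_patterns("UGAGGUA"), "at least 8")
})

test_that("seed sites are found with longest-match suppression", {
  d <- find_seed_sites("GGGCUACCUCAGGG", LET7A)
  expect_equal(nrow(d), 1L)
  expect_equal(d$site_type, "EIGHT_MER")
  expect_equal(c(d$start, d$end), c(3L, 11L))
  expect_equal(nrow(find_seed_sites("GGGGGGG", LET7A)), 0L)
  # tandem site arrangement: leading 6mer plus an 8mer that swallows the
  # nested 7mers
  d2 <- find_seed_sites("UACCUCUACCUCA", LET7A)
  expect_equal(d2$site_type, c("SIX_MER", "EIGHT_MER"))
  expect_equal(d2$start, c(0L, 5L))
  expect_equal(d2$end, c(6L, 13L))
})

test_that("seed finder agrees exactly with the substring-scan oracle", {
  set.seed(101)
  for (r in 1:80) {
    utr <- random_rna(sample(50:400, 1), gc = runif(1, 0.3, 0.7))
    got <- find_seed_sites(utr, LET7A)
    want <- oracle_find_sites(utr, LET7A)
    expect_equal(got[c("start", "end", "site_type")],
                 want[c("start", "end", "site_type")],
                 ignore_attr = TRUE)
  }
})

test_that("cohort-scale finder matches the per-UTR finder", {
  set.seed(7)
  tx <- data.frame(
    transcript_id = sprintf("t%02d", 1:40),
    utr3_seq = vapply(1:40, function(i) random_rna(sample(60:500, 1)), ""),
    species_tag = "s", stringsAsFactors = FALSE)
  mir <- list(mirna_id = "let-7a", seq = LET7A)
  all <- m6Amir:::find_seed_sites_cohort(tx, mir)
  for (i in seq_len(nrow(tx))) {
    one <- find_seed_sites(tx$utr3_seq[i], LET7A, tx$transcript_id[i], "let-7a")
    sub <- all[all$transcript_id == tx$transcript_id[i], , drop = FALSE]
    rownames(sub) <- NULL
    expect_equal(sub[c("start", "end", "site_type")],
                 one[c("start", "end", "site_type")], ignore_attr = TRUE)
  }
})

test_that("representative site prefers 8mers, then stronger hybridization", {
  s <- function(type, dg, start) {
    data.frame(transcript_id = "t", mirna_id = "m", start = start,
               end = start + SEED_WIDTHS_FOR_TEST[type], site_type = type,
               dg_hybrid = dg, dg_open = NA_real_, dg_total = NA_real_,
               m6a_status = "UNSET", cons_score = NA_real_,
               stringsAsFactors = FALSE)
  }
  SEED_WIDTHS_FOR_TEST <- c(SIX_MER = 6L, SEVEN_MER_A1 = 7L,
                            SEVEN_MER_M8 = 7L, EIGHT_MER = 8L)
  # 8mer wins even with weaker hybridization than the 7mer
  r <- representative_site(rbind(s("SEVEN_MER_A1", -9.1, 10),
                                 s("EIGHT_MER", -7.0, 50)))
  expect_equal(r$site_type, "EIGHT_MER")
  # among equal widths the stronger (more negative) energy wins
  r2 <- representative_site(rbind(s("EIGHT_MER", -10.2, 90),
                                  s("EIGHT_MER", -8.0, 10)))
  expect_equal(r2$start, 90L)
  # energy ties break to the smaller start
  r3 <- representative_site(rbind(s("SEVEN_MER_M8", -5, 80),
                                  s("SEVEN_MER_A1", -5, 20)))
  expect_equal(r3$start, 20L)
  r4 <- representative_site(s("SIX_MER", -3, 4))
  expect_equal(r4$site_type, "SIX_MER")
  expect_error(representative_site(s("SIX_MER", -3, 4)[0, ]), "empty")
})

test_that("target classification follows the strongest site class", {
  d <- find_seed_sites("GGGCUACCUCGGG", LET7A)   # 7mer-m8 only
  expect_equal(classify_target(d), "SEED_78")
  d6 <- find_seed_sites("GGUACCUCGGG", LET7A)    # 6mer only
  expect_equal(classify_target(d6), "SIXMER_ONLY")
  expect_equal(classify_target(d6[0, ]), "NONE")
})

test_that("chimera fragments yield seed or best-window seedless sites", {
  chim <- list(mirna_id = "let-7a", mirna_seq = LET7A, transcript_id = "t1",
               frag_start = 100L, frag_end = 118L,
               frag_seq = "GGGCUACCUCAGGGAAAA")
  site <- find_chimera_site(chim)
  expect_equal(site$site_type, "EIGHT_MER")
  expect_equal(c(site$start, site$end), c(103L, 111L))  # UTR coordinates

  # poly-A fragment vs poly-A miRNA cannot pair at all -> no site
  chim2 <- list(mirna_id = "pA", mirna_seq = "AAAAAAAA", transcript_id = "t1",
                frag_start = 0L, frag_end = 15L, frag_seq = strrep("A", 15))
  expect_null(find_chimera_site(chim2))

  # seedless: perfect 10-nt complement to the miRNA 3' region, no seed match
  rc10 <- m6Amir:::rna_revcomp(substr(LET7A, 13, 22))
  frag <- paste0("AAAAA", rc10, "AAAAA")
  chim3 <- list(mirna_id = "let-7a", mirna_seq = LET7A, transcript_id = "t1",
                frag_start = 50L, frag_end = 50L + nchar(frag),
                frag_seq = frag)
  site3 <- find_chimera_site(chim3)
  expect_equal(site3$site_type, "SEEDLESS")
  # the chosen window must be the energy argmin over all 10-nt windows
  dgs <- vapply(0:(nchar(frag) - 10), function(s)
    duplex_energy(LET7A, substr(frag, s + 1, s + 10))$dg_hybrid, 0)
  expect_equal(site3$start - 50L, which.min(dgs) - 1L)
  expect_equal(site3$dg_hybrid, min(dgs))
})
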