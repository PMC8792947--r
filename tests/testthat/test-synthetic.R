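test_that("cohort generation is deterministic and writes byte-identical files", {
  cfg <- synth_config(n_transcripts = 60, n_chimeras = 30, rng_seed = 5)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$transcripts, co2$transcripts)
  expect_identical(co1$expression, co2$expression)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(co1, d1)
  write_cohort(co2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("planted sites are recovered exactly at their planted coordinates", {
  co <- generate_cohort(synth_config(n_transcripts = 300, rng_seed = 8))
  sites <- m6Amir:::find_seed_sites_cohort(co$transcripts, as.list(co$mirna[1, ]))
  truth <- co$truth$sites
  key <- function(d, s, e, ty) paste(d, s, e, ty)
  found <- key(sites$transcript_id, sites$start, sites$end, sites$site_type)
  planted <- key(truth$transcript_id, truth$site_start, truth$site_end,
                 truth$site_type)
  expect_true(all(planted %in% found))
})

test_that("generator truth agrees with the classification modules", {
  co <- generate_cohort(synth_config(n_transcripts = 250, rng_seed = 9))
  idx <- build_m6a_index(co$m6a_sites, co$transcripts$transcript_id)
  truth <- co$truth$transcripts
  status <- vapply(truth$transcript_id, classify_transcript, "", index = idx)
  expect_equal(unname(status == "M6A_POS"), truth$methylated)
  # planted-site m6A status matches the truth flag
  tsites <- truth[truth$is_target, ]
  st <- vapply(seq_len(nrow(tsites)), function(i)
    classify_site(list(transcript_id = tsites$transcript_id[i],
                       start = tsites$site_start[i],
                       end = tsites$site_end[i]), idx), "")
  expect_equal(unname(st == "M6A_POS"), tsites$site_has_m6a)
  # every m6A position falls on an adenosine
  seqs <- setNames(co$transcripts$utr3_seq, co$transcripts$transcript_id)
  base <- substr(seqs[co$m6a_sites$transcript_id],
                 co$m6a_sites$position + 1, co$m6a_sites$position + 1)
  expect_true(all(base == "A"))
})

test_that("planted expression effects have the configured sizes", {
  cfg <- synth_config(n_transcripts = 6000, rng_seed = 10,
                      with_conservation = FALSE, with_chimeras = FALSE)
  co <- generate_cohort(cfg)
  truth <- co$truth$transcripts
  fc <- co$expression$log2fc
  tgt <- truth$is_target
  # m6A+ targets vs m6A- targets differ by delta_m6a
  a <- fc[tgt & truth$methylated]; b <- fc[tgt & !truth$methylated]
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs((mean(a) - mean(b)) - cfg$delta_m6a), 3 * se)
  # non-targets are centered at zero
  z <- fc[!tgt]
  expect_lt(abs(mean(z)), 3 * sd(z) / sqrt(length(z)))
})

test_that("degenerate configurations surface the documented errors", {
  co <- generate_cohort(synth_config(n_transcripts = 150, p_methylated = 0,
                                     rng_seed = 11, with_conservation = FALSE,
                                     with_chimeras = FALSE))
  expect_error(
    analyze_cohort(co, energy = "hybrid", dg_threshold = "none",
                   confounders = FALSE),
    "m6a_pos")
  expect_error(synth_config(p_target = 1.4), "\\[0,1\\]")
  expect_error(synth_config(site_type_mix = c(SIX_MER = 0.5, SEVEN_MER_A1 = 0.2,
                                              SEVEN_MER_M8 = 0.2, EIGHT_MER = 0.2)),
               "sum to 1")
})
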