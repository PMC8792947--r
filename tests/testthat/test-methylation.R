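mk_index <- function(sites, ids) {
  build_m6a_index(
    data.frame(transcript_id = rep(names(sites), lengths(sites)),
               position = unlist(sites, use.names = FALSE),
               source_tag = "t", stringsAsFactors = FALSE), ids)
}

test_that("transcripts are m6A+ iff they carry at least one site", {
  idx <- mk_index(list(t1 = 5L, t3 = c(1L, 7L, 9L, 12L, 20L, 33L, 40L)),
                  c("t1", "t2", "t3"))
  expect_equal(classify_transcript("t1", idx), "M6A_POS")
  expect_equal(classify_transcript("t2", idx), "M6A_NEG")
  expect_equal(classify_transcript("t3", idx), "M6A_POS")
  expect_error(classify_transcript("t9", idx), "unknown")
})

test_that("site status uses half-open overlap", {
  idx <- mk_index(list(t1 = 10L, t2 = 11L), c("t1", "t2", "t3"))
  expect_equal(classify_site(list(transcript_id = "t1", start = 3, end = 11), idx),
               "M6A_POS")   # 10 in [3,11)
  expect_equal(classify_site(list(transcript_id = "t2", start = 3, end = 11), idx),
               "M6A_NEG")   # 11 not in [3,11)
  expect_equal(classify_site(list(transcript_id = "t3", start = 3, end = 11), idx),
               "M6A_NEG")
})

test_that("site m6A+ implies transcript m6A+", {
  set.seed(51)
  ids <- sprintf("t%d", 1:30)
  for (r in 1:50) {
    pos <- lapply(setNames(nm = sample(ids, 12)), function(i)
      sort(sample(0:300, sample(1:4, 1))))
    idx <- mk_index(pos, ids)
    st <- sample(0:290, 1)
    site <- list(transcript_id = sample(ids, 1), start = st, end = st + 8)
    if (classify_site(site, idx) == "M6A_POS")
      expect_equal(classify_transcript(site$transcript_id, idx), "M6A_POS")
  }
})

test_that("nearest distance is 0 on overlap, else the gap to the closest m6A", {
  idx <- mk_index(list(t1 = 10L, t2 = c(5L, 300L), t3 = 22L), c("t1", "t2", "t3", "t4"))
  expect_equal(nearest_m6a_distance(list(transcript_id = "t1", start = 20, end = 28), idx), 10L)
  expect_equal(nearest_m6a_distance(list(transcript_id = "t2", start = 20, end = 28), idx), 15L)
  expect_equal(nearest_m6a_distance(list(transcript_id = "t3", start = 20, end = 28), idx), 0L)
  expect_error(nearest_m6a_distance(list(transcript_id = "t4", start = 20, end = 28), idx),
               "m6A\\+ targets only")
})

test_that("nearest distance agrees with brute force on random configurations", {
  set.seed(52)
  for (r in 1:200) {
    pos <- sort(sample(0:500, sample(1:8, 1)))
    idx <- mk_index(list(tx = pos), "tx")
    st <- sample(0:492, 1)
    got <- nearest_m6a_distance(list(transcript_id = "tx", start = st, end = st + 8), idx)
    expect_equal(got, oracle_nearest_distance(st, st + 8, pos))
  }
})

test_that("distance subsets partition at the cutoff with boundary in 'longer'", {
  targets <- data.frame(transcript_id = c("a", "b", "c", "d"),
                        nearest_distance = c(99L, 100L, 0L, 250L),
                        stringsAsFactors = FALSE)
  ds <- distance_subsets(targets, cutoff = 100)
  expect_equal(ds$shorter$transcript_id, c("a", "c"))
  expect_equal(ds$longer$transcript_id, c("b", "d"))
  expect_equal(nrow(ds$shorter) + nrow(ds$longer), nrow(targets))
  all0 <- data.frame(transcript_id = "x", nearest_distance = 0L)
  expect_equal(nrow(distance_subsets(all0)$longer), 0L)
})

test_that("proximal-only keeps non-overlapping m6A within the window, inclusive", {
  targets <- data.frame(transcript_id = c("ov", "near", "edge", "far"),
                        nearest_distance = c(0L, 150L, 200L, 201L),
                        stringsAsFactors = FALSE)
  keep <- proximal_only_targets(targets, window = 200)
  expect_equal(keep$transcript_id, c("near", "edge"))
})
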