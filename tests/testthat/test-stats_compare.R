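test_that("KS statistic and p behave on identical and disjoint samples", {
  r <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)
  r2 <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$D, 1)
  expect_equal(r2$p, 0.1)  # exact: 2 of the C(6,3) = 20 labelings are as extreme
  expect_error(ks_two_sample(numeric(0), 1), "empty")
})

test_that("small-sample KS p-values match exact labeling enumeration", {
  set.seed(61)
  for (r in 1:25) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    a <- rnorm(n); b <- rnorm(m, mean = runif(1, -1, 1))
    got <- ks_two_sample(a, b)
    expect_true(got$exact)
    expect_equal(got$p, oracle_ks_exact_p(a, b), tolerance = 1e-9,
                 label = sprintf("n=%d m=%d", n, m))
    expect_equal(got$D, oracle_ks_D(a, b), tolerance = 1e-12)
  }
})

test_that("GC content is the G+C percentage", {
  expect_equal(gc_content("AUGC"), 50)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("AUAU"), 0)
  expect_equal(gc_content(c("AUGC", "GGCC")), c(50, 100))
  expect_error(gc_content(""), "empty")
})

test_that("site conservation averages available scores with a coverage rule", {
  expect_equal(site_conservation(0, 8, rep(0.8, 20)), 0.8)
  expect_equal(site_conservation(2, 8, c(NA, NA, 0.2, 0.4, 0.6, 0.8, 1.0, 1.0)),
               mean(c(0.2, 0.4, 0.6, 0.8, 1.0, 1.0)))
  v <- c(0.5, rep(NA, 7))
  expect_true(is.na(site_conservation(0, 8, v)))     # 7 of 8 missing
  v4 <- c(rep(0.5, 4), rep(NA, 4))
  expect_equal(site_conservation(0, 8, v4), 0.5)     # exactly half present
  expect_error(site_conservation(0, 9, rep(0.5, 8)), "outside")
})

test_that("relative location follows (k/n) x 100 with 1-based k", {
  expect_equal(relative_location(249, 1000), 25)    # k = 250
  expect_equal(relative_location(199, 200), 100)    # k = n
  expect_equal(relative_location(0, 200), 0.5)      # site at UTR start
})

test_that("regulation groups partition the expressed transcriptome", {
  cl <- data.frame(
    transcript_id = sprintf("t%d", 1:8),
    klass = c("SEED_78", "SEED_78", "SIXMER_ONLY", "SIXMER_ONLY",
              "NONE", "NONE", "SEED_78", "SIXMER_ONLY"),
    tx_status = c("M6A_POS", "M6A_NEG", "M6A_POS", "M6A_NEG",
                  "M6A_POS", "M6A_NEG", "M6A_POS", "M6A_NEG"),
    rep_dg_total = c(NA, NA, -12, -2, NA, NA, NA, -20),
    stringsAsFactors = FALSE)
  expr <- data.frame(transcript_id = cl$transcript_id, log2fc = rnorm(8),
                     basal = 1, perturbation = "overexpression",
                     stringsAsFactors = FALSE)
  g <- build_regulation_groups(cl, expr, dg_threshold = -10)
  expect_setequal(g$m6a_pos, c("t1", "t7"))
  expect_equal(g$m6a_neg, "t2")
  expect_setequal(g$excluded_6mer, c("t3", "t8"))   # dg_total <= -10
  expect_setequal(g$others, c("t4", "t5", "t6"))
  # disjoint and exhaustive
  ids <- c(g$m6a_pos, g$m6a_neg, g$others, g$excluded_6mer)
  expect_setequal(ids, cl$transcript_id)
  expect_equal(anyDuplicated(ids), 0L)

  # median6mer drops the stronger half of the 6mer-only transcripts
  g2 <- build_regulation_groups(cl, expr, dg_threshold = "median6mer")
  expect_setequal(g2$excluded_6mer, c("t3", "t8"))  # median(-12,-2,-20) = -12
  g3 <- build_regulation_groups(cl, expr, dg_threshold = "none")
  expect_equal(length(g3$excluded_6mer), 0L)
  expect_error(build_regulation_groups(cl, rbind(expr,
    data.frame(transcript_id = "zz", log2fc = 0, basal = 1,
               perturbation = "overexpression"))), "zz")
})

test_that("knockout mode keeps only up-regulated transcripts", {
  cl <- data.frame(transcript_id = sprintf("t%d", 1:40),
                   klass = rep(c("SEED_78", "NONE"), 20),
                   tx_status = rep(c("M6A_POS", "M6A_NEG"), each = 20),
                   rep_dg_total = NA_real_, stringsAsFactors = FALSE)
  set.seed(62)
  expr <- data.frame(transcript_id = cl$transcript_id,
                     log2fc = c(rnorm(20, 1), rnorm(20, -1)),
                     basal = 1, perturbation = "knockout",
                     stringsAsFactors = FALSE)
  g <- build_regulation_groups(cl, expr, "none")
  cmp <- compare_regulation(g, expr, "positive_only")
  keep <- expr$log2fc > 0
  expect_equal(cmp$n_a[1] + cmp$n_b[1] + cmp$n_b[2],
               sum(keep))
  # an empty group is a named error
  g_empty <- g; g_empty$m6a_neg <- character(0)
  expect_error(compare_regulation(g_empty, expr), "m6a_neg")
})

test_that("length bin resampling balances groups per bin deterministically", {
  set.seed(63)
  pos <- setNames(sample(50:6000, 400), sprintf("p%d", 1:400))
  neg <- setNames(sample(50:6000, 300), sprintf("n%d", 1:300))
  rs1 <- length_bin_resample(pos, neg, bin = 500, size = 30, seed = 9)
  rs2 <- length_bin_resample(pos, neg, bin = 500, size = 30, seed = 9)
  expect_identical(rs1$pos_ids, rs2$pos_ids)
  expect_identical(rs1$neg_ids, rs2$neg_ids)
  expect_equal(length(rs1$pos_ids), length(rs1$neg_ids))
  # per-bin equality and the min rule
  cb <- function(x) cut(x, c(seq(0, 5000, 500), Inf), right = TRUE)
  tp <- table(cb(pos[rs1$pos_ids]))
  tn <- table(cb(neg[rs1$neg_ids]))
  expect_equal(as.vector(tp), as.vector(tn))
  expect_true(all(rs1$counts$n_sampled ==
                    pmin(30, rs1$counts$n_pos, rs1$counts$n_neg)))
  # a small bin contributes min(size, n+, n-) from each side
  pos2 <- setNames(rep(250, 10), sprintf("p%d", 1:10))
  neg2 <- setNames(rep(250, 4), sprintf("n%d", 1:4))
  rs3 <- length_bin_resample(pos2, neg2, size = 3000, seed = 1)
  expect_equal(length(rs3$pos_ids), 4L)
  expect_equal(length(rs3$neg_ids), 4L)
  expect_error(length_bin_resample(pos2, neg2, size = 0), ">= 1")
  # boundary length 500 lands in exactly one bin: (0,500]
  rs4 <- length_bin_resample(setNames(500, "x"), setNames(500, "y"),
                             size = 5, seed = 2)
  expect_equal(rs4$counts$n_sampled[1], 1L)
  expect_equal(sum(rs4$counts$n_sampled), 1L)
})
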