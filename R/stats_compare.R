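# Comparative statistics: two-sample Kolmogorov-Smirnov machinery, group
# construction (m6A+ / m6A- / Others), conservation and GC metrics, UTR
# length bin-matched resampling, and the confounder battery.

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided KS test on the maximum ECDF gap D. For small samples
#' (min(n, m) <= 10 by default) the exact conditional null distribution
#' of D is used; otherwise the asymptotic Kolmogorov distribution.
#' P-values are raw (uncorrected), matching the reporting convention of
#' the analyses built on top.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact logical; default `min(length(a), length(b)) <= 10`.
#' @return `list(D =, p =, n = c(na, nb), exact =)`.
#' @export
ks_two_sample <- function(a, b, exact = NULL) {
  if (!length(a) || !length(b)) stop("KS test: empty sample")
  if (is.null(exact)) exact <- min(length(a), length(b)) <= 10
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(kt$statistic), p = max(kt$p.value, .Machine$double.xmin),
       n = c(length(a), length(b)), exact = exact)
}

#' GC content of a sequence
#'
#' @param seq character vector of non-empty A/C/G/U(/T) sequences.
#' @return Percentage of G+C, per sequence.
#' @export
gc_content <- function(seq) {
  if (any(!nzchar(seq))) stop("gc_content: empty sequence")
  100 * stringi::stri_count_regex(seq, "[GCgc]") / nchar(seq)
}

#' Site conservation score
#'
#' Mean of the available per-nucleotide conservation scores over the
#' site interval \[start, end). Positions absent from the track (`NA`)
#' are excluded from the mean; if fewer than half of the site's
#' positions have scores, the site score is missing (`NA`).
#'
#' @param start,end site coordinates, 0-based half-open.
#' @param scores per-nucleotide conservation vector for the transcript
#'   (`NA` for track gaps).
#' @return The site conservation score in \[0,1\], or `NA`.
#' @export
site_conservation <- function(start, end, scores) {
  if (end > length(scores) || start < 0 || start >= end)
    stop("site outside conservation track")
  v <- scores[(start + 1L):end]
  if (sum(!is.na(v)) < (end - start) / 2) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Relative location of a site within its 3'-UTR
#'
#' For the site's 5'-most nucleotide at 1-based position k of an n-nt
#' UTR, the relative location is (k / n) * 100 percent.
#'
#' @param start site start, 0-based.
#' @param utr_len UTR length n.
#' @return Percentage in (0, 100\].
#' @export
relative_location <- function(start, utr_len) {
  k <- start + 1
  if (any(k < 1 | k > utr_len)) stop("site start outside UTR")
  (k / utr_len) * 100
}

#' Build the m6A+ / m6A- / Others regulation groups
#'
#' Expressed transcripts are partitioned by target class and transcript
#' m6A status: `m6a_pos` are transcripts with a 7mer or 8mer site
#' (SEED_78) that are m6A+, `m6a_neg` SEED_78 transcripts that are
#' m6A-, and `others` all remaining transcripts minus 6mer-only
#' transcripts whose representative site looks like a confident target
#' (dg_total at or below `dg_threshold`) -- those are excluded
#' entirely. The threshold is a configurable proxy for a trained
#' site-confidence model, which is not part of this package; it is
#' flagged as such in outputs.
#'
#' @param classification per-transcript data.frame with columns
#'   `transcript_id`, `klass` (SEED_78 / SIXMER_ONLY / NONE),
#'   `tx_status` (M6A_POS / M6A_NEG) and, for SIXMER_ONLY rows when a
#'   threshold is used, `rep_dg_total`.
#' @param expression expression data.frame; every expressed transcript
#'   must appear in `classification`.
#' @param dg_threshold numeric threshold in kcal/mol, or "median6mer"
#'   (cohort median of the 6mer representative dg_total), or "none" to
#'   keep all 6mer-only transcripts in Others.
#' @return `list(m6a_pos =, m6a_neg =, others =, excluded_6mer =)` of
#'   transcript id vectors (disjoint; union = expressed transcripts).
#' @export
build_regulation_groups <- function(classification, expression,
                                    dg_threshold = "median6mer") {
  missing_tx <- setdiff(expression$transcript_id, classification$transcript_id)
  if (length(missing_tx))
    stop("expressed transcript(s) not in the cohort FASTA: ",
         paste(head(missing_tx, 5), collapse = ", "))
  cl <- classification[match(expression$transcript_id,
                             classification$transcript_id), ]
  seed78 <- cl$klass == "SEED_78"
  m6a_pos <- cl$transcript_id[seed78 & cl$tx_status == "M6A_POS"]
  m6a_neg <- cl$transcript_id[seed78 & cl$tx_status == "M6A_NEG"]
  rest <- cl[!seed78, , drop = FALSE]
  excluded <- character(0)
  if (!identical(dg_threshold, "none")) {
    six <- rest[rest$klass == "SIXMER_ONLY", , drop = FALSE]
    dg <- six$rep_dg_total
    if (identical(dg_threshold, "median6mer")) {
      thr <- if (any(is.finite(dg))) median(dg[is.finite(dg)]) else -Inf
    } else {
      thr <- as.numeric(dg_threshold)
    }
    excluded <- six$transcript_id[!is.na(dg) & dg <= thr]
  }
  others <- setdiff(rest$transcript_id, excluded)
  list(m6a_pos = m6a_pos, m6a_neg = m6a_neg, others = others,
       excluded_6mer = excluded)
}

group_comparison <- function(metric, label_a, label_b, a, b, note = "") {
  ks <- ks_two_sample(a, b)
  data.frame(metric = metric, group_a = label_a, group_b = label_b,
             n_a = length(a), n_b = length(b), ks_D = ks$D, p_value = ks$p,
             exact = ks$exact, note = note, stringsAsFactors = FALSE)
}

#' Compare miRNA-mediated regulation across m6A groups
#'
#' Three pairwise KS comparisons of log2 fold changes: m6A+ vs m6A-,
#' m6A+ vs Others, m6A- vs Others. In knockout mode
#' (`direction_filter = "positive_only"`) only up-regulated transcripts
#' (log2fc > 0) enter the comparison, since target de-repression is the
#' expected direction.
#'
#' @param groups output of [build_regulation_groups()].
#' @param expression expression data.frame.
#' @param direction_filter "none" or "positive_only".
#' @return A data.frame with one row per comparison (metric, group
#'   labels, sizes, KS D, p-value).
#' @export
compare_regulation <- function(groups, expression,
                               direction_filter = c("none", "positive_only")) {
  direction_filter <- match.arg(direction_filter)
  expr <- expression
  if (direction_filter == "positive_only")
    expr <- expr[expr$log2fc > 0, , drop = FALSE]
  fc <- setNames(expr$log2fc, expr$transcript_id)
  sam <- lapply(groups[c("m6a_pos", "m6a_neg", "others")],
                function(ids) unname(fc[intersect(ids, names(fc))]))
  empty <- names(sam)[vapply(sam, length, 1L) == 0L]
  if (length(empty))
    stop("empty regulation group(s): ", paste(empty, collapse = ", "))
  rbind(
    group_comparison("log2fc", "m6a_pos", "m6a_neg", sam$m6a_pos, sam$m6a_neg,
                     note = direction_filter),
    group_comparison("log2fc", "m6a_pos", "others", sam$m6a_pos, sam$others,
                     note = direction_filter),
    group_comparison("log2fc", "m6a_neg", "others", sam$m6a_neg, sam$others,
                     note = direction_filter))
}

#' Bin-matched resampling of UTR lengths
#'
#' Controls for 3'-UTR length: lengths are binned into (0,500],
#' (500,1000], ..., (4500,5000] and (5000, Inf) nt, and from every bin
#' the same number of transcripts -- `min(size, bin count in m6A+, bin
#' count in m6A-)` -- is drawn without replacement from each group, so
#' both groups contribute equally per bin and the pooled length
#' distributions are bin-balanced by construction.
#'
#' @param pos_lengths,neg_lengths named numeric vectors (names =
#'   transcript ids) of UTR lengths for the m6A+ and m6A- targets.
#' @param bin bin width in nt.
#' @param size preset common sampling size per bin.
#' @param seed RNG seed; identical seeds give identical id sets.
#' @return `list(seed, bin_edges, counts, pos_ids, neg_ids)` where
#'   `counts` tabulates per-bin group sizes before and after sampling.
#' @export
length_bin_resample <- function(pos_lengths, neg_lengths, bin = 500,
                                size = 3000, seed = 1) {
  if (size < 1) stop("sampling size must be >= 1")
  edges <- c(seq(0, 5000, by = bin), Inf)
  cut_bins <- function(x) cut(x, breaks = edges, right = TRUE,
                              include.lowest = FALSE)
  bp <- cut_bins(pos_lengths)
  bn <- cut_bins(neg_lengths)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  pos_ids <- character(0); neg_ids <- character(0)
  counts <- data.frame(bin = levels(bp), n_pos = 0L, n_neg = 0L,
                       n_sampled = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(levels(bp))) {
    lev <- levels(bp)[k]
    ip <- names(pos_lengths)[which(bp == lev)]
    im <- names(neg_lengths)[which(bn == lev)]
    take <- min(size, length(ip), length(im))
    counts$n_pos[k] <- length(ip)
    counts$n_neg[k] <- length(im)
    counts$n_sampled[k] <- take
    if (take > 0L) {
      pos_ids <- c(pos_ids, sample(ip, take))
      neg_ids <- c(neg_ids, sample(im, take))
    }
  }
  list(seed = seed, bin_edges = edges, counts = counts,
       pos_ids = sort(pos_ids), neg_ids = sort(neg_ids))
}

#' ECDF comparison plot
#'
#' Base-graphics cumulative distribution plot in the conventional
#' color scheme: m6A+ red, m6A- green, Others blue.
#'
#' @param samples named list of 2 or 3 numeric vectors.
#' @param main,xlab plot annotation.
#' @param cols line colors, recycled over `samples`.
#' @return Invisibly, `NULL`.
#' @export
plot_ecdf_comparison <- function(samples, main = "", xlab = "value",
                                 cols = c("red", "darkgreen", "blue")) {
  rng <- range(unlist(samples), finite = TRUE)
  plot(NA, xlim = rng, ylim = c(0, 1), main = main, xlab = xlab,
       ylab = "cumulative fraction")
  for (i in seq_along(samples)) {
    x <- sort(samples[[i]][is.finite(samples[[i]])])
    lines(x, seq_along(x) / length(x), type = "s", col = cols[i], lwd = 2)
  }
  legend("bottomright", legend = names(samples), col = cols[seq_along(samples)],
         lwd = 2, bty = "n")
  invisible(NULL)
}
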