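# Independent oracles used to validate the package's dynamic programs and
# scanners. These are deliberately naive (substring scans, exhaustive
# enumeration) and share no code with the implementation paths they check.

ORACLE_BASES <- c("A", "C", "G", "U")

random_rna <- function(n, gc = 0.5) {
  paste(sample(ORACLE_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

oracle_pair_name <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% c("AU", "UA", "CG", "GC", "GU", "UG")) p else NA_character_
}

# ---- site-finder oracle: position-by-position substring comparison --------

oracle_revcomp <- function(s) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_find_sites <- function(utr, mirna) {
  stopifnot(nchar(mirna) >= 8)
  m <- strsplit(mirna, "")[[1]]
  p6 <- oracle_revcomp(substr(mirna, 2, 7))
  p7m8 <- oracle_revcomp(substr(mirna, 2, 8))
  pats <- list(SIX_MER = p6, SEVEN_MER_A1 = paste0(p6, "A"),
               SEVEN_MER_M8 = p7m8, EIGHT_MER = paste0(p7m8, "A"))
  hits <- data.frame(start = integer(0), end = integer(0),
                     site_type = character(0), stringsAsFactors = FALSE)
  L <- nchar(utr)
  for (ty in names(pats)) {
    w <- nchar(pats[[ty]])
    s <- 0L
    while (s + w <= L) {
      if (substr(utr, s + 1L, s + w) == pats[[ty]])
        hits <- rbind(hits, data.frame(start = s, end = s + w, site_type = ty,
                                       stringsAsFactors = FALSE))
      s <- s + 1L
    }
  }
  if (!nrow(hits)) return(hits)
  w <- hits$end - hits$start
  keep <- vapply(seq_len(nrow(hits)), function(i)
    !any(w > w[i] & hits$start <= hits$start[i] & hits$end >= hits$end[i]),
    TRUE)
  hits <- hits[keep, , drop = FALSE]
  ty_rank <- match(hits$site_type,
                   c("SIX_MER", "SEVEN_MER_A1", "SEVEN_MER_M8", "EIGHT_MER"))
  hits <- hits[order(hits$start, ty_rank), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# ---- duplex oracle: depth-first enumeration of all antiparallel chains ----

oracle_step_energy <- function(p1, p2, g1, g2, par) {
  if (g1 == 0 && g2 == 0) return(par$stack[p1, p2])
  if (g1 > 0 && g2 > 0) return(par$internal_base + par$internal_per_nt * (g1 + g2))
  par$bulge_base + par$bulge_per_nt * (g1 + g2)
}

oracle_duplex <- function(mirna, target, par = energy_params()) {
  m <- strsplit(mirna, "")[[1]]
  t <- strsplit(target, "")[[1]]
  cand <- NULL
  for (i in seq_along(m)) for (j in seq_along(t)) {
    p <- oracle_pair_name(m[i], t[j])
    if (!is.na(p)) cand <- rbind(cand, data.frame(i = i, j = j, p = p))
  }
  if (is.null(cand)) return(Inf)
  ci <- cand$i; cj <- cand$j; cp <- cand$p
  succ <- lapply(seq_along(ci), function(k) which(ci > ci[k] & cj < cj[k]))
  best <- Inf
  rec <- function(k, e) {
    best <<- min(best, e)
    for (k2 in succ[[k]]) {
      g1 <- ci[k2] - ci[k] - 1
      g2 <- cj[k] - cj[k2] - 1
      rec(k2, e + oracle_step_energy(cp[k], cp[k2], g1, g2, par))
    }
  }
  for (k in seq_along(ci)) rec(k, 0)
  best
}

# ---- fold oracle: enumerate all structures, score each independently -----

# All non-crossing pairings of region [i, j] (1-based, inclusive) with
# allowed pairs, hairpin >= min_hairpin, and forced-unpaired respected.
# Each structure is a (possibly 0-row) matrix of (i, j) pairs.
oracle_enumerate <- function(seq_chars, forced0, min_hairpin = 3) {
  n <- length(seq_chars)
  forced <- rep(FALSE, n)
  forced[forced0 + 1] <- TRUE
  memo <- new.env(parent = emptyenv())
  enum <- function(i, j) {
    if (j - i + 1 <= min_hairpin) return(list(matrix(0L, 0, 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- oracle_enumerate_region(i, j)
    memo[[key]] <- res
    res
  }
  oracle_enumerate_region <- function(i, j) {
    res <- enum(i, j - 1)                      # j unpaired
    kmax <- j - min_hairpin - 1
    if (kmax < i) return(res)
    for (k in i:kmax) {
      if (forced[k] || forced[j]) next
      if (is.na(oracle_pair_name(seq_chars[k], seq_chars[j]))) next
      left <- if (k > i) enum(i, k - 1) else list(matrix(0L, 0, 2))
      inner <- enum(k + 1, j - 1)
      for (L in left) for (I in inner)
        res <- c(res, list(rbind(L, c(k, j), I)))
    }
    res
  }
  enum(1, n)
}

# Score one structure by explicit loop decomposition; independent of the DP.
oracle_score <- function(seq_chars, pairs, par = energy_params()) {
  if (nrow(pairs) == 0) return(0)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  np <- nrow(pairs)
  # parent of each pair = smallest enclosing pair
  parent <- rep(0L, np)
  for (q in seq_len(np)) {
    enc <- which(pairs[, 1] < pairs[q, 1] & pairs[, 2] > pairs[q, 2])
    if (length(enc)) parent[q] <- enc[which.min(pairs[enc, 2] - pairs[enc, 1])]
  }
  e <- 0
  for (q in seq_len(np)) {
    i <- pairs[q, 1]; j <- pairs[q, 2]
    kids <- which(parent == q)
    pq <- oracle_pair_name(seq_chars[i], seq_chars[j])
    if (length(kids) == 0) {
      e <- e + par$hairpin_base + par$hairpin_per_nt * (j - i - 1)
    } else if (length(kids) == 1) {
      k <- pairs[kids, 1]; l <- pairs[kids, 2]
      g1 <- k - i - 1; g2 <- j - l - 1
      if (g1 == 0 && g2 == 0) {
        e <- e + par$stack[pq, oracle_pair_name(seq_chars[k], seq_chars[l])]
      } else if (g1 > 0 && g2 > 0) {
        if (g1 + g2 > par$max_internal) return(Inf)
        e <- e + par$internal_base + par$internal_per_nt * (g1 + g2)
      } else {
        if (g1 + g2 > par$max_internal) return(Inf)
        e <- e + par$bulge_base + par$bulge_per_nt * (g1 + g2)
      }
    } else {
      unpaired <- (j - i - 1) - sum(pairs[kids, 2] - pairs[kids, 1] + 1)
      e <- e + par$multiloop_a + par$multiloop_b * (length(kids) + 1) +
        par$multiloop_c * unpaired
    }
  }
  e
}

oracle_fold_mfe <- function(seq, forced0 = integer(0), par = energy_params()) {
  ch <- strsplit(seq, "")[[1]]
  structs <- oracle_enumerate(ch, forced0, par$min_hairpin)
  min(vapply(structs, function(s) oracle_score(ch, s, par), 0))
}

# dot-bracket -> pair matrix (for checking traceback consistency)
db_to_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  stk <- integer(0)
  out <- matrix(0L, 0, 2)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stk <- c(stk, i)
    else if (ch[i] == ")") {
      out <- rbind(out, c(stk[length(stk)], i))
      stk <- stk[-length(stk)]
    }
  }
  stopifnot(length(stk) == 0)
  out
}

# ---- exact two-sample KS oracle: enumerate all labelings ------------------

oracle_ks_D <- function(a, b) {
  z <- sort(unique(c(a, b)))
  Fa <- vapply(z, function(t) mean(a <= t), 0)
  Fb <- vapply(z, function(t) mean(b <= t), 0)
  max(abs(Fa - Fb))
}

oracle_ks_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  d_obs <- oracle_ks_D(a, b)
  labelings <- utils::combn(length(pooled), n)
  ds <- apply(labelings, 2, function(ix)
    oracle_ks_D(pooled[ix], pooled[-ix]))
  mean(ds >= d_obs - 1e-12)
}

# ---- brute-force m6A distance --------------------------------------------

oracle_nearest_distance <- function(start, end, positions) {
  d <- vapply(as.integer(positions), function(p) {
    if (p >= start && p < end) 0L
    else if (p < start) as.integer(start - p)
    else as.integer(p - (end - 1L))
  }, 0L)
  min(d)
}
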