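# Canonical seed-site identification. Site types follow the standard seed
# nomenclature: the seed is miRNA nucleotides 2-8 from the 5' end, matched
# on the target by Watson-Crick complementarity only (G.U wobbles are never
# seed matches, although they are allowed in folding and duplexes).

rna_revcomp <- function(seq) {
  stringi::stri_reverse(chartr("ACGU", "UGCA", seq))
}

#' Target-site strings for the four canonical seed site types
#'
#' For a miRNA given 5'->3', the target-site strings (read 5'->3' on the
#' UTR) are: 6mer = reverse complement of miRNA positions 2-7;
#' 7mer-m8 = reverse complement of positions 2-8; 7mer-A1 = the 6mer
#' followed by an A (the target adenosine opposite miRNA position 1);
#' 8mer = the 7mer-m8 followed by an A.
#'
#' @param mirna_seq miRNA sequence, 5'->3', at least 8 nt.
#' @return Named character vector with elements `SIX_MER`,
#'   `SEVEN_MER_A1`, `SEVEN_MER_M8`, `EIGHT_MER`.
#' @examples
#' seed_site_patterns("UGAGGUAGUAGGUUGUAUAGUU")  # let-7a
#' @export
seed_site_patterns <- function(mirna_seq) {
  mirna_seq <- toupper(chartr("Tt", "Uu", mirna_seq))
  if (nchar(mirna_seq) < 8) stop("miRNA must be at least 8 nt")
  if (grepl("[^ACGU]", mirna_seq)) stop("invalid miRNA alphabet")
  p6 <- rna_revcomp(substr(mirna_seq, 2, 7))
  p7m8 <- rna_revcomp(substr(mirna_seq, 2, 8))
  c(SIX_MER = p6,
    SEVEN_MER_A1 = paste0(p6, "A"),
    SEVEN_MER_M8 = p7m8,
    EIGHT_MER = paste0(p7m8, "A"))
}

empty_sites <- function() {
  data.frame(transcript_id = character(0), mirna_id = character(0),
             start = integer(0), end = integer(0), site_type = character(0),
             dg_hybrid = numeric(0), dg_open = numeric(0),
             dg_total = numeric(0), m6a_status = character(0),
             cons_score = numeric(0), stringsAsFactors = FALSE)
}

# Drop any match whose interval is contained in a strictly longer match
# (longest-match-wins at a locus: an 8mer occurrence hides the 7mer/6mer
# matches nested inside it, a 7mer hides nested 6mers).
suppress_nested <- function(start, width) {
  n <- length(start)
  if (n <= 1L) return(rep(TRUE, n))
  keep <- rep(TRUE, n)
  end <- start + width
  for (i in seq_len(n)) {
    keep[i] <- !any(width > width[i] & start <= start[i] & end >= end[i])
  }
  keep
}

#' Find canonical seed sites on a 3'-UTR
#'
#' All occurrences of the four seed patterns are located (including
#' overlapping occurrences at different offsets); matches nested inside
#' a longer match are suppressed so one locus is not double-counted.
#' Output is sorted by start, then site type.
#'
#' @param utr_seq UTR sequence over A/C/G/U.
#' @param mirna_seq miRNA sequence, 5'->3', >= 8 nt.
#' @param transcript_id,mirna_id identifiers copied into the result.
#' @return A binding-site data.frame with 0-based half-open `start`,
#'   `end`, `site_type`, and unset energy/status columns (`dg_hybrid`,
#'   `dg_open`, `dg_total` `NA`; `m6a_status` "UNSET"; `cons_score` `NA`).
#' @export
find_seed_sites <- function(utr_seq, mirna_seq, transcript_id = "utr",
                            mirna_id = "mirna") {
  pats <- seed_site_patterns(mirna_seq)
  starts <- integer(0); types <- character(0)
  for (ty in names(pats)) {
    loc <- stringi::stri_locate_all_fixed(
      utr_seq, pats[[ty]], overlap = TRUE)[[1]]
    if (!is.na(loc[1, 1])) {
      starts <- c(starts, loc[, 1] - 1L)
      types <- c(types, rep(ty, nrow(loc)))
    }
  }
  if (!length(starts)) return(empty_sites())
  width <- SEED_WIDTHS[types]
  keep <- suppress_nested(starts, width)
  d <- data.frame(transcript_id = transcript_id, mirna_id = mirna_id,
                  start = as.integer(starts[keep]),
                  end = as.integer(starts[keep] + width[keep]),
                  site_type = types[keep],
                  dg_hybrid = NA_real_, dg_open = NA_real_,
                  dg_total = NA_real_, m6a_status = "UNSET",
                  cons_score = NA_real_, stringsAsFactors = FALSE)
  ord <- order(d$start, match(d$site_type, SEED_TYPES))
  d <- d[ord, , drop = FALSE]
  rownames(d) <- NULL
  d
}

# Cohort-scale variant: one stri_locate_all_fixed call per pattern over all
# UTRs, then per-transcript nested-match suppression.
find_seed_sites_cohort <- function(transcripts, mirna) {
  pats <- seed_site_patterns(mirna$seq)
  pieces <- vector("list", length(pats))
  for (k in seq_along(pats)) {
    ty <- names(pats)[k]
    locs <- stringi::stri_locate_all_fixed(transcripts$utr3_seq, pats[[k]],
                                           overlap = TRUE)
    nhit <- vapply(locs, function(m) if (is.na(m[1, 1])) 0L else nrow(m),
                   integer(1))
    if (sum(nhit) == 0L) next
    pieces[[k]] <- data.frame(
      transcript_id = rep(transcripts$transcript_id, nhit),
      start = unlist(lapply(locs[nhit > 0L], function(m) m[, 1])) - 1L,
      site_type = ty, stringsAsFactors = FALSE)
  }
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces)) return(empty_sites())
  d <- do.call(rbind, pieces)
  d$width <- SEED_WIDTHS[d$site_type]
  keep <- unlist(lapply(split(seq_len(nrow(d)), d$transcript_id), function(ix)
    ix[suppress_nested(d$start[ix], d$width[ix])]), use.names = FALSE)
  d <- d[sort(keep), , drop = FALSE]
  out <- data.frame(transcript_id = d$transcript_id, mirna_id = mirna$mirna_id,
                    start = as.integer(d$start),
                    end = as.integer(d$start + d$width),
                    site_type = d$site_type,
                    dg_hybrid = NA_real_, dg_open = NA_real_,
                    dg_total = NA_real_, m6a_status = "UNSET",
                    cons_score = NA_real_, stringsAsFactors = FALSE)
  ord <- order(out$transcript_id, out$start, match(out$site_type, SEED_TYPES))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

site_width_class <- function(site_type) {
  ifelse(site_type == "EIGHT_MER", 8L,
         ifelse(site_type %in% c("SEVEN_MER_A1", "SEVEN_MER_M8"), 7L, 6L))
}

#' Representative binding site for one transcript/miRNA pair
#'
#' When a transcript carries several sites, a single representative is
#' chosen: an 8mer is preferred over a 7mer of either type (7mer-A1 and
#' 7mer-m8 form one width class), and among multiple sites of the chosen
#' width the one with the strongest (most negative) hybridization energy
#' wins; remaining ties go to the smallest start coordinate.
#'
#' @param sites non-empty binding-site data.frame for one transcript and
#'   one miRNA, with `dg_hybrid` filled in.
#' @return The selected one-row data.frame.
#' @export
representative_site <- function(sites) {
  if (is.null(sites) || nrow(sites) == 0L)
    stop("representative_site: empty site list")
  wc <- site_width_class(sites$site_type)
  cand <- sites[wc == max(wc), , drop = FALSE]
  if (nrow(cand) > 1L) {
    if (any(is.na(cand$dg_hybrid)))
      stop("representative_site: dg_hybrid must be set to break ties")
    cand <- cand[order(cand$dg_hybrid, cand$start), , drop = FALSE]
  }
  cand[1L, , drop = FALSE]
}

#' Classify a transcript by its strongest seed-site class
#'
#' `SEED_78` if the transcript has at least one 7mer or 8mer site,
#' `SIXMER_ONLY` if it only has 6mers, `NONE` otherwise.
#'
#' @param sites binding-site data.frame for one transcript (may be empty).
#' @return One of "SEED_78", "SIXMER_ONLY", "NONE".
#' @export
classify_target <- function(sites) {
  if (is.null(sites) || nrow(sites) == 0L) return("NONE")
  wc <- site_width_class(sites$site_type)
  seed <- sites$site_type %in% SEED_TYPES
  if (any(seed & wc >= 7L)) return("SEED_78")
  if (any(seed)) return("SIXMER_ONLY")
  "NONE"
}

#' Locate the binding site within a CLASH chimera fragment
#'
#' If the fragment contains a canonical seed site for the chimera's
#' miRNA, the representative seed site is returned. Otherwise the
#' fragment is scanned with a sliding window (default 10 nt, stride 1)
#' and the window with the most negative intermolecular duplex energy
#' is reported as a SEEDLESS site. Coordinates are in UTR space. A
#' fragment with no pairable window at all (duplex energy `+Inf`
#' everywhere) yields `NULL`, flagged for downstream exclusion.
#'
#' @param chimera one chimera record (one-row data.frame or list) with
#'   `mirna_id`, `mirna_seq`, `transcript_id`, `frag_start`, `frag_end`,
#'   `frag_seq`.
#' @param params an [energy_params()] object.
#' @param seed_window SEEDLESS scan window length (nt).
#' @param hyb_flank 5' extension used when scoring seed-site hybridization.
#' @return A one-row binding-site data.frame, or `NULL` if no site.
#' @export
find_chimera_site <- function(chimera, params = energy_params(),
                              seed_window = 10L, hyb_flank = 15L) {
  frag <- chimera$frag_seq
  seed <- find_seed_sites(frag, chimera$mirna_seq,
                          transcript_id = chimera$transcript_id,
                          mirna_id = chimera$mirna_id)
  if (nrow(seed) > 0L) {
    for (i in seq_len(nrow(seed))) {
      h0 <- max(0L, seed$start[i] - hyb_flank)
      win <- substr(frag, h0 + 1L, seed$end[i])
      seed$dg_hybrid[i] <- duplex_energy(chimera$mirna_seq, win, params)$dg_hybrid
    }
    rep <- representative_site(seed)
    rep$start <- rep$start + chimera$frag_start
    rep$end <- rep$end + chimera$frag_start
    return(rep)
  }
  L <- nchar(frag)
  w <- min(seed_window, L)
  best <- Inf; best_s <- NA_integer_
  for (s in 0:(L - w)) {
    dg <- duplex_energy(chimera$mirna_seq, substr(frag, s + 1L, s + w),
                        params)$dg_hybrid
    if (dg < best) { best <- dg; best_s <- s }
  }
  if (!is.finite(best)) return(NULL)  # no pairable window: "no-site"
  data.frame(transcript_id = chimera$transcript_id,
             mirna_id = chimera$mirna_id,
             start = as.integer(chimera$frag_start + best_s),
             end = as.integer(chimera$frag_start + best_s + w),
             site_type = "SEEDLESS", dg_hybrid = best, dg_open = NA_real_,
             dg_total = NA_real_, m6a_status = "UNSET",
             cons_score = NA_real_, stringsAsFactors = FALSE)
}
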