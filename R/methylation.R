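# m6A+/m6A- classification of transcripts and binding sites, and the
# distance / proximity relations between m6A marks and miRNA-binding sites.
# A transcript is m6A+ if it carries at least one m6A site; a binding site
# is m6A+ if at least one m6A position falls inside its half-open interval.

#' Build a per-transcript m6A position index
#'
#' @param m6a_sites m6A site data.frame from [read_m6a_bed()].
#' @param transcript_ids all transcript identifiers of the cohort;
#'   transcripts without sites get an empty entry so they classify m6A-.
#' @return An object of class `m6a_index`: a named list of strictly
#'   increasing 0-based position vectors.
#' @export
build_m6a_index <- function(m6a_sites, transcript_ids) {
  if (anyDuplicated(transcript_ids))
    stop("duplicate transcript ids")
  idx <- lapply(setNames(nm = transcript_ids), function(id) integer(0))
  if (nrow(m6a_sites)) {
    unknown <- setdiff(m6a_sites$transcript_id, transcript_ids)
    if (length(unknown))
      stop("m6A sites on unknown transcript(s): ", paste(unknown, collapse = ", "))
    by_tx <- split(m6a_sites$position, m6a_sites$transcript_id)
    for (id in names(by_tx)) idx[[id]] <- sort(unique(as.integer(by_tx[[id]])))
  }
  class(idx) <- "m6a_index"
  idx
}

#' Classify a transcript as m6A+ or m6A-
#'
#' @param transcript_id transcript identifier.
#' @param index an [build_m6a_index()] object covering the cohort.
#' @return "M6A_POS" if the transcript has at least one m6A site,
#'   "M6A_NEG" otherwise. Unknown transcripts are an error.
#' @export
classify_transcript <- function(transcript_id, index) {
  pos <- index[[transcript_id]]
  if (is.null(pos)) stop("unknown transcript: ", transcript_id)
  if (length(pos)) "M6A_POS" else "M6A_NEG"
}

#' Classify a binding site as m6A+ or m6A-
#'
#' A site \[start, end) is m6A+ iff some m6A position p satisfies
#' start <= p < end.
#'
#' @param site one binding-site row (needs `transcript_id`, `start`, `end`).
#' @param index an `m6a_index`.
#' @return "M6A_POS" or "M6A_NEG".
#' @export
classify_site <- function(site, index) {
  pos <- index[[site$transcript_id]]
  if (is.null(pos)) stop("unknown transcript: ", site$transcript_id)
  if (any(pos >= site$start & pos < site$end)) "M6A_POS" else "M6A_NEG"
}

# vectorized site classification over a sites table
classify_sites <- function(sites, index) {
  if (!nrow(sites)) return(character(0))
  out <- character(nrow(sites))
  for (ix in split(seq_len(nrow(sites)), sites$transcript_id)) {
    id <- sites$transcript_id[ix[1]]
    pos <- index[[id]]
    if (is.null(pos)) stop("unknown transcript: ", id)
    if (!length(pos)) { out[ix] <- "M6A_NEG"; next }
    # count of positions < x, via binary search on the sorted index
    nlt <- function(x) findInterval(x - 0.5, pos)
    out[ix] <- ifelse(nlt(sites$end[ix]) - nlt(sites$start[ix]) > 0,
                      "M6A_POS", "M6A_NEG")
  }
  out
}

#' Distance from a binding site to the nearest m6A site
#'
#' 0 if an m6A position overlaps the site; otherwise the gap in
#' nucleotides between the m6A position and the nearest site nucleotide.
#' With multiple m6A sites on the UTR, the shortest distance is used.
#'
#' @param site one binding-site row.
#' @param index an `m6a_index`; the transcript must be m6A+ (callers
#'   filter to m6A+ targets first).
#' @return Nonnegative integer distance in nt.
#' @export
nearest_m6a_distance <- function(site, index) {
  pos <- index[[site$transcript_id]]
  if (is.null(pos)) stop("unknown transcript: ", site$transcript_id)
  if (!length(pos))
    stop("no m6A sites on transcript ", site$transcript_id,
         " (distance is defined for m6A+ targets only)")
  if (any(pos >= site$start & pos < site$end)) return(0L)
  d <- ifelse(pos < site$start, site$start - pos, pos - (site$end - 1L))
  as.integer(min(d))
}

#' Split m6A+ targets by m6A-to-site distance
#'
#' Partition at `cutoff` nucleotides: the "shorter" subset has distances
#' strictly under the cutoff, the "longer" subset distances at or above
#' it (the boundary lands in "longer").
#'
#' @param targets data.frame with a `nearest_distance` column.
#' @param cutoff distance cutoff in nt.
#' @return `list(shorter =, longer =)` of data.frames; an exhaustive,
#'   disjoint partition of the input.
#' @export
distance_subsets <- function(targets, cutoff = 100) {
  stopifnot("nearest_distance" %in% names(targets))
  list(shorter = targets[targets$nearest_distance < cutoff, , drop = FALSE],
       longer = targets[targets$nearest_distance >= cutoff, , drop = FALSE])
}

#' m6A+ targets whose m6A is proximal but not overlapping
#'
#' Keeps targets where no m6A site overlaps the representative binding
#' site and at least one m6A lies within `window` nt of it
#' (0 < distance <= window, boundary inclusive); targets with an
#' overlapping m6A or with all m6A sites beyond the window are removed.
#'
#' @param targets data.frame of m6A+ targets with `nearest_distance`.
#' @param window proximity window in nt.
#' @return The retained subset.
#' @export
proximal_only_targets <- function(targets, window = 200) {
  stopifnot("nearest_distance" %in% names(targets))
  targets[targets$nearest_distance > 0 & targets$nearest_distance <= window, ,
          drop = FALSE]
}
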