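RNA_BASES <- c("A", "C", "G", "U")

encode_rna <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(v, RNA_BASES) - 1L
  if (anyNA(code))
    stop(sprintf("invalid RNA alphabet: '%s' at position %d",
                 v[which(is.na(code))[1]], which(is.na(code))[1]))
  code
}

#' Minimum free energy of an intermolecular miRNA:target duplex
#'
#' Computes the minimum-energy antiparallel duplex between a miRNA and a
#' target window under the reduced nearest-neighbor model: consecutive
#' base pairs contribute stacking energies, and gaps on one or both
#' strands contribute linear bulge or internal-loop penalties.
#' Intramolecular pairing and branching are forbidden, as in hybrid-MFE
#' tools. A single isolated pair has energy 0; if no allowed pair exists
#' at all, the sentinel `+Inf` is returned.
#'
#' @param mirna_seq miRNA sequence, 5'->3', over A/C/G/U.
#' @param target_seq target window sequence, 5'->3'.
#' @param params an [energy_params()] object.
#' @return A list with `dg_hybrid` (kcal/mol, `+Inf` if no duplex) and
#'   `pairing`, a two-column matrix of 0-based (miRNA index, target index)
#'   pairs of the optimal duplex (empty when `dg_hybrid` is `+Inf`).
#' @examples
#' duplex_energy("ACGU", "ACGU")$dg_hybrid
#' @export
duplex_energy <- function(mirna_seq, target_seq, params = energy_params()) {
  if (nchar(mirna_seq) < 1 || nchar(target_seq) < 1)
    stop("sequences must be non-empty")
  res <- .rcpp_duplex(encode_rna(mirna_seq), encode_rna(target_seq),
                      unclass(params))
  list(dg_hybrid = res$dg, pairing = res$pairing)
}

#' Minimum free energy secondary structure with unpaired constraints
#'
#' Zuker-style MFE folding under the reduced model (stacking energies,
#' linear hairpin/internal/bulge penalties, affine multiloops; no
#' dangles, no coaxial stacking, G.U allowed). Positions listed in
#' `forced_unpaired` are never paired. The empty structure is always
#' feasible, so the returned energy is <= 0.
#'
#' @param seq RNA sequence over A/C/G/U.
#' @param forced_unpaired integer vector of 0-based positions kept unpaired.
#' @param params an [energy_params()] object.
#' @return A list with `energy` (kcal/mol) and `structure` (dot-bracket).
#' @examples
#' fold_mfe("GGGAAAACCC")
#' @export
fold_mfe <- function(seq, forced_unpaired = integer(0), params = energy_params()) {
  if (nchar(seq) < 1) stop("sequence must be non-empty")
  forced_unpaired <- as.integer(forced_unpaired)
  if (length(forced_unpaired) &&
      (min(forced_unpaired) < 0 || max(forced_unpaired) >= nchar(seq)))
    stop("forced_unpaired indices out of range")
  res <- .rcpp_fold(encode_rna(seq), forced_unpaired, unclass(params))
  list(energy = res$energy, structure = res$structure)
}

#' Opening (disruption) energy of a target site
#'
#' The free-energy cost of making a site single-stranded: the UTR is
#' folded locally over the site plus `flank` nucleotides on each side,
#' once unconstrained and once with every site position forced unpaired;
#' the difference is the opening energy. It is always >= 0, and 0 exactly
#' when some unconstrained MFE structure already leaves the site open.
#'
#' @param utr_seq 3'-UTR sequence.
#' @param start,end site coordinates, 0-based half-open.
#' @param flank folding window extension on each side (nt).
#' @param params an [energy_params()] object.
#' @return Opening energy in kcal/mol (>= 0).
#' @export
opening_energy <- function(utr_seq, start, end, flank = 100,
                           params = energy_params()) {
  L <- nchar(utr_seq)
  if (start < 0 || end > L || start >= end)
    stop("site must satisfy 0 <= start < end <= UTR length")
  w0 <- max(0L, as.integer(start) - as.integer(flank))
  w1 <- min(L, as.integer(end) + as.integer(flank))
  window <- substr(utr_seq, w0 + 1L, w1)
  site_idx <- seq.int(start - w0, end - w0 - 1L)
  e_open <- .rcpp_fold(encode_rna(window), as.integer(site_idx),
                       unclass(params))$energy
  e_free <- .rcpp_fold(encode_rna(window), integer(0), unclass(params))$energy
  dg <- e_open - e_free
  if (dg < -1e-6) stop("internal error: negative opening energy")
  max(dg, 0)
}

#' Total hybridization energy as an accessibility measure
#'
#' Combines the duplex hybridization energy with the site opening
#' energy: `dg_total = dg_hybrid + dg_open`. The duplex is computed
#' against the site extended `hyb_flank` nucleotides toward the UTR
#' 5' end, where miRNA 3'-end pairing lands. Because `dg_open >= 0`,
#' a larger opening energy gives a larger (less negative) `dg_total`,
#' i.e. lower site accessibility. A site window with no pairable
#' nucleotides propagates the `+Inf` sentinel.
#'
#' @param utr_seq 3'-UTR sequence.
#' @param start,end site coordinates, 0-based half-open.
#' @param mirna_seq miRNA sequence, 5'->3'.
#' @param params an [energy_params()] object.
#' @param flank folding window extension for the opening energy (nt).
#' @param hyb_flank 5' extension of the duplex target window (nt).
#' @return A list with `dg_hybrid`, `dg_open` and `dg_total` (kcal/mol).
#' @export
delta_g_total <- function(utr_seq, start, end, mirna_seq,
                          params = energy_params(), flank = 100,
                          hyb_flank = 15) {
  L <- nchar(utr_seq)
  if (start < 0 || end > L || start >= end)
    stop("site must satisfy 0 <= start < end <= UTR length")
  h0 <- max(0L, as.integer(start) - as.integer(hyb_flank))
  target_window <- substr(utr_seq, h0 + 1L, end)
  dg_hyb <- duplex_energy(mirna_seq, target_window, params)$dg_hybrid
  dg_open <- opening_energy(utr_seq, start, end, flank, params)
  list(dg_hybrid = dg_hyb, dg_open = dg_open, dg_total = dg_hyb + dg_open)
}
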