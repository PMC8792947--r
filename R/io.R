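# Readers and writers for every external format the pipeline touches.
# All coordinates are 0-based, half-open, in transcript (3'-UTR) local space;
# BED and bedGraph inputs are interpreted per their standards, which already
# use that convention. DNA-alphabet input (T) is normalized to RNA (U) once,
# at parse time.

normalize_rna <- function(seq, what = "sequence") {
  out <- toupper(chartr("Tt", "Uu", seq))
  bad <- stringi::stri_locate_first_regex(out, "[^ACGU]")[, 1]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    stop(sprintf("invalid %s alphabet: non-ACGU character at position %d",
                 what, bad[i]))
  }
  out
}

read_fasta_raw <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(trimws(first), ">"))
    stop(sprintf("malformed FASTA '%s': line 1 does not start with '>'", path))
  x <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, "", 1)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate FASTA id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  setNames(as.character(x), ids)
}

#' Read 3'-UTR sequences from FASTA
#'
#' Sequences are case-folded to upper case and DNA T is normalized to U.
#' Non-ACGU characters and duplicate identifiers are errors.
#'
#' @param path FASTA file.
#' @param species_tag free-form species label attached to every record.
#' @return A data.frame with columns `transcript_id`, `utr3_seq`,
#'   `species_tag`.
#' @export
read_utr_fasta <- function(path, species_tag = "unspecified") {
  seqs <- read_fasta_raw(path)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence in FASTA: ", names(seqs)[nchar(seqs) == 0L][1])
  for (i in seq_along(seqs)) {
    seqs[i] <- tryCatch(normalize_rna(seqs[i], "UTR"),
                        error = function(e)
                          stop(sprintf("%s (transcript '%s')",
                                       conditionMessage(e), names(seqs)[i])))
  }
  data.frame(transcript_id = names(seqs), utr3_seq = unname(seqs),
             species_tag = species_tag, stringsAsFactors = FALSE)
}

#' Read miRNA sequences from FASTA
#'
#' @param path FASTA file; each sequence must be at least 8 nt (the seed
#'   region spans miRNA positions 1-8).
#' @return A data.frame with columns `mirna_id`, `seq`.
#' @export
read_mirna_fasta <- function(path) {
  seqs <- read_fasta_raw(path)
  seqs[] <- vapply(seqs, normalize_rna, "", what = "miRNA")
  if (any(nchar(seqs) < 8))
    stop("miRNA shorter than 8 nt: ", names(seqs)[nchar(seqs) < 8][1])
  data.frame(mirna_id = names(seqs), seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Read single-nucleotide m6A sites from BED
#'
#' BED is 0-based half-open; every record must be single-nucleotide
#' (end = start + 1). The chrom field carries the transcript identifier.
#' When `transcripts` is supplied, positions are checked against UTR
#' lengths (error) and the base at each position is checked to be A
#' (warning only; real modification maps contain edge cases).
#'
#' @param path BED3+ file.
#' @param transcripts optional transcript data.frame from [read_utr_fasta()].
#' @return A data.frame with columns `transcript_id`, `position`
#'   (0-based), `source_tag`.
#' @export
read_m6a_bed <- function(path, transcripts = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L)
    return(data.frame(transcript_id = character(0), position = integer(0),
                      source_tag = character(0), stringsAsFactors = FALSE))
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) != 1L))
    stop("m6A sites must be single-nucleotide (BED end = start + 1)")
  nm <- if (!is.null(gr$name)) as.character(gr$name) else rep("", length(gr))
  sites <- data.frame(
    transcript_id = as.character(GenomicRanges::seqnames(gr)),
    position = GenomicRanges::start(gr) - 1L,  # back to 0-based
    source_tag = nm, stringsAsFactors = FALSE)
  if (!is.null(transcripts)) {
    lens <- setNames(nchar(transcripts$utr3_seq), transcripts$transcript_id)
    unknown <- setdiff(sites$transcript_id, names(lens))
    if (length(unknown))
      stop("m6A sites on unknown transcript(s): ",
           paste(unique(unknown), collapse = ", "))
    bad <- sites$position < 0 | sites$position >= lens[sites$transcript_id]
    if (any(bad))
      stop("m6A position out of UTR range for: ",
           paste(unique(sites$transcript_id[bad]), collapse = ", "))
    seqs <- setNames(transcripts$utr3_seq, transcripts$transcript_id)
    base <- substr(seqs[sites$transcript_id], sites$position + 1L,
                   sites$position + 1L)
    if (any(base != "A"))
      warning(sprintf("%d m6A site(s) do not fall on an A", sum(base != "A")))
  }
  sites
}

EXPRESSION_HEADER <- c("transcript_id", "log2fc", "basal", "perturbation")

#' Read per-transcript expression response from TSV
#'
#' Expected header: `transcript_id  log2fc  basal  perturbation`, where
#' `log2fc` is the log2 fold change under miRNA perturbation, `basal`
#' the control-sample expression (>= 0), and `perturbation` one of
#' "overexpression" or "knockout".
#'
#' @param path TSV file.
#' @return A data.frame with those four columns.
#' @export
read_expression_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!identical(names(d), EXPRESSION_HEADER))
    stop("expression TSV header must be: ",
         paste(EXPRESSION_HEADER, collapse = "\\t"))
  if (any(!is.finite(d$log2fc))) stop("non-finite log2fc value(s)")
  if (any(!is.finite(d$basal)) || any(d$basal < 0))
    stop("basal expression must be finite and >= 0")
  if (!all(d$perturbation %in% c("overexpression", "knockout")))
    stop("perturbation must be 'overexpression' or 'knockout'")
  d
}

#' Read per-nucleotide conservation from bedGraph
#'
#' Expands half-open bedGraph intervals into one score per UTR
#' nucleotide. Positions not covered by any interval are missing (`NA`),
#' not zero; they are excluded from site conservation means downstream.
#'
#' @param path bedGraph file (chrom field = transcript id, scores in
#'   \[0,1\]).
#' @param transcripts transcript data.frame from [read_utr_fasta()].
#' @return A named list, one numeric vector (with `NA` gaps) per
#'   transcript present in the file.
#' @export
read_conservation_bedgraph <- function(path, transcripts) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  lens <- setNames(nchar(transcripts$utr3_seq), transcripts$transcript_id)
  ids <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(ids), names(lens))
  if (length(unknown))
    stop("conservation for unknown transcript(s): ",
         paste(unknown, collapse = ", "))
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)       # GRanges end is closed; back to half-open
  score <- gr$score
  if (any(score < 0 | score > 1))
    stop("conservation scores must lie in [0,1]")
  if (any(s0 < 0 | e0 > lens[ids] | s0 >= e0))
    stop("conservation interval outside UTR bounds")
  tracks <- lapply(setNames(nm = unique(ids)), function(id)
    rep(NA_real_, lens[[id]]))
  for (k in seq_along(ids)) {
    tracks[[ids[k]]][(s0[k] + 1L):e0[k]] <- score[k]
  }
  tracks
}

CHIMERA_HEADER <- c("mirna_id", "mirna_seq", "transcript_id",
                    "frag_start", "frag_end", "frag_seq")

#' Read CLASH chimera records from TSV
#'
#' Each record joins a miRNA to the target fragment it was ligated to.
#' Fragment coordinates are 0-based half-open on the UTR; `frag_seq`
#' must equal the corresponding UTR slice and be at least 15 nt.
#'
#' @param path TSV with header `mirna_id  mirna_seq  transcript_id
#'   frag_start  frag_end  frag_seq`.
#' @param transcripts transcript data.frame from [read_utr_fasta()].
#' @return A data.frame of validated chimera records.
#' @export
read_chimeras_tsv <- function(path, transcripts) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!identical(names(d), CHIMERA_HEADER))
    stop("chimera TSV header must be: ", paste(CHIMERA_HEADER, collapse = "\\t"))
  seqs <- setNames(transcripts$utr3_seq, transcripts$transcript_id)
  unknown <- setdiff(d$transcript_id, names(seqs))
  if (length(unknown))
    stop("chimeras on unknown transcript(s): ", paste(unique(unknown), collapse = ", "))
  d$mirna_seq <- vapply(d$mirna_seq, normalize_rna, "", what = "miRNA",
                        USE.NAMES = FALSE)
  d$frag_seq <- vapply(d$frag_seq, normalize_rna, "", what = "fragment",
                       USE.NAMES = FALSE)
  if (any(d$frag_end - d$frag_start < 15))
    stop("chimera fragments must be >= 15 nt")
  utr_slice <- substr(seqs[d$transcript_id], d$frag_start + 1L, d$frag_end)
  bad <- utr_slice != d$frag_seq
  if (any(bad))
    stop("chimera frag_seq does not match the UTR slice for: ",
         paste(unique(d$transcript_id[bad]), collapse = ", "))
  d
}

# ------------------------------------------------------------- writers ----

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(is.infinite(x), ifelse(x > 0, "Inf", "-Inf"),
                formatC(x, digits = 12, format = "g")))
}

write_tsv <- function(d, path) {
  num <- vapply(d, is.double, TRUE)
  d[num] <- lapply(d[num], fmt_num)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @param transcripts transcript data.frame.
#' @param path output file path.
#' @export
write_utr_fasta <- function(transcripts, path) {
  writeLines(paste0(">", transcripts$transcript_id, "\n", transcripts$utr3_seq),
             path)
  invisible(path)
}

write_mirna_fasta <- function(mirna, path) {
  writeLines(paste0(">", mirna$mirna_id, "\n", mirna$seq), path)
  invisible(path)
}

write_m6a_bed <- function(sites, path) {
  tag <- if (is.null(sites$source_tag)) rep("m6A", nrow(sites)) else sites$source_tag
  writeLines(sprintf("%s\t%d\t%d\t%s", sites$transcript_id, sites$position,
                     sites$position + 1L, tag), path)
  invisible(path)
}

write_expression_tsv <- function(expression, path) {
  write_tsv(expression[EXPRESSION_HEADER], path)
}

write_conservation_bedgraph <- function(tracks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (id in names(tracks)) {
    v <- tracks[[id]]
    ok <- which(!is.na(v))
    if (!length(ok)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", id, ok - 1L, ok, fmt_num(v[ok])), con)
  }
  invisible(path)
}

write_chimeras_tsv <- function(chimeras, path) {
  write_tsv(chimeras[CHIMERA_HEADER], path)
}

#' Write the analysis report tables
#'
#' Emits one TSV per result table held in an analysis object (see
#' [analyze_cohort()]): site classification, binding sites with
#' energies, the group comparisons and the confounder battery.
#'
#' @param results an `m6a_analysis` object.
#' @param dir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_report_tables <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(results$classification, file.path(dir, "classification.tsv"))
  write_tsv(results$sites, file.path(dir, "sites.tsv"))
  write_tsv(results$comparisons, file.path(dir, "comparisons.tsv"))
  write_tsv(results$confounders, file.path(dir, "confounders.tsv"))
  invisible(dir)
}
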