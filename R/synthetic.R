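# Synthetic cohort generator. Emulates the statistical structure of the
# study inputs -- 3'-UTR sequences with GC elevated on methylated
# transcripts, single-nucleotide m6A maps, planted canonical seed sites,
# log2 fold-change responses with a configurable m6A enhancement, basal
# expression, per-nucleotide conservation elevated at methylated sites, and
# CLASH-style chimeric fragments -- so the whole pipeline runs and is
# validated without downloads. All randomness flows from one seed through
# named per-stage substreams.

# sample() without the scalar-x surprise
resample <- function(x, k) x[sample.int(length(x), k)]

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
          else assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

#' Synthetic cohort configuration
#'
#' Defaults describe a cohort of 4000 transcripts with lognormal UTR
#' lengths (median ~665 nt), 45% background GC (+5 points on methylated
#' transcripts), half the transcripts methylated with ~2 m6A sites each
#' and methylation odds rising with UTR length, 60% of transcripts
#' receiving one planted seed site, a -0.2 log2FC targeting effect with
#' a -0.3 additional shift when the target is methylated, N(0, 0.5)
#' expression noise, Beta(2,5) per-nucleotide conservation with a +0.2
#' elevation at methylated site footprints, and 300 chimeric fragments.
#'
#' @param n_transcripts number of transcripts.
#' @param utr_len_meanlog,utr_len_sdlog lognormal UTR length parameters
#'   (lengths are clipped to \[50, 20000\] nt).
#' @param gc_base background GC fraction.
#' @param gc_m6a_shift extra GC fraction on methylated transcripts.
#' @param p_methylated marginal probability a transcript is methylated.
#' @param meth_length_slope log-odds increase of methylation per unit of
#'   centered log UTR length (methylated transcripts have longer UTRs,
#'   as in real maps; 0 decouples methylation from length).
#' @param m6a_per_tx_mean mean m6A sites per methylated transcript
#'   (1 + Poisson(mean - 1)).
#' @param p_target fraction of transcripts receiving a planted seed site.
#' @param site_type_mix probabilities over the four seed site types.
#' @param p_site_overlap_m6a probability the planted site on a
#'   methylated transcript contains an m6A position.
#' @param delta_target log2FC shift for all planted targets.
#' @param delta_m6a additional log2FC shift for methylated targets (the
#'   planted m6A enhancement).
#' @param delta_length_per_kb log2FC shift per kb of UTR length (capped
#'   at 5 kb) for targets; used to build length-confounded scenarios.
#' @param noise_sigma expression noise SD.
#' @param cons_shape1,cons_shape2 Beta parameters of per-nucleotide
#'   conservation.
#' @param cons_m6a_site_shift conservation elevation at m6A+ planted
#'   site footprints (clipped to 1).
#' @param cons_missing_rate fraction of track positions left missing.
#' @param basal_meanlog,basal_sdlog lognormal basal expression parameters.
#' @param perturbation "overexpression" or "knockout".
#' @param mirna_id,mirna_seq the perturbed miRNA (default let-7a).
#' @param n_chimeras number of chimeric fragments.
#' @param chimera_flank_range min/max extension of fragments beyond the
#'   planted site, per side (nt).
#' @param with_conservation,with_chimeras stage toggles.
#' @param species_tag species label for the transcripts.
#' @param rng_seed master seed (mandatory; no wall-clock seeding).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_transcripts = 4000,
                         utr_len_meanlog = 6.5, utr_len_sdlog = 0.9,
                         gc_base = 0.45, gc_m6a_shift = 0.05,
                         p_methylated = 0.5, meth_length_slope = 0.8,
                         m6a_per_tx_mean = 2,
                         p_target = 0.6,
                         site_type_mix = c(SIX_MER = 0.2, SEVEN_MER_A1 = 0.25,
                                           SEVEN_MER_M8 = 0.25, EIGHT_MER = 0.3),
                         p_site_overlap_m6a = 0.3,
                         delta_target = -0.2, delta_m6a = -0.3,
                         delta_length_per_kb = 0,
                         noise_sigma = 0.5,
                         cons_shape1 = 2, cons_shape2 = 5,
                         cons_m6a_site_shift = 0.2, cons_missing_rate = 0.05,
                         basal_meanlog = 5, basal_sdlog = 1,
                         perturbation = "overexpression",
                         mirna_id = "let-7a",
                         mirna_seq = "UGAGGUAGUAGGUUGUAUAGUU",
                         n_chimeras = 300,
                         chimera_flank_range = c(5, 15),
                         with_conservation = TRUE, with_chimeras = TRUE,
                         species_tag = "synthetic",
                         rng_seed = 1) {
  cfg <- as.list(environment())
  probs <- c(cfg$gc_base, cfg$p_methylated, cfg$p_target,
             cfg$p_site_overlap_m6a, cfg$cons_missing_rate, cfg$site_type_mix)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (abs(sum(cfg$site_type_mix) - 1) > 1e-9)
    stop("site_type_mix must sum to 1")
  if (!setequal(names(cfg$site_type_mix), SEED_TYPES))
    stop("site_type_mix must be named by the four seed site types")
  if (cfg$n_transcripts < 1) stop("n_transcripts must be >= 1")
  if (!cfg$perturbation %in% c("overexpression", "knockout"))
    stop("perturbation must be 'overexpression' or 'knockout'")
  if (nchar(cfg$mirna_seq) < 8) stop("miRNA must be at least 8 nt")
  if (max(SEED_WIDTHS) > 50)
    stop("planted site wider than the minimum UTR length")
  class(cfg) <- "synth_config"
  cfg
}

sample_bases <- function(n_per_tx, gc_per_tx) {
  N <- sum(n_per_tx)
  gc_rep <- rep(gc_per_tx, n_per_tx)
  is_gc <- runif(N) < gc_rep
  second <- runif(N) >= 0.5
  c("A", "U", "G", "C")[1L + second + 2L * is_gc]
}

#' Generate a synthetic cohort
#'
#' Deterministic given `config$rng_seed`. Planted sites are substituted
#' into the background sequence (never truncated), so generator truth is
#' exactly recoverable by the seed-site finder; chance background seed
#' matches are expected and allowed.
#'
#' @param config a [synth_config()] object.
#' @return An `m6a_cohort` list: `transcripts`, `m6a_sites`, `mirna`,
#'   `expression`, `conservation` (named list or NULL), `chimeras`
#'   (or NULL), `truth` (per-transcript truth table and planted-site
#'   table), and the `config`.
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  stage_seeds <- with_seed(cfg$rng_seed,
                           sample.int(.Machine$integer.max - 1L, 8L))
  n <- cfg$n_transcripts
  ids <- sprintf("tx%06d", seq_len(n))

  # -- lengths and methylation assignment
  len <- with_seed(stage_seeds[1], {
    pmin(pmax(round(rlnorm(n, cfg$utr_len_meanlog, cfg$utr_len_sdlog)), 50), 20000)
  })
  methylated <- with_seed(stage_seeds[2], {
    if (cfg$p_methylated %in% c(0, 1)) {
      rep(cfg$p_methylated == 1, n)
    } else {
      p <- plogis(qlogis(cfg$p_methylated) +
                    cfg$meth_length_slope * (log(len) - cfg$utr_len_meanlog))
      runif(n) < p
    }
  })

  # -- background sequence
  gc <- pmin(0.95, pmax(0.05, cfg$gc_base + cfg$gc_m6a_shift * methylated))
  seqs <- with_seed(stage_seeds[3], {
    bases <- sample_bases(len, gc)
    big <- stringi::stri_flatten(bases)
    to <- cumsum(len)
    stringi::stri_sub(big, to - len + 1L, to)
  })

  # -- plant one seed site per target transcript
  pats <- seed_site_patterns(cfg$mirna_seq)
  plant <- with_seed(stage_seeds[4], {
    is_target <- runif(n) < cfg$p_target
    ty <- rep(NA_character_, n)
    s0 <- rep(NA_integer_, n)
    ti <- which(is_target)
    if (length(ti)) {
      ty[ti] <- sample(names(cfg$site_type_mix), length(ti), replace = TRUE,
                       prob = cfg$site_type_mix)
      w <- SEED_WIDTHS[ty[ti]]
      s0[ti] <- as.integer(floor(runif(length(ti)) * (len[ti] - w + 1L)))
    }
    list(is_target = is_target, type = ty, start = s0)
  })
  ti <- which(plant$is_target)
  if (length(ti)) {
    w <- SEED_WIDTHS[plant$type[ti]]
    stringi::stri_sub(seqs[ti], plant$start[ti] + 1L, plant$start[ti] + w) <-
      pats[plant$type[ti]]
    # Break chance single-base extensions of a planted site into a wider
    # site type (e.g. a 6mer followed by an accidental A reads as a
    # 7mer-A1), which would shift the recoverable coordinates. The flanks
    # are set deterministically, so generation stays seed-reproducible.
    c8 <- substr(pats[["SEVEN_MER_M8"]], 1, 1)  # base that extends m8-ward
    alt_left <- if (c8 == "G") "C" else "G"
    for (q in seq_along(ti)) {
      i <- ti[q]
      ty <- plant$type[i]
      s <- plant$start[i]
      e <- s + SEED_WIDTHS[[ty]]
      if (ty %in% c("SIX_MER", "SEVEN_MER_A1") && s > 0 &&
          substr(seqs[i], s, s) == c8)
        substr(seqs[i], s, s) <- alt_left
      if (ty %in% c("SIX_MER", "SEVEN_MER_M8") && e < len[i] &&
          substr(seqs[i], e + 1L, e + 1L) == "A")
        substr(seqs[i], e + 1L, e + 1L) <- "C"
    }
  }
  site_end <- ifelse(plant$is_target,
                     plant$start + SEED_WIDTHS[plant$type], NA_integer_)

  # -- m6A sites (positions must be adenosines)
  m6a <- with_seed(stage_seeds[5], {
    mi <- which(methylated)
    k <- if (length(mi))
      1L + rpois(length(mi), max(0, cfg$m6a_per_tx_mean - 1)) else integer(0)
    overlap_draw <- runif(n) < cfg$p_site_overlap_m6a
    tx_out <- character(0); pos_out <- integer(0)
    site_has <- rep(FALSE, n)
    drop_meth <- integer(0)
    for (q in seq_along(mi)) {
      i <- mi[q]
      a_pos <- stringi::stri_locate_all_fixed(seqs[i], "A")[[1]][, 1]
      if (length(a_pos) == 0L || is.na(a_pos[1])) { drop_meth <- c(drop_meth, i); next }
      a_pos <- a_pos - 1L  # 0-based
      picked <- integer(0)
      in_site <- if (plant$is_target[i])
        a_pos >= plant$start[i] & a_pos < site_end[i] else rep(FALSE, length(a_pos))
      if (plant$is_target[i] && overlap_draw[i] && any(in_site)) {
        picked <- resample(a_pos[in_site], 1L)
        site_has[i] <- TRUE
      }
      rest <- a_pos[!in_site]
      need <- k[q] - length(picked)
      if (need > 0L && length(rest))
        picked <- c(picked, resample(rest, min(need, length(rest))))
      tx_out <- c(tx_out, rep(ids[i], length(picked)))
      pos_out <- c(pos_out, sort(picked))
    }
    list(sites = data.frame(transcript_id = tx_out, position = pos_out,
                            source_tag = rep("synthetic", length(tx_out)),
                            stringsAsFactors = FALSE),
         site_has_m6a = site_has, drop = drop_meth)
  })
  if (length(m6a$drop)) methylated[m6a$drop] <- FALSE

  # -- expression response
  expression <- with_seed(stage_seeds[6], {
    shift <- cfg$delta_target * plant$is_target +
      cfg$delta_m6a * (plant$is_target & methylated) +
      cfg$delta_length_per_kb * (pmin(len, 5000) / 1000) * plant$is_target
    if (cfg$perturbation == "knockout") shift <- -shift
    data.frame(transcript_id = ids,
               log2fc = rnorm(n, 0, cfg$noise_sigma) + shift,
               basal = rlnorm(n, cfg$basal_meanlog, cfg$basal_sdlog),
               perturbation = cfg$perturbation, stringsAsFactors = FALSE)
  })

  # -- conservation tracks
  conservation <- NULL
  if (cfg$with_conservation) {
    conservation <- with_seed(stage_seeds[7], {
      tr <- lapply(seq_len(n), function(i) {
        v <- rbeta(len[i], cfg$cons_shape1, cfg$cons_shape2)
        if (plant$is_target[i] && m6a$site_has_m6a[i]) {
          span <- (plant$start[i] + 1L):site_end[i]
          v[span] <- pmin(1, v[span] + cfg$cons_m6a_site_shift)
        }
        if (cfg$cons_missing_rate > 0)
          v[runif(len[i]) < cfg$cons_missing_rate] <- NA_real_
        v
      })
      setNames(tr, ids)
    })
  }

  # -- chimeric fragments around planted sites
  chimeras <- NULL
  if (cfg$with_chimeras && cfg$n_chimeras > 0 && length(ti)) {
    chimeras <- with_seed(stage_seeds[8], {
      pick <- ti[sample.int(length(ti), cfg$n_chimeras, replace = TRUE)]
      lf <- sample(cfg$chimera_flank_range[1]:cfg$chimera_flank_range[2],
                   cfg$n_chimeras, replace = TRUE)
      rf <- sample(cfg$chimera_flank_range[1]:cfg$chimera_flank_range[2],
                   cfg$n_chimeras, replace = TRUE)
      s <- pmax(0L, plant$start[pick] - lf)
      e <- pmin(len[pick], site_end[pick] + rf)
      short <- (e - s) < 15L
      e[short] <- pmin(len[pick[short]], s[short] + 15L)
      s[short] <- pmax(0L, e[short] - 15L)
      data.frame(mirna_id = cfg$mirna_id, mirna_seq = cfg$mirna_seq,
                 transcript_id = ids[pick], frag_start = as.integer(s),
                 frag_end = as.integer(e),
                 frag_seq = substr(seqs[pick], s + 1L, e),
                 stringsAsFactors = FALSE)
    })
  }

  truth_tx <- data.frame(
    transcript_id = ids, utr_len = as.integer(len), methylated = methylated,
    is_target = plant$is_target, site_type = plant$type,
    site_start = plant$start, site_end = as.integer(site_end),
    site_has_m6a = m6a$site_has_m6a, stringsAsFactors = FALSE)
  truth_sites <- truth_tx[truth_tx$is_target,
                          c("transcript_id", "site_start", "site_end",
                            "site_type", "site_has_m6a")]
  rownames(truth_sites) <- NULL

  structure(list(
    transcripts = data.frame(transcript_id = ids, utr3_seq = seqs,
                             species_tag = cfg$species_tag,
                             stringsAsFactors = FALSE),
    m6a_sites = m6a$sites,
    mirna = data.frame(mirna_id = cfg$mirna_id, seq = cfg$mirna_seq,
                       stringsAsFactors = FALSE),
    expression = expression,
    conservation = conservation,
    chimeras = chimeras,
    truth = list(transcripts = truth_tx, sites = truth_sites),
    config = cfg), class = "m6a_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits the file set the pipeline readers consume: `utr3.fa`,
#' `mirna.fa`, `m6a_sites.bed`, `expression.tsv`,
#' `conservation.bedgraph`, `chimeras.tsv`, plus the generator truth
#' tables (`truth_transcripts.tsv`, `truth_sites.tsv`).
#'
#' @param cohort an `m6a_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "m6a_cohort"))
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  write_utr_fasta(cohort$transcripts, file.path(dir, "utr3.fa"))
  write_mirna_fasta(cohort$mirna, file.path(dir, "mirna.fa"))
  write_m6a_bed(cohort$m6a_sites, file.path(dir, "m6a_sites.bed"))
  write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  if (!is.null(cohort$conservation))
    write_conservation_bedgraph(cohort$conservation,
                                file.path(dir, "conservation.bedgraph"))
  if (!is.null(cohort$chimeras))
    write_chimeras_tsv(cohort$chimeras, file.path(dir, "chimeras.tsv"))
  write_tsv(cohort$truth$transcripts, file.path(dir, "truth_transcripts.tsv"))
  write_tsv(cohort$truth$sites, file.path(dir, "truth_sites.tsv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @param species_tag species label for the transcripts.
#' @return An `m6a_cohort`-shaped list (without generator truth unless
#'   present on disk).
#' @export
read_cohort <- function(dir, species_tag = "unspecified") {
  transcripts <- read_utr_fasta(file.path(dir, "utr3.fa"), species_tag)
  mirna <- read_mirna_fasta(file.path(dir, "mirna.fa"))
  cons_path <- file.path(dir, "conservation.bedgraph")
  chim_path <- file.path(dir, "chimeras.tsv")
  structure(list(
    transcripts = transcripts,
    m6a_sites = read_m6a_bed(file.path(dir, "m6a_sites.bed"), transcripts),
    mirna = mirna,
    expression = read_expression_tsv(file.path(dir, "expression.tsv")),
    conservation = if (file.exists(cons_path))
      read_conservation_bedgraph(cons_path, transcripts) else NULL,
    chimeras = if (file.exists(chim_path))
      read_chimeras_tsv(chim_path, transcripts) else NULL,
    truth = NULL, config = NULL), class = "m6a_cohort")
}
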