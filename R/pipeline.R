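# End-to-end analysis orchestration: classification, site identification,
# energies, group comparisons, confounder battery, and the file-based
# run-all entry point used by the command-line script.

#' Analyze a cohort end to end
#'
#' Runs the full comparative analysis on an in-memory cohort: builds the
#' m6A index, finds seed sites, classifies transcripts and sites,
#' computes hybridization energies (and, with `energy = "full"`, opening
#' energies and dg_total), selects representative sites, scores site
#' conservation, forms the m6A+/m6A-/Others groups, runs the
#' regulation / conservation / GC / accessibility comparisons and the
#' confounder battery, and locates CLASH chimera sites when chimeras are
#' present.
#'
#' @param cohort an `m6a_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param params an [energy_params()] object.
#' @param energy "full" (hybridization energies for every site plus
#'   opening energies for representative sites), "hybrid"
#'   (hybridization only; accessibility comparisons and the
#'   median-6mer threshold are then unavailable), or "none" (skip
#'   thermodynamics entirely, for replicate studies of the group
#'   statistics).
#' @param flank,hyb_flank thermodynamic window parameters, nt.
#' @param dg_threshold passed to [build_regulation_groups()].
#' @param distance_cutoff m6A-distance split, nt.
#' @param proximal_window proximal-m6A window, nt.
#' @param bin_size,sample_size,resample_seed length bin-matched
#'   resampling parameters.
#' @param confounders logical; run the confounder battery.
#' @return An object of class `m6a_analysis`: list with `classification`,
#'   `sites`, `chimera_sites`, `groups`, `comparisons`, `confounders`,
#'   and the options used.
#' @export
analyze_cohort <- function(cohort, params = energy_params(),
                           energy = c("full", "hybrid", "none"),
                           flank = 100, hyb_flank = 15,
                           dg_threshold = "median6mer",
                           distance_cutoff = 100, proximal_window = 200,
                           bin_size = 500, sample_size = 3000,
                           resample_seed = 1, confounders = TRUE) {
  energy <- match.arg(energy)
  tx <- cohort$transcripts
  lens <- setNames(nchar(tx$utr3_seq), tx$transcript_id)
  index <- build_m6a_index(cohort$m6a_sites, tx$transcript_id)
  mirna <- as.list(cohort$mirna[1, ])

  sites <- find_seed_sites_cohort(tx, mirna)
  if (nrow(sites)) {
    sites$m6a_status <- classify_sites(sites, index)
    seqs <- setNames(tx$utr3_seq, tx$transcript_id)
    if (energy != "none") {
      for (i in seq_len(nrow(sites))) {
        h0 <- max(0L, sites$start[i] - hyb_flank)
        win <- substr(seqs[[sites$transcript_id[i]]], h0 + 1L, sites$end[i])
        sites$dg_hybrid[i] <- duplex_energy(mirna$seq, win, params)$dg_hybrid
      }
    }
    if (!is.null(cohort$conservation)) {
      for (i in seq_len(nrow(sites))) {
        tr <- cohort$conservation[[sites$transcript_id[i]]]
        if (!is.null(tr))
          sites$cons_score[i] <- site_conservation(sites$start[i],
                                                   sites$end[i], tr)
      }
    }
  }

  # ---- per-transcript classification and representative sites
  cl <- data.frame(transcript_id = tx$transcript_id,
                   utr_len = unname(lens),
                   gc = gc_content(tx$utr3_seq),
                   m6a_count = vapply(index[tx$transcript_id], length, 1L),
                   stringsAsFactors = FALSE)
  cl$tx_status <- ifelse(cl$m6a_count > 0L, "M6A_POS", "M6A_NEG")
  cl$klass <- "NONE"
  for (col in c("rep_start", "rep_end"))
    cl[[col]] <- NA_integer_
  cl$rep_site_type <- NA_character_
  for (col in c("rep_dg_hybrid", "rep_dg_open", "rep_dg_total"))
    cl[[col]] <- NA_real_
  cl$rep_site_status <- NA_character_
  cl$nearest_distance <- NA_integer_
  cl$rel_location <- NA_real_
  if (nrow(sites)) {
    wc <- site_width_class(sites$site_type)
    has78 <- tapply(wc >= 7L, sites$transcript_id, any)
    cl$klass[match(names(has78), cl$transcript_id)] <-
      ifelse(has78, "SEED_78", "SIXMER_ONLY")
    # representative site: widest class, then strongest dg_hybrid, then start
    ord <- order(sites$transcript_id, -wc, sites$dg_hybrid, sites$start)
    rep_ix <- ord[!duplicated(sites$transcript_id[ord])]
    if (energy == "full") {
      # opening energies are costly (two window folds per site); they are
      # computed for representative sites, which carry all downstream
      # accessibility comparisons
      seqs <- setNames(tx$utr3_seq, tx$transcript_id)
      for (i in rep_ix) {
        sites$dg_open[i] <- opening_energy(seqs[[sites$transcript_id[i]]],
                                           sites$start[i], sites$end[i],
                                           flank, params)
      }
      sites$dg_total <- sites$dg_hybrid + sites$dg_open
    }
    reps <- sites[rep_ix, , drop = FALSE]
    m <- match(reps$transcript_id, cl$transcript_id)
    cl$rep_start[m] <- reps$start
    cl$rep_end[m] <- reps$end
    cl$rep_site_type[m] <- reps$site_type
    cl$rep_dg_hybrid[m] <- reps$dg_hybrid
    cl$rep_dg_open[m] <- reps$dg_open
    cl$rep_dg_total[m] <- reps$dg_total
    cl$rep_site_status[m] <- reps$m6a_status
    cl$rel_location[m] <- relative_location(reps$start, lens[reps$transcript_id])
    for (k in seq_len(nrow(reps))) {
      i <- m[k]
      if (cl$m6a_count[i] > 0L)
        cl$nearest_distance[i] <- nearest_m6a_distance(
          list(transcript_id = reps$transcript_id[k],
               start = reps$start[k], end = reps$end[k]), index)
    }
  }

  # ---- chimera sites (CLASH)
  chimera_sites <- NULL
  if (!is.null(cohort$chimeras) && nrow(cohort$chimeras)) {
    found <- vector("list", nrow(cohort$chimeras))
    for (i in seq_len(nrow(cohort$chimeras))) {
      found[[i]] <- find_chimera_site(cohort$chimeras[i, ], params,
                                      hyb_flank = hyb_flank)
    }
    found <- found[!vapply(found, is.null, TRUE)]
    if (length(found)) {
      chimera_sites <- do.call(rbind, found)
      chimera_sites$m6a_status <- classify_sites(chimera_sites, index)
      if (!is.null(cohort$conservation)) {
        for (i in seq_len(nrow(chimera_sites))) {
          tr <- cohort$conservation[[chimera_sites$transcript_id[i]]]
          if (!is.null(tr))
            chimera_sites$cons_score[i] <- site_conservation(
              chimera_sites$start[i], chimera_sites$end[i], tr)
        }
      }
    }
  }

  # ---- groups and headline comparisons
  thr <- if (energy != "full" && identical(dg_threshold, "median6mer"))
    "none" else dg_threshold
  groups <- build_regulation_groups(cl, cohort$expression, thr)
  direction <- if (cohort$expression$perturbation[1] == "knockout")
    "positive_only" else "none"
  comparisons <- compare_regulation(groups, cohort$expression, direction)

  cmp_sites <- function(d, metric, value_col) {
    a <- d[[value_col]][d$m6a_status == "M6A_POS"]
    b <- d[[value_col]][d$m6a_status == "M6A_NEG"]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (!length(a) || !length(b)) return(NULL)
    group_comparison(metric, "m6a_pos_sites", "m6a_neg_sites", a, b)
  }
  if (nrow(sites) && !is.null(cohort$conservation))
    comparisons <- rbind(comparisons,
                         cmp_sites(sites, "site_conservation", "cons_score"))
  gc_a <- cl$gc[cl$transcript_id %in% groups$m6a_pos]
  gc_b <- cl$gc[cl$transcript_id %in% groups$m6a_neg]
  if (length(gc_a) && length(gc_b))
    comparisons <- rbind(comparisons,
                         group_comparison("gc_content", "m6a_pos", "m6a_neg",
                                          gc_a, gc_b))
  if (energy == "full" && nrow(sites))
    comparisons <- rbind(comparisons,
                         cmp_sites(sites, "dg_total", "dg_total"))
  if (!is.null(chimera_sites) && !is.null(cohort$conservation))
    comparisons <- rbind(comparisons,
                         cmp_sites(chimera_sites, "clash_site_conservation",
                                   "cons_score"))

  analysis <- structure(list(
    classification = cl, sites = sites, chimera_sites = chimera_sites,
    groups = groups, comparisons = comparisons, confounders = NULL,
    expression = cohort$expression, direction = direction,
    options = list(energy = energy, flank = flank, hyb_flank = hyb_flank,
                   dg_threshold = thr, distance_cutoff = distance_cutoff,
                   proximal_window = proximal_window, bin_size = bin_size,
                   sample_size = sample_size, resample_seed = resample_seed)),
    class = "m6a_analysis")
  if (confounders)
    analysis$confounders <- confounder_battery(analysis)
  analysis
}

#' Confounder battery
#'
#' Re-examines the regulation signal against six potential confounders:
#' (1) distance from the m6A site to the binding site (shorter vs longer
#' subsets at the cutoff); (2) 3'-UTR length -- the raw m6A+ vs m6A-
#' length KS plus the regulation comparison after 500-nt bin-matched
#' resampling; (3) relative site location within the UTR; (4) basal
#' expression in the control sample; (5) the 8mer share among
#' representative sites (two-proportion chi-square test); (6) the
#' regulation comparison restricted to proximal-only m6A+ targets
#' (m6A near but not overlapping the site).
#'
#' @param analysis an `m6a_analysis` from [analyze_cohort()].
#' @return A data.frame, one row per test: confounder, group sizes,
#'   statistic, p-value, note.
#' @export
confounder_battery <- function(analysis) {
  cl <- analysis$classification
  expr <- analysis$expression
  if (analysis$direction == "positive_only")
    expr <- expr[expr$log2fc > 0, , drop = FALSE]
  fc <- setNames(expr$log2fc, expr$transcript_id)
  basal <- setNames(analysis$expression$basal, analysis$expression$transcript_id)
  opt <- analysis$options
  g <- analysis$groups
  pos <- cl[cl$transcript_id %in% g$m6a_pos, , drop = FALSE]
  neg <- cl[cl$transcript_id %in% g$m6a_neg, , drop = FALSE]
  row <- function(confounder, n_a, n_b, statistic, p, note = "") {
    data.frame(confounder = confounder, n_a = n_a, n_b = n_b,
               statistic = statistic, p_value = p, note = note,
               stringsAsFactors = FALSE)
  }
  with_name <- function(name, f) {
    tryCatch(f(), error = function(e)
      stop(sprintf("confounder '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  out <- list()

  out$distance <- with_name("m6a_distance", function() {
    ds <- distance_subsets(pos, cutoff = opt$distance_cutoff)
    a <- fc[intersect(ds$shorter$transcript_id, names(fc))]
    b <- fc[intersect(ds$longer$transcript_id, names(fc))]
    ks <- ks_two_sample(a, b)
    row("m6a_distance_regulation", length(a), length(b), ks$D, ks$p,
        sprintf("shorter (<%d nt) vs longer", opt$distance_cutoff))
  })

  out$len_raw <- with_name("utr_length", function() {
    ks <- ks_two_sample(pos$utr_len, neg$utr_len)
    row("utr_length", nrow(pos), nrow(neg), ks$D, ks$p, "raw lengths")
  })

  out$len_matched <- with_name("utr_length_matched", function() {
    rs <- length_bin_resample(setNames(pos$utr_len, pos$transcript_id),
                              setNames(neg$utr_len, neg$transcript_id),
                              bin = opt$bin_size, size = opt$sample_size,
                              seed = opt$resample_seed)
    a <- fc[intersect(rs$pos_ids, names(fc))]
    b <- fc[intersect(rs$neg_ids, names(fc))]
    ks <- ks_two_sample(a, b)
    row("regulation_length_matched", length(a), length(b), ks$D, ks$p,
        sprintf("bin-matched resample, bin=%d, size=%d",
                opt$bin_size, opt$sample_size))
  })

  out$rel_loc <- with_name("relative_location", function() {
    ks <- ks_two_sample(pos$rel_location, neg$rel_location)
    row("relative_location", nrow(pos), nrow(neg), ks$D, ks$p, "")
  })

  out$basal <- with_name("basal_expression", function() {
    a <- basal[intersect(pos$transcript_id, names(basal))]
    b <- basal[intersect(neg$transcript_id, names(basal))]
    ks <- ks_two_sample(a, b)
    row("basal_expression", length(a), length(b), ks$D, ks$p, "control sample")
  })

  out$seed_prop <- with_name("seed_type_proportion", function() {
    x <- c(sum(pos$rep_site_type == "EIGHT_MER", na.rm = TRUE),
           sum(neg$rep_site_type == "EIGHT_MER", na.rm = TRUE))
    nn <- c(nrow(pos), nrow(neg))
    pt <- suppressWarnings(prop.test(x, nn))
    row("eightmer_proportion", nn[1], nn[2], unname(pt$statistic), pt$p.value,
        sprintf("8mer share %.3f vs %.3f", x[1] / nn[1], x[2] / nn[2]))
  })

  out$proximal <- with_name("proximal_m6a", function() {
    keep <- proximal_only_targets(pos, window = opt$proximal_window)
    a <- fc[intersect(keep$transcript_id, names(fc))]
    b <- fc[intersect(neg$transcript_id, names(fc))]
    ks <- ks_two_sample(a, b)
    row("proximal_only_regulation", length(a), length(b), ks$D, ks$p,
        sprintf("0 < d <= %d nt, no overlap", opt$proximal_window))
  })

  do.call(rbind, unname(out))
}

#' @export
print.m6a_analysis <- function(x, ...) {
  g <- x$groups
  cat("m6A/miRNA regulation analysis\n")
  cat(sprintf("  transcripts: %d; binding sites: %d\n",
              nrow(x$classification), nrow(x$sites)))
  cat(sprintf("  groups: m6A+ %d, m6A- %d, Others %d (excluded 6mer: %d)\n",
              length(g$m6a_pos), length(g$m6a_neg), length(g$others),
              length(g$excluded_6mer)))
  cat("  comparisons:\n")
  cmp <- x$comparisons
  for (i in seq_len(nrow(cmp)))
    cat(sprintf("    %-24s %s vs %s: D=%.3f, p=%.3g\n", cmp$metric[i],
                cmp$group_a[i], cmp$group_b[i], cmp$ks_D[i], cmp$p_value[i]))
  invisible(x)
}

#' Run configuration for the file-based pipeline
#'
#' @param fasta,m6a_bed,expression_tsv required input paths.
#' @param conservation_bedgraph,chimeras_tsv optional input paths.
#' @param mirna_fasta miRNA FASTA (first record used).
#' @param params_yaml optional energy-parameter YAML; package default
#'   otherwise.
#' @param out_dir output directory.
#' @param energy,flank,hyb_flank,dg_threshold,distance_cutoff,proximal_window,bin_size,sample_size
#'   analysis options, see [analyze_cohort()].
#' @param seed seed for the resampling stage.
#' @param species_tag species label.
#' @param plots write ECDF plots (PNG) alongside the tables.
#' @return A `run_config` list.
#' @export
run_config <- function(fasta, m6a_bed, expression_tsv, mirna_fasta,
                       out_dir, conservation_bedgraph = NULL,
                       chimeras_tsv = NULL, params_yaml = NULL,
                       energy = "full", flank = 100, hyb_flank = 15,
                       dg_threshold = "median6mer", distance_cutoff = 100,
                       proximal_window = 200, bin_size = 500,
                       sample_size = 3000, seed = 1,
                       species_tag = "unspecified", plots = FALSE) {
  rc <- as.list(environment())
  class(rc) <- "run_config"
  rc
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  required <- c("fasta", "m6a_bed", "expression_tsv", "mirna_fasta", "out_dir")
  miss <- setdiff(required, names(y))
  if (length(miss))
    stop("run config missing required field(s): ", paste(miss, collapse = ", "))
  do.call(run_config, y)
}

#' Run the full file-based analysis
#'
#' Reads the inputs named in the run configuration, analyzes the cohort,
#' and writes the report tables (classification, sites, comparisons,
#' confounders) plus run metadata to the output directory. Tables are
#' written with a `.partial` suffix while the run is in progress and
#' renamed on success, so an interrupted run is recognizable. A stage
#' failure aborts with the stage name. Outputs are deterministic: the
#' same configuration (including `seed`) yields byte-identical files.
#'
#' @param rc a [run_config()] object.
#' @return The `m6a_analysis`, invisibly.
#' @export
run_all <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  stage <- function(name, f) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(f(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[m6Amir] %-12s %6.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    r
  }
  inputs <- stage("read", function() {
    transcripts <- read_utr_fasta(rc$fasta, rc$species_tag)
    mirna <- read_mirna_fasta(rc$mirna_fasta)[1, , drop = FALSE]
    cons <- NULL
    if (!is.null(rc$conservation_bedgraph)) {
      if (!file.exists(rc$conservation_bedgraph))
        stop("conservation file not found: ", rc$conservation_bedgraph)
      cons <- read_conservation_bedgraph(rc$conservation_bedgraph, transcripts)
    }
    chim <- NULL
    if (!is.null(rc$chimeras_tsv)) {
      if (!file.exists(rc$chimeras_tsv))
        stop("chimera file not found: ", rc$chimeras_tsv)
      chim <- read_chimeras_tsv(rc$chimeras_tsv, transcripts)
    }
    structure(list(transcripts = transcripts,
                   m6a_sites = read_m6a_bed(rc$m6a_bed, transcripts),
                   mirna = mirna,
                   expression = read_expression_tsv(rc$expression_tsv),
                   conservation = cons, chimeras = chim,
                   truth = NULL, config = NULL), class = "m6a_cohort")
  })
  params <- stage("params", function() {
    if (is.null(rc$params_yaml)) energy_params()
    else read_energy_params(rc$params_yaml)
  })
  analysis <- stage("analyze", function()
    analyze_cohort(inputs, params = params, energy = rc$energy,
                   flank = rc$flank, hyb_flank = rc$hyb_flank,
                   dg_threshold = rc$dg_threshold,
                   distance_cutoff = rc$distance_cutoff,
                   proximal_window = rc$proximal_window,
                   bin_size = rc$bin_size, sample_size = rc$sample_size,
                   resample_seed = rc$seed))
  stage("write", function() {
    dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
    tabs <- list(classification = analysis$classification,
                 sites = analysis$sites,
                 comparisons = analysis$comparisons,
                 confounders = analysis$confounders)
    if (!is.null(analysis$chimera_sites))
      tabs$chimera_sites <- analysis$chimera_sites
    paths <- file.path(rc$out_dir, paste0(names(tabs), ".tsv"))
    for (i in seq_along(tabs))
      write_tsv(tabs[[i]], paste0(paths[i], ".partial"))
    meta <- data.frame(
      key = c("package", "version", "config_md5", "seed", "energy",
              "dg_threshold"),
      value = c("m6Amir", as.character(packageVersion("m6Amir")),
                config_md5(rc), as.character(rc$seed), rc$energy,
                as.character(rc$dg_threshold)), stringsAsFactors = FALSE)
    write_tsv(meta, file.path(rc$out_dir, "run_metadata.tsv.partial"))
    if (isTRUE(rc$plots)) write_plots(analysis, rc$out_dir)
    for (p in c(paths, file.path(rc$out_dir, "run_metadata.tsv")))
      file.rename(paste0(p, ".partial"), p)
    invisible(NULL)
  })
  invisible(analysis)
}

config_md5 <- function(rc) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(rc[order(names(rc))]), f)
  unname(tools::md5sum(f))
}

write_plots <- function(analysis, dir) {
  fc <- setNames(analysis$expression$log2fc, analysis$expression$transcript_id)
  g <- analysis$groups
  grDevices::png(file.path(dir, "regulation_ecdf.png"), width = 600, height = 600)
  plot_ecdf_comparison(list(`m6A+` = unname(fc[g$m6a_pos]),
                            `m6A-` = unname(fc[g$m6a_neg]),
                            Others = unname(fc[g$others])),
                       main = "miRNA-mediated regulation",
                       xlab = "log2 fold change")
  grDevices::dev.off()
  invisible(NULL)
}
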