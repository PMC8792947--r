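PAIR_NAMES <- c("AU", "UA", "CG", "GC", "GU", "UG")
# duplex-reversal image of each pair (5'X-Y3' read from the other strand)
PAIR_REV <- c(AU = "UA", UA = "AU", CG = "GC", GC = "CG", GU = "UG", UG = "GU")

#' Default base-pair stacking table
#'
#' A 6x6 matrix of stacking free energies (kcal/mol) indexed by
#' outer pair (row) and inner pair (column), over the allowed pairs
#' AU, UA, CG, GC, GU and UG. Values are negative (stabilizing) and of
#' Turner-rule magnitude, and the table is symmetric under duplex
#' reversal: `S[p, q] == S[rev(q), rev(p)]` where `rev` swaps the two
#' bases of a pair.
#'
#' @return A named 6x6 numeric matrix.
#' @export
default_stack_table <- function() {
  s <- matrix(c(
    # inner:  AU    UA    CG    GC    GU    UG
    -0.9, -1.1, -2.2, -2.1, -0.6, -1.4,  # outer AU
    -1.3, -0.9, -2.4, -2.1, -1.0, -1.3,  # outer UA
    -2.1, -2.1, -3.3, -2.4, -1.4, -2.1,  # outer CG
    -2.4, -2.2, -3.4, -3.3, -1.5, -2.5,  # outer GC
    -1.3, -1.4, -2.5, -2.1, -0.5, -0.4,  # outer GU
    -1.0, -0.6, -1.5, -1.4, -0.6, -0.5   # outer UG
  ), nrow = 6, byrow = TRUE, dimnames = list(PAIR_NAMES, PAIR_NAMES))
  s
}

#' Reduced nearest-neighbor energy parameters
#'
#' Builds the parameter set used by [duplex_energy()], [fold_mfe()],
#' [opening_energy()] and [delta_g_total()]. The model comprises
#' sequence-dependent stacking energies plus linear loop penalties
#' (`base + per_nt * loop_size`, all in kcal/mol) for hairpin, internal
#' and bulge loops, and an affine multiloop cost
#' `a + b * branches + c * unpaired` (branches include the closing pair).
#' Interior loops larger than `max_internal` unpaired nucleotides are
#' disallowed, the usual computational cap.
#'
#' @param stack 6x6 stacking matrix, see [default_stack_table()].
#' @param hairpin_base,hairpin_per_nt hairpin loop penalty (>= 0).
#' @param internal_base,internal_per_nt internal loop penalty (>= 0).
#' @param bulge_base,bulge_per_nt bulge loop penalty (>= 0).
#' @param multiloop_a,multiloop_b,multiloop_c affine multiloop terms (>= 0).
#' @param min_hairpin minimum hairpin loop size in nucleotides.
#' @param max_internal maximum total unpaired size of an interior loop.
#' @return An object of class `energy_params`.
#' @export
energy_params <- function(stack = default_stack_table(),
                          hairpin_base = 3.5, hairpin_per_nt = 0.3,
                          internal_base = 2.0, internal_per_nt = 0.35,
                          bulge_base = 3.0, bulge_per_nt = 0.35,
                          multiloop_a = 3.4, multiloop_b = 0.4,
                          multiloop_c = 0.1,
                          min_hairpin = 3L, max_internal = 30L) {
  p <- list(stack = stack,
            hairpin_base = hairpin_base, hairpin_per_nt = hairpin_per_nt,
            internal_base = internal_base, internal_per_nt = internal_per_nt,
            bulge_base = bulge_base, bulge_per_nt = bulge_per_nt,
            multiloop_a = multiloop_a, multiloop_b = multiloop_b,
            multiloop_c = multiloop_c,
            min_hairpin = as.integer(min_hairpin),
            max_internal = as.integer(max_internal))
  validate_energy_params(p)
  class(p) <- "energy_params"
  p
}

validate_energy_params <- function(p) {
  s <- p$stack
  if (!is.matrix(s) || !identical(dim(s), c(6L, 6L)))
    stop("stack table must be a 6x6 matrix")
  if (is.null(dimnames(s)) || !identical(rownames(s), PAIR_NAMES) ||
      !identical(colnames(s), PAIR_NAMES))
    stop("stack table must be named by pairs ", paste(PAIR_NAMES, collapse = ", "))
  if (any(s > 0))
    stop("stacking energies must be <= 0 (stabilizing)")
  for (a in PAIR_NAMES) for (b in PAIR_NAMES) {
    if (abs(s[a, b] - s[PAIR_REV[[b]], PAIR_REV[[a]]]) > 1e-9)
      stop(sprintf("stack table not symmetric under duplex reversal at (%s,%s)", a, b))
  }
  pen <- unlist(p[c("hairpin_base", "hairpin_per_nt", "internal_base",
                    "internal_per_nt", "bulge_base", "bulge_per_nt",
                    "multiloop_a", "multiloop_b", "multiloop_c")])
  if (any(!is.finite(pen)) || any(pen < 0))
    stop("loop and multiloop penalties must be finite and >= 0")
  if (p$min_hairpin < 1L) stop("min_hairpin must be >= 1")
  invisible(p)
}

#' Read energy parameters from a YAML file
#'
#' The file carries three sections: `stacks` (a nested map,
#' outer pair -> inner pair -> kcal/mol), `loops` (hairpin/internal/bulge
#' `base` and `per_nt`, `min_hairpin`, `max_internal`) and `multiloop`
#' (`a`, `b`, `c`). The default table shipped with the package is at
#' `system.file("extdata", "energy_params.yaml", package = "m6Amir")`.
#'
#' @param path YAML file path.
#' @return An `energy_params` object.
#' @export
read_energy_params <- function(path) {
  y <- yaml::read_yaml(path)
  if (!all(c("stacks", "loops", "multiloop") %in% names(y)))
    stop("energy parameter file must have sections: stacks, loops, multiloop")
  s <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_NAMES, PAIR_NAMES))
  for (a in PAIR_NAMES) for (b in PAIR_NAMES) {
    v <- y$stacks[[a]][[b]]
    if (is.null(v)) stop(sprintf("stack entry missing for (%s,%s)", a, b))
    s[a, b] <- as.numeric(v)
  }
  lo <- y$loops
  ml <- y$multiloop
  energy_params(stack = s,
                hairpin_base = lo$hairpin$base, hairpin_per_nt = lo$hairpin$per_nt,
                internal_base = lo$internal$base, internal_per_nt = lo$internal$per_nt,
                bulge_base = lo$bulge$base, bulge_per_nt = lo$bulge$per_nt,
                multiloop_a = ml$a, multiloop_b = ml$b, multiloop_c = ml$c,
                min_hairpin = lo$min_hairpin, max_internal = lo$max_internal)
}

#' Write energy parameters to a YAML file
#'
#' @param params an `energy_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energy_params <- function(params, path) {
  validate_energy_params(params)
  stacks <- lapply(setNames(PAIR_NAMES, PAIR_NAMES), function(a)
    as.list(setNames(params$stack[a, ], PAIR_NAMES)))
  y <- list(
    stacks = stacks,
    loops = list(
      hairpin = list(base = params$hairpin_base, per_nt = params$hairpin_per_nt),
      internal = list(base = params$internal_base, per_nt = params$internal_per_nt),
      bulge = list(base = params$bulge_base, per_nt = params$bulge_per_nt),
      min_hairpin = params$min_hairpin,
      max_internal = params$max_internal),
    multiloop = list(a = params$multiloop_a, b = params$multiloop_b,
                     c = params$multiloop_c))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @export
print.energy_params <- function(x, ...) {
  cat("Reduced nearest-neighbor energy parameters\n")
  cat(sprintf("  stacks: 6x6, range [%.2f, %.2f] kcal/mol\n",
              min(x$stack), max(x$stack)))
  cat(sprintf("  hairpin %.2f + %.2f/nt; internal %.2f + %.2f/nt; bulge %.2f + %.2f/nt\n",
              x$hairpin_base, x$hairpin_per_nt, x$internal_base,
              x$internal_per_nt, x$bulge_base, x$bulge_per_nt))
  cat(sprintf("  multiloop %.2f + %.2f/branch + %.2f/unpaired; min hairpin %d; max interior %d\n",
              x$multiloop_a, x$multiloop_b, x$multiloop_c,
              x$min_hairpin, x$max_internal))
  invisible(x)
}
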