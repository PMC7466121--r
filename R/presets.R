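#' Built-in reaction-condition presets
#'
#' Presets describing reverse transcription of yeast tRNA with EpiScript RT
#' in its magnesium reference buffer (3 mM MgCl2) and in buffers replacing
#' MgCl2 with MnCl2 at 0.5, 1, 3 and 5 mM. The two directly comparable
#' conditions carry reported average rates for m1A sites: under magnesium,
#' arrest 0.82 with a misincorporation mass of 0.54 given read-through;
#' under 3 mM manganese, arrest 0.24 and misincorporation mass 0.80 —
#' manganese promotes nucleotide skipping and misincorporation over
#' synthesis abortion. Intermediate concentrations interpolate between the
#' two anchors (effects peak at 3 mM and fall off slightly at 5 mM); the
#' additional m22G, m1G and m3C entries, the jump-class split and the
#' unmodified-site background (per-feature event probabilities in the
#' 0.5–2.5% range, higher under manganese) are package calibrations chosen
#' to be realistic rather than reported values. The manganese-driven jump
#' increase is carried by the delayed class so that the deletion classes
#' entering the coverage-drop arrest estimator (direct and double) stay
#' constant across conditions; see the package vignette.
#'
#' @return named list of [rt_condition_params()] objects, keyed by
#'   condition label (`"EpiScript_Mg_3mM"`, `"EpiScript_Mn_0.5mM"`,
#'   `"EpiScript_Mn_1mM"`, `"EpiScript_Mn_3mM"`, `"EpiScript_Mn_5mM"`).
#' @examples
#' builtin_presets()[["EpiScript_Mg_3mM"]]$per_mod[["m1A"]]$p_arrest
#' @export
builtin_presets <- function() {
  # misincorporation mass `mass` split over the off-bases of `ref` with
  # fixed composition; remaining mass is correct incorporation
  dist_for <- function(ref, mass, comp) {
    d <- setNames(numeric(5), c("A", "C", "G", "T", "N"))
    d[names(comp)] <- mass * comp
    d[ref] <- 1 - mass
    d
  }
  # mismatching-base composition observed to be prebase- and
  # modification-dependent; fixed per modification here
  comp_m1A <- c(G = 0.62, T = 0.31, C = 0.07)
  comp_m22G <- c(A = 0.50, T = 0.30, C = 0.20)
  comp_m1G <- c(T = 0.45, A = 0.35, C = 0.20)
  comp_m3C <- c(T = 0.70, A = 0.15, G = 0.15)

  m1A <- function(arrest, mass, delayed)
    mod_event_params(p_arrest = arrest, p_jump_direct = 0.005,
                     p_jump_delayed = delayed, p_jump_double = 0.020,
                     mismatch_dist = dist_for("A", mass, comp_m1A))
  m22G <- function(arrest, mass)
    mod_event_params(p_arrest = arrest, p_jump_direct = 0.004,
                     p_jump_delayed = 0.010, p_jump_double = 0.006,
                     mismatch_dist = dist_for("G", mass, comp_m22G))
  m1G <- function(arrest, mass)
    mod_event_params(p_arrest = arrest, p_jump_direct = 0.004,
                     p_jump_delayed = 0.008, p_jump_double = 0.005,
                     mismatch_dist = dist_for("G", mass, comp_m1G))
  m3C <- function(arrest, mass)
    mod_event_params(p_arrest = arrest, p_jump_direct = 0.003,
                     p_jump_delayed = 0.008, p_jump_double = 0.004,
                     mismatch_dist = dist_for("C", mass, comp_m3C))
  background <- function(scale)
    mod_event_params(p_arrest = 0.002 * scale,
                     p_jump_direct = 0.0005 * scale,
                     p_jump_delayed = 0.0005 * scale,
                     p_jump_double = 0.0002 * scale,
                     p_mismatch = min(0.010 * scale, 0.025))

  cond <- function(label, bg_scale, m1A_arrest, m1A_mass, m1A_delayed,
                   other_arrest, other_mass)
    rt_condition_params(
      label = label,
      per_mod = list(
        m1A = m1A(m1A_arrest, m1A_mass, m1A_delayed),
        m22G = m22G(other_arrest[1], other_mass[1]),
        m1G = m1G(other_arrest[2], other_mass[2]),
        m3C = m3C(other_arrest[3], other_mass[3])),
      background = background(bg_scale),
      n_molecules_per_ref = 500L, read_length = 75L,
      paired_fraction = 0.5)

  list(
    EpiScript_Mg_3mM = cond("EpiScript_Mg_3mM", 1,
                            0.82, 0.54, 0.015,
                            c(0.60, 0.55, 0.50), c(0.35, 0.30, 0.25)),
    `EpiScript_Mn_0.5mM` = cond("EpiScript_Mn_0.5mM", 1.3,
                                0.70, 0.62, 0.040,
                                c(0.52, 0.47, 0.42), c(0.38, 0.35, 0.32)),
    EpiScript_Mn_1mM = cond("EpiScript_Mn_1mM", 1.6,
                            0.50, 0.70, 0.080,
                            c(0.42, 0.38, 0.33), c(0.41, 0.42, 0.42)),
    EpiScript_Mn_3mM = cond("EpiScript_Mn_3mM", 2.2,
                            0.24, 0.80, 0.100,
                            c(0.25, 0.20, 0.18), c(0.45, 0.50, 0.55)),
    EpiScript_Mn_5mM = cond("EpiScript_Mn_5mM", 2.5,
                            0.30, 0.77, 0.090,
                            c(0.28, 0.24, 0.21), c(0.43, 0.47, 0.52)))
}

#' Read / write a reaction condition as YAML
#'
#' One YAML document per condition, holding the label, library settings,
#' the background [mod_event_params()] and one entry per modification code.
#'
#' @param cond an [rt_condition_params()] object.
#' @param path YAML file path.
#' @return `write_condition_yaml()` returns `path` invisibly;
#'   `read_condition_yaml()` returns the [rt_condition_params()] object.
#' @export
write_condition_yaml <- function(cond, path) {
  stopifnot(inherits(cond, "RTConditionParams"))
  as_plain <- function(p) {
    out <- list(p_arrest = p$p_arrest, p_jump_direct = p$p_jump_direct,
                p_jump_delayed = p$p_jump_delayed,
                p_jump_double = p$p_jump_double)
    if (!is.null(p$mismatch_dist))
      out$mismatch_dist <- as.list(p$mismatch_dist)
    else out$p_mismatch <- p$p_mismatch
    out
  }
  doc <- list(label = cond$label,
              n_molecules_per_ref = cond$n_molecules_per_ref,
              read_length = cond$read_length,
              paired_fraction = cond$paired_fraction,
              background = as_plain(cond$background),
              per_mod = lapply(cond$per_mod, as_plain))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_condition_yaml
#' @export
read_condition_yaml <- function(path) {
  if (!file.exists(path)) stop("condition file not found: ", path)
  doc <- yaml::read_yaml(path)
  from_plain <- function(p) {
    md <- if (!is.null(p$mismatch_dist)) unlist(p$mismatch_dist) else NULL
    mod_event_params(p_arrest = p$p_arrest %||% 0,
                     p_jump_direct = p$p_jump_direct %||% 0,
                     p_jump_delayed = p$p_jump_delayed %||% 0,
                     p_jump_double = p$p_jump_double %||% 0,
                     mismatch_dist = md,
                     p_mismatch = p$p_mismatch %||% 0)
  }
  rt_condition_params(
    label = doc$label,
    per_mod = lapply(doc$per_mod %||% list(), from_plain),
    background = from_plain(doc$background %||% list()),
    n_molecules_per_ref = doc$n_molecules_per_ref %||% 500L,
    read_length = doc$read_length %||% 75L,
    paired_fraction = doc$paired_fraction %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
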