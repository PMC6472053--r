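#' Proton assignment table for the milk lipid fraction
#'
#' Returns the fixed table of \eqn{^1}H resonance assignments used both to
#' simulate milk lipid-extract spectra and to annotate chemometric markers.
#' Chemical shifts follow the standard triacylglycerol assignments for milk
#' lipid extracts in CDCl3: terminal methyls at 0.88 ppm (generic chains),
#' 0.95 ppm (butyric) and 0.98 ppm (alpha-linolenic), bulk methylenes at
#' 1.27/1.29 ppm, C3 methylenes at 1.62 ppm (1.65 for butyric), allylic
#' protons at 2.02 ppm, alpha-carbonyl C2 protons at 2.33 ppm (2.32 ppm
#' distorted triplet, 3J = 7.2 Hz, for butyric), bis-allylic protons at
#' 2.77 ppm (linoleic, 2H) and 2.81 ppm (alpha-linolenic, 4H), glycerol
#' backbone protons at 4.15/4.28/5.27 ppm (TAG) and 3.73 ppm (1,2-DAG),
#' olefinic protons near 5.33 ppm, the caproleic terminal vinyl protons
#' (H10a 4.99, H10b 4.93, H9 5.80 ppm) and the conjugated-diene protons of
#' the CLA isomers (cis,trans H11 at 6.28 ppm; trans,trans H10/H11 at
#' 5.99 ppm).
#'
#' Proton counts are per acyl chain. Longitudinal relaxation times
#' \code{t1_s} drive the steady-state intensity weighting in simulation; the
#' caproleic terminal vinyl protons carry the slowest measured milk T1
#' (3.2 s), other groups carry typical lipid values between 0.7 and 2.5 s.
#'
#' @return A data frame with columns \code{species_id}, \code{group_label},
#'   \code{shift_ppm}, \code{protons_per_chain}, \code{multiplicity} (a list
#'   column of scalar couplings in Hz, one entry per coupled equivalent
#'   proton; empty numeric = singlet) and \code{t1_s}.
#' @seealso [integration_windows()], [simulate_spectrum()]
#' @export
#' @examples
#' tab <- assignment_table()
#' tab[tab$group_label == "CLA ct H11", "shift_ppm"]
assignment_table <- function() {
  row <- function(species, group, shift, protons, t1, mult = numeric(0)) {
    data.frame(species_id = species, group_label = group, shift_ppm = shift,
               protons_per_chain = protons, t1_s = t1,
               multiplicity = I(list(mult)), stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row("butyric",         "butyric CH3",          0.95, 3L, 1.1),
    row("butyric",         "butyric C3H2",         1.65, 2L, 0.9),
    row("butyric",         "butyric C2H2",         2.32, 2L, 1.0, c(7.2, 7.2)),
    row("saturated_pool",  "saturated CH3",        0.88, 3L, 1.1),
    row("saturated_pool",  "saturated chain CH2",  1.27, 20L, 0.9),
    row("saturated_pool",  "saturated C3H2",       1.62, 2L, 0.9),
    row("saturated_pool",  "saturated C2H2",       2.33, 2L, 1.0),
    row("oleic_pool",      "oleic CH3",            0.88, 3L, 1.1),
    row("oleic_pool",      "oleic chain CH2",      1.29, 20L, 0.9),
    row("oleic_pool",      "oleic C3H2",           1.62, 2L, 0.9),
    row("oleic_pool",      "oleic allylic",        2.02, 4L, 1.0),
    row("oleic_pool",      "oleic C2H2",           2.33, 2L, 1.0),
    row("oleic_pool",      "oleic olefinic",       5.33, 2L, 1.6),
    row("linoleic",        "linoleic CH3",         0.88, 3L, 1.1),
    row("linoleic",        "linoleic chain CH2",   1.29, 14L, 0.9),
    row("linoleic",        "linoleic C3H2",        1.62, 2L, 0.9),
    row("linoleic",        "linoleic allylic",     2.02, 4L, 1.0),
    row("linoleic",        "linoleic C2H2",        2.33, 2L, 1.0),
    row("linoleic",        "linoleic bis-allylic", 2.77, 2L, 1.3),
    row("linoleic",        "linoleic olefinic",    5.33, 4L, 1.6),
    row("alpha_linolenic", "linolenic CH3",        0.98, 3L, 1.1),
    row("alpha_linolenic", "linolenic chain CH2",  1.29, 8L, 0.9),
    row("alpha_linolenic", "linolenic C3H2",       1.62, 2L, 0.9),
    row("alpha_linolenic", "linolenic allylic",    2.02, 4L, 1.0),
    row("alpha_linolenic", "linolenic C2H2",       2.33, 2L, 1.0),
    row("alpha_linolenic", "linolenic bis-allylic", 2.81, 4L, 1.3),
    row("alpha_linolenic", "linolenic olefinic",   5.33, 6L, 1.6),
    row("cla_ct",          "CLA ct CH3",           0.88, 3L, 1.1),
    row("cla_ct",          "CLA ct chain CH2",     1.29, 16L, 0.9),
    row("cla_ct",          "CLA ct C3H2",          1.62, 2L, 0.9),
    row("cla_ct",          "CLA ct allylic",       2.02, 4L, 1.0),
    row("cla_ct",          "CLA ct C2H2",          2.33, 2L, 1.0),
    row("cla_ct",          "CLA ct H9",            5.33, 1L, 1.6),
    row("cla_ct",          "CLA ct H12",           5.64, 1L, 1.6),
    row("cla_ct",          "CLA ct H10",           5.93, 1L, 1.8),
    row("cla_ct",          "CLA ct H11",           6.28, 1L, 1.8),
    row("cla_tt",          "CLA tt CH3",           0.88, 3L, 1.1),
    row("cla_tt",          "CLA tt chain CH2",     1.29, 16L, 0.9),
    row("cla_tt",          "CLA tt C3H2",          1.62, 2L, 0.9),
    row("cla_tt",          "CLA tt allylic",       2.02, 4L, 1.0),
    row("cla_tt",          "CLA tt C2H2",          2.33, 2L, 1.0),
    row("cla_tt",          "CLA tt H9/H12",        5.60, 2L, 1.6),
    row("cla_tt",          "CLA tt H10/H11",       5.99, 2L, 1.8),
    row("caproleic",       "caproleic chain CH2",  1.27, 8L, 0.9),
    row("caproleic",       "caproleic C3H2",       1.62, 2L, 0.9),
    row("caproleic",       "caproleic allylic",    2.02, 2L, 1.0),
    row("caproleic",       "caproleic C2H2",       2.33, 2L, 1.0),
    row("caproleic",       "caproleic H10b",       4.93, 1L, 3.2),
    row("caproleic",       "caproleic H10a",       4.99, 1L, 3.2),
    row("caproleic",       "caproleic H9",         5.80, 1L, 2.5),
    # glycerol backbone signals: per glycerol unit, i.e. per three chains in
    # TAG; handled with fractional weight by the simulator, not per chain
    row("tag_backbone",    "TAG sn-1/3 Ha",        4.15, 2L, 0.7),
    row("tag_backbone",    "TAG sn-1/3 Hb",        4.28, 2L, 0.7),
    row("tag_backbone",    "TAG sn-2",             5.27, 1L, 0.7),
    row("dag_backbone",    "1,2-DAG 3'-CH2OH",     3.73, 2L, 0.7)
  )
  validate_assignments(tab)
  tab
}

#' Look up a single assignment by group label
#'
#' @param group_label exact group label as in [assignment_table()].
#' @param assignments assignment table; defaults to the shipped one.
#' @return one-row data frame.
#' @export
lookup_assignment <- function(group_label, assignments = assignment_table()) {
  hit <- assignments[assignments$group_label == group_label, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop("no assignment with group_label '", group_label, "'", call. = FALSE)
  }
  hit
}

validate_assignments <- function(tab) {
  stopifnot(is.data.frame(tab))
  need <- c("species_id", "group_label", "shift_ppm", "protons_per_chain",
            "t1_s", "multiplicity")
  if (!all(need %in% names(tab))) {
    stop("assignment table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$shift_ppm < 0 | tab$shift_ppm > 7)) {
    stop("assignment shift_ppm outside 0-7 ppm", call. = FALSE)
  }
  if (any(tab$protons_per_chain < 1)) stop("protons_per_chain must be >= 1", call. = FALSE)
  if (any(tab$t1_s <= 0)) stop("t1_s must be positive", call. = FALSE)
  invisible(tab)
}

# species the quantification equations address (and the simulator accepts)
fa_species <- function() {
  c("butyric", "saturated_pool", "oleic_pool", "linoleic",
    "alpha_linolenic", "cla_ct", "cla_tt", "caproleic")
}

#' Default integration windows for the quantification integrals
#'
#' One window per named integral (I0.88, I0.95, I2.02 = D, I2.33 = C, I2.77,
#' I2.81, I4.99, I5.80, I5.99, I6.28). The printed method names integral
#' centers only, so the bounds are a declared convention of this package:
#' each window isolates its signal from the neighbours in the assignment
#' table, the methyl windows jointly cover the 0.88/0.95/0.98 ppm methyls
#' (the 0.98 ppm alpha-linolenic methyl falls in I0.95), the allylic window
#' is the 1.93-2.09 ppm region, and the alpha-carbonyl window (2.23-2.43)
#' excludes the separately treated 2.09-2.18 ppm region while matching the
#' allylic window's Lorentzian tail truncation, keeping the D/C integral
#' ratio of the total-unsaturation equation unbiased.
#'
#' @param overrides optional named list of \code{c(lo, hi)} ppm bounds that
#'   replace individual defaults; windows must remain pairwise disjoint.
#' @return data frame with columns \code{name}, \code{lo_ppm}, \code{hi_ppm}.
#' @export
#' @examples
#' integration_windows()
#' integration_windows(list(`I2.33` = c(2.25, 2.38)))
integration_windows <- function(overrides = NULL) {
  win <- data.frame(
    name = c("I0.88", "I0.95", "I2.02", "I2.33", "I2.77",
             "I2.81", "I4.99", "I5.80", "I5.99", "I6.28"),
    lo_ppm = c(0.82, 0.92, 1.93, 2.23, 2.73, 2.79, 4.95, 5.75, 5.95, 6.22),
    hi_ppm = c(0.92, 1.02, 2.09, 2.43, 2.79, 2.85, 5.04, 5.86, 6.05, 6.33),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("window overrides must be a named list", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), win$name)
    if (length(unknown)) {
      stop("unknown window name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(overrides)) {
      b <- as.numeric(overrides[[nm]])
      if (length(b) != 2L || anyNA(b)) {
        stop("override for ", nm, " must be c(lo, hi)", call. = FALSE)
      }
      win[win$name == nm, c("lo_ppm", "hi_ppm")] <- b
    }
  }
  validate_windows(win)
  win
}

validate_windows <- function(win) {
  if (any(win$lo_ppm >= win$hi_ppm)) {
    bad <- win$name[win$lo_ppm >= win$hi_ppm]
    stop("window(s) with lo_ppm >= hi_ppm: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(win$lo_ppm)
  lo <- win$lo_ppm[ord]; hi <- win$hi_ppm[ord]; nm <- win$name[ord]
  if (any(lo[-1] < hi[-length(hi)])) {
    i <- which(lo[-1] < hi[-length(hi)])[1]
    stop("overlapping windows: ", nm[i], " and ", nm[i + 1L], call. = FALSE)
  }
  invisible(win)
}

#' Write / read the spectral library (assignments + windows) as YAML
#'
#' @param path file path.
#' @param assignments,windows tables as returned by [assignment_table()] and
#'   [integration_windows()].
#' @return `write_spectral_library()` returns `path` invisibly;
#'   `read_spectral_library()` returns `list(assignments, windows)`.
#' @export
write_spectral_library <- function(path, assignments = assignment_table(),
                                   windows = integration_windows()) {
  obj <- list(
    assignments = lapply(seq_len(nrow(assignments)), function(i) {
      list(species_id = assignments$species_id[i],
           group_label = assignments$group_label[i],
           shift_ppm = assignments$shift_ppm[i],
           protons_per_chain = assignments$protons_per_chain[i],
           multiplicity = as.numeric(assignments$multiplicity[[i]]),
           t1_s = assignments$t1_s[i])
    }),
    windows = lapply(seq_len(nrow(windows)), function(i) {
      list(name = windows$name[i], lo_ppm = windows$lo_ppm[i],
           hi_ppm = windows$hi_ppm[i])
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_spectral_library
#' @export
read_spectral_library <- function(path) {
  obj <- yaml::read_yaml(path)
  assignments <- do.call(rbind, lapply(obj$assignments, function(a) {
    data.frame(species_id = a$species_id, group_label = a$group_label,
               shift_ppm = a$shift_ppm,
               protons_per_chain = as.integer(a$protons_per_chain),
               t1_s = a$t1_s,
               multiplicity = I(list(as.numeric(unlist(a$multiplicity)))),
               stringsAsFactors = FALSE)
  }))
  windows <- do.call(rbind, lapply(obj$windows, function(w) {
    data.frame(name = w$name, lo_ppm = w$lo_ppm, hi_ppm = w$hi_ppm,
               stringsAsFactors = FALSE)
  }))
  validate_assignments(assignments)
  validate_windows(windows)
  list(assignments = assignments, windows = windows)
}
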