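#' Guide RNA specification
#'
#' A guide is described by its 20-nt protospacer (written as the non-target
#' strand / protospacer sequence, 5'->3', ending immediately adjacent to the
#' PAM) and an IUPAC PAM pattern (NGG for SpCas9, NRN for the near-PAMless
#' SpRY variant).
#'
#' @param protospacer 20-character string over A/C/G/T.
#' @param pam_pattern 3-character IUPAC string, default "NGG".
#' @return An object of class `guide_spec`.
#' @examples
#' hek4_guide()
#' @export
guide_spec <- function(protospacer, pam_pattern = "NGG") {
  protospacer <- toupper(protospacer)
  pam_pattern <- toupper(pam_pattern)
  if (nchar(protospacer) != 20L ||
      !all(strsplit(protospacer, "")[[1]] %in% DNA_BASES)) {
    stop("protospacer must be a 20-nt sequence over {A,C,G,T}")
  }
  if (nchar(pam_pattern) != 3L ||
      !all(strsplit(pam_pattern, "")[[1]] %in% names(IUPAC_SETS))) {
    stop("pam_pattern must be a 3-character IUPAC string")
  }
  structure(list(protospacer = protospacer, pam_pattern = pam_pattern),
            class = "guide_spec")
}

#' The HEK4 guide used throughout the worked examples
#'
#' The well-characterised, promiscuous HEK site 4 guide. Its protospacer has
#' cytosines at PAM-relative positions -18, -16 and -13 (the CBE target
#' cytosines) and the target adenine at -17 (the ABE target).
#'
#' @param pam_pattern PAM pattern, "NGG" by default.
#' @return A [guide_spec()].
#' @export
hek4_guide <- function(pam_pattern = "NGG") {
  guide_spec("GGCACTGCGGCTGGAGGTGG", pam_pattern)
}

#' @export
print.guide_spec <- function(x, ...) {
  cat("guide_spec:", x$protospacer, "+", x$pam_pattern, "PAM\n")
  invisible(x)
}

#' Base editor activity profile
#'
#' Describes the per-position conversion behaviour of a deaminase base editor
#' in PAM-relative coordinates (position -1 abuts the PAM; more negative is
#' PAM-distal). Conversion probabilities are the probability that the target
#' base is converted in a genome that carries an R-loop (occupancy 1).
#'
#' Two frames are modelled. `nts_window` holds conversions of `base_from` on
#' the non-target strand (NTS) -- the displaced ssDNA strand the deaminase
#' acts on. `ts_window` holds target-strand conversions, reported in the same
#' NTS coordinate frame (a TS cytosine edit at a plus-strand site appears on
#' the reference as G>A). Cytosine editors additionally show damped periodic
#' out-of-protospacer NTS editing tracking the DNA helical repeat.
#'
#' @param name profile label.
#' @param base_from,base_to conversion on the NTS, e.g. "C" -> "T".
#' @param nts_window named numeric, PAM-relative position -> probability.
#' @param ts_window named numeric for TS-frame conversions (empty for ABEs).
#' @param out_of_protospacer_period helical period in bp (NULL for ABEs).
#' @param context_multipliers named numeric: 5' neighbour base on the NTS ->
#'   multiplicative factor on the conversion probability (clipped at 1).
#' @param pam_pattern IUPAC PAM the editor's Cas9 requires.
#' @return An object of class `editor_profile`.
#' @seealso [cbe_ebe_profile()], [abe8e_profile()]
#' @export
editor_profile <- function(name, base_from, base_to, nts_window,
                           ts_window = numeric(0),
                           out_of_protospacer_period = NULL,
                           context_multipliers = c(A = 1, C = 1, G = 1, T = 1),
                           pam_pattern = "NGG") {
  stopifnot(base_from %in% DNA_BASES, base_to %in% DNA_BASES)
  if (length(nts_window) && (any(nts_window < 0) || any(nts_window > 1))) {
    stop("nts_window probabilities must lie in [0,1]")
  }
  if (length(ts_window) && (any(ts_window < 0) || any(ts_window > 1))) {
    stop("ts_window probabilities must lie in [0,1]")
  }
  structure(list(name = name, base_from = base_from, base_to = base_to,
                 nts_window = nts_window, ts_window = ts_window,
                 out_of_protospacer_period = out_of_protospacer_period,
                 context_multipliers = context_multipliers,
                 pam_pattern = toupper(pam_pattern)),
            class = "editor_profile")
}

#' @export
print.editor_profile <- function(x, ...) {
  cat("editor_profile:", x$name, sprintf("(%s>%s, PAM %s)\n",
      x$base_from, x$base_to, x$pam_pattern))
  cat("  NTS window positions:", paste(names(x$nts_window), collapse = " "),
      "\n")
  if (length(x$ts_window)) {
    cat("  TS window positions:", paste(names(x$ts_window), collapse = " "),
        "\n")
  }
  invisible(x)
}

# Damped cosine out-of-protospacer editing band for cytosine editors.
# Local maxima fall at -38, -49, -60 for the default 11-bp period.
periodic_band <- function(positions = -60:-31, amplitude = 0.08,
                          period = 11, phase_max = -38, damping = 0.97) {
  amp <- amplitude * damping^(abs(positions) - 31)
  p <- amp * (0.5 + 0.5 * cos(2 * pi * (positions - phase_max) / period))
  setNames(p, positions)
}

#' Default cytosine base editor (eBE / hA3A deaminase) profile
#'
#' A wide NTS C>T editing window peaking 13-19 bp 5' of the PAM, a secondary
#' target-strand band 20-30 bp 5' of the PAM, a damped ~11-bp periodic
#' out-of-protospacer component, and a 5'TC context preference characteristic
#' of the APOBEC3A deaminase. Window probabilities at the three HEK4 target
#' cytosines (-18, -16, -13) are set to the on-target conversion frequencies
#' this editor attains at full occupancy.
#'
#' @return An `editor_profile`.
#' @export
cbe_ebe_profile <- function() {
  nts <- c(`-19` = 0.30, `-18` = 0.683, `-17` = 0.55, `-16` = 0.783,
           `-15` = 0.50, `-14` = 0.45, `-13` = 0.644)
  nts <- c(periodic_band(), nts)
  ts <- setNames(0.25 * (1 - abs(-30:-20 + 25) / 6), -30:-20)
  editor_profile("CBE-eBE", "C", "T", nts_window = nts, ts_window = ts,
                 out_of_protospacer_period = 11,
                 context_multipliers = c(A = 1, C = 0.8, G = 0.7, T = 1.3),
                 pam_pattern = "NGG")
}

#' Default adenine base editor (ABE8e) profile
#'
#' A narrow NTS A>G window confined to 13-18 bp 5' of the PAM, no
#' target-strand activity and no out-of-protospacer component. The window
#' value at the HEK4 target adenine (-17) is the 70% on-target conversion at
#' full occupancy.
#'
#' @param pam_pattern "NGG" (wild type) or "NRN" (SpRY near-PAMless variant).
#' @return An `editor_profile`.
#' @export
abe8e_profile <- function(pam_pattern = "NGG") {
  nts <- c(`-18` = 0.20, `-17` = 0.70, `-16` = 0.55, `-15` = 0.45,
           `-14` = 0.30, `-13` = 0.15)
  nm <- if (pam_pattern == "NRN") "ABE8e-SpRY" else "ABE8e"
  editor_profile(nm, "A", "G", nts_window = nts,
                 context_multipliers = c(A = 1, C = 0.9, G = 1.1, T = 0.9),
                 pam_pattern = pam_pattern)
}

#' Look up a bundled editor profile by name
#' @param name one of "CBE-eBE", "ABE8e", "ABE8e-SpRY".
#' @return An `editor_profile`.
#' @export
get_editor_profile <- function(name) {
  switch(name,
         "CBE-eBE" = cbe_ebe_profile(),
         "ABE8e" = abe8e_profile("NGG"),
         "ABE8e-SpRY" = abe8e_profile("NRN"),
         stop("unknown editor profile: ", name))
}
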