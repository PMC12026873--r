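# Rule-based oral bioavailability screening.
#
# The Abbott bioavailability score estimates the probability of a compound
# reaching >10% oral bioavailability in rat from its charge state, polar
# surface area and rule-of-five compliance; it takes one of five values
# (0.11, 0.17, 0.55, 0.56, 0.85). Compounds are kept when the score meets
# a minimum (default 0.10).

#' Count rule-of-five violations for a physicochemical profile
#'
#' Violations among MW <= 500 g/mol, logP <= 5, H-bond donors <= 5,
#' H-bond acceptors <= 10. A profile "passes" with at most one violation.
#'
#' @param profile A list or one-row data.frame with numeric `mw`, `logp`,
#'   `hbd`, `hba`.
#' @return Integer count of violations (0-4).
#' @export
ro5_violations <- function(profile) {
  need <- c("mw", "logp", "hbd", "hba")
  miss <- need[!vapply(need, function(f)
    !is.null(profile[[f]]) && !is.na(profile[[f]]), TRUE)]
  if (length(miss)) np_stop("profile missing fields: ",
                            paste(miss, collapse = ", "))
  sum(profile$mw > 500, profile$logp > 5, profile$hbd > 5, profile$hba > 10)
}

#' Abbott bioavailability score from a physicochemical profile
#'
#' Rule table: for predominantly anionic species near pH 7, the score is
#' driven by topological polar surface area (TPSA > 150 A^2 -> 0.11;
#' 75 < TPSA <= 150 -> 0.56; TPSA <= 75 -> 0.85); otherwise it is driven
#' by rule-of-five compliance (pass, i.e. <= 1 violation -> 0.55;
#' fail -> 0.17). Deterministic: the same profile always yields the same
#' score.
#'
#' @param profile A list or one-row data.frame with `anionic` (logical),
#'   `tpsa` (A^2) and, for non-anionic species, `mw`, `logp`, `hbd`, `hba`
#'   (or a precomputed `ro5_violations` count).
#' @return One of 0.11, 0.17, 0.55, 0.56, 0.85.
#' @export
bioavailability_score <- function(profile) {
  if (is.null(profile$anionic) || is.na(profile$anionic)) {
    np_stop("profile missing fields: anionic")
  }
  if (isTRUE(as.logical(profile$anionic))) {
    if (is.null(profile$tpsa) || is.na(profile$tpsa)) {
      np_stop("profile missing fields: tpsa")
    }
    if (profile$tpsa > 150) return(0.11)
    if (profile$tpsa > 75) return(0.56)
    return(0.85)
  }
  v <- if (!is.null(profile$ro5_violations) &&
           !is.na(profile$ro5_violations)) {
    profile$ro5_violations
  } else {
    ro5_violations(profile)
  }
  if (v <= 1) 0.55 else 0.17
}

#' Screen compounds by bioavailability score
#'
#' Partitions a compound table into compounds kept (`bs >= bs_min`) and
#' removed, preserving input order. When a compound lacks a `bs` value it
#' is computed from its physicochemical columns; a compound with neither
#' is an error naming the compound. Supplying `bs` directly mirrors the
#' common workflow where scores come from an external ADME service.
#'
#' @param compounds data.frame with column `id` and either a numeric `bs`
#'   column or profile columns (`anionic`, `tpsa`, `mw`, `logp`, `hbd`, `hba`).
#' @param bs_min Minimum score to keep (default 0.10).
#' @return A list with `kept` and `removed` data.frames (each carrying a
#'   filled `bs` column) and a `report` list of counts.
#' @export
screen_compounds <- function(compounds, bs_min = 0.10) {
  check_fraction(bs_min, "bs_min")
  if (nrow(compounds) == 0) {
    out <- compounds
    out$bs <- numeric(0)
    return(list(kept = out, removed = out,
                report = list(n_in = 0L, n_kept = 0L, n_removed = 0L)))
  }
  if (is.null(compounds$id)) np_stop("compounds must have an 'id' column")
  bs <- if (!is.null(compounds$bs)) as.numeric(compounds$bs)
        else rep(NA_real_, nrow(compounds))
  for (i in which(is.na(bs))) {
    bs[i] <- tryCatch(
      bioavailability_score(compounds[i, , drop = FALSE]),
      error = function(e) np_stop(
        "compound '", compounds$id[i], "': no bs value and ",
        conditionMessage(e)))
  }
  if (any(bs < 0 | bs > 1)) {
    np_stop("bs values must lie in [0, 1] (offending compound: ",
            compounds$id[which(bs < 0 | bs > 1)[1]], ")")
  }
  compounds$bs <- bs
  keep <- bs >= bs_min
  list(kept = compounds[keep, , drop = FALSE],
       removed = compounds[!keep, , drop = FALSE],
       report = list(n_in = nrow(compounds), n_kept = sum(keep),
                     n_removed = sum(!keep)))
}
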