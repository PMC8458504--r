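# Post-classification verification: degradation-site proximity filter
# (pass iff the docked pose lies within 5.0 A of the tagged lysines,
# inclusive), chaperone-interface clash check, deterministic ranking.

#' Apply the degradation-site proximity filter
#'
#' A candidate passes iff its minimum pose-to-site distance is at most
#' `cutoff` (inclusive at exactly the cutoff; candidates farther than
#' the cutoff are discarded from the ranking but retained with
#' `site_pass = FALSE`).
#'
#' @param verdicts data.frame with at least `min_site_distance`.
#' @param cutoff proximity cutoff in Angstroms (default 5.0).
#' @return the data.frame with a logical `site_pass` column.
#' @export
apply_site_filter <- function(verdicts, cutoff = 5.0) {
  verdicts$site_pass <- verdicts$min_site_distance <= cutoff
  verdicts
}

#' Count clashes between a pose and an interface region
#'
#' Checks a candidate pose against the atoms of a (possibly deleted)
#' interface component, e.g. the chaperone peptide occupying the target
#' surface in the template complex.
#'
#' @param pose a pose (`$xyz`, `$elements`).
#' @param interface_xyz interface atom coordinates (n x 3).
#' @param interface_elements element symbols (default carbon).
#' @param tolerance clash tolerance in Angstroms.
#' @return integer clash count.
#' @export
interface_clash_check <- function(pose, interface_xyz,
                                  interface_elements = NULL,
                                  tolerance = 0.4) {
  interface_xyz <- rbind(interface_xyz)
  if (!nrow(interface_xyz)) stop("interface coordinate set is empty")
  nrow(find_clashes(pose$xyz, interface_xyz, tolerance = tolerance,
                    elementsA = pose$elements,
                    elementsB = interface_elements))
}

#' Rank screened candidates
#'
#' Passing candidates are ordered by classifier score (descending), with
#' ties broken by higher contact count and then lexicographic molecule
#' id; they receive ranks 1..n. Non-passing candidates follow, unranked
#' (`rank = NA`). The result is a pure function of its input: the same
#' verdicts give a byte-identical ordering.
#'
#' @param verdicts data.frame with `id`, `classifier_score`, `contacts`
#'   and `site_pass`.
#' @return the data.frame reordered, with a `rank` column.
#' @export
rank_candidates <- function(verdicts) {
  if (!nrow(verdicts)) stop("need at least one verdict")
  pass <- verdicts[verdicts$site_pass, , drop = FALSE]
  fail <- verdicts[!verdicts$site_pass, , drop = FALSE]
  if (nrow(pass)) {
    ord <- order(-pass$classifier_score, -pass$contacts, pass$id)
    pass <- pass[ord, , drop = FALSE]
    pass$rank <- seq_len(nrow(pass))
  } else pass$rank <- integer(0)
  if (nrow(fail)) {
    fail <- fail[order(fail$id), , drop = FALSE]
    fail$rank <- NA_integer_
  } else fail$rank <- integer(0)
  out <- rbind(pass, fail)
  rownames(out) <- NULL
  out
}
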