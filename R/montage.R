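#' Electrode montage for the infant segmentation paradigm
#'
#' Describes the 27-channel infant cap used by the analysis: twenty scalp
#' electrodes grouped into four quadrants of five (left/right x
#' frontal/posterior), seven electrodes excluded from analysis (the two
#' occipital sites and the midline), the linked-mastoid reference pair and
#' the two ocular (EOG) channels.
#'
#' The within-quadrant electrode order is meaningful: position 1..5 within
#' each quadrant is the level of the crossed five-level Electrode factor in
#' the repeated-measures ANOVA.
#'
#' @param quadrants named list of four character vectors of length 5.
#' @param excluded electrodes recorded but excluded from analysis.
#' @param reference the two mastoid channels (left, right).
#' @param eog the vertical and horizontal EOG channels.
#' @return An object of class `montage`.
#' @examples
#' m <- default_montage()
#' m$quadrants$left_frontal
#' @export
montage <- function(quadrants, excluded = character(), reference = c("M1", "M2"),
                    eog = c("VEOG", "HEOG")) {
  stopifnot(is.list(quadrants), length(quadrants) == 4L,
            !is.null(names(quadrants)))
  all_q <- unlist(quadrants, use.names = FALSE)
  if (anyDuplicated(all_q))
    abort("montage quadrants must be disjoint electrode sets")
  if (length(reference) != 2L)
    abort("montage needs exactly two reference (mastoid) channels")
  structure(list(quadrants = quadrants, excluded = excluded,
                 reference = reference, eog = eog),
            class = "montage")
}

#' @rdname montage
#' @export
default_montage <- function() {
  montage(
    quadrants = list(
      left_frontal    = c("F7", "F3", "FT7", "FC3", "C3"),
      right_frontal   = c("F8", "F4", "FC4", "FT8", "C4"),
      left_posterior  = c("LT", "LTP", "CP3", "LP", "P3"),
      right_posterior = c("RT", "RTP", "CP4", "RP", "P4")
    ),
    excluded = c("PO7", "PO8", "Fz", "FCz", "Cz", "Pz", "Oz")
  )
}

#' Analysis electrodes of a montage
#'
#' @param m a [montage].
#' @return Character vector of the 20 analysis electrodes, quadrant by
#'   quadrant in within-quadrant order.
#' @export
analysis_electrodes <- function(m) unlist(m$quadrants, use.names = FALSE)

#' Map electrodes to quadrant and within-quadrant position
#'
#' @param m a [montage].
#' @return A tibble with columns `electrode`, `quadrant`, `electrode_pos`.
#' @export
electrode_table <- function(m) {
  purrr::imap_dfr(m$quadrants, function(el, q)
    tibble::tibble(electrode = el, quadrant = q,
                   electrode_pos = seq_along(el)))
}

#' All channels a simulated recording carries
#' @noRd
recording_channels <- function(m) {
  c(analysis_electrodes(m), m$excluded, m$reference, m$eog)
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> 4 quadrants x 5 electrodes\n")
  for (q in names(x$quadrants))
    cat(sprintf("  %-16s %s\n", q, paste(x$quadrants[[q]], collapse = ", ")))
  cat("  excluded:       ", paste(x$excluded, collapse = ", "), "\n")
  cat("  reference:      ", paste(x$reference, collapse = ", "),
      "  eog:", paste(x$eog, collapse = ", "), "\n")
  invisible(x)
}
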