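# Named bundles of track-exclusion thresholds for the different assay modes.

#' Track filter policy
#'
#' A named bundle of the exclusion thresholds applied to spot-tracking output
#' before any velocity or displacement statistic is computed. Thresholds set
#' to `NULL` disable the corresponding rule.
#'
#' @param max_step maximum allowed displacement between adjacent frames
#'   (micrometres); larger steps indicate spurious floating-cell readings.
#' @param max_gap maximum allowed run of consecutive lost frames.
#' @param min_frames minimum number of detected frames per track.
#' @param annulus_min,annulus_max radial band (micrometres from the reference
#'   point) a track's first detection must fall in; both `NULL` disables the
#'   annulus rule. Requires a reference point at filter time.
#' @param max_total_path maximum total path length (micrometres) for the
#'   slow-subpopulation rule used by [mean_velocity()].
#' @param min_frames_subpop minimum frames for that subpopulation.
#' @return an object of class `filter_policy`.
#' @details Three presets mirror the standard assay modes:
#' \describe{
#'   \item{`policy_schistosome()`}{time-lapse tracking around a sporocyst:
#'     steps > 11.2 um excluded, gaps > 3 frames excluded, tracks >= 3 frames
#'     kept, first position restricted to the 70-240 um annulus around the
#'     prey (closer cells may already touch it by filopodia, farther cells sit
#'     at the field-of-view edge).}
#'   \item{`policy_cytation()`}{plate-reader motility assay: the reported mean
#'     velocity comes from the subpopulation of cells that migrated <= 60 um
#'     in total and were tracked for >= 18 frames.}
#'   \item{`policy_fluo4()`}{calcium-indicator assay: steps > 2.30 um
#'     excluded, gaps > 3 frames excluded; intensity analysis additionally
#'     requires complete traces (see [normalize_fluor()]).}
#' }
#' @export
filter_policy <- function(max_step = NULL, max_gap = NULL, min_frames = NULL,
                          annulus_min = NULL, annulus_max = NULL,
                          max_total_path = NULL, min_frames_subpop = NULL) {
  for (nm in c("max_step", "max_gap", "min_frames", "annulus_min",
               "annulus_max", "max_total_path", "min_frames_subpop")) {
    v <- get(nm)
    if (!is.null(v)) .check_nonneg(v, nm)
  }
  if (xor(is.null(annulus_min), is.null(annulus_max)))
    stop("give both `annulus_min` and `annulus_max`, or neither", call. = FALSE)
  if (!is.null(annulus_min) && annulus_min >= annulus_max)
    stop("`annulus_min` must be < `annulus_max`", call. = FALSE)
  structure(list(max_step = max_step, max_gap = max_gap,
                 min_frames = min_frames, annulus_min = annulus_min,
                 annulus_max = annulus_max, max_total_path = max_total_path,
                 min_frames_subpop = min_frames_subpop),
            class = "filter_policy")
}

#' @rdname filter_policy
#' @export
policy_schistosome <- function() {
  filter_policy(max_step = 11.2, max_gap = 3, min_frames = 3,
                annulus_min = 70, annulus_max = 240)
}

#' @rdname filter_policy
#' @export
policy_cytation <- function() {
  filter_policy(max_total_path = 60, min_frames_subpop = 18)
}

#' @rdname filter_policy
#' @export
policy_fluo4 <- function() {
  filter_policy(max_step = 2.30, max_gap = 3)
}

#' @export
print.filter_policy <- function(x, ...) {
  cat("<filter_policy>\n")
  for (nm in names(x)) if (!is.null(x[[nm]])) cat(sprintf("  %s: %g\n", nm, x[[nm]]))
  invisible(x)
}
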