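# Editing-window width, positional selectivity and editor comparison tables.

#' Editing-window width of a C-to-T profile
#'
#' The window is the minimal contiguous PAM-relative interval containing
#' every position whose activity is at least `relThreshold` times the
#' profile maximum; its width is the interval length in nt. The threshold
#' rule is a property of this package's reporting (field usage quotes widths
#' without a formal rule) and is therefore always emitted with the number.
#' The width is invariant under rescaling the profile by any positive
#' constant. An all-zero profile has width 0 and an empty interval.
#'
#' @param profile named numeric, C-to-T fraction per PAM-relative offset
#'   (names are offsets, values in `[0, 1]`).
#' @param relThreshold numeric(1) in (0, 1], fraction of the maximum
#'   activity a position must reach to belong to the window (default 0.3).
#' @return An [EditingWindow-class].
#' @export
windowWidth <- function(profile, relThreshold = 0.3) {
  if (length(profile) == 0L) stop("profile is empty", call. = FALSE)
  if (any(profile < 0 | profile > 1))
    stop("profile values must lie in [0, 1]", call. = FALSE)
  offs <- as.integer(names(profile))
  if (anyNA(offs)) stop("profile names must be integer offsets", call. = FALSE)
  rule <- sprintf("minimal contiguous interval covering all offsets with activity >= %.3g x max", relThreshold)
  mx <- max(profile)
  if (mx == 0) {
    return(new("EditingWindow", offsets = integer(0), width = 0L,
               rule = rule, threshold = relThreshold))
  }
  active <- offs[profile >= relThreshold * mx]
  interval <- seq.int(min(active), max(active))
  new("EditingWindow", offsets = interval, width = length(interval),
      rule = rule, threshold = relThreshold)
}

#' Positional selectivity (fold preference) of a focal position
#'
#' The activity at the focal offset divided by the maximum activity over the
#' neighbour offsets. When the neighbours are all inactive but the focal
#' position is not, the true fold is unbounded and a capped value
#' `profile[focal] / eps` is reported with attribute `capped = TRUE` (never
#' infinity). When both are zero the result is `NA`.
#'
#' @param profile named numeric profile as in [windowWidth()].
#' @param focal integer(1) focal PAM-relative offset.
#' @param neighbors integer vector of neighbour offsets; defaults to all
#'   other target offsets present in the profile.
#' @param eps numeric(1) denominator floor for capped reporting.
#' @return numeric(1) fold; attribute `"capped"` is `TRUE` when the bound
#'   was applied.
#' @export
positionalSelectivity <- function(profile, focal, neighbors = NULL,
                                  eps = 1e-6) {
  offs <- as.integer(names(profile))
  focal <- as.integer(focal)
  if (!focal %in% offs) stop("focal offset absent from profile", call. = FALSE)
  if (is.null(neighbors)) neighbors <- setdiff(offs, focal)
  neighbors <- as.integer(neighbors)
  if (length(neighbors) == 0L || !all(neighbors %in% offs))
    stop("neighbors must be a non-empty subset of the profile offsets",
         call. = FALSE)
  f <- unname(profile[match(focal, offs)])
  d <- max(profile[match(neighbors, offs)])
  if (d == 0) {
    if (f == 0) return(NA_real_)
    return(structure(f / eps, capped = TRUE))
  }
  structure(f / d, capped = FALSE)
}

#' Compare editors by window and selectivity metrics
#'
#' One row per editor: maximum activity, the offset attaining it, the window
#' width (with the rule's threshold), the positional selectivity at a focal
#' offset, and (when product distributions are supplied) the single-edit
#' product fraction at the focal offset.
#'
#' @param profiles named list of profiles (named numeric vectors sharing the
#'   same offset domain).
#' @param focal integer(1) focal offset for selectivity (default: the offset
#'   with the highest mean activity across editors).
#' @param relThreshold window threshold, see [windowWidth()].
#' @param distributions optional named list of
#'   [ProductDistribution-class] objects parallel to `profiles`.
#' @return data.frame with one row per editor.
#' @export
editorComparison <- function(profiles, focal = NULL, relThreshold = 0.3,
                             distributions = NULL) {
  if (length(profiles) == 0L) stop("no profiles supplied", call. = FALSE)
  domains <- lapply(profiles, function(p) sort(as.integer(names(p))))
  if (!all(vapply(domains, identical, logical(1), domains[[1L]])))
    stop("profiles must share the same offset domain", call. = FALSE)
  if (is.null(focal)) {
    avg <- Reduce(`+`, profiles) / length(profiles)
    focal <- as.integer(names(avg)[which.max(avg)])
  }
  rows <- lapply(names(profiles), function(ed) {
    p <- profiles[[ed]]
    w <- windowWidth(p, relThreshold)
    sel <- positionalSelectivity(p, focal)
    sef <- NA_real_
    if (!is.null(distributions) && !is.null(distributions[[ed]]))
      sef <- singleEditFraction(distributions[[ed]], focal)
    data.frame(editor = ed,
               maxActivity = max(p),
               argmaxOffset = as.integer(names(p)[which.max(p)]),
               windowWidth = w@width,
               windowThreshold = relThreshold,
               focalOffset = focal,
               selectivity = as.numeric(sel),
               selectivityCapped = isTRUE(attr(sel, "capped")),
               singleEditFraction = sef)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

setMethod("show", "EditingWindow", function(object) {
  cat("EditingWindow: width ", object@width, " nt",
      if (object@width > 0L)
        paste0(" [", min(object@offsets), " .. ", max(object@offsets), "]"),
      "\n  rule: ", object@rule, "\n", sep = "")
})
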