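#' Construct a planar scan
#'
#' Pairs one anterior and one posterior count matrix with the acquisition
#' metadata needed to turn counts into activity.
#'
#' @param anterior,posterior Matrices of non-negative counts, equal shape.
#' @param time_post_injection Time post injection (h), positive.
#' @param duration Acquisition duration (s), positive.
#' @param sensitivity Camera sensitivity (counts per MBq.s), positive.
#' @return An object of class `planar_scan`.
#' @export
planar_scan <- function(anterior, posterior, time_post_injection, duration,
                        sensitivity) {
  anterior <- as.matrix(anterior); posterior <- as.matrix(posterior)
  if (!identical(dim(anterior), dim(posterior)))
    stop("anterior and posterior matrices must share shape")
  if (any(anterior < 0) || any(posterior < 0))
    stop("count matrices must be non-negative")
  stopifnot(time_post_injection > 0, duration > 0, sensitivity > 0)
  structure(
    list(anterior = anterior, posterior = posterior,
         time_post_injection = time_post_injection,
         duration = duration, sensitivity = sensitivity),
    class = "planar_scan"
  )
}

# Coerce a render_planar_pair() result into a planar_scan.
as_planar_scan <- function(pair) {
  planar_scan(pair$anterior, pair$posterior,
              time_post_injection = pair$time_h,
              duration = pair$duration_s, sensitivity = pair$sensitivity)
}

#' Construct an ROI set
#'
#' Regions of interest are carried as an integer label mask over the image
#' frame: 0 is unassigned, each source (organ, lesion, whole body) has one
#' positive label, and one label is designated as background. Each source
#' also carries its body transmission factor `exp(-mu * thickness)` used by
#' the conjugate-view method.
#'
#' @param labels Integer matrix, same shape as the scans; 0 = unassigned.
#' @param sources Named integer vector mapping source id to label.
#' @param background_label Label of the background region, or `NA` to disable
#'   background correction.
#' @param transmission Named numeric vector in (0, 1]: per-source body
#'   transmission factor.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(labels, sources, background_label = NA_integer_,
                    transmission) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  stopifnot(is.numeric(sources), length(sources) >= 1L,
            !is.null(names(sources)), all(nzchar(names(sources))))
  sources <- vapply(sources, as.integer, integer(1))
  if (anyDuplicated(sources)) stop("source labels must be distinct")
  if (!is.na(background_label)) {
    if (background_label %in% sources)
      stop("background region must be disjoint from source regions")
    if (!any(labels == background_label))
      stop("background label absent from the mask")
  }
  missing_tx <- setdiff(names(sources), names(transmission))
  if (length(missing_tx))
    stop("missing transmission factor for: ", paste(missing_tx, collapse = ", "))
  tx <- transmission[names(sources)]
  if (any(tx <= 0 | tx > 1)) stop("transmission factors must lie in (0, 1]")
  for (s in names(sources))
    if (!any(labels == sources[[s]]))
      stop(sprintf("source '%s': empty ROI", s))
  structure(
    list(labels = labels, sources = sources,
         background_label = background_label, transmission = tx),
    class = "roi_set"
  )
}

#' ROI set matching a phantom
#'
#' Convenience constructor for synthetic studies: one rectangular ROI per
#' phantom organ, an optional whole-body ROI covering the full frame and a
#' background ROI in the first organ-free corner region. All sources share
#' the slab transmission factor `exp(-mu * thickness)`.
#'
#' @param spec A [phantom_spec()].
#' @param whole_body Add a `"whole body"` source covering the frame.
#' @param background Add a background region (16 organ-free pixels).
#' @return An [roi_set()].
#' @export
phantom_roi_set <- function(spec, whole_body = TRUE, background = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$image_dim
  labels <- matrix(0L, dims[1], dims[2])
  ids <- names(spec$organs)
  for (i in seq_along(spec$organs)) {
    fp <- spec$organs[[i]]$footprint
    labels[fp[1]:fp[2], fp[3]:fp[4]] <- i
  }
  sources <- stats::setNames(seq_along(ids), ids)
  bg_label <- NA_integer_
  if (background) {
    free <- which(labels == 0L)
    if (length(free) < 16L) stop("no organ-free pixels left for a background ROI")
    bg_label <- length(ids) + 1L
    labels[free[seq_len(16L)]] <- bg_label
  }
  wb <- NULL
  if (whole_body) {
    sources <- c(sources, "whole body" = length(ids) + 2L)
    wb <- length(ids) + 2L
  }
  tx <- exp(-spec$attenuation_coefficient * spec$body_thickness)
  rs <- structure(
    list(labels = labels, sources = sources, background_label = bg_label,
         transmission = stats::setNames(rep(tx, length(sources)),
                                        names(sources)),
         whole_body_label = wb),
    class = "roi_set"
  )
  rs
}

# Pixel mask for one source: the whole-body pseudo-label (if any) covers the
# entire frame, every other source is its label region.
roi_mask <- function(roiset, source) {
  lab <- roiset$sources[[source]]
  if (!is.null(roiset$whole_body_label) &&
      identical(lab, roiset$whole_body_label))
    matrix(TRUE, nrow(roiset$labels), ncol(roiset$labels))
  else roiset$labels == lab
}

#' Background-corrected ROI counts
#'
#' Sums anterior and posterior counts over the source ROI and subtracts the
#' mean background count per pixel (estimated from the background region)
#' times the ROI pixel count, flooring at zero.
#'
#' @param scan A [planar_scan()].
#' @param roiset An [roi_set()].
#' @param source Source id present in `roiset`.
#' @return A list with `anterior`, `posterior` (corrected counts), `n_pixels`
#'   and `clipped` (`TRUE` when the background estimate exceeded the raw ROI
#'   sum in either view and the result was floored at 0).
#' @export
roi_counts <- function(scan, roiset, source) {
  stopifnot(inherits(scan, "planar_scan"), inherits(roiset, "roi_set"))
  if (!source %in% names(roiset$sources))
    stop(sprintf("source '%s' not present in the ROI set", source))
  if (!identical(dim(scan$anterior), dim(roiset$labels)))
    stop("scan and ROI mask shapes differ")
  mask <- roi_mask(roiset, source)
  npx <- sum(mask)
  if (npx == 0L) stop(sprintf("source '%s': empty ROI", source))
  raw_a <- sum(scan$anterior[mask])
  raw_p <- sum(scan$posterior[mask])
  bg_a <- bg_p <- 0
  if (!is.na(roiset$background_label) &&
      !(!is.null(roiset$whole_body_label) &&
        identical(roiset$sources[[source]], roiset$whole_body_label))) {
    bmask <- roiset$labels == roiset$background_label
    bg_a <- mean(scan$anterior[bmask]) * npx
    bg_p <- mean(scan$posterior[bmask]) * npx
  }
  ca <- raw_a - bg_a
  cp <- raw_p - bg_p
  clipped <- ca < 0 || cp < 0
  if (clipped)
    warning(sprintf("source '%s': background exceeds ROI counts; floored at 0",
                    source))
  list(anterior = max(ca, 0), posterior = max(cp, 0), n_pixels = npx,
       clipped = clipped)
}

#' Conjugate-view (geometric-mean) activity estimate
#'
#' The geometric mean of anterior and posterior counts cancels the source
#' depth in a slab body, leaving the whole-body transmission correction:
#' `A = sqrt(cA * cP / transmission) / (sensitivity * duration)`.
#'
#' @param counts_anterior,counts_posterior Background-corrected counts, >= 0.
#' @param transmission Body transmission factor `exp(-mu * thickness)`,
#'   in (0, 1].
#' @param scan The [planar_scan()] providing sensitivity and duration.
#' @return Activity in MBq.
#' @examples
#' s <- planar_scan(matrix(0, 2, 2), matrix(0, 2, 2), 24, 100, 10)
#' conjugate_view_activity(8000, 2000, 0.16, s)  # 10 MBq
#' @export
conjugate_view_activity <- function(counts_anterior, counts_posterior,
                                    transmission, scan) {
  if (counts_anterior < 0 || counts_posterior < 0)
    stop("counts must be non-negative")
  if (transmission <= 0 || transmission > 1)
    stop("transmission must lie in (0, 1]")
  sqrt(counts_anterior * counts_posterior / transmission) /
    (scan$sensitivity * scan$duration)
}

#' Build time-activity series from a scan sequence
#'
#' Applies ROI summation, background correction and the conjugate-view
#' estimator to every source at every time point and expresses the result as
#' fraction of injected activity. Optionally rescales all fractions so the
#' whole-body ROI at the first scan equals 1 (whole-body normalisation).
#'
#' @param scans List of [planar_scan()] at strictly increasing times, >= 2.
#' @param roiset An [roi_set()].
#' @param injected_activity Injected activity (MBq).
#' @param normalize_first_wholebody Rescale so the first whole-body fraction
#'   is exactly 1 (default `FALSE`).
#' @return Data frame of class `timed_activity_samples` with columns
#'   `source`, `time_h`, `fraction_ia`, `sd`.
#' @export
build_time_activity_series <- function(scans, roiset, injected_activity,
                                       normalize_first_wholebody = FALSE) {
  stopifnot(length(scans) >= 2L,
            all(vapply(scans, inherits, logical(1), "planar_scan")),
            injected_activity > 0)
  times <- vapply(scans, `[[`, numeric(1), "time_post_injection")
  if (any(diff(times) <= 0)) stop("scan times must be strictly increasing")
  if (normalize_first_wholebody && !"whole body" %in% names(roiset$sources))
    stop("whole-body ROI required when normalize_first_wholebody is set")
  rows <- list()
  for (scan in scans) {
    k <- scan$sensitivity * scan$duration
    for (src in names(roiset$sources)) {
      cc <- roi_counts(scan, roiset, src)
      a <- conjugate_view_activity(cc$anterior, cc$posterior,
                                   roiset$transmission[[src]], scan)
      # delta-method Poisson SD of the geometric mean, in fraction units
      sd_a <- if (cc$anterior > 0 && cc$posterior > 0)
        a / 2 * sqrt(1 / cc$anterior + 1 / cc$posterior) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        source = src, time_h = scan$time_post_injection,
        fraction_ia = a / injected_activity,
        sd = sd_a / injected_activity)
    }
  }
  out <- do.call(rbind, rows)
  if (normalize_first_wholebody) {
    f0 <- out$fraction_ia[out$source == "whole body" &
                            out$time_h == min(out$time_h)]
    if (length(f0) != 1L || f0 <= 0)
      stop("cannot normalise: first whole-body fraction missing or zero")
    out$fraction_ia <- out$fraction_ia / f0
    out$sd <- out$sd / f0
  }
  class(out) <- c("timed_activity_samples", "data.frame")
  out
}
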