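#' Trace tight-junction strands along the edges of a segmented vessel
#'
#' Junctional reporters appear in maximum-intensity projections as strands
#' running along the two long edges of each vessel. For each edge, the
#' expected strand path is constructed by offsetting the vessel centerline
#' by its local radius along the path normal; the junction channel is
#' sampled along that path (maximum over a short probe perpendicular to the
#' path, robust to sub-pixel offset error) and compared with the foreground
#' threshold (mean + 2 population sd of a background ROI by default). An
#' edge with any supra-threshold signal yields one strand; a vessel with no
#' junction signal on either edge yields a single record flagged
#' `absent = TRUE` (capturing vessels that have lost their strands
#' entirely).
#'
#' @param junction_image 2-D numeric matrix (junction reporter channel).
#' @param vessel A `vessel_segment` from [segment_vessels()].
#' @param pixel_size um per pixel.
#' @param background_roi Logical matrix of background pixels (used when
#'   `threshold` is NULL).
#' @param threshold Optional explicit foreground threshold.
#' @param step_px Sampling step along the path, pixels.
#' @param probe_halfwidth_px Perpendicular probe half-width, pixels.
#' @return List of `tj_strand` objects: `id`, `vessel`, `side`, `path`
#'   (row/col matrix), `step_um`, `profile`, `present`, `threshold`,
#'   `absent`, `length_um`.
#' @export
trace_tj_strands <- function(junction_image, vessel, pixel_size,
                             background_roi = NULL, threshold = NULL,
                             step_px = 0.5, probe_halfwidth_px = 2) {
  stopifnot(inherits(vessel, "vessel_segment"))
  if (is.null(threshold)) {
    if (is.null(background_roi))
      stop("supply either a background ROI or an explicit threshold", call. = FALSE)
    v <- junction_image[background_roi]
    threshold <- mean(v) + 2 * sd_pop(v)
  }
  cl <- vessel$centerline
  absent_record <- function() {
    structure(list(id = 1L, vessel = vessel$id, side = NA_real_,
                   path = matrix(numeric(0), 0, 2), step_um = step_px * pixel_size,
                   profile = numeric(0), present = logical(0),
                   threshold = threshold, absent = TRUE, length_um = 0),
              class = "tj_strand")
  }
  if (is.null(cl) || nrow(cl) < 5L) return(list(absent_record()))
  path <- resample_path(smooth_path(cl, 9L), step_px)
  m <- nrow(path)
  if (m < 3L) return(list(absent_record()))
  # central-difference tangents, then unit normals
  tang <- rbind(path[2, ] - path[1, ],
                (path[-(1:2), , drop = FALSE] - path[1:(m - 2), , drop = FALSE]) / 2,
                path[m, ] - path[m - 1, ])
  norms <- sqrt(rowSums(tang^2)); norms[norms == 0] <- 1
  tang <- tang / norms
  nrm <- cbind(-tang[, 2], tang[, 1])
  offs <- seq(-probe_halfwidth_px, probe_halfwidth_px, by = 1)

  strands <- list()
  for (side in c(1, -1)) {
    base <- path + side * vessel$radius_px * nrm
    prof <- rep(-Inf, m)
    for (o in offs) {
      q <- base + o * nrm
      prof <- pmax(prof, bilinear(junction_image, q[, 1], q[, 2]))
    }
    present <- prof > threshold
    if (!any(present)) next
    strands[[length(strands) + 1L]] <- structure(list(
      id = length(strands) + 1L, vessel = vessel$id, side = side,
      path = base, step_um = step_px * pixel_size, profile = prof,
      present = present, threshold = threshold, absent = FALSE,
      length_um = (m - 1) * step_px * pixel_size),
      class = "tj_strand")
  }
  if (length(strands) == 0) return(list(absent_record()))
  strands
}

#' Measure gap lengths along a tight-junction strand
#'
#' A gap is a maximal contiguous run of sampling points along the strand's
#' expected path whose junction intensity falls below the foreground
#' threshold, between the first and last supra-threshold points (the strand
#' ends themselves are not gaps). Gap length = run length x sampling step;
#' runs shorter than `gap_min` (default 0.4 um, the detection floor of the
#' assay) are discarded.
#'
#' @param strand A `tj_strand` from [trace_tj_strands()].
#' @param gap_min Minimum reportable gap length, um.
#' @return Numeric vector of gap lengths in um (empty for continuous or
#'   absent strands).
#' @export
measure_gaps <- function(strand, gap_min = 0.4) {
  stopifnot(inherits(strand, "tj_strand"))
  if (strand$absent) return(numeric(0))
  pr <- strand$present
  first <- which(pr)[1]
  last <- max(which(pr))
  if (last - first < 2L) return(numeric(0))
  runs <- rle(pr[first:last])
  lens <- runs$lengths[!runs$values] * strand$step_um
  lens[lens >= gap_min]
}

#' Bin strand gaps and report per-bin strand fractions
#'
#' A strand counts once in the small-gap bin if it has at least one gap in
#' `[0.4, 2.5]` um (closed interval) and once in the big-gap bin if any gap
#' exceeds 2.5 um (the pathological cutoff). Fractions are over strands
#' with detectable signal; absent strands are reported separately.
#'
#' @param strands List of `tj_strand` objects, each carrying a `gaps`
#'   element (as produced by [quantify_tj()], or attach [measure_gaps()]
#'   output yourself).
#' @param small_range um, default `c(0.4, 2.5)`.
#' @param big_cutoff um, default 2.5 (exclusive lower bound of the big bin).
#' @return List with `per_strand` (data frame), `n_strands`, `n_present`,
#'   `n_absent`, `frac_gap_small`, `frac_gap_big`, `frac_absent`, and
#'   `undefined` (TRUE when no strands with signal exist).
#' @export
bin_gaps_and_fractions <- function(strands, small_range = c(0.4, 2.5),
                                   big_cutoff = 2.5) {
  if (length(strands) == 0) stop("no strands supplied", call. = FALSE)
  per <- do.call(rbind, lapply(seq_along(strands), function(i) {
    s <- strands[[i]]
    g <- s$gaps %||% numeric(0)
    data.frame(strand = i, vessel = s$vessel, side = s$side, absent = s$absent,
               n_gaps = length(g),
               has_gap_small = any(g >= small_range[1] & g <= small_range[2]),
               has_gap_big = any(g > big_cutoff))
  }))
  n_present <- sum(!per$absent)
  undef <- n_present == 0
  list(per_strand = per,
       n_strands = nrow(per), n_present = n_present, n_absent = sum(per$absent),
       frac_gap_small = if (undef) NA_real_ else sum(per$has_gap_small[!per$absent]) / n_present,
       frac_gap_big = if (undef) NA_real_ else sum(per$has_gap_big[!per$absent]) / n_present,
       frac_absent = sum(per$absent) / nrow(per),
       undefined = undef)
}

#' Trace, measure and bin tight-junction gaps for a set of vessels
#'
#' Convenience wrapper running [trace_tj_strands()] and [measure_gaps()]
#' for every vessel and summarizing with [bin_gaps_and_fractions()].
#'
#' @inheritParams trace_tj_strands
#' @param vessels List of `vessel_segment`.
#' @param gap_min Minimum reportable gap, um.
#' @return List with `strands` (each with `$gaps` attached) and `summary`.
#' @export
quantify_tj <- function(junction_image, vessels, pixel_size,
                        background_roi = NULL, threshold = NULL,
                        gap_min = 0.4) {
  strands <- list()
  for (v in vessels) {
    st <- trace_tj_strands(junction_image, v, pixel_size,
                           background_roi = background_roi, threshold = threshold)
    for (s in st) {
      s$gaps <- measure_gaps(s, gap_min = gap_min)
      strands[[length(strands) + 1L]] <- s
    }
  }
  list(strands = strands, summary = bin_gaps_and_fractions(strands))
}
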