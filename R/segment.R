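get_volume_data <- function(x) {
  if (inherits(x, "ct_volume")) x$data else x
}

get_volume_pitch <- function(x, pitch_um = NULL) {
  if (!is.null(pitch_um)) return(pitch_um)
  if (inherits(x, "ct_volume")) x$pitch_um else NA_real_
}

#' Otsu's threshold by exhaustive between-class-variance scan
#'
#' Scans every histogram bin boundary and returns the gray value maximizing
#' the between-class variance `w0 w1 (m0 - m1)^2`.
#'
#' @param x numeric array/vector (or `ct_volume`).
#' @param n_bins histogram bins.
#' @return threshold (gray value).
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  v <- as.numeric(get_volume_data(x))
  rng <- range(v)
  if (diff(rng) == 0) stop("constant image has no threshold")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- as.numeric(
    tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins),
             nbins = n_bins)
  )
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  tot <- w[n_bins]; mtot <- m[n_bins]
  w0 <- w[-n_bins]; w1 <- tot - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1)
  bcv[valid] <- (mtot * w0[valid] / tot - m[-n_bins][valid])^2 * tot /
    (w0[valid] * w1[valid])
  edges[which.max(bcv) + 1]
}

#' Automatic gray-level threshold at the histogram valley
#'
#' CT volumes of an air-filled lung have a bimodal histogram: an air peak
#' and a tissue peak. The threshold is chosen at the bottom of the valley
#' between the two highest peaks of the smoothed histogram (moving average,
#' width `smooth_frac` of the bin count); ties are broken toward the
#' midpoint between the peaks. When no interior valley exists the method
#' falls back to Otsu's criterion (with a message) unless disabled.
#'
#' @param x numeric array or `ct_volume`.
#' @param n_bins histogram bins.
#' @param smooth_frac moving-average width as a fraction of `n_bins`.
#' @param fallback_otsu allow the Otsu fallback on unimodal histograms.
#' @param clip_quantiles histogram range as quantiles of the gray values;
#'   the default trims 0.5% tails so that sparse extremes (edge-enhancement
#'   over/undershoots) do not stretch the binning and merge the air and
#'   tissue modes. Use `c(0, 1)` for the full range.
#' @param min_dip a candidate valley is only accepted when its smoothed
#'   count dips below `min_dip` times the lower of the two peak counts;
#'   shallower dips are treated as sampling ripple on a unimodal
#'   histogram and trigger the fallback.
#' @return list with `histogram` (a `histogram_model`: `edges`, `mids`,
#'   `counts`, `smoothed`, `peaks`, `valley`) and `threshold`.
#' @export
valley_threshold <- function(x, n_bins = 256, smooth_frac = 1 / 64,
                             fallback_otsu = TRUE,
                             clip_quantiles = c(0.005, 0.995),
                             min_dip = 0.95) {
  v <- as.numeric(get_volume_data(x))
  rng <- stats::quantile(v, clip_quantiles, names = FALSE)
  if (diff(rng) == 0) rng <- range(v)
  if (diff(rng) == 0) stop("constant image has no histogram valley")
  v <- v[v >= rng[1] & v <= rng[2]]
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w <- max(3, 2 * floor(n_bins * smooth_frac / 2) + 1)  # odd width
  kern <- rep(1 / w, w)
  sm <- as.numeric(stats::filter(counts, kern, sides = 2))
  # renormalize the truncated windows at the ends
  wts <- as.numeric(stats::filter(rep(1, n_bins), kern, sides = 2))
  sm <- sm / wts * 1
  sm[is.na(sm)] <- counts[is.na(sm)]
  # local maxima of the smoothed histogram
  pk <- which(diff(sign(diff(sm))) < 0) + 1
  model <- structure(list(edges = edges, mids = mids, counts = counts,
                          smoothed = sm, peaks = mids[pk],
                          valley = NA_real_),
                     class = "histogram_model")
  thr <- NA_real_
  if (length(pk) >= 2) {
    top2 <- sort(pk[order(sm[pk], decreasing = TRUE)][1:2])
    inter <- seq(top2[1] + 1, top2[2] - 1)
    if (length(inter) > 0) {
      vmin <- min(sm[inter])
      if (vmin <= min_dip * min(sm[top2])) {
        cand <- inter[sm[inter] <= vmin + 1e-12]
        midpoint <- mean(mids[top2])
        best <- cand[which.min(abs(mids[cand] - midpoint))]
        thr <- mids[best]
        model$valley <- thr
        model$peaks <- mids[top2]
      }
    }
  }
  if (is.na(thr)) {
    if (!fallback_otsu) {
      stop("histogram has no interior valley and the Otsu fallback is disabled")
    }
    message("no interior histogram valley; falling back to Otsu's criterion")
    thr <- otsu_threshold(v, n_bins = n_bins)
  }
  list(histogram = model, threshold = thr)
}

#' @export
plot.histogram_model <- function(x, log = "y", ...) {
  graphics::plot(x$mids, pmax(x$counts, 0.5), type = "h", col = "grey70",
                 log = log, xlab = "gray value", ylab = "count", ...)
  graphics::lines(x$mids, pmax(x$smoothed, 0.5), col = "black")
  if (!is.na(x$valley)) graphics::abline(v = x$valley, lty = 2)
  if (length(x$peaks)) graphics::abline(v = x$peaks, lty = 3, col = "grey40")
  invisible(x)
}

#' @export
print.histogram_model <- function(x, ...) {
  cat(sprintf("<histogram_model> %d bins, peaks at %s, valley at %s\n",
              length(x$counts),
              paste(signif(x$peaks, 4), collapse = ", "),
              format(signif(x$valley, 4))))
  invisible(x)
}

#' Zero sub-threshold voxels and rescale the survivors
#'
#' Background suppression as applied to the lung CT slices: voxels below
#' the threshold are set to zero (removing background noise) and the
#' surviving gray values are affinely rescaled to `[0, 1]` (the gray-scale
#' transformation), with `threshold -> 0` and `max -> 1`.
#'
#' @param x numeric array or `ct_volume`.
#' @param threshold gray threshold within the volume's range.
#' @return same type as the input.
#' @export
zero_below_and_rescale <- function(x, threshold) {
  v <- get_volume_data(x)
  if (threshold > max(v)) stop("all voxels fall below the threshold")
  keep <- v >= threshold
  hi <- max(v)
  out <- v
  out[!keep] <- 0
  out[keep] <- if (hi > threshold) {
    (v[keep] - threshold) / (hi - threshold)
  } else {
    1
  }
  if (inherits(x, "ct_volume")) {
    x$data <- out
    x
  } else {
    out
  }
}

new_label_volume <- function(labels, legend, pitch_um) {
  structure(list(labels = labels, legend = legend, pitch_um = pitch_um),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  nz <- sum(x$labels > 0)
  cat(sprintf("<label_volume> %s, %d labelled voxels, legend: %s\n",
              paste(dim(x$labels), collapse = " x "), nz,
              paste(names(x$legend), x$legend, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Segment bone (ribs) by high threshold
#'
#' Bone has a distinctly higher reconstructed gray level than soft tissue,
#' so a single threshold suffices: the mask is all voxels at or above
#' `bone_threshold`, with connected components smaller than `min_voxels`
#' removed as noise.
#'
#' @param ct `ct_volume` or array.
#' @param bone_threshold gray threshold (above the tissue level).
#' @param min_voxels smallest component kept.
#' @param connectivity 6 or 26.
#' @param pitch_um voxel pitch when `ct` is a bare array.
#' @return a `label_volume` with legend `c(bone = 1)`.
#' @export
segment_bone <- function(ct, bone_threshold, min_voxels = 27,
                         connectivity = 26, pitch_um = NULL) {
  v <- get_volume_data(ct)
  mask <- v >= bone_threshold
  lab <- label_components_cpp(mask, as.integer(dim(v)),
                              as.integer(connectivity))
  if (max(lab) > 0 && min_voxels > 1) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(sizes >= min_voxels)
    mask <- array(lab %in% keep & lab > 0L, dim = dim(v))
  }
  if (!any(mask)) warning("bone mask is empty at threshold ", bone_threshold)
  new_label_volume(array(as.integer(mask), dim = dim(v)),
                   c(bone = 1L), get_volume_pitch(ct, pitch_um))
}

#' Segment the whole lung airways by manual threshold
#'
#' Air reconstructs dark (low gray value), so the airway mask is all voxels
#' at or below the caller-chosen threshold, restricted to the lung interior:
#' connected components touching the volume border (the air surrounding the
#' body) are removed. Set `air_low = FALSE` for the opposite gray polarity.
#'
#' @param ct `ct_volume` or array.
#' @param airway_threshold gray threshold separating air from tissue.
#' @param connectivity 6 or 26.
#' @param air_low polarity flag (air below the threshold when `TRUE`).
#' @param pitch_um voxel pitch when `ct` is a bare array.
#' @return a `label_volume` with legend `c(airways = 1)`.
#' @export
segment_airways <- function(ct, airway_threshold, connectivity = 26,
                            air_low = TRUE, pitch_um = NULL) {
  v <- get_volume_data(ct)
  mask <- if (air_low) v <= airway_threshold else v >= airway_threshold
  lab <- label_components_cpp(mask, as.integer(dim(v)),
                              as.integer(connectivity))
  if (max(lab) > 0) {
    d <- dim(v)
    border <- unique(c(
      lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]
    ))
    border <- border[border > 0L]
    keep_mask <- array(lab > 0L & !(lab %in% border), dim = d)
  } else {
    keep_mask <- array(FALSE, dim = dim(v))
  }
  if (!any(keep_mask)) {
    stop("airway mask is empty; ",
         if (air_low) "raise" else "lower", " the threshold (",
         format(airway_threshold), ")")
  }
  new_label_volume(array(as.integer(keep_mask), dim = dim(v)),
                   c(airways = 1L), get_volume_pitch(ct, pitch_um))
}

#' Extract the bronchial tree by seeded 3D region growing
#'
#' From a manually placed seed voxel in the bronchus, grows the maximal
#' connected voxel set in which every voxel satisfies the intensity
#' predicate (value at or below the threshold for air). The result is
#' set-valued and order-independent: growing stops wherever the intensity
#' threshold is exceeded, which separates the tree from the surrounding
#' chambers.
#'
#' @param ct `ct_volume` or array.
#' @param seed_voxel 1-based voxel index triple `c(i, j, k)`.
#' @param threshold intensity threshold controlling the growth.
#' @param connectivity 6 or 26.
#' @param air_low grow over values `<= threshold` when `TRUE`.
#' @param pitch_um voxel pitch when `ct` is a bare array.
#' @return a `label_volume` with legend `c(bronchial_tree = 1)`.
#' @export
region_grow_3d <- function(ct, seed_voxel, threshold, connectivity = 26,
                           air_low = TRUE, pitch_um = NULL) {
  v <- get_volume_data(ct)
  d <- dim(v)
  seed_voxel <- as.integer(round(seed_voxel))
  if (length(seed_voxel) != 3 || any(seed_voxel < 1) ||
      any(seed_voxel > d)) {
    stop("seed voxel must be a 1-based index triple inside the volume")
  }
  sv <- v[seed_voxel[1], seed_voxel[2], seed_voxel[3]]
  okseed <- if (air_low) sv <= threshold else sv >= threshold
  if (!okseed) {
    stop("seed voxel value ", signif(sv, 4),
         " fails the intensity predicate at threshold ",
         signif(threshold, 4))
  }
  mask <- region_grow_cpp(v, as.integer(d), seed_voxel - 1L, threshold,
                          air_low, as.integer(connectivity))
  new_label_volume(array(as.integer(mask), dim = d),
                   c(bronchial_tree = 1L), get_volume_pitch(ct, pitch_um))
}
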