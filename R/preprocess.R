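# Preprocessing: repetition synchronization by dynamic time warping,
# zero-phase Butterworth filtering, 101-point time normalization,
# per-subject centering and Tukey-tapered concatenation.

#' Dynamic time warping
#'
#' Globally optimal monotone alignment of two multichannel series under the
#' step set \{(1,1), (1,0), (0,1)\} by dynamic programming, with the local
#' cost the Euclidean distance between samples and ties broken in favour of
#' the diagonal step.
#'
#' @param reference,query Numeric vectors or matrices (rows = samples,
#'   columns = channels); both must share the channel count.
#' @return A list with the optimal cumulative \code{cost} and the warping
#'   \code{path}, a two-column matrix of 1-based (reference, query) index
#'   pairs from (1, 1) to (n, m).
#' @examples
#' dtw(c(0, 1, 2), c(0, 1, 1, 2))$cost  # 0
#' @export
dtw <- function(reference, query) {
  if (is.null(dim(reference))) reference <- matrix(reference, ncol = 1)
  if (is.null(dim(query))) query <- matrix(query, ncol = 1)
  if (nrow(reference) == 0 || nrow(query) == 0)
    stop("series must be non-empty", call. = FALSE)
  if (ncol(reference) != ncol(query))
    stop("series must share the channel count", call. = FALSE)
  res <- dtw_cpp(reference, query)
  list(cost = res$cost, path = cbind(i = res$i, j = res$j))
}

# Map raw-series indices through a warping path onto the reference time base:
# for a query index j, the (first) reference index aligned with it.
map_index_through_path <- function(path, j_idx) {
  vapply(j_idx, function(j) path[match(j, path[, 2]), 1], numeric(1))
}

# Warp a query matrix onto the reference length along a path; query samples
# mapped to one reference index are averaged.
warp_onto_reference <- function(path, x, n_ref) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  sums <- rowsum(x[path[, 2], , drop = FALSE], group = path[, 1])
  cnt <- as.vector(table(factor(path[, 1], levels = seq_len(n_ref))))
  out <- sums / cnt
  dimnames(out) <- if (is.null(colnames(x))) NULL else list(NULL, colnames(x))
  out
}

#' Synchronize the repetitions of a transport
#'
#' Aligns repetitions 2..k of the same transport onto the time base of
#' repetition 1 using the DTW path computed on the 3-D hand-sensor position
#' trajectory; all angle and position channels are warped along that path
#' (query samples mapped to one reference instant are averaged). Ground-truth
#' grasp/release indices, when present, are mapped through the path.
#'
#' @param series_list List of \code{joint_angles} objects for the repetitions
#'   of one (subject, object, origin, destination) combination; repetition 1
#'   is the reference.
#' @return A list of \code{joint_angles} objects, all on the reference time
#'   base.
#' @export
synchronize_repetitions <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  if (length(series_list) < 2) {
    warning("fewer than 2 repetitions: returning input unchanged")
    return(series_list)
  }
  keys <- vapply(series_list, function(s)
    paste(s$meta$subject, s$meta$object, s$meta$origin, s$meta$destination),
    character(1))
  if (length(unique(keys)) != 1)
    stop("repetitions must share metadata except the repetition index",
         call. = FALSE)
  ref <- series_list[[1]]
  n_ref <- nrow(ref$angles)
  out <- vector("list", length(series_list))
  out[[1]] <- ref
  out[[1]]$provenance <- "synchronized"
  for (k in seq_along(series_list)[-1]) {
    qry <- series_list[[k]]
    al <- dtw(ref$hand_pos, qry$hand_pos)
    w <- qry
    w$angles <- warp_onto_reference(al$path, qry$angles, n_ref)
    colnames(w$angles) <- colnames(qry$angles)
    w$hand_pos <- warp_onto_reference(al$path, qry$hand_pos, n_ref)
    w$t <- ref$t
    if (!is.null(qry$truth)) {
      w$truth$grasp_idx <- map_index_through_path(al$path, qry$truth$grasp_idx)
      w$truth$release_idx <- map_index_through_path(al$path, qry$truth$release_idx)
      w$truth$grasp_tau_idx <- as.integer(round(100 * (w$truth$grasp_idx - 1) / (n_ref - 1)))
      w$truth$release_tau_idx <- as.integer(round(100 * (w$truth$release_idx - 1) / (n_ref - 1)))
    }
    w$provenance <- "synchronized"
    out[[k]] <- w
  }
  out
}

#' Butterworth low-pass filter
#'
#' Order-3 Butterworth low-pass (design via \code{signal::butter}), applied
#' forward only or forward-backward (zero phase, squared magnitude response).
#' Edges are handled by odd reflection padding of at least three filter
#' orders at each end.
#'
#' @param x Numeric vector, or matrix filtered column-wise.
#' @param cutoff Cutoff frequency (Hz), in (0, rate/2).
#' @param rate Sampling rate (Hz).
#' @param order Filter order.
#' @param zero_phase Forward-backward application (default), giving zero lag.
#' @return Filtered series, same shape as \code{x}.
#' @export
butterworth_lowpass <- function(x, cutoff, rate, order = 3, zero_phase = TRUE) {
  if (cutoff <= 0 || cutoff >= rate / 2)
    stop("cutoff must lie in (0, rate/2)", call. = FALSE)
  if (is.matrix(x))
    return(apply(x, 2, butterworth_lowpass, cutoff = cutoff, rate = rate,
                 order = order, zero_phase = zero_phase))
  n <- length(x)
  bf <- signal::butter(order, 2 * cutoff / rate, type = "low")
  pad <- min(n - 1, max(3 * order, 24))
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(left, x, right)
  # steady-state initial conditions at the first padded value, so a constant
  # signal passes through with exactly unit gain
  run <- function(v) as.numeric(signal::filter(bf$b, bf$a, v,
                                               init.x = rep(v[1], order),
                                               init.y = rep(v[1], order)))
  y <- run(xp)
  if (zero_phase) y <- rev(run(rev(y)))
  y[seq(pad + 1, pad + n)]
}

#' Resample a series onto the normalized 101-point grid
#'
#' Linear interpolation onto normalized times 0.00, 0.01, ..., 1.00; the
#' first and last samples are preserved exactly.
#'
#' @param x Numeric vector or matrix (rows = samples).
#' @param n Number of output samples (default 101).
#' @return Resampled vector or matrix with \code{n} rows.
#' @export
resample_normalized <- function(x, n = 101) {
  if (is.matrix(x)) {
    out <- apply(x, 2, resample_normalized, n = n)
    return(out)
  }
  m <- length(x)
  if (m < 2) stop("series must have at least 2 samples", call. = FALSE)
  out <- approx(x = seq(0, 1, length.out = m), y = x,
                xout = seq(0, 1, length.out = n))$y
  out[1] <- x[1]
  out[n] <- x[m]
  out
}

#' Preprocess a raw study into normalized trials
#'
#' Runs the full treatment chain on every trial: joint-angle extraction,
#' DTW synchronization of the repetitions of each transport onto repetition
#' 1, low-pass filtering of the angle and hand-position channels, and linear
#' resampling onto the 101-point normalized grid.
#'
#' @param study A \code{wrist_study} from [generate_study()].
#' @param cutoff Butterworth cutoff (Hz).
#' @param zero_phase Zero-phase (forward-backward) filtering.
#' @param synchronize Synchronize repetitions by DTW before filtering.
#' @return A list of \code{normalized_trial} objects (class
#'   \code{normalized_study}): 101-sample angle and hand-position series with
#'   metadata and mapped ground-truth event indices.
#' @export
preprocess_study <- function(study, cutoff = 5, zero_phase = TRUE,
                             synchronize = TRUE) {
  design <- attr(study, "design")
  model <- attr(study, "model")
  series <- lapply(study, extract_joint_angles, model = model)
  keys <- vapply(series, function(s)
    paste(s$meta$subject, s$meta$object, s$meta$origin, s$meta$destination),
    character(1))
  out <- vector("list", length(series))
  for (key in unique(keys)) {
    idx <- which(keys == key)
    idx <- idx[order(vapply(series[idx], function(s) s$meta$repetition, numeric(1)))]
    grp <- series[idx]
    if (synchronize && length(grp) >= 2) grp <- synchronize_repetitions(grp)
    for (g in seq_along(grp)) {
      s <- grp[[g]]
      rate <- 1 / stats::median(diff(s$t))
      ang <- butterworth_lowpass(s$angles, cutoff, rate, zero_phase = zero_phase)
      hp <- butterworth_lowpass(s$hand_pos, cutoff, rate, zero_phase = zero_phase)
      n_raw <- nrow(s$angles)
      nt <- list(meta = s$meta,
                 tau = seq(0, 1, by = 0.01),
                 angles = resample_normalized(ang, 101),
                 hand_pos = resample_normalized(hp, 101),
                 truth_pk = if (!is.null(s$truth)) as.integer(
                   round(100 * (s$truth$grasp_idx - 1) / (n_raw - 1))) else NULL,
                 truth_pl = if (!is.null(s$truth)) as.integer(
                   round(100 * (s$truth$release_idx - 1) / (n_raw - 1))) else NULL,
                 pk = NULL, pl = NULL, centered = FALSE)
      colnames(nt$angles) <- ANGLE_NAMES
      colnames(nt$hand_pos) <- c("x", "y", "z")
      out[[idx[g]]] <- structure(nt, class = "normalized_trial")
    }
  }
  structure(out, class = "normalized_study",
            design = design, cutoff = cutoff, zero_phase = zero_phase)
}

#' Center angles by subject
#'
#' Re-expresses every angle channel as the difference from that subject's
#' mean value of the channel over all of the subject's trials and samples,
#' removing systematic sensor-placement and posture offsets between
#' subjects. The offsets are returned for the inverse transform.
#'
#' @param trials A \code{normalized_study} (list of normalized trials).
#' @return A list with \code{trials} (centered) and \code{offsets}
#'   (subject x 9 matrix, degrees).
#' @export
center_by_subject <- function(trials) {
  subjects <- vapply(trials, function(x) x$meta$subject, character(1))
  offs <- matrix(0, length(unique(subjects)), 9,
                 dimnames = list(sort(unique(subjects)), ANGLE_NAMES))
  for (sub in rownames(offs)) {
    idx <- which(subjects == sub)
    stacked <- do.call(rbind, lapply(trials[idx], function(x) x$angles))
    offs[sub, ] <- colMeans(stacked)
  }
  out <- lapply(trials, function(x) {
    if (isTRUE(x$centered)) return(x)
    x$angles <- sweep(x$angles, 2, offs[x$meta$subject, ])
    x$centered <- TRUE
    x
  })
  attributes(out) <- attributes(trials)
  list(trials = out, offsets = offs)
}

#' Undo per-subject centering
#'
#' @param trials Centered \code{normalized_study}.
#' @param offsets Offset matrix from [center_by_subject()].
#' @return The trials with original angle values restored.
#' @export
uncenter_by_subject <- function(trials, offsets) {
  out <- lapply(trials, function(x) {
    if (!isTRUE(x$centered)) return(x)
    x$angles <- sweep(x$angles, 2, offsets[x$meta$subject, ], FUN = "+")
    x$centered <- FALSE
    x
  })
  attributes(out) <- attributes(trials)
  out
}

# Tukey taper: flat window with cosine ramps spanning `taper_len` samples at
# each end; w[0] = w[n-1] = 0, samples taper_len .. n-1-taper_len unaltered.
tukey_taper <- function(n, taper_len) {
  k <- seq_len(n) - 1
  w <- rep(1, n)
  ramp <- k < taper_len
  w[ramp] <- 0.5 * (1 - cos(pi * k[ramp] / taper_len))
  w[rev(ramp)] <- rev(w[ramp])
  w
}

#' Concatenate trials into one tapered series
#'
#' Multiplies every channel of each 101-sample trial by a Tukey window whose
#' cosine ramps span exactly \code{taper_len} samples at each end (so the
#' first and last \code{taper_len} instants are modified and the central
#' samples are untouched), then concatenates the trials in a seeded, recorded
#' order. Time-delay networks are trained on such concatenations; the taper
#' removes the jumps at trial boundaries.
#'
#' @param trials List of normalized trials (101 samples each).
#' @param taper_len Ramp length in samples (must be below 50).
#' @param seed Seed for the concatenation order; \code{NULL} keeps the input
#'   order.
#' @return A list with \code{angles} ((101 k) x 9 matrix), \code{boundaries}
#'   (0-based start index of each trial in the concatenation), \code{order}
#'   (trial permutation used) and \code{meta} (per-trial metadata in that
#'   order).
#' @export
taper_concatenate <- function(trials, taper_len = 5, seed = NULL) {
  if (taper_len >= 50) stop("taper_len must be below 50", call. = FALSE)
  stopifnot(all(vapply(trials, function(x) nrow(x$angles), numeric(1)) == 101))
  ord <- seq_along(trials)
  if (!is.null(seed)) ord <- with_seed(seed, sample(ord))
  w <- tukey_taper(101, taper_len)
  pieces <- lapply(trials[ord], function(x) x$angles * w)
  list(angles = do.call(rbind, pieces),
       boundaries = (seq_along(trials) - 1) * 101,
       order = ord,
       meta = lapply(trials[ord], function(x) x$meta))
}
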