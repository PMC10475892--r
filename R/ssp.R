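#' Savitzky-Golay over-smoothing
#'
#' Local least-squares polynomial smoothing (cubic, 23 ms frame by default).
#' At these settings the filter passes the P wave and the slow atrial
#' repolarization ramps essentially unchanged while strongly attenuating the
#' ~100 Hz His deflection, so its output estimates the atrial component of a
#' PR epoch.
#'
#' @param x A [sampled_trace()], [epoch_stack()], or numeric vector/matrix
#'   (rows = epochs).
#' @param order Polynomial order (default 3, cubic).
#' @param frame_ms Frame length in ms; converted to samples and rounded to
#'   the nearest odd count (23 ms at 1 kHz is the canonical 23-sample frame).
#' @param fs Sampling rate, required only when `x` is a bare vector/matrix.
#' @return Same class as the input, smoothed.
#' @export
oversmooth <- function(x, order = 3L, frame_ms = 23, fs = NULL) {
  if (inherits(x, "epoch_stack")) {
    out <- x
    out$epochs <- oversmooth(x$epochs, order, frame_ms, x$fs)
    return(out)
  }
  if (inherits(x, "sampled_trace"))
    return(sampled_trace(oversmooth(x$samples, order, frame_ms, x$fs), x$fs))
  if (is.null(fs)) stop("oversmooth: fs required for bare numeric input")
  frame <- as.integer(round(frame_ms * fs / 1000))
  if (frame %% 2L == 0L) frame <- frame + 1L
  if (frame <= order) stop("oversmooth: frame length must exceed the order")
  if (is.null(dim(x))) return(as.vector(signal::sgolayfilt(x, p = order, n = frame)))
  t(apply(x, 1L, function(r) signal::sgolayfilt(r, p = order, n = frame)))
}

#' Orthonormal basis of the atrial subspace
#'
#' Singular value decomposition of the time-by-beats matrix of over-smoothed
#' epochs; the left singular vectors are retained until their cumulative
#' squared singular values reach `energy_rule` of the total (capped at
#' `m - 1`, strictly fewer basis vectors than epochs). The span of the
#' retained vectors is the atrial subspace.
#'
#' @param smoothed An [epoch_stack()] of over-smoothed epochs (or a beats x
#'   time matrix), `m >= 2`.
#' @param energy_rule Retained-energy fraction in (0, 1].
#' @return An object of class `atrial_basis` with fields `U` (T x n,
#'   orthonormal columns), `n`, `singular_values`, `energy_rule`.
#' @export
build_atrial_basis <- function(smoothed, energy_rule = 0.99) {
  E <- if (inherits(smoothed, "epoch_stack")) smoothed$epochs else as.matrix(smoothed)
  m <- nrow(E)
  if (m < 2L) stop("build_atrial_basis: need at least 2 epochs")
  stopifnot(energy_rule > 0, energy_rule <= 1)
  if (all(E == 0)) stop("atrial subspace undefined: all-zero input")
  sv <- svd(t(E))                         # T x m
  cum <- cumsum(sv$d^2) / sum(sv$d^2)
  n <- which(cum >= energy_rule)[1L]
  n <- min(n, m - 1L)
  structure(list(U = sv$u[, seq_len(n), drop = FALSE],
                 n = as.integer(n),
                 singular_values = sv$d,
                 energy_rule = energy_rule),
            class = "atrial_basis")
}

#' @export
print.atrial_basis <- function(x, ...) {
  cat(sprintf("<atrial_basis> rank %d (energy rule %g), T = %d\n",
              x$n, x$energy_rule, nrow(x$U)))
  invisible(x)
}

#' Orthogonal-complement projector of the atrial subspace
#'
#' Materializes `P_per = I - U U^T`: symmetric, idempotent, and annihilating
#' every vector in the atrial subspace. For application to epochs prefer
#' [extract_hbs()], which uses the equivalent `x - U (U^T x)` form without
#' forming the T x T matrix.
#'
#' @param basis An [build_atrial_basis()] result.
#' @return A T x T projection matrix.
#' @export
projection_operator <- function(basis) {
  stopifnot(inherits(basis, "atrial_basis"))
  diag(nrow(basis$U)) - tcrossprod(basis$U)
}

#' Project epochs onto the complement of the atrial subspace
#'
#' Applies `P_per` to every (wavelet-thresholded) epoch row, removing the
#' atrial components and selectively retrieving the His bundle signal in
#' each beat. Computed as `b - U (U^T b)`, which agrees with the
#' materialized projector to machine precision.
#'
#' @param stack An [epoch_stack()] (typically after [apply_threshold()]).
#' @param basis An [build_atrial_basis()] result with matching epoch length.
#' @return An `hbs_stack`: an [epoch_stack()] subclass carrying provenance.
#' @export
extract_hbs <- function(stack, basis) {
  stopifnot(inherits(stack, "epoch_stack"), inherits(basis, "atrial_basis"))
  if (ncol(stack$epochs) != nrow(basis$U))
    stop("extract_hbs: epoch length does not match the basis")
  E <- stack$epochs
  out <- stack
  out$epochs <- E - (E %*% basis$U) %*% t(basis$U)
  class(out) <- c("hbs_stack", class(stack))
  attr(out, "provenance") <- list(basis_rank = basis$n,
                                  energy_rule = basis$energy_rule)
  out
}

#' Full beat-by-beat extraction pipeline
#'
#' Runs the stage order of the method on a stack of raw PR epochs: apply the
#' stored interval-dependent threshold spec to every epoch, over-smooth the
#' thresholded epochs to estimate the atrial set, build the atrial subspace
#' by SVD of the smoothed epochs, and back-project the thresholded epochs
#' onto its orthogonal complement. Deterministic given its inputs.
#'
#' @param stack An [epoch_stack()] of raw PR epochs.
#' @param spec A [build_threshold_spec()] result.
#' @param sg_order,sg_frame_ms Savitzky-Golay settings for [oversmooth()].
#' @param energy_rule Retained-energy fraction for [build_atrial_basis()].
#' @return An `hbs_stack` of extracted His bundle signals, with the
#'   intermediate `atrial_basis` attached as attribute `"basis"` and the
#'   thresholded stack as `"thresholded"`.
#' @export
run_pipeline <- function(stack, spec, sg_order = 3L, sg_frame_ms = 23,
                         energy_rule = 0.99) {
  stopifnot(inherits(stack, "epoch_stack"))
  thresholded <- tryCatch(apply_threshold(stack, spec),
                          error = function(e) stop("pipeline stage idwt: ",
                                                   conditionMessage(e)))
  smoothed <- tryCatch(oversmooth(thresholded, sg_order, sg_frame_ms),
                       error = function(e) stop("pipeline stage oversmooth: ",
                                                conditionMessage(e)))
  basis <- tryCatch(build_atrial_basis(smoothed, energy_rule),
                    error = function(e) stop("pipeline stage atrial_basis: ",
                                             conditionMessage(e)))
  hbs <- tryCatch(extract_hbs(thresholded, basis),
                  error = function(e) stop("pipeline stage ssp: ",
                                           conditionMessage(e)))
  attr(hbs, "basis") <- basis
  attr(hbs, "thresholded") <- thresholded
  hbs
}
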