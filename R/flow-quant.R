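#' Gate specifications
#'
#' Gates operate in log10 signal space, the flow-cytometry convention.
#' `rectangular_gate` keeps events with both channels inside half-open
#' bounds `[lo, hi)`; `diagonal_gate` keeps events strictly on one side of
#' the line `log10(phospho) = m * log10(expression) + c`. Diagonal gates are
#' what de-biases selection against ligand-independent activation of highly
#' expressing wild-type cells.
#'
#' @param expression_lo,expression_hi,phospho_lo,phospho_hi Rectangular
#'   bounds in log10 units (lo < hi).
#' @param slope,intercept Diagonal gate in log10-log10 space.
#' @param side `"above"` keeps `log10(phospho) - slope * log10(expression)
#'   > intercept`; `"below"` keeps `<`.
#' @return A list of class `gate_spec`.
#' @export
rectangular_gate <- function(expression_lo, expression_hi,
                             phospho_lo = -Inf, phospho_hi = Inf) {
  stopifnot(expression_lo < expression_hi, phospho_lo < phospho_hi)
  structure(list(type = "rectangular",
                 expression = c(expression_lo, expression_hi),
                 phospho = c(phospho_lo, phospho_hi)),
            class = "gate_spec")
}

#' @rdname rectangular_gate
#' @export
diagonal_gate <- function(slope, intercept, side = c("above", "below")) {
  side <- match.arg(side)
  structure(list(type = "diagonal", slope = slope, intercept = intercept,
                 side = side),
            class = "gate_spec")
}

drop_nonpositive <- function(events) {
  bad <- events$expression <= 0 | events$phospho <= 0
  if (any(bad)) {
    message("dropping ", sum(bad), " event(s) with non-positive signal")
    events <- events[!bad, , drop = FALSE]
  }
  events
}

#' Apply a rectangular gate
#'
#' Keeps events with both channels inside the half-open, lower-inclusive
#' log10 bounds. An empty result is allowed and flagged with a message.
#'
#' @param events A `flow_event_set`.
#' @param gate A [rectangular_gate()].
#' @return The gated `flow_event_set`.
#' @export
gate_rectangular <- function(events, gate) {
  stopifnot(inherits(gate, "gate_spec"), gate$type == "rectangular")
  events <- drop_nonpositive(events)
  le <- log10(events$expression)
  lp <- log10(events$phospho)
  keep <- le >= gate$expression[1L] & le < gate$expression[2L] &
    lp >= gate$phospho[1L] & lp < gate$phospho[2L]
  out <- events[keep, , drop = FALSE]
  if (nrow(out) == 0L) message("rectangular gate selected no events")
  out
}

#' Apply a diagonal gate
#'
#' Keeps events strictly above (or below) the line `log10(phospho) =
#' slope * log10(expression) + intercept`. With slope 1 the gated fraction is
#' invariant under a common gain applied to both channels.
#'
#' @param events A `flow_event_set`.
#' @param gate A [diagonal_gate()].
#' @return The gated `flow_event_set`.
#' @export
gate_diagonal <- function(events, gate) {
  stopifnot(inherits(gate, "gate_spec"), gate$type == "diagonal")
  events <- drop_nonpositive(events)
  score <- log10(events$phospho) - gate$slope * log10(events$expression)
  keep <- if (gate$side == "above") score > gate$intercept
          else score < gate$intercept
  out <- events[keep, , drop = FALSE]
  if (nrow(out) == 0L) message("diagonal gate selected no events")
  out
}

#' Geometric mean fluorescence intensity
#'
#' `exp(mean(log(values)))`; all values must be strictly positive.
#'
#' @param values Positive numeric vector.
#' @return The geometric mean.
#' @export
gmfi <- function(values) {
  if (length(values) == 0L) stop("gmfi of an empty vector is undefined")
  if (any(values <= 0)) stop("gmfi requires strictly positive values")
  exp(mean(log(values)))
}

#' Background-subtracted, wild-type-normalized activation
#'
#' Per replicate, `activation = (gMFI_sample - gMFI_background) /
#' (gMFI_wt - gMFI_wt_background)`; the background is the gMFI of
#' nontransfected cells without ligand, and wild type without ligand defines
#' activation 1. Replicates are normalized first, then aggregated as
#' mean +/- SD; the p-value is a two-tailed paired t-test of the
#' background-subtracted sample signal against the wild-type signal across
#' replicates (uncorrected).
#'
#' @param gmfi_sample,gmfi_bg,gmfi_wt,gmfi_wt_bg Numeric vectors of
#'   per-replicate gMFI values (recycled to a common length).
#' @return A list of class `activation_result`: `activation` (per
#'   replicate), `mean`, `sd`, `t`, `p_value`.
#' @export
normalize_activation <- function(gmfi_sample, gmfi_bg, gmfi_wt,
                                 gmfi_wt_bg = gmfi_bg) {
  n <- max(lengths(list(gmfi_sample, gmfi_bg, gmfi_wt, gmfi_wt_bg)))
  gmfi_sample <- rep_len(gmfi_sample, n); gmfi_bg <- rep_len(gmfi_bg, n)
  gmfi_wt <- rep_len(gmfi_wt, n); gmfi_wt_bg <- rep_len(gmfi_wt_bg, n)
  wt_net <- gmfi_wt - gmfi_wt_bg
  if (any(wt_net <= 0)) {
    stop("non-positive wild-type net signal; normalization undefined")
  }
  activation <- (gmfi_sample - gmfi_bg) / wt_net
  tt <- if (n >= 2L) {
    paired_t_test(gmfi_sample - gmfi_bg, wt_net)
  } else {
    list(t = NA_real_, p_value = NA_real_)
  }
  structure(list(activation = activation, mean = mean(activation),
                 sd = if (n >= 2L) sd(activation) else NA_real_,
                 t = tt$t, p_value = tt$p_value),
            class = "activation_result")
}

#' @export
print.activation_result <- function(x, ...) {
  cat(sprintf("<activation_result> mean %.3f +/- %.3f (n = %d), p = %.3g\n",
              x$mean, x$sd, length(x$activation), x$p_value))
  invisible(x)
}

#' Two-tailed paired t-test
#'
#' The classical statistic on paired differences: `t = mean(d) /
#' (sd(d) / sqrt(n))` with a two-sided p-value from the t distribution with
#' `n - 1` degrees of freedom. Degenerate cases: all differences zero gives
#' `t = 0, p = 1`; zero-variance differences with nonzero mean give the
#' infinite-t limit `p = 0`.
#'
#' @param a,b Numeric vectors of equal length `n >= 2`.
#' @return A list with `t`, `df`, `p_value`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  n <- length(d)
  s <- sd(d)
  m <- mean(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, df = n - 1L, p_value = 1))
    return(list(t = sign(m) * Inf, df = n - 1L, p_value = 0))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1L, p_value = 2 * pt(-abs(t), df = n - 1L))
}

#' Bead-based surface-receptor calibration
#'
#' Least-squares fit of `log10(molecules)` against `log10(intensity)` over
#' the bead levels of a quantitation kit; applying the calibration maps a
#' gMFI to antibody-binding sites (molecules) per cell.
#'
#' @param bead_intensities Positive intensities of the bead levels (>= 2).
#' @param bead_molecule_counts Positive molecule counts per bead level.
#' @return A list of class `quantibrite_calibration` with `slope`,
#'   `intercept` (log10 space) and `apply(gmfi)`.
#' @export
quantibrite_calibrate <- function(bead_intensities, bead_molecule_counts) {
  stopifnot(length(bead_intensities) >= 2L,
            length(bead_intensities) == length(bead_molecule_counts),
            all(bead_intensities > 0), all(bead_molecule_counts > 0))
  if (anyDuplicated(bead_intensities) &&
      anyDuplicated(paste(bead_intensities, bead_molecule_counts)) == 0L) {
    warning("duplicate bead intensities at different molecule counts; ",
            "fit is ill-conditioned")
  }
  fit <- lm(log10(bead_molecule_counts) ~ log10(bead_intensities))
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  cal <- list(slope = slope, intercept = intercept)
  cal$apply <- function(gmfi) {
    stopifnot(all(gmfi > 0))
    10^(intercept + slope * log10(gmfi))
  }
  class(cal) <- "quantibrite_calibration"
  cal
}
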