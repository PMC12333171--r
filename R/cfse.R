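# Kernel-density peak finder shared by the gate and generation logic.
# Returns peak locations (descending intensity) with density heights.
find_peaks <- function(x, bw, min_height_frac = 0.05) {
  d <- stats::density(x, bw = bw, n = 1024)
  y <- d$y
  is_max <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  keep <- is_max & y >= min_height_frac * max(y)
  ord <- order(d$x[keep], decreasing = TRUE)
  list(location = d$x[keep][ord], height = y[keep][ord])
}

#' Derive the undivided gate from a non-activated control
#'
#' Places the proliferation gate at `mode - k_sigma * MAD` of the
#' non-activated control's log10 CFSE intensities: events below the gate
#' are counted as divided. The mode is the highest kernel-density peak and
#' the spread is the scaled median absolute deviation.
#'
#' @param control numeric vector of log10 CFSE intensities of the
#'   non-activated control (at least 100 events).
#' @param k_sigma multiplier on the robust spread (default 2.5).
#' @return list of class `gate_spec` with `gate`, `mode`, `spread` and
#'   `k_sigma`.
#' @export
fit_undivided_gate <- function(control, k_sigma = 2.5) {
  control <- control[is.finite(control)]
  if (length(control) < 100)
    stop("need at least 100 control events for a stable mode")
  spread <- stats::mad(control)
  bw <- max(spread / 2, 1e-3)
  pk <- find_peaks(control, bw = bw, min_height_frac = 0.25)
  if (length(pk$location) > 1 &&
      diff(range(pk$location)) > log10(2) / 2)
    stop("control looks multimodal; supply the non-activated control")
  mode_ <- pk$location[which.max(pk$height)]
  structure(list(gate = mode_ - k_sigma * spread, mode = mode_,
                 spread = spread, k_sigma = k_sigma),
            class = "gate_spec")
}

#' Percent proliferating cells
#'
#' Fraction of events strictly below the undivided gate, as a percentage.
#' Events exactly at the gate count as undivided.
#'
#' @param sample numeric vector of log10 CFSE intensities.
#' @param gate a [fit_undivided_gate()] result, or a numeric gate value.
#' @return percent in `[0, 100]`.
#' @export
percent_proliferating <- function(sample, gate) {
  g <- if (inherits(gate, "gate_spec")) gate$gate else as.numeric(gate)
  100 * mean(sample < g - NPX_EPS)
}

#' Count daughter-cell generations
#'
#' Finds kernel-density peaks of the log10 intensity distribution and walks
#' down from the undivided peak, accepting each next peak if its gap from
#' the previous accepted peak is within `spacing * (1 +/- tolerance)`
#' (one division halves the dye: spacing log10(2) ~ 0.301 decades). Peaks
#' at an off-ladder spacing are rejected with a warning.
#'
#' @param sample numeric vector of log10 CFSE intensities (>= 1000 events).
#' @param spacing expected per-division decrement (default `log10(2)`).
#' @param tolerance relative tolerance on the spacing (default 0.2).
#' @param min_height_frac minimum peak height relative to the tallest peak
#'   (default 0.05).
#' @return integer number of daughter-generation peaks.
#' @export
count_generations <- function(sample, spacing = log10(2), tolerance = 0.2,
                              min_height_frac = 0.05) {
  sample <- sample[is.finite(sample)]
  if (length(sample) < 1000)
    stop("need at least 1000 events to count generations")
  pk <- find_peaks(sample, bw = spacing / 8,
                   min_height_frac = min_height_frac)
  if (!length(pk$location))
    stop("no undivided peak detectable")
  loc <- pk$location  # descending intensity; first = undivided peak
  gens <- 0L
  prev <- loc[1]
  rejected <- 0L
  for (p in loc[-1]) {
    gap <- prev - p
    if (gap >= spacing * (1 - tolerance) && gap <= spacing * (1 + tolerance)) {
      gens <- gens + 1L
      prev <- p
    } else {
      rejected <- rejected + 1L
    }
  }
  if (rejected > 0L)
    warning(rejected, " density peak(s) at off-ladder spacing were rejected")
  gens
}

#' Proliferation-inhibition index
#'
#' `100 * (1 - treated / activated)`: the percent reduction of the
#' proliferating fraction in a treated arm relative to the activated
#' control. Used to rank MSC supernatants (the conditioned D3-cMSC
#' supernatant was the strongest inhibitor in the source study).
#'
#' @param treated_percent percent proliferating under treatment.
#' @param activated_percent percent proliferating in the activated control;
#'   must be positive.
#' @return percent inhibition (<= 100; negative values mean enhancement).
#' @export
inhibition_index <- function(treated_percent, activated_percent) {
  if (any(activated_percent <= 0))
    stop("activated control percent must be positive")
  100 * (1 - treated_percent / activated_percent)
}
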