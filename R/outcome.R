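#' Simulate binary toxicity outcomes from NTCP values
#'
#' Draws one independent Bernoulli outcome per patient,
#' `label_i ~ Bernoulli(ntcp_i)`.  Within a Monte Carlo iteration the same
#' label vector is shared by both the ground-truth and alternative model
#' fits; the draw is repeated afresh in every iteration.
#'
#' Uses the current R RNG state, so results are reproducible under
#' `set.seed()`.
#'
#' @param ntcp_values numeric vector of probabilities in `[0, 1]`.
#' @param rng_state_tag optional identifier of the random substream recorded
#'   alongside the labels (bookkeeping only; it does not touch the RNG).
#' @return An object of class `outcome_vector`: list with `labels` (0/1
#'   integer vector), `event_fraction` (`mean(labels)`), `degenerate` (TRUE
#'   when all labels are equal, in which case the downstream fit is
#'   impossible) and `rng_state_tag`.
#' @examples
#' set.seed(1)
#' o <- simulate_outcomes(rep(0.5, 10))
#' o$event_fraction
#' @export
simulate_outcomes <- function(ntcp_values, rng_state_tag = NA_character_) {
  if (!is.numeric(ntcp_values) || length(ntcp_values) == 0L)
    stop("'ntcp_values' must be a non-empty numeric vector")
  if (any(!is.finite(ntcp_values)) ||
      any(ntcp_values < 0) || any(ntcp_values > 1))
    stop("'ntcp_values' must lie in [0, 1]")
  labels <- rbinom(length(ntcp_values), size = 1L, prob = ntcp_values)
  structure(list(labels = as.integer(labels),
                 event_fraction = mean(labels),
                 degenerate = all(labels == labels[1L]),
                 rng_state_tag = rng_state_tag),
            class = "outcome_vector")
}

#' @export
print.outcome_vector <- function(x, ...) {
  cat(sprintf("Simulated outcomes: n = %d, events = %d (%.1f%%)%s\n",
              length(x$labels), sum(x$labels), 100 * x$event_fraction,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
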