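#' Memory-guided saccade task paradigm
#'
#' Defines the six-interval trial structure: central fixation (1500 ms), an
#' eccentric target flash (200 ms) during which fixation must be held, a
#' memory interval (1300 ms), the reaction interval opened by the "go" signal
#' (central dot offset, 1500 ms), a confirmation interval with a visible dot
#' at the target location (2500 ms), and an inter-trial blank (700 ms).
#' Targets appear left or right of centre at one of two eccentricities
#' (10 deg = "near", 18 deg = "far"); ten trials per position give 40 trials,
#' roughly five minutes of recording at the defaults.
#'
#' @param central_fixation_ms,target_flash_ms,memory_ms,reaction_ms,confirmation_ms,intertrial_ms
#'   Interval durations in milliseconds.
#' @param eccentricities_deg Horizontal target eccentricities in degrees;
#'   the smaller is classed "near", the larger "far".
#' @param sides Target sides.
#' @param trials_per_position Trials for each (side, eccentricity) pair.
#' @param sample_rate_hz Tracker sampling rate.
#' @return An object of class `paradigm_spec` with the fields above plus the
#'   derived `trial_duration_ms` and `n_trials`.
#' @export
paradigm_spec <- function(central_fixation_ms = 1500, target_flash_ms = 200,
                          memory_ms = 1300, reaction_ms = 1500,
                          confirmation_ms = 2500, intertrial_ms = 700,
                          eccentricities_deg = c(10, 18),
                          sides = c("left", "right"),
                          trials_per_position = 10,
                          sample_rate_hz = 250) {
  durs <- c(central_fixation_ms, target_flash_ms, memory_ms, reaction_ms,
            confirmation_ms, intertrial_ms)
  if (!all(is.finite(durs)) || any(durs <= 0)) {
    stop("all interval durations must be finite and strictly positive")
  }
  if (length(eccentricities_deg) != 2 || any(eccentricities_deg <= 0) ||
      eccentricities_deg[1] == eccentricities_deg[2]) {
    stop("eccentricities_deg must be two distinct positive values")
  }
  if (!all(sides %in% c("left", "right")) || anyDuplicated(sides)) {
    stop("sides must be a subset of c('left', 'right') without duplicates")
  }
  if (trials_per_position < 1 || sample_rate_hz <= 0) {
    stop("trials_per_position must be >= 1 and sample_rate_hz positive")
  }
  sides <- sort(sides)
  spec <- list(
    central_fixation_ms = central_fixation_ms,
    target_flash_ms = target_flash_ms,
    memory_ms = memory_ms,
    reaction_ms = reaction_ms,
    confirmation_ms = confirmation_ms,
    intertrial_ms = intertrial_ms,
    eccentricities_deg = sort(eccentricities_deg),
    sides = sides,
    trials_per_position = as.integer(trials_per_position),
    sample_rate_hz = sample_rate_hz
  )
  spec$trial_duration_ms <- sum(durs)
  spec$n_trials <- length(eccentricities_deg) * length(sides) *
    spec$trials_per_position
  structure(spec, class = "paradigm_spec")
}

#' @export
print.paradigm_spec <- function(x, ...) {
  cat(sprintf(
    "<paradigm_spec> %d trials (%d per position), trial %g ms, session %.2f min\n",
    x$n_trials, x$trials_per_position, x$trial_duration_ms,
    x$n_trials * x$trial_duration_ms / 60000
  ))
  cat(sprintf("  eccentricities: %s deg; sides: %s; %g Hz sampling\n",
              paste(x$eccentricities_deg, collapse = "/"),
              paste(x$sides, collapse = "/"), x$sample_rate_hz))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Build a randomised trial schedule
#'
#' Produces the ordered trial list for one session: a seeded uniform shuffle
#' of the (side x eccentricity) multiset, with the interval boundary times of
#' every trial. Boundary columns are milliseconds from trial start;
#' `trial_start_ms` places each trial in session time.
#'
#' @param spec A [paradigm_spec()].
#' @param seed Integer seed for the shuffle; `NULL` uses the current RNG state.
#' @return A data frame of class `trial_schedule`, one row per trial, with
#'   columns `trial`, `side`, `target_sign` (-1 left, +1 right),
#'   `eccentricity_deg`, `eccentricity_class` ("near"/"far"),
#'   `trial_start_ms`, and the within-trial boundaries `flash_on_ms`,
#'   `memory_on_ms`, `go_ms`, `confirm_on_ms`, `intertrial_on_ms`,
#'   `trial_end_ms`. The generating spec is attached as attribute `"spec"`.
#' @export
trial_schedule <- function(spec = paradigm_spec(), seed = NULL) {
  stopifnot(inherits(spec, "paradigm_spec"))
  combos <- expand.grid(side = spec$sides,
                        eccentricity_deg = spec$eccentricities_deg,
                        stringsAsFactors = FALSE)
  pool <- combos[rep(seq_len(nrow(combos)), each = spec$trials_per_position), ]
  ord <- with_seed(seed, sample.int(nrow(pool)))
  pool <- pool[ord, , drop = FALSE]

  near <- min(spec$eccentricities_deg)
  flash_on <- spec$central_fixation_ms
  memory_on <- flash_on + spec$target_flash_ms
  go <- memory_on + spec$memory_ms
  confirm_on <- go + spec$reaction_ms
  intertrial_on <- confirm_on + spec$confirmation_ms

  sched <- data.frame(
    trial = seq_len(nrow(pool)),
    side = pool$side,
    target_sign = ifelse(pool$side == "left", -1, 1),
    eccentricity_deg = pool$eccentricity_deg,
    eccentricity_class = ifelse(pool$eccentricity_deg == near, "near", "far"),
    trial_start_ms = (seq_len(nrow(pool)) - 1) * spec$trial_duration_ms,
    flash_on_ms = flash_on,
    memory_on_ms = memory_on,
    go_ms = go,
    confirm_on_ms = confirm_on,
    intertrial_on_ms = intertrial_on,
    trial_end_ms = spec$trial_duration_ms,
    row.names = NULL
  )
  attr(sched, "spec") <- spec
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}
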