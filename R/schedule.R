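# Trial-schedule generation: learning and test phases of the recalibration
# paradigm, with counterbalancing and catch trials.

#' Experiment design configuration
#'
#' Bundles the structural constants of the recalibration paradigm: block
#' layout, the adaptation lag presented during learning, the test-phase SOA
#' grid with its per-condition repetition counts, and catch-trial rates.
#' Defaults reproduce the standard design: 70 blocks, a fixed +/-234 ms
#' audio-visual lag during learning, 13 test SOAs from -233 to +233 ms
#' presented 8..20..8 times per condition (176 trials per condition, 704
#' in total over the 2 x 2 design), and 20% catch trials in both phases.
#'
#' @param n_blocks Number of blocks (each a learning phase followed by a short
#'   test phase).
#' @param learning_trials_per_block Learning trials per block after the first.
#' @param learning_trials_first_block Learning trials in block 1.
#' @param test_trials_per_block Nominal test trials per block after the first.
#' @param test_trials_first_block Nominal test trials in block 1.
#' @param adaptation_lag_ms Absolute audio-visual lag (ms) during learning.
#' @param action_to_stimulus_delay_ms Delay (ms) between the key-press and the
#'   first stimulus of the pair.
#' @param learning_catch_rate,test_catch_rate Proportion of catch trials.
#' @param soa_grid_ms Test-phase SOA grid (ms), strictly increasing and
#'   symmetric about 0; negative = audio before video.
#' @param per_condition_soa_counts Presentations of each SOA per condition;
#'   same length as `soa_grid_ms` and symmetric.
#' @param catch_increment Relative luminance/loudness increment of learning
#'   catch stimuli (carried as metadata only).
#'
#' @return A `design_config` object (validated list).
#' @examples
#' cfg <- design_config()
#' sum(cfg$per_condition_soa_counts) # 176 per condition
#' @export
design_config <- function(n_blocks = 70,
                          learning_trials_per_block = 20,
                          learning_trials_first_block = 40,
                          test_trials_per_block = 10,
                          test_trials_first_block = 12,
                          adaptation_lag_ms = 234,
                          action_to_stimulus_delay_ms = 200,
                          learning_catch_rate = 0.20,
                          test_catch_rate = 0.20,
                          soa_grid_ms = c(-233, -166, -133, -100, -66, -33, 0,
                                          33, 66, 100, 133, 166, 233),
                          per_condition_soa_counts = c(8, 10, 12, 14, 16, 18, 20,
                                                       18, 16, 14, 12, 10, 8),
                          catch_increment = 0.133) {
  assert_count(n_blocks, "n_blocks", lower = 1)
  assert_count(learning_trials_per_block, "learning_trials_per_block")
  assert_count(learning_trials_first_block, "learning_trials_first_block")
  assert_count(test_trials_per_block, "test_trials_per_block")
  assert_count(test_trials_first_block, "test_trials_first_block")
  assert_scalar_number(adaptation_lag_ms, "adaptation_lag_ms", lower = 0)
  assert_scalar_number(action_to_stimulus_delay_ms, "action_to_stimulus_delay_ms", lower = 0)
  assert_scalar_number(learning_catch_rate, "learning_catch_rate", 0, 0.999)
  assert_scalar_number(test_catch_rate, "test_catch_rate", 0, 0.999)
  assert_scalar_number(catch_increment, "catch_increment", lower = 0)

  n <- length(soa_grid_ms)
  if (length(per_condition_soa_counts) != n) {
    abort("`per_condition_soa_counts` must have the same length as `soa_grid_ms`.",
          class = "avrecal_config_error")
  }
  if (n > 1 && any(diff(soa_grid_ms) <= 0)) {
    abort("`soa_grid_ms` must be strictly increasing.", class = "avrecal_config_error")
  }
  if (any(soa_grid_ms + rev(soa_grid_ms) != 0)) {
    abort("`soa_grid_ms` must be symmetric about 0.", class = "avrecal_config_error")
  }
  if (any(per_condition_soa_counts < 0) ||
      any(per_condition_soa_counts != as.integer(per_condition_soa_counts))) {
    abort("`per_condition_soa_counts` must be nonnegative integers.",
          class = "avrecal_config_error")
  }
  if (any(per_condition_soa_counts != rev(per_condition_soa_counts))) {
    abort("`per_condition_soa_counts` must be symmetric.", class = "avrecal_config_error")
  }

  structure(
    list(
      n_blocks = as.integer(n_blocks),
      learning_trials_per_block = as.integer(learning_trials_per_block),
      learning_trials_first_block = as.integer(learning_trials_first_block),
      test_trials_per_block = as.integer(test_trials_per_block),
      test_trials_first_block = as.integer(test_trials_first_block),
      adaptation_lag_ms = adaptation_lag_ms,
      action_to_stimulus_delay_ms = action_to_stimulus_delay_ms,
      learning_catch_rate = learning_catch_rate,
      test_catch_rate = test_catch_rate,
      soa_grid_ms = as.numeric(soa_grid_ms),
      per_condition_soa_counts = as.integer(per_condition_soa_counts),
      catch_increment = catch_increment
    ),
    class = "design_config"
  )
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  cat("  blocks:", x$n_blocks,
      sprintf("(learning %d/%d, test %d/%d trials first/later)\n",
              x$learning_trials_first_block, x$learning_trials_per_block,
              x$test_trials_first_block, x$test_trials_per_block))
  cat("  adaptation lag:", x$adaptation_lag_ms, "ms; catch rates:",
      x$learning_catch_rate, "(learning),", x$test_catch_rate, "(test)\n")
  cat("  SOA grid (ms):", paste(x$soa_grid_ms, collapse = ", "), "\n")
  cat("  per-condition counts:", paste(x$per_condition_soa_counts, collapse = ", "),
      sprintf("(sum %d; %d over 4 conditions)\n",
              sum(x$per_condition_soa_counts), 4L * sum(x$per_condition_soa_counts)))
  invisible(x)
}

#' Counterbalancing mapping
#'
#' A mapping specification ties together the three binary counterbalancing
#' choices of the paradigm: which flash colour goes with which tone, which
#' action (or cue) produces which audio-visual pair, and which action's pair
#' carries the sound-first versus sound-second lag during learning.
#'
#' @param color_tone_map Named character vector of length 2 mapping flash
#'   colours to tone frequencies, e.g. `c(yellow = "1600Hz", cyan = "400Hz")`.
#' @param action_pair_map Named character vector mapping the two actions (or
#'   cues) to the two audio-visual pair labels.
#' @param action_order_map Named character vector mapping the two actions (or
#'   cues) to `"sound-first"` / `"sound-second"`.
#' @param experiment_mode One of `"action"`, `"visual-cue"`, `"tactile-cue"`.
#'
#' @return A `mapping_spec` object. Each component is checked to be a
#'   bijection.
#' @seealso [assign_counterbalancing()] to enumerate all 8 cells.
#' @export
mapping_spec <- function(color_tone_map, action_pair_map, action_order_map,
                         experiment_mode = "action") {
  check_bijection <- function(m, name) {
    if (!is.character(m) || length(m) != 2L || is.null(names(m)) ||
        anyDuplicated(names(m)) || anyDuplicated(m)) {
      abort(sprintf("`%s` must map 2 distinct keys to 2 distinct values.", name),
            class = "avrecal_config_error")
    }
  }
  check_bijection(color_tone_map, "color_tone_map")
  check_bijection(action_pair_map, "action_pair_map")
  check_bijection(action_order_map, "action_order_map")
  if (!setequal(action_order_map, adaptation_orders())) {
    abort("`action_order_map` values must be 'sound-first' and 'sound-second'.",
          class = "avrecal_config_error")
  }
  if (!setequal(names(action_pair_map), names(action_order_map))) {
    abort("`action_pair_map` and `action_order_map` must share the same actions.",
          class = "avrecal_config_error")
  }
  experiment_mode <- match.arg(experiment_mode, c("action", "visual-cue", "tactile-cue"))
  structure(
    list(color_tone_map = color_tone_map,
         action_pair_map = action_pair_map,
         action_order_map = action_order_map,
         experiment_mode = experiment_mode),
    class = "mapping_spec"
  )
}

#' @export
print.mapping_spec <- function(x, ...) {
  cat("<mapping_spec>", x$experiment_mode, "mode\n")
  for (nm in c("color_tone_map", "action_pair_map", "action_order_map")) {
    cat(" ", nm, ":", paste(names(x[[nm]]), x[[nm]], sep = " -> ", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Assign a subject to one of the 8 counterbalancing cells
#'
#' The three binary mappings (colour-tone pairing, action-to-pair assignment,
#' action-to-temporal-order assignment) define 2 x 2 x 2 = 8 cells; subjects
#' are assigned by cycling deterministically through them, so subject `i` and
#' subject `i + 8` share a cell.
#'
#' @param subject_index Zero-based subject index.
#' @param experiment_mode `"action"` uses left/right key-presses; the control
#'   modes use circle/square visual cues or left/right tactile cues.
#' @return A [mapping_spec()].
#' @examples
#' identical(assign_counterbalancing(0), assign_counterbalancing(8))
#' @export
assign_counterbalancing <- function(subject_index, experiment_mode = "action") {
  assert_count(subject_index, "subject_index", lower = 0)
  experiment_mode <- match.arg(experiment_mode, c("action", "visual-cue", "tactile-cue"))
  cell <- subject_index %% 8
  b1 <- cell %% 2          # colour-tone pairing
  b2 <- (cell %/% 2) %% 2  # action -> pair
  b3 <- (cell %/% 4) %% 2  # action -> temporal order

  actions <- switch(experiment_mode,
    "action" = c("left", "right"),
    "visual-cue" = c("circle", "square"),
    "tactile-cue" = c("left-tactile", "right-tactile")
  )
  tones <- if (b1 == 0) c("1600Hz", "400Hz") else c("400Hz", "1600Hz")
  color_tone <- setNames(tones, c("yellow", "cyan"))
  pairs <- paste(c("yellow", "cyan"), color_tone, sep = "+")
  if (b2 == 1) pairs <- rev(pairs)
  action_pair <- setNames(pairs, actions)
  orders <- if (b3 == 0) adaptation_orders() else rev(adaptation_orders())
  action_order <- setNames(orders, actions)

  mapping_spec(color_tone, action_pair, action_order, experiment_mode)
}

empty_trials <- function() {
  tibble::tibble(
    subject_id = character(), experiment_mode = character(), block = integer(),
    phase = character(), trial = integer(), action_or_cue = character(),
    adaptation_order = character(), outcome_predicted = logical(),
    soa_ms = numeric(), is_catch = logical(), response = character()
  )
}

# Action that triggers a trial whose *presented* pair was learned with the
# given adaptation order: the matching action when the outcome is predicted,
# the other action when it is unpredicted.
action_for_condition <- function(mapping, order, predicted) {
  learned <- names(mapping$action_order_map)[match(order, mapping$action_order_map)]
  if (predicted) learned else setdiff(names(mapping$action_order_map), learned)
}

#' Generate the test-phase trial schedule
#'
#' Builds every test trial of one subject's session: for each of the four
#' conditions (adaptation order x outcome predictedness) each SOA of the grid
#' appears exactly its per-condition count of times (704 non-catch trials
#' under the default design), plus identity-probe catch trials interleaved at
#' the configured rate. Catch trials are additional rows, so the per-condition
#' analysis counts are untouched. Trial order is a seeded permutation and
#' trials are partitioned over blocks (12 in the first block, 10 thereafter,
#' any surplus in the final block).
#'
#' @param config A [design_config()].
#' @param mapping A [mapping_spec()], typically from
#'   [assign_counterbalancing()].
#' @param seed Integer seed; the schedule is a deterministic function of
#'   `(config, mapping, seed)`.
#' @param subject_id Identifier written into every row.
#'
#' @return A tibble of trial records with columns `subject_id`,
#'   `experiment_mode`, `block`, `phase`, `trial`, `action_or_cue`,
#'   `adaptation_order`, `outcome_predicted`, `soa_ms`, `is_catch`,
#'   `response` (filled with `"none"`; see [simulate_responses()]).
#' @examples
#' sched <- build_test_schedule(design_config(), assign_counterbalancing(0), seed = 1)
#' sum(!sched$is_catch) # 704
#' @export
build_test_schedule <- function(config, mapping, seed, subject_id = "s01") {
  stopifnot(inherits(config, "design_config"), inherits(mapping, "mapping_spec"))
  counts <- config$per_condition_soa_counts
  grid <- config$soa_grid_ms
  n_cond <- sum(counts)
  if (n_cond == 0L) return(empty_trials())

  conds <- expand.grid(adaptation_order = adaptation_orders(),
                       outcome_predicted = c(TRUE, FALSE),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  noncatch <- dplyr::bind_rows(lapply(seq_len(nrow(conds)), function(k) {
    ord <- conds$adaptation_order[k]
    pred <- conds$outcome_predicted[k]
    tibble::tibble(
      action_or_cue = action_for_condition(mapping, ord, pred),
      adaptation_order = ord,
      outcome_predicted = pred,
      soa_ms = rep(grid, counts),
      is_catch = FALSE
    )
  }))
  n_nc <- nrow(noncatch)

  rate <- config$test_catch_rate
  n_catch <- round(rate / (1 - rate) * n_nc)

  withr::with_seed(seed, {
    if (n_catch > 0) {
      k <- sample.int(nrow(conds), n_catch, replace = TRUE)
      catch <- tibble::tibble(
        action_or_cue = vapply(k, function(i) {
          action_for_condition(mapping, conds$adaptation_order[i], conds$outcome_predicted[i])
        }, character(1)),
        adaptation_order = conds$adaptation_order[k],
        outcome_predicted = conds$outcome_predicted[k],
        soa_ms = sample(grid, n_catch, replace = TRUE, prob = counts / sum(counts)),
        is_catch = TRUE
      )
    } else {
      catch <- noncatch[0, ]
    }

    # Block sizes for the scheduled (non-catch) trials: nominal first/later
    # sizes, with any surplus carried by the final block.
    sizes <- c(config$test_trials_first_block,
               rep(config$test_trials_per_block, config$n_blocks - 1L))
    surplus <- n_nc - sum(sizes)
    sizes[config$n_blocks] <- sizes[config$n_blocks] + surplus
    if (sizes[config$n_blocks] < 0L) {
      # Fewer trials than the nominal layout: fill blocks in order instead.
      sizes <- pmax(pmin(sizes, n_nc - c(0, cumsum(sizes))[seq_along(sizes)]), 0L)
    }
    noncatch <- noncatch[sample.int(n_nc), ]
    noncatch$block <- rep.int(seq_len(config$n_blocks), times = sizes)
    if (n_catch > 0) catch$block <- sample.int(config$n_blocks, n_catch, replace = TRUE)

    trials <- dplyr::bind_rows(noncatch, catch)
    trials$.key <- runif(nrow(trials))
  })

  trials <- dplyr::arrange(trials, .data$block, .data$.key)
  trials$.key <- NULL
  trials$subject_id <- subject_id
  trials$experiment_mode <- mapping$experiment_mode
  trials$phase <- "test"
  trials$trial <- seq_len(nrow(trials))
  trials$response <- "none"
  trials[, names(empty_trials())]
}

#' Generate the learning-phase trial schedule
#'
#' Each block's learning phase exposes the subject to the fixed audio-visual
#' adaptation lag: the action (or cue) chosen on each trial determines, via
#' the counterbalancing mapping, whether the sound leads (`soa_ms` =
#' `-adaptation_lag_ms`) or lags (`+adaptation_lag_ms`) the flash. Block 1
#' has the longer initial learning phase. A seeded subset of trials at the
#' configured rate is flagged as catch trials (brighter flash / louder tone).
#' Actions are chosen Bernoulli(0.5) per trial, mirroring the instruction to
#' balance left and right presses.
#'
#' @inheritParams build_test_schedule
#' @return A tibble of trial records (`phase == "learning"`,
#'   `outcome_predicted` is `NA`).
#' @examples
#' lrn <- build_learning_schedule(design_config(), assign_counterbalancing(0), seed = 1)
#' nrow(lrn) # 40 + 69 * 20 = 1420
#' @export
build_learning_schedule <- function(config, mapping, seed, subject_id = "s01") {
  stopifnot(inherits(config, "design_config"), inherits(mapping, "mapping_spec"))
  sizes <- c(config$learning_trials_first_block,
             rep(config$learning_trials_per_block, config$n_blocks - 1L))
  n <- sum(sizes)
  if (n == 0L) return(empty_trials())
  actions <- names(mapping$action_order_map)

  withr::with_seed(seed, {
    act <- sample(actions, n, replace = TRUE)
    n_catch <- round(config$learning_catch_rate * n)
    catch_idx <- sample.int(n, n_catch)
  })

  ord <- unname(mapping$action_order_map[act])
  is_catch <- logical(n)
  is_catch[catch_idx] <- TRUE
  tibble::tibble(
    subject_id = subject_id,
    experiment_mode = mapping$experiment_mode,
    block = rep.int(seq_len(config$n_blocks), times = sizes),
    phase = "learning",
    trial = seq_len(n),
    action_or_cue = act,
    adaptation_order = ord,
    outcome_predicted = NA,
    soa_ms = ifelse(ord == "sound-first", -config$adaptation_lag_ms,
                    config$adaptation_lag_ms),
    is_catch = is_catch,
    response = "none"
  )
}
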