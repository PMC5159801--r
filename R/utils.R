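# Internal helpers shared across modules.

# Deterministic seed spawning: one master seed yields independent stage seeds
# (Lehmer-style multiplicative step, kept inside the 32-bit integer range so
# set.seed() accepts the result on any platform).
spawn_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1
  s <- (abs(master) %% m) + 1
  for (k in seq_len(2L)) s <- (s * 48271) %% m
  as.integer((s + abs(stage)) %% m)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].", name, lower, upper),
          class = "avrecal_config_error")
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0) {
  assert_scalar_number(x, name, lower = lower)
  if (x != as.integer(x)) {
    abort(sprintf("`%s` must be a whole number.", name), class = "avrecal_config_error")
  }
  invisible(x)
}

# Single condition key used in fits tables and reports, split back on demand.
condition_label <- function(adaptation_order, outcome_predicted) {
  paste0(adaptation_order, "/", ifelse(outcome_predicted, "predicted", "unpredicted"))
}

split_condition_label <- function(label) {
  parts <- strsplit(label, "/", fixed = TRUE)
  tibble::tibble(
    adaptation_order = vapply(parts, `[[`, character(1), 1L),
    outcome_predicted = vapply(parts, `[[`, character(1), 2L) == "predicted"
  )
}

adaptation_orders <- function() c("sound-first", "sound-second")

format_p <- function(p) {
  ifelse(p < 0.001, "< 0.001", sprintf("= %.3f", p))
}

# Atomic write: materialize next to the destination, then rename, so a failed
# run never leaves a truncated artifact behind.
write_atomically <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}
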