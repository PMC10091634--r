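# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Separations (number of digit distractors strictly between T1 and T2)
# used by the task design: {0, 1, 2, 4, 5, 6, 8}.
RSVP_SEPARATIONS <- c(0L, 1L, 2L, 4L, 5L, 6L, 8L)

# Separations entering the global AB/AM summary metrics.
GLOBAL_SEPARATIONS <- c(0L, 1L, 2L)

GROUP_LEVELS <- c("CI", "HC")

# Classed condition so callers can catch specific failures with
# tryCatch(..., rsvp_error_<class> = ...) or testthat::expect_error(class =).
stop_rsvp <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("rsvp_error_", class), "rsvp_error")))
}

assert_group <- function(group) {
  if (!(is.character(group) && length(group) == 1L && group %in% GROUP_LEVELS)) {
    stop_rsvp(sprintf("group must be one of %s", paste(GROUP_LEVELS, collapse = ", ")),
              "invalid_group")
  }
  group
}

assert_separation <- function(separation) {
  if (!(length(separation) == 1L && is.numeric(separation) &&
        separation %in% RSVP_SEPARATIONS)) {
    stop_rsvp(sprintf("separation must be one of {%s}",
                      paste(RSVP_SEPARATIONS, collapse = ", ")),
              "invalid_separation")
  }
  as.integer(separation)
}

# Labels as a character vector restricted to CI/HC.
assert_labels <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% GROUP_LEVELS)) {
    stop_rsvp("labels must all be 'CI' or 'HC'", "invalid_label")
  }
  labels
}
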