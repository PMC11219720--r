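# internal helpers

abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "hemobia_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

SEGMENTS <- c("right_arm", "left_arm", "torso", "right_leg", "left_leg")
FREQUENCIES_KHZ <- c(1, 5, 50, 250, 500, 1000)
FLUID_KINDS <- c("balanced_crystalloid", "dextrose5", "albumin20", "whole_blood")
GROUPS <- c("crystalloid", "crystalloid_dextrose", "crystalloid_albumin")
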