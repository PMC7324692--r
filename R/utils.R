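# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# round half away from zero (documented convention for slice indices);
# base round() rounds half to even, which would make the middle-slice
# index depend on parity of the slice count
round_half_up <- function(x) floor(x + 0.5)

qa_abort <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "mvctqa_error"), ...)
}

qa_warn <- function(msg, class) {
  rlang::warn(msg, class = c(class, "mvctqa_warning"))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# rotation of (x, z) points by multiples of 90 degrees, exact
rotate_xz <- function(xz, angle_deg) {
  stopifnot(angle_deg %in% c(0, 90, 180, 270))
  xz <- matrix(xz, ncol = 2L)
  r <- switch(as.character(angle_deg),
    "0"   = diag(2),
    "90"  = matrix(c(0, 1, -1, 0), 2, 2),
    "180" = matrix(c(-1, 0, 0, -1), 2, 2),
    "270" = matrix(c(0, -1, 1, 0), 2, 2)
  )
  xz %*% t(r)
}
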