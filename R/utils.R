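# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a private RNG stream; the caller's .Random.seed is
# restored afterwards so no simulation leaks global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

sg_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "staygreenr_error")))
}

sg_assert <- function(cond, msg, class = "sg_invalid_argument") {
  if (!isTRUE(cond)) sg_stop(msg, class)
}

# Rectangles are c(r0, c0, r1, c1): 0-based, half-open in both axes
# (rows r0 <= r < r1, cols c0 <= c < c1), matching array row/col order.
as_rect <- function(x) {
  sg_assert(is.numeric(x) && length(x) == 4L && all(is.finite(x)),
            "rectangle must be four finite numbers c(r0, c0, r1, c1)")
  x <- as.integer(x)
  sg_assert(x[1] < x[3] && x[2] < x[4],
            "rectangle must satisfy r0 < r1 and c0 < c1")
  sg_assert(all(x[1:2] >= 0L), "rectangle indices are 0-based, must be >= 0")
  x
}

rect_rows <- function(rect) (rect[1] + 1L):rect[3]
rect_cols <- function(rect) (rect[2] + 1L):rect[4]
rect_npix <- function(rect) (rect[3] - rect[1]) * (rect[4] - rect[2])

rect_in_bounds <- function(rect, dims) {
  rect[1] >= 0L && rect[2] >= 0L && rect[3] <= dims[1] && rect[4] <= dims[2]
}

rects_overlap <- function(a, b) {
  a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
}
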