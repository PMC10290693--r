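#' Stain-specific HSV gates
#'
#' Each immunohistochemical stain produces a characteristic chromogen color
#' distribution (DAB brown for 4G8 and 6E10, Nova Red for NAB228), captured
#' as inclusive per-channel intervals on the 8-bit OpenCV-style HSV scale:
#' H in `[0, 179]` (degrees halved), S and V in `[0, 255]`. A pixel passes
#' the gate when all three of its HSV components fall inside the intervals.
#'
#' The built-in profiles are the workflow's published gate values:
#' \describe{
#'   \item{4G8}{H (0, 40), S (10, 255), V (0, 220)}
#'   \item{NAB228}{H (0, 100), S (1, 255), V (0, 250)}
#'   \item{6E10}{H (0, 40), S (10, 255), V (0, 220)}
#' }
#'
#' @param name one of `"4G8"`, `"NAB228"`, `"6E10"`, or `"custom"`.
#' @param h_range,s_range,v_range inclusive integer intervals `c(lo, hi)`;
#'   required for `"custom"`, ignored otherwise.
#' @return An object of class `stain_profile`.
#' @examples
#' stain_profile("4G8")
#' stain_profile("custom", c(0, 30), c(50, 255), c(0, 200))
#' @export
stain_profile <- function(name, h_range = NULL, s_range = NULL, v_range = NULL) {
  builtin <- list(
    `4G8`    = list(h = c(0, 40),  s = c(10, 255), v = c(0, 220)),
    `NAB228` = list(h = c(0, 100), s = c(1, 255),  v = c(0, 250)),
    `6E10`   = list(h = c(0, 40),  s = c(10, 255), v = c(0, 220))
  )
  if (identical(name, "custom")) {
    assert_that(!is.null(h_range) && !is.null(s_range) && !is.null(v_range),
                "custom stain profile needs h_range, s_range and v_range")
    gates <- list(h = h_range, s = s_range, v = v_range)
  } else {
    assert_that(name %in% names(builtin),
                "unknown stain '%s' (use 4G8, NAB228, 6E10 or custom)", name)
    gates <- builtin[[name]]
    if (!is.null(h_range)) gates$h <- h_range
    if (!is.null(s_range)) gates$s <- s_range
    if (!is.null(v_range)) gates$v <- v_range
  }
  for (ch in c("h", "s", "v")) {
    g <- gates[[ch]]
    assert_that(is.numeric(g) && length(g) == 2L && g[1] <= g[2],
                "stain gate '%s' must be c(lo, hi) with lo <= hi", ch)
  }
  structure(list(name = name, h_range = as.numeric(gates$h),
                 s_range = as.numeric(gates$s), v_range = as.numeric(gates$v)),
            class = "stain_profile")
}

#' @export
print.stain_profile <- function(x, ...) {
  cat(sprintf("<stain_profile> %s: H [%g, %g], S [%g, %g], V [%g, %g]\n",
              x$name, x$h_range[1], x$h_range[2], x$s_range[1], x$s_range[2],
              x$v_range[1], x$v_range[2]))
  invisible(x)
}

as_stain_profile <- function(stain) {
  if (inherits(stain, "stain_profile")) return(stain)
  if (is.character(stain) && length(stain) == 1L) return(stain_profile(stain))
  stop("`stain` must be a stain_profile or a stain name", call. = FALSE)
}
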