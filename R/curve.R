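#' AFM force-curve container
#'
#' A force curve is a two-column tibble: either a relaxation curve
#' (`time_ms`, `force_nN`; force at fixed approach vs. delay time) or
#' a loading curve (`z_nm`, `force_nN`; force vs. Z-piezo
#' displacement). The abscissa must be strictly increasing.
#'
#' @param x Abscissa: time in ms (relaxation) or Z displacement in nm
#'   (loading), strictly increasing.
#' @param force Force (nN), same length as `x`.
#' @param kind `"relaxation"` or `"loading"`.
#' @param id Optional curve identifier stored as an attribute.
#' @param notes Optional acquisition notes stored as an attribute.
#' @return A tibble of class `"afm_curve"` with columns named per
#'   `kind` and attributes `kind`, `id`, `notes`.
#' @examples
#' afm_curve(c(0, 100, 200), c(104, 80, 70), kind = "relaxation")
#' @export
afm_curve <- function(x, force, kind = c("relaxation", "loading"),
                      id = NULL, notes = NULL) {
  kind <- match.arg(kind)
  if (length(x) != length(force)) {
    abort_data("`x` and `force` must have the same length.")
  }
  if (any(!is.finite(x)) || any(!is.finite(force))) {
    abort_data("force-curve values must be finite.")
  }
  if (length(x) >= 2 && any(diff(x) <= 0)) {
    abort_data(sprintf("the %s axis must be strictly increasing.",
                       if (kind == "relaxation") "time" else "displacement"))
  }
  out <- if (kind == "relaxation") {
    tibble::tibble(time_ms = as.numeric(x), force_nN = as.numeric(force))
  } else {
    tibble::tibble(z_nm = as.numeric(x), force_nN = as.numeric(force))
  }
  class(out) <- c("afm_curve", class(out))
  attr(out, "kind") <- kind
  attr(out, "id") <- id
  attr(out, "notes") <- notes
  out
}

#' @export
print.afm_curve <- function(x, ...) {
  cat(sprintf("<AFM %s curve, %d points%s>\n", curve_kind(x), nrow(x),
              if (is.null(attr(x, "id"))) "" else paste0(", id: ", attr(x, "id"))))
  NextMethod()
}

#' Kind of a force curve
#'
#' @param curve An [afm_curve()].
#' @return `"relaxation"` or `"loading"`.
#' @export
curve_kind <- function(curve) {
  k <- attr(curve, "kind")
  if (!is.null(k)) {
    return(k)
  }
  if ("time_ms" %in% names(curve)) "relaxation" else "loading"
}

curve_x <- function(curve) {
  if (curve_kind(curve) == "relaxation") curve$time_ms else curve$z_nm
}
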