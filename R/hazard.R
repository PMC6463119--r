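#' Fixed hazard ratios by smoking status
#'
#' The model elevates the never-smoker lung cancer hazard \eqn{\lambda} by a
#' factor `kS` for current smokers and `kE` for ex-smokers, and the
#' non-lung-cancer mortality \eqn{\mu} by factors `1 + qS` and `1 + qE`.
#' These four quantities are not estimated: they are taken from the
#' epidemiological literature and held fixed during fitting; the sensitivity
#' analysis perturbs `kS` only.
#'
#' @param kS lung cancer hazard ratio for current smokers (vs never-smokers).
#' @param kE lung cancer hazard ratio for ex-smokers.
#' @param qS excess fraction of other-cause mortality for current smokers.
#' @param qE excess fraction of other-cause mortality for ex-smokers.
#' @return An object of class `lc_hazard_ratios`.
#' @seealso [default_hazard_ratios()] for literature values by sex.
#' @export
hazard_ratios <- function(kS, kE, qS, qE) {
  v <- c(kS = kS, kE = kE, qS = qS, qE = qE)
  if (any(!is.finite(v)) || any(v < 0))
    stop("hazard ratios must be finite and nonnegative", call. = FALSE)
  structure(as.list(v), class = "lc_hazard_ratios")
}

#' Literature hazard ratios for Japanese men and women
#'
#' Default fixed values of the smoking-related hazard ratios: for men
#' `kS = 4.94`, `kE = 2.20`, `qS = 0.49`, `qE = 0.20`; for women `kS = 4.25`,
#' `kE = 2.19`, `qS = 0.51`, `qE = 0.46`.
#'
#' @param sex `"male"` or `"female"`.
#' @return An `lc_hazard_ratios` object.
#' @export
default_hazard_ratios <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (sex == "male") {
    hazard_ratios(kS = 4.94, kE = 2.20, qS = 0.49, qE = 0.20)
  } else {
    hazard_ratios(kS = 4.25, kE = 2.19, qS = 0.51, qE = 0.46)
  }
}

#' @export
print.lc_hazard_ratios <- function(x, ...) {
  cat(sprintf("<hazard ratios> kS = %.3g, kE = %.3g, qS = %.3g, qE = %.3g\n",
              x$kS, x$kE, x$qS, x$qE))
  invisible(x)
}

.check_hr <- function(hr) {
  if (!inherits(hr, "lc_hazard_ratios"))
    stop("expected an `lc_hazard_ratios` object (see `hazard_ratios()`)",
         call. = FALSE)
  hr
}
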