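#' Treatment codes of the six-bottle microcosm design
#'
#' The experimental design exposes the same seawater to six manipulations:
#' unfiltered controls under a light/dark cycle and in continuous dark
#' (`CT_L`, `CT_D`), 1-um prefiltration removing most protistan grazers
#' (`PR_L`, `PR_D`), a 1:4 dilution with 0.2-um filtrate reducing both
#' grazing encounters and resource competition (`DI_L`), and a 1:4 dilution
#' with 30-kDa filtrate additionally reducing viral pressure (`VR_L`).
#'
#' Each treatment retains a fraction of the ambient grazing, resource and
#' viral pressures. The controls retain all of them; predator reduction
#' zeroes grazing; dilution scales encounter-dependent grazing and resource
#' competition by the dilution factor `D` but leaves viruses untouched
#' (0.2-um filtrate passes viruses); virus reduction scales all three by
#' `D`. Dark incubations exist only for CT and PR.
#'
#' @param D Dilution factor: fraction of whole seawater retained after
#'   dilution with particle-free water. Dimensionless, in (0, 1); the
#'   study design uses 0.25 (a 1:4 dilution).
#'
#' @return A tibble with one row per treatment code and columns `code`,
#'   `light` (logical), `grazer_factor`, `resource_factor`, `virus_factor`
#'   (fractions of ambient pressure retained) and `start_dilution` (the
#'   fraction of starting cells retained: `D` for DI and VR, 1 otherwise).
#'
#' @examples
#' treatment_codes()
#' @export
treatment_codes <- function(D = 0.25) {
  check_dilution_factor(D)
  tibble::tibble(
    code            = c("CT_L", "CT_D", "PR_L", "PR_D", "DI_L", "VR_L"),
    light           = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    grazer_factor   = c(1, 1, 0, 0, D, D),
    resource_factor = c(1, 1, 1, 1, D, D),
    virus_factor    = c(1, 1, 1, 1, 1, D),
    start_dilution  = c(1, 1, 1, 1, D, D)
  )
}

check_dilution_factor <- function(D) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D)) {
    stop("`D` must be a single finite number", call. = FALSE)
  }
  if (D <= 0 || D >= 1) {
    stop("`D` must lie strictly between 0 and 1 (D = 1 makes the ",
         "treatment system singular); got ", D, call. = FALSE)
  }
  invisible(D)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`", name, "` must be finite numeric; got ",
         paste(utils::head(x, 3), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
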