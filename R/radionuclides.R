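#' Radionuclide physical and biological half-times
#'
#' Bundles the three half-times that drive the biexponential tumor dose-rate
#' curve of radioimmunotherapy: the physical half-life `Tp` of the
#' radionuclide and the biological uptake (`Tu`) and clearance (`Tb`)
#' half-times of the radiolabeled antibody in the tumor.  All times are in
#' days.  `Tb > Tu` is required: clearance slower than uptake is what makes
#' the effective clearance half-time exceed the effective uptake half-time,
#' so that the dose rate is non-negative.
#'
#' @param name character label, e.g. `"225Ac"`.
#' @param Tp physical half-life, days.
#' @param Tb biological clearance half-time, days.
#' @param Tu biological uptake half-time, days.
#' @return an object of class `radionuclide`.
#' @seealso [effective_times()], [radionuclide_registry()]
#' @examples
#' radionuclide("90Y", Tp = 64.1 / 24, Tb = 8, Tu = 3)
#' @export
radionuclide <- function(name, Tp, Tb, Tu) {
  stopifnot(is.character(name), length(name) == 1L)
  for (v in list(Tp = Tp, Tb = Tb, Tu = Tu)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("half-times 'Tp', 'Tb', 'Tu' must be single positive numbers",
           call. = FALSE)
    }
  }
  if (Tb <= Tu) {
    stop("'Tb' must exceed 'Tu' (clearance slower than uptake), otherwise ",
         "the effective clearance half-time would not exceed the effective ",
         "uptake half-time", call. = FALSE)
  }
  structure(list(name = name, Tp = Tp, Tb = Tb, Tu = Tu),
            class = "radionuclide")
}

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf("<radionuclide %s>  Tp = %.4g d,  Tb = %.4g d,  Tu = %.4g d\n",
              x$name, x$Tp, x$Tb, x$Tu))
  invisible(x)
}

#' Built-in radionuclide registry
#'
#' The four radionuclides commonly considered for radioimmunotherapy, with
#' their physical half-lives and the biological uptake/clearance half-times
#' of their radiolabeled antibodies.  Nominal physical half-lives are the
#' rounded literature values (8 d for 131I, 10 d for 225Ac);
#' `exact_half_lives = TRUE` substitutes the exact isotope values
#' (8.02 d and 9.92 d).
#'
#' @param exact_half_lives logical; use exact isotope physical half-lives
#'   for 131I and 225Ac instead of the nominal rounded ones.
#' @return named list of [radionuclide()] objects
#'   (`"90Y"`, `"131I"`, `"177Lu"`, `"225Ac"`).
#' @examples
#' names(radionuclide_registry())
#' radionuclide_registry()[["177Lu"]]
#' @export
radionuclide_registry <- function(exact_half_lives = FALSE) {
  list(
    "90Y"   = radionuclide("90Y",   Tp = 64.1 / 24, Tb = 8.00, Tu = 3.00),
    "131I"  = radionuclide("131I",  Tp = if (exact_half_lives) 8.02 else 8.0,
                           Tb = 2.50, Tu = 1.20),
    "177Lu" = radionuclide("177Lu", Tp = 6.7,  Tb = 3.50, Tu = 1.15),
    "225Ac" = radionuclide("225Ac", Tp = if (exact_half_lives) 9.92 else 10.0,
                           Tb = 9.50, Tu = 3.20)
  )
}

#' Look up a radionuclide by name, with optional overrides
#'
#' @param name registry key (`"90Y"`, `"131I"`, `"177Lu"`, `"225Ac"`).
#' @param overrides optional named list overriding `Tp`, `Tb` or `Tu` (days).
#' @inheritParams radionuclide_registry
#' @return a [radionuclide()] object.
#' @examples
#' get_radionuclide("131I")$Tb        # 2.5 days
#' get_radionuclide("90Y", overrides = list(Tb = 6))
#' @export
get_radionuclide <- function(name, overrides = NULL, exact_half_lives = FALSE) {
  reg <- radionuclide_registry(exact_half_lives)
  if (!name %in% names(reg)) {
    stop(sprintf("unknown radionuclide '%s'; available: %s", name,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  }
  ph <- reg[[name]]
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), c("Tp", "Tb", "Tu"))
    if (length(bad)) {
      stop("unknown override field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (f in names(overrides)) ph[[f]] <- overrides[[f]]
    ph <- radionuclide(ph$name, ph$Tp, ph$Tb, ph$Tu)  # re-validate
  }
  ph
}

#' Effective uptake and clearance half-times
#'
#' The physical decay of the radionuclide and the biological transport of the
#' antibody combine harmonically: the effective clearance half-time is
#' `Te = Tp*Tb/(Tp + Tb)` and the effective uptake half-time is
#' `Teu = Tp*Tu/(Tp + Tu)`.  Their difference `tau_e = Te - Teu` is the
#' effective irradiation time that sets the total dose.
#'
#' @param phys a [radionuclide()] object (or a list with positive fields
#'   `Tp`, `Tb`, `Tu` satisfying `Tb > Tu`).
#' @return object of class `effective_times`: list with `Te`, `Teu`,
#'   `tau_e` (days).
#' @examples
#' effective_times(get_radionuclide("225Ac"))   # Te ~ 4.87 d, Teu ~ 2.42 d
#' @export
effective_times <- function(phys) {
  if (!inherits(phys, "radionuclide")) {
    phys <- radionuclide(phys$name %||% "custom", phys$Tp, phys$Tb, phys$Tu)
  }
  Te  <- phys$Tp * phys$Tb / (phys$Tp + phys$Tb)
  Teu <- phys$Tp * phys$Tu / (phys$Tp + phys$Tu)
  structure(list(Te = Te, Teu = Teu, tau_e = Te - Teu, name = phys$name),
            class = "effective_times")
}

#' @export
print.effective_times <- function(x, ...) {
  cat(sprintf("<effective_times %s>  Te = %.4f d,  Teu = %.4f d,  tau_e = %.4f d\n",
              x$name, x$Te, x$Teu, x$tau_e))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
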