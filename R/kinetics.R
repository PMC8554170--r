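#' Avogadro's number (1/mol)
#' @keywords internal
#' @noRd
AVOGADRO <- 6.02214076e23

#' Michaelis-Menten specification
#'
#' Bundles the three macroscopic quantities that define a saturating enzyme:
#' the limiting velocity `Vmax` (uM/s), the half-saturation constant `Km`
#' (uM) and the total enzyme concentration `Et` (uM).
#'
#' @param Vmax Limiting velocity, uM/s. Must be > 0.
#' @param Km Michaelis constant, uM. Must be > 0.
#' @param Et Total enzyme concentration, uM. Must be > 0.
#' @return An object of class `mm_spec`.
#' @examples
#' mm_spec(Vmax = 1, Km = 0.5, Et = 1)
#' @export
mm_spec <- function(Vmax, Km, Et) {
  stopifnot(is.numeric(Vmax), is.numeric(Km), is.numeric(Et))
  if (Vmax <= 0 || Km <= 0 || Et <= 0)
    stop("mm_spec: Vmax, Km and Et must all be positive", call. = FALSE)
  structure(list(Vmax = Vmax, Km = Km, Et = Et), class = "mm_spec")
}

#' @export
print.mm_spec <- function(x, ...) {
  cat(sprintf("Michaelis-Menten spec: Vmax = %g uM/s, Km = %g uM, Et = %g uM\n",
              x$Vmax, x$Km, x$Et))
  invisible(x)
}

#' Elementary mass-action triplet for an enzymatic step
#'
#' The three elementary constants of E + S <-> ES -> E + P:
#' `k1` ((uM s)^-1, binding), `k_minus1` (s^-1, dissociation) and
#' `k2` (s^-1, catalysis).
#'
#' @param k1 Binding constant, (uM s)^-1. Must be > 0.
#' @param k_minus1 Dissociation constant, s^-1. Must be > 0.
#' @param k2 Catalytic constant, s^-1. Must be > 0.
#' @return An object of class `ma_triplet`. The element `equilibrium_ok`
#'   records whether the rapid-equilibrium conversion is self-consistent
#'   (`k2/k_minus1 < 0.1`; see [equilibrium_validity()]).
#' @export
ma_triplet <- function(k1, k_minus1, k2) {
  stopifnot(is.numeric(k1), is.numeric(k_minus1), is.numeric(k2))
  if (k1 <= 0 || k_minus1 <= 0 || k2 <= 0)
    stop("ma_triplet: all three constants must be positive", call. = FALSE)
  structure(list(k1 = k1, k_minus1 = k_minus1, k2 = k2,
                 equilibrium_ok = (k2 / k_minus1) < 0.1),
            class = "ma_triplet")
}

#' @export
print.ma_triplet <- function(x, ...) {
  cat(sprintf("Mass-action triplet: k1 = %g (uM s)^-1, k-1 = %g s^-1, k2 = %g s^-1\n",
              x$k1, x$k_minus1, x$k2))
  v <- equilibrium_validity(x)
  cat(sprintf("  equilibrium approximation: k2/k-1 = %g (%s)\n", v$ratio, v$flag))
  invisible(x)
}

#' Michaelis-Menten closed-form velocity
#'
#' The hyperbolic initial-velocity law d\[P\]/dt = S * Vmax / (S + Km). Used
#' throughout the package only as the analytic oracle against which converted
#' elementary triplets are validated.
#'
#' @param spec An [mm_spec()].
#' @param S Substrate concentration(s), uM; vectorised, each >= 0.
#' @return Product-formation velocity in uM/s, same length as `S`.
#' @examples
#' s <- mm_spec(Vmax = 2, Km = 1, Et = 1)
#' mm_velocity(s, c(0, 1, 100))  # 0, Vmax/2, ~Vmax
#' @export
mm_velocity <- function(spec, S) {
  stopifnot(inherits(spec, "mm_spec"))
  if (any(S < 0)) stop("mm_velocity: substrate concentration must be >= 0", call. = FALSE)
  S * spec$Vmax / (S + spec$Km)
}

#' Convert a Michaelis-Menten spec to an elementary mass-action triplet
#'
#' Rapid-equilibrium decomposition of a saturating enzyme into elementary
#' steps: the catalytic constant is `k2 = Vmax / Et` and, for an arbitrary
#' (user-chosen) binding constant `k1`, the dissociation constant is scaled
#' by the Michaelis constant, `k_minus1 = k1 * Km`. Only the ratio
#' `k_minus1 / k1` affects the quasi-equilibrium kinetics, so `k1` sets a
#' relaxation timescale, not the velocity curve.
#'
#' @param spec An [mm_spec()].
#' @param k1 Chosen binding constant, (uM s)^-1. Must be > 0. The packaged
#'   models use 10 (uM s)^-1 for both Dicer and RISC.
#' @return An [ma_triplet()].
#' @examples
#' mm_to_mass_action(mm_spec(Vmax = 1, Km = 0.5, Et = 1), k1 = 10)
#' @export
mm_to_mass_action <- function(spec, k1) {
  stopifnot(inherits(spec, "mm_spec"))
  if (!is.numeric(k1) || length(k1) != 1L || k1 <= 0)
    stop("mm_to_mass_action: k1 must be a single positive number", call. = FALSE)
  if (spec$Et <= 0) stop("mm_to_mass_action: Et must be positive", call. = FALSE)
  ma_triplet(k1 = k1, k_minus1 = k1 * spec$Km, k2 = spec$Vmax / spec$Et)
}

#' Recover the Michaelis-Menten parameters from an elementary triplet
#'
#' Inverse of [mm_to_mass_action()]: `Vmax = k2 * Et`, `Km = k_minus1 / k1`.
#'
#' @param triplet An [ma_triplet()].
#' @param Et Total enzyme concentration, uM.
#' @return An [mm_spec()].
#' @export
mass_action_to_mm <- function(triplet, Et) {
  stopifnot(inherits(triplet, "ma_triplet"))
  if (!is.numeric(Et) || Et <= 0)
    stop("mass_action_to_mm: Et must be positive", call. = FALSE)
  mm_spec(Vmax = triplet$k2 * Et, Km = triplet$k_minus1 / triplet$k1, Et = Et)
}

#' Check the rapid-equilibrium validity of a triplet
#'
#' The rapid-equilibrium decomposition assumes catalysis is much slower than
#' complex dissociation. The documented package threshold is
#' `k2 / k_minus1 < 0.1` for a "valid" flag; larger ratios get "warn".
#'
#' @param triplet An [ma_triplet()].
#' @return A list with elements `ratio` (k2/k_minus1) and `flag`
#'   ("valid" or "warn").
#' @export
equilibrium_validity <- function(triplet) {
  stopifnot(inherits(triplet, "ma_triplet"))
  if (triplet$k_minus1 == 0)
    stop("equilibrium_validity: k_minus1 is zero, ratio undefined", call. = FALSE)
  ratio <- triplet$k2 / triplet$k_minus1
  list(ratio = ratio, flag = if (ratio < 0.1) "valid" else "warn")
}

#' Convert a macroscopic rate constant to a stochastic propensity constant
#'
#' Stochastic simulation works in molecule counts, while macroscopic
#' constants are expressed in concentration units (uM). For a compartment of
#' volume `volume` (liters):
#' \itemize{
#'   \item order 0 (source, k in uM/s): `c = k * NA * V * 1e-6` molecules/s,
#'   \item order 1 (k in s^-1): `c = k`, volume-independent,
#'   \item order 2 (k in (uM s)^-1): `c = k / (NA * V * 1e-6)` per reactant
#'     pair per second.
#' }
#'
#' @param k Macroscopic rate constant (units set by `order`).
#' @param order Reaction order: 0, 1 or 2.
#' @param volume Compartment volume in liters; must be > 0.
#' @return The propensity constant `c` (a bare number in stochastic units).
#' @examples
#' macroscopic_to_propensity(0.1, order = 1, volume = 2e-12)   # 0.1
#' macroscopic_to_propensity(10, order = 2, volume = 2e-12)
#' @export
macroscopic_to_propensity <- function(k, order, volume) {
  if (!is.numeric(k) || length(k) != 1L || k < 0)
    stop("macroscopic_to_propensity: k must be a single non-negative number", call. = FALSE)
  if (!order %in% c(0, 1, 2))
    stop("macroscopic_to_propensity: order must be 0, 1 or 2", call. = FALSE)
  if (!is.numeric(volume) || volume <= 0)
    stop("macroscopic_to_propensity: volume must be positive", call. = FALSE)
  scale <- AVOGADRO * volume * 1e-6  # molecules per uM
  switch(as.character(order),
         "0" = k * scale,
         "1" = k,
         "2" = k / scale)
}

#' Inverse of [macroscopic_to_propensity()]
#'
#' @param c_prop Stochastic propensity constant.
#' @param order Reaction order: 0, 1 or 2.
#' @param volume Compartment volume in liters.
#' @return The macroscopic constant in uM-based units.
#' @export
propensity_to_macroscopic <- function(c_prop, order, volume) {
  if (!order %in% c(0, 1, 2))
    stop("propensity_to_macroscopic: order must be 0, 1 or 2", call. = FALSE)
  if (!is.numeric(volume) || volume <= 0)
    stop("propensity_to_macroscopic: volume must be positive", call. = FALSE)
  scale <- AVOGADRO * volume * 1e-6
  switch(as.character(order),
         "0" = c_prop / scale,
         "1" = c_prop,
         "2" = c_prop * scale)
}
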