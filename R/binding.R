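#' Free toxin concentration at single-site binding equilibrium
#'
#' For a toxin `S` binding a single site on a binder `A` with equilibrium
#' constant `KB = [AS] / ([S][A])`, mass action plus the two mass balances
#' give a quadratic in the free toxin concentration whose physical root is
#'
#' \deqn{C_s = \frac{-(C_a + 1/K_B - C_t) + \sqrt{(C_a + 1/K_B - C_t)^2 + 4 C_t/K_B}}{2}}
#'
#' where `Ct` is total toxin and `Ca` total binder. The root is evaluated in
#' the numerically stable form (divide-by-conjugate when the linear
#' coefficient is positive) so that trace toxin against excess binder does not
#' lose precision to cancellation.
#'
#' @param c_total Total toxin concentration, mol/L (vectorised).
#' @param c_binder Total binder concentration, mol/L.
#' @param KB Binding constant, 1/M.
#' @return Free toxin concentration, mol/L. Satisfies
#'   `KB = (Ct - Cs) / (Cs * (Ca - Ct + Cs))` to 1e-10 relative and
#'   `0 <= Cs <= Ct`.
#' @examples
#' free_toxin(2.57e-4, 3.01e-4, 5e6)  # mostly bound: small free fraction
#' free_toxin(1e-4, 0, 5e6)           # no binder: all free
#' @export
free_toxin <- function(c_total, c_binder, KB) {
  if (length(KB) != 1 || !is.finite(KB) || KB <= 0) {
    stop("invalid parameter: KB must be a positive scalar", call. = FALSE)
  }
  n <- max(length(c_total), length(c_binder))
  c_total <- rep_len(c_total, n)
  c_binder <- rep_len(c_binder, n)
  if (any(!is.finite(c_total)) || any(!is.finite(c_binder)) ||
      any(c_total < 0) || any(c_binder < 0)) {
    stop("invalid parameter: concentrations must be finite and non-negative",
         call. = FALSE)
  }
  b <- c_binder + 1 / KB - c_total   # linear coefficient of Cs^2 + b*Cs - Ct/KB
  q <- c_total / KB
  disc <- b^2 + 4 * q
  if (any(disc < 0)) {
    stop("numeric misuse: discriminant of the binding quadratic is negative",
         call. = FALSE)
  }
  s <- sqrt(disc)
  # stable root: for b > 0 the subtraction (-b + s) cancels; use 2q/(b + s)
  out <- ifelse(b > 0, 2 * q / (b + s), (s - b) / 2)
  pmin(pmax(out, 0), c_total)
}
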