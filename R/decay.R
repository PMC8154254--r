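# Tunneling decay law: q = A * exp(-B * (r - R)) per edge kind, following
# the empirical pathways model of protein electron transfer in which each
# covalent bond, hydrogen bond or through-space jump multiplies the
# donor-acceptor coupling by a kind-specific decay factor.

#' Decay-law parameters per edge kind
#'
#' Each edge kind (covalent bond, hydrogen bond, through-space jump) carries
#' a triple (A, B, R) of the exponential decay law
#' `q = A * exp(-B * (r - R))`, with `q` clamped at `A` so that no jump ever
#' scores better than the kind's contact value.  Defaults are the classic
#' pathways-model values: a distance-independent 0.6 per covalent bond; the
#' hydrogen-bond term equivalent to two covalent bonds at its reference
#' heavy-atom separation of 2.8 Angstrom (0.6^2 = 0.36); and a space jump
#' decaying from 0.6 at 1.4 Angstrom.
#'
#' @param covalent,hbond,space lists with elements `A` (dimensionless, in
#'   (0, 1]), `B` (per Angstrom, >= 0) and `R` (Angstrom, >= 0)
#' @return object of class `et_decay_params`
#' @export
decay_parameters <- function(covalent = list(A = 0.6, B = 0.0, R = 0.0),
                             hbond = list(A = 0.36, B = 1.7, R = 2.8),
                             space = list(A = 0.6, B = 1.7, R = 1.4)) {
  p <- list(covalent = covalent, hbond = hbond, space = space)
  for (kind in names(p)) {
    k <- p[[kind]]
    if (!all(c("A", "B", "R") %in% names(k)))
      stop(kind, " parameters need A, B and R")
    if (k$A <= 0 || k$A > 1) stop(kind, ": A must be in (0, 1]")
    if (k$B < 0 || k$R < 0) stop(kind, ": B and R must be >= 0")
  }
  structure(p, class = "et_decay_params")
}

#' Per-edge decay factor
#'
#' @param r edge length(s), Angstrom
#' @param kind edge kind(s): "covalent", "hbond" or "space"
#' @param params an [decay_parameters()] object
#' @return decay factor(s) `q` in (0, A]
#' @export
edge_decay <- function(r, kind, params = decay_parameters()) {
  if (any(!is.finite(r))) stop("non-finite edge length")
  A <- vapply(params[kind], `[[`, numeric(1), "A")
  B <- vapply(params[kind], `[[`, numeric(1), "B")
  R <- vapply(params[kind], `[[`, numeric(1), "R")
  unname(pmin(A * exp(-B * (r - R)), A))
}

# Dijkstra edge weight: -ln(q) >= 0 by the clamp above.
edge_weights <- function(edges, params) {
  -log(edge_decay(edges$r, edges$kind, params))
}
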