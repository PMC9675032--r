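#' Elastic element contract
#'
#' Every mechanical element of the Ndc80-microtubule link (the two-bond
#' freely jointed chain of the Ndc80 complex, the worm-like-chain
#' microtubule, the protofilament flare, the PEG tether, or a plain
#' constant-stiffness spring) implements two evaluables: its extension
#' `z(F)` along the pulling axis in nm and its differential stiffness
#' `c(F) = (dz/dF)^-1` in pN/nm.  The two are consistent by construction:
#' for each element the closed-form or semi-analytic stiffness equals the
#' inverse numerical derivative of the extension.
#'
#' @param object an elastic element.
#' @param force tension in pN (vectorised).
#' @param ... passed to methods.
#' @return `extension()`: extension in nm; `stiffness()`: stiffness in
#'   pN/nm.  Both are vectorised over `force`.
#' @seealso [fjc_ndc80()], [mt_wlc()], [pf_flare()], [peg_chain()],
#'   [constant_spring()], [rigid_element()]
#' @export
extension <- function(object, force, ...) UseMethod("extension")

#' @rdname extension
#' @export
stiffness <- function(object, force, ...) UseMethod("stiffness")

#' @export
print.elastic_element <- function(x, ...) {
  cat("<", class(x)[1], "> ", sep = "")
  p <- x[vapply(x, is.numeric, logical(1))]
  cat(paste(names(p), signif(unlist(p), 4), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Constant-stiffness spring
#'
#' A Hookean element with force-independent stiffness, used e.g. to
#' represent a laterally attached (non-stiffening) link or to stand in
#' for elements in composition tests.
#'
#' @param k stiffness in pN/nm (> 0).
#' @export
constant_spring <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k > 0)
  structure(list(k = k), class = c("constant_spring", "elastic_element"))
}

#' @export
stiffness.constant_spring <- function(object, force, ...) {
  rep_len(object$k, length(force))
}

#' @export
extension.constant_spring <- function(object, force, ...) force / object$k

#' Rigid placeholder element
#'
#' Infinitely stiff element with zero extension.  Used as a placeholder
#' for the (unquantified) Ndc80-microtubule bond so that the serial
#' spring architecture can be written down in full; a rigid element drops
#' out of any serial combination.
#'
#' @export
rigid_element <- function() {
  structure(list(), class = c("rigid_element", "elastic_element"))
}

#' @export
stiffness.rigid_element <- function(object, force, ...) {
  rep_len(Inf, length(force))
}

#' @export
extension.rigid_element <- function(object, force, ...) {
  rep_len(0, length(force))
}

#' Power-law spring
#'
#' An element whose stiffness follows `c(F) = a F^m + c0`, the empirical
#' law fitted to measured stiffness-force relations.  Its extension is
#' the integrated compliance from a small reference force, so the element
#' can drive the trap simulator with a known ground-truth law.
#'
#' @param amplitude `a` in pN^(1-m) nm^-1 (> 0).
#' @param exponent `m`, dimensionless (> 0).
#' @param offset `c0` in pN/nm (>= 0).
#' @param f_ref reference force (pN) at which the extension is zero.
#' @export
powerlaw_spring <- function(amplitude, exponent, offset = 0, f_ref = 0.01) {
  stopifnot(amplitude > 0, exponent > 0, offset >= 0, f_ref > 0)
  structure(list(amplitude = amplitude, exponent = exponent, offset = offset,
                 f_ref = f_ref),
            class = c("powerlaw_spring", "elastic_element"))
}

#' @export
stiffness.powerlaw_spring <- function(object, force, ...) {
  object$amplitude * force^object$exponent + object$offset
}

#' @export
extension.powerlaw_spring <- function(object, force, ...) {
  vapply(force, function(f) {
    s <- if (f >= object$f_ref) 1 else -1
    s * integrate(function(u) 1 / stiffness(object, u),
                  min(object$f_ref, f), max(object$f_ref, f),
                  rel.tol = 1e-10)$value
  }, numeric(1))
}
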