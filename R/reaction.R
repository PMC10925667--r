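#' Reaction specification
#'
#' Bundles the local reaction kind, the reaction rate `r` and the Allee
#' threshold concentration `theta_c` into one object. The reaction acts
#' identically and independently at every node (homogeneity assumption): the
#' reaction contribution to node `i` is `r * g(theta_i)`.
#'
#' Kinds:
#' \describe{
#'   \item{`logistic`}{`g(theta) = theta (1 - theta)`; exponential growth at
#'     small concentration saturating at carrying capacity 1 (the FKPP
#'     nonlinearity).}
#'   \item{`strong_allee`}{`g(theta) = theta (theta - theta_c)(1 - theta)`;
#'     per-capita growth is negative below `theta_c`, so small concentrations
#'     die out.}
#'   \item{`neutral_allee`}{`g(theta) = max((theta - theta_c)(1 - theta), 0)`;
#'     growth is switched off (exactly zero) below `theta_c`, so
#'     sub-threshold concentrations are frozen in place apart from diffusion.}
#'   \item{`none`}{`g = 0`; recovers pure network diffusion.}
#' }
#'
#' @param kind one of `"logistic"`, `"strong_allee"`, `"neutral_allee"`,
#'   `"none"`.
#' @param r reaction rate, `> 0` (per unit time; time units are arbitrary).
#' @param theta_c Allee threshold concentration in `[0, 1)`; ignored for
#'   `logistic` and `none`.
#' @return object of class `reaction_spec`.
#' @examples
#' reaction_spec("neutral_allee", r = 1, theta_c = 0.001)
#' @export
reaction_spec <- function(kind = c("logistic", "strong_allee", "neutral_allee",
                                   "none"),
                          r = 1, theta_c = 0.001) {
  kind <- match.arg(kind)
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r <= 0)
    stop("r must be a single positive number", call. = FALSE)
  if (!is.numeric(theta_c) || length(theta_c) != 1 ||
      !is.finite(theta_c) || theta_c < 0 || theta_c >= 1)
    stop("theta_c must lie in [0, 1)", call. = FALSE)
  structure(list(kind = kind, r = r, theta_c = theta_c),
            class = "reaction_spec")
}

#' @exportS3Method base::print
print.reaction_spec <- function(x, ...) {
  cat(sprintf("<reaction_spec> kind = %s, r = %g%s\n", x$kind, x$r,
              if (x$kind %in% c("strong_allee", "neutral_allee"))
                sprintf(", theta_c = %g", x$theta_c) else ""))
  invisible(x)
}

#' Logistic growth term g(theta) = theta (1 - theta)
#'
#' @param theta concentration (vectorised).
#' @return growth-rate contribution, same shape as `theta`.
#' @export
g_logistic <- function(theta) theta * (1 - theta)

#' Strong Allee term g(theta) = theta (theta - theta_c) (1 - theta)
#'
#' Negative for `0 < theta < theta_c` (sub-threshold concentrations decay),
#' positive for `theta_c < theta < 1`.
#'
#' @param theta concentration (vectorised).
#' @param theta_c Allee threshold in `[0, 1)`.
#' @return growth-rate contribution, same shape as `theta`.
#' @export
g_strong_allee <- function(theta, theta_c) {
  theta * (theta - theta_c) * (1 - theta)
}

#' Neutral Allee term g(theta) = max((theta - theta_c)(1 - theta), 0)
#'
#' Exactly zero for `theta <= theta_c`: below the threshold the concentration
#' neither grows nor decays (diffusion aside). Intermediate between the weak
#' and strong Allee effects.
#'
#' @param theta concentration (vectorised).
#' @param theta_c Allee threshold in `[0, 1)`.
#' @return growth-rate contribution, same shape as `theta`.
#' @export
g_neutral_allee <- function(theta, theta_c) {
  pmax((theta - theta_c) * (1 - theta), 0)
}

#' Evaluate the reaction contribution r * g(theta) elementwise
#'
#' @param spec a [reaction_spec()].
#' @param theta numeric concentration vector.
#' @return numeric vector of the same length: `r * g(theta_i)` per node
#'   (the zero vector for kind `"none"`).
#' @export
reaction_rate <- function(spec, theta) {
  stopifnot(inherits(spec, "reaction_spec"))
  switch(spec$kind,
    logistic      = spec$r * g_logistic(theta),
    strong_allee  = spec$r * g_strong_allee(theta, spec$theta_c),
    neutral_allee = spec$r * g_neutral_allee(theta, spec$theta_c),
    none          = numeric(length(theta)),
    stop("unknown reaction kind: ", spec$kind, call. = FALSE)
  )
}
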