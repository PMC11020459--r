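#' Linking-model specification
#'
#' The three area-level Fay-Herriot variants share a Normal sampling model
#' for the direct proportion and differ only in the linking model, which
#' regresses a transform of the true proportion on auxiliary covariates:
#' identity (the classical matched model), log, or logit.  A `link_spec`
#' bundles the transform, its inverse, and the domain of valid proportions.
#'
#' @param link One of `"identity"`, `"log"`, `"logit"`.
#'
#' @return An object of class `link_spec` with elements `link` (name),
#'   `transform` (proportion scale to link scale), `inverse` (back), and
#'   `domain_ok` (predicate: is a proportion in the link's domain).
#' @examples
#' ls <- link_spec("logit")
#' ls$inverse(ls$transform(0.28))
#' @export
link_spec <- function(link = c("logit", "log", "identity")) {
  link <- match.arg(link)
  spec <- switch(link,
    identity = list(
      transform = function(theta) theta,
      inverse   = function(mu) mu,
      domain_ok = function(theta) is.finite(theta)
    ),
    log = list(
      transform = function(theta) log(theta),
      inverse   = function(mu) exp(mu),
      domain_ok = function(theta) is.finite(theta) & theta > 0
    ),
    logit = list(
      transform = function(theta) stats::qlogis(theta),
      inverse   = function(mu) stats::plogis(mu),
      domain_ok = function(theta) is.finite(theta) & theta > 0 & theta < 1
    )
  )
  structure(c(list(link = link), spec), class = "link_spec")
}

as_link_spec <- function(link) {
  if (inherits(link, "link_spec")) link else link_spec(link)
}

#' @export
print.link_spec <- function(x, ...) {
  cat("<link_spec>", x$link, "\n")
  invisible(x)
}
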